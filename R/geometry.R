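#' Contour-length geometry model
#'
#' Converts sequence separation on an annotated protein into physical
#' length. A folded immunoglobulin-like domain contributes a fixed ~40 Å
#' regardless of its residue count; unstructured regions contribute 4 Å per
#' amino acid. Distances are contour lengths (maximal reach along the
#' chain), an upper-bound interpretation suited to estimating a biotin
#' ligase's range of activity.
#'
#' @param folded_domain_length_nm physical length of one folded domain (nm).
#' @param unstructured_nm_per_residue length per unstructured residue (nm).
#' @return a `geometry_model` list.
#' @export
geometry_model <- function(folded_domain_length_nm = 4.0,
                           unstructured_nm_per_residue = 0.4) {
  if (folded_domain_length_nm <= 0 || unstructured_nm_per_residue <= 0) {
    stop_input("geometry constants must be strictly positive")
  }
  structure(list(folded_domain_length_nm = folded_domain_length_nm,
                 unstructured_nm_per_residue = unstructured_nm_per_residue),
            class = "geometry_model")
}

#' Physical length of one annotated segment
#'
#' @param kind `"folded_domain"` or `"unstructured"`.
#' @param n_residues number of residues in the segment (ignored for folded
#'   domains, whose length is fixed).
#' @param model a [geometry_model()].
#' @return length in nm.
#' @examples
#' segment_length("folded_domain", 89)  # 4 nm regardless of residue count
#' segment_length("unstructured", 10)   # 4 nm at 0.4 nm per residue
#' @export
segment_length <- function(kind, n_residues, model = geometry_model()) {
  if (n_residues < 0) stop_input("n_residues must be >= 0")
  switch(kind,
         folded_domain = model$folded_domain_length_nm,
         unstructured = n_residues * model$unstructured_nm_per_residue,
         stop_input("unknown segment kind '%s'", kind))
}

#' Physical distance between two residues along the chain
#'
#' Sums contour-length contributions along the chain between two residue
#' positions. Each unit step between consecutive residues contributes the
#' unstructured per-residue length when either endpoint lies in an
#' unstructured segment; every folded domain traversed (at least one step
#' fully inside it) contributes its full fixed length, however partially it
#' is spanned — intra-domain geometry is not resolvable from sequence, so
#' the rigid domain counts as a whole. The result is symmetric and zero
#' only for identical positions.
#'
#' @param annotation a [domain_annotation()].
#' @param pos_a,pos_b 1-based residue positions (vectorized, recycled).
#' @param model a [geometry_model()].
#' @return distance(s) in nm.
#' @export
residue_distance <- function(annotation, pos_a, pos_b, model = geometry_model()) {
  n <- max(length(pos_a), length(pos_b))
  pos_a <- rep_len(as.integer(pos_a), n)
  pos_b <- rep_len(as.integer(pos_b), n)
  len <- annotation_length(annotation)
  if (any(pos_a < 1L | pos_a > len | pos_b < 1L | pos_b > len)) {
    stop_input("positions must lie in 1..%d", len)
  }
  vapply(seq_len(n), function(i) {
    residue_distance_one(annotation, pos_a[i], pos_b[i], model)
  }, numeric(1))
}

residue_distance_one <- function(annotation, a, b, model) {
  if (a == b) return(0)
  lo <- min(a, b)
  hi <- max(a, b)
  res <- lo:hi
  seg <- findInterval(res, annotation$start)
  kind <- annotation$kind[seg]
  u <- kind == "unstructured"
  m <- length(res)
  # unit steps with an unstructured endpoint
  step_u <- u[-m] | u[-1L]
  dist <- sum(step_u) * model$unstructured_nm_per_residue
  # folded domains traversed by at least one fully interior step
  inside <- seg[-m] == seg[-1L] & !u[-m]
  dist + length(unique(seg[-m][inside])) * model$folded_domain_length_nm
}

#' Estimate the ligase's radius of action from a hotspot
#'
#' Computes the minimum and maximum contour distance from the ligase
#' insertion residue to the member sites of a hotspot (sites at the
#' insertion residue itself are excluded), reported as a closed interval.
#'
#' @param annotation a [domain_annotation()].
#' @param insertion_residue 1-based residue index of the ligase insertion.
#' @param primary_hotspot a one-row hotspot (from [detect_hotspots()]) or a
#'   list/data.frame with a `members` field of residue positions.
#' @param model a [geometry_model()].
#' @return named numeric vector `c(min_nm, max_nm)`.
#' @export
estimate_radius <- function(annotation, insertion_residue, primary_hotspot,
                            model = geometry_model()) {
  members <- hotspot_members(primary_hotspot)
  members <- members[members != insertion_residue]
  if (length(members) == 0L) {
    stop_input("hotspot has no member sites away from the insertion residue")
  }
  d <- residue_distance(annotation, insertion_residue, members, model)
  c(min_nm = min(d), max_nm = max(d))
}

hotspot_members <- function(hotspot) {
  if (is.data.frame(hotspot)) {
    if (nrow(hotspot) != 1L) stop_input("expected a single hotspot row")
    members <- hotspot$members[[1L]]
  } else {
    members <- hotspot$members
  }
  if (is.null(members) || length(members) == 0L) stop_input("empty hotspot")
  as.integer(members)
}
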