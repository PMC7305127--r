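#' Cluster biotinylation sites into hotspots along the residue axis
#'
#' Single-linkage clustering in physical (contour-length) space: sites are
#' sorted by position and consecutive sites are merged into one hotspot
#' whenever their contour distance is at most `merge_gap_nm`. Each hotspot's
#' aggregate intensity is the sum over member sites of the median intensity
#' across knock-in samples (missing values excluded); hotspots are ranked by
#' aggregate intensity, the largest being `"primary"`, the second
#' `"secondary"`, the rest `"other"`. Rank ties are broken by smaller span,
#' then lower start residue.
#'
#' @param table a filtered [site_table()] for one protein.
#' @param annotation a [domain_annotation()] for that protein.
#' @param model a [geometry_model()].
#' @param merge_gap_nm positive merge distance in nm. The default, twice the
#'   ~15 nm outer labeling radius, merges sites reachable from one tether
#'   position.
#' @param aggregate `"median"` (default, robust to intensity-dependent
#'   dropout) or `"mean"`.
#' @return a `hotspot_set` data.frame with columns `rank_label`, `center`
#'   (intensity-weighted mean residue), `span_min`, `span_max`, `n_sites`,
#'   `aggregate_intensity` and a list-column `members`.
#' @export
detect_hotspots <- function(table, annotation, model = geometry_model(),
                            merge_gap_nm = 30, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (merge_gap_nm <= 0) stop_input("merge_gap_nm must be > 0")
  design <- site_design(table)
  df <- as.data.frame(table)
  empty <- data.frame(rank_label = character(0), center = numeric(0),
                      span_min = integer(0), span_max = integer(0),
                      n_sites = integer(0), aggregate_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(df) == 0L) return(structure(empty, class = c("hotspot_set", "data.frame")))

  ord <- order(df$position)
  pos <- df$position[ord]
  ki <- intensity_matrix(table, design_samples(design, "knockin"))[ord, , drop = FALSE]
  site_value <- apply(ki, 1L, function(v) {
    v <- v[v > 0]
    if (length(v) == 0L) 0 else if (aggregate == "median") stats::median(v) else mean(v)
  })

  n <- length(pos)
  cluster <- integer(n)
  cluster[1L] <- 1L
  if (n > 1L) {
    gaps <- residue_distance(annotation, pos[-n], pos[-1L], model)
    cluster <- cumsum(c(1L, as.integer(gaps > merge_gap_nm)))
  }

  rows <- lapply(split(seq_len(n), cluster), function(i) {
    w <- site_value[i]
    center <- if (sum(w) > 0) sum(pos[i] * w) / sum(w) else mean(pos[i])
    out <- data.frame(center = center,
                      span_min = min(pos[i]), span_max = max(pos[i]),
                      n_sites = length(i), aggregate_intensity = sum(w),
                      stringsAsFactors = FALSE)
    out$members <- list(pos[i])
    out
  })
  hs <- do.call(rbind, rows)
  ord2 <- order(-hs$aggregate_intensity, hs$span_max - hs$span_min, hs$span_min)
  hs <- hs[ord2, , drop = FALSE]
  hs$rank_label <- c("primary", "secondary", rep("other", max(0L, nrow(hs) - 2L)))[seq_len(nrow(hs))]
  hs <- hs[c("rank_label", "center", "span_min", "span_max", "n_sites",
             "aggregate_intensity", "members")]
  rownames(hs) <- NULL
  structure(hs, class = c("hotspot_set", "data.frame"))
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("Hotspot set: %d hotspot(s)\n", nrow(x)))
  show <- as.data.frame(x)[setdiff(names(x), "members")]
  print.data.frame(show, ...)
  invisible(x)
}

hotspot_aggregate <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_input("expected a single hotspot row")
    return(x$aggregate_intensity)
  }
  x$aggregate_intensity
}

#' Select one hotspot from a hotspot set by rank label
#'
#' @param hotspots a `hotspot_set` from [detect_hotspots()].
#' @param rank_label `"primary"`, `"secondary"` or `"other"`.
#' @return the matching one-row hotspot, or `NULL` if absent.
#' @export
hotspot_by_rank <- function(hotspots, rank_label) {
  i <- which(hotspots$rank_label == rank_label)
  if (length(i) == 0L) return(NULL)
  hotspots[i[1L], , drop = FALSE]
}

#' Relative intensity of a secondary vs. the primary hotspot
#'
#' @param secondary,primary one-row hotspots (or bare aggregate
#'   intensities). The primary aggregate must be positive.
#' @return the ratio `secondary / primary`, in `[0, Inf)`.
#' @examples
#' hotspot_ratio(7.5, 100)  # 0.075
#' @export
hotspot_ratio <- function(secondary, primary) {
  s <- hotspot_aggregate(secondary)
  p <- hotspot_aggregate(primary)
  if (p <= 0) stop_input("primary aggregate intensity must be > 0")
  s / p
}

#' Parameters of the dwell-time model
#'
#' @param cycle_duration_s duration of one contraction cycle in seconds
#'   (default: the ~0.15 s murine cardiac cycle).
#' @param proportional flag asserting that the amount of biotinylation is
#'   proportional to the duration of colocalization; no alternative model is
#'   implemented.
#' @return a `dwell_params` list.
#' @export
dwell_params <- function(cycle_duration_s = 0.15, proportional = TRUE) {
  if (cycle_duration_s <= 0) stop_input("cycle_duration_s must be > 0")
  structure(list(cycle_duration_s = cycle_duration_s,
                 proportional = isTRUE(proportional)),
            class = "dwell_params")
}

#' Convert a hotspot intensity ratio into a colocalization dwell fraction
#'
#' Under the proportionality assumption the intensity ratio is itself the
#' fraction of the cycle the two regions spend within labeling range;
#' ratios above 1 are clipped to 1 with a warning.
#'
#' @param ratio non-negative hotspot intensity ratio.
#' @param params a [dwell_params()] with `proportional = TRUE`.
#' @return dwell fraction in `[0, 1]`.
#' @export
dwell_fraction <- function(ratio, params = dwell_params()) {
  if (!params$proportional) {
    stop_input("only the proportional biotinylation model is supported")
  }
  if (any(ratio < 0)) stop_input("ratio must be >= 0")
  if (any(ratio > 1)) {
    warning("hotspot ratio > 1 clipped to dwell fraction 1", call. = FALSE)
  }
  pmin(ratio, 1)
}

#' Absolute colocalization dwell time per contraction cycle
#'
#' @param fraction dwell fraction in `[0, 1]`.
#' @param params a [dwell_params()].
#' @return dwell time in seconds (`fraction * cycle_duration_s`).
#' @examples
#' dwell_time(0.075)  # 0.01125 s of the 0.15 s cycle, ~0.01 s
#' @export
dwell_time <- function(fraction, params = dwell_params()) {
  if (any(fraction < 0 | fraction > 1)) {
    stop_input("fraction must lie in [0, 1]")
  }
  fraction * params$cycle_duration_s
}
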