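# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles are deliberately written as literal loops so they stay
# independent of the vectorized implementations they check.

two_group_design <- function(n_ki = 4L, n_wt = 4L) {
  sample_design(c(paste0("ki", seq_len(n_ki)), paste0("wt", seq_len(n_wt))),
                c(rep("knockin", n_ki), rep("wildtype", n_wt)))
}

make_site_table <- function(positions, ki, wt, protein_id = "P1") {
  # ki, wt: matrices with one row per position
  ki <- rbind(ki); wt <- rbind(wt)
  d <- two_group_design(ncol(ki), ncol(wt))
  rec <- data.frame(protein_id = rep_len(protein_id, length(positions)),
                    position = positions, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ki))) rec[[paste0("ki", j)]] <- ki[, j]
  for (j in seq_len(ncol(wt))) rec[[paste0("wt", j)]] <- wt[, j]
  site_table(rec, d)
}

make_pg_table <- function(ki, wt, peptides = NULL, ids = NULL) {
  ki <- rbind(ki); wt <- rbind(wt)
  n <- nrow(ki)
  d <- two_group_design(ncol(ki), ncol(wt))
  rows <- data.frame(protein_id = if (is.null(ids)) sprintf("P%03d", seq_len(n)) else ids,
                     peptide_count = if (is.null(peptides)) rep(5L, n) else peptides,
                     stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ki))) rows[[paste0("ki", j)]] <- ki[, j]
  for (j in seq_len(ncol(wt))) rows[[paste0("wt", j)]] <- wt[, j]
  proteingroup_table(rows, d)
}

unstructured_annotation <- function(len = 1000L, protein_id = "P1") {
  domain_annotation(protein_id, data.frame(
    start = 1L, end = len, kind = "unstructured", label = "chain"))
}

# per-bond accumulation oracle for the contour-length distance
oracle_residue_distance <- function(annotation, a, b, model = geometry_model()) {
  if (a == b) return(0)
  lo <- min(a, b); hi <- max(a, b)
  seg_of <- function(p) {
    for (i in seq_len(nrow(annotation))) {
      if (p >= annotation$start[i] && p <= annotation$end[i]) return(i)
    }
    stop("position out of range")
  }
  total <- 0
  counted_domains <- integer(0)
  for (j in lo:(hi - 1L)) {
    s1 <- seg_of(j); s2 <- seg_of(j + 1L)
    k1 <- annotation$kind[s1]; k2 <- annotation$kind[s2]
    if (k1 == "unstructured" || k2 == "unstructured") {
      total <- total + model$unstructured_nm_per_residue
    }
    if (s1 == s2 && k1 == "folded_domain" && !(s1 %in% counted_domains)) {
      total <- total + model$folded_domain_length_nm
      counted_domains <- c(counted_domains, s1)
    }
  }
  total
}

# row-by-row oracle for the knock-in-specificity site filter
oracle_filter_keep <- function(ki_row, wt_row, min_valid = 3L, min_excess = 2L) {
  n_ki <- sum(ki_row > 0)
  n_wt <- sum(wt_row > 0)
  n_ki >= min_valid && n_ki >= n_wt + min_excess
}

# row-by-row oracle for the protein-group min-valid filter
oracle_min_valid_keep <- function(ki_row, wt_row, min_valid = 3L) {
  sum(ki_row > 0) >= min_valid || sum(wt_row > 0) >= min_valid
}

# union-find single-linkage clustering oracle over pairwise distances
oracle_single_linkage <- function(positions, annotation, gap_nm,
                                  model = geometry_model()) {
  n <- length(positions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          oracle_residue_distance(annotation, positions[i], positions[j],
                                  model) <= gap_nm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(positions, roots), sort))
}

# per-pixel AND-mask oracle for overlap intervals
oracle_overlap_mask <- function(x, a, b, presence = 0.25) {
  norm <- function(v) (v - min(v)) / (max(v) - min(v))
  mask <- norm(a) > presence & norm(b) > presence
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(start = x[starts[keep]], end = x[ends[keep]])
}

# random annotation with alternating random segments
random_annotation <- function(protein_id = "R1", n_segments = 6L, seed_kinds) {
  lens <- sample(5:60, n_segments, replace = TRUE)
  kinds <- sample(c("folded_domain", "unstructured"), n_segments, replace = TRUE)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  domain_annotation(protein_id, data.frame(
    start = starts, end = ends, kind = kinds,
    label = paste0("seg", seq_len(n_segments))))
}
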