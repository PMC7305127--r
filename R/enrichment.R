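#' Protein-group quantification table
#'
#' One row per protein group with per-sample label-free intensities
#' (0 = missing) and a peptide count.
#'
#' @param rows data.frame with columns `protein_id`, `peptide_count`, and
#'   one numeric intensity column per design sample.
#' @param design a [sample_design()].
#' @return a `proteingroup_table` data.frame.
#' @export
proteingroup_table <- function(rows, design) {
  stopifnot(inherits(design, "sample_design"))
  missing_cols <- setdiff(c("protein_id", "peptide_count", design$sample), names(rows))
  if (length(missing_cols)) {
    stop_input("rows lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  rows$protein_id <- as.character(rows$protein_id)
  if (anyDuplicated(rows$protein_id)) stop_input("protein ids must be unique")
  if (nrow(rows) && any(rows$peptide_count < 0)) stop_input("peptide_count must be >= 0")
  for (s in design$sample) {
    v <- rows[[s]]
    if (!is.numeric(v)) stop_input("intensity column '%s' is not numeric", s)
    v[is.na(v)] <- 0
    if (length(v) && any(v < 0)) stop_input("negative intensity in column '%s'", s)
    rows[[s]] <- as.numeric(v)
  }
  structure(rows, design = design,
            class = c("proteingroup_table", "data.frame"))
}

restore_pg_table <- function(rows, design) {
  structure(rows, design = design, class = c("proteingroup_table", "data.frame"))
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Accepts id columns `protein_id`, `Protein IDs` or `Majority protein IDs`,
#' peptide counts from `peptide_count` or `Peptides`, and intensities from
#' `"Intensity <sample>"` or bare sample-name columns. Reverse hits and
#' contaminants are dropped as in [read_site_table()].
#'
#' @param path path to the tab-separated file.
#' @param design a [sample_design()].
#' @return a [proteingroup_table()].
#' @export
read_proteingroups <- function(path, design) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- intersect(c("protein_id", "Protein IDs", "Majority protein IDs"),
                      names(df))[1L]
  if (is.na(id_col)) stop_input("%s: no protein id column found", path)
  pep_col <- intersect(c("peptide_count", "Peptides"), names(df))[1L]
  df <- df[!maxquant_dropped_rows(df, id_col), , drop = FALSE]
  rows <- data.frame(protein_id = as.character(df[[id_col]]),
                     peptide_count = if (is.na(pep_col)) 1L else df[[pep_col]],
                     stringsAsFactors = FALSE)
  for (s in design$sample) {
    cand <- intersect(c(paste("Intensity", s), s), names(df))
    if (length(cand) == 0L) {
      stop_input("%s: missing intensity column for sample '%s'", path, s)
    }
    v <- df[[cand[1L]]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop_input("%s: non-numeric intensity in column '%s', data row %d",
                   path, cand[1L], bad[1L])
      }
      v <- num
    }
    v[is.na(v)] <- 0
    rows[[s]] <- v
  }
  rownames(rows) <- NULL
  proteingroup_table(rows, design)
}

#' Write a protein-group table as tab-separated text
#' @param table a [proteingroup_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteingroups <- function(table, path) {
  design <- site_design(table)
  df <- as.data.frame(table)
  out <- data.frame(`Protein IDs` = df$protein_id, Peptides = df$peptide_count,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in design$sample) out[[paste("Intensity", s)]] <- df[[s]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter protein groups on valid values per genotype group
#'
#' Keeps rows with at least `min_valid` values > 0 in at least one genotype
#' group (the usual Perseus "min valid in at least one group" reading);
#' `scope = "each"` instead requires the minimum in every group.
#'
#' @param table a [proteingroup_table()].
#' @param min_valid minimum number of valid values.
#' @param scope `"any"` (default) or `"each"` genotype group.
#' @return the filtered [proteingroup_table()].
#' @export
filter_min_valid <- function(table, min_valid = 3L, scope = c("any", "each")) {
  scope <- match.arg(scope)
  design <- check_two_genotypes(site_design(table))
  ki <- valid_counts(table, "knockin")
  wt <- valid_counts(table, "wildtype")
  keep <- if (scope == "any") ki >= min_valid | wt >= min_valid
          else ki >= min_valid & wt >= min_valid
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  restore_pg_table(out, design)
}

#' Log2-transform a protein-group table into a matrix
#'
#' @param table a [proteingroup_table()].
#' @return numeric matrix (proteins x samples) of log2 intensities with
#'   `NA` for missing (zero-intensity) cells; rownames are protein ids.
#' @export
log2_transform <- function(table) {
  m <- intensity_matrix(table)
  m[m == 0] <- NA_real_
  m <- log2(m)
  rownames(m) <- as.data.frame(table)$protein_id
  m
}

#' Parameters of down-shifted normal imputation
#'
#' Missing values are drawn from a normal distribution whose standard
#' deviation is `width` times the SD of the measured log2 values and whose
#' mean is down-shifted from the measured mean by `downshift` SDs — the
#' Perseus convention for left-censored label-free data.
#'
#' @param width SD shrinkage factor (> 0), default 0.3.
#' @param downshift down-shift in observed SDs, default 1.8.
#' @param per_column compute observed mean/SD per sample column (default)
#'   or from the whole matrix.
#' @param seed optional integer seed for reproducible draws.
#' @return an `imputation_params` list.
#' @export
imputation_params <- function(width = 0.3, downshift = 1.8, per_column = TRUE,
                              seed = NULL) {
  if (width <= 0) stop_input("width must be > 0")
  structure(list(width = width, downshift = downshift,
                 per_column = isTRUE(per_column), seed = seed),
            class = "imputation_params")
}

#' Impute missing values in a log2 intensity matrix
#'
#' Replaces each `NA` cell by a draw from
#' `Normal(mean_obs - downshift * sd_obs, (width * sd_obs)^2)` with the
#' observed statistics taken per sample column (or from the whole matrix
#' when `per_column = FALSE`). Observed cells are returned untouched.
#'
#' @param log2_table numeric matrix of log2 intensities with `NA` missing.
#' @param params an [imputation_params()].
#' @return the matrix with no missing values.
#' @export
impute_missing <- function(log2_table, params = imputation_params()) {
  if (!is.matrix(log2_table)) log2_table <- as.matrix(log2_table)
  if (!anyNA(log2_table)) return(log2_table)
  with_seed_or_not(params$seed, {
    if (params$per_column) {
      for (j in seq_len(ncol(log2_table))) {
        col <- log2_table[, j]
        miss <- is.na(col)
        if (!any(miss)) next
        obs <- col[!miss]
        if (length(obs) < 2L) {
          stop_input("column %d has fewer than 2 observed values; its SD is undefined", j)
        }
        log2_table[miss, j] <- stats::rnorm(sum(miss),
                                            mean = mean(obs) - params$downshift * stats::sd(obs),
                                            sd = params$width * stats::sd(obs))
      }
    } else {
      miss <- is.na(log2_table)
      obs <- log2_table[!miss]
      if (length(obs) < 2L) stop_input("fewer than 2 observed values in the matrix")
      log2_table[miss] <- stats::rnorm(sum(miss),
                                       mean = mean(obs) - params$downshift * stats::sd(obs),
                                       sd = params$width * stats::sd(obs))
    }
    log2_table
  })
}

#' Row-wise two-sample Student's t-test (knock-in vs. wild-type)
#'
#' Classical equal-variance two-sample t statistic with two-sided p value,
#' computed for every row of a complete (imputed) log2 matrix. The log2
#' fold change is `mean(knockin) - mean(wildtype)`. Rows with zero pooled
#' variance and equal means yield `t = 0, p = 1`. Welch's unequal-variance
#' test is available via `var_equal = FALSE`.
#'
#' @param log2_table complete numeric matrix, columns named as in `design`.
#' @param design a [sample_design()] with >= 2 samples per genotype.
#' @param var_equal pool the variances (default, Student) or not (Welch).
#' @return data.frame with columns `protein_id`, `log2fc`, `t`, `p`.
#' @export
two_sample_ttest <- function(log2_table, design, var_equal = TRUE) {
  check_two_genotypes(design)
  ki_cols <- design_samples(design, "knockin")
  wt_cols <- design_samples(design, "wildtype")
  if (length(ki_cols) < 2L || length(wt_cols) < 2L) {
    stop_input("need >= 2 samples per genotype")
  }
  x <- log2_table[, ki_cols, drop = FALSE]
  y <- log2_table[, wt_cols, drop = FALSE]
  res <- ttest_rows(x, y, var_equal = var_equal)
  data.frame(protein_id = rownames(log2_table) %||% as.character(seq_len(nrow(log2_table))),
             log2fc = res$log2fc, t = res$t, p = res$p,
             stringsAsFactors = FALSE)
}

ttest_rows <- function(x, y, var_equal = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t <- diff / se
  degenerate <- se == 0
  t[degenerate & diff == 0] <- 0
  t[degenerate & diff != 0] <- sign(diff[degenerate & diff != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate & diff == 0] <- 1
  p[degenerate & diff != 0] <- 0
  list(log2fc = diff, t = t, p = p)
}

#' Parameters of the permutation false-discovery-rate estimate
#'
#' @param n_permutations number of genotype-label reassignments (default
#'   250; all distinct reassignments are enumerated when fewer exist).
#' @param fdr significance cut-off on the q value, default 0.05.
#' @param s0 SAM-style fold-change moderation constant added to the
#'   per-protein standard error; 0 (default) gives the plain t statistic.
#' @return a `permutation_fdr_params` list.
#' @export
permutation_fdr_params <- function(n_permutations = 250L, fdr = 0.05, s0 = 0) {
  if (n_permutations < 1L) stop_input("n_permutations must be >= 1")
  if (fdr <= 0 || fdr >= 1) stop_input("fdr must lie in (0, 1)")
  if (s0 < 0) stop_input("s0 must be >= 0")
  structure(list(n_permutations = as.integer(n_permutations), fdr = fdr, s0 = s0),
            class = "permutation_fdr_params")
}

#' Permutation-based q values for protein enrichment results
#'
#' Recomputes the row t statistics under random reassignments of the
#' genotype labels and estimates, for each protein, the q value as the mean
#' number of permuted `|t'|` at or above its observed `|t|` divided by the
#' number of observed `|t|` at or above it, clipped to `[0, 1]` and made
#' monotone non-increasing in `|t|` (step-up enforcement). When fewer
#' distinct reassignments exist than requested, all distinct ones are used
#' and the count is recorded in the `n_permutations_used` attribute.
#'
#' @param results data.frame from [two_sample_ttest()].
#' @param log2_table the complete (imputed) log2 matrix the results came
#'   from.
#' @param design the [sample_design()].
#' @param params a [permutation_fdr_params()].
#' @param seed optional integer seed for the permutation draw.
#' @return `results` with a `q` column appended.
#' @export
permutation_fdr <- function(results, log2_table, design,
                            params = permutation_fdr_params(), seed = NULL) {
  check_two_genotypes(design)
  samples <- design$sample
  is_ki <- design$genotype[match(colnames(log2_table), samples)] == "knockin"
  n <- length(samples)
  n1 <- sum(is_ki)
  perms <- make_permutations(n, n1, which(is_ki), params$n_permutations, seed)
  B <- ncol(perms)

  obs_abs <- compute_abs_stat(log2_table, is_ki, params$s0, results)
  perm_abs <- numeric(0)
  for (b in seq_len(B)) {
    ki_b <- logical(n)
    ki_b[perms[, b]] <- TRUE
    x <- log2_table[, ki_b, drop = FALSE]
    y <- log2_table[, !ki_b, drop = FALSE]
    r <- ttest_rows(x, y)
    tb <- if (params$s0 > 0) {
      se <- r$log2fc / r$t
      se[!is.finite(se)] <- 0
      r$log2fc / (se + params$s0)
    } else r$t
    perm_abs <- c(perm_abs, abs(tb))
  }
  perm_sorted <- sort(perm_abs[is.finite(perm_abs)])
  obs_sorted <- sort(obs_abs)
  n_obs <- length(obs_abs)

  # counts at or above each observed |t|
  V <- (length(perm_sorted) -
          findInterval(obs_abs, perm_sorted, left.open = TRUE)) / B
  R <- n_obs - findInterval(obs_abs, obs_sorted, left.open = TRUE)
  q <- pmin(pmax(V / pmax(R, 1L), 0), 1)

  # step-up: q may not exceed the q of any less significant protein
  ord <- order(-obs_abs)
  q[ord] <- rev(cummin(rev(q[ord])))

  results$q <- q
  attr(results, "n_permutations_used") <- B
  results
}

compute_abs_stat <- function(log2_table, is_ki, s0, results) {
  if (s0 > 0) {
    x <- log2_table[, is_ki, drop = FALSE]
    y <- log2_table[, !is_ki, drop = FALSE]
    r <- ttest_rows(x, y)
    se <- r$log2fc / r$t
    se[!is.finite(se)] <- 0
    abs(r$log2fc / (se + s0))
  } else {
    abs(results$t)
  }
}

make_permutations <- function(n, n1, observed_ki, n_requested, seed) {
  total <- choose(n, n1)
  if (total - 1 <= n_requested) {
    all_sets <- utils::combn(n, n1)
    keep <- !apply(all_sets, 2L, function(s) identical(sort(s), sort(observed_ki)))
    return(all_sets[, keep, drop = FALSE])
  }
  with_seed_or_not(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, nrow = n1, ncol = 0L)
    obs_key <- paste(sort(observed_ki), collapse = ",")
    while (ncol(out) < n_requested) {
      s <- sort(sample.int(n, n1))
      key <- paste(s, collapse = ",")
      if (key == obs_key || !is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out <- cbind(out, s)
    }
    unname(out)
  })
}

#' Call titin-associated (enriched) proteins
#'
#' A protein is significant when its permutation q value is below `fdr`, it
#' was identified with at least `min_peptides` peptides, and it is enriched
#' in the knock-in group (`log2fc > 0`).
#'
#' @param results data.frame from [permutation_fdr()] with a `q` column.
#' @param peptide_counts named integer vector (names = protein ids) or a
#'   [proteingroup_table()] supplying peptide counts.
#' @param fdr q-value cut-off, default 0.05.
#' @param min_peptides minimum peptide count, default 3.
#' @return `results` with `peptide_count` and logical `significant` columns;
#'   the significant protein ids are in the `called` attribute.
#' @export
call_associated <- function(results, peptide_counts, fdr = 0.05, min_peptides = 3L) {
  if (is.null(results$q)) stop_input("results lack q values; run permutation_fdr first")
  if (inherits(peptide_counts, "proteingroup_table")) {
    df <- as.data.frame(peptide_counts)
    peptide_counts <- stats::setNames(df$peptide_count, df$protein_id)
  }
  results$peptide_count <- as.integer(peptide_counts[results$protein_id])
  results$significant <- results$q < fdr &
    results$peptide_count >= min_peptides & results$log2fc > 0
  results$significant[is.na(results$significant)] <- FALSE
  attr(results, "called") <- results$protein_id[results$significant]
  results
}

#' Full protein-enrichment pipeline on one table
#'
#' Valid-value filtering, log2 transform, down-shifted imputation,
#' two-sample Student's t-test, permutation FDR, and the associated-protein
#' call, in one step.
#'
#' @param table a [proteingroup_table()].
#' @param min_valid minimum valid values per group, see [filter_min_valid()].
#' @param imputation an [imputation_params()].
#' @param fdr_params a [permutation_fdr_params()].
#' @param min_peptides minimum peptide count for a call.
#' @param seed integer seed controlling imputation and permutations.
#' @return a `TestResult` data.frame (protein_id, log2fc, t, p, q,
#'   peptide_count, significant) with the called id set in attribute
#'   `called`.
#' @export
enrich_proteins <- function(table, min_valid = 3L,
                            imputation = imputation_params(),
                            fdr_params = permutation_fdr_params(),
                            min_peptides = 3L, seed = NULL) {
  design <- site_design(table)
  filtered <- filter_min_valid(table, min_valid)
  if (nrow(filtered) == 0L) {
    out <- data.frame(protein_id = character(0), log2fc = numeric(0),
                      t = numeric(0), p = numeric(0), q = numeric(0),
                      peptide_count = integer(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "called") <- character(0)
    return(out)
  }
  lm <- log2_transform(filtered)
  if (!is.null(seed)) imputation$seed <- seed
  imputed <- impute_missing(lm, imputation)
  res <- two_sample_ttest(imputed, design)
  res <- permutation_fdr(res, imputed, design, fdr_params,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  call_associated(res, filtered, fdr = fdr_params$fdr, min_peptides = min_peptides)
}
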