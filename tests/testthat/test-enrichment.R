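test_that("min-valid filter keeps rows quantified in at least one group", {
  tb <- make_pg_table(ki = rbind(c(1, 2, 3, 4), c(1, 2, 0, 0)),
                      wt = rbind(c(0, 0, 0, 0), c(3, 4, 0, 0)))
  expect_equal(filter_min_valid(tb)$protein_id, "P001")
  # strict reading requires the minimum in every group
  expect_equal(nrow(filter_min_valid(tb, scope = "each")), 0L)
})

test_that("min-valid filter matches the row oracle on random tables", {
  withr::with_seed(71, {
    for (rep in 1:40) {
      n <- 25L
      ki <- matrix(rbinom(n * 4, 1, 0.5) * rexp(n * 4), n)
      wt <- matrix(rbinom(n * 4, 1, 0.5) * rexp(n * 4), n)
      tb <- make_pg_table(ki, wt)
      kept <- filter_min_valid(tb)$protein_id
      want <- vapply(seq_len(n), function(i) oracle_min_valid_keep(ki[i, ], wt[i, ]),
                     logical(1))
      expect_equal(kept, sprintf("P%03d", seq_len(n))[want])
    }
  })
})

test_that("imputation draws down-shifted values and preserves observed cells", {
  m <- matrix(rnorm(40, 20, 1), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_identical(impute_missing(m), m)

  m2 <- m
  m2[c(1, 5, 12, 33)] <- NA
  i1 <- impute_missing(m2, imputation_params(seed = 9))
  i2 <- impute_missing(m2, imputation_params(seed = 9))
  expect_identical(i1, i2)
  expect_false(anyNA(i1))
  expect_identical(i1[!is.na(m2)], m2[!is.na(m2)])

  thin <- matrix(c(1, NA, NA, NA), 2, 2)
  expect_error(impute_missing(thin), "fewer than 2 observed")
})

test_that("imputed moments converge to the down-shift and width parameters", {
  n <- 20000L
  col <- withr::with_seed(81, c(rnorm(n), rep(NA_real_, n)))
  m <- matrix(col, ncol = 1)
  imp <- impute_missing(m, imputation_params(seed = 82))[(n + 1):(2 * n), 1]
  obs <- col[1:n]
  downshift <- (mean(obs) - mean(imp)) / sd(obs)
  expect_lt(abs(downshift - 1.8), 3 * 0.3 / sqrt(n))
  expect_lt(abs(sd(imp) / sd(obs) - 0.3), 0.3 * 0.02)
})

test_that("row t-test agrees with the reference implementation", {
  d <- two_group_design(3, 3)
  m <- matrix(c(1, 2, 3, 1, 2, 3), 1, dimnames = list("P1", d$sample))
  r <- two_sample_ttest(m, d)
  expect_equal(r$log2fc, 0)
  expect_equal(r$t, 0)

  flat <- matrix(rep(2, 6), 1, dimnames = list("P1", d$sample))
  r0 <- two_sample_ttest(flat, d)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  withr::with_seed(91, {
    n <- 500L
    mat <- matrix(rnorm(n * 6, 20, 2), n, dimnames = list(NULL, d$sample))
    got <- two_sample_ttest(mat, d)
    want_p <- vapply(seq_len(n), function(i) {
      stats::t.test(mat[i, 1:3], mat[i, 4:6], var.equal = TRUE)$p.value
    }, numeric(1))
    expect_lt(max(abs(got$p - want_p)), 1e-10)
  })
})

test_that("swapping genotype labels negates fold changes and t exactly", {
  withr::with_seed(101, {
    d <- two_group_design(4, 4)
    d_swap <- sample_design(d$sample, ifelse(d$genotype == "knockin",
                                             "wildtype", "knockin"))
    mat <- matrix(rnorm(50 * 8, 20, 2), 50, dimnames = list(NULL, d$sample))
    a <- two_sample_ttest(mat, d)
    b <- two_sample_ttest(mat, d_swap)
    expect_equal(a$log2fc, -b$log2fc)
    expect_equal(a$t, -b$t)
  })
})

test_that("a statistic beyond every permuted value earns q = 0", {
  withr::with_seed(111, {
    d <- sample_design(c(paste0("ki", 1:4), paste0("wt", 1:3)),
                       c(rep("knockin", 4), rep("wildtype", 3)))
    mat <- matrix(rnorm(30 * 7, 20, 0.5), 30, dimnames = list(NULL, d$sample))
    mat[1, 1:4] <- mat[1, 1:4] + 50  # clean separation under the true labels
    res <- two_sample_ttest(mat, d)
    res <- permutation_fdr(res, mat, d, permutation_fdr_params(), seed = 1)
    expect_equal(res$q[1], 0)
    expect_true(all(res$q >= 0 & res$q <= 1))
    # q values are monotone non-increasing in |t|
    ord <- order(-abs(res$t))
    expect_true(all(diff(res$q[ord]) >= -1e-12))
  })
})

test_that("strong-signal simulation recovers all enriched proteins", {
  withr::with_seed(121, {
    total_called <- 0L
    total_false <- 0L
    for (i in 1:10) {
      cfg <- sim_config(seed = 500L + i, enrichment_log2fc = 4,
                        n_null_proteins = 200L, n_enriched_proteins = 10L,
                        mnar_midpoint = -Inf)
      sim <- simulate_proteingroups(cfg)
      res <- enrich_proteins(sim$table, seed = 600L + i)
      called <- attr(res, "called")
      # the peptide-count rule intentionally drops sub-threshold identifications
      df <- as.data.frame(sim$table)
      callable <- intersect(sim$truth, df$protein_id[df$peptide_count >= 3L])
      expect_true(all(callable %in% called))
      total_called <- total_called + length(called)
      total_false <- total_false + length(setdiff(called, sim$truth))
    }
    se <- sqrt(0.05 * 0.95 / total_called)
    expect_lte(total_false / total_called, 0.05 + 3 * se)
  })
})

test_that("association calls require q, peptides and knock-in enrichment", {
  res <- data.frame(protein_id = c("A", "B", "C"),
                    log2fc = c(3, 2, -2), t = c(5, 4, -4),
                    p = c(1e-4, 1e-3, 1e-3), q = c(0.01, 0.04, 0.04),
                    stringsAsFactors = FALSE)
  pep <- c(A = 2L, B = 3L, C = 8L)
  out <- call_associated(res, pep)
  expect_equal(attr(out, "called"), "B")
  expect_false(out$significant[out$protein_id == "A"])  # too few peptides
  expect_false(out$significant[out$protein_id == "C"])  # wild-type enriched
})

test_that("empty tables flow through the enrichment pipeline", {
  tb <- make_pg_table(ki = matrix(0, 0, 4), wt = matrix(0, 0, 4),
                      peptides = integer(0), ids = character(0))
  res <- enrich_proteins(tb)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "called"), character(0))
})
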