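test_that("generators are bit-identical under a fixed config and seed", {
  ann <- sim_annotation()
  cfg <- sim_config(seed = 17, insertion_residue = 300L,
                    secondary_site_residue = 1200L)
  expect_identical(as.data.frame(simulate_site_table(cfg, ann)),
                   as.data.frame(simulate_site_table(cfg, ann)))
  s1 <- simulate_proteingroups(cfg)
  s2 <- simulate_proteingroups(cfg)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_profiles(n = 2, seed = 17)
  p2 <- simulate_profiles(n = 2, seed = 17)
  expect_identical(p1[[2]]$channels, p2[[2]]$channels)
})

test_that("degenerate parameters silence the secondary cluster and background", {
  ann <- sim_annotation()
  cfg <- sim_config(seed = 2, insertion_residue = 300L,
                    secondary_site_residue = 1200L, dwell_fraction = 0,
                    wt_background_rate = 0)
  tb <- simulate_site_table(cfg, ann)
  truth <- attr(tb, "truth")
  expect_true(all(truth$cluster == "primary"))
  wt <- as.matrix(as.data.frame(tb)[, design_samples(site_design(tb), "wildtype")])
  expect_true(all(wt == 0))
  expect_error(simulate_site_table(sim_config(insertion_residue = 10000L), ann),
               "insertion_residue")
  expect_error(sim_config(dwell_fraction = 1.5), "dwell_fraction")
})

test_that("secondary aggregate intensity tracks the dwell fraction", {
  ann <- sim_annotation()
  # conservation holds exactly at the level of expected intensities
  cfg0 <- sim_config(seed = 1, insertion_residue = 300L,
                     secondary_site_residue = 1200L, dwell_fraction = 0.075)
  truth0 <- attr(simulate_site_table(cfg0, ann), "truth")
  expect_equal(sum(truth0$expected_intensity[truth0$cluster == "secondary"]) /
                 sum(truth0$expected_intensity[truth0$cluster == "primary"]),
               0.075)
  ratios <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 3000L + i, insertion_residue = 300L,
                      secondary_site_residue = 1200L, dwell_fraction = 0.075,
                      n_knockin = 50L, mnar_midpoint = -Inf)
    tb <- simulate_site_table(cfg, ann)
    truth <- attr(tb, "truth")
    ki <- as.matrix(as.data.frame(tb)[, design_samples(site_design(tb), "knockin")])
    med <- apply(ki, 1, function(v) { v <- v[v > 0]; if (length(v)) median(v) else 0 })
    sum(med[truth$cluster == "secondary"]) / sum(med[truth$cluster == "primary"])
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.075), 3 * se + 1e-12)
})

test_that("MNAR dropout is monotone in true intensity and switches off", {
  cfg <- sim_config(seed = 23, n_null_proteins = 2000L,
                    n_enriched_proteins = 0L, enrichment_log2fc = 0)
  sim <- simulate_proteingroups(cfg, between_protein_sd = 4)
  tb <- sim$table
  base <- attr(tb, "base_log2")
  m <- as.matrix(as.data.frame(tb)[, site_design(tb)$sample])
  decile <- cut(base, quantile(base, 0:10 / 10), include.lowest = TRUE,
                labels = FALSE)
  miss_rate <- vapply(1:10, function(d) mean(m[decile == d, ] == 0), numeric(1))
  n_cells <- vapply(1:10, function(d) sum(decile == d) * ncol(m), numeric(1))
  slack <- 3 * sqrt(0.25 / min(n_cells))
  expect_true(all(diff(miss_rate) <= slack))
  expect_gt(miss_rate[1], miss_rate[10])

  cfg_off <- sim_config(seed = 23, n_null_proteins = 200L,
                        n_enriched_proteins = 0L, mnar_midpoint = -Inf)
  m_off <- as.matrix(as.data.frame(simulate_proteingroups(cfg_off)$table)[, 3:10])
  expect_true(all(m_off > 0))
})

test_that("enriched proteins are shifted by the configured log2 fold change", {
  diffs <- vapply(1:100, function(i) {
    cfg <- sim_config(seed = 4000L + i, enrichment_log2fc = 4,
                      n_null_proteins = 50L, n_enriched_proteins = 10L,
                      mnar_midpoint = -Inf)
    sim <- simulate_proteingroups(cfg)
    m <- log2(as.matrix(as.data.frame(sim$table)[, site_design(sim$table)$sample]))
    enr <- as.data.frame(sim$table)$protein_id %in% sim$truth
    mean(rowMeans(m[enr, 1:4]) - rowMeans(m[enr, 5:8]))
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 4), 3 * se)
})

test_that("noiseless profiles have exact band geometry and mirror symmetry", {
  p <- simulate_profiles(sarcomere_length_um = 2, pixel_nm = 10, noise_sd = 0,
                         psf_sigma_nm = 0, n = 1)[[1]]
  s <- measure_sarcomere(p)
  expect_equal(mean(diff(s$peak_positions_nm)), 2000)
  # mirror symmetry about the central Z-disc
  center <- s$peak_positions_nm[which.min(abs(s$peak_positions_nm -
                                              mean(range(p$position_nm))))]
  for (ch in names(p$channels)) {
    v <- p$channels[[ch]]
    idx <- round((2 * center - p$position_nm) / p$pixel_nm) + 1L
    ok <- idx >= 1 & idx <= length(v)
    expect_equal(v[ok], v[idx[ok]], tolerance = 1e-9)
  }
})

test_that("zero hotspot offset collapses the secondary band onto the Z edge", {
  p <- simulate_profiles(sarcomere_length_um = 2, pixel_nm = 10, noise_sd = 0,
                         psf_sigma_nm = 0, hotspot_offset_nm = 0, n = 1)[[1]]
  pk_b <- find_peaks(p, "biotin")
  pk_a <- find_peaks(p, "actinin")
  z <- pk_a$position[which.min(abs(pk_a$position - mean(range(p$position_nm))))]
  edges <- z + c(-50, 50)
  # biotin peaks flanking the central Z-disc sit exactly on its edges
  near <- pk_b$position[abs(pk_b$position - z) < 500]
  expect_true(all(vapply(near, function(x) min(abs(x - edges)) <= p$pixel_nm,
                         logical(1))))
})

test_that("long myosin filaments reach the Z-disc edge in short sarcomeres", {
  p <- simulate_profiles(sarcomere_length_um = 1.7, pixel_nm = 10, noise_sd = 0,
                         psf_sigma_nm = 0, myosin_halflength_nm = 810,
                         n = 1)[[1]]
  m <- measure_profile(p)
  expect_gt(m$n_overlap_intervals, 0)
  expect_gt(m$overlap_total_nm, 0)
  expect_error(simulate_profiles(pixel_nm = 0), "pixel_nm")
})
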