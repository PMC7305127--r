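triangle_profile <- function(L = 400, pixel = 10) {
  x <- seq(0, L, by = pixel)
  y <- 1 - abs(x - L / 2) / (L / 2)
  intensity_profile(x, list(band = y))
}

test_that("normalization is an exact min-max rescale and gain invariant", {
  p <- triangle_profile()
  expect_equal(normalize_channel(p, "band")$channels$band, p$channels$band)
  p2 <- p
  p2$channels$band <- 2 * p2$channels$band
  expect_equal(normalize_channel(p2, "band")$channels$band, p$channels$band)
  withr::with_seed(131, {
    p3 <- intensity_profile(seq(0, 100, 5), list(ch = runif(21, 2, 9)))
    v <- normalize_channel(p3, "ch")$channels$ch
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  })
  flat <- intensity_profile(seq(0, 100, 5), list(ch = rep(1, 21)))
  expect_error(normalize_channel(flat, "ch"), "constant")
  expect_equal(nrow(find_edges(flat, "ch")), 0L)
})

test_that("75% edges of triangular and trapezoidal bands are analytic", {
  p <- triangle_profile(L = 400, pixel = 10)
  e <- find_edges(p, "band")
  # linear geometry: value 0.75 at 0.75 * L/2 from either end
  expect_equal(e$position, c(150, 250))
  expect_equal(e$direction, c("rising", "falling"))

  # trapezoid: ramps of width 80 onto a plateau [180, 320]
  x <- seq(0, 500, 10)
  y <- pmin(1, pmax(0, pmin((x - 100) / 80, (400 - x) / 80)))
  tz <- intensity_profile(x, list(band = y))
  e2 <- find_edges(tz, "band")
  expect_equal(e2$position, c(100 + 0.75 * 80, 400 - 0.75 * 80), tolerance = 1e-9)
})

test_that("overlap intervals have interpolated bounds and detect disjunction", {
  x <- seq(0, 2000, 10)
  # ramps crossing 0.25 of their unit range at 800 and 900 exactly
  a <- pmin(1, pmax(0, (x - 750) / 200))          # 0.25 at 800, rising
  b <- pmin(1, pmax(0, (950 - x) / 200))          # 0.25 at 900, falling
  p <- intensity_profile(x, list(a = a, b = b))
  ov <- overlap_intervals(p, "a", "b")
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$start, 800, tolerance = 1e-9)
  expect_equal(ov$end, 900, tolerance = 1e-9)

  a2 <- exp(-0.5 * ((x - 300) / 50)^2)
  b2 <- exp(-0.5 * ((x - 1700) / 50)^2)
  expect_equal(nrow(overlap_intervals(intensity_profile(x, list(a = a2, b = b2)),
                                      "a", "b")), 0L)
})

test_that("overlap intervals match the per-pixel AND-mask oracle", {
  withr::with_seed(141, {
    for (rep in 1:60) {
      nx <- 80L
      x <- seq(0, by = 10, length.out = nx)
      mk <- function() {
        v <- rep(0, nx)
        for (k in seq_len(sample(1:3, 1))) {
          i <- sort(sample(nx, 2))
          v[i[1]:i[2]] <- v[i[1]:i[2]] + runif(1, 0.5, 2)
        }
        v + runif(nx, 0, 0.1)
      }
      p <- intensity_profile(x, list(a = mk(), b = mk()))
      got <- overlap_intervals(p, "a", "b")
      want <- oracle_overlap_mask(x, p$channels$a, p$channels$b)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_true(all(abs(got$start - want$start) <= 10 + 1e-9))
        expect_true(all(abs(got$end - want$end) <= 10 + 1e-9))
      }
    }
  })
})

test_that("peak spacing and FWHM reproduce constructed band geometry", {
  x <- seq(0, 2700, 10)
  y <- exp(-0.5 * ((x - 500) / 60)^2) + exp(-0.5 * ((x - 2200) / 60)^2)
  p <- intensity_profile(x, list(actinin = y))
  s <- measure_sarcomere(p)
  expect_equal(s$sarcomere_length_um, 1.7, tolerance = 10 / 1700)
  expect_lt(abs(s$zdisc_width_nm - 2 * sqrt(2 * log(2)) * 60), 10)
  lone <- intensity_profile(x, list(actinin = exp(-0.5 * ((x - 500) / 60)^2)))
  expect_error(measure_sarcomere(lone), "fewer than 2")
})

test_that("hotspot displacement measures outward distance from the Z edge", {
  x <- seq(0, 2000, 10)
  biotin <- exp(-0.5 * ((x - 900) / 40)^2) + 0.6 * exp(-0.5 * ((x - 1200) / 40)^2)
  p <- intensity_profile(x, list(biotin = biotin))
  expect_equal(hotspot_displacement(p, "biotin", c(800, 1000)), 200,
               tolerance = 1e-9)
  # secondary peak exactly at the edge
  b2 <- exp(-0.5 * ((x - 850) / 30)^2) + 0.6 * exp(-0.5 * ((x - 1000) / 30)^2)
  p2 <- intensity_profile(x, list(biotin = b2))
  expect_equal(hotspot_displacement(p2, "biotin", c(700, 1000)), 0)
  # no secondary peak at all: an absent value, not zero
  p3 <- intensity_profile(x, list(biotin = exp(-0.5 * ((x - 900) / 40)^2)))
  expect_true(is.na(hotspot_displacement(p3, "biotin", c(700, 1100))))
})

test_that("profile measurements are invariant to grid translation and gain", {
  p <- simulate_profiles(n = 1, seed = 151)[[1]]
  m1 <- measure_profile(p)
  shifted <- intensity_profile(p$position_nm + 12345, p$channels)
  m2 <- measure_profile(shifted)
  expect_equal(m2$sarcomere_length_um, m1$sarcomere_length_um)
  expect_equal(m2$zdisc_width_nm, m1$zdisc_width_nm)
  expect_equal(m2$hotspot_displacement_nm, m1$hotspot_displacement_nm)
  expect_equal(m2$zdisc_edge_left_nm - 12345, m1$zdisc_edge_left_nm)
  scaled <- intensity_profile(p$position_nm,
                              lapply(p$channels, function(v) 7.5 * v))
  m3 <- measure_profile(scaled)
  expect_equal(m3$overlap_total_nm, m1$overlap_total_nm)
  expect_equal(m3$hotspot_displacement_nm, m1$hotspot_displacement_nm)
})

test_that("profile averaging reproduces the mean and SEM formulas", {
  ps <- simulate_profiles(n = 3, seed = 161, noise_sd = 0)
  tr <- average_profiles(ps)
  sub <- tr[tr$channel == "biotin" & tr$n == 3, ]
  expect_true(all(sub$sem < 1e-6))

  noisy <- simulate_profiles(n = 6, seed = 171)
  tr2 <- average_profiles(noisy)
  # oracle: textbook mean/SEM over the aligned stack for one channel
  pk <- vapply(noisy, function(p) {
    f <- find_peaks(p, "actinin")
    f$position[which.max(f$height)]
  }, numeric(1))
  full <- tr2[tr2$channel == "myosin" & tr2$n == 6, ]
  probe <- full$position_nm[round(seq(2, nrow(full) - 1, length.out = 5))]
  for (pos in probe) {
    vals <- vapply(seq_along(noisy), function(k) {
      idx <- which(abs(noisy[[k]]$position_nm - pk[k] - pos) < 1e-6)
      noisy[[k]]$channels$myosin[idx]
    }, numeric(1))
    row <- full[abs(full$position_nm - pos) < 1e-9, ]
    expect_equal(row$mean, mean(vals), tolerance = 1e-12)
    expect_equal(row$sem, sd(vals) / sqrt(6), tolerance = 1e-9)
  }
})

test_that("profiles round-trip through CSV", {
  p <- simulate_profiles(n = 1, seed = 181)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, path)
  back <- read_profile(path)
  expect_equal(back$position_nm, p$position_nm)
  expect_equal(back$channels$biotin, p$channels$biotin, tolerance = 1e-12)
})
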