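#' Configuration of the synthetic-data generator
#'
#' Bundles every knob of the generative model used to emulate a knock-in
#' proximity-labeling experiment: two genotype groups, a distance-decay
#' biotinylation signal around the ligase insertion residue, an optional
#' secondary hotspot carrying a configurable dwell fraction of the primary
#' labeling budget, log-normal MS intensities with intensity-dependent
#' (MNAR) dropout, wild-type background biotinylation, and a protein-group
#' fixture with truly enriched interactors among nulls.
#'
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @param n_knockin,n_wildtype replicate counts (>= 1).
#' @param insertion_residue 1-based residue index of the ligase insertion.
#' @param labeling_radius_nm maximal labeling reach in nm; site intensities
#'   decay as a half-Gaussian of this scale within it.
#' @param secondary_site_residue 1-based index of the secondary hotspot
#'   center, or `NULL` for none.
#' @param dwell_fraction fraction in `[0, 1]` of the primary labeling
#'   budget assigned to the secondary hotspot.
#' @param intensity_scale log-normal median intensity of a site at zero
#'   distance.
#' @param intensity_cv coefficient of variation of the multiplicative
#'   intensity noise.
#' @param mnar_midpoint log2 intensity of 50% dropout; default 8 log2 units
#'   below `log2(intensity_scale)`, confining dropout to the low tail.
#'   `-Inf` disables missingness.
#' @param mnar_slope logistic steepness of the dropout curve per log2 unit.
#' @param wt_background_rate probability in `[0, 1]` that a wild-type cell
#'   carries background biotinylation.
#' @param n_null_proteins,n_enriched_proteins protein counts for the
#'   protein-group fixture.
#' @param enrichment_log2fc log2 fold change of enriched proteins in the
#'   knock-in group.
#' @param site_spacing spacing (residues) of lysine-eligible site positions.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_knockin = 4L, n_wildtype = 4L,
                       insertion_residue = 500L,
                       labeling_radius_nm = 10,
                       secondary_site_residue = NULL,
                       dwell_fraction = 0.075,
                       intensity_scale = 1e6,
                       intensity_cv = 0.25,
                       mnar_midpoint = NULL,
                       mnar_slope = 1,
                       wt_background_rate = 0.05,
                       n_null_proteins = 500L,
                       n_enriched_proteins = 25L,
                       enrichment_log2fc = 2,
                       site_spacing = 5L) {
  if (n_knockin < 1L || n_wildtype < 1L) stop_input("replicate counts must be >= 1")
  if (labeling_radius_nm <= 0) stop_input("labeling_radius_nm must be > 0")
  if (dwell_fraction < 0 || dwell_fraction > 1) {
    stop_input("dwell_fraction must lie in [0, 1]")
  }
  if (intensity_scale <= 0 || intensity_cv <= 0) {
    stop_input("intensity_scale and intensity_cv must be > 0")
  }
  if (wt_background_rate < 0 || wt_background_rate > 1) {
    stop_input("wt_background_rate must lie in [0, 1]")
  }
  if (!is.finite(enrichment_log2fc)) stop_input("enrichment_log2fc must be finite")
  if (site_spacing < 1L) stop_input("site_spacing must be >= 1")
  structure(list(
    seed = as.integer(seed),
    n_knockin = as.integer(n_knockin), n_wildtype = as.integer(n_wildtype),
    insertion_residue = as.integer(insertion_residue),
    labeling_radius_nm = labeling_radius_nm,
    secondary_site_residue = if (is.null(secondary_site_residue)) NULL
                             else as.integer(secondary_site_residue),
    dwell_fraction = dwell_fraction,
    intensity_scale = intensity_scale, intensity_cv = intensity_cv,
    mnar_midpoint = mnar_midpoint %||% (log2(intensity_scale) - 8),
    mnar_slope = mnar_slope,
    wt_background_rate = wt_background_rate,
    n_null_proteins = as.integer(n_null_proteins),
    n_enriched_proteins = as.integer(n_enriched_proteins),
    enrichment_log2fc = enrichment_log2fc,
    site_spacing = as.integer(site_spacing)),
    class = "sim_config")
}

sim_design <- function(config) {
  sample_design(c(paste0("KI", seq_len(config$n_knockin)),
                  paste0("WT", seq_len(config$n_wildtype))),
                c(rep("knockin", config$n_knockin),
                  rep("wildtype", config$n_wildtype)))
}

sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Titin-like synthetic domain annotation
#'
#' Builds a single-protein annotation with an N-terminal unstructured
#' repeat region followed by alternating folded Ig-like domains and
#' unstructured linkers — the architecture of an elastic sarcomeric protein
#' around its Z-disc region.
#'
#' @param protein_id protein identifier.
#' @param n_ig number of folded Ig-like domains.
#' @param ig_length residues per folded domain.
#' @param linker_length residues per unstructured linker.
#' @param zrepeat_length residues of the leading unstructured repeat
#'   region.
#' @return a [domain_annotation()].
#' @export
sim_annotation <- function(protein_id = "TTN_SYN", n_ig = 10L, ig_length = 89L,
                           linker_length = 35L, zrepeat_length = 450L) {
  starts <- ends <- integer(0)
  kinds <- labels <- character(0)
  cur <- 1L
  add <- function(len, kind, label) {
    starts <<- c(starts, cur); ends <<- c(ends, cur + len - 1L)
    kinds <<- c(kinds, kind); labels <<- c(labels, label)
    cur <<- cur + len
  }
  add(as.integer(zrepeat_length), "unstructured", "Z-repeat region")
  for (k in seq_len(n_ig)) {
    add(as.integer(ig_length), "folded_domain", paste0("Ig", k))
    add(as.integer(linker_length), "unstructured", paste0("linker", k))
  }
  domain_annotation(protein_id, data.frame(start = starts, end = ends,
                                           kind = kinds, label = labels,
                                           stringsAsFactors = FALSE))
}

#' Lysine-eligible positions reachable from a center residue
#' @noRd
reachable_sites <- function(annotation, center, radius_nm, spacing, model) {
  len <- annotation_length(annotation)
  pick <- function(step) {
    out <- integer(0)
    p <- center
    repeat {
      p <- p + step * spacing
      if (p < 1L || p > len) break
      if (residue_distance(annotation, center, p, model) > radius_nm) break
      out <- c(out, p)
    }
    out
  }
  sort(c(pick(-1L), center, pick(1L)))
}

#' Simulate a biotinylation-site table with known ground truth
#'
#' Knock-in samples carry intensities decaying as a half-Gaussian of the
#' contour distance from the insertion residue (scale = labeling radius,
#' hard support within it); an optional secondary cluster around
#' `secondary_site_residue` carries an expected aggregate intensity of
#' `dwell_fraction` times the primary aggregate. Wild-type samples carry
#' only sparse background. Missing values are encoded as intensity 0.
#'
#' @param config a [sim_config()] with `insertion_residue` (and, if set,
#'   `secondary_site_residue`) inside the annotation.
#' @param annotation a [domain_annotation()].
#' @param model a [geometry_model()].
#' @return a [site_table()]; the generator truth (site positions, expected
#'   intensities, cluster assignment) is in attribute `truth`.
#' @export
simulate_site_table <- function(config, annotation, model = geometry_model()) {
  len <- annotation_length(annotation)
  if (config$insertion_residue < 1L || config$insertion_residue > len) {
    stop_input("insertion_residue %d outside 1..%d", config$insertion_residue, len)
  }
  has_secondary <- !is.null(config$secondary_site_residue) && config$dwell_fraction > 0
  if (has_secondary &&
      (config$secondary_site_residue < 1L || config$secondary_site_residue > len)) {
    stop_input("secondary_site_residue %d outside 1..%d",
               config$secondary_site_residue, len)
  }
  design <- sim_design(config)
  r <- config$labeling_radius_nm

  pri_pos <- reachable_sites(annotation, config$insertion_residue, r,
                             config$site_spacing, model)
  d_pri <- residue_distance(annotation, config$insertion_residue, pri_pos, model)
  w_pri <- exp(-d_pri^2 / (2 * r^2))
  mu_pri <- config$intensity_scale * w_pri

  sec_pos <- integer(0)
  mu_sec <- numeric(0)
  if (has_secondary) {
    sec_pos <- reachable_sites(annotation, config$secondary_site_residue, r,
                               config$site_spacing, model)
    sec_pos <- setdiff(sec_pos, pri_pos)
    d_sec <- residue_distance(annotation, config$secondary_site_residue, sec_pos, model)
    w_sec <- exp(-d_sec^2 / (2 * r^2))
    # expected secondary aggregate = dwell_fraction x primary aggregate
    mu_sec <- config$dwell_fraction * sum(mu_pri) * w_sec / sum(w_sec)
  }

  pos <- c(pri_pos, sec_pos)
  mu <- c(mu_pri, mu_sec)
  cluster <- c(rep("primary", length(pri_pos)), rep("secondary", length(sec_pos)))
  n_sites <- length(pos)
  sdlog <- sdlog_from_cv(config$intensity_cv)

  records <- withr::with_seed(config$seed, {
    rec <- data.frame(protein_id = annotation_protein(annotation),
                      position = pos, stringsAsFactors = FALSE)
    for (s in design_samples(design, "knockin")) {
      v <- mu * exp(stats::rnorm(n_sites, 0, sdlog))
      p_miss <- mnar_dropout_prob(log2(v), config$mnar_midpoint, config$mnar_slope)
      v[stats::runif(n_sites) < p_miss] <- 0
      rec[[s]] <- v
    }
    bg_scale <- config$intensity_scale / 100
    for (s in design_samples(design, "wildtype")) {
      v <- numeric(n_sites)
      hit <- stats::runif(n_sites) < config$wt_background_rate
      v[hit] <- bg_scale * exp(stats::rnorm(sum(hit), 0, sdlog))
      rec[[s]] <- v
    }
    rec
  })
  out <- site_table(records, design)
  attr(out, "truth") <- data.frame(position = pos, expected_intensity = mu,
                                   cluster = cluster, stringsAsFactors = FALSE)
  out
}

#' Simulate a protein-group table with a known enriched set
#'
#' Null proteins share one log-normal intensity distribution across
#' genotypes; enriched proteins are shifted by `enrichment_log2fc` in the
#' knock-in samples. MNAR dropout is applied on the log2 scale; peptide
#' counts are simulated >= 1.
#'
#' @param config a [sim_config()] with `n_null_proteins +
#'   n_enriched_proteins >= 2`.
#' @param between_protein_sd SD (log2) of protein base abundances.
#' @return list with elements `table` (a [proteingroup_table()]) and
#'   `truth` (character vector of truly enriched protein ids).
#' @export
simulate_proteingroups <- function(config, between_protein_sd = 2) {
  n_prot <- config$n_null_proteins + config$n_enriched_proteins
  if (n_prot < 2L) stop_input("need at least 2 proteins")
  design <- sim_design(config)
  ids <- sprintf("P%04d", seq_len(n_prot))
  withr::with_seed(config$seed, {
    enriched <- sort(sample(ids, config$n_enriched_proteins))
    base <- stats::rnorm(n_prot, log2(config$intensity_scale), between_protein_sd)
    sd_log2 <- sdlog_from_cv(config$intensity_cv) / log(2)
    rows <- data.frame(protein_id = ids,
                       peptide_count = 1L + stats::rpois(n_prot, 5),
                       stringsAsFactors = FALSE)
    shift <- ifelse(ids %in% enriched, config$enrichment_log2fc, 0)
    for (s in design$sample) {
      x <- base + stats::rnorm(n_prot, 0, sd_log2)
      if (design$genotype[design$sample == s] == "knockin") x <- x + shift
      p_miss <- mnar_dropout_prob(x, config$mnar_midpoint, config$mnar_slope)
      raw <- 2^x
      raw[stats::runif(n_prot) < p_miss] <- 0
      rows[[s]] <- raw
    }
    out <- proteingroup_table(rows, design)
    attr(out, "base_log2") <- stats::setNames(base, ids)
    list(table = out, truth = enriched)
  })
}

gauss_band <- function(x, center, sigma, amplitude = 1) {
  if (sigma <= 0) return(ifelse(x == center, amplitude, 0))
  amplitude * exp(-0.5 * ((x - center) / sigma)^2)
}

plateau_band <- function(x, center, halflength, sigma) {
  if (sigma <= 0) return(as.numeric(x >= center - halflength & x <= center + halflength))
  stats::pnorm(x, center - halflength, sigma) - stats::pnorm(x, center + halflength, sigma)
}

#' Simulate noisy periodic two-channel sarcomere line profiles
#'
#' Builds an `"actinin"` channel of Gaussian Z-disc bands spaced by the
#' sarcomere length, a `"biotin"` channel with a primary band at each
#' Z-disc edge plus a weaker secondary band `hotspot_offset_nm` outward
#' from the edge, and a `"myosin"` plateau of half-length
#' `myosin_halflength_nm` centered mid-sarcomere. All structures are
#' convolved with a Gaussian point-spread function of `psf_sigma_nm` (done
#' in closed form) and perturbed by additive Gaussian noise clipped at 0.
#'
#' @param sarcomere_length_um sarcomere length in micrometers.
#' @param zdisc_width_nm FWHM of the Z-disc actinin band.
#' @param hotspot_offset_nm outward offset of the secondary biotin band
#'   from the Z-disc edge.
#' @param myosin_halflength_nm half-length of the myosin filament plateau.
#' @param psf_sigma_nm Gaussian PSF sigma (0 = no blurring).
#' @param pixel_nm sampling step, > 0.
#' @param noise_sd additive noise SD on the unit-amplitude scale.
#' @param n number of replicate profiles (>= 1).
#' @param seed integer seed, or `NULL`.
#' @param n_sarcomeres number of sarcomeres covered by the grid.
#' @param band_sigma_nm intrinsic sigma of the biotin bands.
#' @param secondary_amplitude peak amplitude of the secondary biotin band
#'   (primary = 1).
#' @return list of `n` [intensity_profile()] objects.
#' @export
simulate_profiles <- function(sarcomere_length_um = 2.0, zdisc_width_nm = 100,
                              hotspot_offset_nm = 200, myosin_halflength_nm = 800,
                              psf_sigma_nm = 30, pixel_nm = 15, noise_sd = 0.05,
                              n = 9L, seed = NULL, n_sarcomeres = 2L,
                              band_sigma_nm = 25, secondary_amplitude = 0.5) {
  if (pixel_nm <= 0) stop_input("pixel_nm must be > 0")
  if (sarcomere_length_um <= 0) stop_input("sarcomere_length_um must be > 0")
  if (n < 1L) stop_input("n must be >= 1")
  sl <- sarcomere_length_um * 1000
  # half-sarcomere margins keep every band interior to the grid
  x <- seq(0, (n_sarcomeres + 1) * sl, by = pixel_nm)
  z_centers <- sl / 2 + seq(0, n_sarcomeres) * sl
  half_w <- zdisc_width_nm / 2
  sigma_z <- sqrt((zdisc_width_nm / (2 * sqrt(2 * log(2))))^2 + psf_sigma_nm^2)
  sigma_b <- sqrt(band_sigma_nm^2 + psf_sigma_nm^2)

  actinin <- rowSums(vapply(z_centers, function(z) gauss_band(x, z, sigma_z),
                            numeric(length(x))))
  biotin <- numeric(length(x))
  for (z in z_centers) {
    for (side in c(-1, 1)) {
      edge <- z + side * half_w
      biotin <- biotin + gauss_band(x, edge, sigma_b) +
        gauss_band(x, edge + side * hotspot_offset_nm, sigma_b,
                   secondary_amplitude)
    }
  }
  mids <- z_centers[-length(z_centers)] + sl / 2
  myosin <- rowSums(vapply(mids, function(m) {
    plateau_band(x, m, myosin_halflength_nm, psf_sigma_nm)
  }, numeric(length(x))))

  clean <- list(actinin = actinin, biotin = biotin, myosin = myosin)
  make_one <- function(i) {
    chans <- lapply(clean, function(v) {
      pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
    })
    intensity_profile(x, chans, metadata = list(replicate = i))
  }
  with_seed_or_not(seed, lapply(seq_len(n), make_one))
}

#' Write a simulation config as JSON
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#' @param path JSON path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a deterministic FASTA sequence for a simulated protein
#'
#' Emits a synthetic sequence with lysines at the generator's
#' lysine-eligible spacing and glycines elsewhere, matching the annotation
#' length.
#'
#' @param annotation a [domain_annotation()].
#' @param path output FASTA path.
#' @param site_spacing lysine spacing in residues.
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(annotation, path, site_spacing = 5L) {
  len <- annotation_length(annotation)
  seq_chars <- rep("G", len)
  seq_chars[seq(site_spacing, len, by = site_spacing)] <- "K"
  lines <- c(paste0(">", annotation_protein(annotation), " synthetic"),
             vapply(split(seq_chars, ceiling(seq_along(seq_chars) / 60)),
                    paste0, character(1), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
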