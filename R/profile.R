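#' 1D multi-channel intensity profile
#'
#' A uniformly sampled line profile (e.g. from super-resolution imaging of
#' sarcomeres) with named channels such as `"actinin"`, `"biotin"`,
#' `"myosin"`.
#'
#' @param position_nm increasing, uniformly spaced positions in nm (>= 2).
#' @param channels named list or data.frame of equal-length non-negative
#'   intensity vectors.
#' @param metadata optional named list (condition label, replicate id, ...).
#' @return an `intensity_profile` object.
#' @export
intensity_profile <- function(position_nm, channels, metadata = list()) {
  position_nm <- as.numeric(position_nm)
  if (length(position_nm) < 2L) stop_input("need >= 2 samples")
  dx <- diff(position_nm)
  if (any(dx <= 0)) stop_input("positions must be strictly increasing")
  if (max(dx) - min(dx) > 1e-6 * mean(dx)) {
    stop_input("positions must be uniformly spaced")
  }
  channels <- lapply(channels, as.numeric)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop_input("channels must be named")
  }
  for (ch in names(channels)) {
    if (length(channels[[ch]]) != length(position_nm)) {
      stop_input("channel '%s' length differs from position grid", ch)
    }
    if (any(channels[[ch]] < 0)) stop_input("channel '%s' has negative intensities", ch)
  }
  structure(list(position_nm = position_nm, channels = channels,
                 pixel_nm = mean(dx), metadata = metadata),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile: %d samples, %.3g nm/pixel, channels: %s\n",
              length(x$position_nm), x$pixel_nm,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(profile, channel) {
  v <- profile$channels[[channel]]
  if (is.null(v)) stop_input("profile has no channel '%s'", channel)
  v
}

#' Fractional intensity thresholds for profile quantification
#'
#' @param edge_fraction fraction of the normalized dynamic range defining a
#'   band/filament edge (default 0.75, the 75% signal-intensity edge).
#' @param presence_fraction fraction above which a signal counts as present
#'   for overlap analysis (default 0.25, the >25% criterion).
#' @return a `profile_thresholds` list.
#' @export
profile_thresholds <- function(edge_fraction = 0.75, presence_fraction = 0.25) {
  if (!(0 < presence_fraction && presence_fraction < edge_fraction &&
        edge_fraction < 1)) {
    stop_input("need 0 < presence_fraction < edge_fraction < 1")
  }
  structure(list(edge_fraction = edge_fraction,
                 presence_fraction = presence_fraction),
            class = "profile_thresholds")
}

#' Min-max normalize one channel to [0, 1]
#'
#' Affine rescaling over the profile's analysis window; the original values
#' are kept alongside as channel `"<channel>.raw"`.
#'
#' @param profile an [intensity_profile()].
#' @param channel channel name.
#' @return the profile with the channel rescaled to span exactly `[0, 1]`.
#' @export
normalize_channel <- function(profile, channel) {
  v <- get_channel(profile, channel)
  rng <- range(v)
  if (rng[2] <= rng[1]) stop_input("channel '%s' is constant; cannot normalize", channel)
  profile$channels[[paste0(channel, ".raw")]] <- v
  profile$channels[[channel]] <- (v - rng[1]) / (rng[2] - rng[1])
  profile
}

normalized_values <- function(profile, channel) {
  v <- get_channel(profile, channel)
  rng <- range(v)
  if (rng[2] <= rng[1]) stop_input("channel '%s' is constant", channel)
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Locate band edges at a fractional intensity threshold
#'
#' Finds all positions where the channel (normalized to its min-max range,
#' so results are invariant to gain) crosses `edge_fraction`, by linear
#' interpolation between adjacent samples.
#'
#' @param profile an [intensity_profile()].
#' @param channel channel name.
#' @param thresholds a [profile_thresholds()].
#' @return data.frame with columns `position` (nm, increasing) and
#'   `direction` (`"rising"`/`"falling"`); empty if there is no crossing.
#' @export
find_edges <- function(profile, channel, thresholds = profile_thresholds()) {
  v <- get_channel(profile, channel)
  if (diff(range(v)) == 0) {
    # a flat channel never crosses a fractional threshold
    return(data.frame(position = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  y <- normalized_values(profile, channel)
  threshold_crossings(profile$position_nm, y, thresholds$edge_fraction)
}

#' Intervals where two channels are simultaneously present
#'
#' Maximal intervals on which both channels exceed `presence_fraction` of
#' their normalized range, with boundaries located by linear interpolation.
#'
#' @param profile an [intensity_profile()].
#' @param channel_a,channel_b channel names.
#' @param thresholds a [profile_thresholds()].
#' @return data.frame with columns `start` and `end` (nm); zero rows when
#'   the presence regions do not intersect.
#' @export
overlap_intervals <- function(profile, channel_a, channel_b,
                              thresholds = profile_thresholds()) {
  a <- normalized_values(profile, channel_a)
  b <- normalized_values(profile, channel_b)
  both <- pmin(a, b)
  intervals_above(profile$position_nm, both, thresholds$presence_fraction)
}

intervals_above <- function(x, y, level) {
  cr <- threshold_crossings(x, y, level)
  starts <- cr$position[cr$direction == "rising"]
  ends <- cr$position[cr$direction == "falling"]
  if (y[1L] >= level) starts <- c(x[1L], starts)
  if (y[length(y)] >= level) ends <- c(ends, x[length(x)])
  if (length(starts) == 0L || length(ends) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = starts, end = ends)
}

#' Detect peaks in a profile channel
#'
#' Strict local maxima of the min-max-normalized channel after 3-point
#' moving-average smoothing, kept when the (unsmoothed) normalized value
#' reaches `presence_fraction` and the peak's topographic prominence on the
#' smoothed curve reaches `min_prominence` — the prominence filter rejects
#' noise wiggles riding on the shoulder of a larger band.
#'
#' @param profile an [intensity_profile()].
#' @param channel channel name.
#' @param thresholds a [profile_thresholds()].
#' @param smooth_width moving-average width in samples (default 3).
#' @param min_prominence minimum prominence on the normalized scale.
#' @return data.frame with columns `position` (nm) and `height` (normalized).
#' @export
find_peaks <- function(profile, channel, thresholds = profile_thresholds(),
                       smooth_width = 3L, min_prominence = 0.1) {
  y <- normalized_values(profile, channel)
  ys <- as.numeric(smooth_ma(y, smooth_width))
  idx <- local_maxima(ys)
  idx <- idx[y[idx] >= thresholds$presence_fraction]
  idx <- idx[peak_prominence(ys, idx) >= min_prominence]
  data.frame(position = profile$position_nm[idx], height = y[idx])
}

#' Topographic prominence of peaks in a sampled curve
#'
#' For each peak, the minimum descent required on either side before
#' reaching higher terrain (or the end of the signal); the prominence is
#' the peak height minus the higher of the two side minima.
#'
#' @param y numeric vector.
#' @param idx integer indices of local maxima in `y`.
#' @return numeric prominences.
#' @noRd
peak_prominence <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    h <- y[i]
    side_base <- function(step) {
      j <- i + step
      m <- h
      while (j >= 1L && j <= n && y[j] <= h) {
        m <- min(m, y[j])
        j <- j + step
      }
      m
    }
    h - max(side_base(-1L), side_base(1L))
  }, numeric(1))
}

#' Sarcomere length and Z-disc width from the alpha-actinin channel
#'
#' Sarcomere length is the mean spacing of consecutive actinin peaks;
#' Z-disc width is the full width at half maximum (FWHM) of the central
#' actinin band, with half-max crossings located by linear interpolation.
#'
#' @param profile an [intensity_profile()].
#' @param actinin_channel channel name, default `"actinin"`.
#' @param thresholds a [profile_thresholds()].
#' @return list with `sarcomere_length_um`, `zdisc_width_nm`,
#'   `peak_positions_nm`.
#' @export
measure_sarcomere <- function(profile, actinin_channel = "actinin",
                              thresholds = profile_thresholds()) {
  peaks <- find_peaks(profile, actinin_channel, thresholds)
  if (nrow(peaks) < 2L) {
    stop_input("fewer than 2 detectable peaks in channel '%s'", actinin_channel)
  }
  sl_um <- mean(diff(peaks$position)) / 1000
  center <- mean(range(profile$position_nm))
  central <- peaks$position[which.min(abs(peaks$position - center))]
  list(sarcomere_length_um = sl_um,
       zdisc_width_nm = band_fwhm(profile, actinin_channel, central),
       peak_positions_nm = peaks$position)
}

#' Half-maximum edges of the band around a peak
#'
#' Positions where the min-max-normalized channel crosses 0.5 on either
#' side of `peak_position`, located by linear interpolation.
#'
#' @param profile an [intensity_profile()].
#' @param channel channel name.
#' @param peak_position position (nm) of the band's peak.
#' @return numeric `c(left, right)` in nm.
#' @export
band_halfmax_edges <- function(profile, channel, peak_position) {
  y <- normalized_values(profile, channel)
  x <- profile$position_nm
  cr <- threshold_crossings(x, y, 0.5)
  left <- cr$position[cr$direction == "rising" & cr$position <= peak_position]
  right <- cr$position[cr$direction == "falling" & cr$position >= peak_position]
  if (length(left) == 0L || length(right) == 0L) {
    stop_input("cannot bracket the band at %g nm at half maximum", peak_position)
  }
  c(max(left), min(right))
}

band_fwhm <- function(profile, channel, peak_position) {
  diff(band_halfmax_edges(profile, channel, peak_position))
}

#' Displacement of the secondary biotin hotspot from the Z-disc edge
#'
#' Among detected biotin peaks, the global maximum is taken as the primary
#' band; the secondary hotspot is the highest remaining peak at or outside
#' the Z-disc edge interval. The displacement is its distance to the nearer
#' edge, positive outward and 0 for a peak exactly at the edge.
#'
#' @param profile an [intensity_profile()].
#' @param biotin_channel channel name, default `"biotin"`.
#' @param zdisc_edges numeric length-2 vector: the Z-disc edge positions
#'   (nm), e.g. from [find_edges()] on the actinin channel.
#' @param thresholds a [profile_thresholds()].
#' @return displacement in nm, or `NA_real_` when no secondary peak exists
#'   outside the Z-disc (distinguishable from a true 0).
#' @export
hotspot_displacement <- function(profile, biotin_channel = "biotin", zdisc_edges,
                                 thresholds = profile_thresholds()) {
  if (length(zdisc_edges) != 2L) stop_input("zdisc_edges must have length 2")
  zdisc_edges <- sort(as.numeric(zdisc_edges))
  peaks <- find_peaks(profile, biotin_channel, thresholds)
  if (nrow(peaks) == 0L) return(NA_real_)
  primary <- which.max(peaks$height)
  cand <- peaks[-primary, , drop = FALSE]
  half_px <- profile$pixel_nm / 2
  outside <- cand$position <= zdisc_edges[1L] + half_px |
    cand$position >= zdisc_edges[2L] - half_px
  cand <- cand[outside, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_real_)
  sec <- cand[which.max(cand$height), ]
  max(0, min(abs(sec$position - zdisc_edges)))
}

#' Restrict a profile to a position window
#'
#' @param profile an [intensity_profile()].
#' @param min_nm,max_nm window bounds in nm (closed interval).
#' @return the windowed [intensity_profile()].
#' @export
window_profile <- function(profile, min_nm, max_nm) {
  keep <- profile$position_nm >= min_nm & profile$position_nm <= max_nm
  if (sum(keep) < 2L) stop_input("window contains fewer than 2 samples")
  intensity_profile(profile$position_nm[keep],
                    lapply(profile$channels, function(v) v[keep]),
                    profile$metadata)
}

#' Average profiles after registration to the dominant actinin peak
#'
#' Each profile is translated so its highest reference-channel peak sits at
#' position 0; profiles must share the pixel size and fall on a common grid
#' after registration. Pointwise mean, standard error of the mean and the
#' number of contributing traces are returned per position and channel.
#'
#' @param profiles list of [intensity_profile()] objects.
#' @param reference_channel channel used for registration, default
#'   `"actinin"`.
#' @return an `averaged_trace` data.frame with columns `position_nm`,
#'   `channel`, `mean`, `sem`, `n`.
#' @export
average_profiles <- function(profiles, reference_channel = "actinin") {
  if (length(profiles) == 0L) stop_input("no profiles to average")
  px <- vapply(profiles, function(p) p$pixel_nm, numeric(1))
  if (max(px) - min(px) > 1e-6 * mean(px)) {
    stop_input("profiles have mismatched pixel sizes")
  }
  pixel <- mean(px)
  shifted <- lapply(profiles, function(p) {
    pk <- find_peaks(p, reference_channel)
    if (nrow(pk) == 0L) stop_input("no reference peak found for registration")
    shift <- pk$position[which.max(pk$height)]
    list(position = p$position_nm - shift, channels = p$channels)
  })
  # registered grids must line up on a common lattice
  offsets <- vapply(shifted, function(s) (s$position[1L] / pixel) %% 1, numeric(1))
  offsets <- pmin(offsets, 1 - offsets)
  if (any(offsets > 1e-6)) stop_input("profile grids are mismatched after registration")

  idx_list <- lapply(shifted, function(s) as.integer(round(s$position / pixel)))
  all_idx <- sort(unique(unlist(idx_list)))
  channels <- names(profiles[[1L]]$channels)
  out <- list()
  for (ch in channels) {
    acc_sum <- acc_sq <- acc_n <- numeric(length(all_idx))
    for (k in seq_along(shifted)) {
      pos <- match(idx_list[[k]], all_idx)
      v <- shifted[[k]]$channels[[ch]]
      acc_sum[pos] <- acc_sum[pos] + v
      acc_sq[pos] <- acc_sq[pos] + v^2
      acc_n[pos] <- acc_n[pos] + 1
    }
    mean_v <- acc_sum / acc_n
    var_v <- ifelse(acc_n > 1, pmax(acc_sq - acc_n * mean_v^2, 0) / (acc_n - 1), NA_real_)
    out[[ch]] <- data.frame(position_nm = all_idx * pixel, channel = ch,
                            mean = mean_v, sem = sqrt(var_v / acc_n),
                            n = as.integer(acc_n), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("averaged_trace", "data.frame"))
}

#' Write profiles to CSV (position_nm plus one column per channel)
#'
#' @param profile an [intensity_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position_nm = profile$position_nm)
  for (ch in names(profile$channels)) df[[ch]] <- profile$channels[[ch]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile from CSV written by [write_profile()]
#'
#' @param path CSV path with a `position_nm` column and one column per
#'   channel.
#' @param metadata optional metadata list to attach.
#' @return an [intensity_profile()].
#' @export
read_profile <- function(path, metadata = list()) {
  df <- utils::read.csv(path)
  if (!"position_nm" %in% names(df)) stop_input("%s: no position_nm column", path)
  intensity_profile(df$position_nm, df[setdiff(names(df), "position_nm")],
                    metadata)
}
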