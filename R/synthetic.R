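# Synthetic two-regime multichannel signal generator.  Emulates the broad
# structure of awake vs. anesthetized cortical recordings: band-limited
# oscillations whose power differs by regime in all but the visual
# regions -- anesthesia adds dominant slow waves and attenuates fast
# desynchronized activity, raising total power -- with per-individual
# gain and spectral-tilt variation and AR(1) background noise.
# Amplitudes are in microvolt-equivalent units so the standard
# preprocessing chain applies unchanged.

#' Regime parameters for the synthetic generator
#'
#' @param label regime label ("awake" or "anesthetized").
#' @param n_regions number of regions.
#' @param freqs oscillation band center frequencies (Hz).
#' @param base_amp per-band base amplitudes (microvolts) for the awake
#'   regime.
#' @param anes_gain per-band multiplicative power gain of the
#'   anesthetized regime in non-visual regions (scalar recycled). The
#'   default makes slow waves dominant while fast desynchronized
#'   activity attenuates -- the signature of dissociative anesthesia --
#'   with total power roughly doubled.
#' @param visual_regions indices of regions where the regime difference is
#'   small (gain ~ 1).
#' @param noise_sd AR(1) innovation SD (microvolts).
#' @param ar smoothness coefficient of the AR(1) background.
#' @export
regime_params <- function(label = c("awake", "anesthetized"),
                          n_regions = 2, freqs = c(4, 20, 45),
                          base_amp = c(25, 110, 60),
                          anes_gain = c(25, 1.3, 0.35),
                          visual_regions = n_regions, noise_sd = 25,
                          ar = 0.95) {
  label <- match.arg(label)
  stopifnot(all(base_amp >= 0), noise_sd > 0, length(freqs) ==
              length(base_amp))
  anes_gain <- rep_len(anes_gain, length(freqs))
  amp <- matrix(rep(base_amp, n_regions), nrow = n_regions, byrow = TRUE)
  if (label == "anesthetized") {
    for (n in seq_len(n_regions)) {
      g <- if (n %in% visual_regions) rep(1.05, length(freqs))
           else sqrt(anes_gain)  # power gain -> amplitude gain
      amp[n, ] <- amp[n, ] * g
    }
  }
  structure(list(label = label, n_regions = n_regions, freqs = freqs,
                 amp = amp, noise_sd = noise_sd, ar = ar),
            class = "regime_params")
}

#' Individual parameters for the synthetic generator
#'
#' Per-channel gain multipliers and a spectral tilt, drawn once per
#' individual from a seeded stream; gain spread is kept smaller than the
#' regime power difference so individuality is a secondary factor.
#'
#' @param id individual identifier.
#' @param n_channels total channel count.
#' @param gain_sd log-normal SD of per-channel gains.
#' @param tilt spectral tilt: multiplies band b amplitude by
#'   \code{exp(tilt * (b - mean(b)))}.
#' @param seed RNG seed.
#' @export
individual_params <- function(id, n_channels, gain_sd = 0.08,
                              tilt = NULL, seed = 1L) {
  set.seed(seed)
  gains <- exp(rnorm(n_channels, 0, gain_sd))
  if (is.null(tilt)) tilt <- rnorm(1, 0, 0.05)
  structure(list(id = id, gains = gains, tilt = tilt, seed = seed),
            class = "individual_params")
}

#' Generate one synthetic multichannel sequence
#'
#' Each channel is a sum of band-limited oscillations with randomized
#' phases and slow random amplitude modulation, plus AR(1) noise, scaled
#' by the individual's channel gains.
#'
#' @param regime a \code{regime_params}.
#' @param individual an \code{individual_params}.
#' @param length_steps sequence length in time steps.
#' @param channels_per_region channels per region.
#' @param rate sampling rate (Hz).
#' @param seed RNG seed for this sequence.
#' @param region_names optional region labels.
#' @return a \code{signal_sequence} in microvolt-equivalent units.
#' @export
generate_sequence <- function(regime, individual, length_steps = 2000,
                              channels_per_region = 2, rate = 1000,
                              seed = 1L, region_names = NULL) {
  stopifnot(length_steps >= 1)
  set.seed(seed)
  R <- regime$n_regions
  C <- channels_per_region
  nch <- R * C
  if (length(individual$gains) != nch)
    stop("individual gains sized for a different channel count")
  if (is.null(region_names))
    region_names <- if (R <= length(CANONICAL_REGIONS))
      CANONICAL_REGIONS[seq_len(R)] else paste0("R", seq_len(R))
  tt <- seq_len(length_steps) / rate
  nb <- length(regime$freqs)
  bmid <- (nb + 1) / 2
  v <- matrix(0, nch, length_steps)
  for (n in seq_len(R)) {
    # oscillatory dynamics are a property of the region: channels of the
    # same region share phases and amplitude modulation (same-region
    # electrodes are strongly correlated), with small per-channel phase
    # offsets, individual gains and independent background noise
    osc <- matrix(0, C, length_steps)
    for (b in seq_len(nb)) {
      amp <- regime$amp[n, b] * exp(individual$tilt * (b - bmid))
      phase <- runif(1, 0, 2 * pi)
      # slow amplitude modulation so the signal is not a pure tone
      am <- 1 + 0.25 * sin(2 * pi * runif(1, 0.3, 1.2) * tt +
                             runif(1, 0, 2 * pi))
      jitter <- rnorm(C, 0, 0.2)
      for (c0 in seq_len(C))
        osc[c0, ] <- osc[c0, ] + amp * am *
          sin(2 * pi * regime$freqs[b] * tt + phase + jitter[c0])
    }
    for (c0 in seq_len(C)) {
      ch <- (n - 1) * C + c0
      noise <- as.numeric(
        stats::arima.sim(list(ar = regime$ar), length_steps,
                         sd = regime$noise_sd * sqrt(1 - regime$ar^2)))
      v[ch, ] <- (osc[c0, ] + noise) * individual$gains[ch]
    }
  }
  signal_sequence(v, sampling_rate = rate,
                  condition = if (regime$label == "anesthetized")
                    "anesthetized" else "awake",
                  individual = individual$id,
                  region_map = rep(region_names, each = C))
}

#' Generate a multi-individual two-regime cohort with CV folds
#'
#' Builds per-individual pools of awake and anesthetized sequences and a
#' leave-one-individual-out fold structure (each fold trains on all but
#' one individual and tests on the held-out one).
#'
#' @param n_individuals number of individuals.
#' @param n_per_condition sequences per condition per individual.
#' @param n_regions,channels_per_region,length_steps,rate generator
#'   geometry.
#' @param regimes optional list with elements \code{awake} and
#'   \code{anesthetized} (\code{regime_params}).
#' @param seed master seed; all per-sequence seeds derive from it.
#' @return list with \code{pools} (individual -> condition -> sequences)
#'   and \code{folds} (list of \code{train_individuals} /
#'   \code{test_individual}).
#' @export
generate_cohort <- function(n_individuals = 4, n_per_condition = 12,
                            n_regions = 2, channels_per_region = 2,
                            length_steps = 2000, rate = 1000,
                            regimes = NULL, seed = 1L) {
  if (is.null(regimes))
    regimes <- list(
      awake = regime_params("awake", n_regions = n_regions),
      anesthetized = regime_params("anesthetized", n_regions = n_regions))
  nch <- n_regions * channels_per_region
  inds <- paste0("I", seq_len(n_individuals))
  pools <- list()
  k <- 0L
  for (i in seq_len(n_individuals)) {
    ip <- individual_params(inds[i], nch, seed = seed * 1000L + i)
    pools[[inds[i]]] <- list()
    for (cond in c("awake", "anesthetized")) {
      pool <- vector("list", n_per_condition)
      for (j in seq_len(n_per_condition)) {
        k <- k + 1L
        pool[[j]] <- generate_sequence(regimes[[cond]], ip,
                                       length_steps = length_steps,
                                       channels_per_region =
                                         channels_per_region,
                                       rate = rate,
                                       seed = seed * 100000L + k)
      }
      pools[[inds[i]]][[cond]] <- pool
    }
  }
  folds <- lapply(seq_len(n_individuals), function(i)
    list(train_individuals = inds[-i], test_individual = inds[i]))
  list(pools = pools, folds = folds, regimes = regimes)
}

#' Preprocess a raw synthetic (or recorded) sequence for modeling
#'
#' Applies the standard chain in order: common-median re-reference,
#' outlier-bin exclusion, linear normalization into (-0.8, 0.8).
#'
#' @param seq a \code{signal_sequence} in microvolt units.
#' @param bin,thresh outlier-exclusion parameters.
#' @export
preprocess_sequence <- function(seq, bin = 2000, thresh = 8) {
  s <- rereference_common_median(seq)
  ex <- exclude_outlier_bins(s, bin = bin, thresh = thresh)
  s2 <- preserve_attrs(ex$values, s, "outlier_exclusion")
  normalize_linear(s2)
}
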