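# Desk-scale study preset: the reduced geometry on which the packaged
# tests and the acceptance script exercise the full pipeline.  One place
# defines the conditions so every consumer sees the same study.

#' Desk-scale two-regime self-consistency study
#'
#' Generates the synthetic cohort and assembles the training set, a
#' regime-transition stream, and the matching network architecture.
#' Geometry: 2 regions x 2 channels (the second region "visual", i.e.
#' nearly regime-invariant), 250 Hz sampling, 500-step training
#' sequences, 4 per condition from one individual; the transition stream
#' crossfades unseen awake and anesthetized sequences of the same
#' individual (a second individual's pools remain available for
#' discriminator training and generalization checks). The meta-prior
#' keeps the reference value 0.001 at all levels (see the methods
#' vignette on the reconstruction/KL balance and on why the desk study
#' is single-individual).
#'
#' @param seed master seed; all generation derives from it.
#' @param n_updates training updates bundled with the preset.
#' @return list with \code{spec}, \code{train} (preprocessed sequences),
#'   \code{transition} (regime-switch stream, switch recorded in its
#'   metadata), \code{cohort}, and the preset's training/assimilation
#'   settings.
#' @export
desk_study <- function(seed = 1L, n_updates = 10000) {
  regimes <- list(
    awake = regime_params("awake", n_regions = 2),
    anesthetized = regime_params("anesthetized", n_regions = 2))
  cohort <- generate_cohort(n_individuals = 2, n_per_condition = 5,
                            n_regions = 2, channels_per_region = 2,
                            length_steps = 500, rate = 250,
                            regimes = regimes, seed = seed + 41L)
  train <- list()
  for (cond in c("awake", "anesthetized"))
    for (sq in cohort$pools[["I1"]][[cond]][1:4])
      train <- c(train, list(preprocess_sequence(sq)))
  # unseen sequences of the same individual, crossfaded at the switch
  a <- preprocess_sequence(cohort$pools[["I1"]]$awake[[5]])
  b <- preprocess_sequence(cohort$pools[["I1"]]$anesthetized[[5]])
  transition <- crossfade_concat(a, b, taper_ms = 30)
  spec <- network_spec(n_regions = 2, channels_per_region = 2, q1 = 1,
                       q2 = 2, q3 = 2, p1 = 8, p2 = 8, tau1 = 2,
                       tau2 = 4, meta_prior = 0.001)
  list(spec = spec, train = train, transition = transition,
       cohort = cohort, n_updates = n_updates, H = 100L, K = 20L,
       disc = list(segment_ms = 500, fmax = 100, kernel = c(2, 7, 11),
                   n_filters = 4, n_updates = 300),
       seed = as.integer(seed))
}

#' Global-latent reference clusters from a trained model
#'
#' Collects the posterior mean of the sequence-constant global latent of
#' every training sequence, labeled by its condition — the reference set
#' against which assimilated latent states are classified.
#'
#' @param model a trained \code{vrnn} (posteriors stored).
#' @param dataset the training sequences (for the labels).
#' @return list with \code{points} (sequences x q3 matrix) and
#'   \code{labels}.
#' @export
training_reference <- function(model, dataset) {
  spec <- model$spec
  pts <- t(vapply(seq_along(model$posterior), function(s) {
    a <- alpha_unpack(spec, model$posterior[[s]],
                      ncol(sequence_values(dataset[[s]])))
    tanh(clamp_num(a$a3mu, spec$clamp))
  }, numeric(spec$q3)))
  labels <- vapply(dataset, function(sq)
    attr(sq, "condition") %||% "unknown", character(1))
  list(points = pts, labels = labels)
}
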