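# Virtual interventions: clamp condition-specific posterior latent states
# at chosen levels while the remaining latents generate from their priors.

#' Estimate condition-specific latent posteriors (fixed window)
#'
#' Full-sequence posterior estimation with frozen weights: the window is
#' fixed at the sequence length so the global latent stays constant and
#' abstracts the whole sequence. One repertoire entry is produced per
#' sequence, keyed by its condition and individual labels.
#'
#' @param model a trained \code{vrnn}.
#' @param sequences list of labeled \code{signal_sequence}s.
#' @param n_updates posterior update iterations (reference setting:
#'   10,000 with H fixed at 2,000).
#' @param optimizer an \code{optimizer_config}.
#' @param sample draw latent noise during optimization.
#' @param seed RNG seed.
#' @return a \code{latent_repertoire}: list of entries with per-level
#'   posterior trajectories (z3 constant) and final deterministic states.
#' @export
estimate_condition_latents <- function(model, sequences, n_updates = 2000,
                                       optimizer = optimizer_config(),
                                       sample = TRUE, seed = 1L) {
  spec <- model$spec
  entries <- list()
  for (s in seq_along(sequences)) {
    sq <- sequences[[s]]
    cond <- attr(sq, "condition")
    if (is.null(cond)) stop("sequence ", s, " has no condition label")
    m <- model
    m$posterior <- list()
    m <- train_vrnn(m, list(sq), n_updates = n_updates,
                    optimizer = optimizer, sample = sample,
                    freeze_weights = TRUE, trace_every = n_updates,
                    seed = seed + s)
    v <- sequence_values(sq)
    T <- ncol(v)
    a <- alpha_unpack(spec, m$posterior[[1]], T)
    fw <- pv_forward(unclass(spec), model$theta, m$posterior[[1]], v,
                     zero_eps(spec, T), TRUE, empty_init(spec), FALSE)
    entries[[s]] <- list(
      condition = cond, individual = attr(sq, "individual"), id = s,
      length = T,
      z3_mu = drop(fw$qm3), z3_sigma = drop(fw$qs3),
      z2_mu = fw$qm2, z2_sigma = fw$qs2,
      z1_mu = fw$qm1, z1_sigma = fw$qs1,
      alpha = m$posterior[[1]], final_loss = fw$loss)
  }
  structure(list(entries = entries, spec = spec),
            class = "latent_repertoire")
}

#' @export
print.latent_repertoire <- function(x, ...) {
  conds <- vapply(x$entries, `[[`, character(1), "condition")
  cat(sprintf("<latent_repertoire> %d entries (%s)\n", length(conds),
              paste(names(table(conds)), table(conds), sep = ":",
                    collapse = ", ")))
  invisible(x)
}

#' Specify a virtual intervention
#'
#' \code{clamp} names which latent levels replay which repertoire entries:
#' \itemize{
#'   \item \code{z3 = entry} clamps the global latent (virtual drug
#'     administration when combined with free lower levels);
#'   \item \code{z2 = list(entry =, units =)} clamps selected network-level
#'     units (functional-network intervention);
#'   \item \code{z1 = list(entry =, regions =)} clamps the local latents of
#'     selected regions (region-targeted intervention).
#' }
#' Unclamped units generate from their priors.
#'
#' @param clamp named list as above; entries are indices into the
#'   repertoire or entry objects themselves.
#' @param duration generated length in steps; defaults to the clamped
#'   trajectory length.
#' @param sample_clamped replay by sampling from the stored posterior
#'   distributions (the default; FALSE injects posterior means).
#'   Mean injection suppresses the stochastic power component of the
#'   generated signals, which matters when a power-sensitive
#'   discriminator evaluates them.
#' @param seed RNG seed for free-unit prior draws.
#' @export
intervention_spec <- function(clamp, duration = NULL,
                              sample_clamped = TRUE, seed = 1L) {
  structure(list(clamp = clamp, duration = duration,
                 sample_clamped = sample_clamped, seed = as.integer(seed)),
            class = "intervention_spec")
}

resolve_entry <- function(repertoire, e) {
  if (is.list(e) && !is.null(e$z3_mu)) e
  else repertoire$entries[[e]]
}

#' Generate a virtual signal sequence under an intervention
#'
#' Clamped latent units replay the stored posterior (the constant global
#' latent, or time-varying network/local trajectories); free units sample
#' from their top-down priors with a fresh seeded stream.
#'
#' @param model a trained \code{vrnn}.
#' @param repertoire a \code{latent_repertoire}.
#' @param spec_iv an \code{intervention_spec}.
#' @param rate sampling rate recorded on the generated sequence (Hz).
#' @return a \code{signal_sequence} of generated (normalized-scale)
#'   signals with the latent trajectories attached as attributes.
#' @export
intervene_generate <- function(model, repertoire, spec_iv, rate = 1000) {
  spec <- model$spec
  Rq <- spec$n_regions * spec$q1
  cl <- spec_iv$clamp
  lens <- integer(0)
  get_len <- function(e) resolve_entry(repertoire, e)$length
  if (!is.null(cl$z2)) lens <- c(lens, get_len(cl$z2$entry))
  if (!is.null(cl$z1)) lens <- c(lens, get_len(cl$z1$entry))
  duration <- spec_iv$duration
  if (is.null(duration))
    duration <- if (length(lens)) min(lens) else
      if (!is.null(cl$z3)) resolve_entry(repertoire, cl$z3)$length else
        stop("duration required when nothing time-varying is clamped")
  if (length(lens) && any(lens < duration))
    stop("clamped trajectory shorter than requested duration")
  set.seed(spec_iv$seed)
  rs <- function(mu, sg) if (spec_iv$sample_clamped)
    mu + sg * rnorm(length(mu)) else mu
  m3 <- rep(0, spec$q3); z3c <- rep(0, spec$q3)
  m2 <- matrix(0, spec$q2, duration); z2c <- m2
  m1 <- matrix(0, Rq, duration); z1c <- m1
  if (!is.null(cl$z3)) {
    e <- resolve_entry(repertoire, cl$z3)
    m3[] <- 1
    z3c <- rs(e$z3_mu, e$z3_sigma)
  }
  if (!is.null(cl$z2)) {
    e <- resolve_entry(repertoire, cl$z2$entry)
    units <- cl$z2$units
    if (is.null(units)) units <- seq_len(spec$q2)
    m2[units, ] <- 1
    z2c[units, ] <- rs(e$z2_mu[units, seq_len(duration), drop = FALSE],
                       e$z2_sigma[units, seq_len(duration), drop = FALSE])
  }
  if (!is.null(cl$z1)) {
    e <- resolve_entry(repertoire, cl$z1$entry)
    regions <- cl$z1$regions
    if (is.null(regions)) regions <- seq_len(spec$n_regions)
    if (is.character(regions))
      regions <- match(regions, spec$region_names)
    rows <- as.vector(vapply(regions, function(n)
      as.integer((n - 1) * spec$q1 + seq_len(spec$q1)),
      integer(spec$q1)))
    m1[rows, ] <- 1
    z1c[rows, ] <- rs(e$z1_mu[rows, seq_len(duration), drop = FALSE],
                      e$z1_sigma[rows, seq_len(duration), drop = FALSE])
  }
  eps <- draw_eps(spec, duration)
  gen <- pv_generate(unclass(spec), model$theta, duration, eps, TRUE,
                     empty_init(spec), m3, z3c, m2, z2c, m1, z1c)
  out <- signal_sequence(gen$xhat, sampling_rate = rate,
                         condition = "mixed", individual = "virtual",
                         region_map = rep(spec$region_names,
                                          each = spec$channels_per_region))
  attr(out, "latents") <- list(z3 = drop(gen$z3), z2 = gen$z2,
                               z1 = gen$z1)
  attr(out, "clamped") <- list(m3 = m3, m2 = m2[, 1], m1 = m1[, 1])
  out
}

#' Evaluate interventions with a discriminator
#'
#' For each clamp target, generates virtual sequences over the repertoire
#' entries of the source condition and reports the proportion classified
#' into the intervention's target condition. A global-state ("z3")
#' intervention inputs the stored posteriors of all three levels (the
#' constant z3 together with the z2 and z1 trajectories), simulating
#' whole-brain drug administration; network ("z2") and region ("z1")
#' interventions clamp only the target units to the source condition,
#' set z3 to the background condition, and leave all other latents
#' prior-driven.
#'
#' @param model a trained \code{vrnn}.
#' @param repertoire a \code{latent_repertoire}.
#' @param discriminator a trained condition classifier, or a function
#'   taking a list of sequences and returning per-segment labels.
#' @param targets list of target descriptions: each a list with
#'   \code{level} ("z3", "z2" or "z1"), optional \code{units} /
#'   \code{regions}, \code{source_condition} (condition whose posterior is
#'   injected) and optional \code{z3_condition} for the background global
#'   state.
#' @param n_draws generated sequences per repertoire entry.
#' @param segment_ms spectrogram segmentation passed to the discriminator.
#' @param rate sampling rate of the generated sequences (Hz).
#' @param seed RNG seed.
#' @return data.frame: target, source condition, mean and SD of the
#'   proportion classified as the source condition.
#' @export
evaluate_intervention <- function(model, repertoire, discriminator,
                                  targets, n_draws = 3,
                                  segment_ms = NULL, rate = 1000,
                                  seed = 1L) {
  conds <- vapply(repertoire$entries, `[[`, character(1), "condition")
  rows <- list()
  for (tg in targets) {
    src_ids <- which(conds == tg$source_condition)
    if (!length(src_ids)) stop("no repertoire entry for condition ",
                               tg$source_condition)
    props <- numeric(0)
    for (id in src_ids) {
      hits <- 0L; tot <- 0L
      for (dr in seq_len(n_draws)) {
        cl <- list()
        if (tg$level == "z3") {
          cl$z3 <- id
          cl$z2 <- list(entry = id)
          cl$z1 <- list(entry = id)
        } else {
          # background global state from a different condition
          bg_cond <- if (!is.null(tg$z3_condition)) tg$z3_condition else
            setdiff(unique(conds), tg$source_condition)[1]
          bg_ids <- which(conds == bg_cond)
          cl$z3 <- bg_ids[1 + (dr - 1) %% length(bg_ids)]
          if (tg$level == "z2")
            cl$z2 <- list(entry = id, units = tg$units)
          if (tg$level == "z1")
            cl$z1 <- list(entry = id, regions = tg$regions)
        }
        iv <- intervention_spec(cl, seed = seed + 1000 * id + dr)
        virt <- intervene_generate(model, repertoire, iv, rate = rate)
        labs <- if (is.function(discriminator)) discriminator(list(virt))
        else classify_sequences(discriminator, list(virt),
                                segment_ms = segment_ms)$labels
        hits <- hits + sum(labs == tg$source_condition)
        tot <- tot + length(labs)
      }
      props <- c(props, hits / tot)
    }
    rows[[length(rows) + 1]] <- data.frame(
      target = tg$name %||% tg$level, level = tg$level,
      source_condition = tg$source_condition,
      proportion = mean(props), sd = sd(props), n_entries = length(src_ids))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
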