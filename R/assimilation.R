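slice3 <- function(arr, t)
  matrix(arr[, , t], nrow = dim(arr)[1], ncol = dim(arr)[2])

# Sliding-window data assimilation: weights frozen, posterior adaptive
# states optimized inside a window that advances one step per incoming
# observation.  Steps that have left the window are frozen; the stored
# deterministic states at the step before the window start seed each
# window's forward pass.

#' Assimilation configuration
#'
#' @param H window length in steps (reference setting: 500; fixed-window
#'   posterior estimation uses the sequence length).
#' @param K posterior update iterations per incoming step (reference: 100).
#' @param optimizer an \code{optimizer_config}.
#' @param seed RNG seed for the latent noise stream.
#' @export
assimilation_config <- function(H = 500, K = 100,
                                optimizer = optimizer_config(),
                                seed = 1L) {
  stopifnot(H >= 1, K >= 0)
  structure(list(H = as.integer(H), K = as.integer(K),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "assimilation_config")
}

# initialize the adaptive state of a new step so its posterior equals the
# prior computed from the previous step's deterministic output (the
# clamped pre-activations ARE the adaptive states under tanh/exp).
prior_handoff <- function(spec, theta, d2_prev, d1_prev) {
  cl <- spec$clamp
  scl <- spec$sigma_clamp
  a2mu <- clamp_num(drop(theta_block(spec, theta, "P2mu") %*% d2_prev), cl)
  a2sg <- clamp_num(drop(theta_block(spec, theta, "P2sg") %*% d2_prev),
                    scl)
  Rq <- spec$n_regions * spec$q1
  a1mu <- a1sg <- numeric(Rq)
  for (n in seq_len(spec$n_regions)) {
    r <- spec$region_names[n]
    rs <- (n - 1) * spec$q1 + seq_len(spec$q1)
    a1mu[rs] <- clamp_num(drop(theta_block(spec, theta,
                                           paste0("P1mu.", r)) %*%
                                 d1_prev[, n]), cl)
    a1sg[rs] <- clamp_num(drop(theta_block(spec, theta,
                                           paste0("P1sg.", r)) %*%
                                 d1_prev[, n]), scl)
  }
  # atanh(tanh(a)) == a inside the clamp: storing pre-activations directly
  list(a2mu = a2mu, a2sg = a2sg, a1mu = a1mu, a1sg = a1sg)
}

#' Real-time sliding-window data assimilation
#'
#' For each incoming step t: (1) the posterior at t is initialized from
#' the prior computed off the previous step's posterior pass; (2-6) K
#' alternations of top-down window prediction and gradient updates of the
#' adaptive states over the window minimizing the summed free energy.
#' Weights stay fixed throughout. At the start of the stream the window
#' grows from 1 to H. An incoming step therefore accumulates H*K update
#' iterations by the time it leaves a full window.
#'
#' @param model a trained \code{vrnn}.
#' @param stream a \code{signal_sequence} (channels x time, normalized).
#' @param cfg an \code{assimilation_config}.
#' @return an \code{assimilation_trace}: per-step summary data.frame
#'   (\code{$steps}), posterior mean/sd trajectories per level, post-hoc
#'   and prior predictions, update counts and final states.
#' @export
assimilate <- function(model, stream, cfg = assimilation_config()) {
  spec <- model$spec
  x <- sequence_values(stream)
  T <- ncol(x)
  if (T < 1) stop("stream must contain at least one step")
  if (nrow(x) != n_channels(spec))
    stop("stream channel count does not match the model")
  H <- cfg$H; K <- cfg$K
  set.seed(cfg$seed)
  theta0 <- model$theta
  Rq <- spec$n_regions * spec$q1
  # full-sequence adaptive states and aligned optimizer moments
  a <- list(a3mu = numeric(spec$q3), a3sg = numeric(spec$q3),
            a2mu = matrix(0, spec$q2, T), a2sg = matrix(0, spec$q2, T),
            a1mu = matrix(0, Rq, T), a1sg = matrix(0, Rq, T))
  mom_m <- rapply(a, function(z) z * 0, how = "replace")
  mom_v <- rapply(a, function(z) z * 0, how = "replace")
  n_opt <- 0L
  # stored deterministic states from the last pass containing each step
  h2s <- matrix(0, spec$p2, T); d2s <- matrix(0, spec$p2, T)
  h1s <- array(0, c(spec$p1, spec$n_regions, T)); d1s <- h1s
  xhat_post <- xhat_prior <- matrix(0, nrow(x), T)
  z3mu <- matrix(0, spec$q3, T); z3sg <- matrix(0, spec$q3, T)
  z2mu <- matrix(0, spec$q2, T); z1mu <- matrix(0, Rq, T)
  update_counts <- integer(T)
  F_before <- F_after <- recon_err <- numeric(T)
  opt <- cfg$optimizer

  for (t in seq_len(T)) {
    t0 <- max(1L, t - H + 1L)
    L <- t - t0 + 1L
    first <- (t0 == 1L)
    # (1) prior handoff for the incoming step
    if (t == 1L) {
      # initial prior is N(0,1): adaptive states zero (already)
    } else {
      ph <- prior_handoff(spec, theta0, d2s[, t - 1], slice3(d1s, t - 1))
      a$a2mu[, t] <- ph$a2mu; a$a2sg[, t] <- ph$a2sg
      a$a1mu[, t] <- ph$a1mu; a$a1sg[, t] <- ph$a1sg
    }
    init <- if (first) empty_init(spec) else
      list(h2 = h2s[, t0 - 1], d2 = d2s[, t0 - 1],
           h1 = slice3(h1s, t0 - 1), d1 = slice3(d1s, t0 - 1))
    xw <- x[, t0:t, drop = FALSE]
    cols <- t0:t
    # free energy at iteration 0 (posterior means) + prior prediction of t
    fw0 <- pv_forward(unclass(spec), theta0,
                      alpha_pack(alpha_window(a, cols)), xw,
                      zero_eps(spec, L), first, init, FALSE)
    F_before[t] <- fw0$loss
    xhat_prior[, t] <- fw0$xhat[, L]
    # (2)-(6) K alternations of prediction and posterior update
    for (k in seq_len(K)) {
      eps <- draw_eps(spec, L)
      fw <- pv_forward(unclass(spec), theta0,
                       alpha_pack(alpha_window(a, cols)), xw, eps,
                       first, init, TRUE)
      if (!is.finite(fw$loss))
        stop(sprintf("non-finite free energy at step %d, iteration %d",
                     t, k))
      g <- alpha_unpack(spec, fw$galpha, L)
      n_opt <- n_opt + 1L
      upd <- function(aa, mm, vv, gg) {
        m <- opt$beta1 * mm + (1 - opt$beta1) * gg
        v <- opt$beta2 * vv + (1 - opt$beta2) * gg^2
        mhat <- m / (1 - opt$beta1^n_opt)
        rho_inf <- 2 / (1 - opt$beta2) - 1
        rho <- rho_inf - 2 * n_opt * opt$beta2^n_opt /
          (1 - opt$beta2^n_opt)
        if (!opt$rectify || rho > 4) {
          r <- if (opt$rectify)
            sqrt(((rho - 4) * (rho - 2) * rho_inf) /
                   ((rho_inf - 4) * (rho_inf - 2) * rho)) else 1
          aa <- aa - opt$alpha * r * mhat /
            (sqrt(v / (1 - opt$beta2^n_opt)) + opt$eps)
        } else aa <- aa - opt$alpha * mhat
        list(a = aa, m = m, v = v)
      }
      u <- upd(a$a3mu, mom_m$a3mu, mom_v$a3mu, g$a3mu)
      a$a3mu <- u$a; mom_m$a3mu <- u$m; mom_v$a3mu <- u$v
      u <- upd(a$a3sg, mom_m$a3sg, mom_v$a3sg, g$a3sg)
      a$a3sg <- u$a; mom_m$a3sg <- u$m; mom_v$a3sg <- u$v
      for (nm in c("a2mu", "a2sg", "a1mu", "a1sg")) {
        u <- upd(a[[nm]][, cols, drop = FALSE],
                 mom_m[[nm]][, cols, drop = FALSE],
                 mom_v[[nm]][, cols, drop = FALSE], g[[nm]])
        a[[nm]][, cols] <- u$a
        mom_m[[nm]][, cols] <- u$m
        mom_v[[nm]][, cols] <- u$v
      }
    }
    update_counts[cols] <- update_counts[cols] + K
    # final mean-field pass: record trace and freeze states
    fw <- pv_forward(unclass(spec), theta0,
                     alpha_pack(alpha_window(a, cols)), xw,
                     zero_eps(spec, L), first, init, FALSE)
    F_after[t] <- fw$loss
    xhat_post[, cols] <- fw$xhat
    h2s[, cols] <- fw$h2; d2s[, cols] <- fw$d2
    h1s[, , cols] <- fw$h1; d1s[, , cols] <- fw$d1
    z3mu[, t] <- fw$qm3; z3sg[, t] <- fw$qs3
    z2mu[, cols] <- fw$qm2
    z1mu[, cols] <- fw$qm1
    recon_err[t] <- sqrt(mean((fw$xhat[, L] - x[, t])^2))
  }

  steps <- data.frame(t = seq_len(T), recon_error = recon_err,
                      F_before = F_before, F_after = F_after,
                      update_count = update_counts)
  structure(list(
    steps = steps, x = x, xhat_post = xhat_post, xhat_prior = xhat_prior,
    z3_mu = z3mu, z3_sigma = z3sg, z2_mu = z2mu, z1_mu = z1mu,
    alpha = a, states = list(h2 = h2s, d2 = d2s, h1 = h1s, d1 = d1s),
    update_counts = update_counts, cfg = cfg,
    theta_unchanged = identical(theta0, model$theta),
    switch_time = attr(stream, "switch_time"),
    sampling_rate = attr(stream, "sampling_rate")
  ), class = "assimilation_trace")
}

#' @export
print.assimilation_trace <- function(x, ...) {
  cat(sprintf(
    "<assimilation_trace> %d steps | H=%d K=%d | final RMS error %.4f\n",
    nrow(x$steps), x$cfg$H, x$cfg$K, mean(tail(x$steps$recon_error, 50))))
  invisible(x)
}

#' Multi-step-ahead prediction by prior rollout
#'
#' Rolls the generative model forward from the assimilation state at step
#' t using priors only (no observations): the global latent is held at its
#' posterior mean, lower-level latents are drawn from (or set to the mean
#' of) their top-down priors.
#'
#' @param model a \code{vrnn}.
#' @param trace an \code{assimilation_trace}.
#' @param n_steps prediction horizon (>= 1).
#' @param from start step (defaults to the last assimilated step).
#' @param sample draw latent noise from the priors; FALSE uses prior means.
#' @param seed RNG seed used when \code{sample} is TRUE.
#' @return predicted channels x n_steps matrix.
#' @export
predict_ahead <- function(model, trace, n_steps, from = NULL,
                          sample = FALSE, seed = 1L) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  spec <- model$spec
  T <- nrow(trace$steps)
  if (is.null(from)) from <- T
  if (from < 1 || from > T) stop("from outside the assimilated range")
  set.seed(seed)
  eps <- if (sample) draw_eps(spec, n_steps) else zero_eps(spec, n_steps)
  init <- list(h2 = trace$states$h2[, from], d2 = trace$states$d2[, from],
               h1 = slice3(trace$states$h1, from),
               d1 = slice3(trace$states$d1, from))
  Rq <- spec$n_regions * spec$q1
  gen <- pv_generate(unclass(spec), model$theta, n_steps, eps, FALSE, init,
                     m3 = rep(1, spec$q3), z3c = trace$z3_mu[, from],
                     m2 = matrix(0, spec$q2, n_steps),
                     z2c = matrix(0, spec$q2, n_steps),
                     m1 = matrix(0, Rq, n_steps),
                     z1c = matrix(0, Rq, n_steps))
  gen$xhat
}

#' Classify assimilated global latent states against reference clusters
#'
#' Assigns each step's global latent posterior mean to a reference cluster
#' (e.g. the per-sequence training posteriors labeled by condition) with
#' k-NN, and reports the proportion assigned to the correct condition
#' before and after a known switch time.
#'
#' @param trace an \code{assimilation_trace}.
#' @param reference list with \code{points} (n x q3 matrix) and
#'   \code{labels}.
#' @param switch_time step of the condition switch (defaults to the
#'   trace's recorded switch time).
#' @param before_label,after_label the correct labels on each side.
#' @param k fixed k, or NULL to select k by leave-one-out CV.
#' @param exclude_window drop the transition window (switch_time - H,
#'   switch_time + H) from scoring when TRUE is replaced by that H; 0
#'   scores every step.
#' @return list with per-step labels and \code{prop_before},
#'   \code{prop_after}.
#' @export
classify_trace_state <- function(trace, reference, switch_time = NULL,
                                 before_label, after_label, k = NULL,
                                 exclude_window = 0) {
  if (length(reference$labels) == 0) stop("empty reference set")
  if (is.null(switch_time)) switch_time <- trace$switch_time
  pts <- t(trace$z3_mu)
  asg <- knn_assign(pts, reference$points, reference$labels, k = k)
  T <- nrow(pts)
  lab <- asg$labels
  pre_idx <- seq_len(max(0, switch_time - exclude_window))
  post_idx <- seq(min(T, switch_time + exclude_window + 1), T)
  list(labels = lab, k = asg$k,
       prop_before = mean(lab[pre_idx] == before_label),
       prop_after = mean(lab[post_idx] == after_label))
}
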