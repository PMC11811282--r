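# Elementary top-down generation operations (reference implementations in
# plain R) plus helpers shared with the compiled fast path: adaptive-state
# packing and seeded noise streams.

clamp_num <- function(x, b) pmin(pmax(x, -b), b)

#' Prior parameters of a latent level
#'
#' The Gaussian prior of latent units is parameterized by the previous
#' deterministic outputs of the same module: mean through \code{tanh},
#' standard deviation through \code{exp}. At the initial time step of a
#' sequence the prior is N(0, 1) for all levels.
#'
#' @param d_prev previous deterministic output vector of the module.
#' @param W_mu,W_sigma weight matrices (latent dim x deterministic dim).
#' @param initial TRUE at the first time step of a sequence.
#' @param sigma_clamp numerical bound on the log-sigma pre-activation.
#' @return list with \code{mu} and \code{sigma}.
#' @export
compute_prior <- function(d_prev, W_mu, W_sigma, initial = FALSE,
                          sigma_clamp = 3) {
  if (initial) {
    q <- nrow(W_mu)
    return(list(mu = rep(0, q), sigma = rep(1, q)))
  }
  if (ncol(W_mu) != length(d_prev) || ncol(W_sigma) != length(d_prev))
    stop("dimension mismatch between d_prev and prior weights")
  list(mu = tanh(drop(W_mu %*% d_prev)),
       sigma = exp(clamp_num(drop(W_sigma %*% d_prev), sigma_clamp)))
}

#' Posterior parameters from adaptive internal states
#'
#' @param a_mu,a_sigma adaptive internal state vectors.
#' @param clamp numerical bound on the mean pre-activation.
#' @param sigma_clamp numerical bound on the log-sigma state.
#' @return list with \code{mu} and \code{sigma}.
#' @export
compute_posterior <- function(a_mu, a_sigma, clamp = 10, sigma_clamp = 3) {
  stopifnot(all(is.finite(a_mu)), all(is.finite(a_sigma)))
  list(mu = tanh(clamp_num(a_mu, clamp)),
       sigma = exp(clamp_num(a_sigma, sigma_clamp)))
}

#' Reparameterized latent sample
#'
#' \code{z = mu + sigma * eps} with \code{eps} standard normal; pass
#' \code{eps} explicitly for a deterministic draw from a seeded stream.
#'
#' @param params list with \code{mu}, \code{sigma}.
#' @param eps standard-normal noise vector; drawn with \code{rnorm} if NULL.
#' @export
sample_latent <- function(params, eps = NULL) {
  if (is.null(eps)) eps <- rnorm(length(params$mu))
  params$mu + params$sigma * eps
}

#' One step of a leaky deterministic unit bank
#'
#' \code{h_t = (1/tau) (W_d d_prev + W_z z + W_td topdown + b) +
#' (1 - 1/tau) h_prev}, \code{d_t = tanh(h_t)}. With \code{tau = 1} this
#' reduces to a standard RNN cell.
#'
#' @param h_prev previous internal state.
#' @param d_prev previous output of the same bank.
#' @param z current-step latent input (optional).
#' @param topdown current-step output of the higher-level bank (optional).
#' @param W_d,W_z,W_td,b connection weights and bias.
#' @param tau time constant (>= 1).
#' @return list with \code{h} and \code{d}.
#' @export
step_deterministic <- function(h_prev, d_prev, tau, W_d, b,
                               W_z = NULL, z = NULL,
                               W_td = NULL, topdown = NULL) {
  u <- drop(W_d %*% d_prev) + b
  if (!is.null(W_z)) u <- u + drop(W_z %*% z)
  if (!is.null(W_td)) u <- u + drop(W_td %*% topdown)
  h <- u / tau + (1 - 1 / tau) * h_prev
  list(h = h, d = tanh(h))
}

#' Predicted output channels of a region module
#' @param W_out output weight matrix (channels x deterministic dim).
#' @param d1 deterministic output vector of the region module.
#' @export
compute_output <- function(W_out, d1) tanh(drop(W_out %*% d1))

# ---- adaptive-state (alpha) packing; layout matches the compiled core ----

alpha_length <- function(spec, T) {
  2L * spec$q3 + 2L * T * (spec$q2 + spec$n_regions * spec$q1)
}

alpha_zero <- function(spec, T) numeric(alpha_length(spec, T))

# fresh adaptive states with posterior sd initialized at init_sigma
alpha_init <- function(spec, T, init_sigma = 0.1) {
  a <- alpha_unpack(spec, alpha_zero(spec, T), T)
  ls <- log(init_sigma)
  a$a3sg[] <- ls; a$a2sg[] <- ls; a$a1sg[] <- ls
  alpha_pack(a)
}

alpha_unpack <- function(spec, alpha, T) {
  q3 <- spec$q3; q2 <- spec$q2; Rq <- spec$n_regions * spec$q1
  off <- 0L
  take <- function(n) { v <- alpha[off + seq_len(n)]; off <<- off + n; v }
  list(a3mu = take(q3), a3sg = take(q3),
       a2mu = matrix(take(q2 * T), q2, T),
       a2sg = matrix(take(q2 * T), q2, T),
       a1mu = matrix(take(Rq * T), Rq, T),
       a1sg = matrix(take(Rq * T), Rq, T))
}

alpha_pack <- function(a) {
  c(a$a3mu, a$a3sg, as.numeric(a$a2mu), as.numeric(a$a2sg),
    as.numeric(a$a1mu), as.numeric(a$a1sg))
}

# windows share the global-level entries; slice the per-step blocks
alpha_window <- function(a, cols) {
  list(a3mu = a$a3mu, a3sg = a$a3sg,
       a2mu = a$a2mu[, cols, drop = FALSE],
       a2sg = a$a2sg[, cols, drop = FALSE],
       a1mu = a$a1mu[, cols, drop = FALSE],
       a1sg = a$a1sg[, cols, drop = FALSE])
}

# ---- noise streams ----

draw_eps <- function(spec, T) {
  list(e3 = rnorm(spec$q3),
       e2 = matrix(rnorm(spec$q2 * T), spec$q2, T),
       e1 = matrix(rnorm(spec$n_regions * spec$q1 * T),
                   spec$n_regions * spec$q1, T))
}

zero_eps <- function(spec, T) {
  list(e3 = numeric(spec$q3),
       e2 = matrix(0, spec$q2, T),
       e1 = matrix(0, spec$n_regions * spec$q1, T))
}

empty_init <- function(spec) {
  list(h2 = numeric(spec$p2), d2 = numeric(spec$p2),
       h1 = matrix(0, spec$p1, spec$n_regions),
       d1 = matrix(0, spec$p1, spec$n_regions))
}

#' Top-down prediction over a window of posterior states
#'
#' Runs posterior computation, latent sampling, deterministic dynamics and
#' output generation for every step of the window, in order. Deterministic
#' given the noise draws in \code{eps} (use \code{eps = NULL} with
#' \code{sample = FALSE} for posterior-mean generation).
#'
#' @param model a \code{vrnn}.
#' @param alpha packed adaptive states for the window (see
#'   \code{fit_posterior} / \code{assimilate} for how these are estimated).
#' @param x observed window (channels x steps), used for the free-energy
#'   bookkeeping of the returned record.
#' @param eps noise draws as returned by the internal stream helpers;
#'   zero noise (posterior means) if NULL and \code{sample} is FALSE.
#' @param sample draw fresh standard-normal noise when \code{eps} is NULL.
#' @param first_is_t1 TRUE when the window starts at sequence step 1.
#' @param init initial deterministic states (NULL for zeros).
#' @return list with predictions \code{xhat}, per-step free-energy
#'   breakdown, latent trajectories and deterministic states.
#' @export
forward_window <- function(model, alpha, x, eps = NULL, sample = FALSE,
                           first_is_t1 = TRUE, init = NULL) {
  spec <- model$spec
  T <- ncol(x)
  if (length(alpha) != alpha_length(spec, T))
    stop("adaptive state vector does not cover every step of the window")
  if (is.null(eps))
    eps <- if (sample) draw_eps(spec, T) else zero_eps(spec, T)
  if (is.null(init)) init <- empty_init(spec)
  pv_forward(unclass(spec), model$theta, alpha, x, eps,
             first_is_t1, init, FALSE)
}

# Pure-R reference forward pass composed from the elementary operations;
# used in tests as an independent oracle for the compiled core.
vrnn_forward_ref <- function(spec, theta, alpha, x, eps,
                             first_is_t1 = TRUE, init = NULL) {
  R <- spec$n_regions; C <- spec$channels_per_region
  T <- ncol(x); cl <- spec$clamp
  a <- alpha_unpack(spec, alpha, T)
  if (is.null(init)) init <- empty_init(spec)
  blk <- function(nm) theta_block(spec, theta, nm)
  A2 <- blk("A2"); B2 <- blk("B2"); B3 <- blk("B3"); b2 <- drop(blk("b2"))
  P2mu <- blk("P2mu"); P2sg <- blk("P2sg")
  reg <- lapply(spec$region_names, function(r) {
    list(A1 = blk(paste0("A1.", r)), B1 = blk(paste0("B1.", r)),
         C1 = blk(paste0("C1.", r)), b1 = drop(blk(paste0("b1.", r))),
         P1mu = blk(paste0("P1mu.", r)), P1sg = blk(paste0("P1sg.", r)),
         O = blk(paste0("O.", r)))
  })
  scl <- spec$sigma_clamp
  q3post <- compute_posterior(a$a3mu, a$a3sg, cl, scl)
  z3 <- sample_latent(q3post, eps$e3)
  h2 <- init$h2; d2 <- init$d2
  h1 <- init$h1; d1 <- init$d1
  xhat <- matrix(0, R * C, T)
  recon <- kl1 <- kl2 <- kl3 <- numeric(T)
  for (t in seq_len(T)) {
    initial <- (t == 1 && first_is_t1)
    pr2 <- compute_prior(d2, P2mu, P2sg, initial = initial,
                         sigma_clamp = scl)
    po2 <- compute_posterior(a$a2mu[, t], a$a2sg[, t], cl, scl)
    z2 <- sample_latent(po2, eps$e2[, t])
    st2 <- step_deterministic(h2, d2, spec$tau2, A2, b2,
                              W_z = B2, z = z2, W_td = B3, topdown = z3)
    kl2[t] <- gaussian_kl(po2$mu, po2$sigma, pr2$mu, pr2$sigma)
    h2 <- st2$h; d2new <- st2$d
    for (n in seq_len(R)) {
      rs <- (n - 1) * spec$q1 + seq_len(spec$q1)
      pr1 <- compute_prior(d1[, n], reg[[n]]$P1mu, reg[[n]]$P1sg,
                           initial = initial, sigma_clamp = scl)
      po1 <- compute_posterior(a$a1mu[rs, t], a$a1sg[rs, t], cl, scl)
      z1 <- sample_latent(po1, eps$e1[rs, t])
      st1 <- step_deterministic(h1[, n], d1[, n], spec$tau1,
                                reg[[n]]$A1, reg[[n]]$b1,
                                W_z = reg[[n]]$B1, z = z1,
                                W_td = reg[[n]]$C1, topdown = d2new)
      kl1[t] <- kl1[t] + gaussian_kl(po1$mu, po1$sigma, pr1$mu, pr1$sigma)
      h1[, n] <- st1$h; d1[, n] <- st1$d
      xhat[(n - 1) * C + seq_len(C), t] <- compute_output(reg[[n]]$O, st1$d)
    }
    d2 <- d2new
    if (initial)
      kl3[t] <- gaussian_kl(q3post$mu, q3post$sigma,
                            rep(0, spec$q3), rep(1, spec$q3))
    recon[t] <- 0.5 * sum((x[, t] - xhat[, t])^2)
  }
  loss <- sum(recon) + spec$w1 * sum(kl1) + spec$w2 * sum(kl2) +
    spec$w3 * sum(kl3)
  list(loss = loss, recon = recon, kl1 = kl1, kl2 = kl2, kl3 = kl3,
       xhat = xhat, z3 = z3)
}
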