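#' Canonical cortical region labels
#'
#' Fixed region order used throughout the package: frontal pole, dorsolateral
#' prefrontal cortex, premotor cortex, primary motor cortex, primary
#' somatosensory cortex, intraparietal sulcus, anterior temporal cortex,
#' auditory cortex, higher visual cortex, primary visual cortex.
#' @export
CANONICAL_REGIONS <- c("FP", "DLPFC", "PM", "M1", "S1",
                       "IPS", "AT", "AC", "HV", "V1")

#' Describe a three-level V-RNN architecture
#'
#' The network has a global state level (sequence-constant latent
#' \code{z3}, latent-only), a functional network level (latent \code{z2}
#' plus deterministic units \code{d2} with time constant \code{tau2}), and
#' one local module per region (latent \code{z1} and deterministic units
#' \code{d1} with time constant \code{tau1}, emitting
#' \code{channels_per_region} output channels each).
#'
#' @param n_regions number of local region modules.
#' @param channels_per_region output channels per region module.
#' @param q1,q2,q3 latent dimensions: per-region local, network, global.
#' @param p1,p2 deterministic unit counts: per region module, network level.
#' @param tau1,tau2 time constants (leak 1/tau) of the local and network
#'   deterministic units; smaller tau means faster dynamics.
#' @param meta_prior KL weight W per level; scalar or length-3
#'   (local, network, global).
#' @param clamp bound applied to posterior-mean pre-activations before
#'   \code{tanh}; numerical guard.
#' @param sigma_clamp bound applied to all log-sigma pre-activations
#'   before \code{exp}; the floor exp(-sigma_clamp) keeps prior sigmas
#'   from collapsing, which would make the KL curvature explode.
#' @param region_names optional character vector of region labels.
#' @return an object of class \code{network_spec}.
#' @export
network_spec <- function(n_regions = 10, channels_per_region = 2,
                         q1 = 1, q2 = 3, q3 = 2, p1 = 15, p2 = 15,
                         tau1 = 2, tau2 = 4, meta_prior = 0.001,
                         clamp = 10, sigma_clamp = 3,
                         region_names = NULL) {
  counts <- c(n_regions, channels_per_region, q1, q2, q3, p1, p2)
  if (any(counts < 1)) stop("all unit counts must be >= 1")
  if (tau1 < 1 || tau2 < 1) stop("time constants must be >= 1")
  if (length(meta_prior) == 1) meta_prior <- rep(meta_prior, 3)
  if (length(meta_prior) != 3 || any(meta_prior < 0))
    stop("meta_prior must be a nonnegative scalar or length-3 vector")
  if (is.null(region_names)) {
    region_names <- if (n_regions <= length(CANONICAL_REGIONS))
      CANONICAL_REGIONS[seq_len(n_regions)]
    else paste0("R", seq_len(n_regions))
  }
  if (length(region_names) != n_regions)
    stop("region_names must have length n_regions")
  structure(list(
    n_regions = as.integer(n_regions),
    channels_per_region = as.integer(channels_per_region),
    q1 = as.integer(q1), q2 = as.integer(q2), q3 = as.integer(q3),
    p1 = as.integer(p1), p2 = as.integer(p2),
    tau1 = tau1, tau2 = tau2,
    w1 = meta_prior[1], w2 = meta_prior[2], w3 = meta_prior[3],
    clamp = clamp, sigma_clamp = sigma_clamp,
    region_names = region_names
  ), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>\n")
  cat(sprintf("  regions: %d x %d channels (%s)\n", x$n_regions,
              x$channels_per_region, paste(x$region_names, collapse = " ")))
  cat(sprintf("  latents: z1=%d/region, z2=%d, z3=%d (constant)\n",
              x$q1, x$q2, x$q3))
  cat(sprintf("  deterministic: d1=%d/region (tau=%g), d2=%d (tau=%g)\n",
              x$p1, x$tau1, x$p2, x$tau2))
  cat(sprintf("  meta-prior W: %g / %g / %g\n", x$w1, x$w2, x$w3))
  invisible(x)
}

#' Number of output channels of a spec
#' @param spec a \code{network_spec}.
#' @export
n_channels <- function(spec) spec$n_regions * spec$channels_per_region

# Weight-vector layout; must match the C++ core's unpack order.
theta_layout <- function(spec) {
  s <- spec
  blocks <- list(
    A2 = c(s$p2, s$p2), B2 = c(s$p2, s$q2), B3 = c(s$p2, s$q3),
    b2 = c(s$p2, 1), P2mu = c(s$q2, s$p2), P2sg = c(s$q2, s$p2))
  for (n in seq_len(s$n_regions)) {
    r <- s$region_names[n]
    blocks[[paste0("A1.", r)]] <- c(s$p1, s$p1)
    blocks[[paste0("B1.", r)]] <- c(s$p1, s$q1)
    blocks[[paste0("C1.", r)]] <- c(s$p1, s$p2)
    blocks[[paste0("b1.", r)]] <- c(s$p1, 1)
    blocks[[paste0("P1mu.", r)]] <- c(s$q1, s$p1)
    blocks[[paste0("P1sg.", r)]] <- c(s$q1, s$p1)
    blocks[[paste0("O.", r)]] <- c(s$channels_per_region, s$p1)
  }
  sizes <- vapply(blocks, prod, numeric(1))
  data.frame(name = names(blocks),
             nrow = vapply(blocks, `[`, numeric(1), 1),
             ncol = vapply(blocks, `[`, numeric(1), 2),
             offset = cumsum(c(0, sizes[-length(sizes)])),
             size = sizes, row.names = NULL)
}

#' Initialize model weights
#'
#' Scaled-uniform (Glorot-style) initialization for connection matrices,
#' zeros for biases, with a recorded seed for reproducibility.
#'
#' @param spec a \code{network_spec}.
#' @param seed integer RNG seed.
#' @return numeric weight vector (the model's flattened parameters).
#' @export
init_weights <- function(spec, seed = 1L) {
  lay <- theta_layout(spec)
  set.seed(seed)
  theta <- numeric(sum(lay$size))
  for (i in seq_len(nrow(lay))) {
    nm <- lay$name[i]
    idx <- lay$offset[i] + seq_len(lay$size[i])
    if (startsWith(nm, "b")) next  # biases start at zero
    lim <- sqrt(6 / (lay$nrow[i] + lay$ncol[i]))
    theta[idx] <- runif(lay$size[i], -lim, lim)
  }
  stopifnot(length(theta) == pv_theta_length(unclass(spec)))
  theta
}

# extract one named weight block as a matrix
theta_block <- function(spec, theta, name) {
  lay <- theta_layout(spec)
  i <- match(name, lay$name)
  if (is.na(i)) stop("unknown weight block: ", name)
  matrix(theta[lay$offset[i] + seq_len(lay$size[i])], lay$nrow[i], lay$ncol[i])
}

#' Build a V-RNN model
#'
#' Couples an architecture description with an initialized weight vector
#' and (initially empty) per-sequence posterior adaptive states.
#'
#' @param spec a \code{network_spec}.
#' @param seed seed for weight initialization.
#' @return an object of class \code{vrnn}.
#' @export
vrnn_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  structure(list(spec = spec, theta = init_weights(spec, seed),
                 posterior = list(), seed = as.integer(seed)),
            class = "vrnn")
}

#' @export
print.vrnn <- function(x, ...) {
  cat(sprintf("<vrnn> %d weights, %d stored posterior(s)\n",
              length(x$theta), length(x$posterior)))
  print(x$spec)
  invisible(x)
}

#' Save / load a network spec as a YAML document
#' @param spec a \code{network_spec}; \code{path} file path.
#' @rdname spec_io
#' @export
write_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @param path file path.
#' @rdname spec_io
#' @export
read_spec <- function(path) {
  v <- yaml::read_yaml(path)
  network_spec(n_regions = v$n_regions,
               channels_per_region = v$channels_per_region,
               q1 = v$q1, q2 = v$q2, q3 = v$q3, p1 = v$p1, p2 = v$p2,
               tau1 = v$tau1, tau2 = v$tau2,
               meta_prior = c(v$w1, v$w2, v$w3), clamp = v$clamp,
               sigma_clamp = v$sigma_clamp %||% 3,
               region_names = v$region_names)
}
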