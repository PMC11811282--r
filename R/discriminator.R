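# Condition / individual discriminator: multitaper spectrograms of fixed
# segments, classified by a small 3-D convolutional network (one conv
# block over channel x frequency x time, ReLU, global average pooling,
# softmax head) trained with Adam on cross-entropy.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the classical symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS; tapers are unit-energy, ordered by
#' concentration.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 4, k = 7) {
  W <- nw / n
  i <- seq_len(n) - 1
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper spectrogram of a signal segment
#'
#' Per channel: the moving window is tapered with each Slepian, the
#' per-taper periodograms are averaged, and the power is restricted to
#' the requested band. Deterministic.
#'
#' @param segment a \code{signal_sequence} or channels x time matrix.
#' @param rate sampling rate (taken from the sequence if present).
#' @param window_ms,step_ms moving-window length and step (ms).
#' @param fmax upper frequency bound (Hz) of the retained band.
#' @param nw,k_tapers multitaper parameters.
#' @return channels x frequency x frames array with attributes
#'   \code{freqs} (Hz) and \code{frame_times} (s); class
#'   \code{spectrogram_stack}.
#' @export
multitaper_spectrogram <- function(segment, rate = NULL, window_ms = 100,
                                   step_ms = 10, fmax = 200, nw = 4,
                                   k_tapers = 7) {
  v <- sequence_values(segment)
  if (is.null(rate)) rate <- attr(segment, "sampling_rate")
  if (is.null(rate)) stop("sampling rate unknown")
  win <- round(window_ms / 1000 * rate)
  stp <- round(step_ms / 1000 * rate)
  T <- ncol(v)
  if (T < win) stop("segment shorter than the moving window")
  nframes <- (T - win) %/% stp + 1L
  tap <- dpss_tapers(win, nw, k_tapers)
  freqs <- (seq_len(win %/% 2 + 1) - 1) * rate / win
  keep <- freqs <= fmax
  nf <- sum(keep)
  out <- array(0, c(nrow(v), nf, nframes))
  for (fr in seq_len(nframes)) {
    cols <- (fr - 1L) * stp + seq_len(win)
    seg <- v[, cols, drop = FALSE]
    for (ch in seq_len(nrow(v))) {
      p <- numeric(win %/% 2 + 1)
      for (j in seq_len(k_tapers)) {
        sp <- fft(seg[ch, ] * tap[, j])
        p <- p + Mod(sp[seq_len(win %/% 2 + 1)])^2
      }
      out[ch, , fr] <- (p / k_tapers)[keep] / rate
    }
  }
  structure(out, freqs = freqs[keep],
            frame_times = ((seq_len(nframes) - 1L) * stp + win / 2) / rate,
            class = "spectrogram_stack")
}

# cut a sequence into fixed-length segments and build spectrogram stacks
segment_spectrograms <- function(seq, segment_ms = 2000, ...) {
  rate <- attr(seq, "sampling_rate")
  v <- sequence_values(seq)
  len <- round(segment_ms / 1000 * rate)
  nseg <- ncol(v) %/% len
  if (nseg < 1) stop("sequence shorter than one segment")
  lapply(seq_len(nseg), function(i) {
    multitaper_spectrogram(v[, (i - 1) * len + seq_len(len), drop = FALSE],
                           rate = rate, ...)
  })
}

# ---- minimal 3-D CNN (im2col formulation) ----

conv_geometry <- function(dims, kernel) {
  odims <- dims - kernel + 1L
  if (any(odims < 1)) stop("kernel larger than input")
  npos <- prod(odims)
  ksz <- prod(kernel)
  # linear indices of each kernel element offset within the input array
  koff <- as.matrix(expand.grid(seq_len(kernel[1]) - 1L,
                                seq_len(kernel[2]) - 1L,
                                seq_len(kernel[3]) - 1L))
  pos <- as.matrix(expand.grid(seq_len(odims[1]), seq_len(odims[2]),
                               seq_len(odims[3])))
  lin <- function(ix) (ix[, 3] - 1L) * dims[1] * dims[2] +
    (ix[, 2] - 1L) * dims[1] + ix[, 1]
  base <- lin(pos)
  offs <- koff[, 3] * dims[1] * dims[2] + koff[, 2] * dims[1] + koff[, 1]
  idx <- outer(base, offs, "+")  # npos x ksz
  list(idx = idx, npos = npos, ksz = ksz, odims = odims)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the spectrogram discriminator
#'
#' Stacks are log-transformed and standardized, then classified by a
#' small 3-D convolutional network whose kernels slide over channel,
#' frequency and time. Trained full-batch with Adam on cross-entropy;
#' a stratified holdout split reports held-out accuracy. Seeded and
#' reproducible.
#'
#' @param stacks list of \code{spectrogram_stack} arrays of equal shape.
#' @param labels class labels (condition or individual), one per stack.
#' @param n_filters number of convolution filters.
#' @param kernel 3-D kernel extent (channel, frequency, time).
#' @param n_updates optimizer steps (reference setting: 100).
#' @param lr Adam learning rate (reference setting: 5e-4).
#' @param holdout held-out fraction for the accuracy estimate.
#' @param spect_params spectrogram parameters to record on the classifier
#'   (as returned by \code{build_stacks}).
#' @param seed RNG seed.
#' @return a \code{spectrogram_classifier} with \code{holdout_accuracy}.
#' @export
train_discriminator <- function(stacks, labels, n_filters = 4,
                                kernel = c(2, 3, 5), n_updates = 100,
                                lr = 5e-4, holdout = 0.2,
                                spect_params = NULL, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (length(stacks) != length(labels)) stop("one label per stack")
  dims <- dim(stacks[[1]])
  kernel <- pmin(kernel, dims)
  geo <- conv_geometry(dims, kernel)
  # feature prep: log power, global standardization
  feats <- lapply(stacks, function(s) log10(as.numeric(s) + 1e-12))
  mu <- mean(unlist(feats)); sdv <- sd(unlist(feats))
  feats <- lapply(feats, function(f) (f - mu) / sdv)
  set.seed(seed)
  # stratified holdout
  test_idx <- unlist(lapply(levels(labels), function(lv) {
    ids <- which(labels == lv)
    if (length(ids) < 2) return(integer(0))
    sample(ids, max(1, round(holdout * length(ids))))
  }))
  train_idx <- setdiff(seq_along(stacks), test_idx)
  nc <- nlevels(labels)
  Wk <- matrix(rnorm(geo$ksz * n_filters, 0,
                     sqrt(2 / (geo$ksz + n_filters))), geo$ksz, n_filters)
  bk <- numeric(n_filters)
  V <- matrix(rnorm(n_filters * nc, 0, sqrt(2 / (n_filters + nc))),
              n_filters, nc)
  cv <- numeric(nc)
  y <- as.integer(labels)
  pars <- list(Wk = Wk, bk = bk, V = V, cv = cv)
  adam <- lapply(pars, function(p) list(m = p * 0, v = p * 0))
  forward_one <- function(f, pars) {
    patches <- matrix(f[geo$idx], geo$npos, geo$ksz)
    act <- patches %*% pars$Wk +
      matrix(pars$bk, geo$npos, length(pars$bk), byrow = TRUE)
    relu <- pmax(act, 0)
    pooled <- colMeans(relu)
    logits <- drop(pooled %*% pars$V) + pars$cv
    list(patches = patches, act = act, pooled = pooled, logits = logits)
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(n_updates)
  for (u in seq_len(n_updates)) {
    g <- lapply(pars, function(p) p * 0)
    loss <- 0
    for (i in train_idx) {
      fw <- forward_one(feats[[i]], pars)
      pr <- softmax_rows(matrix(fw$logits, 1))[1, ]
      loss <- loss - log(pr[y[i]] + 1e-12)
      dlog <- pr; dlog[y[i]] <- dlog[y[i]] - 1
      g$V <- g$V + outer(fw$pooled, dlog)
      g$cv <- g$cv + dlog
      dpool <- drop(pars$V %*% dlog)
      dact <- (fw$act > 0) *
        matrix(dpool / geo$npos, geo$npos, length(dpool), byrow = TRUE)
      g$Wk <- g$Wk + crossprod(fw$patches, dact)
      g$bk <- g$bk + colSums(dact)
    }
    for (nm in names(pars)) {
      adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * g[[nm]]
      adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * g[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - beta1^u)
      vhat <- adam[[nm]]$v / (1 - beta2^u)
      pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    loss_trace[u] <- loss / length(train_idx)
  }
  clf <- structure(list(pars = pars, geo = geo, dims = dims,
                        kernel = kernel, levels = levels(labels),
                        feat_mu = mu, feat_sd = sdv,
                        spect_params = spect_params,
                        loss_trace = loss_trace),
                   class = "spectrogram_classifier")
  preds <- classify_stacks(clf, stacks[test_idx])
  clf$holdout_accuracy <- if (length(test_idx))
    mean(preds$labels == as.character(labels[test_idx])) else NA_real_
  clf$holdout_n <- length(test_idx)
  clf
}

#' @export
print.spectrogram_classifier <- function(x, ...) {
  cat(sprintf(
    "<spectrogram_classifier> classes: %s | held-out accuracy %.3f (n=%d)\n",
    paste(x$levels, collapse = "/"), x$holdout_accuracy, x$holdout_n))
  invisible(x)
}

#' Classify spectrogram stacks
#'
#' @param clf a \code{spectrogram_classifier}.
#' @param stacks list of spectrogram arrays matching the training
#'   geometry.
#' @return list with predicted \code{labels} and per-class
#'   \code{proportions} (proportions sum to 1; empty input gives an empty
#'   table).
#' @export
classify_stacks <- function(clf, stacks) {
  if (!length(stacks))
    return(list(labels = character(0),
                proportions = table(factor(character(0),
                                           levels = clf$levels))))
  if (!all(dim(stacks[[1]]) == clf$dims))
    stop("stack geometry does not match the classifier")
  labs <- vapply(stacks, function(s) {
    f <- (log10(as.numeric(s) + 1e-12) - clf$feat_mu) / clf$feat_sd
    patches <- matrix(f[clf$geo$idx], clf$geo$npos, clf$geo$ksz)
    act <- pmax(patches %*% clf$pars$Wk +
                  matrix(clf$pars$bk, clf$geo$npos,
                         length(clf$pars$bk), byrow = TRUE), 0)
    logits <- drop(colMeans(act) %*% clf$pars$V) + clf$pars$cv
    clf$levels[which.max(logits)]
  }, character(1))
  list(labels = labs,
       proportions = table(factor(labs, levels = clf$levels)) /
         length(labs))
}

#' Build labeled spectrogram stacks from a set of sequences
#'
#' Segments each sequence and computes one multitaper spectrogram stack
#' per segment, labeling it with the sequence's condition or individual.
#'
#' @param sequences list of \code{signal_sequence}s.
#' @param task label source: "condition" or "individual".
#' @param segment_ms segment length (ms).
#' @param ... passed to \code{multitaper_spectrogram}.
#' @return list with \code{stacks}, \code{labels} and the spectrogram
#'   parameters used.
#' @export
build_stacks <- function(sequences, task = c("condition", "individual"),
                         segment_ms = 2000, ...) {
  task <- match.arg(task)
  stacks <- list(); labs <- character(0)
  for (sq in sequences) {
    st <- segment_spectrograms(sq, segment_ms = segment_ms, ...)
    stacks <- c(stacks, st)
    labs <- c(labs, rep(attr(sq, task), length(st)))
  }
  list(stacks = stacks, labels = labs,
       spect_params = c(list(segment_ms = segment_ms), list(...)))
}

#' Classify signal sequences via their spectrograms
#'
#' Segments each sequence with the spectrogram parameters recorded at
#' training time (or supplied here) and classifies each segment.
#'
#' @param clf a \code{spectrogram_classifier}.
#' @param sequences list of \code{signal_sequence}s.
#' @param segment_ms segment length (ms); defaults to the classifier's
#'   recorded value.
#' @param ... passed to \code{multitaper_spectrogram}.
#' @export
classify_sequences <- function(clf, sequences, segment_ms = NULL, ...) {
  sp <- clf$spect_params
  if (is.null(segment_ms)) segment_ms <- sp$segment_ms
  if (is.null(segment_ms))
    stop("segment_ms unknown: supply it or train via build_stacks params")
  extra <- sp[setdiff(names(sp), "segment_ms")]
  args_extra <- utils::modifyList(as.list(extra), list(...))
  stacks <- list()
  for (sq in sequences)
    stacks <- c(stacks, do.call(segment_spectrograms,
                                c(list(sq, segment_ms = segment_ms),
                                  args_extra)))
  classify_stacks(clf, stacks)
}
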