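# Signal conditioning chain applied before modeling, in fixed order:
# common-median re-reference -> outlier-bin exclusion -> linear
# normalization; plus crossfaded concatenation and dataset assembly.

preserve_attrs <- function(new_values, template, step = NULL) {
  out <- signal_sequence(new_values,
                         sampling_rate = attr(template, "sampling_rate"),
                         condition = attr(template, "condition"),
                         individual = attr(template, "individual"),
                         region_map = attr(template, "region_map"),
                         switch_time = attr(template, "switch_time"))
  steps <- c(attr(template, "preprocessing"), step)
  attr(out, "preprocessing") <- steps
  out
}

#' Common median re-reference
#'
#' Subtracts the across-channel median from every channel at each time
#' step. With a single channel the input is returned unchanged with a
#' warning.
#'
#' @param seq a \code{signal_sequence} (or channels x time matrix).
#' @export
rereference_common_median <- function(seq) {
  v <- sequence_values(seq)
  if (nrow(v) < 2) {
    warning("common median reference needs >= 2 channels; returning input")
    return(seq)
  }
  med <- apply(v, 2, median)
  out <- sweep(v, 2, med, "-")
  if (inherits(seq, "signal_sequence"))
    preserve_attrs(out, seq, "rereference") else out
}

#' Exclude high-amplitude outlier bins
#'
#' Divides the recording into fixed-size bins and drops every bin in which
#' any sample in any channel deviates more than \code{thresh} standard
#' deviations from that channel's mean, together with both immediate
#' neighbor bins. Standard deviations are computed per channel over the
#' whole recording.
#'
#' @param seq a \code{signal_sequence} or channels x time matrix.
#' @param bin bin length in time steps.
#' @param thresh exclusion threshold in channel standard deviations.
#' @return list with \code{keep} (logical per bin), \code{segments}
#'   (retained data as a list of matrices, one per run of kept bins) and
#'   \code{values} (retained samples concatenated).
#' @export
exclude_outlier_bins <- function(seq, bin = 2000, thresh = 8) {
  v <- sequence_values(seq)
  T <- ncol(v)
  if (T < 1) stop("empty recording")
  nb <- ceiling(T / bin)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  sdv[sdv == 0] <- Inf  # flat channels can never exceed the threshold
  flagged <- logical(nb)
  for (b in seq_len(nb)) {
    cols <- ((b - 1) * bin + 1):min(b * bin, T)
    dev <- abs(v[, cols, drop = FALSE] - mu) / sdv
    flagged[b] <- any(dev > thresh)
  }
  drop_bins <- flagged
  drop_bins[which(flagged) - 1L] <- TRUE
  hi <- which(flagged) + 1L
  drop_bins[hi[hi <= nb]] <- TRUE
  keep <- !drop_bins
  if (!any(keep))
    stop(sprintf("all %d bins excluded (%d flagged)", nb, sum(flagged)))
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segments <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    cols <- ((starts[i] - 1) * bin + 1):min(ends[i] * bin, T)
    segments[[length(segments) + 1]] <- v[, cols, drop = FALSE]
  }
  list(keep = keep, segments = segments,
       values = do.call(cbind, segments))
}

#' Linear amplitude normalization
#'
#' Affine map of \code{in_range} onto \code{out_range} (defaults map
#' [-1000, 1000] microvolts to [-0.8, 0.8], i.e. y = 0.0008 x). Values
#' outside the input range pass through the same affine map; no clipping.
#'
#' @param seq a \code{signal_sequence} or numeric matrix/vector.
#' @param in_range,out_range length-2 numeric ranges (lo, hi).
#' @export
normalize_linear <- function(seq, in_range = c(-1000, 1000),
                             out_range = c(-0.8, 0.8)) {
  if (in_range[1] >= in_range[2] || out_range[1] >= out_range[2])
    stop("degenerate range")
  scale <- diff(out_range) / diff(in_range)
  shift <- out_range[1] - in_range[1] * scale
  f <- function(x) x * scale + shift
  if (inherits(seq, "signal_sequence"))
    preserve_attrs(f(sequence_values(seq)), seq, "normalize")
  else f(seq)
}

#' Linear crossfade concatenation
#'
#' Joins two sequences by overlapping their boundary: over the taper
#' region the tail of \code{seq_a} ramps linearly down while the head of
#' \code{seq_b} ramps up, and the two are summed. Total length is
#' \code{len(a) + len(b) - taper} samples.
#'
#' @param seq_a,seq_b \code{signal_sequence}s with equal channel count and
#'   sampling rate.
#' @param taper_ms taper width in milliseconds.
#' @export
crossfade_concat <- function(seq_a, seq_b, taper_ms = 30) {
  rate <- attr(seq_a, "sampling_rate")
  if (!isTRUE(all.equal(rate, attr(seq_b, "sampling_rate"))))
    stop("sampling rates differ")
  a <- sequence_values(seq_a); b <- sequence_values(seq_b)
  if (nrow(a) != nrow(b)) stop("channel counts differ")
  w <- round(taper_ms / 1000 * rate)
  if (w > ncol(a) || w > ncol(b)) stop("taper longer than a sequence")
  if (w == 0) {
    out <- cbind(a, b)
  } else {
    ramp <- seq(1, 0, length.out = w)  # weight of A over the taper
    ta <- ncol(a) - w + seq_len(w)
    mix <- a[, ta, drop = FALSE] * rep(ramp, each = nrow(a)) +
      b[, seq_len(w), drop = FALSE] * rep(1 - ramp, each = nrow(a))
    out <- cbind(a[, seq_len(ncol(a) - w), drop = FALSE], mix,
                 b[, -seq_len(w), drop = FALSE])
  }
  cond_a <- attr(seq_a, "condition"); cond_b <- attr(seq_b, "condition")
  signal_sequence(out, sampling_rate = rate,
                  condition = if (identical(cond_a, cond_b)) cond_a
                              else "mixed",
                  individual = attr(seq_a, "individual"),
                  region_map = attr(seq_a, "region_map"),
                  switch_time = if (!identical(cond_a, cond_b))
                    ncol(a) - w %/% 2 else NULL)
}

#' Assemble a training set from per-individual sequence pools
#'
#' Seeded sampling without replacement of \code{n_per_condition} sequences
#' per condition from each individual's pool. With the reference settings
#' (3 individuals, 12 per condition, 2000-step sequences) this yields 72
#' sequences / 144,000 steps.
#'
#' @param pools named list: \code{pools[[individual]][[condition]]} is a
#'   list of \code{signal_sequence}s.
#' @param n_per_condition sequences drawn per condition per individual.
#' @param seed RNG seed.
#' @return list of selected \code{signal_sequence}s.
#' @export
assemble_training_set <- function(pools, n_per_condition = 12, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (ind in names(pools)) {
    for (cond in names(pools[[ind]])) {
      pool <- pools[[ind]][[cond]]
      if (length(pool) < n_per_condition)
        stop(sprintf("pool exhausted for %s/%s (%d < %d)", ind, cond,
                     length(pool), n_per_condition))
      pick <- sample(length(pool), n_per_condition)
      out <- c(out, pool[pick])
    }
  }
  out
}

#' Assemble condition-transition test sequences
#'
#' Builds sequences whose first part comes from one condition and whose
#' second part from the other, joined by linear crossfade, in both
#' directions. The switch index is recorded in each sequence's metadata.
#'
#' @param pools named list as in \code{assemble_training_set}, with
#'   conditions "awake" and "anesthetized".
#' @param n number of sequences per direction.
#' @param first,second lengths (steps) of the leading and trailing parts.
#' @param taper_ms crossfade taper width.
#' @param seed RNG seed.
#' @export
assemble_transition_set <- function(pools, n = 25, first = 2500,
                                    second = 1500, taper_ms = 30,
                                    seed = 1L) {
  set.seed(seed)
  inds <- names(pools)
  out <- list()
  take_piece <- function(cond, len) {
    ind <- sample(inds, 1)
    pool <- pools[[ind]][[cond]]
    s <- pool[[sample(length(pool), 1)]]
    if (ncol(s) < len) stop("pool sequence shorter than requested part")
    start <- sample(ncol(s) - len + 1, 1)
    preserve_attrs(sequence_values(s)[, start + seq_len(len) - 1,
                                      drop = FALSE], s)
  }
  for (dir in c("awake_to_anesthetized", "anesthetized_to_awake")) {
    c1 <- if (dir == "awake_to_anesthetized") "awake" else "anesthetized"
    c2 <- setdiff(c("awake", "anesthetized"), c1)
    for (i in seq_len(n)) {
      s <- crossfade_concat(take_piece(c1, first), take_piece(c2, second),
                            taper_ms = taper_ms)
      attr(s, "switch_time") <- first
      attr(s, "direction") <- dir
      out[[length(out) + 1]] <- s
    }
  }
  out
}
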