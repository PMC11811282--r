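#' Multichannel signal sequence
#'
#' A channels x time numeric matrix carrying its sampling rate, condition
#' label, individual id and a channel-to-region map as attributes.
#'
#' @param values channels x time numeric matrix.
#' @param sampling_rate sampling rate in Hz.
#' @param condition one of "awake", "anesthetized", "mixed".
#' @param individual individual identifier.
#' @param region_map character vector, one region label per channel.
#' @param switch_time optional step index of a known condition switch
#'   (for transition sequences).
#' @return an object of class \code{signal_sequence}.
#' @export
signal_sequence <- function(values, sampling_rate,
                            condition = c("awake", "anesthetized", "mixed"),
                            individual = "unknown", region_map = NULL,
                            switch_time = NULL) {
  values <- as.matrix(values)
  condition <- match.arg(condition)
  if (anyNA(values)) stop("signal values contain NA")
  if (ncol(values) < 1) stop("time length must be >= 1")
  if (is.null(region_map))
    region_map <- paste0("R", seq_len(nrow(values)))
  if (length(region_map) != nrow(values))
    stop("region_map must cover all channels")
  if (is.null(rownames(values)))
    rownames(values) <- make.unique(paste0(region_map, "_ch"), sep = "")
  structure(values, class = c("signal_sequence", "matrix"),
            sampling_rate = sampling_rate, condition = condition,
            individual = individual, region_map = region_map,
            switch_time = switch_time)
}

#' Plain numeric matrix of a signal sequence
#' @param x a \code{signal_sequence} or numeric matrix.
#' @export
sequence_values <- function(x) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v), dimnames = dimnames(v))
  v
}

#' @export
print.signal_sequence <- function(x, ...) {
  cat(sprintf("<signal_sequence> %d channels x %d steps @ %g Hz\n",
              nrow(x), ncol(x), attr(x, "sampling_rate")))
  cat(sprintf("  condition: %s | individual: %s | regions: %s\n",
              attr(x, "condition"), attr(x, "individual"),
              paste(unique(attr(x, "region_map")), collapse = " ")))
  invisible(x)
}

#' Write / read a signal sequence as delimited text plus a metadata sidecar
#'
#' The signal matrix is written time-by-row with a header row of channel
#' names; sampling rate, labels and the region map go to
#' \code{<path>.meta.yaml}. Round-trips to printed precision.
#'
#' @param seq a \code{signal_sequence}.
#' @param path file path for the delimited matrix.
#' @rdname signal_io
#' @export
write_signals <- function(seq, path) {
  stopifnot(inherits(seq, "signal_sequence"))
  m <- t(sequence_values(seq))
  utils::write.table(format(m, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(sampling_rate = attr(seq, "sampling_rate"),
               condition = attr(seq, "condition"),
               individual = attr(seq, "individual"),
               region_map = as.list(setNames(attr(seq, "region_map"),
                                             rownames(seq))))
  if (!is.null(attr(seq, "switch_time")))
    meta$switch_time <- attr(seq, "switch_time")
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname signal_io
#' @export
read_signals <- function(path) {
  metapath <- paste0(path, ".meta.yaml")
  if (!file.exists(metapath))
    stop("metadata sidecar not found: ", metapath)
  meta <- yaml::read_yaml(metapath)
  for (field in c("sampling_rate", "condition", "individual", "region_map"))
    if (is.null(meta[[field]]))
      stop("metadata field missing: ", field)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (anyNA(m)) stop("parsed signal matrix contains NA values in ", path)
  vals <- t(m)
  rm <- unlist(meta$region_map)
  signal_sequence(vals, sampling_rate = meta$sampling_rate,
                  condition = meta$condition, individual = meta$individual,
                  region_map = unname(rm[rownames(vals)]),
                  switch_time = meta$switch_time)
}
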