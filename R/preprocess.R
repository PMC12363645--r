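#' Block-mean downsampling
#'
#' Reduces the sampling rate by averaging every `factor` consecutive
#' timepoints: rows are partitioned into non-overlapping blocks of
#' `factor` rows and each output row is the arithmetic mean of its block.
#' A trailing partial block (fewer than `factor` rows) is averaged and
#' kept as the final row, so the output has `ceiling(n / factor)` rows.
#' Downsampling a 10 Hz peri-event trace by 10 yields a ~1 Hz trace.
#'
#' The data model carries no time axis — timepoints are row indices — so
#' callers track the effective sampling rate themselves (e.g. when
#' choosing a consecutive threshold; see
#' [recommend_consecutive_threshold()]).
#'
#' @param dataset a [peri_dataset()].
#' @param factor positive integer block size, at most `n_timepoints`;
#'   `factor = 1` returns the dataset unchanged.
#' @return a [peri_dataset()] with the same groups and columns and
#'   `ceiling(n / factor)` timepoints.
#' @export
downsample <- function(dataset, factor) {
  stopifnot(inherits(dataset, "peri_dataset"))
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor)
      || factor < 1)
    stop("`factor` must be a single positive integer", call. = FALSE)
  factor <- as.integer(factor)
  n <- n_timepoints(dataset)
  if (factor > n)
    stop("`factor` (", factor, ") exceeds the number of timepoints (", n, ")",
         call. = FALSE)
  if (factor == 1L) return(dataset)
  block <- rep(seq_len(ceiling(n / factor)), each = factor, length.out = n)
  size <- tabulate(block)
  groups <- lapply(dataset, function(m) {
    out <- rowsum(m, block, reorder = TRUE) / size
    rownames(out) <- NULL
    out
  })
  peri_dataset(groups, source_path = attr(dataset, "source_path"))
}

# normalise a bin spec (list of c(start, end) or 2-column matrix, 0-based
# inclusive) into an integer matrix with columns start, end
as_bin_matrix <- function(bins) {
  if (is.list(bins)) bins <- do.call(rbind, bins)
  if (is.null(bins) || length(bins) == 0L)
    stop("`bins` must be a non-empty list of (start, end) row pairs",
         call. = FALSE)
  bins <- as.matrix(bins)
  if (ncol(bins) != 2L || nrow(bins) < 1L)
    stop("`bins` must be a non-empty list of (start, end) row pairs",
         call. = FALSE)
  if (any(!is.finite(bins)) || any(bins != round(bins)))
    stop("bin indices must be integers", call. = FALSE)
  storage.mode(bins) <- "integer"
  colnames(bins) <- c("start", "end")
  bins
}

#' Mean time bins
#'
#' Averages each animal/trial column over user-defined row windows, e.g.
#' a baseline period and post-event intervals. Bins are 0-based inclusive
#' row index pairs (row 0 is the first data row); they may overlap or
#' leave gaps but must lie within the data. Row indices must be
#' non-negative and at most `n_timepoints - 1`.
#'
#' @param dataset a [peri_dataset()].
#' @param bins a list of `c(start, end)` pairs or a 2-column matrix,
#'   0-based inclusive.
#' @return a `time_bin_table`: a named list with one `bins x trials`
#'   matrix per group, in the order the bins were given, carrying the bin
#'   matrix and the input stem as attributes. Write it out with
#'   [write_time_bin_means()].
#' @examples
#' d <- peri_dataset(list(g = matrix(1:4, 4, 1)))
#' time_bin_means(d, list(c(0, 1), c(2, 3)))$g
#' @export
time_bin_means <- function(dataset, bins) {
  stopifnot(inherits(dataset, "peri_dataset"))
  bins <- as_bin_matrix(bins)
  n <- n_timepoints(dataset)
  if (any(bins < 0L) || any(bins[, 2L] > n - 1L))
    stop("bin row indices must be non-negative and the data to be analyzed ",
         "should be equal to or less than the maximum number of rows ",
         "(max row index ", n - 1L, ")", call. = FALSE)
  if (any(bins[, 1L] > bins[, 2L]))
    stop("each bin must have start <= end", call. = FALSE)
  tab <- lapply(dataset, function(m) {
    out <- t(apply(bins, 1L, function(b)
      colMeans(m[(b[1L] + 1L):(b[2L] + 1L), , drop = FALSE])))
    if (ncol(m) == 1L) out <- matrix(out, ncol = 1L)  # apply() drops dims
    dimnames(out) <- list(NULL, colnames(m))
    out
  })
  structure(tab, bins = bins, stem = dataset_stem(dataset),
            class = c("time_bin_table", "list"))
}
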