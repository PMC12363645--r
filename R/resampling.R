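# Per-timepoint bootstrapped confidence intervals and binary significance
# maps. The exchangeable unit is the animal/trial (a whole column): each
# bootstrap iteration draws n column indices with replacement once and
# averages the selected waveforms across all timepoints, so the resampled
# traces keep their temporal coherence while the per-timepoint marginals
# equal those of independent per-timepoint resampling.

#' Bootstrap analysis configuration
#'
#' @param confidence_level CI level as a proportion in (0, 1); 0.95 and
#'   0.99 are the conventional choices.
#' @param n_resamples number of bootstrap resamples; 1,000 is standard —
#'   more resamples give a more representative bootstrap distribution
#'   (they do not narrow the CI) and the benefit asymptotes quickly.
#' @param consecutive_threshold minimum run length (in samples) of
#'   consecutive significant timepoints for significance to be retained;
#'   0 or 1 disables thresholding. See
#'   [recommend_consecutive_threshold()].
#' @param design `"between"` (independent groups; bootstrap each group
#'   and subtract the distributions) or `"within"` (paired animals/trials;
#'   bootstrap the column-wise differences).
#' @param seed optional integer seed making all resampling reproducible;
#'   when absent the current RNG state is used.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(confidence_level = 0.95, n_resamples = 1000L,
                             consecutive_threshold = 0L,
                             design = c("between", "within"), seed = NULL) {
  design <- match.arg(design)
  if (!is.numeric(confidence_level) || length(confidence_level) != 1L ||
      confidence_level <= 0 || confidence_level >= 1)
    stop("`confidence_level` must be a proportion strictly between 0 and 1",
         call. = FALSE)
  if (n_resamples < 1L || n_resamples != round(n_resamples))
    stop("`n_resamples` must be a positive integer", call. = FALSE)
  if (consecutive_threshold < 0L ||
      consecutive_threshold != round(consecutive_threshold))
    stop("`consecutive_threshold` must be a non-negative integer",
         call. = FALSE)
  structure(list(confidence_level = confidence_level,
                 n_resamples = as.integer(n_resamples),
                 consecutive_threshold = as.integer(consecutive_threshold),
                 design = design,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "bootstrap_config")
}

# evaluate expr under a fixed seed without disturbing the caller's RNG;
# NULL seed = use (and advance) the current stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(seed, expr)
}

#' Bootstrap distribution of the group mean at every timepoint
#'
#' Draws `n_resamples` bootstrap samples of the `n` animal/trial columns
#' (with replacement, one draw of n column indices per resample) and
#' returns the mean trace of each resample.
#'
#' @param x numeric matrix, rows = timepoints, columns = animals/trials.
#' @param n_resamples number of bootstrap resamples.
#' @return an `n_resamples x T` matrix; row b is the mean of the b-th
#'   resampled set of columns at every timepoint.
#' @export
bootstrap_mean_samples <- function(x, n_resamples) {
  x <- as.matrix(x)
  if (length(x) == 0L)
    stop("`x` must be a non-empty numeric matrix", call. = FALSE)
  if (n_resamples < 1L || n_resamples != round(n_resamples))
    stop("`n_resamples` must be a positive integer", call. = FALSE)
  n <- ncol(x)
  B <- as.integer(n_resamples)
  idx <- matrix(sample.int(n, B * n, replace = TRUE), nrow = B, ncol = n)
  xt <- t(x)                      # n x T; rows indexable by drawn column
  acc <- xt[idx[, 1L], , drop = FALSE]
  if (n > 1L)
    for (j in 2:n) acc <- acc + xt[idx[, j], , drop = FALSE]
  acc / n
}

#' Percentile bootstrap CI with small-sample narrowness adjustment
#'
#' The raw bounds are the `(1 - level) / 2` and `1 - (1 - level) / 2`
#' empirical quantiles of the bootstrap distribution (linear interpolation
#' between order statistics). Because percentile intervals from n
#' animals/trials are systematically narrow at small n, the interval is
#' then widened about the bootstrap mean `m` by `f = sqrt(n / (n - 1))`:
#' `low = m - f * (m - q_low)`, `high = m + f * (q_high - m)`. For
#' `n = 1` the factor is defined as 1 (degenerate interval).
#'
#' @param samples numeric vector of bootstrap estimates for one
#'   timepoint.
#' @param confidence_level CI level in (0, 1).
#' @param n number of animals/trials the bootstrap resampled.
#' @return `c(lower, upper)`.
#' @export
adjusted_percentile_ci <- function(samples, confidence_level, n) {
  if (confidence_level <= 0 || confidence_level >= 1)
    stop("`confidence_level` must be strictly between 0 and 1",
         call. = FALSE)
  if (length(samples) == 0L)
    stop("`samples` must be non-empty", call. = FALSE)
  stopifnot(n >= 1L)
  alpha <- (1 - confidence_level) / 2
  q <- stats::quantile(samples, probs = c(alpha, 1 - alpha),
                       names = FALSE, type = 7)
  m <- mean(samples)
  f <- narrowness_factor(n)
  c(m - f * (m - q[1L]), m + f * (q[2L] - m))
}

# the small-sample adjustment, isolated so the functional form can be
# swapped in one place
narrowness_factor <- function(n) {
  if (n <= 1L) 1 else sqrt(n / (n - 1))
}

# vectorized CI band + flags from a B x T bootstrap sample matrix
ci_band_from_samples <- function(S, confidence_level, n) {
  alpha <- (1 - confidence_level) / 2
  q <- apply(S, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
             names = FALSE, type = 7)
  m <- colMeans(S)
  f <- narrowness_factor(n)
  lower <- m - f * (m - q[1L, ])
  upper <- m + f * (q[2L, ] - m)
  band <- list(lower = lower, upper = upper, point_estimate = m)
  class(band) <- "ci_band"
  # strict exclusion of the null: an endpoint exactly 0 still contains 0
  flags <- as.integer(lower > 0 | upper < 0)
  list(band = band, map = flags)
}

#' Per-timepoint significance of one group against the baseline null of 0
#'
#' Bootstraps the group mean at every timepoint and flags timepoints
#' whose adjusted CI strictly excludes 0. The data are assumed already
#' normalized (e.g. baseline z-scored) so that 0 is the baseline null; no
#' re-baselining is performed. The consecutive threshold is *not* applied
#' here — compose with [apply_consecutive_threshold()].
#'
#' @param group numeric matrix (timepoints x animals/trials).
#' @param cfg a [bootstrap_config()].
#' @return list with `band` (a `ci_band`: `lower`, `upper`,
#'   `point_estimate`, each length T) and `map` (integer 0/1 vector,
#'   1 = significant).
#' @export
baseline_significance <- function(group, cfg) {
  group <- as.matrix(group)
  with_seed_if(cfg$seed, {
    S <- bootstrap_mean_samples(group, cfg$n_resamples)
    ci_band_from_samples(S, cfg$confidence_level, ncol(group))
  })
}

#' Between-subjects per-timepoint group difference
#'
#' Bootstraps the mean of each group independently (same number of
#' resamples), subtracts the bootstrap distributions row-wise, and flags
#' timepoints whose adjusted CI of the difference strictly excludes 0.
#' Column counts may differ; the narrowness adjustment conservatively
#' uses `n = min(nA, nB)`.
#'
#' @param group_a,group_b numeric matrices sharing the number of rows.
#' @param cfg a [bootstrap_config()].
#' @return as [baseline_significance()]; the band is for A minus B.
#' @export
between_group_difference <- function(group_a, group_b, cfg) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) != nrow(group_b))
    stop("groups must share the same number of timepoints", call. = FALSE)
  with_seed_if(cfg$seed, {
    SA <- bootstrap_mean_samples(group_a, cfg$n_resamples)
    SB <- bootstrap_mean_samples(group_b, cfg$n_resamples)
    ci_band_from_samples(SA - SB, cfg$confidence_level,
                         min(ncol(group_a), ncol(group_b)))
  })
}

#' Within-subjects (paired) per-timepoint group difference
#'
#' Subtracts each animal/trial between the groups (column j of A paired
#' with column j of B), bootstraps the paired differences, and flags
#' timepoints whose adjusted CI strictly excludes 0. Requires the same
#' number of animals/trials in each group.
#'
#' @param group_a,group_b numeric matrices with identical dimensions.
#' @param cfg a [bootstrap_config()].
#' @return as [baseline_significance()]; the band is for A minus B.
#' @export
within_group_difference <- function(group_a, group_b, cfg) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) != nrow(group_b))
    stop("groups must share the same number of timepoints", call. = FALSE)
  if (ncol(group_a) != ncol(group_b))
    stop("within-groups analysis needs the same number of animals/trials ",
         "in each group; with unequal groups it is appropriate to run the ",
         "between-groups analysis", call. = FALSE)
  d <- group_a - group_b
  with_seed_if(cfg$seed, {
    S <- bootstrap_mean_samples(d, cfg$n_resamples)
    ci_band_from_samples(S, cfg$confidence_level, ncol(d))
  })
}

#' Consecutive-threshold filtering of a binary significance map
#'
#' Per-timepoint testing produces spurious short crossings; requiring a
#' minimum number of consecutive significant samples controls this
#' family-wise Type 1 error without the cost in Type 2 error of a global
#' correction. Every maximal run of 1s shorter than `k` samples is
#' zeroed; runs of length >= k are kept intact. `k` of 0 or 1 returns the
#' map unchanged (any single significant point stands).
#'
#' @param map integer/logical 0-1 vector.
#' @param k non-negative integer minimum run length, in samples.
#' @return integer 0/1 vector of the same length.
#' @examples
#' apply_consecutive_threshold(c(1, 1, 0, 1), 2)
#' @export
apply_consecutive_threshold <- function(map, k) {
  if (k < 0 || k != round(k))
    stop("`k` must be a non-negative integer", call. = FALSE)
  map <- as.integer(map)
  if (!all(map %in% c(0L, 1L)))
    stop("`map` must be binary (0/1)", call. = FALSE)
  if (k <= 1L || length(map) == 0L) return(map)
  r <- rle(map)
  r$values[r$values == 1L & r$lengths < k] <- 0L
  inverse.rle(r)
}

#' Recommend a consecutive threshold from sensor and filter properties
#'
#' The shortest physiologically meaningful deviation is bounded below by
#' the sensor kinetics (rise time plus half-decay time) and by any
#' low-pass filtering (rule of thumb: 1 s divided by the filter cutoff,
#' the "low-pass frequency window"). The recommended duration is the most
#' conservative (longest) of these and any user-supplied minimum, then
#' converted to samples at the current sampling rate (round half up,
#' floor of 1 sample). For a dopamine sensor with ~0.08 s rise and
#' ~0.33 s half-decay sampled at 10 Hz this gives 4 samples; a 6 Hz
#' low-pass alone gives 2 samples.
#'
#' @param rise_s sensor rise (on) time, seconds.
#' @param half_decay_s sensor half-decay (off) time, seconds.
#' @param low_pass_hz optional low-pass filter cutoff applied during
#'   recording, Hz.
#' @param sampling_hz sampling rate of the data being thresholded, Hz
#'   (after any downsampling).
#' @param user_min_s optional user-defined minimum duration, seconds
#'   (e.g. the time a behaviour of interest takes).
#' @return integer number of samples.
#' @export
recommend_consecutive_threshold <- function(rise_s, half_decay_s,
                                            low_pass_hz = NULL, sampling_hz,
                                            user_min_s = NULL) {
  if (sampling_hz <= 0)
    stop("`sampling_hz` must be positive", call. = FALSE)
  if (rise_s < 0 || half_decay_s < 0)
    stop("durations must be non-negative", call. = FALSE)
  constraint_s <- rise_s + half_decay_s
  if (!is.null(low_pass_hz)) {
    if (low_pass_hz <= 0) stop("`low_pass_hz` must be positive", call. = FALSE)
    constraint_s <- max(constraint_s, 1 / low_pass_hz)
  }
  if (!is.null(user_min_s)) {
    if (user_min_s < 0) stop("`user_min_s` must be non-negative", call. = FALSE)
    constraint_s <- max(constraint_s, user_min_s)
  }
  max(1L, as.integer(floor(constraint_s * sampling_hz + 0.5)))
}

#' Row indices of the significant timepoints of a map
#'
#' @param map integer/logical 0-1 vector.
#' @return ascending 0-based row indices where the map is 1 (matching the
#'   workbook row-index convention where the first data row is row 0).
#' @export
significant_rows <- function(map) {
  map <- as.integer(map)
  if (!all(map %in% c(0L, 1L)))
    stop("`map` must be binary (0/1)", call. = FALSE)
  which(map == 1L) - 1L
}
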