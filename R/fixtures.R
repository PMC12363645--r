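# Seeded synthetic peri-event datasets. The defaults emulate a typical
# peri-event layout for a fast fluorescent sensor experiment: 813
# timepoints spanning -20 s to +60 s at ~10 Hz (event at row 213, i.e.
# rows 0-212 are the pre-event baseline), 3 groups of n = 7
# animals/trials, unit-variance noise on a baseline z-scored scale.

#' Specification of a synthetic peri-event dataset
#'
#' Each animal/trial column is i.i.d. Gaussian noise plus, from the event
#' row onward, a peak-normalized difference-of-exponentials transient
#' `(1 - exp(-t / rise_s)) * exp(-t / decay_s)` scaled by the group
#' amplitude plus a per-subject random offset. The pre-event expected
#' mean is 0, matching baseline-normalized data.
#'
#' @param n_groups number of groups (sheets).
#' @param n_subjects animals/trials per group.
#' @param n_timepoints rows per sheet.
#' @param sampling_hz nominal sampling rate used to convert the kernel
#'   time constants to rows.
#' @param event_row 0-based row at which the transient starts.
#' @param amplitudes per-group response amplitude in noise-SD (z) units;
#'   length `n_groups`. All-zero amplitudes give a pure-noise null
#'   dataset.
#' @param rise_s,decay_s kernel rise and decay time constants, seconds.
#'   Defaults mirror a fast dopamine sensor (~0.08 s rise; decay constant
#'   0.48 s, i.e. ~0.33 s half-decay).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param subject_sd SD of the per-subject amplitude offset.
#' @param paired if `TRUE`, subject offsets (and subject identity) are
#'   shared across groups, giving the correlated columns a
#'   within-subjects design assumes.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_groups = 3L, n_subjects = 7L,
                           n_timepoints = 813L, sampling_hz = 10,
                           event_row = 213L,
                           amplitudes = rep(0, n_groups),
                           rise_s = 0.08, decay_s = 0.48,
                           noise_sd = 1, subject_sd = 0,
                           paired = TRUE, seed = 1L) {
  if (n_groups < 1L || n_subjects < 1L || n_timepoints < 2L)
    stop("counts must be positive (and n_timepoints >= 2)", call. = FALSE)
  if (event_row < 0L || event_row >= n_timepoints)
    stop("`event_row` must lie inside the peri-event window", call. = FALSE)
  if (length(amplitudes) != n_groups)
    stop("`amplitudes` must have one entry per group", call. = FALSE)
  if (noise_sd < 0 || subject_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (sampling_hz <= 0 || rise_s <= 0 || decay_s <= 0)
    stop("rates and time constants must be positive", call. = FALSE)
  structure(list(n_groups = as.integer(n_groups),
                 n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 sampling_hz = sampling_hz,
                 event_row = as.integer(event_row),
                 amplitudes = as.numeric(amplitudes),
                 rise_s = rise_s, decay_s = decay_s,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 paired = isTRUE(paired), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# peak-normalized difference-of-exponentials transient on the rows at and
# after the event
transient_kernel <- function(spec) {
  kern <- numeric(spec$n_timepoints)
  t_post <- (seq_len(spec$n_timepoints) - 1L - spec$event_row) /
    spec$sampling_hz
  post <- t_post >= 0
  raw <- (1 - exp(-t_post[post] / spec$rise_s)) *
    exp(-t_post[post] / spec$decay_s)
  peak <- max(raw)
  kern[post] <- if (peak > 0) raw / peak else raw
  kern
}

#' Generate a synthetic peri-event dataset
#'
#' @param spec a [synthetic_spec()].
#' @return a [peri_dataset()] with groups `group_1 ... group_k`,
#'   bit-identical for identical specs.
#' @examples
#' d <- generate_event_dataset(synthetic_spec(n_timepoints = 100,
#'                                            event_row = 20, seed = 7))
#' @export
generate_event_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kern <- transient_kernel(spec)
  withr::with_seed(spec$seed, {
    shared_offsets <- stats::rnorm(spec$n_subjects, 0, spec$subject_sd)
    groups <- lapply(seq_len(spec$n_groups), function(g) {
      noise <- matrix(stats::rnorm(spec$n_timepoints * spec$n_subjects,
                                   0, spec$noise_sd),
                      spec$n_timepoints, spec$n_subjects)
      offsets <- if (spec$paired) shared_offsets
                 else stats::rnorm(spec$n_subjects, 0, spec$subject_sd)
      noise + outer(kern, spec$amplitudes[g] + offsets)
    })
    names(groups) <- paste0("group_", seq_len(spec$n_groups))
    peri_dataset(groups)
  })
}

#' Generate a pure-noise (null) peri-event dataset
#'
#' Convenience wrapper: [generate_event_dataset()] with all amplitudes 0.
#'
#' @param n_groups,n_subjects,n_timepoints,noise_sd,seed see
#'   [synthetic_spec()].
#' @return a [peri_dataset()] of i.i.d. Gaussian noise.
#' @export
generate_null_dataset <- function(n_groups = 3L, n_subjects = 7L,
                                  n_timepoints = 813L, noise_sd = 1,
                                  seed = 1L) {
  spec <- synthetic_spec(n_groups = n_groups, n_subjects = n_subjects,
                         n_timepoints = n_timepoints,
                         event_row = max(1L, n_timepoints %/% 4L),
                         amplitudes = rep(0, n_groups),
                         noise_sd = noise_sd, seed = seed)
  generate_event_dataset(spec)
}
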