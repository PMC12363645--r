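# Window-level permutation tests. Each animal/trial is first reduced to
# its mean over the window, so the exchangeable unit is the animal/trial,
# matching the bootstrap design. The test statistic is the absolute
# difference of group means (two-sided).

#' Permutation test configuration
#'
#' @param n_permutations number of random permutations; 1,000 is
#'   standard. The smallest resolvable p value is
#'   `1 / n_permutations` — raise it for finer resolution, especially at
#'   small sample sizes.
#' @param design `"between"` (group labels shuffled) or `"within"`
#'   (signs of the paired differences flipped).
#' @param seed optional integer seed.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 1000L,
                               design = c("between", "within"),
                               seed = NULL) {
  design <- match.arg(design)
  if (n_permutations < 1L || n_permutations != round(n_permutations))
    stop("`n_permutations` must be a positive integer", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 design = design,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "permutation_config")
}

#' Per-animal mean over a row window
#'
#' @param x numeric matrix (timepoints x animals/trials).
#' @param start,end 0-based inclusive row indices of the window.
#' @return numeric vector: the window mean of each column.
#' @export
window_subject_means <- function(x, start, end) {
  x <- as.matrix(x)
  if (start < 0 || end < start || end > nrow(x) - 1L)
    stop("window row indices must be non-negative and the data to be ",
         "analyzed should be equal to or less than the maximum number of ",
         "rows (max row index ", nrow(x) - 1L, ")", call. = FALSE)
  colMeans(x[(start + 1L):(end + 1L), , drop = FALSE])
}

#' Monte-Carlo permutation test on per-animal window means
#'
#' Tests whether the observed difference of group means could have come
#' from one common distribution. Between design: the pooled values are
#' randomly reassigned to the two groups (preserving group sizes)
#' `n_permutations` times. Within design: the sign of each paired
#' difference is flipped at random. The two-sided p value is the
#' proportion of permuted absolute differences at least as large as the
#' observed absolute difference (`count / n_permutations`, full
#' precision; a reported 0 means below `1 / n_permutations`).
#'
#' @param a,b numeric vectors of per-animal window means (see
#'   [window_subject_means()]); paired element-wise for the within
#'   design.
#' @param cfg a [permutation_config()].
#' @return list with `observed_mean_difference` (`mean(a) - mean(b)`,
#'   signed) and `p_value`.
#' @export
permutation_test <- function(a, b, cfg) {
  stopifnot(inherits(cfg, "permutation_config"))
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  observed <- mean(a) - mean(b)
  B <- cfg$n_permutations
  p <- with_seed_if(cfg$seed, {
    if (cfg$design == "within") {
      if (length(a) != length(b))
        stop("within-groups analysis needs the same number of ",
             "animals/trials in each group", call. = FALSE)
      d <- a - b
      n <- length(d)
      signs <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
      stat <- abs(as.vector(signs %*% d) / n)
      sum(stat >= abs(observed)) / B
    } else {
      z <- c(a, b)
      na <- length(a); N <- length(z); nb <- N - na
      total <- sum(z)
      sa <- vapply(seq_len(B), function(i)
        sum(z[sample.int(N, na)]), 0)
      stat <- abs(sa / na - (total - sa) / nb)
      sum(stat >= abs(observed)) / B
    }
  })
  list(observed_mean_difference = observed, p_value = p)
}

#' Exact permutation p value by full enumeration
#'
#' Reference oracle for small samples: enumerates every equal-size label
#' assignment (between design) or every sign pattern of the paired
#' differences (within design) and returns the exact two-sided p value —
#' the proportion of assignments whose absolute mean difference is at
#' least the observed one.
#'
#' @param a,b numeric vectors of per-animal window means.
#' @param design `"between"` or `"within"`.
#' @return exact p value in (0, 1].
#' @export
exact_permutation_p <- function(a, b, design = c("between", "within")) {
  design <- match.arg(design)
  a <- as.numeric(a); b <- as.numeric(b)
  observed <- abs(mean(a) - mean(b))
  tol <- 1e-12 * max(1, observed)  # guard >= against representation noise
  if (design == "within") {
    if (length(a) != length(b))
      stop("within design requires paired groups of equal size",
           call. = FALSE)
    d <- a - b
    n <- length(d)
    if (2^n > 1e6)
      stop("enumeration too large (2^", n, " sign patterns); ",
           "use the Monte-Carlo permutation_test()", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(as.vector(signs %*% d) / n)
    sum(stat >= observed - tol) / nrow(signs)
  } else {
    z <- c(a, b)
    na <- length(a); N <- length(z); nb <- N - na
    if (choose(N, na) > 1e6)
      stop("enumeration too large (", choose(N, na), " assignments); ",
           "use the Monte-Carlo permutation_test()", call. = FALSE)
    combos <- utils::combn(N, na)
    total <- sum(z)
    sa <- colSums(matrix(z[combos], nrow = na))
    stat <- abs(sa / na - (total - sa) / nb)
    sum(stat >= observed - tol) / ncol(combos)
  }
}

#' Baseline/comparison window specification
#'
#' 0-based inclusive row index windows (row 0 is the first data row; the
#' maximum usable index is `n_timepoints - 1`).
#'
#' @param baseline_start,baseline_end rows of the baseline (pre-event)
#'   period.
#' @param comparison_start,comparison_end rows of the comparison
#'   (post-event) period.
#' @return a `window_spec` list.
#' @export
window_spec <- function(baseline_start, baseline_end,
                        comparison_start, comparison_end) {
  w <- lapply(list(baseline_start = baseline_start,
                   baseline_end = baseline_end,
                   comparison_start = comparison_start,
                   comparison_end = comparison_end), function(v) {
    if (length(v) != 1L || !is.finite(v) || v != round(v) || v < 0)
      stop("window row indices must be non-negative integers",
           call. = FALSE)
    as.integer(v)
  })
  if (w$baseline_start > w$baseline_end ||
      w$comparison_start > w$comparison_end)
    stop("each window must have start <= end", call. = FALSE)
  structure(w, class = "window_spec")
}

check_windows <- function(windows, n) {
  stopifnot(inherits(windows, "window_spec"))
  if (windows$baseline_end > n - 1L || windows$comparison_end > n - 1L)
    stop("window row indices must be non-negative and the data to be ",
         "analyzed should be equal to or less than the maximum number of ",
         "rows (max row index ", n - 1L, ")", call. = FALSE)
  invisible(TRUE)
}

# deterministic substream seeds: one per task, derived from the master
# seed so results do not depend on evaluation order or worker count
derive_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) + 1000003 * index) %% 2147483647)
}

#' Full pairwise analysis suite
#'
#' For every unordered pair of groups: a permutation test of the window
#' means over the baseline period and over the comparison period, and a
#' per-timepoint difference significance map (between- or within-subjects
#' per the bootstrap config) with the consecutive threshold applied. For
#' every group: a per-timepoint significance-from-baseline map (null of
#' 0), also thresholded. All resampling draws come from substreams
#' derived deterministically from the config seeds, so a fixed seed gives
#' bit-identical results regardless of evaluation order.
#'
#' @param dataset a [peri_dataset()].
#' @param windows a [window_spec()].
#' @param boot_cfg a [bootstrap_config()]; its `design` selects the
#'   pairwise map method and, for `"within"`, requires equal column
#'   counts.
#' @param perm_cfg a [permutation_config()]; its design should normally
#'   match `boot_cfg$design`.
#' @return a `results_bundle`: `pairwise_results` (data frame with the
#'   comparison label, baseline/comparison observed mean differences and
#'   permutation p values at full precision, and the list of significant
#'   timepoints), `pairwise_maps` and `baseline_maps` (T x k 0/1
#'   matrices), `pairwise_bands` and `baseline_bands` (CI bands), and
#'   `settings` (the echoed [settings_record()]).
#' @export
run_pairwise_suite <- function(dataset, windows, boot_cfg, perm_cfg) {
  stopifnot(inherits(dataset, "peri_dataset"),
            inherits(boot_cfg, "bootstrap_config"),
            inherits(perm_cfg, "permutation_config"))
  n <- n_timepoints(dataset)
  check_windows(windows, n)
  if (boot_cfg$design == "within" || perm_cfg$design == "within")
    validate_equal_columns(dataset)
  gn <- group_names(dataset)
  G <- length(gn)
  k <- boot_cfg$consecutive_threshold

  baseline_maps <- matrix(0L, n, G, dimnames = list(NULL, gn))
  baseline_bands <- vector("list", G); names(baseline_bands) <- gn
  task <- 0L
  for (g in seq_len(G)) {
    task <- task + 1L
    cfg_g <- boot_cfg
    cfg_g$seed <- derive_seed(boot_cfg$seed, task)
    res <- baseline_significance(dataset[[g]], cfg_g)
    baseline_maps[, g] <- apply_consecutive_threshold(res$map, k)
    baseline_bands[[g]] <- res$band
  }

  pairs <- if (G >= 2L) utils::combn(G, 2L) else
    matrix(integer(0), nrow = 2L)
  np <- ncol(pairs)
  pair_label <- if (np) sprintf("%s_vs_%s", gn[pairs[1L, ]], gn[pairs[2L, ]])
                else character(0)
  pairwise_maps <- matrix(0L, n, np, dimnames = list(NULL, pair_label))
  pairwise_bands <- vector("list", np); names(pairwise_bands) <- pair_label
  base_diff <- base_p <- comp_diff <- comp_p <- numeric(np)
  sig_rows <- vector("list", np)

  for (p in seq_len(np)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    a <- dataset[[i]]; b <- dataset[[j]]

    task <- task + 1L
    cfg_p <- boot_cfg
    cfg_p$seed <- derive_seed(boot_cfg$seed, task)
    res <- if (boot_cfg$design == "within")
      within_group_difference(a, b, cfg_p)
    else
      between_group_difference(a, b, cfg_p)
    pairwise_maps[, p] <- apply_consecutive_threshold(res$map, k)
    pairwise_bands[[p]] <- res$band
    sig_rows[[p]] <- significant_rows(pairwise_maps[, p])

    for (win in c("baseline", "comparison")) {
      task <- task + 1L
      pcfg <- perm_cfg
      pcfg$seed <- derive_seed(perm_cfg$seed, task)
      ws <- windows[[paste0(win, "_start")]]
      we <- windows[[paste0(win, "_end")]]
      pt <- permutation_test(window_subject_means(a, ws, we),
                             window_subject_means(b, ws, we), pcfg)
      if (win == "baseline") {
        base_diff[p] <- pt$observed_mean_difference
        base_p[p] <- pt$p_value
      } else {
        comp_diff[p] <- pt$observed_mean_difference
        comp_p[p] <- pt$p_value
      }
    }
  }

  settings <- settings_record(
    confidence_level = boot_cfg$confidence_level,
    n_resamples = boot_cfg$n_resamples,
    n_permutations = perm_cfg$n_permutations,
    consecutive_threshold = k,
    design = boot_cfg$design,
    baseline_start = windows$baseline_start,
    baseline_end = windows$baseline_end,
    comparison_start = windows$comparison_start,
    comparison_end = windows$comparison_end,
    seed = boot_cfg$seed,
    input_path = attr(dataset, "source_path"))

  pairwise_results <- data.frame(
    comparison = pair_label,
    baseline_mean_difference = base_diff,
    baseline_p_value = base_p,
    comparison_mean_difference = comp_diff,
    comparison_p_value = comp_p,
    stringsAsFactors = FALSE)
  pairwise_results$significant_timepoints <- sig_rows

  structure(list(pairwise_results = pairwise_results,
                 pairwise_maps = pairwise_maps,
                 baseline_maps = baseline_maps,
                 pairwise_bands = pairwise_bands,
                 baseline_bands = baseline_bands,
                 settings = settings),
            class = "results_bundle")
}
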