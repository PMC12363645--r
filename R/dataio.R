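# Workbook I/O for group-per-sheet peri-event data.
#
# Canonical input is an XLSX workbook: one sheet per group/condition, one
# column per animal or trial, one row per peri-event timepoint. A directory
# of CSV files (one file per group, filename = group name) is accepted as a
# plain-text equivalent.

# Convert a sheet read as text into a numeric matrix, applying the header
# heuristic: the first row is data if every cell parses as a number,
# otherwise it is taken as column labels.
sheet_to_matrix <- function(cells, where) {
  if (length(cells) == 0L || nrow(cells) == 0L || ncol(cells) == 0L)
    stop("Non-numeric data found in Excel sheets or input file is empty: ",
         where, " has no data", call. = FALSE)
  cells <- as.matrix(cells)
  first <- suppressWarnings(as.numeric(cells[1L, ]))
  if (anyNA(first)) {
    labels <- as.character(cells[1L, ])
    cells <- cells[-1L, , drop = FALSE]
  } else {
    labels <- paste0("trial_", seq_len(ncol(cells)) - 1L)
  }
  if (nrow(cells) == 0L)
    stop("Non-numeric data found in Excel sheets or input file is empty: ",
         where, " has a header but no data rows", call. = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals))
    stop("Non-numeric data found in Excel sheets or input file is empty: ",
         where, " contains non-numeric or blank cells", call. = FALSE)
  m <- matrix(vals, nrow = nrow(cells), ncol = ncol(cells))
  colnames(m) <- labels
  m
}

#' Read a group-per-sheet workbook into a peri-event dataset
#'
#' Each sheet of the workbook is one group of data and each column one
#' animal/trial; timepoints are represented by the row index. Sheet order
#' is preserved. If the first row of a sheet is entirely numeric it is
#' treated as data; otherwise it is taken as the animal/trial labels.
#' Alternatively `path` may be a directory containing one CSV file per
#' group (filename stem = group name, comma separated, `.` decimal);
#' files are read in lexicographic order.
#'
#' All cells inside the data rectangle must be numeric: blank or text
#' cells, and sheets with differing row counts, raise a validation error
#' rather than being silently dropped.
#'
#' @param path an `.xlsx` workbook, or a directory of per-group `.csv`
#'   files.
#' @return a [peri_dataset()] whose `source_path` is `path`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop("cannot read input: no such file or directory: ", path,
         call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L)
      stop("Non-numeric data found in Excel sheets or input file is empty: ",
           "no .csv files in ", path, call. = FALSE)
    groups <- lapply(files, function(f) {
      cells <- tryCatch(
        utils::read.csv(f, header = FALSE, colClasses = "character",
                        strip.white = TRUE),
        error = function(e)
          stop("Non-numeric data found in Excel sheets or input file is ",
               "empty: ", f, " (", conditionMessage(e), ")", call. = FALSE))
      sheet_to_matrix(cells, paste0("file '", basename(f), "'"))
    })
    names(groups) <- sub("\\.csv$", "", basename(files))
    return(peri_dataset(groups, source_path = path))
  }
  sheets <- readxl::excel_sheets(path)
  if (length(sheets) == 0L)
    stop("Non-numeric data found in Excel sheets or input file is empty: ",
         path, call. = FALSE)
  groups <- lapply(sheets, function(s) {
    cells <- readxl::read_excel(path, sheet = s, col_names = FALSE,
                                col_types = "text",
                                .name_repair = "minimal")
    sheet_to_matrix(cells, paste0("sheet '", s, "'"))
  })
  names(groups) <- sheets
  peri_dataset(groups, source_path = path)
}

#' Write a peri-event dataset as a group-per-sheet workbook
#'
#' One sheet per group; the header row carries the animal/trial labels so
#' the output indexes how many columns were analyzed per sheet.
#'
#' @param dataset a [peri_dataset()].
#' @param path output `.xlsx` path; overwritten (with a warning) if it
#'   exists.
#' @return the output path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "peri_dataset"))
  sheets <- lapply(dataset, function(m)
    as.data.frame(m, check.names = FALSE))
  write_workbook(sheets, path)
  invisible(path)
}

#' Downsample a dataset and write it with the standard output name
#'
#' Applies [downsample()] and writes the result as
#' `<input stem>_downsampled_<factor>.xlsx` in `out_dir`, preserving the
#' sheet and column structure of the input.
#'
#' @param dataset a [peri_dataset()].
#' @param factor positive integer block size (see [downsample()]).
#' @param out_dir output directory; must exist and be writable.
#' @return the output file path.
#' @export
write_downsampled <- function(dataset, factor, out_dir) {
  check_out_dir(out_dir)
  ds <- downsample(dataset, factor)
  out <- file.path(out_dir, sprintf("%s_downsampled_%d.xlsx",
                                    dataset_stem(dataset), as.integer(factor)))
  write_dataset(ds, out)
  out
}

#' Write mean time bins with the standard output name
#'
#' Writes the table produced by [time_bin_means()] as
#' `<input stem>_time_bin_means.xlsx`: one sheet per group (rows = bins,
#' columns = animals/trials) plus a settings sheet recording the number of
#' bins and the 0-based inclusive start/end row index of each bin.
#'
#' @param table a `time_bin_table` from [time_bin_means()].
#' @param bins the bin specification; defaults to the bins stored in
#'   `table`.
#' @param out_dir output directory.
#' @return the output file path.
#' @export
write_time_bin_means <- function(table, bins = attr(table, "bins"), out_dir) {
  stopifnot(inherits(table, "time_bin_table"))
  check_out_dir(out_dir)
  bins <- as_bin_matrix(bins)
  sheets <- lapply(table, function(m) as.data.frame(m, check.names = FALSE))
  sheets$settings <- data.frame(
    setting = c("n_bins",
                sprintf("bin_%d_start_row", seq_len(nrow(bins))),
                sprintf("bin_%d_end_row", seq_len(nrow(bins)))),
    value = as.character(c(nrow(bins), bins[, 1L], bins[, 2L])),
    stringsAsFactors = FALSE)
  out <- file.path(out_dir, sprintf("%s_time_bin_means.xlsx",
                                    attr(table, "stem")))
  write_workbook(sheets, out)
  out
}

#' Write an analysis results workbook
#'
#' Writes `<input stem>_results.xlsx` with four sheets:
#' `pairwise_comparisons` (per group pair: baseline-window mean difference
#' and permutation p, comparison-window mean difference and permutation p,
#' and a final column listing all significant timepoints),
#' `pairwise_maps` (per-timepoint binary significance of each pairwise
#' difference; 1 denotes significance), `baseline_maps` (per-group
#' significance against the baseline null of 0), and `settings` (the exact
#' analysis settings used). P values are rendered to three decimals — a
#' rendered value of 0.000 means p < 0.001 at 1,000 permutations — while
#' full precision is retained in the in-memory bundle.
#'
#' @param bundle a `results_bundle` from [run_pairwise_suite()].
#' @param out_dir output directory.
#' @return the output file path.
#' @export
write_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  check_out_dir(out_dir)
  pw <- bundle$pairwise_results
  comp_df <- data.frame(
    comparison = pw$comparison,
    baseline_mean_difference = pw$baseline_mean_difference,
    baseline_p_value = sprintf("%.3f", pw$baseline_p_value),
    comparison_mean_difference = pw$comparison_mean_difference,
    comparison_p_value = sprintf("%.3f", pw$comparison_p_value),
    significant_timepoints = vapply(pw$significant_timepoints,
                                    function(v) paste(v, collapse = ","), ""),
    stringsAsFactors = FALSE)
  tp <- data.frame(timepoint = seq_len(nrow(bundle$pairwise_maps)) - 1L)
  out <- file.path(out_dir, sprintf("%s_results.xlsx",
                                    bundle$settings$input_stem))
  write_workbook(list(
    pairwise_comparisons = comp_df,
    pairwise_maps = cbind(tp, as.data.frame(bundle$pairwise_maps,
                                            check.names = FALSE)),
    baseline_maps = cbind(tp, as.data.frame(bundle$baseline_maps,
                                            check.names = FALSE)),
    settings = render_settings(bundle$settings)), out)
  out
}

check_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir))
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  invisible(TRUE)
}

# Settings record: exact echo of the values a run used, serializable to
# one two-column sheet. Text rendering here is the canonical form.
settings_record <- function(confidence_level, n_resamples, n_permutations,
                            consecutive_threshold, design,
                            baseline_start, baseline_end,
                            comparison_start, comparison_end,
                            seed = NULL, input_path = NA_character_) {
  list(confidence_level = confidence_level,
       n_resamples = as.integer(n_resamples),
       n_permutations = as.integer(n_permutations),
       consecutive_threshold = as.integer(consecutive_threshold),
       design = design,
       baseline_start = as.integer(baseline_start),
       baseline_end = as.integer(baseline_end),
       comparison_start = as.integer(comparison_start),
       comparison_end = as.integer(comparison_end),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
       input_path = input_path,
       input_stem = if (is.na(input_path)) "dataset"
                    else sub("\\.[A-Za-z0-9]+$", "", basename(input_path)))
}

render_settings <- function(s) {
  keys <- c("confidence_level", "n_resamples", "n_permutations",
            "consecutive_threshold", "design",
            "baseline_start", "baseline_end",
            "comparison_start", "comparison_end", "seed", "input_path")
  data.frame(setting = keys,
             value = vapply(keys, function(k) {
               v <- s[[k]]
               if (length(v) == 1L && is.na(v)) "" else as.character(v)
             }, ""),
             stringsAsFactors = FALSE)
}
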