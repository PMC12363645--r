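#' Peri-event dataset: ordered groups of timepoint-by-subject matrices
#'
#' A `peri_dataset` holds one numeric matrix per experimental group or
#' condition. Rows are peri-event timepoints (all groups share one time
#' axis), columns are animals or trials. The signal is assumed to be
#' already preprocessed upstream (e.g. baseline z-scored dF/F), so that a
#' value of 0 is the baseline null.
#'
#' @param groups named list of numeric matrices, one per group; rows =
#'   timepoints, columns = animals/trials. Names must be unique and
#'   non-empty. Column names, if present, are kept as animal/trial labels;
#'   otherwise labels `trial_0 ... trial_{n-1}` are assigned.
#' @param source_path optional path of the workbook the data came from,
#'   used to derive output file names.
#' @return an object of class `peri_dataset`: the validated list of group
#'   matrices with attributes `n_timepoints` and `source_path`.
#' @examples
#' d <- peri_dataset(list(ctrl = matrix(rnorm(20), 10, 2),
#'                        drug = matrix(rnorm(30), 10, 3)))
#' n_timepoints(d)
#' @export
peri_dataset <- function(groups, source_path = NA_character_) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("`groups` must be a non-empty list of numeric matrices", call. = FALSE)
  nms <- names(groups)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("every group must have a non-empty name", call. = FALSE)
  if (anyDuplicated(nms))
    stop("group names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  groups <- lapply(groups, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  for (g in seq_along(groups)) {
    m <- groups[[g]]
    if (ncol(m) < 1L || nrow(m) < 2L)
      stop("group '", nms[g], "' must have at least 1 column and 2 rows",
           call. = FALSE)
    if (!all(is.finite(m)))
      stop("Non-numeric data found in Excel sheets or input file is empty: ",
           "group '", nms[g], "' contains missing or non-finite values",
           call. = FALSE)
    if (is.null(colnames(m)))
      colnames(groups[[g]]) <- paste0("trial_", seq_len(ncol(m)) - 1L)
  }
  rows <- vapply(groups, nrow, 0L)
  if (length(unique(rows)) != 1L)
    stop("all groups must share the same number of timepoints (rows); got ",
         paste(sprintf("%s=%d", nms, rows), collapse = ", "), call. = FALSE)
  structure(groups,
            n_timepoints = unname(rows[1L]),
            source_path = source_path,
            class = "peri_dataset")
}

#' @rdname peri_dataset
#' @param x a `peri_dataset`.
#' @export
n_timepoints <- function(x) {
  stopifnot(inherits(x, "peri_dataset"))
  attr(x, "n_timepoints")
}

#' @rdname peri_dataset
#' @export
group_names <- function(x) {
  stopifnot(inherits(x, "peri_dataset"))
  names(x)
}

#' @export
print.peri_dataset <- function(x, ...) {
  cat(sprintf("peri_dataset: %d group(s) x %d timepoints\n",
              length(x), attr(x, "n_timepoints")))
  for (g in names(x))
    cat(sprintf("  %s: %d animals/trials\n", g, ncol(x[[g]])))
  if (!is.na(attr(x, "source_path")))
    cat("  source:", attr(x, "source_path"), "\n")
  invisible(x)
}

#' Require equal group sizes for a paired (within-subjects) analysis
#'
#' The within-subjects comparison subtracts animal/trial columns point by
#' point, so every group must carry the same number of columns. Unequal
#' designs must use the between-subjects analysis, which subtracts the
#' bootstrapped group distributions instead.
#'
#' @param dataset a [peri_dataset()].
#' @return invisibly `TRUE`; raises an error if column counts differ.
#' @export
validate_equal_columns <- function(dataset) {
  stopifnot(inherits(dataset, "peri_dataset"))
  ncols <- vapply(dataset, ncol, 0L)
  if (length(unique(ncols)) > 1L)
    stop("within-groups analysis needs the same number of animals/trials ",
         "in each group (got ",
         paste(sprintf("%s=%d", names(dataset), ncols), collapse = ", "),
         "); with unequal groups it is appropriate to run the ",
         "between-groups analysis", call. = FALSE)
  invisible(TRUE)
}

# stem of the input file used to build output names
dataset_stem <- function(dataset, default = "dataset") {
  sp <- attr(dataset, "source_path")
  if (is.null(sp) || is.na(sp) || !nzchar(sp)) return(default)
  sub("\\.[A-Za-z0-9]+$", "", basename(sp))
}
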