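# Minimal Office Open XML workbook writer.
#
# Only what the output contracts need: multiple named sheets, numeric cells
# at full double precision (%.17g survives a read/parse round trip), text
# cells as inline strings. Built on the `zip` package; read back with readxl.

xl_col_letter <- function(j) {
  s <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    s <- paste0(LETTERS[r + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

xl_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xl_cell <- function(ref, value) {
  if (is.na(value))
    return(sprintf('<c r="%s"/>', ref))
  if (is.character(value))
    return(sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                   ref, xl_escape(value)))
  sprintf('<c r="%s"><v>%s</v></c>', ref, sprintf("%.17g", value))
}

# df: data.frame whose columns are numeric or character; headers written
# from names(df) unless col_names = FALSE
xl_sheet_xml <- function(df, col_names = TRUE) {
  nc <- ncol(df)
  rows <- character(0)
  ri <- 1L
  letters_ <- vapply(seq_len(nc), xl_col_letter, "")
  if (isTRUE(col_names)) {
    cells <- vapply(seq_len(nc), function(j)
      xl_cell(paste0(letters_[j], ri), as.character(names(df)[j])), "")
    rows <- c(rows, sprintf('<row r="%d">%s</row>', ri,
                            paste(cells, collapse = "")))
    ri <- ri + 1L
  }
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_len(nc), function(j)
      xl_cell(paste0(letters_[j], ri), df[[j]][i]), "")
    rows <- c(rows, sprintf('<row r="%d">%s</row>', ri,
                            paste(cells, collapse = "")))
    ri <- ri + 1L
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""),
         '</sheetData></worksheet>')
}

# sheets: named list of data.frames; writes <path> and returns it
write_workbook <- function(sheets, path, col_names = TRUE) {
  stopifnot(is.list(sheets), length(sheets) > 0L,
            !is.null(names(sheets)), all(nzchar(names(sheets))))
  n <- length(sheets)
  if (length(col_names) == 1L) col_names <- rep(col_names, n)
  root <- tempfile("xlsxwb")
  on.exit(unlink(root, recursive = TRUE), add = TRUE)
  dir.create(file.path(root, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(root, "_rels"))
  dir.create(file.path(root, "xl", "_rels"))

  overrides <- paste(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    overrides, '</Types>'),
    file.path(root, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'),
    file.path(root, "_rels", ".rels"))

  sheet_tags <- paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                              xl_escape(names(sheets)), seq_len(n), seq_len(n)),
                      collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheet_tags, '</sheets></workbook>'),
    file.path(root, "xl", "workbook.xml"))

  rels <- paste(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, '</Relationships>'),
    file.path(root, "xl", "_rels", "workbook.xml.rels"))

  for (k in seq_len(n))
    writeLines(xl_sheet_xml(as.data.frame(sheets[[k]],
                                          check.names = FALSE,
                                          stringsAsFactors = FALSE),
                            col_names = col_names[k]),
               file.path(root, "xl", "worksheets", sprintf("sheet%d.xml", k)))

  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (file.exists(path)) {
    warning("overwriting existing output file: ", path, call. = FALSE)
    unlink(path)
  }
  # zip() runs from `root`, so the target must be absolute; normalize via
  # the parent directory (the file itself may not exist yet)
  abs_path <- file.path(normalizePath(dirname(path)), basename(path))
  zip::zip(abs_path,
           files = c("[Content_Types].xml", "_rels", "xl"),
           root = root, mode = "mirror")
  invisible(path)
}
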