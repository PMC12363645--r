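# shared builders for tiny in-code fixtures

tiny_dataset <- function(n_groups = 2L, n_rows = 5L, n_cols = 3L,
                         seed = 42L) {
  withr::with_seed(seed, {
    g <- lapply(seq_len(n_groups), function(i)
      matrix(rnorm(n_rows * n_cols), n_rows, n_cols))
    names(g) <- paste0("grp", LETTERS[seq_len(n_groups)])
    peri_dataset(g)
  })
}

constant_group <- function(value, n_rows = 4L, n_cols = 3L) {
  matrix(value, n_rows, n_cols)
}

# workbook on disk for I/O tests; returns the path
tiny_workbook <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                          name = "mydata.xlsx", ...) {
  d <- tiny_dataset(...)
  path <- file.path(dir, name)
  write_dataset(d, path)
  list(path = path, dataset = d)
}
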