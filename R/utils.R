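#' Read a delimited text file, autodetecting tab vs comma
#' @keywords internal
read_delim_auto <- function(path) {
  stopifnot(is.character(path), file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Write a data frame as tab-separated text
#' @keywords internal
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a derived RNG seed, restoring the caller's RNG state.
# Used by the synthetic renderers so each (strain, temperature, replicate)
# stream is reproducible in isolation.
#' @keywords internal
with_sub_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# Stable small-integer hash for deriving per-spectrum sub-seeds.
#' @keywords internal
sub_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  s <- as.numeric(seed)
  for (p in parts) s <- (s * 1103515245 + p * 12345) %% 2147483563
  as.integer(s)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
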