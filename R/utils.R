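#' Evaluate an expression with a local, restored RNG state
#'
#' All randomness in the package flows through explicit seeds; the caller's
#' global RNG stream is left untouched.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Deterministic numeric formatting used by all tabular writers so that a
## fixed config + inputs gives byte-identical output files.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

write_tsv_file <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write a labelled square matrix as TSV
#'
#' Residue labels form the header row and first column.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  labs <- rownames(m)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(m)))
  body <- apply(m, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  lines <- c(paste(c("residue", colnames(m) %||% labs), collapse = "\t"),
             paste(labs, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stable hash of an R object via its canonical JSON serialization (used to
## stamp run manifests; md5 of the serialized text).
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}
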