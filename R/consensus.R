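## Agreement metrics between dynamic networks derived by different methods
## (trajectory cross-correlation, ensemble model, experimental reference
## sets).  "Percent consistency" is read as recall of the reference set --
## the fraction of reference residues recovered by the query -- and the
## symmetric Jaccard index is co-reported so directional and symmetric
## comparisons are never conflated.

#' Percent consistency between a query and a reference region set
#'
#' percent = |residues(query) ∩ residues(reference)| / |residues(reference)|
#' x 100.  An empty reference leaves the percent undefined (reported as
#' `NA` with a warning).  The Jaccard index (intersection over union) is
#' reported alongside.
#'
#' @param query a `region_set` (e.g. the computed network).
#' @param reference a `region_set` (e.g. the experimental network).
#' @param labels optional `c(query =, reference =)` method labels.
#' @return a `consistency_report`: list with `percent`, `jaccard`,
#'   `recovered`, `reference_size`, `query_size`, a per-interval breakdown,
#'   and the labels.
#' @export
consistency_percent <- function(query, reference,
                                labels = c(query = "query",
                                           reference = "reference")) {
  stopifnot(inherits(query, "region_set"), inherits(reference, "region_set"))
  check_same_index(query, reference)
  q <- region_residues(query)
  r <- region_residues(reference)
  inter <- intersect(q, r)
  percent <- if (length(r) == 0L) {
    warning("empty reference set: percent consistency undefined")
    NA_real_
  } else 100 * length(inter) / length(r)
  uni <- union(q, r)
  jaccard <- if (length(uni) == 0L) NA_real_ else
    length(inter) / length(uni)
  iv <- reference$intervals
  breakdown <- if (nrow(iv)) {
    data.frame(start = iv$start, end = iv$end,
               recovered = vapply(seq_len(nrow(iv)), function(k)
                 sum(q >= iv$start[k] & q <= iv$end[k]), integer(1L)),
               size = iv$end - iv$start + 1L)
  } else data.frame(start = integer(), end = integer(),
                    recovered = integer(), size = integer())
  structure(list(percent = percent, jaccard = jaccard,
                 recovered = length(inter),
                 reference_size = length(r), query_size = length(q),
                 breakdown = breakdown, labels = labels),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency: %s vs %s\n", x$labels[["query"]],
              x$labels[["reference"]]))
  cat(sprintf("  recovered %d of %d reference residues (%.1f%%), Jaccard %.3f\n",
              x$recovered, x$reference_size,
              ifelse(is.na(x$percent), NaN, x$percent), x$jaccard))
  invisible(x)
}

#' Per-residue track table of labelled region sets
#'
#' One row per method and one column per residue (1 = inside the method's
#' network, 0 = outside), the tabular form of a sequence-track comparison
#' figure.  Deterministic given the inputs.
#'
#' @param sets named list of `region_set` objects.
#' @param n_residues residue index space size; all sets must fit inside it.
#' @return integer matrix, rows named by method, columns by residue index.
#' @export
render_track <- function(sets, n_residues) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            !is.null(names(sets)), !anyDuplicated(names(sets)))
  m <- matrix(0L, nrow = length(sets), ncol = n_residues,
              dimnames = list(names(sets), as.character(seq_len(n_residues))))
  for (k in seq_along(sets)) {
    res <- region_residues(sets[[k]])
    if (length(res) && (min(res) < 1L || max(res) > n_residues))
      stop("region set '", names(sets)[k], "' has residues outside [1, ",
           n_residues, "]")
    m[k, res] <- 1L
  }
  m
}

#' Write a track table as TSV
#'
#' @param track matrix from [render_track()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  df <- data.frame(method = rownames(track), track, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
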