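## Region sets: ordered residue intervals with a tier label, the shared
## currency between the correlation classifier, the EAM susceptibility
## extractor, and the consensus metrics.  Residues are addressed by their
## 1-based sequential node index (reports also carry chain/resno labels via
## the owning structure).

#' Construct a region set
#'
#' @param intervals data frame with integer columns `start`, `end` and a
#'   character column `tier`; intervals within one tier must be disjoint
#'   (they are sorted and merged by the constructor).
#' @param n_residues length of the residue index space.
#' @param note free-text provenance (e.g. anchor residue and method).
#' @return a `region_set` object.
#' @export
region_set <- function(intervals, n_residues, note = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- data.frame(start = integer(), end = integer(),
                            tier = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("start", "end", "tier") %in% names(intervals)),
            is.numeric(n_residues), n_residues >= 1L)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (nrow(intervals)) {
    if (any(intervals$start < 1L) || any(intervals$end > n_residues) ||
        any(intervals$start > intervals$end))
      stop("invalid interval bounds for residue index space [1, ",
           n_residues, "]")
    ## canonicalize: per tier, merge touching/overlapping runs and sort
    merged <- do.call(rbind, lapply(split(intervals, intervals$tier),
                                    function(d) {
      res <- sort(unique(unlist(Map(seq.int, d$start, d$end))))
      runs_to_intervals(res, d$tier[1L])
    }))
    intervals <- merged[order(intervals_tier_rank(merged$tier),
                              merged$start), , drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(intervals = intervals, n_residues = as.integer(n_residues),
                 note = note),
            class = "region_set")
}

## fixed display order for the correlation tiers; unknown tiers go last
intervals_tier_rank <- function(tier) {
  known <- c("red", "orange", "yellow", "anti", "region")
  r <- match(tier, known)
  r[is.na(r)] <- length(known) + 1L
  r
}

runs_to_intervals <- function(res, tier) {
  if (length(res) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      tier = character(), stringsAsFactors = FALSE))
  grp <- cumsum(c(1L, diff(res) != 1L))
  data.frame(start = tapply(res, grp, min), end = tapply(res, grp, max),
             tier = tier, row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a region set from a plain residue index vector
#'
#' Contiguous runs are merged into intervals.
#'
#' @param residues integer residue indices.
#' @param n_residues index space size.
#' @param tier tier label for all intervals.
#' @param note provenance note.
#' @return a `region_set`.
#' @export
regions_from_residues <- function(residues, n_residues, tier = "region",
                                  note = NULL) {
  residues <- sort(unique(as.integer(residues)))
  region_set(runs_to_intervals(residues, tier), n_residues, note)
}

#' Residue indices covered by a region set
#'
#' @param rs a `region_set`.
#' @param tiers optional tier labels to restrict to.
#' @return sorted integer vector of residue indices.
#' @export
region_residues <- function(rs, tiers = NULL) {
  stopifnot(inherits(rs, "region_set"))
  iv <- rs$intervals
  if (!is.null(tiers)) iv <- iv[iv$tier %in% tiers, , drop = FALSE]
  if (nrow(iv) == 0L) return(integer())
  sort(unique(unlist(Map(seq.int, iv$start, iv$end))))
}

check_same_index <- function(a, b) {
  if (a$n_residues != b$n_residues)
    stop("region sets are over different residue index spaces (",
         a$n_residues, " vs ", b$n_residues, ")")
}

#' Union of region sets
#'
#' Tier labels are dropped: the union is an untyped set of intervals
#' (re-merged at residue level).
#'
#' @param region_sets list of `region_set` objects over the same index space.
#' @return a `region_set` with tier `"region"`.
#' @export
combine_regions <- function(region_sets) {
  stopifnot(is.list(region_sets), length(region_sets) >= 1L,
            all(vapply(region_sets, inherits, logical(1L), "region_set")))
  n <- region_sets[[1L]]$n_residues
  lapply(region_sets, check_same_index, b = region_sets[[1L]])
  res <- sort(unique(unlist(lapply(region_sets, region_residues))))
  regions_from_residues(res, n, tier = "region",
                        note = "union of region sets")
}

#' Residue-level intersection of two region sets
#'
#' @param a,b `region_set` objects over the same index space.
#' @return a `region_set` with tier `"region"`.
#' @export
common_regions <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  check_same_index(a, b)
  res <- intersect(region_residues(a), region_residues(b))
  regions_from_residues(res, a$n_residues, tier = "region",
                        note = "intersection of region sets")
}

#' Write / read a region set as BED-like TSV
#'
#' Columns: start, end, tier (1-based inclusive residue indices).
#'
#' @param rs a `region_set`.
#' @param path file path.
#' @return the path (write) or a `region_set` (read).
#' @export
write_region_tsv <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  hdr <- sprintf("# n_residues=%d", rs$n_residues)
  lines <- c(hdr, paste("start", "end", "tier", sep = "\t"),
             sprintf("%d\t%d\t%s", rs$intervals$start, rs$intervals$end,
                     rs$intervals$tier))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_region_tsv
#' @param n_residues index space size; if `NULL`, taken from the file header.
#' @export
read_region_tsv <- function(path, n_residues = NULL) {
  lines <- readLines(path)
  if (is.null(n_residues)) {
    m <- regmatches(lines[1L], regexec("n_residues=([0-9]+)", lines[1L]))[[1L]]
    if (length(m) < 2L) stop("no n_residues header in ", path)
    n_residues <- as.integer(m[2L])
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  region_set(df, n_residues)
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set over", x$n_residues, "residues:",
      nrow(x$intervals), "interval(s),",
      length(region_residues(x)), "residue(s)\n")
  if (nrow(x$intervals)) print(x$intervals)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
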