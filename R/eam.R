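## Ensemble allosteric model (COREX/BEST-style).
##
## The chain is tiled into contiguous "folding units" (window of 8 residues,
## terminal units no shorter than 4).  Each unit is either folded or
## unfolded, giving 2^U exhaustively enumerated states; a state's free
## energy is the sum of the unfolding penalties g_u of its unfolded units,
## with the fully folded state at G = 0.  Boltzmann probabilities
## P = exp(-G/RT)/Z define, for every residue j, the stability constant
##
##   kappa_f,j = P(j folded) / P(j unfolded),   dG_f,j = -RT ln kappa_f,j
##
## and a mutation at residue k, modelled as an energetic perturbation
## delta_k of k's unit, changes every residue's free energy by
##
##   ddG_j,mut k = dG_f,j^mut - dG_f,j^WT.
##
## The full surface-area-based COREX energy function is unpublished; the
## unit energies here are a declared, pluggable surrogate (uniform
## calibration to an overall stability, user-supplied values, or
## contact-density derived), which leaves the ensemble machinery above
## intact.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal/(mol K)

#' Partition a chain into folding units
#'
#' Consecutive blocks of `window` residues from the N-terminus.  An
#' optional leading block of `shift` residues slides the partition; a
#' leading or trailing remainder shorter than `min_terminal` is merged into
#' its neighbouring unit, one of at least `min_terminal` stands alone.
#'
#' @param n_residues chain length.
#' @param window interior unit size (default 8).
#' @param min_terminal minimum terminal unit size (default 4).
#' @param shift leading offset in `[0, window)`.
#' @return a `folding_partition`: list with `units` (data frame `start`,
#'   `end`), `n_residues`, and the parameters.
#' @export
make_partition <- function(n_residues, window = 8L, min_terminal = 4L,
                           shift = 0L) {
  n_residues <- as.integer(n_residues)
  window <- as.integer(window); min_terminal <- as.integer(min_terminal)
  shift <- as.integer(shift)
  if (window < min_terminal) stop("window must be >= min_terminal")
  if (shift < 0L || shift >= window) stop("shift must be in [0, window)")
  if (n_residues < min_terminal)
    stop("chain shorter than the minimum terminal unit")
  starts <- integer(); ends <- integer()
  pos <- 1L
  if (shift > 0L) {
    if (shift >= min_terminal) {
      starts <- 1L; ends <- shift; pos <- shift + 1L
    }
    ## shift < min_terminal: leading remainder merges into the first
    ## window-sized unit (handled by leaving pos at 1 and widening below)
  }
  first_len <- if (shift > 0L && shift < min_terminal) window + shift else
    window
  while (pos <= n_residues) {
    len <- if (length(starts) == 0L && pos == 1L) first_len else window
    end <- min(pos + len - 1L, n_residues)
    remainder <- n_residues - end
    if (remainder > 0L && remainder < min_terminal) end <- n_residues
    starts <- c(starts, pos); ends <- c(ends, end)
    pos <- end + 1L
  }
  structure(list(units = data.frame(start = starts, end = ends),
                 n_residues = n_residues, window = window,
                 min_terminal = min_terminal, shift = shift),
            class = "folding_partition")
}

#' @export
print.folding_partition <- function(x, ...) {
  cat("folding_partition:", nrow(x$units), "units over", x$n_residues,
      "residues (window", x$window, ", min terminal", x$min_terminal, ")\n")
  invisible(x)
}

n_units <- function(partition) nrow(partition$units)

## unit index of each residue
residue_units <- function(partition) {
  u <- integer(partition$n_residues)
  for (k in seq_len(n_units(partition)))
    u[partition$units$start[k]:partition$units$end[k]] <- k
  u
}

#' Enumerate the folding-unit conformational ensemble
#'
#' All 2^U states are enumerated exhaustively (no sampling); the cap of
#' U = 24 keeps enumeration exact -- use a coarser window for longer
#' chains.  With `energies = NULL` the unit unfolding penalties are uniform
#' and calibrated so that the fully unfolded state sits at `overall_dg`
#' (g_u = overall_dg / U).
#'
#' @param partition a `folding_partition`.
#' @param energies per-unit unfolding penalties g_u in kcal/mol, or `NULL`
#'   for the uniform calibration.
#' @param overall_dg overall stability in kcal/mol used by the uniform
#'   calibration (default 5).
#' @param temperature temperature in K (default 298.15, i.e. 25 C).
#' @return an `ensemble_model`: partition, `g_u`, state free energies `G`,
#'   Boltzmann probabilities `P`, `temperature`, `RT`.
#' @export
enumerate_ensemble <- function(partition, energies = NULL, overall_dg = 5,
                               temperature = 298.15) {
  stopifnot(inherits(partition, "folding_partition"))
  U <- n_units(partition)
  if (U > 24L)
    stop("2^", U, " states exceed the exhaustive-enumeration cap (U <= 24); ",
         "use a coarser window")
  g <- if (is.null(energies)) rep(overall_dg / U, U) else as.numeric(energies)
  if (length(g) != U) stop("need one unfolding energy per unit")
  if (any(!is.finite(g))) stop("unit energies must be finite")
  RT <- GAS_CONSTANT_KCAL * temperature
  nstates <- 2L^U
  states <- seq_len(nstates) - 1L          # bit u set = unit u unfolded
  G <- numeric(nstates)
  for (u in seq_len(U)) {
    unfolded <- bitwAnd(states, bitwShiftL(1L, u - 1L)) != 0L
    G[unfolded] <- G[unfolded] + g[u]
  }
  w <- exp(-G / RT)
  P <- w / sum(w)
  structure(list(partition = partition, g_u = g, G = G, P = P,
                 temperature = temperature, RT = RT,
                 R = GAS_CONSTANT_KCAL),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model:", n_units(x$partition), "units,", length(x$P),
      "states, T =", x$temperature, "K\n")
  invisible(x)
}

## per-unit folded probability of an enumerated ensemble
unit_folded_probability <- function(ensemble) {
  U <- n_units(ensemble$partition)
  states <- seq_along(ensemble$P) - 1L
  vapply(seq_len(U), function(u) {
    folded <- bitwAnd(states, bitwShiftL(1L, u - 1L)) == 0L
    sum(ensemble$P[folded])
  }, numeric(1L))
}

#' Residue stability constants and residue-specific free energies
#'
#' kappa_f,j is the ratio of the summed Boltzmann probabilities of states
#' in which residue j's unit is folded versus unfolded;
#' dG_f,j = -RT ln kappa_f,j.  Residues in the same unit share identical
#' values.  If no unfolded state has any weight, kappa is reported as +Inf
#' and dG_f as -Inf (flagged, never NaN).
#'
#' @param ensemble an `ensemble_model`.
#' @return data frame with columns `residue`, `unit`, `kappa`, `dG_f`.
#' @export
residue_stability <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  pf <- unit_folded_probability(ensemble)
  pu <- 1 - pf
  kappa <- ifelse(pu > 0, pf / pu, Inf)
  dG <- ifelse(is.finite(kappa), -ensemble$RT * log(kappa), -Inf)
  ru <- residue_units(ensemble$partition)
  data.frame(residue = seq_len(ensemble$partition$n_residues),
             unit = ru, kappa = kappa[ru], dG_f = dG[ru])
}

#' Default alanine-scan perturbation for a residue type
#'
#' The energetic treatment of an Ala substitution in the published COREX
#' parameterization is not available; the bundled default scales with the
#' side-chain truncation: delta = -0.12 kcal/mol per side-chain heavy atom
#' removed relative to alanine (destabilizing, since truncation removes
#' packing interactions; glycine gains an atom and gets +0.12).  Always
#' overridable per run.
#'
#' @param resid 3-letter residue code(s).
#' @return perturbation(s) in kcal/mol.
#' @export
ala_scan_delta <- function(resid) {
  heavy <- c(GLY = 0, ALA = 1, SER = 2, CYS = 2, THR = 3, VAL = 3, PRO = 3,
             ASP = 4, ASN = 4, ILE = 4, LEU = 4, MET = 4, GLU = 5, GLN = 5,
             LYS = 5, HIS = 6, ARG = 7, PHE = 7, TYR = 8, TRP = 10)
  h <- heavy[toupper(resid)]
  if (any(is.na(h))) stop("unknown residue type: ",
                          paste(resid[is.na(h)], collapse = ", "))
  unname(-0.12 * (h - 1))
}

#' Thermodynamic mutation scan
#'
#' A mutation at residue k perturbs the folding energetics of k's unit: the
#' mutant ensemble is the wild-type ensemble with `delta` added to that
#' unit's unfolding penalty (equivalently, every state in which the unit is
#' folded is shifted by -delta).  Returns the change in residue-specific
#' free energy ddG_j = dG_f,j^mut - dG_f,j^WT for every residue j; a zero
#' perturbation returns identically zero.
#'
#' @param ensemble a wild-type `ensemble_model`.
#' @param site mutated residue (1-based index along the chain).
#' @param delta energetic perturbation in kcal/mol; if `NULL`, looked up
#'   with [ala_scan_delta()] from `resid`.
#' @param resid 3-letter code of the wild-type residue at `site` (only used
#'   when `delta` is `NULL`).
#' @return data frame with columns `residue`, `unit`, `ddG`.
#' @export
mutation_scan <- function(ensemble, site, delta = NULL, resid = NULL) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  part <- ensemble$partition
  site <- as.integer(site)
  if (site < 1L || site > part$n_residues)
    stop("site ", site, " outside chain of length ", part$n_residues)
  if (is.null(delta)) {
    if (is.null(resid)) stop("give either delta or the residue type")
    delta <- ala_scan_delta(resid)
  }
  if (!is.finite(delta)) stop("perturbation must be finite")
  ru <- residue_units(part)
  ku <- ru[site]
  g_mut <- ensemble$g_u
  g_mut[ku] <- g_mut[ku] + delta
  mut <- enumerate_ensemble(part, energies = g_mut,
                            temperature = ensemble$temperature)
  wt_tab <- residue_stability(ensemble)
  mut_tab <- residue_stability(mut)
  data.frame(residue = wt_tab$residue, unit = wt_tab$unit,
             ddG = mut_tab$dG_f - wt_tab$dG_f)
}

#' Extract susceptible regions from a mutation-response profile
#'
#' Residues whose free-energy response exceeds the cutoff are merged into
#' intervals.  The default mode thresholds the absolute change (the
#' convention used for highlighting highly affected residues); signed mode
#' keeps only destabilized residues (ddG > cutoff).
#'
#' @param ddg data frame from [mutation_scan()] (columns `residue`, `ddG`)
#'   or a plain numeric vector of per-residue responses.
#' @param cutoff susceptibility cutoff in kcal/mol (> 0); published
#'   analyses use 0.2, 0.6 or 1.0 depending on the perturbation scale.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @param exclude_site optional residue index excluded from its own report
#'   (the mutated residue itself).
#' @return a `region_set`.
#' @export
susceptible_regions <- function(ddg, cutoff, mode = c("absolute", "signed"),
                                exclude_site = NULL) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.data.frame(ddg)) {
    vals <- ddg$ddG
    n <- max(ddg$residue)
  } else {
    vals <- as.numeric(ddg)
    n <- length(vals)
  }
  hit <- if (mode == "absolute") abs(vals) > cutoff else vals > cutoff
  res <- which(hit)
  if (!is.null(exclude_site)) res <- setdiff(res, as.integer(exclude_site))
  regions_from_residues(res, n, tier = "region",
                        note = sprintf("ddG cutoff=%.3g mode=%s", cutoff,
                                       mode))
}

#' Contact-density derived unit energies
#'
#' A structure-derived surrogate for the unit unfolding penalties: g_u
#' proportional to the unit's mean node contact number at a 7.0 A cutoff
#' (better-packed units cost more to unfold), rescaled so the fully
#' unfolded state sits at `overall_dg`.
#'
#' @param structure a `pdb_structure`.
#' @param partition a `folding_partition` over the structure's residues.
#' @param overall_dg overall stability in kcal/mol.
#' @param cutoff contact cutoff in A.
#' @return numeric vector of per-unit energies summing to `overall_dg`.
#' @export
contact_unit_energies <- function(structure, partition, overall_dg = 5,
                                  cutoff = 7.0) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(partition, "folding_partition"),
            n_residues(structure) == partition$n_residues)
  m <- node_coordinates(structure, "CB")
  a <- as.matrix(stats::dist(m)) <= cutoff
  diag(a) <- FALSE
  degree <- rowSums(a)
  ru <- residue_units(partition)
  raw <- vapply(seq_len(n_units(partition)),
                function(u) mean(degree[ru == u]), numeric(1L))
  raw * overall_dg / sum(raw)
}
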