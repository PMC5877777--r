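test_that("folding partitions follow the window/terminal rule", {
  p <- make_partition(164, window = 8, min_terminal = 4)
  expect_equal(nrow(p$units), 21L)
  lens <- p$units$end - p$units$start + 1L
  expect_equal(sum(lens == 8L), 20L)
  expect_equal(lens[21L], 4L)

  p13 <- make_partition(13)
  expect_equal(p13$units$start, c(1L, 9L))
  expect_equal(p13$units$end, c(8L, 13L))

  expect_equal(nrow(make_partition(8)$units), 1L)
  # trailing remainder below the terminal minimum merges into the last unit
  p11 <- make_partition(11)
  expect_equal(p11$units$end, 11L)

  # units tile the chain exactly once
  for (n in c(9, 17, 40, 83)) {
    pu <- make_partition(n)
    covered <- unlist(Map(seq.int, pu$units$start, pu$units$end))
    expect_identical(covered, seq_len(n))
  }

  expect_error(make_partition(20, window = 3, min_terminal = 4),
               "window")
  expect_error(make_partition(3), "shorter")
  expect_error(make_partition(20, shift = 8), "shift")
})

test_that("shifted partitions keep terminal-size guarantees", {
  p <- make_partition(30, shift = 5)       # 5 >= min_terminal: own unit
  expect_equal(p$units$start[1:2], c(1L, 6L))
  expect_equal(p$units$end[1], 5L)
  p2 <- make_partition(30, shift = 2)      # 2 < 4: merged into first unit
  expect_equal(p2$units$start[1], 1L)
  expect_equal(p2$units$end[1], 10L)
  for (pp in list(p, p2)) {
    covered <- unlist(Map(seq.int, pp$units$start, pp$units$end))
    expect_identical(covered, seq_len(30L))
  }
})

test_that("ensemble enumeration normalizes and calibrates uniformly", {
  e2 <- enumerate_ensemble(make_partition(16), overall_dg = 5)
  expect_length(e2$P, 4L)
  expect_equal(sum(e2$P), 1, tolerance = 1e-12)

  # uniform calibration: U = 5 units at overall 5 kcal/mol -> g_u = 1 each
  e5 <- enumerate_ensemble(make_partition(40), overall_dg = 5)
  expect_equal(e5$g_u, rep(1, 5))
  # fully unfolded state sits at the overall stability
  expect_equal(max(e5$G), 5)

  # Boltzmann ratio, single unit: P(folded)/P(unfolded) = exp(g/RT)
  e1 <- enumerate_ensemble(make_partition(8), energies = 5)
  expect_equal(e1$P[1] / e1$P[2], exp(5 / e1$RT), tolerance = 1e-10)
  expect_equal(e1$RT, 1.987e-3 * 298.15)

  expect_error(enumerate_ensemble(make_partition(8), energies = c(1, 2)),
               "one unfolding energy per unit")
  expect_error(enumerate_ensemble(make_partition(8), energies = NaN),
               "finite")
  expect_error(enumerate_ensemble(make_partition(8 * 30)), "cap")
})

test_that("residue stability matches closed forms and the brute oracle", {
  # symmetric two-state system: kappa = 1, dG = 0
  e0 <- enumerate_ensemble(make_partition(8), energies = 0)
  rs0 <- residue_stability(e0)
  expect_equal(rs0$kappa, rep(1, 8))
  expect_equal(rs0$dG_f, rep(0, 8))

  # single unit at g = 5: dG_f = -5 exactly
  e1 <- enumerate_ensemble(make_partition(8), energies = 5)
  expect_equal(residue_stability(e1)$dG_f, rep(-5, 8), tolerance = 1e-12)

  # unequal three-unit toy vs state-by-state Boltzmann summation
  part <- make_partition(20)   # units 8, 8, 4
  g <- c(0.7, 2.1, 1.4)
  ens <- enumerate_ensemble(part, energies = g)
  rs <- residue_stability(ens)
  oracle <- brute_eam(g, ens$RT)
  ru <- allonet:::residue_units(part)
  expect_equal(rs$kappa, oracle$kappa[ru], tolerance = 1e-10)
  expect_equal(rs$dG_f, oracle$dG[ru], tolerance = 1e-10)
  # identity dG = -RT ln kappa holds to machine precision
  expect_equal(rs$dG_f, -ens$RT * log(rs$kappa), tolerance = 1e-15)
})

test_that("stability is monotone in the unit unfolding penalty", {
  part <- make_partition(20)
  kap <- vapply(c(0.5, 1, 1.5, 2), function(g1) {
    ens <- enumerate_ensemble(part, energies = c(g1, 1, 1))
    residue_stability(ens)$kappa[1]
  }, numeric(1L))
  expect_true(all(diff(kap) > 0))
})

test_that("mutation scans follow the free-energy difference definition", {
  e1 <- enumerate_ensemble(make_partition(8), energies = 5)
  # stabilizing the single unit by 1 shifts every residue by -1
  ms <- mutation_scan(e1, 3, delta = 1)
  expect_equal(ms$ddG, rep(-1, 8), tolerance = 1e-12)
  # zero perturbation is the identity
  expect_equal(mutation_scan(e1, 3, delta = 0)$ddG, rep(0, 8))

  # two-unit toy vs brute-force re-enumeration
  part <- make_partition(12)   # units 8, 4
  g <- c(1.2, 0.8); delta <- -0.5
  ens <- enumerate_ensemble(part, energies = g)
  ms2 <- mutation_scan(ens, 2, delta = delta)
  wt <- brute_eam(g, ens$RT)
  mut <- brute_eam(c(g[1] + delta, g[2]), ens$RT)
  ru <- allonet:::residue_units(part)
  expect_equal(ms2$ddG, (mut$dG - wt$dG)[ru], tolerance = 1e-10)

  expect_error(mutation_scan(ens, 40, delta = 1), "outside chain")
  expect_error(mutation_scan(ens, 2, delta = Inf), "finite")
  expect_error(mutation_scan(ens, 2), "residue type")
})

test_that("the alanine-scan table scales with side-chain truncation", {
  expect_equal(ala_scan_delta("ALA"), 0)
  expect_equal(ala_scan_delta("GLY"), 0.12)
  expect_equal(ala_scan_delta("TRP"), -0.12 * 9)
  expect_equal(ala_scan_delta(c("LEU", "PHE")), c(-0.36, -0.72))
  expect_error(ala_scan_delta("XYZ"), "unknown residue")
})

test_that("susceptible regions are hand-thresholdable at every cutoff", {
  prof <- c(0.1, 0.25, 0.3, 0.1)
  rs <- susceptible_regions(prof, cutoff = 0.2)
  expect_equal(rs$intervals$start, 2L)
  expect_equal(rs$intervals$end, 3L)
  expect_length(region_residues(susceptible_regions(prof, 1.0)), 0L)
  expect_length(region_residues(susceptible_regions(rep(0, 6), 0.2)), 0L)

  # absolute vs signed thresholding
  mixed <- c(-0.9, 0.1, 0.9)
  expect_identical(region_residues(susceptible_regions(mixed, 0.6)),
                   c(1L, 3L))
  expect_identical(region_residues(susceptible_regions(mixed, 0.6,
                                                       mode = "signed")),
                   3L)
  # the mutated residue can be excluded from its own report
  expect_identical(region_residues(susceptible_regions(mixed, 0.6,
                                                       exclude_site = 1)),
                   3L)
  expect_error(susceptible_regions(mixed, 0), "cutoff")
})

test_that("contact-derived unit energies rescale to the overall stability", {
  b <- make_helical_bundle(2, 10, seed = 2)
  part <- make_partition(20)
  g <- contact_unit_energies(b, part, overall_dg = 5)
  expect_length(g, nrow(part$units))
  expect_equal(sum(g), 5)
  expect_true(all(g > 0))
})
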