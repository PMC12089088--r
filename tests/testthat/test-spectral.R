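test_that("small-molecule spectra match closed forms", {
  expect_equal(adjacencySpectrum(benzene()), c(-2, -1, -1, 1, 1, 2),
               tolerance = 1e-12)
  expect_equal(adjacencySpectrum(molecularGraph(rbind(c(1, 2)))), c(-1, 1),
               tolerance = 1e-12)
})

test_that("bipartite spectra obey Coulson-Rushbrooke pairing", {
  for (sp in list(fractalSpec("ZHCF", 1), fractalSpec("ZHCF", 2),
                  fractalSpec("AHCF", 2), fractalSpec("RCF", 2, m = 2))) {
    ev <- adjacencySpectrum(generateFractal(sp))
    expect_equal(ev, -rev(ev), tolerance = 1e-9)
    expect_lt(abs(sum(ev)), 1e-9 * length(ev))
  }
})

test_that("total pi-energy follows the occupied-orbital formula", {
  expect_equal(totalPiEnergy(adjacencySpectrum(benzene())), 8)
  # even p equals sum of |eigenvalues| for bipartite systems
  for (g in list(generateFractal("ZHCF", 1), naphthalene())) {
    ev <- adjacencySpectrum(g)
    expect_equal(totalPiEnergy(ev), sum(abs(ev)), tolerance = 1e-9)
  }
  # odd p: singly occupied middle level counts once (allyl radical: sqrt 2)
  allyl <- molecularGraph(rbind(c(1, 2), c(2, 3)))
  expect_equal(totalPiEnergy(adjacencySpectrum(allyl)), 2 * sqrt(2),
               tolerance = 1e-12)
})

test_that("published pi-energies are reproduced", {
  expect_equal(totalPiEnergy(adjacencySpectrum(generateFractal("ZHCF", 1))),
               194.662, tolerance = 1e-3 / 194)
  expect_equal(totalPiEnergy(adjacencySpectrum(generateFractal("RCF", 2, m = 2))),
               640.3919, tolerance = 1e-3 / 640)
})

test_that("frontier levels are selected by rank", {
  expect_equal(unname(homoLumoGap(adjacencySpectrum(benzene()))),
               c(1, -1, 2), tolerance = 1e-12)
  ev1 <- adjacencySpectrum(generateFractal("ZHCF", 1))
  hl <- homoLumoGap(ev1)
  expect_equal(unname(hl["gap"]), 0.7638, tolerance = 1e-3 / 0.76)
  # bipartite: gap = 2 HOMO
  expect_equal(unname(hl["gap"]), 2 * unname(hl["homo"]), tolerance = 1e-9)
  ev2 <- adjacencySpectrum(generateFractal("ZHCF", 2))
  expect_equal(unname(homoLumoGap(ev2)["gap"]), 0.65732, tolerance = 1e-4)
  expect_warning(homoLumoGap(c(-1, 0, 1)), "odd atom count")
})

test_that("spectral diameter matches printed values and trivial cases", {
  expect_equal(spectralDiameter(adjacencySpectrum(benzene())), 4,
               tolerance = 1e-12)
  expect_equal(spectralDiameter(c(-1, 1)), 2)
  expect_equal(spectralDiameter(adjacencySpectrum(generateFractal("AHCF", 2))),
               5.65682, tolerance = 1e-4)
})

test_that("per-atom energies divide by the vertex count", {
  expect_equal(unname(perAtomEnergies(8, 6)), c(8 / 6, 2 / 6))
  ev <- adjacencySpectrum(generateFractal("ZHCF", 1))
  pa <- perAtomEnergies(totalPiEnergy(ev), 132)
  expect_equal(unname(pa["ePiPerAtom"]), 1.475, tolerance = 5e-4 / 1.475)
  expect_equal(unname(pa["delocPerAtom"]), 0.474712, tolerance = 1e-5)
  ev3 <- adjacencySpectrum(generateFractal("ZHCF", 3))
  expect_equal(unname(perAtomEnergies(totalPiEnergy(ev3), 1152)["ePiPerAtom"]),
               1.488, tolerance = 5e-4)
})

test_that("determinant-based Kekule counts agree with brute-force matching", {
  cases <- list(list(g = benzene(), kc = 2),
                list(g = naphthalene(), kc = 3),
                list(g = anthracene(), kc = 4),
                list(g = coroneneUnit(), kc = 20))
  for (cs in cases) {
    expect_identical(count_matchings_bruteforce(cs$g), as.integer(cs$kc))
    k <- kekuleCount(cs$g, method = "exact")
    expect_equal(k$count, cs$kc)
    expect_equal(k$logCount, log(cs$kc))
  }
  # perylene-type template: no frozen constant, pure dual-route check
  pery <- template_graph(buildTemplate(fractalSpec("RCF", 2, m = 2)))
  expect_equal(kekuleCount(pery, method = "exact")$count,
               count_matchings_bruteforce(pery))
})

test_that("Kekule counting flags odd and unmatched graphs", {
  expect_error(kekuleCount(molecularGraph(rbind(c(1, 2), c(2, 3)))), "odd")
  # even star K_{1,3} plus isolated atom: unequal colour classes, count 0
  star <- molecularGraph(rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_identical(kekuleCount(star)$count, 0)
})

test_that("exact and log-determinant Kekule routes agree in range", {
  g <- generateFractal("ZHCF", 1)
  ke <- kekuleCount(g, method = "exact")
  kl <- kekuleCount(g, method = "logdet")
  expect_equal(ke$count, 37718065)
  expect_true(is.na(kl$count))
  expect_equal(kl$logCount, ke$logCount, tolerance = 1e-10)
})

test_that("resonance energy per atom matches the published value", {
  g <- generateFractal("ZHCF", 1)
  kc <- kekuleCount(g)$count
  expect_equal(resonancePerAtom(kc, 132), 0.156614, tolerance = 1e-5 / 0.15)
  expect_identical(resonancePerAtom(1, 10), 0)
  expect_error(resonancePerAtom(0, 10), "positive")
  r22 <- generateFractal("RCF", 2, m = 2)
  lk <- kekuleCount(r22, method = "logdet")$logCount
  expect_equal(resonancePerAtom(p = 432, logKc = lk), 0.158714,
               tolerance = 1e-5 / 0.15)
})

test_that("gap decreases and resonance increases with size within a family", {
  reports <- lapply(1:2, function(n) spectralReport(generateFractal("ZHCF", n)))
  expect_lt(reports[[2]]@gap, reports[[1]]@gap)
  expect_gt(reports[[2]]@delocPerAtom, reports[[1]]@delocPerAtom)
  expect_gt(reports[[2]]@resonancePerAtom, reports[[1]]@resonancePerAtom)
})

test_that("spectralTable assembles the energetics columns", {
  tab <- spectralTable(list(fractalSpec("ZHCF", 1), fractalSpec("RCF", 1, m = 1)))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$ePi[1], tab$ePi[2], tolerance = 1e-9)  # size-1 twins
  expect_equal(tab$ePi[1], 194.662, tolerance = 1e-3)
})
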