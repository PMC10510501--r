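test_that("descriptor panel values are forced by atomic composition", {
  p <- compute_profile(c("c1ccccc1", "CC", "CNC(C)=O"))

  benzene <- p[1, ]
  expect_equal(benzene$molar_mass, 78.11, tolerance = 0.01 / 78)
  expect_equal(benzene$hac, 6L)
  expect_equal(benzene$n_aromatic_rings, 1L)
  expect_equal(benzene$fsp3, 0)
  expect_equal(benzene$n_hbd, 0L)
  expect_equal(benzene$heteroatom_ratio, 0)

  ethane <- p[2, ]
  expect_equal(ethane$fsp3, 1)
  expect_equal(ethane$n_rings, 0L)
  expect_equal(ethane$n_rotb, 0L)

  nma <- p[3, ]
  expect_equal(nma$n_noncyclic_amide, 1L)
  expect_equal(nma$n_o_plus_n, 2L)
  expect_equal(nma$heteroatom_ratio, 2 / 5)
  expect_equal(nma$n_acid_base, nma$n_acidic + nma$n_basic)
})

test_that("profiles are invariant under SMILES renumbering", {
  variants <- list(
    c("CC(=O)Nc1ccc(O)cc1", "Oc1ccc(NC(C)=O)cc1", "c1cc(O)ccc1NC(=O)C"),
    c("NCCCCC(N)C(=O)O", "OC(=O)C(N)CCCCN"))
  for (v in variants) {
    profs <- compute_profile(v)
    for (i in 2:nrow(profs)) {
      expect_equal(profs[i, -1], profs[1, -1], ignore_attr = TRUE)
    }
  }
})

test_that("acid/base group counting matches the shipped pattern lists", {
  p <- compute_profile(c("CC(=O)O", "NCCCCC(N)C(=O)O", "NC(N)=N", "c1ccccc1"))
  expect_equal(p$n_acidic, c(1L, 1L, 0L, 0L))
  expect_equal(p$n_basic, c(0L, 2L, 1L, 0L))
  expect_equal(p$n_acid_base, p$n_acidic + p$n_basic)
})

test_that("gates follow the documented boundary semantics", {
  base <- data.frame(molar_mass = 250, logp = 1, psa = 40, n_hba = 2,
                     n_hbd = 1, n_rotb = 2, n_rings = 2)
  at <- function(...) {
    row <- base
    mods <- list(...)
    for (nm in names(mods)) row[[nm]] <- mods[[nm]]
    apply_gates(row)
  }
  # ro3 molar mass bound is strict <; every other bound inclusive
  expect_true(at(molar_mass = 299, logp = 3, n_hbd = 3, n_hba = 3,
                 n_rotb = 3, psa = 60)$ro3)
  expect_false(at(molar_mass = 300)$ro3)
  expect_true(at(molar_mass = 500)$ro5)
  expect_false(at(molar_mass = 500.01)$ro5)
  expect_true(at(molar_mass = 200)$lead_like)
  expect_true(at(molar_mass = 450)$lead_like)
  expect_false(at(molar_mass = 199.9)$lead_like)
  expect_false(at(logp = 4.6)$lead_like)
  expect_true(at(logp = -3.5)$lead_like)
  expect_false(at(molar_mass = 600)$ro5)
  expect_false(at(n_hba = 11)$ro5)

  expect_error(apply_gates(base[, -1]), "lacks")
})

test_that("rule-of-three compliance implies rule-of-five compliance", {
  cat0 <- generate_catalog(catalog_spec(
    25, c(carboxylic_acid = 0.25, amine = 0.25, alcohol = 0.2,
          aryl_halide = 0.15, boronic_acid = 0.15), seed = 5))
  lib <- enumerate_library(cat0, RS, steps = 2)
  prof <- compute_profile(c(cat0$smiles, lib$smiles))
  gates <- apply_gates(prof)
  expect_true(all(gates$ro5[gates$ro3]))
})

test_that("integer descriptors agree exactly with the OpenBabel toolkit", {
  panel <- c("CC(=O)Nc1ccc(O)cc1", "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "NCCCCC(N)C(=O)O",
             "c1ccc2ccccc2c1", "OCC(O)CO")
  prof <- compute_profile(panel)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(panel, seq_along(panel)))
  ob <- ChemmineR::propOB(sdf)
  ac <- ChemmineR::atomcount(sdf)
  hac <- vapply(ac, function(x) sum(x[names(x) != "H"]), numeric(1))
  o_n <- vapply(ac, function(x) sum(x[names(x) %in% c("N", "O")]), numeric(1))
  bonds <- vapply(seq_along(panel), function(i)
    nrow(ChemmineR::bondblock(sdf[[i]])), numeric(1))
  atoms <- vapply(seq_along(panel), function(i)
    nrow(ChemmineR::atomblock(sdf[[i]])), numeric(1))
  expect_equal(prof$hac, as.integer(hac))
  expect_equal(prof$n_o_plus_n, as.integer(o_n))
  expect_equal(prof$n_rings, as.integer(bonds - atoms + 1))  # cyclomatic
  expect_equal(prof$n_hbd, as.integer(ob$HBD))
  expect_equal(prof$molar_mass, ob$MW, tolerance = 1e-4)
})
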