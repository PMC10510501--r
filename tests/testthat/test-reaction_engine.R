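test_that("the shipped rule set loads complete and validated", {
  expect_length(RS$rules, 7L)
  expect_setequal(names(RS$rules), c("amide", "ester", "snar", "buchwald",
                                     "suzuki", "sonogashira", "heck"))
  expect_gte(length(RS$side_patterns), 20L)
  expect_true(all(lengths(lapply(RS$side_patterns, `[[`, "blocks_under")) > 0))
})

test_that("incomplete or malformed rule configs abort the load", {
  cfg <- yaml::read_yaml(system.file("extdata", "reaction_rules.yaml",
                                     package = "diylib"))
  path <- withr::local_tempfile(fileext = ".yaml")

  broken <- cfg
  broken$main_reactions$heck <- NULL
  yaml::write_yaml(broken, path)
  expect_error(load_rule_set(path), "heck")

  broken <- cfg
  broken$side_reactions$aldehyde$blocks_under <- list()
  yaml::write_yaml(broken, path)
  expect_error(load_rule_set(path), "blocks_under")

  broken <- cfg
  broken$main_reactions$amide$smirks <- "[C:1](((>>[C:1]"
  yaml::write_yaml(broken, path)
  expect_error(load_rule_set(path), "amide")
})

test_that("site scanning reports roles and side hits deterministically", {
  acid <- scan_sites("CC(=O)O", RS)
  expect_true(all(c("amide", "ester") %in%
                    acid$matches$rule[acid$matches$role == "a"]))

  inert <- scan_sites("c1ccccc1", RS)
  expect_equal(nrow(inert$matches), 0L)
  expect_equal(nrow(inert$side_hits), 0L)

  bromo_amine <- scan_sites("NCCBr", RS)
  expect_true("amide" %in% bromo_amine$matches$rule[bromo_amine$matches$role == "b"])
  expect_true("aliphatic_halide" %in% bromo_amine$side_hits$name)

  # repeated scans give identical reports
  expect_identical(scan_sites("NCCCCC(N)C(=O)O", RS)$matches,
                   scan_sites("NCCCCC(N)C(=O)O", RS)$matches)
})

test_that("pair compatibility implements side-reaction and ambiguity vetoes", {
  acid <- scan_sites("CC(=O)O", RS)

  # a Suzuki-capable partner does not veto an amide coupling: no Pd present
  ok <- compatible(acid, scan_sites("NCc1ccc(B(O)O)cc1", RS), "amide", RS)
  expect_true(ok$compatible)

  # an aliphatic halide forms byproducts under every condition class
  veto <- compatible(acid, scan_sites("NCCBr", RS), "amide", RS)
  expect_false(veto$compatible)
  expect_match(veto$reason, "aliphatic_halide")

  # amide and ester are both coupling-agent reactions: ambiguous pairing
  amb <- compatible(acid, scan_sites("NCCO", RS), "amide", RS)
  expect_false(amb$compatible)
  expect_match(amb$reason, "ambiguity")

  # symmetry under argument swap, across molecules and rules
  probes <- lapply(c("CC(=O)O", "NCCO", "CN", "Brc1ccccc1", "OB(O)c1ccccc1",
                     "Clc1ccncc1", "C#CCC", "C=CCC", "OCC", "NCCBr"),
                   scan_sites, rule_set = RS)
  for (rn in names(RS$rules)) {
    for (i in seq_along(probes)) {
      for (j in seq_along(probes)) {
        expect_equal(compatible(probes[[i]], probes[[j]], rn, RS)$compatible,
                     compatible(probes[[j]], probes[[i]], rn, RS)$compatible)
      }
    }
  }
})

test_that("rule application produces the expected named products", {
  amide <- apply_rule("CC(=O)O", "CN", "amide", RS)
  expect_equal(amide$smiles, "CNC(C)=O")

  suzuki <- apply_rule("Brc1ccccc1", "OB(O)c1ccccc1", "suzuki", RS)
  expect_equal(suzuki$smiles, "c1ccc(-c2ccccc2)cc1")

  snar <- apply_rule("Clc1ccncc1", "CN", "snar", RS)
  expect_equal(snar$smiles, "CNc1ccncc1")

  # symmetric diamine: two site-products collapse to one by InChI
  diamine <- apply_rule("NCCCN", "CC(=O)O", "amide", RS)
  expect_equal(nrow(diamine), 1L)

  # output is independent of reagent order
  fwd <- apply_rule("CC(=O)O", "CCN", "amide", RS)
  rev <- apply_rule("CCN", "CC(=O)O", "amide", RS)
  expect_setequal(fwd$inchi, rev$inchi)
})

test_that("heck products carry the E-configured new double bond", {
  prod <- apply_rule("Brc1ccccc1", "C=CCC", "heck", RS)
  expect_match(prod$smiles, "/C=C/")
})

test_that("every product respects the mass-balance invariant (sampled)", {
  role_b_source <- list(
    amide = "CCN", ester = "OCC", snar = "CN", buchwald = "CCN",
    suzuki = "OB(O)c1ccccc1", sonogashira = "C#CCC", heck = "C=CCC")
  role_a_source <- list(
    amide = "CC(=O)O", ester = "CC(=O)O", snar = "Clc1ccncc1",
    buchwald = "Brc1ccccc1", suzuki = "Brc1ccccc1",
    sonogashira = "Brc1ccccc1", heck = "Brc1ccccc1")
  for (rn in names(RS$rules)) {
    a <- standardize(role_a_source[[rn]])
    b <- standardize(role_b_source[[rn]])
    prods <- apply_rule(a$canonical_smiles, b$canonical_smiles, rn, RS)
    expect_gt(nrow(prods), 0L)
    for (k in seq_len(nrow(prods))) {
      expect_true(balances(a$formula[[1]], b$formula[[1]],
                           prods$formula[[k]], RS$rules[[rn]]),
                  label = paste("mass balance", rn, prods$smiles[k]))
    }
  }
})
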