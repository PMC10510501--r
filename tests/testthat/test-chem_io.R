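test_that("standardization canonicalizes, strips salts, and is idempotent", {
  std <- standardize(c("OC(=O)C", "CC(=O)O.[Na+].[Cl-]", "C1=CC=CC=C1",
                       "c1ccccc1"))
  expect_equal(std$canonical_smiles[1], "CC(=O)O")
  expect_equal(std$canonical_smiles[2], "CC(=O)O")       # largest fragment
  expect_equal(std$inchi[3], std$inchi[4])               # aromatic perception

  for (smi in c("OC(=O)C", "NCc1ccc(B(O)O)cc1", "Clc1ccncc1",
                "CC(O)C(=O)O.[K+]")) {
    once <- standardize(smi)
    twice <- standardize(once$canonical_smiles)
    expect_equal(twice$canonical_smiles, once$canonical_smiles)
    expect_equal(twice$inchi, once$inchi)
  }
  expect_error(standardize("not_a_smiles"), "not_a_smiles")
})

test_that("catalog CSV reading validates records and skips bad structures", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,price",
               'bb1,"CC(=O)O",5.0',
               "bb2,CN,3.0"), path)
  cat1 <- read_catalog(path)
  expect_s3_class(cat1, "diy_catalog")
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$smiles, c("CC(=O)O", "CN"))
  expect_equal(cat1$price, c(5, 3))

  writeLines(c("id,smiles,price", "bb1,CC(=O)O,5", "bb3,not_a_smiles,5"), path)
  expect_warning(cat2 <- read_catalog(path), "skipped")
  expect_equal(nrow(cat2), 1L)

  writeLines(c("id,smiles,price", "bb1,CC(=O)O,0"), path)
  expect_error(read_catalog(path), "positive")

  writeLines(c("id,smiles,price", "bb1,CC(=O)O,5", "bb1,CN,3"), path)
  expect_error(read_catalog(path), "bb1")

  writeLines(c("id,smiles", "bb1,CC(=O)O"), path)
  expect_error(read_catalog(path), "price")

  writeLines(c("id,smiles,price", "bbx,not_a_smiles,5"), path)
  expect_error(suppressWarnings(read_catalog(path)), "zero valid")
})

test_that("SMILES and SDF catalogs round-trip id, price and structure key", {
  cat0 <- make_catalog(c("CC(=O)O", "NCc1ccccc1"), price = c(5.5, 7.25),
                       ids = c("a1", "a2"))
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(paste(cat0$smiles, cat0$id, cat0$price, sep = "\t"), smi)
  back <- read_catalog(smi)
  expect_equal(back$id, cat0$id)
  expect_equal(back$price, cat0$price)
  expect_equal(back$inchi, cat0$inchi)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat0, csv)
  back2 <- read_catalog(csv)
  expect_equal(back2$id, cat0$id)
  expect_equal(back2$price, cat0$price)
  expect_equal(back2$inchi, cat0$inchi)

  sdf <- withr::local_tempfile(fileext = ".sdf")
  recs <- lapply(seq_len(nrow(cat0)), function(i)
    list(smiles = cat0$smiles[i], name = cat0$id[i],
         props = list(price_per_g = cat0$price[i])))
  writeLines(diylib:::kernel_call("write_sdf", records = recs)$text, sdf)
  back3 <- read_catalog(sdf)
  expect_equal(back3$id, cat0$id)
  expect_equal(back3$price, cat0$price)
  expect_equal(back3$inchi, cat0$inchi)
})

test_that("library writing follows the schema and round-trips InChI keys", {
  cat0 <- make_catalog(c("CC(=O)O", "CN", "NCCN"), price = c(5, 3, 4))
  lib <- enumerate_library(cat0, RS, steps = 2)
  expect_gt(nrow(lib), 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  n <- write_library(lib, path, blocks = cat0)
  expect_equal(n, nrow(lib))
  back <- read_library(path)
  expect_named(back, c("product_smiles", "inchi", "step_count", "rule_1",
                       "rule_2", "bb_ids", "route_cost"))
  expect_setequal(back$inchi, lib$inchi)
  one_step <- back[back$step_count == 1L, ]
  expect_true(all(one_step$rule_2 == "" | is.na(one_step$rule_2)))
  expect_true(all(lengths(strsplit(one_step$bb_ids, ";")) == 2L))
  two_step <- back[back$step_count == 2L, ]
  expect_true(all(lengths(strsplit(two_step$bb_ids, ";")) == 3L))

  # empty library writes a header-only file
  n0 <- write_library(diylib:::empty_library(), path)
  expect_equal(n0, 0L)
  expect_equal(nrow(read_library(path)), 0L)
})
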