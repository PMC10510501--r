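test_that("monofunctional cross enumeration gives the product combinatorics", {
  acids <- c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O")
  amines <- c("CN", "CCN", "CCCN", "CCCCN")
  cat0 <- make_catalog(c(acids, amines))
  lib <- enumerate_step1(cat0, RS)
  expect_equal(nrow(lib), 12L)
  tab <- tabulate_by_rule(lib)
  expect_equal(tab$n_products[tab$rule == "amide" & tab$step == 1], 12L)
  expect_equal(sum(tab$n_products), 12L)
  expect_equal(attr(tab, "total_unique"), 12L)

  # no residual handles: the second step is empty
  lib2 <- enumerate_step2(lib, cat0, RS)
  expect_equal(nrow(lib2), 0L)

  halides <- c("Brc1ccccc1", "CCc1ccc(Br)cc1")
  boronics <- c("OB(O)c1ccc(C)cc1", "OB(O)c1ccc(OC)cc1")
  suz <- enumerate_step1(make_catalog(c(halides, boronics)), RS)
  expect_equal(nrow(suz), 4L)

  inert <- enumerate_step1(make_catalog(c("c1ccccc1", "Cc1ccccc1", "CCCCCC")), RS)
  expect_equal(nrow(inert), 0L)
})

test_that("second step pairs intermediates with original blocks only", {
  cat0 <- make_catalog(c("CC(=O)O", "CCC(=O)O", "NCCN"),
                       ids = c("acA", "acB", "dia"))
  lib1 <- enumerate_step1(cat0, RS)
  expect_equal(nrow(lib1), 2L)            # two monoamides of the diamine
  lib2 <- enumerate_step2(lib1, cat0, RS)
  # bis-amides AA, AB(=BA), BB
  expect_equal(nrow(lib2), 3L)
  for (i in seq_len(nrow(lib2))) {
    for (rt in lib2$routes[[i]]) {
      expect_equal(rt$step_count, 2L)
      expect_length(diylib:::route_blocks(rt), 3L)
      # the final reagent must be an original catalog block
      final <- rt$steps[[rt$step_count]]$bb_ids
      expect_true(all(final %in% cat0$id))
    }
  }

  full <- enumerate_library(cat0, RS, steps = 2)
  expect_equal(nrow(full), 5L)

  # naive ordered-pair oracle agrees on the key set
  naive <- naive_enumerate(cat0, RS, steps = 2)
  expect_setequal(full$inchi, naive$inchi)
})

test_that("a bifunctional block records an ordered three-block route", {
  # chloropyrimidine boronic acid: SNAr first, Suzuki second
  cat0 <- make_catalog(c("OB(O)c1ccc(Cl)nc1", "CNC", "Brc1ccccc1"),
                       ids = c("bif", "dma", "arx"))
  lib <- enumerate_library(cat0, RS, steps = 2)
  routes <- unlist(lib$routes, recursive = FALSE)
  two_step <- Filter(function(rt) rt$step_count == 2L, routes)
  expect_gt(length(two_step), 0L)
  hit <- Filter(function(rt) {
    rt$steps[[1]]$rule == "snar" &&
      setequal(rt$steps[[1]]$bb_ids, c("bif", "dma")) &&
      rt$steps[[2]]$rule == "suzuki" &&
      identical(rt$steps[[2]]$bb_ids, "arx")
  }, two_step)
  expect_length(hit, 1L)
})

test_that("enumeration is invariant to catalog order and partition count", {
  spec <- catalog_spec(14, c(carboxylic_acid = 0.3, amine = 0.3,
                             aryl_halide = 0.15, boronic_acid = 0.15),
                       bifunctional_fraction = 0.1, seed = 33)
  cat0 <- generate_catalog(spec)
  lib <- enumerate_library(cat0, RS, steps = 2)

  shuffled <- cat0[rev(seq_len(nrow(cat0))), , drop = FALSE]
  lib_shuf <- enumerate_library(shuffled, RS, steps = 2)
  expect_identical(lib$inchi, lib_shuf$inchi)

  lib_part <- enumerate_library(cat0, RS, steps = 2, workers = 4)
  expect_identical(lib$inchi, lib_part$inchi)

  # pool-logic audit: every 2-step route ends in an original block
  for (i in seq_len(nrow(lib))) {
    for (rt in lib$routes[[i]]) {
      if (rt$step_count == 2L) {
        expect_true(all(rt$steps[[2]]$bb_ids %in% cat0$id))
      }
    }
  }
})

test_that("route cost estimation follows the stated arithmetic", {
  blocks <- make_catalog(c("CC(=O)O", "CN", "CCN"), price = c(5, 3, 9),
                         ids = c("b1", "b2", "b3"))
  one_step <- lib_row("k1", "CNC(C)=O",
                      list(mk_route(list(rule = "amide",
                                         bb_ids = c("b1", "b2")))))
  cost1 <- estimate_route_cost(one_step, blocks, overhead = c(0.1, 2.5),
                               solvent = 1.0)
  expect_equal(cost1$min_cost, 9.1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cost1$max_cost, 11.5, tolerance = 1e-12, ignore_attr = TRUE)

  two_step <- lib_row("k2", "X",
                      list(mk_route(list(rule = "amide", bb_ids = c("b3", "b3")),
                                    list(rule = "amide", bb_ids = "b3"))))
  cost2 <- estimate_route_cost(two_step, blocks)
  expect_equal(cost2$min_cost, 29.2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cost2$max_cost, 34.0, tolerance = 1e-12, ignore_attr = TRUE)

  # two routes: cheapest wins
  multi <- lib_row("k3", "X", list(
    mk_route(list(rule = "amide", bb_ids = c("b1", "b2"))),
    mk_route(list(rule = "amide", bb_ids = c("b3", "b2")))))
  cost3 <- estimate_route_cost(multi, blocks)
  expect_equal(cost3$min_cost, 9.1, tolerance = 1e-12, ignore_attr = TRUE)

  bad <- lib_row("k4", "X",
                 list(mk_route(list(rule = "amide", bb_ids = c("zz", "b2")))))
  expect_error(estimate_route_cost(bad, blocks), "unknown")
})

test_that("per-rule tabulation counts each product once per cell", {
  lib <- lib_row("k1", "X", list(
    mk_route(list(rule = "amide", bb_ids = c("a", "b"))),
    mk_route(list(rule = "amide", bb_ids = c("a", "c")))))
  tab <- tabulate_by_rule(lib)
  expect_equal(tab$n_products[tab$rule == "amide" & tab$step == 1], 1L)

  empty <- tabulate_by_rule(diylib:::empty_library())
  expect_true(all(empty$n_products == 0L))
  expect_equal(attr(empty, "total_unique"), 0L)
})
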