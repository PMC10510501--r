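test_that("reaction score is products per price with set semantics", {
  blocks <- make_catalog(rep("CC(=O)O", 3), price = c(5, 4, 2),
                         ids = c("x", "y", "z"))
  lib <- do.call(rbind, c(
    lapply(1:10, function(i) lib_row(paste0("k", i), "S",
      list(mk_route(list(rule = "amide", bb_ids = c("x", "z")))))),
    list(make.row.names = FALSE)))
  lib <- structure(lib, class = c("diy_library", "data.frame"))
  expect_equal(reaction_score("x", lib, blocks), 2.0)
  expect_equal(reaction_score("y", lib, blocks), 0.0)
  expect_error(reaction_score("nope", lib, blocks), "unknown")

  # a block used twice within one route still counts that product once
  twice <- lib_row("k", "S", list(mk_route(list(rule = "amide",
                                                bb_ids = c("y", "y")))))
  expect_equal(reaction_score("y", twice,
                              make_catalog("CC(=O)O", price = 4, ids = "y")),
               0.25)
})

test_that("elimination removes the zero-score block first and stops on target", {
  cat0 <- make_catalog(c("CC(=O)O", "CCC(=O)O", "CN", "CCN", "c1ccccc1"),
                       price = rep(5, 5),
                       ids = c("a1", "a2", "n1", "n2", "dead"))
  lib <- enumerate_step1(cat0, RS)
  expect_equal(nrow(lib), 4L)

  identity_trace <- eliminate(cat0, lib, nrow(cat0))
  expect_equal(nrow(identity_trace$iterations), 0L)
  expect_setequal(identity_trace$retained, cat0$id)

  tr <- eliminate(cat0, lib, 4L)
  expect_equal(tr$iterations$removed_id[1], "dead")
  expect_equal(tr$iterations$score[1], 0)

  expect_error(eliminate(cat0, lib, 0L), ">= 1")
  expect_error(eliminate(cat0, lib, 99L), "exceeds")
})

test_that("incremental elimination equals from-scratch recomputation", {
  for (seed in c(2, 5, 9)) {
    spec <- catalog_spec(8, c(carboxylic_acid = 0.4, amine = 0.4,
                              boronic_acid = 0.1),
                         bifunctional_fraction = 0.1,
                         price_range = c(4.5, 10), seed = seed)
    cat0 <- generate_catalog(spec)
    lib <- enumerate_library(cat0, RS, steps = 2)
    target <- 3L
    fast <- eliminate(cat0, lib, target)
    naive <- naive_eliminate(cat0, lib$contributing_blocks, target)
    expect_equal(fast$iterations, naive$iterations)
    expect_identical(sort(fast$retained), sort(naive$retained))
    expect_length(fast$retained, target)
  }
})

test_that("budget curves carry one point per state with monotone columns", {
  cat0 <- generate_catalog(catalog_spec(
    10, c(carboxylic_acid = 0.5, amine = 0.5), seed = 21))
  lib <- enumerate_library(cat0, RS, steps = 1)
  tr <- eliminate(cat0, lib, 4L)
  curve <- budget_curve(tr)
  expect_equal(nrow(curve), nrow(tr$iterations) + 1L)
  expect_true(all(diff(curve$n_products) <= 0))
  expect_true(all(diff(curve$total_price) < 0))
  expect_equal(curve$total_price[nrow(curve)],
               sum(cat0$price[cat0$id %in% tr$retained]))
})

test_that("knee detection recovers planted breakpoints", {
  # piecewise-linear products-vs-budget with a single breakpoint at n = 50
  n_blocks <- 1:100
  price <- n_blocks * 10
  products <- ifelse(n_blocks <= 50, 20 * n_blocks,
                     20 * 50 + 120 * (n_blocks - 50))
  curve <- data.frame(n_blocks = rev(n_blocks), n_products = rev(products),
                      total_price = rev(price))
  expect_equal(as.numeric(knee_point(curve, smooth = 1)), 50)

  # straight line: degenerate, flagged
  flat <- data.frame(n_blocks = 1:20, n_products = 5 * (1:20),
                     total_price = 10 * (1:20))
  expect_warning(kp <- knee_point(flat), "curvature|flat")
  expect_true(attr(kp, "degenerate"))
  expect_equal(as.numeric(kp), 20)

  expect_error(knee_point(curve[1:4, ]), "5")

  # noisy knees, seeded: recovery within +-2 blocks
  for (seed in c(3, 14, 27)) {
    noisy <- curve
    set.seed(seed)
    noisy$n_products <- noisy$n_products +
      round(stats::rnorm(nrow(noisy), sd = 0.005 * max(noisy$n_products)))
    kp <- knee_point(noisy)
    expect_lte(abs(as.numeric(kp) - 50), 2)
  }
})
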