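# One- and two-step forward enumeration with route provenance ----------------

new_library <- function(df) {
  structure(df, class = c("diy_library", "data.frame"))
}

empty_library <- function() {
  df <- data.frame(inchi = character(), smiles = character(),
                   stringsAsFactors = FALSE)
  df$formula <- list()
  df$routes <- list()
  df$contributing_blocks <- list()
  new_library(df)
}

route_key <- function(route) {
  paste(vapply(route$steps, function(s)
    paste(s$rule, paste(s$bb_ids, collapse = ","), sep = ":"),
    character(1)), collapse = "|")
}

new_route <- function(steps) {
  list(steps = steps, step_count = length(steps))
}

# Per-rule n x m compatibility matrices between two scanned molecule sets.
# Implements the same semantics as compatible(), vectorized over all pairs.
pair_compatibility <- function(scan_a, scan_b, rule_set) {
  rm_a <- scan_a$role_match; rm_b <- scan_b$role_match
  sb_a <- scan_a$side_block; sb_b <- scan_b$side_block
  possible <- lapply(rule_set$rules, function(r) {
    outer(rm_a[, r$role_a], rm_b[, r$role_b], "&") |
      outer(rm_a[, r$role_b], rm_b[, r$role_a], "&")
  })
  names(possible) <- names(rule_set$rules)
  out <- lapply(rule_set$rules, function(r) {
    cls <- r$condition_class
    ok <- possible[[r$name]] &
      outer(!sb_a[, cls], !sb_b[, cls], "&")
    for (other in rule_set$rules) {
      if (other$name != r$name && other$condition_class == cls) {
        ok <- ok & !possible[[other$name]]
      }
    }
    ok
  })
  names(out) <- names(rule_set$rules)
  out
}

# Build oriented reaction jobs for the compatible (i, j) pairs of one rule.
oriented_jobs <- function(idx, rule, scan_a, scan_b) {
  rm_a <- scan_a$role_match; rm_b <- scan_b$role_match
  i <- idx[, 1]; j <- idx[, 2]
  fwd <- rm_a[i, rule$role_a] & rm_b[j, rule$role_b]
  rev <- rm_b[j, rule$role_a] & rm_a[i, rule$role_b]
  same <- !is.null(scan_a$same_set) && isTRUE(scan_a$same_set)
  rows <- list()
  for (k in seq_len(nrow(idx))) {
    if (fwd[k]) {
      rows[[length(rows) + 1L]] <- c(i[k], j[k], 0L)   # a from set A
    }
    if (rev[k] && !(same && i[k] == j[k] && fwd[k])) {
      rows[[length(rows) + 1L]] <- c(i[k], j[k], 1L)   # a from set B
    }
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, rows)
  colnames(m) <- c("i", "j", "swap")
  m
}

run_react_jobs <- function(jobs_df, smiles_a, smiles_b, rule_set,
                           max_products, workers = 1L) {
  if (is.null(jobs_df) || nrow(jobs_df) == 0L) return(list())
  payload <- lapply(seq_len(nrow(jobs_df)), function(k) {
    rule <- rule_set$rules[[jobs_df$rule[k]]]
    if (jobs_df$swap[k] == 0L) {
      list(a = smiles_a[jobs_df$i[k]], b = smiles_b[jobs_df$j[k]],
           smirks = rule$smirks)
    } else {
      list(a = smiles_b[jobs_df$j[k]], b = smiles_a[jobs_df$i[k]],
           smirks = rule$smirks)
    }
  })
  # Partition into `workers` chunks; results are combined in job order, so
  # the outcome is identical for any partitioning.
  chunk_id <- rep(seq_len(max(workers, 1L)), length.out = length(payload))
  res <- vector("list", length(payload))
  for (w in sort(unique(chunk_id))) {
    sel <- which(chunk_id == w)
    res[sel] <- kernel_call("react", jobs = payload[sel],
                            max_products = max_products)
  }
  res
}

new_accumulator <- function() {
  acc <- new.env(parent = emptyenv())
  acc$products <- new.env(hash = TRUE, parent = emptyenv())
  acc$dropped <- 0L
  acc
}

accumulate_products <- function(acc, res, jobs_df, make_routes) {
  dropped <- 0L
  store <- acc$products
  for (k in seq_along(res)) {
    r <- res[[k]]
    if (!isTRUE(r$ok)) next
    dropped <- dropped + r$dropped
    if (!length(r$products)) next
    routes <- make_routes(k)
    for (p in r$products) {
      key <- p$inchi
      entry <- get0(key, envir = store, inherits = FALSE)
      if (is.null(entry)) {
        entry <- list(smiles = p$canonical_smiles,
                      formula = formula_from_list(p$formula),
                      routes = list(), route_keys = character())
      }
      for (rt in routes) {
        rk <- route_key(rt)
        if (!(rk %in% entry$route_keys)) {
          entry$routes[[length(entry$routes) + 1L]] <- rt
          entry$route_keys <- c(entry$route_keys, rk)
        }
      }
      assign(key, entry, envir = store)
    }
  }
  acc$dropped <- acc$dropped + dropped
  acc
}

finalize_library <- function(acc, max_routes = 10L) {
  keys <- ls(acc$products, sorted = TRUE)
  if (!length(keys)) return(empty_library())
  entries <- mget(keys, envir = acc$products)
  df <- data.frame(
    inchi = keys,
    smiles = vapply(entries, `[[`, character(1), "smiles"),
    stringsAsFactors = FALSE)
  df$formula <- lapply(entries, `[[`, "formula")
  df$routes <- lapply(entries, function(e) {
    rts <- e$routes[order(vapply(e$routes, `[[`, integer(1), "step_count"),
                          vapply(e$routes, route_key, character(1)))]
    utils::head(rts, max_routes)
  })
  df$contributing_blocks <- lapply(df$routes, function(rts) {
    sort(unique(unlist(lapply(rts, route_blocks))))
  })
  rownames(df) <- NULL
  out <- new_library(df)
  attr(out, "dropped") <- acc$dropped
  out
}

#' Enumerate all one-step products of a catalog
#'
#' Tests every unordered block pair (including a block with itself: two
#' physical copies of one reagent) against every main-reaction rule under
#' the compatibility semantics of [compatible()], applies the transforms,
#' and deduplicates products by InChI with route merging.
#'
#' @param blocks A `diy_catalog`.
#' @param rule_set A [load_rule_set()] result.
#' @param self_pairing Allow a block to react with a second copy of itself.
#' @param max_products Per-pair product cap (polyfunctional guard).
#' @param max_routes Routes retained per product.
#' @param workers Number of partitions for the reaction jobs; results are
#'   independent of this value.
#' @return A `diy_library` data frame: `inchi`, `smiles`, list columns
#'   `formula`, `routes`, `contributing_blocks`.
#' @export
enumerate_step1 <- function(blocks, rule_set, self_pairing = TRUE,
                            max_products = 8L, max_routes = 10L,
                            workers = 1L) {
  n <- nrow(blocks)
  if (n == 0L) return(empty_library())
  scan <- scan_batch(blocks$smiles, rule_set)
  scan$same_set <- TRUE
  compat <- pair_compatibility(scan, scan, rule_set)

  jobs <- list()
  for (rn in names(compat)) {
    m <- compat[[rn]]
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) next
    idx <- idx[idx[, 1] < idx[, 2] |
               (self_pairing & idx[, 1] == idx[, 2]), , drop = FALSE]
    if (!nrow(idx)) next
    om <- oriented_jobs(idx, rule_set$rules[[rn]], scan, scan)
    if (is.null(om)) next
    jobs[[length(jobs) + 1L]] <- data.frame(
      rule = rn, i = om[, "i"], j = om[, "j"], swap = om[, "swap"],
      stringsAsFactors = FALSE)
  }
  jobs_df <- if (length(jobs)) do.call(rbind, jobs) else NULL
  res <- run_react_jobs(jobs_df, blocks$smiles, blocks$smiles, rule_set,
                        max_products, workers)
  acc <- new_accumulator()
  acc <- accumulate_products(acc, res, jobs_df, make_routes = function(k) {
    ids <- if (jobs_df$swap[k] == 0L) {
      c(blocks$id[jobs_df$i[k]], blocks$id[jobs_df$j[k]])
    } else {
      c(blocks$id[jobs_df$j[k]], blocks$id[jobs_df$i[k]])
    }
    list(new_route(list(list(rule = jobs_df$rule[k], bb_ids = ids))))
  })
  finalize_library(acc, max_routes = max_routes)
}

#' Enumerate second-step products
#'
#' Each step-1 product is re-scanned for remaining reactive sites and paired
#' against the *original* catalog blocks only (never intermediate against
#' intermediate), under the same compatibility semantics including the
#' ambiguity veto.  Resulting products carry three-block routes.  Products
#' also reachable in one step keep their one-step route first.
#'
#' @param step1_library The [enumerate_step1()] result for `blocks`.
#' @param blocks The original `diy_catalog`.
#' @inheritParams enumerate_step1
#' @return A `diy_library` of the step-2 products (merged with step-1 routes
#'   where a product is reachable both ways via [combine_libraries()]).
#' @export
enumerate_step2 <- function(step1_library, blocks, rule_set,
                            max_products = 8L, max_routes = 10L,
                            workers = 1L) {
  if (nrow(step1_library) == 0L || nrow(blocks) == 0L) return(empty_library())
  scan_int <- scan_batch(step1_library$smiles, rule_set)
  scan_blk <- scan_batch(blocks$smiles, rule_set)
  compat <- pair_compatibility(scan_int, scan_blk, rule_set)

  jobs <- list()
  for (rn in names(compat)) {
    idx <- which(compat[[rn]], arr.ind = TRUE)
    if (!nrow(idx)) next
    om <- oriented_jobs(idx, rule_set$rules[[rn]], scan_int, scan_blk)
    if (is.null(om)) next
    jobs[[length(jobs) + 1L]] <- data.frame(
      rule = rn, i = om[, "i"], j = om[, "j"], swap = om[, "swap"],
      stringsAsFactors = FALSE)
  }
  jobs_df <- if (length(jobs)) do.call(rbind, jobs) else NULL
  res <- run_react_jobs(jobs_df, step1_library$smiles, blocks$smiles,
                        rule_set, max_products, workers)
  acc <- new_accumulator()
  acc <- accumulate_products(acc, res, jobs_df, make_routes = function(k) {
    int_routes <- step1_library$routes[[jobs_df$i[k]]]
    bb <- blocks$id[jobs_df$j[k]]
    lapply(int_routes, function(rt) {
      new_route(c(rt$steps, list(list(rule = jobs_df$rule[k], bb_ids = bb))))
    })
  })
  step2 <- finalize_library(acc, max_routes = max_routes)
  # a molecule already reachable in 1 step keeps its 1-step routes preferred
  combine_libraries(step1_library, step2, max_routes = max_routes,
                    only_keys = step2$inchi)
}

# Merge two libraries by InChI with route union; 1-step routes sort first.
# only_keys restricts the output to the given keys (used so enumerate_step2
# returns step-2 products, with 1-step routes attached where they exist).
combine_libraries <- function(lib1, lib2, max_routes = 10L, only_keys = NULL) {
  keys <- sort(union(lib1$inchi, lib2$inchi))
  if (!is.null(only_keys)) keys <- sort(intersect(keys, only_keys))
  w1 <- match(keys, lib1$inchi)
  w2 <- match(keys, lib2$inchi)
  base <- ifelse(is.na(w1), 2L, 1L)
  df <- data.frame(
    inchi = keys,
    smiles = ifelse(base == 1L, lib1$smiles[w1], lib2$smiles[w2]),
    stringsAsFactors = FALSE)
  df$formula <- lapply(seq_along(keys), function(k)
    if (base[k] == 1L) lib1$formula[[w1[k]]] else lib2$formula[[w2[k]]])
  df$routes <- lapply(seq_along(keys), function(k) {
    routes <- c(if (!is.na(w1[k])) lib1$routes[[w1[k]]] else list(),
                if (!is.na(w2[k])) lib2$routes[[w2[k]]] else list())
    rk <- vapply(routes, route_key, character(1))
    routes <- routes[!duplicated(rk)]
    routes <- routes[order(vapply(routes, `[[`, integer(1), "step_count"),
                           vapply(routes, route_key, character(1)))]
    utils::head(routes, max_routes)
  })
  df$contributing_blocks <- lapply(df$routes, function(rts)
    sort(unique(unlist(lapply(rts, route_blocks)))))
  rownames(df) <- NULL
  new_library(df)
}

#' Enumerate a full one- or two-step library
#'
#' @inheritParams enumerate_step1
#' @param steps 1 or 2.
#' @return A `diy_library` containing all unique products with merged
#'   routes.
#' @export
enumerate_library <- function(blocks, rule_set, steps = 2L,
                              self_pairing = TRUE, max_products = 8L,
                              max_routes = 10L, workers = 1L) {
  stopifnot(steps %in% c(1L, 2L))
  lib1 <- enumerate_step1(blocks, rule_set, self_pairing = self_pairing,
                          max_products = max_products,
                          max_routes = max_routes, workers = workers)
  if (steps == 1L) return(lib1)
  lib2 <- enumerate_step2(lib1, blocks, rule_set,
                          max_products = max_products,
                          max_routes = max_routes, workers = workers)
  combine_libraries(lib1, lib2, max_routes = max_routes)
}

#' Tabulate product counts per (rule, step)
#'
#' A product counts once in every `(rule, step)` cell that appears in any of
#' its routes; the total number of unique products is reported separately in
#' the `"total_unique"` attribute.
#'
#' @param library A `diy_library`.
#' @return Data frame `rule`, `step`, `n_products`.
#' @export
tabulate_by_rule <- function(library) {
  cells <- list()
  for (i in seq_len(nrow(library))) {
    seen <- character()
    for (rt in library$routes[[i]]) {
      for (s in seq_along(rt$steps)) {
        key <- paste(rt$steps[[s]]$rule, s, sep = "\r")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          cells[[key]] <- (if (is.null(cells[[key]])) 0L else cells[[key]]) + 1L
        }
      }
    }
  }
  grid <- expand.grid(rule = MAIN_RULE_NAMES, step = c(1L, 2L),
                      stringsAsFactors = FALSE)
  grid$n_products <- vapply(seq_len(nrow(grid)), function(k) {
    key <- paste(grid$rule[k], grid$step[k], sep = "\r")
    if (is.null(cells[[key]])) 0L else cells[[key]]
  }, integer(1))
  attr(grid, "total_unique") <- nrow(library)
  grid
}

#' Estimate the synthesis cost range of a product
#'
#' Route cost = sum of building-block prices + per-step reagent/catalyst
#' overhead (a min/max range, e.g. 0.1-2.5 currency units per reaction) +
#' per-step solvent constant.  The cheapest route over all recorded routes
#' is reported.
#'
#' @param product One row of a `diy_library`.
#' @param blocks The catalog resolving all route `bb_ids`.
#' @param overhead Length-2 numeric: per-step overhead range.
#' @param solvent Per-step solvent cost.
#' @return List `min_cost`, `max_cost`, `route` (the cheapest route), and
#'   `per_route` (data frame of all routes).
#' @export
estimate_route_cost <- function(product, blocks, overhead = c(0.1, 2.5),
                                solvent = 1.0) {
  stopifnot(nrow(product) == 1L, length(overhead) == 2L)
  routes <- product$routes[[1]]
  per <- lapply(routes, function(rt) {
    ids <- route_blocks(rt)
    w <- match(ids, blocks$id)
    if (anyNA(w)) stop("route references unknown building block id(s): ",
                       paste(ids[is.na(w)], collapse = ", "))
    bb <- sum(blocks$price[w])
    k <- rt$step_count
    c(min = bb + k * overhead[1] + k * solvent,
      max = bb + k * overhead[2] + k * solvent)
  })
  mins <- vapply(per, `[[`, numeric(1), "min")
  maxs <- vapply(per, `[[`, numeric(1), "max")
  best <- which.min(mins)
  per_route <- data.frame(
    route = vapply(routes, route_key, character(1)),
    step_count = vapply(routes, `[[`, integer(1), "step_count"),
    min_cost = mins, max_cost = maxs)
  list(min_cost = mins[best], max_cost = maxs[best],
       route = routes[[best]], per_route = per_route)
}
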