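# Naive re-implementations used as independent oracles.
#
# The enumerator tries every ordered pair against every rule with scalar
# scan_sites()/compatible()/apply_rule() calls and no indexing or batching;
# the eliminator recomputes every score from scratch each iteration with no
# inverted index.  Both deliberately avoid the package's vectorized paths.

naive_enumerate <- function(catalog, rule_set, steps = 2L) {
  reports <- lapply(catalog$smiles, scan_sites, rule_set = rule_set)
  products <- list()

  add_product <- function(p, route) {
    entry <- products[[p$inchi]]
    if (is.null(entry)) {
      entry <- list(smiles = p$smiles, routes = list())
    }
    keys <- vapply(entry$routes, function(r)
      paste(vapply(r$steps, function(s)
        paste(s$rule, paste(s$bb_ids, collapse = ","), sep = ":"),
        character(1)), collapse = "|"), character(1))
    rk <- paste(vapply(route$steps, function(s)
      paste(s$rule, paste(s$bb_ids, collapse = ","), sep = ":"),
      character(1)), collapse = "|")
    if (!(rk %in% keys)) entry$routes <- c(entry$routes, list(route))
    products[[p$inchi]] <<- entry
  }

  n <- nrow(catalog)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next                      # unordered pairs incl. self
      for (rn in names(rule_set$rules)) {
        ok <- compatible(reports[[i]], reports[[j]], rn, rule_set)
        if (!ok$compatible) next
        prods <- apply_rule(catalog$smiles[i], catalog$smiles[j], rn, rule_set)
        rule <- rule_set$rules[[rn]]
        for (k in seq_len(nrow(prods))) {
          # route order follows the role assignment
          fwd <- reports[[i]]$role_match[[rule$role_a]] &&
                 reports[[j]]$role_match[[rule$role_b]]
          ids <- if (fwd) c(catalog$id[i], catalog$id[j]) else
                          c(catalog$id[j], catalog$id[i])
          add_product(prods[k, ], list(steps = list(list(rule = rn, bb_ids = ids)),
                                       step_count = 1L))
        }
      }
    }
  }
  step1_keys <- names(products)

  if (steps >= 2L) {
    step1 <- products
    for (key in step1_keys) {
      int_smiles <- step1[[key]]$smiles
      int_report <- scan_sites(int_smiles, rule_set)
      for (j in seq_len(n)) {
        for (rn in names(rule_set$rules)) {
          ok <- compatible(int_report, reports[[j]], rn, rule_set)
          if (!ok$compatible) next
          prods <- apply_rule(int_smiles, catalog$smiles[j], rn, rule_set)
          for (k in seq_len(nrow(prods))) {
            for (rt in step1[[key]]$routes) {
              add_product(prods[k, ],
                          list(steps = c(rt$steps,
                                         list(list(rule = rn,
                                                   bb_ids = catalog$id[j]))),
                               step_count = 2L))
            }
          }
        }
      }
    }
  }

  keys <- sort(names(products))
  df <- data.frame(
    inchi = keys,
    smiles = vapply(products[keys], `[[`, character(1), "smiles"),
    stringsAsFactors = FALSE)
  df$routes <- lapply(products[keys], `[[`, "routes")
  df$min_step <- vapply(df$routes, function(rts)
    min(vapply(rts, `[[`, integer(1), "step_count")), integer(1))
  df$contributing_blocks <- lapply(df$routes, function(rts)
    sort(unique(unlist(lapply(rts, function(rt)
      unlist(lapply(rt$steps, `[[`, "bb_ids")))))))
  rownames(df) <- NULL
  df
}

naive_rule_counts <- function(naive_lib) {
  cells <- list()
  for (i in seq_len(nrow(naive_lib))) {
    seen <- character()
    for (rt in naive_lib$routes[[i]]) {
      for (s in seq_along(rt$steps)) {
        key <- paste(rt$steps[[s]]$rule, s, sep = "\r")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          cells[[key]] <- (cells[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  if (!length(cells)) {
    return(data.frame(rule = character(), step = integer(),
                      n_products = integer()))
  }
  parts <- strsplit(names(cells), "\r", fixed = TRUE)
  out <- data.frame(rule = vapply(parts, `[[`, character(1), 1L),
                    step = as.integer(vapply(parts, `[[`, character(1), 2L)),
                    n_products = unlist(cells, use.names = FALSE))
  out[order(out$rule, out$step), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# From-scratch greedy elimination: no incidence matrix, no incremental
# updates; block-product membership recomputed from the surviving product
# list at every iteration.
naive_eliminate <- function(blocks, contributing_blocks, target_count) {
  alive_products <- contributing_blocks    # list of id vectors
  ids <- blocks$id
  prices <- blocks$price
  alive <- rep(TRUE, length(ids))
  iters <- list()
  while (sum(alive) > target_count) {
    scores <- vapply(seq_along(ids), function(b) {
      if (!alive[b]) return(Inf)
      sum(vapply(alive_products, function(cb) ids[b] %in% cb, logical(1))) /
        prices[b]
    }, numeric(1))
    lo <- min(scores)
    cand <- which(scores == lo)
    if (length(cand) > 1L) {
      cand <- cand[prices[cand] == max(prices[cand])]
      if (length(cand) > 1L) cand <- cand[order(ids[cand], decreasing = TRUE)]
    }
    drop <- cand[1]
    alive[drop] <- FALSE
    alive_products <- Filter(function(cb) !(ids[drop] %in% cb), alive_products)
    iters[[length(iters) + 1L]] <- data.frame(
      removed_id = ids[drop], score = lo,
      products_remaining = length(alive_products),
      budget_remaining = sum(prices[alive]), stringsAsFactors = FALSE)
  }
  list(iterations = if (length(iters))
         do.call(rbind, c(iters, list(make.row.names = FALSE)))
       else data.frame(removed_id = character(), score = numeric(),
                       products_remaining = integer(),
                       budget_remaining = numeric()),
       retained = ids[alive])
}
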