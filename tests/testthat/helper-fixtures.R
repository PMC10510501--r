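# Shared fixtures: one rule set per test session, and a catalog constructor
# for hand-picked reagent lists.

RS <- diylib::load_rule_set()

make_catalog <- function(smiles, price = NULL, ids = NULL) {
  std <- diylib::standardize(smiles)
  n <- length(smiles)
  if (is.null(price)) price <- rep(5, n)
  if (is.null(ids)) ids <- sprintf("tb%03d", seq_len(n))
  df <- data.frame(id = ids, smiles = std$canonical_smiles, inchi = std$inchi,
                   price = price, source_row = seq_len(n),
                   stringsAsFactors = FALSE)
  df$formula <- std$formula
  structure(df, class = c("diy_catalog", "data.frame"))
}

# formula helpers re-exported for balance checks
f_add <- diylib:::formula_add
f_sub <- diylib:::formula_subtract
f_eq <- diylib:::formula_equal

# hand-built single-product library rows for bookkeeping tests
lib_row <- function(inchi, smiles, routes) {
  df <- data.frame(inchi = inchi, smiles = smiles, stringsAsFactors = FALSE)
  df$formula <- list(NULL)
  df$routes <- list(routes)
  df$contributing_blocks <- list(sort(unique(unlist(
    lapply(routes, function(rt) unlist(lapply(rt$steps, `[[`, "bb_ids")))))))
  structure(df, class = c("diy_library", "data.frame"))
}

mk_route <- function(...) {
  steps <- list(...)
  list(steps = steps, step_count = length(steps))
}

# does reagents - product match one of the rule's admissible leaving groups?
balances <- function(fa, fb, fp, rule) {
  left <- f_sub(f_add(fa, fb), fp)
  any(vapply(rule$leaving, function(lv) f_eq(left, lv), logical(1)))
}
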