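# Deterministic synthetic catalogs -------------------------------------------
#
# The generator assembles building blocks from a fixed pool of simple
# ring/chain cores decorated with requested reactive handles.  Cores are
# chosen to carry no side-reaction pattern and no main-reaction role of
# their own, so a block's reactivity is exactly its requested handles.

FRAGMENTS <- c(
  amine = "CN",             # aminomethyl -> primary aliphatic amine
  carboxylic_acid = "C(=O)O",
  alcohol = "CO",           # hydroxymethyl
  aryl_halide = "Br",
  boronic_acid = "B(O)O",
  terminal_alkyne = "C#C",
  olefin = "C=C",
  thiol = "CS",
  inert = "C")

AROMATIC_CORES <- c(
  "c1ccc(%s)cc1", "Cc1ccc(%s)cc1", "CCc1ccc(%s)cc1", "COc1ccc(%s)cc1",
  "Fc1ccc(%s)cc1", "c1ccc2cc(%s)ccc2c1", "Cc1cccc(%s)c1",
  "CC(C)c1ccc(%s)cc1", "c1ccc(-c2ccc(%s)cc2)cc1", "CCOc1ccc(%s)cc1")

ALIPHATIC_CORES <- c(
  "C1CCC(%s)CC1", "C1CCCC(%s)C1", "C1CCC(%s)C1", "CC1CCC(%s)CC1",
  "C1CCOC(%s)C1", "CCC%s", "CCCC%s", "CCCCC%s", "CC(C)C%s", "CCCCCC%s")

# chloroazines: the built-in Cl sits at an electron-poor (ring N) position
AZINE_CORES <- c("Clc1ccc(%s)cn1", "Clc1ccc(%s)nc1", "Clc1ncc(%s)cn1")

AROMATIC_CORES2 <- c("c1cc(%s)cc(%s)c1", "c1cc(%s)ccc1%s",
                     "Cc1cc(%s)cc(%s)c1")
ALIPHATIC_CORES2 <- c("C1CC(%s)CC(%s)C1", "CC(C%s)CC%s")

HANDLE_CHOICES <- c("amine", "carboxylic_acid", "alcohol", "aryl_halide",
                    "heteroaryl_halide", "boronic_acid", "terminal_alkyne",
                    "olefin", "thiol", "inert")

#' Describe a synthetic catalog
#'
#' @param n_blocks Number of building blocks.
#' @param group_mix Named fractions over handle types (`amine`,
#'   `carboxylic_acid`, `alcohol`, `aryl_halide`, `heteroaryl_halide`,
#'   `boronic_acid`, `terminal_alkyne`, `olefin`, `thiol`); any remainder
#'   up to 1 becomes inert blocks.
#' @param bifunctional_fraction Fraction of blocks carrying a second handle.
#' @param price_range Positive `c(min, max)` price per gram.
#' @param price_distribution `"uniform"` or `"loguniform"`.
#' @param seed Integer seed; the same spec always yields the same catalog.
#' @return A `diy_catalog_spec` list.
#' @export
catalog_spec <- function(n_blocks, group_mix, bifunctional_fraction = 0,
                         price_range = c(4.5, 10),
                         price_distribution = c("uniform", "loguniform"),
                         seed = 1L) {
  price_distribution <- match.arg(price_distribution)
  stopifnot(n_blocks >= 1, length(price_range) == 2L,
            all(price_range > 0), price_range[1] <= price_range[2],
            bifunctional_fraction >= 0, bifunctional_fraction <= 1)
  if (is.null(names(group_mix)) ||
      !all(names(group_mix) %in% setdiff(HANDLE_CHOICES, "inert"))) {
    stop("group_mix must be named with known handle types")
  }
  if (sum(group_mix) > 1 + 1e-9) {
    stop("group_mix fractions must sum to at most 1")
  }
  structure(list(n_blocks = as.integer(n_blocks), group_mix = group_mix,
                 bifunctional_fraction = bifunctional_fraction,
                 price_range = price_range,
                 price_distribution = price_distribution,
                 seed = as.integer(seed)),
            class = "diy_catalog_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Largest-remainder allocation of the named handle counts; blocks not
# covered by the mix (sum of fractions < 1) stay inert.
allocate_counts <- function(fracs, n) {
  raw <- fracs * n
  counts <- floor(raw)
  target <- round(sum(fracs) * n)
  left <- target - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

build_block_smiles <- function(type1, type2, core_draw) {
  if (is.na(type2)) {
    if (type1 == "heteroaryl_halide") {
      core <- AZINE_CORES[core_draw %% length(AZINE_CORES) + 1L]
      return(sprintf(core, FRAGMENTS[["inert"]]))
    }
    pool <- if (type1 == "aryl_halide") AROMATIC_CORES
            else c(AROMATIC_CORES, ALIPHATIC_CORES)
    core <- pool[core_draw %% length(pool) + 1L]
    return(sprintf(core, FRAGMENTS[[type1]]))
  }
  # bifunctional
  if ("heteroaryl_halide" %in% c(type1, type2)) {
    other <- setdiff(c(type1, type2), "heteroaryl_halide")[1]
    if (is.na(other) || other == "heteroaryl_halide") other <- "inert"
    core <- AZINE_CORES[core_draw %% length(AZINE_CORES) + 1L]
    return(sprintf(core, FRAGMENTS[[other]]))
  }
  pool <- if ("aryl_halide" %in% c(type1, type2)) AROMATIC_CORES2
          else c(AROMATIC_CORES2, ALIPHATIC_CORES2)
  core <- pool[core_draw %% length(pool) + 1L]
  sprintf(core, FRAGMENTS[[type1]], FRAGMENTS[[type2]])
}

#' Generate a deterministic synthetic priced catalog
#'
#' @param spec A [catalog_spec()].
#' @return A `diy_catalog` with attribute `"handles"`: a data frame of the
#'   handle types planted in each block.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "diy_catalog_spec"))
  n <- spec$n_blocks
  with_local_seed(spec$seed, {
    counts <- allocate_counts(spec$group_mix, n)
    types <- c(rep(names(spec$group_mix), counts),
               rep("inert", n - sum(counts)))
    types <- sample(types)
    n_bi <- round(spec$bifunctional_fraction * n)
    type2 <- rep(NA_character_, n)
    if (n_bi > 0) {
      candidates <- which(types != "inert")
      if (length(candidates) < n_bi) {
        stop("infeasible spec: bifunctional_fraction exceeds the fraction ",
             "of handle-bearing blocks")
      }
      bi_idx <- if (length(candidates) == 1L) candidates else
        sample(candidates, n_bi)
      pool <- names(spec$group_mix)
      type2[bi_idx] <- sample(pool, n_bi, replace = TRUE)
    }
    core_draw <- sample.int(1000L, n, replace = TRUE)
    smiles <- vapply(seq_len(n), function(i)
      build_block_smiles(types[i], type2[i], core_draw[i]), character(1))
    price <- switch(spec$price_distribution,
      uniform = stats::runif(n, spec$price_range[1], spec$price_range[2]),
      loguniform = exp(stats::runif(n, log(spec$price_range[1]),
                                    log(spec$price_range[2]))))
    price <- round(price, 2)

    std <- standardize(smiles)
    out <- data.frame(
      id = sprintf("bb%04d", seq_len(n)),
      smiles = std$canonical_smiles,
      inchi = std$inchi,
      price = price,
      source_row = seq_len(n),
      stringsAsFactors = FALSE)
    out$formula <- std$formula
    out <- new_catalog(validate_catalog(out))
    attr(out, "handles") <- data.frame(id = out$id, type1 = types,
                                       type2 = type2,
                                       stringsAsFactors = FALSE)
    out
  })
}

# Known-answer micro-world ----------------------------------------------------

#' The hand-verified known-answer catalog and its frozen expectations
#'
#' A nine-block micro-world (three carboxylic acids, four amines, one aryl
#' bromide, one arylboronic acid) whose full two-step library and greedy
#' elimination trace were computed with the naive pair-by-pair oracle and
#' frozen as plain-text fixtures; used as a regression anchor.
#'
#' @return List: `catalog` (a `diy_catalog`), `expected_products` (frozen
#'   data frame `inchi`, `smiles`, `min_step`), `expected_counts` (frozen
#'   per-(rule, step) product counts), `expected_trace` (frozen elimination
#'   trace down to five retained blocks), `keep` (the trace's target count).
#' @export
generate_known_answer_set <- function() {
  smiles <- c("CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O",
              "CN", "CCN", "CC(C)N", "NCc1ccccc1",
              "Brc1ccccc1", "OB(O)c1ccccc1")
  price <- c(5, 6, 7, 3, 4, 5, 6, 8, 9)
  std <- standardize(smiles)
  catalog <- data.frame(
    id = sprintf("ka%02d", seq_along(smiles)),
    smiles = std$canonical_smiles, inchi = std$inchi,
    price = price, source_row = seq_along(smiles),
    stringsAsFactors = FALSE)
  catalog$formula <- std$formula
  catalog <- new_catalog(validate_catalog(catalog))

  dir <- system.file("extdata", "known_answer", package = "diylib")
  list(catalog = catalog,
       expected_products = utils::read.csv(file.path(dir, "products.csv"),
                                           stringsAsFactors = FALSE),
       expected_counts = utils::read.csv(file.path(dir, "rule_counts.csv"),
                                         stringsAsFactors = FALSE),
       expected_trace = utils::read.csv(file.path(dir, "trace.csv"),
                                        stringsAsFactors = FALSE),
       keep = 5L)
}
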