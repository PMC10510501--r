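# Catalog and library I/O with structure standardization ---------------------

#' Standardize structures to canonical SMILES and InChI keys
#'
#' Keeps the largest organic fragment (salts/solvates stripped), normalizes
#' functional-group representations and neutralizes charges where
#' unambiguous, then derives the canonical SMILES and standard InChI.  Two
#' molecules are treated as identical throughout the package if and only if
#' their InChI strings are byte-identical; tautomers are deliberately not
#' collapsed beyond what the InChI tautomer layer itself does.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data frame with columns `input`, `canonical_smiles`, `inchi`,
#'   and a list column `formula` (named element-count vectors).
#' @examples \dontrun{standardize("OC(=O)C")}
#' @export
standardize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(data.frame(input = character(), canonical_smiles = character(),
                      inchi = character()))
  }
  res <- kernel_call("standardize", smiles = as.list(smiles))
  bad <- vapply(res, function(r) !isTRUE(r$ok), logical(1))
  if (any(bad)) {
    stop("standardization failed for: ",
         paste(vapply(res[bad], function(r) r$error, character(1)), collapse = "; "))
  }
  out <- data.frame(
    input = smiles,
    canonical_smiles = vapply(res, `[[`, character(1), "canonical_smiles"),
    inchi = vapply(res, `[[`, character(1), "inchi"),
    stringsAsFactors = FALSE
  )
  out$formula <- lapply(res, function(r) formula_from_list(r$formula))
  out
}

# Lenient variant used by readers: failures become NA rows, not errors.
standardize_quietly <- function(smiles) {
  res <- kernel_call("standardize", smiles = as.list(smiles))
  data_ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  out <- data.frame(
    input = smiles,
    canonical_smiles = ifelse(data_ok,
      vapply(res, function(r) if (isTRUE(r$ok)) r$canonical_smiles else NA_character_,
             character(1)), NA_character_),
    inchi = vapply(res, function(r) if (isTRUE(r$ok)) r$inchi else NA_character_,
                   character(1)),
    ok = data_ok,
    stringsAsFactors = FALSE
  )
  out$formula <- lapply(res, function(r) if (isTRUE(r$ok)) formula_from_list(r$formula))
  out
}

new_catalog <- function(df) {
  stopifnot(all(c("id", "smiles", "inchi", "price", "source_row") %in% names(df)))
  structure(df, class = c("diy_catalog", "data.frame"))
}

validate_catalog <- function(df) {
  if (any(duplicated(df$id))) {
    stop("duplicate building-block id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(!is.finite(df$price) | df$price <= 0)) {
    stop("building-block prices must be positive; offending id(s): ",
         paste(df$id[!is.finite(df$price) | df$price <= 0], collapse = ", "))
  }
  if (nrow(df) == 0L) stop("catalog contains zero valid records")
  df
}

#' Read a priced building-block catalog
#'
#' CSV needs header columns `id`, `smiles`, `price`; SMILES files are
#' `SMILES<TAB>id<TAB>price`; SDF carries the price in a `price_per_g`
#' property field.  Structures are standardized on read; records that fail
#' to parse are skipped with a warning reporting the count.  Duplicate ids
#' and non-positive prices are hard errors.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"sdf"`, `"smi"`; default guessed from the
#'   file extension.
#' @return A `diy_catalog` data frame: `id`, `smiles` (canonical), `inchi`,
#'   `price`, `source_row`, plus a `formula` list column.
#' @export
read_catalog <- function(path, format = c("auto", "csv", "sdf", "smi")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", sdf = "sdf", smi = "smi", txt = "smi",
                     stop("cannot guess catalog format from extension: ", path))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- switch(format,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
      need <- c("id", "smiles", "price")
      if (!all(need %in% names(df))) {
        stop("catalog CSV must have header columns id, smiles, price; missing: ",
             paste(setdiff(need, names(df)), collapse = ", "))
      }
      data.frame(id = df$id, smiles = df$smiles,
                 price = suppressWarnings(as.numeric(df$price)),
                 source_row = seq_len(nrow(df)), stringsAsFactors = FALSE)
    },
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(parts) < 3L)) {
        stop("SMILES catalog lines must be SMILES<TAB>id<TAB>price")
      }
      data.frame(id = vapply(parts, `[[`, character(1), 2L),
                 smiles = vapply(parts, `[[`, character(1), 1L),
                 price = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L))),
                 source_row = seq_along(parts), stringsAsFactors = FALSE)
    },
    sdf = {
      recs <- kernel_call("read_sdf", text = paste(readLines(path, warn = FALSE),
                                                   collapse = "\n"))
      price <- vapply(recs, function(r) {
        if (!isTRUE(r$ok)) return(NA_character_)
        if (is.null(r$props$price_per_g)) {
          stop("SDF record '", r$name, "' lacks the price_per_g property field")
        }
        r$props$price_per_g
      }, character(1))
      data.frame(
        id = vapply(recs, function(r) if (isTRUE(r$ok)) r$name else NA_character_,
                    character(1)),
        smiles = vapply(recs, function(r) if (isTRUE(r$ok)) r$smiles else NA_character_,
                        character(1)),
        price = suppressWarnings(as.numeric(price)),
        source_row = seq_along(recs), stringsAsFactors = FALSE)
    }
  )
  if (anyNA(raw$price[!is.na(raw$smiles)])) {
    stop("missing or non-numeric price for id(s): ",
         paste(raw$id[is.na(raw$price) & !is.na(raw$smiles)], collapse = ", "))
  }

  parse_ok <- !is.na(raw$smiles)
  std <- standardize_quietly(raw$smiles[parse_ok])
  keep <- parse_ok
  keep[parse_ok] <- std$ok
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) failed structure parsing and were skipped",
            call. = FALSE)
  }
  out <- raw[keep, , drop = FALSE]
  out$smiles <- std$canonical_smiles[std$ok]
  out$inchi <- std$inchi[std$ok]
  out$formula <- std$formula[std$ok]
  rownames(out) <- NULL
  new_catalog(validate_catalog(out[c("id", "smiles", "inchi", "price",
                                     "source_row", "formula")]))
}

#' Write a priced catalog back to CSV
#' @param catalog A `diy_catalog`.
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog[c("id", "smiles", "price")], path, row.names = FALSE)
  invisible(nrow(catalog))
}

# Library I/O -----------------------------------------------------------------

route_rules <- function(route) vapply(route$steps, `[[`, character(1), "rule")
route_blocks <- function(route) unlist(lapply(route$steps, `[[`, "bb_ids"),
                                       use.names = FALSE)

library_rows <- function(products, blocks = NULL,
                         overhead = c(0.1, 2.5), solvent = 1.0) {
  rows <- lapply(seq_len(nrow(products)), function(i) {
    routes <- products$routes[[i]]
    steps <- vapply(routes, `[[`, integer(1), "step_count")
    pref <- routes[[order(steps)[1]]]
    rules <- route_rules(pref)
    cost <- if (!is.null(blocks)) {
      rng <- estimate_route_cost(products[i, , drop = FALSE], blocks,
                                 overhead = overhead, solvent = solvent)
      mean(c(rng$min_cost, rng$max_cost))
    } else NA_real_
    data.frame(
      product_smiles = products$smiles[i],
      inchi = products$inchi[i],
      step_count = pref$step_count,
      rule_1 = rules[1],
      rule_2 = if (length(rules) > 1L) rules[2] else "",
      bb_ids = paste(route_blocks(pref), collapse = ";"),
      route_cost = cost,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write an enumerated product library
#'
#' CSV schema: `product_smiles, inchi, step_count, rule_1, rule_2, bb_ids,
#' route_cost` with the preferred (fewest-step) route; `bb_ids` are
#' semicolon-joined in route order.  A round-trip read reproduces the same
#' InChI key set.
#'
#' @param products A `diy_library` (see [enumerate_step1()]).
#' @param path Output path.
#' @param format `"csv"`, `"smi"`, or `"sdf"`.
#' @param blocks Optional catalog used to fill `route_cost` (cheapest-route
#'   midpoint); omitted, the column is `NA`.
#' @return Invisibly, the number of records written.
#' @export
write_library <- function(products, path, format = c("csv", "smi", "sdf"),
                          blocks = NULL) {
  format <- match.arg(format)
  rows <- if (nrow(products) > 0L) library_rows(products, blocks) else
    data.frame(product_smiles = character(), inchi = character(),
               step_count = integer(), rule_1 = character(),
               rule_2 = character(), bb_ids = character(),
               route_cost = numeric())
  switch(format,
    csv = utils::write.csv(rows, path, row.names = FALSE),
    smi = writeLines(paste(rows$product_smiles, rows$inchi, sep = "\t"), path),
    sdf = {
      recs <- lapply(seq_len(nrow(rows)), function(i) {
        list(smiles = rows$product_smiles[i], name = rows$inchi[i],
             props = list(step_count = rows$step_count[i],
                          rule_1 = rows$rule_1[i], rule_2 = rows$rule_2[i],
                          bb_ids = rows$bb_ids[i]))
      })
      res <- kernel_call("write_sdf", records = recs)
      if (!is.null(res$error)) stop(res$error)
      writeLines(res$text, path)
    })
  invisible(nrow(rows))
}

#' Read a product library written by [write_library()] (CSV only)
#' @param path CSV path.
#' @return Data frame in the written schema.
#' @export
read_library <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
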