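# Reaction rules, site scanning, and pair compatibility ----------------------

MAIN_RULE_NAMES <- c("amide", "ester", "snar", "buchwald", "suzuki",
                     "sonogashira", "heck")
CONDITION_CLASSES <- c("coupling_agent", "base_only", "pd_catalyst")

#' Load and validate a reaction rule set
#'
#' Reads the main-reaction and side-reaction configuration (the shipped
#' default covers all seven rules: amide, ester, SNAr, Buchwald-Hartwig,
#' Suzuki, Sonogashira, Heck, and 20+ side-reaction patterns).  Every
#' transform is validated by applying it to its bundled smoke-test reagent
#' pair; a transform that yields no product aborts the load.
#'
#' @param config Path to a YAML rule configuration; `NULL` loads the shipped
#'   default set.
#' @return A `diy_rule_set`: `$rules` (named list with `role_a`, `role_b`
#'   SMARTS ids, `condition_class`, `smirks`, `leaving` formulas),
#'   `$side_patterns`, `$role_patterns`.
#' @export
load_rule_set <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "reaction_rules.yaml", package = "diylib")
  }
  cfg <- yaml::read_yaml(config)
  for (field in c("role_patterns", "main_reactions", "side_reactions")) {
    if (is.null(cfg[[field]])) stop("rule config lacks section: ", field)
  }
  missing <- setdiff(MAIN_RULE_NAMES, names(cfg$main_reactions))
  if (length(missing)) {
    stop("rule config must define all seven main reactions; missing: ",
         paste(missing, collapse = ", "))
  }
  if (length(cfg$side_reactions) < 20L) {
    stop("rule config must define at least 20 side-reaction patterns (found ",
         length(cfg$side_reactions), ")")
  }

  roles <- vapply(cfg$role_patterns, identity, character(1))
  rules <- lapply(names(cfg$main_reactions), function(nm) {
    r <- cfg$main_reactions[[nm]]
    for (f in c("role_a", "role_b", "condition_class", "smirks", "leaving")) {
      if (is.null(r[[f]])) stop("rule '", nm, "' lacks field: ", f)
    }
    if (!r$condition_class %in% CONDITION_CLASSES) {
      stop("rule '", nm, "': unknown condition class ", r$condition_class)
    }
    if (!all(c(r$role_a, r$role_b) %in% names(roles))) {
      stop("rule '", nm, "': role pattern id not in role_patterns")
    }
    list(name = nm, role_a = r$role_a, role_b = r$role_b,
         condition_class = r$condition_class, smirks = r$smirks,
         leaving = lapply(unlist(r$leaving), parse_formula),
         smoke = r$smoke)
  })
  names(rules) <- names(cfg$main_reactions)

  sides <- lapply(names(cfg$side_reactions), function(nm) {
    s <- cfg$side_reactions[[nm]]
    blocks <- unlist(s$blocks_under)
    if (is.null(s$pattern) || !length(blocks)) {
      stop("side pattern '", nm, "' needs a pattern and a nonempty blocks_under")
    }
    if (!all(blocks %in% CONDITION_CLASSES)) {
      stop("side pattern '", nm, "': unknown condition class in blocks_under")
    }
    list(name = nm, pattern = s$pattern, blocks_under = blocks)
  })
  names(sides) <- names(cfg$side_reactions)

  # validate SMIRKS syntax, then smoke-test each transform
  val <- kernel_call("validate_smirks",
                     smirks = unname(lapply(rules, `[[`, "smirks")))
  bad <- which(vapply(val, function(v) !isTRUE(v$ok), logical(1)))
  if (length(bad)) {
    stop("malformed transform for rule(s): ",
         paste(names(rules)[bad], collapse = ", "))
  }
  jobs <- lapply(rules, function(r) list(a = r$smoke$a, b = r$smoke$b,
                                         smirks = r$smirks))
  res <- kernel_call("react", jobs = unname(jobs), max_products = 4)
  dead <- vapply(res, function(r) !isTRUE(r$ok) || length(r$products) == 0L,
                 logical(1))
  if (any(dead)) {
    stop("transform produced no product on its smoke-test pair for rule(s): ",
         paste(names(rules)[dead], collapse = ", "))
  }

  structure(list(rules = rules, side_patterns = sides, role_patterns = roles),
            class = "diy_rule_set")
}

#' @export
print.diy_rule_set <- function(x, ...) {
  cat("diy_rule_set:", length(x$rules), "main reactions,",
      length(x$side_patterns), "side patterns\n")
  invisible(x)
}

# Batched scan: role-pattern and side-pattern matches for many molecules.
# Returns per-molecule unique-atom-set hits plus boolean convenience
# matrices used by the vectorized pair-compatibility computation.
scan_batch <- function(smiles, rule_set) {
  patterns <- c(
    lapply(names(rule_set$role_patterns), function(id)
      list(id = paste0("role:", id), smarts = rule_set$role_patterns[[id]])),
    lapply(rule_set$side_patterns, function(s)
      list(id = paste0("side:", s$name), smarts = s$pattern))
  )
  res <- kernel_call("scan", smiles = as.list(smiles), patterns = unname(patterns))
  bad <- which(vapply(res, function(r) !isTRUE(r$ok), logical(1)))
  if (length(bad)) stop("scan failed for SMILES: ",
                        paste(smiles[bad], collapse = ", "))
  role_ids <- names(rule_set$role_patterns)
  side_ids <- names(rule_set$side_patterns)
  n <- length(smiles)

  role_match <- matrix(FALSE, n, length(role_ids),
                       dimnames = list(NULL, role_ids))
  side_match <- matrix(FALSE, n, length(side_ids),
                       dimnames = list(NULL, side_ids))
  hits <- vector("list", n)
  for (i in seq_len(n)) {
    h <- res[[i]]$hits
    hits[[i]] <- h
    for (id in names(h)) {
      if (startsWith(id, "role:")) {
        role_match[i, sub("^role:", "", id)] <- TRUE
      } else {
        side_match[i, sub("^side:", "", id)] <- TRUE
      }
    }
  }
  # molecule x condition-class veto matrix
  side_block <- matrix(FALSE, n, length(CONDITION_CLASSES),
                       dimnames = list(NULL, CONDITION_CLASSES))
  for (s in rule_set$side_patterns) {
    hit <- side_match[, s$name]
    for (cls in s$blocks_under) side_block[, cls] <- side_block[, cls] | hit
  }
  list(smiles = smiles, hits = hits, role_match = role_match,
       side_match = side_match, side_block = side_block)
}

scan_hit_atoms <- function(hits, key) {
  h <- hits[[key]]
  if (is.null(h)) list() else lapply(h, function(m) sort(unlist(m)))
}

#' Scan a molecule for main-reaction roles and side-reaction patterns
#'
#' Reports every main-reaction role match and side-pattern match as unique
#' atom-index sets (0-based, RDKit order), deterministically ordered by rule
#' name then lowest atom index.
#'
#' @param smiles A single standardized SMILES string.
#' @param rule_set A [load_rule_set()] result.
#' @return A `diy_site_report`: `$smiles`, `$matches` (data frame `rule`,
#'   `role`, list column `atoms`), `$side_hits` (`name`, `atoms`).
#' @export
scan_sites <- function(smiles, rule_set) {
  stopifnot(length(smiles) == 1L)
  sb <- scan_batch(smiles, rule_set)
  h <- sb$hits[[1]]

  match_rows <- list()
  for (rule in rule_set$rules) {
    for (role in c("a", "b")) {
      role_id <- if (role == "a") rule$role_a else rule$role_b
      atoms <- scan_hit_atoms(h, paste0("role:", role_id))
      for (at in atoms) {
        match_rows[[length(match_rows) + 1L]] <-
          list(rule = rule$name, role = role, atoms = at)
      }
    }
  }
  matches <- if (length(match_rows)) {
    df <- data.frame(
      rule = vapply(match_rows, `[[`, character(1), "rule"),
      role = vapply(match_rows, `[[`, character(1), "role"),
      stringsAsFactors = FALSE)
    df$atoms <- lapply(match_rows, `[[`, "atoms")
    first_atom <- vapply(df$atoms, function(a) a[1], numeric(1))
    df <- df[order(df$rule, df$role, first_atom), , drop = FALSE]
    rownames(df) <- NULL
    # collapse duplicates with identical atom sets within a (rule, role)
    key <- paste(df$rule, df$role,
                 vapply(df$atoms, paste, character(1), collapse = ","))
    df[!duplicated(key), , drop = FALSE]
  } else {
    data.frame(rule = character(), role = character())
  }

  side_rows <- list()
  for (s in rule_set$side_patterns) {
    atoms <- scan_hit_atoms(h, paste0("side:", s$name))
    for (at in atoms) {
      side_rows[[length(side_rows) + 1L]] <- list(name = s$name, atoms = at)
    }
  }
  side_hits <- if (length(side_rows)) {
    df <- data.frame(name = vapply(side_rows, `[[`, character(1), "name"),
                     stringsAsFactors = FALSE)
    df$atoms <- lapply(side_rows, `[[`, "atoms")
    first_atom <- vapply(df$atoms, function(a) a[1], numeric(1))
    df <- df[order(df$name, first_atom), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(name = character())
  }

  structure(list(smiles = sb$smiles[1], matches = matches,
                 side_hits = side_hits,
                 role_match = sb$role_match[1, ],
                 side_block = sb$side_block[1, ]),
            class = "diy_site_report")
}

#' @export
print.diy_site_report <- function(x, ...) {
  cat("diy_site_report for", x$smiles, "\n")
  cat("  role matches:", nrow(x$matches), " side hits:", nrow(x$side_hits), "\n")
  invisible(x)
}

report_roles <- function(report) {
  if (!is.null(report$role_match)) return(report$role_match)
  stop("not a diy_site_report")
}

#' Decide whether two reagents may react under a rule
#'
#' A pairing is allowed iff (i) the two molecules carry the rule's two role
#' patterns (either assignment), (ii) neither molecule carries a side
#' pattern that interferes under the rule's condition class, and (iii) no
#' *other* main reaction of the same condition class is simultaneously
#' possible across the pair (the ambiguity veto).  Main reactions that would
#' need a different condition class never veto: e.g. a boronic acid on the
#' amine partner does not block an amide coupling, because Suzuki coupling
#' cannot proceed without the Pd catalyst.
#'
#' @param a,b `diy_site_report`s from [scan_sites()], same rule set.
#' @param rule A rule name or a rule entry of the rule set.
#' @param rule_set The [load_rule_set()] result both reports were built with.
#' @return A list `compatible` (logical) and `reason` (`""` when allowed;
#'   otherwise `"role_mismatch"`, `"side:<pattern>"`, or
#'   `"ambiguity:<rule>"`).
#' @export
compatible <- function(a, b, rule, rule_set) {
  if (is.character(rule)) rule <- rule_set$rules[[rule]]
  if (is.null(rule)) stop("unknown rule")
  ra <- report_roles(a); rb <- report_roles(b)

  ori1 <- ra[[rule$role_a]] && rb[[rule$role_b]]
  ori2 <- rb[[rule$role_a]] && ra[[rule$role_b]]
  if (!ori1 && !ori2) {
    return(list(compatible = FALSE, reason = "role_mismatch"))
  }

  cls <- rule$condition_class
  for (rep in list(a, b)) {
    if (rep$side_block[[cls]]) {
      hit <- vapply(rule_set$side_patterns, function(s) {
        cls %in% s$blocks_under && s$name %in% rep$side_hits$name
      }, logical(1))
      return(list(compatible = FALSE,
                  reason = paste0("side:", names(which(hit))[1])))
    }
  }

  for (other in rule_set$rules) {
    if (other$name == rule$name || other$condition_class != cls) next
    poss <- (ra[[other$role_a]] && rb[[other$role_b]]) ||
            (rb[[other$role_a]] && ra[[other$role_b]])
    if (poss) {
      return(list(compatible = FALSE, reason = paste0("ambiguity:", other$name)))
    }
  }
  list(compatible = TRUE, reason = "")
}

#' Apply a reaction rule to a compatible reagent pair
#'
#' Generates one product per distinct reactive-site combination (both role
#' assignments are tried when both match), standardizes, and deduplicates by
#' InChI.  Chemically invalid transform outputs are dropped and counted; a
#' per-pair cap (default 8) guards against polyfunctional blowup.
#'
#' @param a,b SMILES strings (standardized).
#' @param rule Rule name or rule entry.
#' @param rule_set A [load_rule_set()] result.
#' @param max_products Per-pair product cap.
#' @return Data frame `smiles`, `inchi` with a `formula` list column; the
#'   number of dropped invalid products in attribute `"dropped"`.
#' @export
apply_rule <- function(a, b, rule, rule_set, max_products = 8L) {
  if (is.character(rule)) rule <- rule_set$rules[[rule]]
  jobs <- list(list(a = a, b = b, smirks = rule$smirks),
               list(a = b, b = a, smirks = rule$smirks))
  res <- kernel_call("react", jobs = jobs, max_products = max_products)
  prods <- list(); dropped <- 0L
  for (r in res) {
    if (!isTRUE(r$ok)) next
    dropped <- dropped + r$dropped
    for (p in r$products) prods[[length(prods) + 1L]] <- p
  }
  if (!length(prods)) {
    out <- data.frame(smiles = character(), inchi = character())
    out$formula <- list()
    attr(out, "dropped") <- dropped
    return(out)
  }
  inchi <- vapply(prods, `[[`, character(1), "inchi")
  keep <- !duplicated(inchi)
  out <- data.frame(
    smiles = vapply(prods, `[[`, character(1), "canonical_smiles")[keep],
    inchi = inchi[keep], stringsAsFactors = FALSE)
  out$formula <- lapply(prods[keep], function(p) formula_from_list(p$formula))
  if (nrow(out) > max_products) out <- out[seq_len(max_products), , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
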