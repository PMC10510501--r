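# Focused-library classification ---------------------------------------------

load_focused_criteria <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "focused_criteria.yaml", package = "diylib")
  }
  cfg <- yaml::read_yaml(config)
  for (f in c("warheads", "amino_acid_backbone", "nucleobase_attached",
              "unwanted_reactive")) {
    if (is.null(cfg[[f]])) stop("focused criteria config lacks section: ", f)
  }
  cfg
}

HANDLE_TYPES <- list(
  amine = "amine",
  carboxylic_acid = "carboxylic_acid",
  alcohol = "aliphatic_alcohol",
  halide = c("aryl_halide", "snar_halide"),
  boronic_acid = "boronic_acid",
  terminal_alkyne = "terminal_alkyne",
  olefin = "mono_olefin",
  thiol = "thiol")

#' Count a molecule's main-reaction handles
#'
#' Number of distinct reactive sites among the main-reaction roles (amine,
#' carboxylic acid, aryl/heteroaryl halide, alcohol, thiol, boronic acid,
#' terminal alkyne, olefin), counting each occurrence once per unique atom
#' set (overlapping aryl-halide patterns collapse to one site).
#'
#' @param smiles Character vector of SMILES (or a `diy_library`).
#' @param rule_set A [load_rule_set()] result supplying the role patterns.
#' @return Integer vector of handle counts.
#' @export
count_reactive_handles <- function(smiles, rule_set) {
  if (inherits(smiles, "diy_library")) smiles <- smiles$smiles
  if (!length(smiles)) return(integer())
  sb <- scan_batch(smiles, rule_set)
  vapply(seq_along(smiles), function(i) {
    h <- sb$hits[[i]]
    total <- 0L
    for (type in names(HANDLE_TYPES)) {
      sets <- list()
      for (role_id in HANDLE_TYPES[[type]]) {
        sets <- c(sets, scan_hit_atoms(h, paste0("role:", role_id)))
      }
      if (length(sets)) {
        total <- total +
          length(unique(vapply(sets, paste, character(1), collapse = ",")))
      }
    }
    total
  }, integer(1))
}

#' Screen molecules against PAINS motifs
#'
#' Defaults to the published PAINS families A/B/C (via the RDKit filter
#' catalog); alternatively a named list of SMARTS patterns can be supplied.
#' An empty user pattern set passes everything with a warning.
#'
#' @param smiles Character vector of SMILES (or a `diy_library`).
#' @param pains_patterns `NULL` for the built-in families, or a named list
#'   of SMARTS strings.
#' @return Data frame `smiles`, `pass`, and list column `matched` (names of
#'   matched patterns).
#' @export
pains_screen <- function(smiles, pains_patterns = NULL) {
  if (inherits(smiles, "diy_library")) smiles <- smiles$smiles
  if (!length(smiles)) {
    out <- data.frame(smiles = character(), pass = logical())
    out$matched <- list()
    return(out)
  }
  if (is.null(pains_patterns)) {
    res <- kernel_call("pains", smiles = as.list(smiles))
    matched <- lapply(res, function(r) {
      if (isTRUE(r$ok)) unlist(r$matches) %||% character() else character()
    })
  } else if (length(pains_patterns) == 0L) {
    warning("empty PAINS pattern set: every molecule passes")
    matched <- rep(list(character()), length(smiles))
  } else {
    patterns <- lapply(names(pains_patterns), function(nm)
      list(id = nm, smarts = pains_patterns[[nm]]))
    res <- kernel_call("match_counts", smiles = as.list(smiles),
                       patterns = patterns)
    matched <- lapply(res, function(r) {
      if (!isTRUE(r$ok)) return(character())
      names(which(vapply(r$counts, function(x) x > 0, logical(1))))
    })
  }
  out <- data.frame(smiles = smiles,
                    pass = lengths(matched) == 0L,
                    stringsAsFactors = FALSE)
  out$matched <- matched
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

SUBSET_LABELS <- c("nucleotide_deriv", "amino_acid_deriv", "warhead_fragment",
                   "warhead_druglike", "del_2site", "del_3site", "bioactive",
                   "general_screening")

#' Classify products into focused-library subsets
#'
#' Labels are non-exclusive: nucleotide derivatives (N-substituted
#' nucleobase), amino-acid derivatives (alpha-amino-acid backbone with a
#' carbon side chain; bare glycine backbones never qualify), covalent
#' warheads split fragment-sized (rule-of-three) vs drug-like
#' (rule-of-five), DNA-encoded-library building blocks by reactive-handle
#' count (exactly 2 or exactly 3; single-handle capping blocks are
#' deliberately not labelled), known bioactives by exact InChI match
#' against a user-supplied annotated reference, and a general-purpose
#' screening subset that requires passing PAINS and carrying no unwanted
#' reactive site.
#'
#' @param library A `diy_library` (or data frame with `smiles`, `inchi`).
#' @param profile Matching [compute_profile()] rows.
#' @param rule_set A [load_rule_set()] result (handle counting).
#' @param criteria Optional path to a YAML criteria config.
#' @param subsets Labels to compute; `"bioactive"` requires
#'   `bioactive_ref`.
#' @param bioactive_ref Character vector of reference InChIs (or a file of
#'   one InChI per line) annotating known bioactives.
#' @param gate_thresholds Optional gate threshold config path.
#' @return Data frame: `inchi`, `smiles`, one logical column per requested
#'   subset.
#' @export
classify <- function(library, profile, rule_set, criteria = NULL,
                     subsets = setdiff(SUBSET_LABELS, "bioactive"),
                     bioactive_ref = NULL, gate_thresholds = NULL) {
  stopifnot(all(subsets %in% SUBSET_LABELS))
  if ("bioactive" %in% subsets && is.null(bioactive_ref)) {
    stop("classifying 'bioactive' needs a bioactive_ref annotated reference")
  }
  smiles <- library$smiles
  inchi <- if (!is.null(library$inchi)) library$inchi else
    standardize(smiles)$inchi
  stopifnot(nrow(profile) == length(smiles))
  cfg <- load_focused_criteria(criteria)
  gates <- apply_gates(profile, gate_thresholds)

  patterns <- c(
    lapply(names(cfg$warheads), function(nm)
      list(id = paste0("warhead:", nm), smarts = cfg$warheads[[nm]])),
    list(list(id = "aa_backbone", smarts = cfg$amino_acid_backbone)),
    lapply(names(cfg$nucleobase_attached), function(nm)
      list(id = paste0("nuc:", nm), smarts = cfg$nucleobase_attached[[nm]])),
    lapply(names(cfg$unwanted_reactive), function(nm)
      list(id = paste0("unwanted:", nm), smarts = cfg$unwanted_reactive[[nm]]))
  )
  mres <- kernel_call("match_counts", smiles = as.list(smiles),
                      patterns = patterns)
  hit <- function(i, prefix) {
    counts <- mres[[i]]$counts
    ids <- grep(prefix, names(counts), value = TRUE)
    any(vapply(counts[ids], function(x) x > 0, logical(1)))
  }
  n <- length(smiles)
  has_warhead <- vapply(seq_len(n), hit, logical(1), prefix = "^warhead:")
  has_aa <- vapply(seq_len(n), hit, logical(1), prefix = "^aa_backbone$")
  has_nuc <- vapply(seq_len(n), hit, logical(1), prefix = "^nuc:")
  has_unwanted <- vapply(seq_len(n), hit, logical(1), prefix = "^unwanted:")

  out <- data.frame(inchi = inchi, smiles = smiles, stringsAsFactors = FALSE)
  needs_handles <- any(c("del_2site", "del_3site") %in% subsets)
  handles <- if (needs_handles) count_reactive_handles(smiles, rule_set)
  for (lab in subsets) {
    out[[lab]] <- switch(lab,
      nucleotide_deriv = has_nuc,
      amino_acid_deriv = has_aa,
      warhead_fragment = has_warhead & gates$ro3,
      warhead_druglike = has_warhead & gates$ro5,
      del_2site = handles == 2L,
      del_3site = handles == 3L,
      bioactive = {
        ref <- if (length(bioactive_ref) == 1L && file.exists(bioactive_ref)) {
          readLines(bioactive_ref, warn = FALSE)
        } else bioactive_ref
        inchi %in% ref
      },
      general_screening = {
        pains <- pains_screen(smiles)
        pains$pass & !has_unwanted
      })
  }
  out
}

#' Summarize subset membership counts and percentages
#' @param labels A [classify()] result.
#' @return Data frame `subset`, `n`, `pct`.
#' @export
subset_summary <- function(labels) {
  subs <- intersect(SUBSET_LABELS, names(labels))
  data.frame(
    subset = subs,
    n = vapply(subs, function(s) sum(labels[[s]]), integer(1)),
    pct = vapply(subs, function(s) 100 * mean(labels[[s]]), numeric(1)),
    row.names = NULL)
}
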