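# 19-descriptor physicochemical panel and property gates ----------------------

load_property_patterns <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "property_patterns.yaml", package = "diylib")
  }
  cfg <- yaml::read_yaml(config)
  stopifnot(!is.null(cfg$acidic), !is.null(cfg$basic))
  cfg
}

PROFILE_FIELDS <- c("molar_mass", "logp", "psa", "n_hba", "n_hbd", "n_rotb",
                    "hac", "n_rings", "fsp3", "refractivity",
                    "n_aromatic_rings", "n_aliphatic_rings",
                    "n_chiral_centers", "n_acidic", "n_basic", "n_acid_base",
                    "n_noncyclic_amide", "n_o_plus_n", "heteroatom_ratio")

#' Compute the 19-descriptor physicochemical profile
#'
#' Molar mass (g/mol), logP (Crippen atom-contribution estimate), polar
#' surface area (topological, \eqn{\mathrm{\AA}^2}), H-bond
#' acceptor/donor counts, rotatable bonds, heavy atom count, ring counts
#' (total/aromatic/aliphatic), fraction of sp3 carbons, molar refractivity,
#' chiral centers (assigned + unassigned), acidic and basic group counts
#' (configurable SMARTS lists), noncyclic amide count, O-plus-N atom count,
#' and heteroatom ratio (non-C heavy atoms over heavy atoms).
#'
#' @param smiles Character vector of SMILES (or a `diy_library`).
#' @param hba_mode `"acceptor"` (acceptor-perception counting, default) or
#'   `"lipinski"` (N+O).
#' @param patterns Optional path to a YAML acidic/basic pattern config.
#' @return Data frame: `smiles` plus the 19 descriptor columns.
#' @export
compute_profile <- function(smiles, hba_mode = c("acceptor", "lipinski"),
                            patterns = NULL) {
  hba_mode <- match.arg(hba_mode)
  if (inherits(smiles, "diy_library")) smiles <- smiles$smiles
  stopifnot(is.character(smiles))
  if (!length(smiles)) {
    out <- data.frame(smiles = character())
    for (f in PROFILE_FIELDS) out[[f]] <- numeric()
    return(out)
  }
  cfg <- load_property_patterns(patterns)
  as_patterns <- function(lst) {
    lapply(names(lst), function(nm) list(id = nm, smarts = lst[[nm]]))
  }
  res <- kernel_call("profile", smiles = as.list(smiles),
                     acidic_patterns = as_patterns(cfg$acidic),
                     basic_patterns = as_patterns(cfg$basic),
                     hba_mode = hba_mode)
  bad <- which(vapply(res, function(r) !isTRUE(r$ok), logical(1)))
  if (length(bad)) {
    stop("profile failed for: ", paste(smiles[bad], collapse = ", "))
  }
  out <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
  for (f in PROFILE_FIELDS) {
    out[[f]] <- vapply(res, function(r) as.numeric(r[[f]]), numeric(1))
  }
  int_fields <- grep("^n_|^hac$", PROFILE_FIELDS, value = TRUE)
  for (f in int_fields) out[[f]] <- as.integer(out[[f]])
  out
}

load_gate_thresholds <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "gate_thresholds.yaml", package = "diylib")
  }
  cfg <- yaml::read_yaml(config)
  need <- list(
    ro5 = c("max_molar_mass", "max_logp", "max_n_hbd", "max_n_hba"),
    ro3 = c("max_molar_mass", "max_logp", "max_n_hbd", "max_n_hba",
            "max_n_rotb", "max_psa"),
    lead_like = c("min_molar_mass", "max_molar_mass", "min_logp", "max_logp",
                  "max_n_rings", "max_n_rotb"))
  for (gate in names(need)) {
    missing <- setdiff(need[[gate]], names(cfg[[gate]]))
    if (length(missing)) {
      stop("malformed gate thresholds: gate '", gate, "' lacks ",
           paste(missing, collapse = ", "))
    }
    if (!all(vapply(cfg[[gate]], is.numeric, logical(1)))) {
      stop("malformed gate thresholds: non-numeric value in gate '", gate, "'")
    }
  }
  cfg
}

#' Apply the rule-of-five / rule-of-three / lead-like gates
#'
#' Pure threshold logic on a computed profile.  Boundary semantics: the
#' rule-of-three molar mass bound is a strict `<`; every other bound is
#' inclusive.  With the shipped defaults the rule-of-three region nests
#' inside the rule-of-five region.
#'
#' @param profile A [compute_profile()] data frame.
#' @param thresholds Optional path to a YAML threshold config.
#' @return Data frame with logical columns `ro3`, `lead_like`, `ro5`.
#' @export
apply_gates <- function(profile, thresholds = NULL) {
  th <- if (is.character(thresholds) || is.null(thresholds)) {
    load_gate_thresholds(thresholds)
  } else thresholds
  for (f in c("molar_mass", "logp", "n_hbd", "n_hba", "n_rotb", "psa",
              "n_rings")) {
    if (is.null(profile[[f]])) stop("profile lacks descriptor: ", f)
  }
  data.frame(
    ro3 = profile$molar_mass < th$ro3$max_molar_mass &
      profile$logp <= th$ro3$max_logp &
      profile$n_hbd <= th$ro3$max_n_hbd &
      profile$n_hba <= th$ro3$max_n_hba &
      profile$n_rotb <= th$ro3$max_n_rotb &
      profile$psa <= th$ro3$max_psa,
    lead_like = profile$molar_mass >= th$lead_like$min_molar_mass &
      profile$molar_mass <= th$lead_like$max_molar_mass &
      profile$logp >= th$lead_like$min_logp &
      profile$logp <= th$lead_like$max_logp &
      profile$n_rings <= th$lead_like$max_n_rings &
      profile$n_rotb <= th$lead_like$max_n_rotb,
    ro5 = profile$molar_mass <= th$ro5$max_molar_mass &
      profile$logp <= th$ro5$max_logp &
      profile$n_hbd <= th$ro5$max_n_hbd &
      profile$n_hba <= th$ro5$max_n_hba)
}
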