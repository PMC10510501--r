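# Fingerprints, t-SNE embedding, and novelty ---------------------------------

#' Morgan (ECFP4-type) fingerprints
#'
#' Circular fingerprints of the given radius (radius 2 corresponds to
#' ECFP4) folded to `n_bits`.  Unparseable inputs are skipped with a
#' warning.
#'
#' @param molecules Character vector of SMILES or a `diy_library` (rows are
#'   keyed by InChI).
#' @param radius Circular radius (default 2).
#' @param n_bits Folded length (default 2048).
#' @return A `diy_fingerprints` object: `$keys`, `$bits` (sparse 0/1 matrix,
#'   rows aligned to keys), `$radius`, `$n_bits`.
#' @export
fingerprint <- function(molecules, radius = 2L, n_bits = 2048L) {
  if (inherits(molecules, "diy_library")) {
    smiles <- molecules$smiles; keys <- molecules$inchi
  } else {
    smiles <- molecules; keys <- molecules
  }
  if (!length(smiles)) {
    return(structure(list(keys = character(),
                          bits = Matrix::sparseMatrix(i = integer(),
                                                      j = integer(),
                                                      dims = c(0, n_bits)),
                          radius = radius, n_bits = n_bits),
                     class = "diy_fingerprints"))
  }
  res <- kernel_call("fingerprint", smiles = as.list(smiles),
                     radius = radius, n_bits = n_bits)
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " molecule(s) failed to parse and were skipped")
  }
  on_bits <- lapply(res[ok], function(r) unlist(r$on_bits))
  i <- rep(seq_along(on_bits), lengths(on_bits))
  j <- unlist(on_bits) + 1L    # RDKit bits are 0-based
  bits <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                               dims = c(sum(ok), n_bits))
  structure(list(keys = keys[ok], bits = bits, radius = radius,
                 n_bits = n_bits),
            class = "diy_fingerprints")
}

#' @export
print.diy_fingerprints <- function(x, ...) {
  cat("diy_fingerprints:", length(x$keys), "molecules x", x$n_bits, "bits\n")
  invisible(x)
}

#' Tanimoto similarity between two fingerprint rows
#' @param fps A `diy_fingerprints`.
#' @param i,j Row indices.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fps, i, j) {
  a <- fps$bits[i, ] > 0; b <- fps$bits[j, ] > 0
  den <- sum(a | b)
  if (den == 0) return(1)
  sum(a & b) / den
}

#' t-SNE embedding of a fingerprint set
#'
#' Barnes-Hut t-SNE on the binary fingerprint matrix (Euclidean distances),
#' randomly initialized, deterministic for a fixed seed.  A perplexity too
#' large for the input (n < 3 * perplexity + 1) is auto-reduced with a
#' warning.
#'
#' @param fps A `diy_fingerprints`.
#' @param perplexity t-SNE perplexity (default 70).
#' @param seed Random seed.
#' @param iterations Gradient-descent iterations (default 1000).
#' @return A `diy_embedding`: `$coords` (n x 2), `$keys`, `$params`.
#' @export
embed_tsne <- function(fps, perplexity = 70, seed = 42L, iterations = 1000L) {
  n <- length(fps$keys)
  if (n < 5L) stop("need at least 5 molecules to embed")
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning("perplexity ", perplexity, " too large for n = ", n,
            "; reduced to ", max_perp)
    perplexity <- max_perp
  }
  # embed in key-sorted order so that permuting the input (same seed)
  # permutes the coordinates identically
  ord <- order(fps$keys)
  x <- as.matrix(fps$bits)[ord, , drop = FALSE]
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      max_iter = as.integer(iterations), theta = 0.5,
                      pca = FALSE, check_duplicates = FALSE, num_threads = 1)
  coords <- matrix(NA_real_, nrow(fit$Y), 2)
  coords[ord, ] <- fit$Y
  structure(list(coords = coords, keys = fps$keys,
                 params = list(perplexity = perplexity, seed = seed,
                               iterations = iterations)),
            class = "diy_embedding")
}

#' @export
print.diy_embedding <- function(x, ...) {
  cat("diy_embedding:", length(x$keys), "points (perplexity",
      x$params$perplexity, ", seed", x$params$seed, ")\n")
  invisible(x)
}

#' Seeded per-subset subsampling helper for large-library maps
#'
#' @param keys Character vector of molecule keys.
#' @param labels Subset label per key.
#' @param n_per_subset Sample size per label (kept whole if smaller).
#' @param seed Random seed.
#' @return Integer indices into `keys`.
#' @export
subsample_by_subset <- function(keys, labels, n_per_subset = 1000L,
                                seed = 42L) {
  stopifnot(length(keys) == length(labels))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- unlist(lapply(sort(unique(labels)), function(lab) {
    w <- which(labels == lab)
    if (length(w) > n_per_subset) sort(sample(w, n_per_subset)) else w
  }))
  sort(unique(idx))
}

#' Exact-match novelty check against a reference set
#'
#' Byte-exact InChI membership: a product is novel iff its InChI does not
#' occur in the reference.  Malformed reference lines (not starting with
#' `InChI=`) are skipped with a warning count.
#'
#' @param products A `diy_library` (or data frame with an `inchi` column).
#' @param reference A file of one InChI per line, or a character vector of
#'   InChIs (possibly empty).
#' @return List `novel` (subset of products), `overlap`, and
#'   `novelty_fraction`.
#' @export
novelty_check <- function(products, reference) {
  ref <- if (length(reference) == 1L && !startsWith(reference, "InChI=") &&
             file.exists(reference)) {
    readLines(reference, warn = FALSE)
  } else as.character(reference)
  ref <- trimws(ref)
  ref <- ref[nzchar(ref)]
  malformed <- !startsWith(ref, "InChI=")
  if (any(malformed)) {
    warning(sum(malformed), " malformed reference line(s) skipped")
    ref <- ref[!malformed]
  }
  is_novel <- !(products$inchi %in% ref)
  list(novel = products[is_novel, , drop = FALSE],
       overlap = products[!is_novel, , drop = FALSE],
       novelty_fraction = if (nrow(products)) mean(is_novel) else NA_real_)
}
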