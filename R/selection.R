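# Cost-efficiency-driven building-block selection -----------------------------

incidence_matrix <- function(library, blocks) {
  i <- rep(seq_len(nrow(library)),
           lengths(library$contributing_blocks))
  j <- match(unlist(library$contributing_blocks), blocks$id)
  if (anyNA(j)) stop("library references building blocks absent from the catalog")
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(library), nrow(blocks)),
                       dimnames = list(NULL, blocks$id))
}

#' Reaction score of a building block
#'
#' The number of distinct surviving end-products whose routes use the block,
#' divided by the block's price.  A block appearing twice in one product's
#' route still counts that product once.
#'
#' @param bb_id Building-block id.
#' @param library A `diy_library` (the current surviving product set).
#' @param blocks The catalog.
#' @return Nonnegative numeric score.
#' @export
reaction_score <- function(bb_id, library, blocks) {
  w <- match(bb_id, blocks$id)
  if (is.na(w)) stop("unknown building block id: ", bb_id)
  n <- sum(vapply(library$contributing_blocks, function(cb) bb_id %in% cb,
                  logical(1)))
  n / blocks$price[w]
}

#' Iterative lowest-reaction-score elimination
#'
#' Repeats until the requested number of blocks remains: recompute every
#' surviving block's reaction score on the *current* surviving product set,
#' remove the single lowest-scoring block (ties: the higher-priced block,
#' then the lexicographically greatest id), and drop every product whose
#' contributing blocks include it.  Bookkeeping is incremental (an inverted
#' product-block index with lazy deletion); its results are contractually
#' identical to full recomputation at every iteration.
#'
#' @param blocks The catalog enumerated from.
#' @param library The enumerated `diy_library`.
#' @param target_count Number of blocks to retain (>= 1).
#' @return A `diy_elimination_trace`: `$iterations` (data frame
#'   `removed_id`, `score`, `products_remaining`, `budget_remaining`) and
#'   `$retained` (final id set).
#' @export
eliminate <- function(blocks, library, target_count) {
  if (target_count < 1L) stop("target_count must be >= 1")
  if (target_count > nrow(blocks)) {
    stop("target_count exceeds the number of blocks")
  }
  inc <- incidence_matrix(library, blocks)
  alive_prod <- rep(TRUE, nrow(library))
  alive_blk <- rep(TRUE, nrow(blocks))
  counts <- as.numeric(Matrix::colSums(inc))     # products per block
  budget <- sum(blocks$price)
  ids <- blocks$id
  prices <- blocks$price

  iters <- list()
  while (sum(alive_blk) > target_count) {
    scores <- counts / prices
    scores[!alive_blk] <- Inf
    lo <- min(scores)
    cand <- which(scores == lo)
    if (length(cand) > 1L) {
      cand <- cand[prices[cand] == max(prices[cand])]
      if (length(cand) > 1L) cand <- cand[order(ids[cand], decreasing = TRUE)]
    }
    drop <- cand[1]
    dying <- alive_prod & (inc[, drop] > 0)
    if (any(dying)) {
      # lazy deletion: subtract the dying products' contributions
      counts <- counts - as.numeric(Matrix::colSums(
        inc[dying, , drop = FALSE]))
      alive_prod[dying] <- FALSE
    }
    alive_blk[drop] <- FALSE
    budget <- budget - prices[drop]
    iters[[length(iters) + 1L]] <- data.frame(
      removed_id = ids[drop], score = lo,
      products_remaining = sum(alive_prod),
      budget_remaining = budget, stringsAsFactors = FALSE)
  }
  iterations <- if (length(iters)) {
    do.call(rbind, c(iters, list(make.row.names = FALSE)))
  } else {
    data.frame(removed_id = character(), score = numeric(),
               products_remaining = integer(), budget_remaining = numeric())
  }
  structure(list(iterations = iterations, retained = ids[alive_blk],
                 initial = list(n_blocks = nrow(blocks),
                                n_products = nrow(library),
                                total_price = sum(blocks$price))),
            class = "diy_elimination_trace")
}

#' @export
print.diy_elimination_trace <- function(x, ...) {
  cat("diy_elimination_trace:", nrow(x$iterations), "removals,",
      length(x$retained), "blocks retained\n")
  invisible(x)
}

#' Blocks/products/budget curve of an elimination trace
#'
#' One point per iteration plus the initial state, ordered by descending
#' block count (the direction the elimination walks).
#'
#' @param trace An [eliminate()] result.
#' @param blocks The catalog (unused beyond validation; the trace carries
#'   the bookkeeping).
#' @return Data frame `n_blocks`, `n_products`, `total_price`.
#' @export
budget_curve <- function(trace, blocks = NULL) {
  it <- trace$iterations
  n0 <- trace$initial$n_blocks
  data.frame(
    n_blocks = c(n0, n0 - seq_len(nrow(it))),
    n_products = c(trace$initial$n_products, it$products_remaining),
    total_price = c(trace$initial$total_price, it$budget_remaining))
}

#' Locate the knee of a products-vs-budget curve
#'
#' Both axes are min-max normalized and the knee is taken as the point of
#' maximum deviation of the (lightly smoothed) product curve from the
#' straight chord joining its endpoints.  For a curve with one slope break
#' this deviation peaks exactly at the break -- the discrete-curvature
#' maximum -- and the chord form is far more robust to sampling noise than
#' second differences.  A near-straight curve (no deviation above `eps`) is
#' degenerate: the largest-block-count endpoint is returned with attribute
#' `degenerate = TRUE` and a warning.
#'
#' @param curve A [budget_curve()] data frame with at least 5 points.
#' @param smooth Odd running-mean window applied to the product axis
#'   (1 = none).
#' @param eps Normalized-deviation floor below which the curve counts as
#'   straight.
#' @return The `n_blocks` value at the knee, with attributes `degenerate`
#'   and `deviation` (the normalized chord deviation at the knee).
#' @export
knee_point <- function(curve, smooth = 3L, eps = 1e-3) {
  if (nrow(curve) < 5L) stop("need at least 5 curve points")
  ord <- order(curve$total_price)
  x <- curve$total_price[ord]
  y <- curve$n_products[ord]
  nb <- curve$n_blocks[ord]
  rngx <- diff(range(x)); rngy <- diff(range(y))
  if (rngx == 0 || rngy == 0) {
    warning("flat curve; returning the full-catalog endpoint")
    out <- max(curve$n_blocks)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  x <- (x - min(x)) / rngx
  y <- (y - min(y)) / rngy
  if (smooth > 1L) {
    k <- as.integer(smooth)
    ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]   # endpoints keep their raw values
    y <- ys
  }
  n <- length(x)
  # perpendicular-free chord deviation: the chord of the normalized curve
  # is y = x, so the deviation is |y - x| up to a constant factor
  chord <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  dev <- abs(y - chord)
  if (max(dev) < eps) {
    warning("no curvature detected; returning the full-catalog endpoint")
    out <- max(curve$n_blocks)
    attr(out, "degenerate") <- TRUE
    attr(out, "deviation") <- max(dev)
    return(out)
  }
  best <- which.max(dev)
  out <- nb[best]
  attr(out, "degenerate") <- FALSE
  attr(out, "deviation") <- max(dev)
  out
}
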