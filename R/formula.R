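# Molecular-formula bookkeeping for the mass-balance invariant.
# Formulas are named integer vectors (element -> count).

parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  if (m[1] == -1) stop("cannot parse formula: ", x)
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(parts)) != nchar(x)) stop("cannot parse formula: ", x)
  out <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

formula_from_list <- function(lst) {
  out <- vapply(lst, function(v) as.integer(v), integer(1))
  out[order(names(out))]
}

formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  names(out) <- els
  out[out != 0L][order(names(out[out != 0L]))]
}

formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) - (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  names(out) <- els
  out[out != 0L][order(names(out[out != 0L]))]
}

formula_equal <- function(a, b) {
  a <- a[a != 0L]; b <- b[b != 0L]
  setequal(names(a), names(b)) &&
    all(vapply(names(a), function(e) a[[e]] == b[[e]], logical(1)))
}

format_formula <- function(f) {
  f <- f[f != 0L]
  f <- f[order(names(f))]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}
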