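#' @importFrom jsonlite toJSON fromJSON
#' @importFrom processx process
NULL

# Persistent chemistry worker ------------------------------------------------
#
# All chemistry primitives (SMILES parsing/canonicalisation, InChI, SMARTS
# matching, reaction-SMIRKS application, descriptors, Morgan fingerprints,
# PAINS catalog) are computed by a bundled RDKit worker script that the
# package keeps alive for the whole session and talks to over stdin/stdout
# with one JSON document per line.  Starting the worker costs a couple of
# seconds (RDKit import); each call afterwards is sub-millisecond plus
# payload, so callers batch aggressively.

.kernel <- new.env(parent = emptyenv())

kernel_python <- function() {
  getOption("diylib.python", Sys.getenv("DIYLIB_PYTHON", "python"))
}

kernel_script <- function() {
  path <- system.file("python", "chem_kernel.py", package = "diylib")
  if (!nzchar(path)) stop("bundled chem_kernel.py not found; is diylib installed?")
  path
}

kernel_alive <- function() {
  !is.null(.kernel$proc) && .kernel$proc$is_alive()
}

kernel_start <- function() {
  if (kernel_alive()) return(invisible(.kernel$proc))
  py <- kernel_python()
  proc <- processx::process$new(
    py, c("-u", kernel_script()),
    stdin = "|", stdout = "|", stderr = "|"
  )
  .kernel$proc <- proc
  .kernel$buf <- ""
  # Fail fast if python/rdkit is unusable.
  res <- tryCatch(kernel_call("ping"), error = function(e) e)
  if (inherits(res, "error")) {
    err <- paste(proc$read_error_lines(), collapse = "\n")
    kernel_stop()
    stop("could not start the RDKit chemistry worker (python = '", py, "').\n",
         conditionMessage(res), if (nzchar(err)) paste0("\nworker stderr:\n", err))
  }
  invisible(proc)
}

#' Shut down the background chemistry worker
#'
#' The worker restarts automatically on the next call that needs it; stopping
#' it is only useful to free the Python process.
#' @return Invisibly `TRUE`.
#' @export
kernel_stop <- function() {
  if (!is.null(.kernel$proc)) {
    try(.kernel$proc$kill(), silent = TRUE)
    .kernel$proc <- NULL
    .kernel$buf <- ""
  }
  invisible(TRUE)
}

kernel_read_line <- function(proc, timeout = 600) {
  deadline <- Sys.time() + timeout
  repeat {
    nl <- regexpr("\n", .kernel$buf, fixed = TRUE)
    if (nl > 0) {
      line <- substr(.kernel$buf, 1L, nl - 1L)
      .kernel$buf <- substr(.kernel$buf, nl + 1L, nchar(.kernel$buf))
      return(line)
    }
    if (!proc$is_alive()) {
      err <- paste(proc$read_error_lines(), collapse = "\n")
      stop("chemistry worker died unexpectedly.\n", err)
    }
    proc$poll_io(200)
    chunk <- proc$read_output()
    if (nzchar(chunk)) .kernel$buf <- paste0(.kernel$buf, chunk)
    if (Sys.time() > deadline) stop("timeout waiting for chemistry worker")
  }
}

kernel_call <- function(op, ..., timeout = 600) {
  kernel_start()
  proc <- .kernel$proc
  req <- c(list(op = op), list(...))
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  # large requests exceed the pipe buffer: write in a poll loop
  remaining <- charToRaw(paste0(payload, "\n"))
  while (length(remaining)) {
    remaining <- proc$write_input(remaining)
    if (length(remaining)) {
      if (!proc$is_alive()) stop("chemistry worker died while writing request")
      proc$poll_io(50)
    }
  }
  line <- kernel_read_line(proc, timeout = timeout)
  resp <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) stop("chemistry worker error: ", resp$error)
  resp$result
}

.onUnload <- function(libpath) {
  kernel_stop()
}
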