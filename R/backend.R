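#' @importFrom jsonlite fromJSON
NULL

# Package-level state: memoisation caches for backend calls.  Keys are raw
# input SMILES (canonicalization) or canonical SMILES + parameters
# (fingerprints, fragmentations), so repeated scoring of the same compounds
# across networks/corpora costs one backend round-trip in total.
.molforge <- new.env(parent = emptyenv())
.molforge$props <- new.env(parent = emptyenv())
.molforge$fp <- new.env(parent = emptyenv())
.molforge$brics <- new.env(parent = emptyenv())

#' Path to the Python interpreter used for the RDKit backend
#'
#' The backend defaults to `python` on the `PATH`; override with
#' `options(molforge.python = "/path/to/python")`.
#'
#' @return Character scalar, the interpreter command.
#' @export
backend_python <- function() {
  getOption("molforge.python", "python")
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "molforge")
  if (!nzchar(path)) stop("chem_backend.py not found in the installed package")
  path
}

#' Low-level call into the RDKit batch backend
#'
#' @param cmd Backend subcommand (`"props"`, `"fp"`, `"brics"`, `"pains"`,
#'   `"smarts"`, `"murcko"`, `"sdf"`).
#' @param input Character vector of SMILES fed to stdin (one per line), or
#'   `NULL` for file-based subcommands.
#' @param args Extra command-line arguments.
#' @return A list with one element per input line, in input order.
#' @keywords internal
backend_call <- function(cmd, input = NULL, args = character()) {
  errfile <- tempfile("molforge_backend_err_")
  on.exit(unlink(errfile), add = TRUE)
  out <- suppressWarnings(system2(
    backend_python(),
    c(shQuote(backend_script()), cmd, args),
    input = if (!is.null(input)) input else "",
    stdout = TRUE, stderr = errfile
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    msg <- paste(readLines(errfile, warn = FALSE), collapse = "\n")
    stop("chemistry backend failed (", cmd, "): ", msg, call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# Memoised backend call: `keys` identify each element of `input`; results for
# unseen keys are computed in one batch and stored in `cache`.
backend_cached <- function(cache, keys, input, cmd, args = character()) {
  stopifnot(length(keys) == length(input))
  miss <- !vapply(keys, function(k) !is.null(cache[[k]]), logical(1))
  if (any(miss)) {
    res <- backend_call(cmd, input = input[miss], args = args)
    if (length(res) != sum(miss)) {
      stop("backend returned ", length(res), " records for ", sum(miss), " inputs")
    }
    mk <- keys[miss]
    for (i in seq_along(res)) cache[[mk[i]]] <- res[[i]]
  }
  lapply(keys, function(k) cache[[k]])
}
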