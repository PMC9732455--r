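#' The six fingerprint families
#'
#' Kind names used throughout the package: `PATH` (RDKit path-enumeration
#' topological fingerprint, maxPath 7), `MACCS166` (166 structural keys),
#' `ATOMPAIR`, `TORSION` (topological torsions), `CIRCULAR` (Morgan radius 2)
#' and `CIRCULAR_FEAT` (Morgan radius 2 with pharmacophoric feature atom
#' invariants).  All hashed kinds default to 2048 bits; MACCS166 is fixed at
#' 166 positions.
#'
#' @export
FP_KINDS <- c("PATH", "MACCS166", "ATOMPAIR", "TORSION", "CIRCULAR", "CIRCULAR_FEAT")

new_fingerprint <- function(bits, nbits, kind) {
  structure(as.integer(bits), nbits = as.integer(nbits), kind = kind,
            class = "molforge_fp")
}

#' @export
print.molforge_fp <- function(x, ...) {
  cat("<fingerprint ", attr(x, "kind"), ": ", length(x), "/",
      attr(x, "nbits"), " bits on>\n", sep = "")
  invisible(x)
}

#' Compute fingerprints for a set of molecules
#'
#' @param smiles Character vector of SMILES (canonicalised internally; the
#'   bit vector of a molecule depends only on its canonical form).
#' @param kinds Subset of [FP_KINDS] (default all six).
#' @param nbits Bit length of the hashed kinds; must be a power of two
#'   (default 2048).  Ignored for `MACCS166`.
#' @return A list (one element per input molecule) of named lists of
#'   `molforge_fp` objects, each a sorted integer vector of 0-based on-bit
#'   positions with attributes `nbits` and `kind`.
#' @export
fingerprints <- function(smiles, kinds = FP_KINDS, nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  kinds <- match.arg(kinds, FP_KINDS, several.ok = TRUE)
  if (bitwAnd(nbits, nbits - 1L) != 0L || nbits <= 0L) {
    stop("nbits must be a positive power of two")
  }
  canon <- canonicalize(smiles)
  keys <- paste0(nbits, "|", paste(kinds, collapse = ","), "|", canon)
  res <- backend_cached(.molforge$fp, keys, canon, "fp",
                        c("--kinds", paste(kinds, collapse = ","),
                          "--nbits", nbits))
  lapply(res, function(r) {
    if (!isTRUE(r$ok)) stop("fingerprinting failed: ", r$error)
    out <- lapply(kinds, function(k) {
      f <- r$fps[[k]]
      new_fingerprint(sort(unlist(f$bits)), f$nbits, k)
    })
    names(out) <- kinds
    out
  })
}

#' Compute a single fingerprint
#'
#' @inheritParams fingerprints
#' @param kind One of [FP_KINDS].
#' @return A `molforge_fp` for one molecule (if `smiles` has length 1) or a
#'   list of them.
#' @export
fingerprint <- function(smiles, kind, nbits = 2048L) {
  kind <- match.arg(kind, FP_KINDS)
  out <- lapply(fingerprints(smiles, kinds = kind, nbits = nbits), `[[`, kind)
  if (length(smiles) == 1) out[[1]] else out
}
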