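#' Parse SMILES strings
#'
#' Vectorised SMILES ingestion.  Each input is parsed and canonicalised by the
#' RDKit backend; invalid inputs are flagged rather than raised, which is what
#' batch consumers (network building, generation metrics) need.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strip_salts Keep only the largest covalent fragment (default `FALSE`).
#' @return A tibble with columns `input`, `valid`, `canonical`, `mw`, `logp`,
#'   `n_heavy`, `error`.
#' @export
parse_smiles <- function(smiles, strip_salts = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(tibble::tibble(input = character(), valid = logical(),
                          canonical = character(), mw = numeric(),
                          logp = numeric(), n_heavy = integer(),
                          error = character()))
  }
  args <- if (strip_salts) "--strip-salts" else character()
  keys <- paste0(if (strip_salts) "s|" else "r|", smiles)
  res <- backend_cached(.molforge$props, keys, smiles, "props", args)
  tibble::tibble(
    input = smiles,
    valid = vapply(res, function(r) isTRUE(r$ok), logical(1)),
    canonical = vapply(res, function(r) if (isTRUE(r$ok)) r$canonical else NA_character_, character(1)),
    mw = vapply(res, function(r) if (isTRUE(r$ok)) r$mw else NA_real_, numeric(1)),
    logp = vapply(res, function(r) if (isTRUE(r$ok)) r$logp else NA_real_, numeric(1)),
    n_heavy = vapply(res, function(r) if (isTRUE(r$ok)) as.integer(r$n_heavy) else NA_integer_, integer(1)),
    error = vapply(res, function(r) if (isTRUE(r$ok)) NA_character_ else r$error, character(1))
  )
}

#' Canonicalise SMILES
#'
#' Strict variant of [parse_smiles()]: two inputs describing the same molecule
#' map to the same output string, and any unparseable input is an error that
#' names the offending SMILES.  Canonicalisation is idempotent.
#'
#' @inheritParams parse_smiles
#' @return Character vector of canonical SMILES.
#' @export
canonicalize <- function(smiles, strip_salts = FALSE) {
  p <- parse_smiles(smiles, strip_salts = strip_salts)
  if (any(!p$valid)) {
    bad <- p$input[!p$valid][1]
    stop("invalid SMILES: '", bad, "' (", p$error[!p$valid][1], ")", call. = FALSE)
  }
  p$canonical
}

#' Build molecule records
#'
#' A molecule record is the unit of data exchanged between modules: an opaque
#' id, the input SMILES, its canonical form, and basic computed descriptors
#' (molecular weight in Da, Crippen cLogP).
#'
#' @param id Character vector of identifiers (defaults to `mol1..molN`).
#' @param smiles Character vector of SMILES, same length as `id`.
#' @inheritParams parse_smiles
#' @return A tibble of class `molecule_record` with columns `id`,
#'   `smiles_input`, `smiles_canonical`, `mw`, `logp`.
#' @export
molecule_record <- function(smiles, id = NULL, strip_salts = FALSE) {
  if (is.null(id)) id <- paste0("mol", seq_along(smiles))
  stopifnot(length(id) == length(smiles), !anyDuplicated(id))
  p <- parse_smiles(smiles, strip_salts = strip_salts)
  if (any(!p$valid)) {
    stop("invalid SMILES for id '", id[!p$valid][1], "': '",
         p$input[!p$valid][1], "'", call. = FALSE)
  }
  out <- tibble::tibble(id = as.character(id), smiles_input = p$input,
                        smiles_canonical = p$canonical, mw = p$mw, logp = p$logp)
  class(out) <- c("molecule_record", class(out))
  out
}

#' Read a SMILES file
#'
#' One molecule per line: `SMILES` or `SMILES<TAB>id`.  Lines starting with
#' `#` and blank lines are skipped.
#'
#' @param path File path.
#' @return A tibble with columns `id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  smiles <- vapply(parts, `[[`, character(1), 1)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][[2]] else paste0("mol", i)
  }, character(1))
  tibble::tibble(id = id, smiles = smiles)
}

#' Read molecules from a CSV with `id,smiles` columns
#' @param path File path.
#' @return A tibble with columns `id`, `smiles`.
#' @export
read_molecules_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("CSV must have 'id' and 'smiles' columns")
  }
  tibble::tibble(id = as.character(df$id), smiles = df$smiles)
}

#' Read molecules from an SDF file
#' @param path File path.
#' @return A tibble with columns `id`, `smiles` (SMILES re-generated by the
#'   backend from the connection table; records that fail to parse are dropped
#'   with a warning).
#' @export
read_sdf <- function(path) {
  res <- backend_call("sdf", input = NULL, args = c("--file", shQuote(path)))
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) warning(sum(!ok), " SDF record(s) could not be parsed and were dropped")
  res <- res[ok]
  id <- vapply(res, function(r) r$id, character(1))
  blank <- !nzchar(id)
  id[blank] <- paste0("mol", which(blank))
  tibble::tibble(id = id, smiles = vapply(res, function(r) r$smiles, character(1)))
}

#' Write molecule records to CSV
#'
#' @param mols A `molecule_record` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules_csv <- function(mols, path) {
  utils::write.csv(
    data.frame(id = mols$id, smiles_canonical = mols$smiles_canonical,
               mw = mols$mw, logp = mols$logp),
    path, row.names = FALSE)
  invisible(path)
}
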