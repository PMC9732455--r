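#' Generation-quality metrics
#'
#' MOSES-style evaluation of a sampled SMILES set:
#' * validity: fraction of samples parsing to a molecule;
#' * uniqueness: unique canonical SMILES among valid / number valid;
#' * novelty: unique valid canonical SMILES absent from the training set /
#'   number of unique valid;
#' * internal diversity: 1 - mean pairwise Morgan (CIRCULAR) Tanimoto over
#'   the unique valid molecules (subsampled to `div_cap` for large sets);
#' * scaffold overlap: fraction of unique-valid Bemis-Murcko frameworks also
#'   present in a reference active set (reported only when a reference is
#'   given).
#'
#' Uniqueness and novelty are `NA` when no sample is valid.
#'
#' @param samples Character vector of sampled SMILES (may include invalid).
#' @param training Character vector: the training corpus (canonicalised
#'   internally).
#' @param reference Optional character vector of reference actives for the
#'   scaffold-overlap metric.
#' @param div_cap Max molecules entering the O(n^2) diversity computation.
#' @param seed Seed for the diversity subsample.
#' @return A `generation_report` list with fields `n_sampled`, `validity`,
#'   `uniqueness`, `novelty`, `internal_diversity`, `scaffold_overlap`.
#' @export
evaluate_generation <- function(samples, training, reference = NULL,
                                div_cap = 500L, seed = 1L) {
  stopifnot(length(samples) >= 1)
  p <- parse_smiles(samples)
  n_valid <- sum(p$valid)
  validity <- n_valid / length(samples)
  uniq <- unique(p$canonical[p$valid])
  uniqueness <- if (n_valid > 0) length(uniq) / n_valid else NA_real_
  novelty <- NA_real_
  if (n_valid > 0) {
    train_canon <- unique(parse_smiles(training)$canonical)
    novelty <- sum(!(uniq %in% train_canon)) / length(uniq)
  }
  internal_diversity <- NA_real_
  if (length(uniq) >= 2) {
    set.seed(seed)
    sub <- if (length(uniq) > div_cap) sample(uniq, div_cap) else uniq
    fps <- lapply(fingerprints(sub, kinds = "CIRCULAR"), `[[`, "CIRCULAR")
    sims <- utils::combn(length(fps), 2, function(ij) {
      similarity(fps[[ij[1]]], fps[[ij[2]]], "TANIMOTO")
    })
    internal_diversity <- 1 - mean(sims)
  }
  scaffold_overlap <- NULL
  if (!is.null(reference) && length(uniq) > 0) {
    ref_scaf <- unique(murcko_scaffolds(reference))
    gen_scaf <- murcko_scaffolds(uniq)
    scaffold_overlap <- mean(gen_scaf %in% ref_scaf)
  }
  out <- list(n_sampled = length(samples), validity = validity,
              uniqueness = uniqueness, novelty = novelty,
              internal_diversity = internal_diversity,
              scaffold_overlap = scaffold_overlap)
  class(out) <- "generation_report"
  out
}

#' @export
print.generation_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.3f", v)
  cat("<generation_report: n=", x$n_sampled,
      " validity=", fmt(x$validity),
      " uniqueness=", fmt(x$uniqueness),
      " novelty=", fmt(x$novelty),
      " intdiv=", fmt(x$internal_diversity),
      if (!is.null(x$scaffold_overlap)) paste0(" scaffold_overlap=",
                                               fmt(x$scaffold_overlap)),
      ">\n", sep = "")
  invisible(x)
}

#' Bemis-Murcko scaffolds
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of scaffold SMILES (empty string for acyclic
#'   molecules).
#' @export
murcko_scaffolds <- function(smiles) {
  res <- backend_call("murcko", input = smiles)
  vapply(res, function(r) {
    if (!isTRUE(r$ok)) stop("scaffold computation failed: ", r$error)
    r$scaffold
  }, character(1))
}

#' Write a generation report to JSON
#' @param report A `generation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
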