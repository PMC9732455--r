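#' BRICS fragmentation of one or more molecules
#'
#' Cleaves the synthetically meaningful bonds of each molecule with the BRICS
#' rule set and returns the resulting fragments (canonical SMILES with
#' attachment points normalised to an unlabelled dummy atom `[*]` unless
#' `keep_isotopes = TRUE`) together with the labels of the broken bond types
#' (`"L1-L3"` style, the sorted pair of BRICS link environments).  A molecule
#' with no cleavable bond is returned as its own single fragment.
#'
#' @param smiles Character vector of SMILES.
#' @param cleave_amides Additionally cleave exocyclic amide C-N bonds missed
#'   by the standard rule set (labelled `AMIDE-AMIDE`); default `FALSE`.
#' @param keep_isotopes Keep BRICS link numbers as dummy-atom isotope labels,
#'   giving a finer (smaller, stricter) effective fragment space.
#' @return A list per molecule: `fragments` (character, with multiplicity)
#'   and `bonds` (character, with multiplicity).
#' @export
fragment_molecules <- function(smiles, cleave_amides = FALSE,
                               keep_isotopes = FALSE) {
  if (length(smiles) == 0) return(list())
  canon <- canonicalize(smiles)
  args <- c(if (cleave_amides) "--cleave-amides",
            if (keep_isotopes) "--keep-isotopes")
  keys <- paste0(as.integer(cleave_amides), as.integer(keep_isotopes), "|", canon)
  res <- backend_cached(.molforge$brics, keys, canon, "brics", args)
  lapply(res, function(r) {
    if (!isTRUE(r$ok)) stop("fragmentation failed: ", r$error)
    list(fragments = as.character(unlist(r$fragments)),
         bonds = as.character(unlist(r$bonds)))
  })
}

#' Build a fragment/bond frequency space from a corpus
#'
#' Fragments every corpus molecule the same way candidate compounds are
#' fragmented and tallies fragment and broken-bond-type occurrences.  The
#' space is the reference against which the RAFSF synthetic-feasibility score
#' judges how precedented a compound's retrosynthetic pieces are.
#'
#' @param corpus Character vector of SMILES (>= 1 valid molecule).
#' @inheritParams fragment_molecules
#' @param corpus_id Free-text provenance label stored with the space.
#' @return A `fragment_space`: list with `fragments` (named integer counts),
#'   `bonds` (named integer counts), `corpus_id`, `corpus_size`, `rules`.
#' @export
build_fragment_space <- function(corpus, cleave_amides = FALSE,
                                 keep_isotopes = FALSE, corpus_id = "corpus") {
  stopifnot(length(corpus) >= 1)
  fr <- fragment_molecules(corpus, cleave_amides = cleave_amides,
                           keep_isotopes = keep_isotopes)
  frag_tab <- table(unlist(lapply(fr, `[[`, "fragments")))
  bond_tab <- table(unlist(lapply(fr, `[[`, "bonds")))
  space <- list(
    fragments = stats::setNames(as.integer(frag_tab), names(frag_tab)),
    bonds = stats::setNames(as.integer(bond_tab), names(bond_tab)),
    corpus_id = corpus_id, corpus_size = length(corpus),
    rules = list(cleave_amides = cleave_amides, keep_isotopes = keep_isotopes))
  class(space) <- "fragment_space"
  space
}

#' @export
print.fragment_space <- function(x, ...) {
  cat("<fragment_space: ", length(x$fragments), " fragments (",
      sum(x$fragments), " occurrences), ", length(x$bonds),
      " bond types, corpus '", x$corpus_id, "' n=", x$corpus_size, ">\n",
      sep = "")
  invisible(x)
}

#' Merge fragment spaces
#'
#' Counts of disjoint corpora add elementwise.
#'
#' @param a,b `fragment_space` objects built with identical rules.
#' @return A merged `fragment_space`.
#' @export
merge_fragment_spaces <- function(a, b) {
  stopifnot(inherits(a, "fragment_space"), inherits(b, "fragment_space"),
            identical(a$rules, b$rules))
  add <- function(x, y) {
    keys <- union(names(x), names(y))
    out <- stats::setNames(integer(length(keys)), keys)
    out[names(x)] <- out[names(x)] + x
    out[names(y)] <- out[names(y)] + y
    out
  }
  space <- list(fragments = add(a$fragments, b$fragments),
                bonds = add(a$bonds, b$bonds),
                corpus_id = paste(a$corpus_id, b$corpus_id, sep = "+"),
                corpus_size = a$corpus_size + b$corpus_size,
                rules = a$rules)
  class(space) <- "fragment_space"
  space
}

rafsf_penalty <- function(count, cmax) {
  ifelse(is.na(count) | count < 1, 1,
         1 - log10(1 + count) / log10(1 + cmax))
}

#' RAFSF synthetic-feasibility score
#'
#' Retrosynthesis-associated fragment-based synthetic feasibility.  Each
#' compound is BRICS-fragmented with the rules of the space; every fragment
#' and broken bond type receives a penalty
#' \deqn{p = 1 - \log_{10}(1 + n) / \log_{10}(1 + C_{max})}
#' where `n` is its occurrence count in the space and `Cmax` the maximum
#' count of its table (fragment or bond), with `p = 1` for pieces absent from
#' the space.  The score is `1 + 9 * max(p)`: a compound is only as
#' synthesizable as its least precedented piece, so the score is 1 (highly
#' feasible) only when every piece attains the space maximum, and 10 (highly
#' unfeasible) exactly when some piece is absent.
#'
#' @param smiles Character vector of SMILES.
#' @param space A [build_fragment_space()] result.
#' @param aggregate Penalty aggregation over a compound's pieces: `"max"`
#'   (default, the documented score) or `"mean"` (pluggable alternative).
#' @return A tibble with `smiles`, `score`, `rarest_piece`,
#'   `rarest_count` (`NA` when absent), and a `detail` list-column of
#'   per-piece tibbles (`piece`, `type`, `count`, `penalty`).
#' @export
rafsf_score <- function(smiles, space, aggregate = c("max", "mean")) {
  stopifnot(inherits(space, "fragment_space"))
  if (length(space$fragments) == 0) stop("empty fragment space")
  aggregate <- match.arg(aggregate)
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(), score = numeric(),
                          rarest_piece = character(),
                          rarest_count = integer(), detail = list()))
  }
  fr <- fragment_molecules(smiles, cleave_amides = space$rules$cleave_amides,
                           keep_isotopes = space$rules$keep_isotopes)
  cmax_f <- max(space$fragments)
  cmax_b <- if (length(space$bonds)) max(space$bonds) else 1L
  rows <- lapply(seq_along(smiles), function(i) {
    f <- fr[[i]]
    piece <- c(f$fragments, f$bonds)
    type <- c(rep("fragment", length(f$fragments)), rep("bond", length(f$bonds)))
    count <- ifelse(type == "fragment",
                    unname(space$fragments[piece]), unname(space$bonds[piece]))
    cmax <- ifelse(type == "fragment", cmax_f, cmax_b)
    penalty <- rafsf_penalty(count, cmax)
    agg <- if (aggregate == "max") max(penalty) else mean(penalty)
    worst <- which.max(penalty)
    tibble::tibble(smiles = smiles[i], score = 1 + 9 * agg,
                   rarest_piece = piece[worst], rarest_count = count[worst],
                   detail = list(tibble::tibble(piece = piece, type = type,
                                                count = count,
                                                penalty = penalty)))
  })
  do.call(rbind, rows)
}

#' Write / read a fragment space file
#'
#' Versioned tab-separated text: a commented header recording provenance and
#' the exact fragmentation rules (so spaces are self-describing), a
#' `fragment<TAB>count` section, a `#BOND` marker, then `bond<TAB>count`
#' lines.  Round-trips losslessly.
#'
#' @param space A `fragment_space`.
#' @param path File path.
#' @return `path` (write) or the restored `fragment_space` (read).
#' @export
write_fragment_space <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#RAFSF-SPACE v1",
    paste0("#corpus_id\t", space$corpus_id),
    paste0("#corpus_size\t", space$corpus_size),
    paste0("#cleave_amides\t", space$rules$cleave_amides),
    paste0("#keep_isotopes\t", space$rules$keep_isotopes)), con)
  writeLines(paste(names(space$fragments), space$fragments, sep = "\t"), con)
  writeLines("#BOND", con)
  writeLines(paste(names(space$bonds), space$bonds, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_fragment_space
#' @export
read_fragment_space <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "#RAFSF-SPACE v1") {
    stop("not a RAFSF space file: ", path)
  }
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, "\t"), lines, value = TRUE)[1]
    strsplit(ln, "\t")[[1]][2]
  }
  bond_at <- which(lines == "#BOND")[1]
  body <- function(lns) {
    lns <- lns[nzchar(lns) & !startsWith(lns, "#")]
    if (!length(lns)) return(stats::setNames(integer(0), character(0)))
    parts <- strsplit(lns, "\t")
    stats::setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                    vapply(parts, `[[`, character(1), 1))
  }
  bond_lines <- if (bond_at < length(lines)) {
    lines[(bond_at + 1):length(lines)]
  } else character(0)
  space <- list(fragments = body(lines[seq_len(bond_at - 1)]),
                bonds = body(bond_lines),
                corpus_id = hdr("corpus_id"),
                corpus_size = as.integer(hdr("corpus_size")),
                rules = list(cleave_amides = as.logical(hdr("cleave_amides")),
                             keep_isotopes = as.logical(hdr("keep_isotopes"))))
  class(space) <- "fragment_space"
  space
}
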