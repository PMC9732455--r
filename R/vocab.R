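TOKEN_REGEX <- "\\[[^\\]]+\\]|Br|Cl|%[0-9]{2}|."

#' Tokenise SMILES strings
#'
#' Character-level tokenisation with multi-character tokens for two-letter
#' elements (`Cl`, `Br`), bracket atoms (`[nH]`, `[O-]`, ...) and two-digit
#' ring-closure labels (`%10`).  Tokenising then concatenating reproduces the
#' input string exactly.
#'
#' @param smiles Character vector.
#' @return List of character vectors, one per input.
#' @export
tokenize_smiles <- function(smiles) {
  regmatches(smiles, gregexpr(TOKEN_REGEX, smiles, perl = TRUE))
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary covers every token occurring in the corpus plus the three
#' specials `<PAD>`, `<BEGIN>`, `<END>`; corpus tokens are sorted so the
#' ordering is deterministic.
#'
#' @param corpus Character vector of (canonical) SMILES.
#' @return A `smiles_vocabulary`: list with `tokens`, `pad`, `begin`, `end`
#'   (integer ids).
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) >= 1)
  toks <- sort(unique(unlist(tokenize_smiles(corpus))))
  vocab <- list(tokens = c("<PAD>", "<BEGIN>", "<END>", toks),
                pad = 1L, begin = 2L, end = 3L)
  class(vocab) <- "smiles_vocabulary"
  vocab
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("<smiles_vocabulary: ", length(x$tokens), " tokens>\n", sep = "")
  invisible(x)
}

#' Encode SMILES as token-id sequences
#'
#' @param vocab A [build_vocabulary()] result.
#' @param smiles Character vector.
#' @param add_specials Wrap each sequence in `<BEGIN>`/`<END>` ids (default
#'   `TRUE`, the form the language model trains on).
#' @return List of integer vectors.  A token absent from the vocabulary is an
#'   error naming the token.
#' @export
encode_smiles <- function(vocab, smiles, add_specials = TRUE) {
  idx <- stats::setNames(seq_along(vocab$tokens), vocab$tokens)
  lapply(tokenize_smiles(smiles), function(tk) {
    ids <- idx[tk]
    if (anyNA(ids)) {
      stop("token not in vocabulary: '", tk[is.na(ids)][1], "'", call. = FALSE)
    }
    ids <- unname(ids)
    if (add_specials) c(vocab$begin, ids, vocab$end) else ids
  })
}

#' Decode token-id sequences back to SMILES
#'
#' Specials are dropped; decoding stops at the first `<END>`.
#'
#' @param vocab A `smiles_vocabulary`.
#' @param ids List of integer vectors (or a single vector).
#' @return Character vector.
#' @export
decode_smiles <- function(vocab, ids) {
  if (!is.list(ids)) ids <- list(ids)
  vapply(ids, function(v) {
    stop_at <- which(v == vocab$end)
    if (length(stop_at)) v <- v[seq_len(stop_at[1] - 1)]
    v <- v[v != vocab$pad & v != vocab$begin]
    paste(vocab$tokens[v], collapse = "")
  }, character(1))
}
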