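#' The six bit-vector similarity measures
#'
#' Names accepted by [similarity()]: Tanimoto, Dice, Sokal, Cosine,
#' Kulczynski and McConnaughey.
#'
#' With `a` = number of on-bits in the first vector, `b` = on-bits in the
#' second, and `c` = common on-bits:
#' \deqn{T = c/(a+b-c),\quad D = 2c/(a+b),\quad Cos = c/\sqrt{ab},}
#' \deqn{S = c/(2a+2b-3c),\quad K = c(a+b)/(2ab),\quad M = (c(a+b)-ab)/(ab).}
#' The first five lie in \[0, 1\]; McConnaughey lies in \[-1, 1\] and equals 1
#' at self-similarity and -1 for disjoint sets.
#'
#' Conventions for degenerate vectors: if either vector has no on-bits the
#' first five measures return 0 (avoids NaN propagation in batch scoring);
#' McConnaughey, whose denominator `ab` vanishes, is an error.
#'
#' @export
SIM_MEASURES <- c("TANIMOTO", "DICE", "SOKAL", "COSINE", "KULCZYNSKI", "MCCONNAUGHEY")

sim_abc <- function(a, b, c, measure) {
  switch(measure,
    TANIMOTO = if (a + b - c == 0) 0 else c / (a + b - c),
    DICE = if (a + b == 0) 0 else 2 * c / (a + b),
    COSINE = if (a * b == 0) 0 else c / sqrt(a * b),
    SOKAL = if (2 * a + 2 * b - 3 * c == 0) 0 else c / (2 * a + 2 * b - 3 * c),
    KULCZYNSKI = if (a * b == 0) 0 else c * (a + b) / (2 * a * b),
    MCCONNAUGHEY = {
      if (a * b == 0) {
        stop("McConnaughey similarity is undefined for an empty bit vector",
             call. = FALSE)
      }
      (c * (a + b) - a * b) / (a * b)
    },
    stop("unknown similarity measure: ", measure))
}

check_pair <- function(fpA, fpB) {
  if (!identical(attr(fpA, "nbits"), attr(fpB, "nbits"))) {
    stop("fingerprint length mismatch: ", attr(fpA, "nbits"), " vs ",
         attr(fpB, "nbits"), call. = FALSE)
  }
}

#' Bit-vector similarity between two fingerprints
#'
#' @param fpA,fpB `molforge_fp` objects (or plain integer vectors of on-bit
#'   positions with an `nbits` attribute) of equal length.
#' @param measure One of [SIM_MEASURES] (case-insensitive).
#' @return A number; range \[0,1\] for the first five measures, \[-1,1\] for
#'   McConnaughey.  Symmetric in its arguments.
#' @export
similarity <- function(fpA, fpB, measure = "TANIMOTO") {
  measure <- match.arg(toupper(measure), SIM_MEASURES)
  check_pair(fpA, fpB)
  a <- length(fpA)
  b <- length(fpB)
  c <- length(intersect(as.integer(fpA), as.integer(fpB)))
  sim_abc(a, b, c, measure)
}

#' All six similarity measures for one fingerprint pair
#'
#' @inheritParams similarity
#' @param strict With `strict = FALSE`, an undefined McConnaughey value
#'   (either vector empty) is reported as 0 instead of an error — the
#'   convention used in batch network scoring, where tiny molecules can have
#'   empty torsion or atom-pair fingerprints.
#' @return Named numeric vector over [SIM_MEASURES].
#' @export
similarity_all <- function(fpA, fpB, strict = TRUE) {
  check_pair(fpA, fpB)
  a <- length(fpA)
  b <- length(fpB)
  c <- length(intersect(as.integer(fpA), as.integer(fpB)))
  vapply(SIM_MEASURES, function(m) {
    if (!strict && m == "MCCONNAUGHEY" && a * b == 0) return(0)
    sim_abc(a, b, c, m)
  }, numeric(1))
}
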