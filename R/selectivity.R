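#' Rescale raw docking scores to the unit interval
#'
#' Min-max rescaling of a kinase panel's raw docking scores (kcal/mol):
#' `(x - min) / (max - min)`, so the most favourable (lowest) raw score maps
#' to 0 and the least favourable to 1, preserving order.  Rescaling is the
#' pluggable "strategy" step ahead of the selectivity score; min-max is the
#' default and only shipped strategy.
#'
#' @param raw Numeric vector of raw scores, length >= 2 with >= 2 distinct
#'   values (a flat panel is a degenerate-panel error).
#' @return Numeric vector in \[0, 1\].
#' @export
rescale_scores <- function(raw) {
  stopifnot(is.numeric(raw))
  if (length(raw) < 2) stop("panel must contain at least 2 scores")
  if (any(!is.finite(raw))) stop("non-finite docking score")
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    stop("degenerate panel: all raw scores identical", call. = FALSE)
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Kinase-panel selectivity score
#'
#' Fraction of panel kinases whose rescaled docking score falls strictly
#' below the threshold:
#' \deqn{S = |\{k : s_k < 0.5\}| / N.}
#' A score exactly at the threshold is not counted ("less than").  Lower `S`
#' means the compound docks favourably against fewer off-target kinases,
#' i.e. a more selective profile.
#'
#' @param rescaled Numeric vector of rescaled scores in \[0, 1\] (see
#'   [rescale_scores()]), one per panel kinase.
#' @param threshold Strict cutoff (default 0.5).
#' @return List with `S`, `n_below`, `panel_size`.
#' @export
selectivity_score <- function(rescaled, threshold = 0.5) {
  if (length(rescaled) == 0) stop("empty kinase panel")
  stopifnot(is.numeric(rescaled), all(is.finite(rescaled)))
  n_below <- sum(rescaled < threshold)
  list(S = n_below / length(rescaled), n_below = n_below,
       panel_size = length(rescaled))
}

#' Read a kinase-panel docking table
#'
#' CSV with columns `kinase_id`, `raw_score` (kcal/mol), one row per panel
#' kinase for one compound.
#'
#' @param path File path.
#' @return Tibble `kinase_id`, `raw_score`.
#' @export
read_dock_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("kinase_id", "raw_score") %in% names(df))) {
    stop("panel CSV needs 'kinase_id' and 'raw_score' columns")
  }
  tibble::tibble(kinase_id = as.character(df$kinase_id),
                 raw_score = as.numeric(df$raw_score))
}

#' Selectivity analysis of one panel table
#'
#' Rescales the raw panel and computes the selectivity score.
#'
#' @param panel Tibble from [read_dock_panel()] (or any data frame with
#'   `kinase_id`, `raw_score`).
#' @param threshold Strict cutoff (default 0.5).
#' @return List with `S`, `n_below`, `panel_size` and the annotated `table`
#'   (tibble with `rescaled` and `below_threshold` columns).
#' @export
panel_selectivity <- function(panel, threshold = 0.5) {
  rescaled <- rescale_scores(panel$raw_score)
  s <- selectivity_score(rescaled, threshold)
  s$table <- tibble::tibble(kinase_id = panel$kinase_id,
                            raw_score = panel$raw_score, rescaled = rescaled,
                            below_threshold = rescaled < threshold)
  s
}
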