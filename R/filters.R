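#' Property-window filter
#'
#' Lead-likeness windows on molecular weight and cLogP.  Both intervals are
#' closed: a value exactly at a bound passes.  The default windows
#' (MW 200-600 Da, cLogP -1..6) are configuration choices bracketing typical
#' kinase-inhibitor chemistry, not constants of the method.
#'
#' @param smiles Character vector of SMILES.
#' @param mw_range,logp_range Numeric `c(min, max)` windows.
#' @return Tibble `smiles`, `pass`, `violations` (comma-separated property
#'   names, empty when passing).
#' @export
property_filter <- function(smiles, mw_range = c(200, 600),
                            logp_range = c(-1, 6)) {
  p <- parse_smiles(smiles)
  if (any(!p$valid)) stop("invalid SMILES: '", p$input[!p$valid][1], "'")
  mw_ok <- p$mw >= mw_range[1] & p$mw <= mw_range[2]
  lp_ok <- p$logp >= logp_range[1] & p$logp <= logp_range[2]
  violations <- mapply(function(m, l) {
    paste(c(if (!m) "mw", if (!l) "logp"), collapse = ",")
  }, mw_ok, lp_ok)
  tibble::tibble(smiles = smiles, pass = mw_ok & lp_ok,
                 violations = unname(violations))
}

#' Structural-alert (PAINS) filter
#'
#' Flags molecules matching pan-assay interference (PAINS) or user-supplied
#' structural-alert substructures.  The default alert set is the public
#' PAINS A/B/C collection as distributed with RDKit's filter catalog; a
#' custom set is a text file of `name<TAB>SMARTS` lines (uncompilable
#' patterns are a configuration error naming the pattern).
#'
#' @param smiles Character vector of SMILES.
#' @param alert_file Optional path to a named-SMARTS alert file; `NULL`
#'   (default) uses the PAINS catalog.
#' @return Tibble `smiles`, `pass` (no alert matched), `alerts`
#'   (comma-separated matched alert names).
#' @export
alert_filter <- function(smiles, alert_file = NULL) {
  canon <- canonicalize(smiles)
  res <- if (is.null(alert_file)) {
    backend_call("pains", input = canon)
  } else {
    backend_call("smarts", input = canon, args = c("--file", shQuote(alert_file)))
  }
  alerts <- vapply(res, function(r) {
    if (!isTRUE(r$ok)) stop("alert matching failed: ", r$error)
    paste(unlist(r$alerts), collapse = ",")
  }, character(1))
  tibble::tibble(smiles = smiles, pass = !nzchar(alerts), alerts = alerts)
}

#' Novelty filter against known actives
#'
#' A molecule fails when its canonical SMILES is already present in the
#' reference active set.  An empty reference passes everything.
#'
#' @param smiles Character vector of SMILES.
#' @param reference Character vector of reference actives.
#' @return Tibble `smiles`, `pass`.
#' @export
novelty_filter <- function(smiles, reference) {
  canon <- canonicalize(smiles)
  ref <- if (length(reference)) unique(canonicalize(reference)) else character(0)
  tibble::tibble(smiles = smiles, pass = !(canon %in% ref))
}

#' A toxicity plug-in that accepts everything
#'
#' The triage funnel exposes a plug-in contract for external toxicity
#' predictors: a function mapping a character vector of SMILES to a tibble
#' with columns `pass` (logical) and `score` (numeric or `NA`).  This null
#' plug-in passes every compound, keeping the funnel's shape intact when no
#' predictor is available.
#'
#' @param smiles Character vector of SMILES.
#' @return Tibble `pass`, `score`.
#' @export
null_toxicity_plugin <- function(smiles) {
  tibble::tibble(pass = rep(TRUE, length(smiles)),
                 score = rep(NA_real_, length(smiles)))
}

#' Apply the lead-like triage funnel
#'
#' Runs the enabled filters over a hit set and combines them conjunctively:
#' a compound survives only if it passes every enabled filter.  Disabled
#' filters are recorded as `NA` (not evaluated), never as passes.
#' Re-applying the funnel to its own survivors changes nothing.
#'
#' @param smiles Character vector of hit SMILES (must all parse).
#' @param filters Character subset of
#'   `c("property", "alerts", "novelty", "feasibility", "toxicity")` to
#'   enable.
#' @param space A `fragment_space` (required when `"feasibility"` enabled).
#' @param reference Reference actives (required when `"novelty"` enabled).
#' @param rafsf_threshold Feasibility cutoff: pass iff RAFSF score <= this
#'   value (default 6.0, a configuration choice).
#' @param mw_range,logp_range Property windows, see [property_filter()].
#' @param alert_file Optional custom alert file, see [alert_filter()].
#' @param toxicity_plugins Named list of plug-in functions (see
#'   [null_toxicity_plugin()]); all must pass.
#' @return A `funnel_verdicts` tibble, one row per input in input order:
#'   `id`, `smiles`, one logical column per filter (`NA` = not evaluated),
#'   `pass` (overall), `reasons`.
#' @export
apply_funnel <- function(smiles,
                         filters = c("property", "alerts", "novelty",
                                     "feasibility", "toxicity"),
                         space = NULL, reference = NULL,
                         rafsf_threshold = 6.0,
                         mw_range = c(200, 600), logp_range = c(-1, 6),
                         alert_file = NULL,
                         toxicity_plugins = list(null = null_toxicity_plugin)) {
  if (length(filters)) {
    filters <- match.arg(filters, c("property", "alerts", "novelty",
                                    "feasibility", "toxicity"),
                         several.ok = TRUE)
  }
  n <- length(smiles)
  na <- rep(NA, n)
  verdict <- tibble::tibble(id = paste0("hit", seq_len(n)), smiles = smiles,
                            property = na, alerts = na, novelty = na,
                            feasibility = na, toxicity = na)
  reasons <- rep("", n)
  add_reason <- function(reasons, fail, what) {
    ifelse(fail, ifelse(nzchar(reasons), paste(reasons, what, sep = "; "),
                        what), reasons)
  }
  if ("property" %in% filters) {
    pf <- property_filter(smiles, mw_range, logp_range)
    verdict$property <- pf$pass
    reasons <- add_reason(reasons, !pf$pass,
                          paste0("property:", pf$violations))
  }
  if ("alerts" %in% filters) {
    af <- alert_filter(smiles, alert_file)
    verdict$alerts <- af$pass
    reasons <- add_reason(reasons, !af$pass, paste0("alerts:", af$alerts))
  }
  if ("novelty" %in% filters) {
    if (is.null(reference)) stop("novelty filter enabled but no reference set")
    nf <- novelty_filter(smiles, reference)
    verdict$novelty <- nf$pass
    reasons <- add_reason(reasons, !nf$pass, "novelty:known active")
  }
  if ("feasibility" %in% filters) {
    if (is.null(space)) stop("feasibility filter enabled but no fragment space")
    rs <- rafsf_score(smiles, space)
    verdict$feasibility <- rs$score <= rafsf_threshold
    reasons <- add_reason(reasons, !verdict$feasibility,
                          paste0("feasibility:RAFSF=", round(rs$score, 2)))
  }
  if ("toxicity" %in% filters) {
    tox_pass <- rep(TRUE, n)
    for (nm in names(toxicity_plugins)) {
      tp <- toxicity_plugins[[nm]](smiles)
      tox_pass <- tox_pass & tp$pass
      reasons <- add_reason(reasons, !tp$pass, paste0("toxicity:", nm))
    }
    verdict$toxicity <- tox_pass
  }
  verdict$pass <- if (length(filters)) {
    apply(as.matrix(verdict[, filters, drop = FALSE]), 1, all)
  } else rep(TRUE, n)
  verdict$reasons <- reasons
  class(verdict) <- c("funnel_verdicts", class(verdict))
  verdict
}

#' Survivors of a funnel run
#' @param verdicts An [apply_funnel()] result.
#' @return Character vector of surviving SMILES, in input order.
#' @export
funnel_survivors <- function(verdicts) {
  verdicts$smiles[verdicts$pass]
}

#' Write funnel verdicts to CSV
#' @param verdicts An [apply_funnel()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  utils::write.csv(as.data.frame(verdicts), path, row.names = FALSE)
  invisible(path)
}
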