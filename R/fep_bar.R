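#' Work samples for one alchemical window
#'
#' Bundles the potential-energy-difference samples of a pair of neighbouring
#' lambda ensembles: `forward` holds samples of `dU_ij = U_j - U_i` evaluated
#' in ensemble i, `backward` the same quantity evaluated in ensemble j, and
#' `beta` the reciprocal thermodynamic temperature `1/kT` in 1/(kcal/mol)
#' (about 1.688 at 300 K).
#'
#' @param forward,backward Non-empty numeric vectors of finite energies
#'   (kcal/mol).
#' @param beta Positive scalar.
#' @return A `work_samples` object.
#' @export
work_samples <- function(forward, backward, beta = 1.688) {
  stopifnot(length(forward) >= 1, length(backward) >= 1, beta > 0,
            all(is.finite(forward)), all(is.finite(backward)))
  structure(list(forward = as.numeric(forward),
                 backward = as.numeric(backward), beta = beta),
            class = "work_samples")
}

#' @export
print.work_samples <- function(x, ...) {
  cat("<work_samples: ", length(x$forward), " forward / ",
      length(x$backward), " backward, beta=", x$beta, ">\n", sep = "")
  invisible(x)
}

bar_residual <- function(dG, w) {
  # Increasing in dG: LHS - RHS of the BAR self-consistency condition.
  mean(1 / (1 + exp(w$beta * (w$forward - dG)))) -
    mean(1 / (1 + exp(w$beta * (-w$backward + dG))))
}

#' Solve the BAR self-consistency equation for one window
#'
#' The Bennett acceptance ratio estimate of the free-energy difference
#' between two ensembles is the unique root of
#' \deqn{\langle f(\beta(\Delta U - \Delta G))\rangle_i =
#'       \langle f(\beta(-\Delta U + \Delta G))\rangle_j,\qquad
#'       f(x) = 1/(1+e^{x}),}
#' which is monotone in \eqn{\Delta G}; it is found by bracketing and
#' Brent root-finding.  Swapping the two ensembles exactly negates the
#' estimate, and scaling all energies together with `1/beta` rescales it.
#'
#' @param samples A [work_samples()] object.
#' @param tolerance Root tolerance in kcal/mol (default 1e-8).
#' @param bracket Half-width of the search interval (default 1e3 kcal/mol);
#'   distributions so far apart that no sign change exists inside it raise a
#'   no-overlap error suggesting more windows.
#' @return List with `dG` (kcal/mol), `residual` at the root, `se`
#'   (asymptotic standard error, see [bar_uncertainty()]), `n_forward`,
#'   `n_backward`.
#' @export
bar_solve <- function(samples, tolerance = 1e-8, bracket = 1e3) {
  stopifnot(inherits(samples, "work_samples"), tolerance > 0)
  lo <- bar_residual(-bracket, samples)
  hi <- bar_residual(bracket, samples)
  if (!(lo < 0 && hi > 0)) {
    stop("no BAR solution within +/-", bracket, " kcal/mol: the two ",
         "ensembles do not overlap; add intermediate lambda windows",
         call. = FALSE)
  }
  root <- stats::uniroot(bar_residual, c(-bracket, bracket), w = samples,
                         tol = tolerance, maxiter = 2000)
  dG <- root$root
  list(dG = dG, residual = bar_residual(dG, samples),
       se = bar_se_analytic(dG, samples),
       n_forward = length(samples$forward),
       n_backward = length(samples$backward))
}

# Bennett's asymptotic variance: relative fluctuation of the Fermi weights
# in each ensemble, added over the two ensembles.
bar_se_analytic <- function(dG, w) {
  ff <- 1 / (1 + exp(w$beta * (w$forward - dG)))
  fb <- 1 / (1 + exp(w$beta * (-w$backward + dG)))
  rel_var <- function(x) (mean(x^2) / mean(x)^2 - 1) / length(x)
  sqrt(rel_var(ff) + rel_var(fb)) / w$beta
}

#' Statistical uncertainty of a BAR estimate
#'
#' `method = "analytic"` evaluates Bennett's asymptotic variance at the
#' solution (cheap, assumes uncorrelated samples).  `method = "bootstrap"`
#' performs a seeded block bootstrap over both sample sets, which is robust
#' to residual time correlation in MD-derived samples.
#'
#' @param samples A [work_samples()] object.
#' @param method `"analytic"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 200).
#' @param block Block length for the block bootstrap (default 10 samples).
#' @param seed Seed for the bootstrap.
#' @return Standard error of the window's dG, in kcal/mol.
#' @export
bar_uncertainty <- function(samples, method = c("analytic", "bootstrap"),
                            n_boot = 200L, block = 10L, seed = 1L) {
  method <- match.arg(method)
  if (method == "analytic") {
    return(bar_solve(samples)$se)
  }
  set.seed(seed)
  resample_blocks <- function(x) {
    n <- length(x)
    nb <- ceiling(n / block)
    starts <- sample.int(max(n - block + 1, 1), nb, replace = TRUE)
    idx <- as.vector(outer(0:(block - 1), starts, `+`))
    x[idx[idx <= n * block][seq_len(n)] %% n + 1]
  }
  est <- vapply(seq_len(n_boot), function(i) {
    w <- work_samples(resample_blocks(samples$forward),
                      resample_blocks(samples$backward), samples$beta)
    bar_solve(w)$dG
  }, numeric(1))
  stats::sd(est)
}

#' Default lambda schedules for the two-leg decoupling
#'
#' Electrostatic interactions are switched off first over uniformly spaced
#' lambda points, then van der Waals interactions over a nonuniform list
#' refined near the endpoint.  Each simulated lambda point is one window;
#' adjacent points form the BAR pairs, so the default schedule has
#' 5 + 16 = 21 windows and 4 + 15 = 19 BAR pairs per leg.
#'
#' @param elec Electrostatic lambda points (start 0, end 1, increasing).
#' @param vdw Van der Waals lambda points (start 0, end 1, increasing).
#' @return A `lambda_schedule` list with `elec`, `vdw`, `n_windows`,
#'   `n_pairs`.
#' @export
lambda_schedule <- function(elec = c(0, 0.25, 0.5, 0.75, 1.0),
                            vdw = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                                    0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95,
                                    1.0)) {
  check <- function(x, nm) {
    if (x[1] != 0 || x[length(x)] != 1 || any(diff(x) <= 0)) {
      stop(nm, " lambda list must start at 0, end at 1, strictly increasing")
    }
  }
  check(elec, "electrostatic")
  check(vdw, "van der Waals")
  structure(list(elec = elec, vdw = vdw,
                 n_windows = length(elec) + length(vdw),
                 n_pairs = (length(elec) - 1L) + (length(vdw) - 1L)),
            class = "lambda_schedule")
}

#' Chain per-window BAR estimates into a leg total
#'
#' A decoupling leg's free energy is the sum of its window free-energy
#' differences.  Any window whose BAR solve fails marks the leg invalid with
#' the failing window's index.
#'
#' @param windows List of [work_samples()] in schedule order.
#' @param schedule Optional [lambda_schedule()]; when given, the number of
#'   windows must equal `schedule$n_pairs`.
#' @param tolerance Per-window root tolerance.
#' @return List with `total` (kcal/mol, `NA` if invalid), `per_window`
#'   (tibble `window`, `dG`, `se`), `valid`, `failed_window`.
#' @export
chain_windows <- function(windows, schedule = NULL, tolerance = 1e-8) {
  stopifnot(length(windows) >= 1)
  if (!is.null(schedule) && length(windows) != schedule$n_pairs) {
    stop("expected ", schedule$n_pairs, " window pair(s) for this schedule, ",
         "got ", length(windows))
  }
  dG <- rep(NA_real_, length(windows))
  se <- rep(NA_real_, length(windows))
  failed <- NA_integer_
  for (i in seq_along(windows)) {
    res <- tryCatch(bar_solve(windows[[i]], tolerance = tolerance),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- i
      break
    }
    dG[i] <- res$dG
    se[i] <- res$se
  }
  valid <- is.na(failed)
  list(total = if (valid) sum(dG) else NA_real_,
       per_window = tibble::tibble(window = seq_along(windows), dG = dG,
                                   se = se),
       valid = valid, failed_window = failed)
}

#' Two-leg binding free-energy ledger
#'
#' Combines the complex-decoupling and water-decoupling legs into a binding
#' free energy.  Sign convention (stated in the output): each leg total is
#' the free energy of switching the ligand's interactions off in that
#' environment, and
#' `dG_bind = dG_water_leg - dG_complex_leg`,
#' so a ligand held more strongly by the protein than by water gives a
#' negative (favourable) binding free energy.  `restraint_correction`
#' (kcal/mol) is added to `dG_bind` as supplied; no correction is guessed.
#'
#' @param complex_windows,water_windows Lists of [work_samples()] per leg.
#' @param schedule Optional [lambda_schedule()] applied to both legs.
#' @param restraint_correction Additive manual correction, default 0.
#' @return A `binding_ledger`: list with `dG_bind`, `complex_leg`,
#'   `water_leg` (each a [chain_windows()] result), `restraint_correction`,
#'   `sign_convention`.
#' @export
binding_free_energy <- function(complex_windows, water_windows,
                                schedule = NULL, restraint_correction = 0) {
  cl <- chain_windows(complex_windows, schedule)
  wl <- chain_windows(water_windows, schedule)
  out <- list(
    dG_bind = if (cl$valid && wl$valid) {
      wl$total - cl$total + restraint_correction
    } else NA_real_,
    complex_leg = cl, water_leg = wl,
    restraint_correction = restraint_correction,
    sign_convention = "dG_bind = dG_decouple(water) - dG_decouple(complex); negative favours binding")
  class(out) <- "binding_ledger"
  out
}

#' @export
print.binding_ledger <- function(x, ...) {
  cat("<binding_ledger: dG_bind = ",
      if (is.na(x$dG_bind)) "invalid" else sprintf("%.3f kcal/mol", x$dG_bind),
      ">\n  ", x$sign_convention, "\n", sep = "")
  invisible(x)
}

#' Read one window's samples from a two-column text file
#'
#' Whitespace-separated lines `label value` with label `fwd` or `bwd`
#' (lines starting with `#` ignored).
#'
#' @param path File path.
#' @param beta Reciprocal temperature passed to [work_samples()].
#' @return A `work_samples` object.
#' @export
read_work_samples <- function(path, beta = 1.688) {
  df <- utils::read.table(path, col.names = c("label", "dU"),
                          stringsAsFactors = FALSE)
  if (!all(df$label %in% c("fwd", "bwd"))) {
    stop("labels must be 'fwd' or 'bwd'")
  }
  work_samples(df$dU[df$label == "fwd"], df$dU[df$label == "bwd"], beta)
}
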