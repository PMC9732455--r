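# Deterministic synthetic-data generators.  They emulate the shape of the
# real study inputs -- a focused kinase-inhibitor chemotype (benzamide
# amides), an interaction network with one true target, Crooks-consistent
# alchemical work samples -- at desk scale, so every module is testable
# offline.  They do not emulate ChEMBL-scale chemical diversity.

#' Default scaffold and substituent sets for the fixture corpus
#'
#' Scaffolds are `sprintf` templates with two substitution slots: `%1$s` is
#' spliced onto the amide nitrogen, `%2$s` onto a ring carbon.  The family
#' deliberately echoes lead-like benzamide chemotypes.
#'
#' @name fixture_chemistry
#' @export
FIXTURE_SCAFFOLDS <- c(
  "O=C(N%1$s)c1ccc(%2$s)cc1",
  "O=C(N%1$s)c1cccc(%2$s)c1",
  "O=C(N%1$s)c1ccc(N%2$s)cc1",
  "O=C(N%1$s)c1ccc(-c2ccc(%2$s)cc2)cc1",
  "O=C(N%1$s)c1ccc(%2$s)cn1",
  "O=C(N%1$s)Nc1ccc(%2$s)cc1"
)

#' @rdname fixture_chemistry
#' @export
FIXTURE_SUBS_N <- c("C", "CC", "CCC", "CCCC", "C(C)C", "CC(C)C", "CCO",
                    "CCN(C)C", "C1CCCC1", "C1CCCCC1", "C1CCNCC1",
                    "Cc1ccccc1")

#' @rdname fixture_chemistry
#' @export
FIXTURE_SUBS_RING <- c("C", "CC", "C(C)C", "C(C)(C)C", "Cl", "F", "O",
                       "OC", "OCC", "N(C)C", "C#N", "C(F)(F)F")

# decoy chemotypes for network fixtures: sulfonamides and aryl ethers,
# structurally unrelated to the benzamide query family
FIXTURE_DECOY_SCAFFOLDS <- c(
  "O=S(=O)(N%1$s)c1ccc(%2$s)cc1",
  "%1$sCOc1ccc(%2$s)cc1",
  "O=C(O%1$s)c1cc(%2$s)ccc1O"
)

enumerate_scaffolds <- function(scaffolds, subs_n, subs_ring) {
  combos <- expand.grid(s = scaffolds, r1 = subs_n, r2 = subs_ring,
                        stringsAsFactors = FALSE)
  sprintf(combos$s, combos$r1, combos$r2)
}

#' Generate a synthetic SMILES corpus
#'
#' Enumerates scaffold x substituent combinations, canonicalises, removes
#' duplicates and invalid splices, and draws a seed-deterministic sample of
#' the requested size.
#'
#' @param n Corpus size (> 0; must not exceed the number of unique
#'   enumerable molecules).
#' @param seed Integer seed.
#' @param scaffolds,subs_n,subs_ring Template and substituent sets; see
#'   [FIXTURE_SCAFFOLDS].
#' @return Character vector of `n` unique canonical SMILES.
#' @export
generate_corpus <- function(n, seed = 1L, scaffolds = FIXTURE_SCAFFOLDS,
                            subs_n = FIXTURE_SUBS_N,
                            subs_ring = FIXTURE_SUBS_RING) {
  if (n <= 0) stop("corpus size must be positive")
  raw <- enumerate_scaffolds(scaffolds, subs_n, subs_ring)
  p <- parse_smiles(raw)
  pool <- unique(p$canonical[p$valid])
  if (n > length(pool)) {
    stop("requested ", n, " molecules but only ", length(pool),
         " unique combinations are enumerable; add substituents")
  }
  set.seed(seed)
  sample(pool, n)
}

#' Single-substituent analogs of a template molecule
#'
#' Re-expresses the template as scaffold + substituents and regenerates it
#' with one slot substituted, yielding the perturbed copies used for planted
#' network targets and fine-tuning sets.
#'
#' @param scaffold One `sprintf` template from the fixture family.
#' @param r1,r2 The template's own substituents.
#' @param n Number of analogs.
#' @param seed Integer seed.
#' @param perturbation_rate Probability that an analog differs from the
#'   template (rate 0 returns identical copies).
#' @inheritParams generate_corpus
#' @return Character vector of `n` canonical SMILES (analogs may repeat).
#' @export
generate_analog_series <- function(scaffold, r1, r2, n, seed = 1L,
                                   perturbation_rate = 1.0,
                                   subs_n = FIXTURE_SUBS_N,
                                   subs_ring = FIXTURE_SUBS_RING) {
  stopifnot(n >= 1, perturbation_rate >= 0, perturbation_rate <= 1)
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    a1 <- r1; a2 <- r2
    if (stats::runif(1) < perturbation_rate) {
      if (stats::runif(1) < 0.5) {
        a1 <- sample(setdiff(subs_n, r1), 1)
      } else {
        a2 <- sample(setdiff(subs_ring, r2), 1)
      }
    }
    out[i] <- sprintf(scaffold, a1, a2)
  }
  canonicalize(out)
}

#' Generate an interaction network with one planted target
#'
#' Builds a protein-ligand interaction table in which one protein (the
#' planted target) is connected to single-substituent perturbations of a
#' designated query molecule while all other proteins carry decoys from
#' unrelated chemotypes.  The ground-truth protein id is returned with the
#' table, enabling recovery experiments.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param ligands_per_protein Ligands attached to each protein.
#' @param seed Integer seed.
#' @param perturbation_rate See [generate_analog_series()].
#' @param query_scaffold,query_r1,query_r2 The query's template decomposition
#'   (defaults give an N-piperidinyl tert-butyl benzamide).
#' @return List with `table` (tibble `protein_id`, `ligand_id`, `smiles`),
#'   `planted` (protein id), `query` (canonical SMILES).
#' @export
generate_network <- function(n_proteins = 10L, ligands_per_protein = 5L,
                             seed = 1L, perturbation_rate = 1.0,
                             query_scaffold = FIXTURE_SCAFFOLDS[1],
                             query_r1 = "C1CCNCC1", query_r2 = "C(C)(C)C") {
  stopifnot(n_proteins >= 2, ligands_per_protein >= 1)
  query <- canonicalize(sprintf(query_scaffold, query_r1, query_r2))
  planted <- generate_analog_series(query_scaffold, query_r1, query_r2,
                                    n = ligands_per_protein, seed = seed,
                                    perturbation_rate = perturbation_rate)
  set.seed(seed + 1L)
  decoy_pool <- enumerate_scaffolds(FIXTURE_DECOY_SCAFFOLDS, FIXTURE_SUBS_N,
                                    FIXTURE_SUBS_RING)
  n_decoys <- (n_proteins - 1L) * ligands_per_protein
  decoys <- sample(decoy_pool, n_decoys, replace = n_decoys > length(decoy_pool))
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  planted_id <- proteins[1]
  table <- tibble::tibble(
    protein_id = rep(proteins, each = ligands_per_protein),
    ligand_id = sprintf("L%03d", seq_len(n_proteins * ligands_per_protein)),
    smiles = c(planted, decoys))
  # shuffle rows so the planted target is not positionally distinguished
  table <- table[sample(nrow(table)), ]
  list(table = table, planted = planted_id, query = query)
}

#' Generate Crooks-consistent Gaussian work samples
#'
#' Draws forward samples from `N(dG + beta*sigma2/2, sigma2)` and backward
#' samples (the energy difference `U_j - U_i` measured in ensemble j) from
#' `N(dG - beta*sigma2/2, sigma2)`; this pair satisfies the Crooks relation
#' exactly, so the BAR estimate converges to `dG`.  Serves as the simulation
#' oracle for the estimator.
#'
#' @param dG Ground-truth free-energy difference (kcal/mol).
#' @param sigma2 Work variance (> 0).
#' @param n Samples per direction.
#' @param beta Reciprocal temperature (default 1).
#' @param seed Integer seed.
#' @return A [work_samples()] object with attribute `truth = dG`.
#' @export
generate_work_samples <- function(dG, sigma2, n, beta = 1, seed = 1L) {
  stopifnot(sigma2 > 0, n >= 1)
  set.seed(seed)
  w <- work_samples(
    forward = stats::rnorm(n, dG + beta * sigma2 / 2, sqrt(sigma2)),
    backward = stats::rnorm(n, dG - beta * sigma2 / 2, sqrt(sigma2)),
    beta = beta)
  attr(w, "truth") <- dG
  w
}

#' Swap the two ensembles of a window
#'
#' Relabels i<->j: forward and backward exchange roles with their signs
#' flipped.  The BAR estimate of the swapped window is exactly the negative
#' of the original.
#'
#' @param w A [work_samples()] object.
#' @return A `work_samples` object.
#' @export
swap_ensembles <- function(w) {
  work_samples(-w$backward, -w$forward, w$beta)
}
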