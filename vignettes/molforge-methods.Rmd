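---
title: "Methods and design notes for molforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for molforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

molforge implements the computational spine of an AI-assisted
hit-to-candidate campaign against a kinase target: reverse target
prediction for an orphan hit, generative chemistry around it, triage of the
generated hits, and the scoring machinery (synthetic feasibility,
selectivity, binding free energy) used to prioritise them.  This vignette
records the models, their assumptions, and the design decisions taken where
the methods left genuine freedom.

## Reverse target prediction

A query compound is scored against every ligand of a bipartite
protein-ligand interaction network.  Six fingerprint families are computed
per molecule — a path-enumeration topological fingerprint (maxPath 7), the
166 MACCS structural keys, hashed atom pairs, topological torsions, and
Morgan radius-2 circular fingerprints with plain and with pharmacophoric
feature atom invariants — and six similarity measures per fingerprint pair
(Tanimoto, Dice, Sokal, Cosine, Kulczynski, McConnaughey), giving 36 values
per query-ligand pair.

Design decisions, where the method statement leaves freedom:

* **Combination rule.** The per-fingerprint ligand score is the *sum* of
  the six measures (not their mean, and not 36 separate rankings): this
  preserves all 36 values while keeping one ranking per fingerprint.
* **Bit lengths and radii.** Hashed fingerprints default to 2048 bits and
  Morgan radius 2; binary (not count) vectors throughout, since the measure
  list is bit-vector native.  All are configuration.
* **Drug selection.** "High-similarity" drugs are the `top_k` (default 100)
  by total score, ties broken by lexicographic ligand id.
* **Degenerate vectors.** Molecules below four heavy atoms can have empty
  torsion or atom-pair fingerprints.  The first five measures are defined
  as 0 there; McConnaughey, whose denominator vanishes, is an error in
  strict use and contributes 0 in batch network scoring.

Each selected drug's per-fingerprint score is propagated to the proteins it
interacts with.  Per fingerprint, proteins are sorted by accumulated score
and the best of the N ranked proteins receives integer rank value N, the
worst 1; the rank score is the rank value divided by the sum
N(N+1)/2, so rank scores within a fingerprint always sum to exactly 1.
Ties receive distinct consecutive rank values (lexicographic tie-break)
rather than averaged ranks, which would break that integer structure.  A
protein's total R sums its six rank scores, and the modified total rank
score R-tilde = R / max(R) puts the top target at exactly 1.

## The SMILES language model

The generator is a character-level LSTM language model over SMILES strings,
written directly on BLAS-batched matrix operations (no deep-learning
framework is involved): one-hot token inputs, two stacked LSTM layers of
256 units, a softmax head, Adam optimisation with gradient-norm clipping at
5, and truncated-at-sequence-end backpropagation through time.
Tokenisation is character-level with multi-character tokens for two-letter
elements (`Cl`, `Br`), bracket atoms and `%nn` ring closures, and
round-trips every corpus string exactly.

Optimisation defaults — minibatches of 16 sequences, learning rate 5e-3
for pretraining and one third of that for fine-tuning — were chosen for
stable convergence of this desk-scale model on regular, scaffold-derived
corpora; they are exposed in `generator_config()`.  A held-out 10% split
tracks generalisation per epoch.  Fine-tuning (transfer learning) continues
training on a small focused set and records the focused-set mean per-token
log-likelihood before and after, the quantity transfer learning is meant to
increase.  Sampling is ancestral with a temperature-scaled softmax; PAD and
BEGIN are masked out, generation stops at END or the length cap, and a
fixed seed makes the sample list exactly reproducible, including across a
checkpoint save/load round-trip.

Generation quality is summarised MOSES-style: validity (fraction of samples
that parse), uniqueness (unique canonical among valid / valid), novelty
(unique valid absent from the training set / unique valid; novelty is
defined as canonical-SMILES absence, since no operational definition is
standard), internal diversity (1 minus mean pairwise Morgan Tanimoto,
subsampled at 500 molecules to keep the quadratic cost bounded) and
Bemis-Murcko scaffold overlap against a reference set.  Uniqueness and
novelty are reported as missing when no sample is valid.

## The synthetic-data generators

Every module is exercised on synthetic fixtures generated in code:

* **Corpus.** Scaffold-by-substituent enumeration over a small family of
  benzamide-like templates (amide nitrogen and ring-carbon substitution
  slots), canonicalised and deduplicated.  The default study scale is a
  500-molecule corpus trained for 20 epochs — small enough for a single
  CPU, large enough that a 2x256 model must generalise across
  substituent combinations rather than memorise.  The fixture family
  emulates the *regularity* of a focused lead-like series, not the
  diversity of a ChEMBL-scale bioactive corpus: passing tests show the
  machinery learns and filters a coherent chemotype, they do not certify
  metric values on real-world corpora.
* **Planted network.** One protein carries single-substituent
  perturbations of a designated query; the other proteins carry decoys
  from unrelated chemotypes (sulfonamides, aryl ethers, salicylates).
  Recovery of the planted protein at R-tilde = 1 is the functional test of
  the ranking pipeline.
* **Work samples.** Forward energy differences are drawn from
  N(dG + beta*sigma2/2, sigma2) and backward ones (dU measured in the
  target ensemble) from N(dG - beta*sigma2/2, sigma2); this pair satisfies
  the Crooks relation exactly, so the BAR estimate must converge to the
  recorded ground truth.

## RAFSF synthetic feasibility

Compounds are fragmented at synthetically meaningful bonds (the BRICS rule
set; a config flag optionally also cleaves exocyclic amide C-N bonds, and
the exact rules are written into the space-file header so spaces are
self-describing).  Fragment attachment points are normalised to an
unlabelled dummy atom by default — erasing the BRICS link-type isotopes
gives coarser matching and a larger effective space; `keep_isotopes`
restores the finer behaviour.

The mapping from frequencies to the 1-10 scale is this package's design:
each fragment or broken-bond type gets penalty
`p = 1 - log10(1 + n) / log10(1 + Cmax)` (1 if absent), and the score is
`1 + 9 * max(p)`.  The max-aggregation encodes the judgement that a
compound is only as synthesizable as its least precedented piece; a mean
aggregation is available behind the same interface.  Consequences worth
knowing: the score is 10 exactly when some piece is unprecedented, 1
exactly when every piece attains the space's maximum count, and monotone
non-decreasing when any non-maximal count drops (lowering the maximal
count itself rescales all penalties, so monotonicity is stated for
fragments below the maximum).

## Triage funnel

Filters are conjunctive and independently toggleable: closed-interval
property windows (defaults MW 200-600 Da, cLogP -1..6 — configuration
choices bracketing lead-like kinase chemistry, not method constants), PAINS
structural alerts (the public PAINS A/B/C collection as shipped with
RDKit's filter catalog; custom named-SMARTS files are supported), novelty
as canonical-SMILES absence from a reference active set, RAFSF feasibility
(pass at score <= 6.0 by default), and a toxicity plug-in contract — any
callable mapping SMILES to pass/fail — with a null plug-in that passes
everything, so the funnel keeps its shape when no proprietary predictor is
available.  Disabled filters are recorded as not-evaluated rather than as
passes, and the funnel is idempotent on its own survivors.

## Selectivity

Raw per-kinase docking scores (kcal/mol) are min-max rescaled per compound
so the most favourable score maps to 0 — the rescaling is deliberately
isolated behind one function, since only "rescaled to a range" is specified
— and the selectivity score is the fraction of panel kinases with rescaled
score strictly below 0.5.  A score exactly at the threshold does not count.
Flat panels (all scores identical) are rejected rather than silently mapped.

## BAR free energies

For one window, the free-energy difference between neighbouring ensembles
is the root of the Bennett self-consistency condition
`<1/(1+exp(beta*(dU - dG)))>_i = <1/(1+exp(beta*(-dU + dG)))>_j`,
which is monotone in dG; it is solved by bracketing within +/-1000
kcal/mol and Brent iteration to 1e-8 kcal/mol.  Ensembles so far apart
that no bracket exists raise a no-overlap error recommending more windows.
Backward samples are the energy difference dU_ij *as measured in ensemble
j* (the literal form of the self-consistency equation); `swap_ensembles()`
performs the role reversal, which exactly negates the estimate.

Uncertainty is available two ways: Bennett's asymptotic variance
(default; cheap, assumes uncorrelated samples) and a seeded block
bootstrap (200 resamples, block length 10) that is robust to residual time
correlation in MD-derived samples.  The tests use the analytic form
because bootstrapping 1e5-sample windows across many cases costs minutes
without adding power at that sample size.

The default lambda schedules switch electrostatics off over
(0, 0.25, 0.5, 0.75, 1) and van der Waals interactions over a nonuniform
16-point list refined near full decoupling; together the two legs'
simulated lambda points give 21 windows and 19 adjacent BAR pairs per leg.
The two-leg ledger states its sign convention explicitly
(`dG_bind = dG_decouple(water) - dG_decouple(complex)`; negative favours
binding) and exposes a manual `restraint_correction` field rather than
guessing a restraint treatment.

## Problem sizes and offline operation

The shipped study scale — 500-molecule corpus, 20 epochs, 1000 samples,
50-trial planted-network recovery, 1e5-sample BAR windows — was chosen so a
full pipeline run and the complete test suite execute on one CPU core in
minutes.  Everything runs offline: all inputs are generated in code, and
the one external record used by the worked example (a ChEMBL-curated
FLT3-active reference ligand) is replaced by a clearly-labelled synthetic
stand-in under `inst/extdata/` when it cannot be fetched; published
similarity values quoted for that record apply to the genuine entry, not
the stand-in.

Standard cheminformatics primitives — SMILES parsing and canonicalisation,
the fingerprint families, BRICS fragmentation, PAINS catalogs, Murcko
scaffolds, descriptors — are delegated to RDKit through a small batch
helper script invoked as an external tool (`python` on the PATH;
`options(molforge.python=)` to override), with results memoised per
canonical SMILES.  The scoring logic, ranking algebra, language model,
feasibility mapping, filters, selectivity and BAR solver are implemented in
R in this package.

## Known limitations

* The fixture chemistry is a narrow chemotype; generation metrics on it do
  not transfer to ChEMBL-scale corpora, where validity is harder and
  diversity much larger.
* The RAFSF frequency-to-score mapping is one defensible choice; scores
  are comparable only against the same space and mapping.
* The BAR module consumes tabulated samples; it does not assess whether
  the upstream simulations were converged or whether restraint corrections
  are needed.
* Toxicity filtering is a contract, not a model: the shipped plug-in
  passes everything.
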