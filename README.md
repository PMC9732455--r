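# molforge

An R toolkit for the computational funnel of AI-assisted kinase-inhibitor
design. Starting from a single active "hit" compound, the package covers:

1. **Reverse target prediction** — rank candidate protein targets of a
   query compound over a protein–ligand interaction network. Six
   fingerprint families (topological path, MACCS keys, atom pair, torsion,
   Morgan, Morgan-with-features) × six similarity measures (Tanimoto, Dice,
   Sokal, Cosine, Kulczynski, McConnaughey) give 36 values per
   query–ligand pair; per fingerprint, protein rank values `N..1` are
   normalised to rank scores `rank value / Σ rank values` (which sum to 1),
   summed over fingerprints to `R`, and reported as the modified total rank
   score `R̃ = R / Rmax ∈ (0, 1]`, with the top target at exactly 1.
2. **Generative chemistry** — a character-level LSTM SMILES language model
   (2×256 by default, implemented in R on BLAS-batched matrix ops):
   pretraining on a corpus, transfer-learning fine-tuning on a focused
   active set, temperature sampling, and MOSES-style metrics (validity,
   uniqueness, novelty, internal diversity, scaffold overlap).
3. **RAFSF synthetic feasibility** — BRICS-fragment/bond frequency spaces
   built from a corpus; each compound piece gets penalty
   `p = 1 − log10(1+n)/log10(1+Cmax)` (1 if unprecedented) and the score
   `1 + 9·max(p)` runs from 1 (highly feasible) to 10 (highly unfeasible).
4. **Lead-like triage** — conjunctive funnel of property windows, PAINS
   structural alerts, novelty, RAFSF feasibility and pluggable toxicity
   predicates.
5. **Kinase-panel selectivity** — per-compound min–max rescaling of raw
   docking scores and the selectivity score
   `S = |{k : rescaled_k < 0.5}| / N` (strict inequality; lower is more
   selective).
6. **BAR free energies** — the Bennett acceptance ratio estimator: per
   window, ΔG solves
   `⟨1/(1+e^{β(ΔU−ΔG)})⟩_i = ⟨1/(1+e^{β(−ΔU+ΔG)})⟩_j`
   over tabulated λ-window samples, chained into two-leg
   (complex/water decoupling) binding free energies with an explicit sign
   convention.

All inputs can be generated synthetically (`generate_corpus()`,
`generate_network()`, `generate_work_samples()`), so the whole pipeline
runs offline on one CPU.

## Worked example

Score a query against a synthetic network with one planted target, then
check the selectivity of the bundled synthetic 48-kinase docking panel:

```r
library(molforge)

fix <- generate_network(n_proteins = 10, ligands_per_protein = 5, seed = 3)
net <- build_network(fix$table)
ranks <- predict_targets(fix$query, net, top_k = 15)
head(ranks$table, 3)
#> # A tibble: 3 × 4
#>   protein_id     R R_tilde  rank
#>   <chr>      <dbl>   <dbl> <int>
#> 1 P01        2       1         1
#> 2 P04        1.53    0.767     2
#> 3 P03        1.27    0.633     3
fix$planted
#> [1] "P01"
```

The planted protein `P01` attains the maximal modified rank score
`R̃ = 1` — the network correctly recovers the designed target.

```r
panel <- read_dock_panel(system.file("extdata", "kinase_panel_SYNTHETIC.csv",
                                     package = "molforge"))
panel_selectivity(panel)[c("S", "n_below", "panel_size")]
#> $S
#> [1] 0.3333333
#> $n_below
#> [1] 16
#> $panel_size
#> [1] 48
```

16 of the 48 kinases dock with a rescaled score below 0.5, giving
selectivity score `S = 0.33`.

A MACCS-keys similarity between the bundled designed candidate and the
shipped reference ligand (`inst/extdata/`; the genuine ChEMBL record must
be fetched online — offline builds use a clearly-labelled synthetic
stand-in):

```r
cand <- read_smiles_file(system.file("extdata", "design_candidate.smi",
                                     package = "molforge"))$smiles
ref  <- read_smiles_file(system.file("extdata",
                                     "flt3_reference_ligand_SYNTHETIC.smi",
                                     package = "molforge"))$smiles
similarity(fingerprint(cand, "MACCS166"), fingerprint(ref, "MACCS166"))
#> [1] 0.4202899
```

## Package layout

| Area | Functions |
| --- | --- |
| Chemistry core | `parse_smiles`, `canonicalize`, `molecule_record`, `fingerprints`, `similarity` |
| Target fishing | `build_network`, `score_query`, `select_drugs`, `rank_proteins`, `predict_targets` |
| Generator | `build_vocabulary`, `pretrain`, `fine_tune`, `sample_smiles`, `evaluate_generation` |
| Feasibility | `fragment_molecules`, `build_fragment_space`, `rafsf_score` |
| Triage | `property_filter`, `alert_filter`, `novelty_filter`, `apply_funnel` |
| Selectivity | `rescale_scores`, `selectivity_score`, `panel_selectivity` |
| Free energy | `work_samples`, `bar_solve`, `chain_windows`, `binding_free_energy`, `lambda_schedule` |
| Fixtures & pipeline | `generate_corpus`, `generate_network`, `generate_work_samples`, `run_pipeline`, `molforge_cli` |

See `vignettes/molforge-methods.Rmd` for the models, assumptions and
design decisions.
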