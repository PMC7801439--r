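# smiformer

Target-conditioned de novo molecule generation in R: an encoder–decoder
transformer that "translates" a protein's amino-acid sequence into SMILES
strings of candidate small-molecule binders, together with the surrounding
workflow a computational drug-discovery group needs around such a model —
BindingDB-style dataset curation, similarity-constrained train/test
splitting, beam-search generation, a molecule evaluation battery backed by
RDKit, and rank-based enrichment analysis of docking scores.

The package is for cheminformatics and machine-learning practitioners who
want a transparent, fully testable R implementation of sequence-to-molecule
translation: every mathematical building block is exported and checked
against independent oracles, and a compiled (RcppArmadillo) engine makes
desk-scale training runs take minutes, not hours.

## The model

De novo design is cast as translation between two character "languages".
The encoder maps residues $(a_1,\dots,a_n)$ to a continuous context
$z = (z_1,\dots,z_n)$; the decoder emits SMILES autoregressively, attending
to its own prefix (causally) and to all of $z$:

- $\mathrm{Attention}(Q,K,V) = \mathrm{softmax}\!\big(QK^\top/\sqrt{d_k}\big)V$
- $\mathrm{Multihead}(Q,K,V) = (\mathrm{head}_1,\dots,\mathrm{head}_h)W^O$,
  $\ \mathrm{head}_i = \mathrm{Attention}(QW_i^Q, KW_i^K, VW_i^V)$
- $PE_{(pos,2i)} = \sin\!\big(pos/b^{2i/d_{model}}\big)$,
  $PE_{(pos,2i+1)} = \cos\!\big(pos/b^{2i/d_{model}}\big)$

Default architecture: 4 encoder and 4 decoder layers, $d_{model}=128$,
4 heads, $d_{ff}=512$; Adam with the inverse-square-root warmup schedule
$lr(s) = d_{model}^{-1/2}\min(s^{-1/2}, s\,w^{-3/2})$ and label-smoothed
cross entropy. Beam search decodes in two modes: `one_per_one` (beam 4,
keep the top molecule per protein) and `ten_per_one` (beam 10, keep all
ten).

Around the model:

- **Curation** (`filter_records()`): the seven standard selection criteria
  for protein–ligand interaction tables (organism whitelist, affinity
  < 100 nM with strict IC50 → Kd → EC50 precedence, identifiers present,
  MW < 1000 Da, 80 < sequence length < 2050), RDKit canonicalization,
  per-criterion drop counts.
- **Splits** (`monte_carlo_splits()`, `verify_split()`): every test protein
  < 20% global-alignment identity (Needleman–Wunsch, BLOSUM62, gap 10/0.5)
  to every train protein, verified by exhaustive realignment.
- **Evaluation** (`evaluation_report()`, `property_profile()`,
  `compliance_table()`, `nearest_neighbor_tanimoto()`): validity,
  uniqueness, reference-set match, logP/MW/H-donors/H-acceptors/rotatable
  bonds/TPSA/QED/SAS, drug-likeness compliance (logP < 5, MW < 500,
  donors < 5, acceptors < 10, rotatable < 10, TPSA < 140 Å², SAS < 6), and
  nearest-neighbor Tanimoto novelty.
- **Score statistics** (`roc_auc()`, `mann_whitney()`,
  `discriminability_filter()`, `group_report()`): ROC/AUC by pair counting
  with the exact identity $AUC = U/(n_1 n_2)$, Mann–Whitney p-values, and
  the AUC < 0.6 structure-discrimination filter for docking receptors.
- **Synthetic data** (`toy_grammar()`, `make_toy_pairs()`,
  `make_toy_bindingdb_table()`, `make_score_sets()`): exactly learnable
  toy corpora and manifests so the whole pipeline is testable without
  downloads.

## Worked example

Train on the toy grammar (each of 8 protein motifs maps to a molecular
fragment; a protein's target molecule is the fragments of its planted
motifs in order), then generate and evaluate:

```r
library(smiformer)

grammar <- toy_grammar(seed = 42)
train <- make_toy_pairs(grammar, n_pairs = 2000, protein_len = 40, seed = 1)
heldout <- make_toy_pairs(grammar, n_pairs = 200, protein_len = 40, seed = 1001)

cfg <- model_config(dropout = 0, warmup_steps = 2000,
                    max_source_len = 60, max_target_len = 40)
model <- train_model(train, cfg, steps = 5000, batch_tokens = 1024, seed = 1)
model
#> Protein-to-SMILES transformer: 4 layers, d_model 128, 4 heads, vocab 29
#>   trained 5000 steps; final training loss 0.6797

exact_match_accuracy(model, heldout)  # fraction decoded exactly right
#> [1] 0.82

rep <- evaluation_report(
  generate_all(model, heldout, mode = "ten_per_one")$smiles,
  reference = train$smiles)
rep
#> # A tibble: 1 x 6
#>   n_generated pct_valid n_valid pct_unique n_unique pct_reference_match
#>         <int>     <dbl>   <int>      <dbl>    <int>               <dbl>
#> 1        2000      77.2    1544       45.7      706                27.6
```

Read: of 2000 beam candidates (10 per held-out protein), 77% parse as valid
molecules; 46% of the valid ones are distinct structures; 28% of those
already occur among the training molecules (the local stand-in for a
compound-database lookup). Greedy one-per-target decoding of the same model
is 96% valid and 82% of held-out proteins decode to exactly the molecule
the toy grammar prescribes — the protein-conditional mapping has largely,
but not completely, been recovered at this desk-scale step budget (the
methods vignette quantifies this trade-off).

Score analysis on simulated docking scores with known separation
(binders at −9 kcal/mol, non-binders at −7, σ = 1, so the closed-form AUC
is Φ(√2) ≈ 0.921):

```r
sim <- make_score_sets(mu_binder = -9, mu_nonbinder = -7, sigma = 1,
                       n = 2000, seed = 1)
r <- roc_auc(sim$scores$score[sim$scores$group == "known_binders"],
             sim$scores$score[sim$scores$group == "random"])
r
#> ROC: n1 = 2000, n2 = 2000, U = 3667909.0, AUC = 0.9170, p = 1e-300
```

The AUC printed is the empirical pair-counting value; `r$U / (r$n1 * r$n2)`
reproduces it exactly, and `plot_roc(r)` draws the curve.

## Command-line interface

A thin CLI over the same functions ships in `inst/cli/smiformer`:

```sh
Rscript inst/cli/smiformer curate   --input raw.tsv --out curated/
Rscript inst/cli/smiformer split    --input curated/curated.tsv --out splits/ \
                                    --threshold 20 --replicates 5 --seed 1
Rscript inst/cli/smiformer train    --input curated/curated.tsv --out model.rds
Rscript inst/cli/smiformer generate --checkpoint model.rds --fasta targets.fa \
                                    --mode ten --out candidates.tsv
Rscript inst/cli/smiformer evaluate --generated candidates.tsv \
                                    --train-ref train.smi --db-ref zinc_local.smi \
                                    --out report.json
Rscript inst/cli/smiformer bindscore --scores docking_scores.tsv --out contrasts.tsv
```

See `vignettes/smiformer-methods.Rmd` for the full account of the model,
its assumptions, the synthetic-data design and known limitations.
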