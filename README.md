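# pseudoU

Prediction of pseudouridine (Ψ) sites in RNA sequences from sequence
information alone.

Pseudouridine is the most abundant post-transcriptional RNA modification;
experimental mapping of Ψ sites is slow and costly, so sequence-based
classifiers are used to prioritize candidate uridines. This package is for
computational biologists who want a fully inspectable, scriptable
implementation of the position-propensity + SVM modeling stack for this
problem: every number it reports can be recomputed from scratch, and every
protocol detail (feature encodings, leakage control, hyperparameter search,
selection order) is exposed as a tested function.

## The model

The unit of prediction is a segment `R_ξ(U) = N₋ξ … N₋1 U N₊1 … N₊ξ`
centered on a uridine (ξ = 10 for 21-nt human/mouse windows, ξ = 15 for
31-nt yeast windows). Five encodings map a segment to features:

* **NC / DC** — nucleotide and overlapping-dinucleotide composition (4 / 16
  frequencies);
* **pseDNC** — DC plus λ tier-correlation factors θⱼ built from z-scored
  physicochemical properties of dinucleotides (free energy, hydrophilicity,
  stacking energy);
* **PSNP / PSDP** — position-specific nucleotide / dinucleotide propensity:
  from training data, per-position class-conditional frequency matrices
  Z⁺ and Z⁻ are fitted and their difference **Z = Z⁺ − Z⁻** encodes a
  segment by lookup, component j = Z[Nⱼ, j].

An RBF-SVM (kernel `K(x,y) = exp(−‖x−y‖²/s²)`, box constraint c; note
γ = 1/s² for libsvm-parameterized libraries) classifies the encoded
segments. Evaluation uses the class-total Sen/Spe/Acc/MCC formulas and
Mann–Whitney AUC. Because PSNP/PSDP are fitted from data, the jackknife
(leave-one-out) protocol **refits the propensity matrices inside every
fold** — encoding a held-out sample with matrices it contributed to leaks
its label into its own features. Greedy sequential forward selection over
the five feature types, with a per-candidate jackknife grid search,
chooses the deployed feature subset.

## Worked example

```r
library(pseudoU)

# A synthetic balanced benchmark: 21-nt segments, central U, a planted
# positional bias of strength 0.6 at four flank positions.
ds <- generate_synthetic(synthetic_config(seed = 1))
ds
#> <psi_dataset> synthetic: 200 segments of length 21 (xi = 10), 100 pos / 100 neg

# Leakage-safe jackknife of the position-propensity feature:
res <- jackknife(ds, feature_recipe("PSNP"), svm_config(cost = 8, kernel_scale = 1))
res
#> <evaluation_result> synthetic, PSNP, c = 8, s = 1
#>   Sen 83.00%  Spe 84.00%  Acc 83.50%  MCC 0.6700  AUC 0.8815
```

Accuracy 83.5% and MCC 0.67 say the planted class signal is recovered well
above the ~50% chance level of this balanced design; the AUC 0.88 is the
probability that a random positive segment outscores a random negative one.

Train and scan a query sequence (every uridine gets a window; windows at
the ends are completed by mirror-image padding):

```r
bundle <- train_model(ds, feature_recipe(c("PSNP", "DC")),
                      svm_config(cost = 8, kernel_scale = 1))
scan_sequence(bundle, "q1", "UAAGCGGAUAACGCAUUAGGCACCGUA")[, 1:4]
#>   id position        score   label
#> 1 q1        1  0.002243348     Psi
#> 2 q1        9 -0.842051728 not-Psi
#> 3 q1       16 -0.322087717 not-Psi
#> 4 q1       17  0.638701065     Psi
#> 5 q1       26 -1.654352969 not-Psi
```

The same operations are available from the shell via the thin CLI at
`inst/exec/pseudoU` (`synth`, `train`, `eval`, `sfs`, `predict`
subcommands), including species presets (`--species human|yeast|mouse`)
matching the published deployable models.

Real curated benchmarks in the canonical FASTA dialect (headers `pos_*` /
`neg_*`, or any header convention via `label_rule`) load with
`load_benchmark(path, xi)`.

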