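# qpisa

Quantitative protease specificity inference from substrate analysis.

`qpisa` profiles the cleavage specificity of exopeptidases — dipeptidyl
peptidases such as DPP4 in particular — from quantified peptide mixtures.
Instead of classifying peptides into products and non-products, it models the
*extent* of proteolysis: every tryptic peptide in an enzyme-versus-buffer
experiment gets a cleavage-oriented log2 fold change Δ (depletion of a
substrate, accumulation of a product), and Δ is regressed on the peptide's
N-terminal residue identities. The result is a quantitative cleavage motif
that captures cooperativity between subsites and scores arbitrary peptides
for predicted cleavage efficiency.

It is intended for proteomics groups running PICS-style experiments (tryptic
digest of a cell lysate, enzyme vs. buffer incubation, TMT-style
quantification) and for protein engineers who want to rank candidate
sequences by predicted susceptibility.

## The model

Positions are named in Schechter–Berger convention: for a dipeptidyl
peptidase the scissile bond lies between the second and third residue of the
peptide, so the N-terminal hexamer covers P2, P1, P1', P2', P3', P4'. Each
position is a 20-state categorical predictor, dummy-coded into 19 indicator
columns against a reference residue; pairwise subsite cooperativity enters
as interaction terms (products of indicator pairs). The central fit is

Δ ≈ μ + β_P2(b) + β_P1(a) + β_P1'(c) + γ_P2:P1(b,a) + γ_P1:P1'(a,c)

estimated by ordinary least squares; models are compared by adjusted R².
A suite of twelve specifications (each single position; linear combinations;
each interaction set) locates where the specificity information sits.

The fitted coefficients are then rearranged into three lookup tables whose
sum reproduces every model prediction exactly:

    score(b, a, c) = term1[a] + term2[b, a] + term3[a, c]

`term1` is the P1 effect (absorbing the intercept and all centring shifts),
`term2` the P2-effect-given-P1 and `term3` the P1'-effect-given-P1. The
tables render directly as multi-panel sequence logos and subtract entrywise
to compare enzymes.

A fully seeded synthetic-experiment generator (skewed residue composition,
in-silico tryptic digestion, motif-driven cleavage with either linear or
first-order kinetics, replicate noise, left-censored dropout) makes the
entire pipeline testable with known ground truth.

## Worked example

```r
library(qpisa)

sim <- simulate_qpisa(n_proteins = 300, truth = default_dpp4_truth(), seed = 1)
run <- run_pipeline(sim$quant, sim$proteome, sim$locations,
                    pipeline_config(product_model = FALSE))
print(run$suite)
```

```
qpisa model suite (12 models, n = 8532 records)
                  model   p adj R2 (%)
                P2 only  17        0.1
                P1 only  17       82.0
               P1' only  17        2.3
               P2' only  17        0.0
               P3' only  17        0.0
               P4' only  19       -0.0
       P2+P1+P1' linear  51       84.2
         all six linear 104       84.2
      P2+P1+P1' +P2:P1' 339       84.2
       P2+P1+P1' +P2:P1 340       84.6
      P2+P1+P1' +P1:P1' 337       90.3
 final (+P2:P1 +P1:P1') 626       90.7
```

P1 identity dominates (82% of variance on its own), the P2:P1' interaction
adds essentially nothing, and the two interactions with P1 lift the final
model to 90.7% — the signature of subsite cooperativity centred on P1, here
recovered from a simulated dipeptidyl-peptidase experiment.

```r
sc <- score_triplets(run$params, c("HAEGTFTSDV", "DAEGTFTSDV", "HAPGTFTSDV"))
round(as.numeric(sc), 2)
#> [1] 2.69 1.74 0.51
```

The three peptides differ only at P2 or P1': swapping His for Asp at P2
lowers the predicted cleavage efficiency (2.69 → 1.74 log2 units), and
putting Pro at P1' nearly abolishes it (0.51) — Pro at P1' is the strongest
negative predictor in the DPP4-like motif.

Real data enter through `read_quant_tsv()` (peptide intensity TSV + sample
sheet) and `read_protein_fasta()`; `inst/scripts/qpisa.R` wraps the same
calls as `simulate` and `run` subcommands for shell use.

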