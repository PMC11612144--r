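---
title: "qpisa: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qpisa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpisa)
```

## The measurement model

A qPISA experiment exposes a complex tryptic peptide mixture to an
exopeptidase and to a buffer control, and quantifies every peptide in both
conditions. The package works with the cleavage-oriented log2 fold change Δ
of each peptide: for substrates Δ = mean log2(buffer) − mean log2(enzyme),
so that depletion — i.e. cleavage — is positive; for products the sign is
flipped, so accumulation is positive. Replicates are averaged within
condition before differencing, giving one Δ per peptide; the number of
observations entering a model is therefore the number of peptides, not the
number of channels. This sign convention makes positive logo heights mean
"promotes cleavage" in every output, and predicts a *negative* correlation
between model scores and measured half-lives (good substrates die fast).

Peptides are first anchored to a protein database. A peptide is *tryptic*
(part of the substrate pool) when it (i) starts downstream of Lys/Arg and
ends with Lys/Arg, (ii) starts downstream of Lys/Arg and ends at the protein
C-terminus, or (iii) ends with Lys/Arg and derives from the protein
N-terminus. Everything else mapped is *semi-tryptic* — the signature of an
exopeptidase product. "Derives from the N-terminus" optionally accepts
position 2 behind an initiator Met (`init_met`, default on), since initiator
Met removal is near-universal; whether the original criteria used trimmed
N-termini is not determinable, so it is a toggle rather than a guess.
Multi-mapping peptides keep the first hit in database order, but records
whose hits disagree about the preceding residue (`ambiguous_flank`) are
removed before modelling, because the classification itself depends on the
flank. Peptides carrying letters outside the 20-residue alphabet are
excluded with a logged count: the categorical model space is the 20 amino
acids, and I/L remain distinct letters throughout.

## Preprocessing

Raw intensities are log2-transformed and every sample column is shifted to
median zero (`log2_median_center()`, idempotent via state flags). Missing
values are treated as left-censored and imputed by a MinProb-style draw:
Gaussian with mean at the `q = 0.01` quantile of all observed values and sd
`spread = 0.3` times the median per-peptide sd, fully determined by a seed.
These two hyperparameters are configurable and recorded in the run manifest;
they are conventional values for left-censored proteomics imputation, chosen
once. Rows below a mean log2 intensity floor are removed — the floor is a
data-dependent choice (−4.7 by default, matching a typical TMT experiment's
noise shoulder) and the comparison is *inclusive*: a row exactly at the
threshold is kept. Redundant modification forms of one sequence collapse to
the most abundant form, with exact ties broken by the lexicographically
smallest form id so reruns are byte-identical. Peptides shorter than six
residues are dropped before any model is fitted, so that all twelve models
in the suite see the identical record set and their adjusted R² values are
comparable.

## The linear model suite

Each of the six N-terminal positions (P2, P1, P1', P2', P3', P4' — for a
dipeptidyl peptidase the scissile bond lies between peptide residues 2 and
3) is a categorical predictor, treatment-coded into 19 dummy columns against
a reference residue. Pairwise cooperativity enters as interaction columns,
the elementwise products of the two dummy blocks (up to 19 × 19 per pair).
The reference residue defaults to Ala (alphabetically first); predictions
and all derived parameters are invariant to this choice as long as the
design has full rank, which the tests verify by refitting with a second
reference.

Columns that are all zero — residues or combinations absent from the data —
are dropped before fitting and reported; their coefficients are fixed at 0
in the output, and predictions touching them are flagged (`novel_levels`,
zero-support flags in the motif tables). Fits use QR-based ordinary least
squares; a rank-deficient design (possible when an interaction combination
is observed only once, in collinear company) falls back to the minimum-norm
SVD solution with a warning rather than failing, since dropped-column
bookkeeping alone cannot guarantee full rank. R² is computed about the mean
of Δ, and model comparison uses adjusted R² with `p` equal to the number of
*retained* predictor columns excluding the intercept — this convention must
be pinned for reproducibility and is echoed in the model metadata.

The canonical suite fits twelve specifications on the same records: the six
single positions, the linear three-position and six-position models, and the
three-position model with each interaction set (P2:P1', P2:P1, P1:P1', and
both P1-centred interactions — the final model). The diagnostic pattern for
an exopeptidase with cooperative subsites is that P1 alone dominates, P2:P1'
adds almost nothing, and the two interactions with P1 produce a distinct
further lift.

## Rearranged parameters and logos

The final model's coefficients are rearranged into three tables whose sum
reproduces the model prediction for every one of the 20³ = 8000 triplets
exactly. With ŷ(b, a, c) the prediction grid (dropped levels contributing
0), and all means uniform over the 20 residues:

* `term1[a]` = mean over b, c of ŷ — the P1 effect, absorbing the intercept
  and every centring shift;
* `term2[b, a]` = mean over c of ŷ − term1[a] — the P2 effect given P1;
* `term3[a, c]` = mean over b of ŷ − term1[a] — the P1' effect given P1.

Because the model contains no P2:P1' term, this decomposition is exact (the
identity is checked to 1e−9 over the full grid in the tests); consequently
rearrangement accepts any specification over {P2, P1, P1'} whose
interactions are a subset of {P2:P1, P1:P1'}, and refuses a P2:P1' term.
The folding passes through an intermediate four-term form (intercept, P1,
P2:P1, P1:P1'), which is kept on the object. Uniform averaging — rather than
observed-frequency weighting — defines the canonical form deliberately: it
keeps the parameters independent of the composition of the peptide mixture,
so parameter sets from different experiments subtract and correlate
meaningfully. Entries never observed in training are emitted with a
zero-support flag rather than omitted; logo rendering (simple base-graphics
letter stacks) is a convenience, the normative artifact being the numeric
tables (820 values: 20 + 400 + 400).

Model comparison (`compare_params()`) is the Pearson correlation over the
concatenated entries, restricted to entries with a minimum training support
in both sets; differential logos are the entrywise difference, with support
the entrywise minimum.

## The product-based variant

The same machinery applies to products: foreground = semi-tryptic peptides
that accumulated by ≥ 1 log2 unit, each extended N-terminally by the
cleavage offset so the record carries the substrate's sequence context;
background = tryptic peptides whose depletion stayed below 1 log2 unit, with
response fixed to 0. The background carries the proteome's composition skew,
the K/R depletion of tryptic digests and the instrument's detection bias,
which a random-peptide background would miss. The stability bound is read
literally as a bound on the *decrease* — strongly increasing tryptic
peptides are not excluded — and no foreground/background weighting is
applied. The foreground keeps the product-orientation Δ so that positive
parameters mean cleavage in both model variants and the two parameter sets
are directly comparable.

## The synthetic generator

`simulate_qpisa()` emulates the statistical structure of the experiment with
known ground truth: a proteome with skewed residue composition (defaults
human-like, e.g. Leu 9.9%, Trp 1.2%), in-silico tryptic digestion (cleavage
after K/R, optional proline suppression, 0–2 missed cleavages), cleavage
driven by a motif in the same three-table form the estimator recovers,
replicate Gaussian noise in log2 space, and left-censored dropout (cells
below a configurable quantile of all values go missing). Two effect modes
exist:

* **linear**: the true depletion is max(score, 0) log2 units — clamped
  because an enzyme cannot increase its substrate — split symmetrically
  around a per-peptide baseline, and the product accumulates by the same
  amount;
* **kinetic**: a fraction f = 1 − exp(−k0·2^score·t) of the substrate is
  cleaved, the substrate change is −log2(1 − f), and the product gains
  exactly the substrate's linear-scale loss, so mass is conserved pair by
  pair (f = 0.5 gives Δ = 1 exactly). Products start at zero buffer
  abundance plus a small pseudocount that cancels in all differences.

`default_dpp4_truth()` is a fixed qualitative motif of a dipeptidyl
peptidase: Pro/Ala strongly promoting at P1, Ser/Thr moderately, Pro at P1'
strongly detrimental after every productive P1 residue, Thr/Val at P1'
mildly beneficial after Pro but detrimental after Ala, and small P2:P1
effects (His favourable, Asp unfavourable before Ala). Most of its triplet
scores are ≤ 0, as for a real enzyme that cleaves a minority of sequences.

For *parameter-recovery* experiments the generator instead uses
`random_truth()`: Gaussian tables with genuine P2:P1 and P1:P1'
cooperativity (sd 0.3 each) and P1 effects centred at +2 (sd 0.8). The
positive centring is a deliberate identifiability choice made up front: the
linear mode's clamping erases the magnitude of negative scores from the
observable depletion, so a predominantly negative motif can only ever be
partially recovered — with a predominantly positive one, clamping affects a
small tail and the full motif is identifiable. This is a documented
limitation, not a property of the estimator: on real data the same effect
means that strongly cleavage-averse combinations are estimated from few,
weak signals.

What the generator does **not** emulate: peptide-specific detection
efficiency (all baselines are i.i.d.), charge/retention behaviour, isotopic
impurity, PSM-level aggregation noise, partial or successive cleavage
chains, and protein-level abundance correlation between peptides. Passing
the recovery tests therefore demonstrates the correctness of the estimator
under the stated noise model, not robustness to every artefact of real
MS data.

## Problem sizes and numerical tolerances

The recovery and concordance experiments use an 800-protein proteome
(~22,000–23,000 substrate peptides after filtering), three replicates per
condition, noise sd 0.3 log2 units, 1% dropout — a scale at which the final
model's ~700 retained parameters are estimated with comfortable degrees of
freedom and a fit takes a few seconds. Unit fixtures use 10–300 proteins.
Exact identities (rearrangement, zero-mean constraints, conservation,
reference invariance) are asserted at 1e−9; the OLS-versus-normal-equations
cross-check at 1e−8; statistical recoveries at the thresholds stated in the
tests (Pearson r ≥ 0.98 for triplet scores, RMSE ≤ 0.1 log2 units on entries
with ≥ 10 observations). All stochastic steps are seeded; reruns are
numerically identical.

## Known limitations

* Scores for triplets containing zero-support entries borrow the reference
  level's effect (they sit at the treatment-coding default); always consult
  the support flags before interpreting them.
* Adjusted R² comparisons assume a shared record set; the package enforces
  this by filtering to hexamer-complete peptides before the suite, which
  discards some genuinely quantified short peptides.
* The half-life validation is correlational: the substrate score carries no
  kinetic units, so only the sign and strength of the association are
  meaningful.
* The product-based model inherits the detection asymmetry of products
  (no baseline in buffer); on synthetic data its parameters track the
  substrate model closely, but on real data it is expected to be the weaker
  of the two, which is why the substrate model is the package's primary
  output.
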