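---
title: "Screening for dicarboxylate-clamp TPR ligands: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for dicarboxylate-clamp TPR ligands: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampscan)
```

## The biological question

Co-chaperones with a dicarboxylate-clamp tetratricopeptide-repeat (dcTPR)
domain bind the extreme C terminus of cytosolic Hsp70/Hsp90 — the EEVD
tail — by clamping the α- and side-chain carboxylates of the terminal
aspartate (glutamate binds, somewhat less well). Any protein ending in a
similar acidic tail is a candidate dcTPR ligand. `clampscan` turns that
observation into a testable pipeline: a rule-based C-terminal scan, a
frequency model of the known ligand tails, over-representation analysis of
the hit set, an evidence network, and a quantitative model of the
peptide-competition binding data that supports a *hierarchy* of clamp
interactions.

## The motif rules

The scan inspects the ten utmost C-terminal residues (position 0 = the last
residue) and requires

* a terminal D or E (the clamped carboxylate pair),
* a bulky hydrophobic anchor (V/L/I/F/Y/W) at position −1,
* at least two acidic residues within the last five positions,
* no lysine or arginine within the last five positions,
* a subcellular localization compatible with the cytosol/nucleus, where
  dcTPR co-chaperones live.

Two windows deserve comment, because the underlying evidence constrains the
last five positions much more strongly than positions −9…−5:

* **`basic_window = 5`, not 10.** The clamp groove contacts concentrate on
  the last five residues, and the reference ligand tails themselves carry
  basic residues upstream of that window (the Hsp90β tail EDASRMEEVD has R
  at −5, the Hsp105 tail EKNSVNMDLD has K at −8, the p23 tail SDDEKMPDLE
  has K at −5). A 10-wide exclusion would reject the prototype ligands, so
  the exclusion is applied where the structural conservation is.
* **`acidic_window = 5` with `min_acidic = 2`.** Whether the "two acidic
  residues" requirement spans five or ten positions cannot be decided from
  the reference tails — all of them satisfy both readings. The package
  defaults to the conservative 5-residue window; both are plain parameters
  of `motif_criteria()`.

Similarly, whether the terminal-residue rule should weight D over E beyond
set membership is left as binary membership: every printed reference tail
passes either way, and a weighting would add a parameter with no data to
fit it.

Degenerate inputs are handled conservatively. Ambiguity letters
(X, B, Z, U, O) in the scanned window fail closed — a peptide that cannot
be confirmed is not a hit. Sequences shorter than the window are evaluated
on what exists and carry a `short` flag; proteins with no usable
localization are retained and flagged `review` rather than silently
dropped, mirroring the manual-inspection step such screens otherwise need.
The verdict itself is the conjunction of the four sequence rules, the
non-ambiguity condition and the localization rule; `short` and `review` are
review flags, not verdict components — dropping every short tail would
make the rule set non-evaluable on exactly the peptides the binding assays
use.

Isoform collapse (`collapse_isoforms()`) is a separate, optional pass:
per gene, the longest passing isoform is kept, ties broken by the
lexicographically smaller id. Keeping it separate lets users work at either
granularity.

## The frequency model and logo arithmetic

`build_pfm()` right-anchors the reference decapeptides (position 0 = C
terminus) and tallies a 20 × 10 count matrix. The information content per
column is `log2(20) − H` bits with `0·log 0 := 0`, optionally minus the
small-sample correction `(1/ln 2)·(s−1)/(2n)`, `s = 20`; values are floored
at 0 and letter heights are `frequency × info`. The correction defaults to
off, matching the naive reading of a rendered logo; with it on, information
shrinks monotonically as the alignment shrinks, which the tests assert.

Two numerical choices matter:

* **Pseudocount 0.5** (Laplace-style) by default, so the log-odds score
  `score_peptide()` never returns −∞ for a residue unseen in eight
  sequences. For *display* arithmetic — reproducing what a logo shows — use
  `pseudocount = 0`: the terminal column of the eight reference tails
  (6 × D, 2 × E) then gives `H = 0.8113` and `info = 3.5106` bits, which
  the acceptance tests pin to 4 decimals.
* **Uniform background** (1/20) by default. A human-proteome composition
  table can be passed instead; it changes scores, not the rule-based
  verdicts.

The training alignment itself is the package's fixture of eight partner
decapeptides; the full membership of the alignment behind the published
logo is not enumerable from the text, so the fixture is a labeled stand-in
with the same documented tails.

## Enrichment

`enrich_terms()` is a fixed-list hypergeometric upper-tail test per term
against the scanned background, with Benjamini–Hochberg correction. This
deliberately replaces two steps of the original analysis chain that do not
belong in an offline, testable pipeline: the threshold-free ranked test of
the GOrilla server (the hit list here is unranked) and REVIGO's
semantic-similarity redundancy reduction (requires an external ontology
graph). The default cutoffs are `p < 1e-3` and `q < 0.01`; the printed
p-cutoff in the source analysis ("< 10 × 10^−4") is internally ambiguous
between 10^−3 and 10^−4, so both are plain parameters and the looser
reading is the default. Under a uniform-sampling null the discrete
hypergeometric p-values are *conservative*, so the calibration test checks
stochastic dominance (empirical false-flag rate at or below the union
bound), not exact uniformity — a Kolmogorov–Smirnov test against the
uniform would reject any discrete test statistic at this sample size.

## The binding model

Dot-blot competition series are modeled as one-site competition with Hill
slope 1, `S(c) = bottom + (top−bottom)/(1 + c/IC50)`. A single clamp groove
argues for the minimal single-site model; the Hill slope is therefore fixed,
not fitted. IC50 is reported as-is — converting to Ki via Cheng–Prusoff
would need the labeled-peptide concentration and its Kd, which are not
available. Whether the original fits floated or fixed the plateaus is
unknown; `fit_ic50()` floats both by default and exposes
`fix_top`/`fix_bottom`.

Fitting is bounded Levenberg–Marquardt least squares with the IC50
parameterized as log10(IC50) (the natural scale for a dilution series);
initialization is `top` = largest per-concentration mean, `bottom` =
smallest, IC50 = geometric midpoint of the positive concentration range;
bounds are `bottom ≥ 0` and IC50 within [min positive conc/100, max
conc·100]. This makes the fit scale-equivariant in concentration units to
optimizer tolerance (asserted at 1e−6 relative). Flat series abort with
"no transition"; non-convergence is reported, not silently dropped.

The simulator adds Gaussian noise clipped at zero — densitometry signals
are non-negative and the actual noise law is unknown; "5% noise" means
`noise_sd = 0.05·top` in signal units. The benchmark assay design is a
triplicate half-log dilution series, 0.5–1000 μM plus a zero-competitor
point (extended to 3000 μM for the weakest binder so the series spans its
transition), matching the span and replication of the published curves.
Under those conditions the fitted IC50 has ≈10% relative standard deviation
and a small (≲5%) downward bias from the zero-clipping, so the ±20%
recovery tolerance used in the tests is about two standard deviations; the
median recovery error over 200 simulated assays stays under 10%, which the
suite asserts.

`classify_affinity_tiers()` encodes the ≥10-fold affinity split: per dcTPR
protein, a pair is low-affinity when its IC50 is at least `fold_threshold`
times the per-protein minimum *and* strictly above the minimum — the
second clause keeps the best binder (and exact ties) in the high-affinity
tier for any threshold, including the boundary threshold of 1.

Displacement algebra uses the ligand-excess approximation (free ≈ total
concentrations), appropriate when peptides at tens of μM vastly exceed
receptor; an exact cubic competitive-equilibrium solver would be the next
refinement if receptor concentrations became comparable. The headline
consequence is analytic: with labeled ligand at its Kd, an equal-dose
competitor with 10-fold weaker affinity lowers occupancy from 1/2 to
1/2.1 (a 4.8% relative loss), while an equal-affinity competitor lowers it
to 1/3 (a 33.3% loss) — low-affinity ligands cannot disrupt high-affinity
clamp interactions.

## What the synthetic data does and does not emulate

`generate_proteome()` plants positives whose tails are drawn from the
reference-peptide frequency matrix (rejection-sampled to satisfy all
rules), and one decoy class per rule, each constructed to violate exactly
that rule and satisfy the rest — this gives per-rule unit coverage rather
than aggregate accuracy only. An optional `random_background` class draws
uniform tails rejection-sampled to fail at least one rule. Body residues
are uniform over the 20 amino acids by default (a composition table can be
supplied); realism of the body affects nothing the scan measures. The
benchmark defaults are 20 positives and 10 decoys per class with lengths
100–500.

Because the rules are deterministic, generator → scan → truth comparison
must give sensitivity = specificity = 1.0; this is the pipeline's core
regression test, not an estimate of real-world performance. Real proteomes
differ in ways the generator does not model: isoform redundancy,
ambiguity-letter records, annotation errors in localization, acidic tails
buried in the fold (invisible to any primary-sequence scan), and the actual
database's composition — which is why a headline hit count from a live
database snapshot is not reproducible here and the scan is validated on
planted truth instead. The term-table generator assigns ~50 background
terms independently at rate 0.05 and one planted term at 20-fold odds among
the positives; real ontologies are hierarchical and correlated, so the
calibration results bound false-flag behavior only for independent terms.

## Problem sizes and determinism

The test suite runs the scan benchmarks at 70–220 proteins, the null
calibration at 1000 Monte-Carlo replicates, and the recovery sweep at 200
simulated assays — sizes chosen so the full suite completes in about two
minutes while keeping Monte-Carlo standard errors well below the asserted
margins. Every stochastic function takes an explicit seed and restores
nothing globally except through `set.seed()` at entry; identical seeds give
byte-identical FASTA output and identical pipeline artifacts, which the
end-to-end test asserts by comparing files.

## Known limitations

* The scan sees primary sequence only; internal acidic patches that mimic
  a C terminus in three dimensions are invisible.
* Localization is whatever the annotation table says; no topology
  prediction is attempted, and the closed vocabulary is a mechanized
  substitute for manual curation.
* The enrichment module does not propagate terms over an ontology graph.
* The curated network edge list shipped in `inst/extdata` is partial by
  construction (the edges explicitly documented in the underlying binding
  work); it illustrates the assembly/export machinery rather than claiming
  completeness.
* IC50s are condition-bound quantities; without labeled-ligand Kd they are
  not binding constants, and cross-assay comparisons assume equal assay
  conditions.
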