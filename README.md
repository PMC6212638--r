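# clampscan

Cytosolic Hsp70 and Hsp90 end in the acidic tetrapeptide EEVD. Co-chaperones
carrying a dicarboxylate-clamp tetratricopeptide-repeat domain (dcTPR)
recognize that tail by clamping the two carboxylates of the terminal
Asp/Glu. Other human proteins end in similar acidic sequences and are
therefore candidate dcTPR ligands. `clampscan` is an R package plus a small
analysis workflow for

* scanning a proteome for Hsp70/Hsp90-like C termini with an explicit,
  configurable rule set,
* summarizing the motif as a C-terminus-anchored frequency matrix with
  sequence-logo information content,
* testing the hit set for term over-representation,
* assembling the partner × dcTPR evidence network, and
* analyzing one-site peptide-competition binding data (IC50 fitting and
  equilibrium displacement algebra).

It is aimed at chaperone/co-chaperone biologists who want the screen and
binding analysis reproducible offline: a synthetic-data module generates
proteomes with planted motif-positive tails and per-rule decoys, annotation
tables with one planted enriched term, and noisy competition series, so
every stage is testable without any database access.

## The rules and the models

A decapeptide tail (position 0 = last residue) is a hit when all of these
hold:

1. terminal residue ∈ {D, E};
2. position −1 is a bulky hydrophobic residue ∈ {V, L, I, F, Y, W};
3. at least 2 acidic residues (D/E) within the last 5 positions;
4. no K/R within the last 5 positions (the clamp contacts concentrate
   there; reference ligands carry K/R further upstream);
5. the protein's localization is compatible with meeting cytosolic dcTPR
   proteins (not extracellular/secreted, ER-luminal, mitochondrial-matrix,
   or membrane with an extracytosolic C terminus).

Ambiguity letters (X, B, Z, U, O) in the tail fail closed. Per-position
information content is the standard logo quantity
`info_j = log2(20) − H_j`, with `H_j` the Shannon entropy of column `j`.
Enrichment uses the hypergeometric upper tail
`P[X ≥ k]` for `X ~ Hypergeom(N, K, n)` with Benjamini–Hochberg correction.
Competition series follow the one-site model
`S(c) = bottom + (top − bottom) / (1 + c / IC50)` (Hill slope 1), fitted by
bounded Levenberg–Marquardt least squares on log10(IC50). Displacement
occupancy under ligand excess is
`occ = (L/KdL) / (1 + L/KdL + I/KdI)`.

## Worked example

```r
library(clampscan)

# the reference partner decapeptides: 8 binders + the poly-D non-binder
sapply(dctpr_partner_peptides(), function(p) passes_criteria(p)$passed)
#>  Hsp90b Hsp70.1  Hsp105     p23   Tom20  DNAAF2   Usp19 NADSYN1   polyD
#>    TRUE    TRUE    TRUE    TRUE    TRUE    TRUE    TRUE    TRUE   FALSE

# logo information at the terminal column (6xD + 2xE among 8 tails)
pfm <- build_pfm(dctpr_partner_peptides(include_polyD = FALSE), pseudocount = 0)
information_content(pfm)$info_bits[10]
#> [1] 3.51065            # of log2(20) = 4.3219 bits possible

# planted-proteome benchmark: 20 positives + 10 decoys per rule class
sim  <- generate_proteome(20, 10, c(100, 500), seed = 7)
hits <- scan_proteome(sim$proteome, sim$annotations)
sum(hits$passed)                                   # 20
setequal(hits$id[hits$passed],
         sim$truth$id[sim$truth$is_positive])      # TRUE

# IC50 recovery from a simulated triplicate series at 5% noise
assay <- simulate_competition_assay(
  competition_params(top = 100, bottom = 0, ic50_uM = 16),
  c(0, 0.5, 1.6, 5, 16, 50, 160, 500, 1000), n_reps = 3,
  noise_sd = 5, seed = 701)
fit_ic50(assay)$params$ic50_uM
#> [1] 16.1762

# why a 10x-weaker competitor cannot displace a high-affinity ligand
displacement_occupancy(1, 10, 1, 1)   # 0.476 vs 0.5 baseline: 4.8% loss
displacement_occupancy(1,  1, 1, 1)   # 0.333               : 33.3% loss
```

The interpretation: the scan recovers planted positives with perfect
sensitivity and specificity because every rule is deterministic; the fitted
IC50 sits within the sampling noise of the generating value; and the
displacement algebra quantifies the hierarchical interaction claim — at
equal dose, a competitor with 10-fold weaker affinity removes under 5% of
the labeled-ligand signal, where an equal-affinity competitor removes a
third.

## The analysis workflow

`analysis/01_simulate_proteome.R` … `06_displacement.R` run the whole
screen end to end on synthetic data and write their tables under
`results/`: proteome + truth, hit table, logo matrix, enrichment table,
GraphML/SIF network, IC50 fits with affinity tiers, displacement grid.
`run_pipeline(pipeline_config(...), out_dir)` does the same from a single
YAML-round-trippable configuration and writes a run manifest with the seeds
and criteria actually applied.

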