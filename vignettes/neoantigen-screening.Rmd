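---
title: "Neoantigen screening with neoscreen: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen screening with neoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscreen)
```

## The screening model

A somatic missense variant substitutes one residue in one protein. Any
8--12-mer window of that protein covering the substituted position is a
potential HLA class I epitope, and each such window defines a mutant/wildtype
(MT/WT) peptide pair differing at exactly one position. `neoscreen` screens
one candidate per variant: the register and patient allele minimizing the
primary predictor's MT IC50, subjected to six criteria.

The criteria and their boundary semantics follow the inequalities as
conventionally printed, and are evaluated independently (no short-circuit)
so a failing candidate reports every reason:

| # | criterion | comparison | default |
|---|-----------|------------|---------|
| 1 | tumor DNA and RNA depth | inclusive ≥ | 10 reads |
| 2 | tumor DNA and RNA VAF | inclusive ≥ | 0.4 |
| 3 | expression | strict > | 1 FPKM |
| 4 | primary MT IC50 | inclusive ≤ | 500 nM |
| 5 | consensus vote | ≥ 3 of 5 at ≤ 500 nM | inclusive |
| 6 | fold change WT/MT | strict > | 1 |

Assumptions worth making explicit:

* **Depth and VAF apply to both samples.** The depth and VAF criteria are
  stated jointly for tumor DNA and RNA; we require both samples to satisfy
  them. VAF is `alt / DP` (total site depth), not `alt / (ref + alt)`, so
  the depth and VAF criteria share a denominator at multi-allelic sites.
  A DNA-only screen is a threshold change away
  (`FilterThresholds()` + screening the RNA columns as copies), but the
  joint reading is the default.
* **All registers are scored.** Whether every 8--12-mer register per
  mutation is scored, or only one per length, is a genuine ambiguity; we
  score all registers (the pVAC-Seq convention) and keep the best.
* **Fold change uses the primary predictor.** The published candidate
  tables print a single IC50 column without naming the algorithm; we take
  the primary predictor (NetMHC in the default panel) for both the
  criterion-4 IC50 and the fold change, computed at the best allele and
  register. A panel-median variant would be a small change to
  `bestAlleleBinding()`; we did not add a switch we cannot validate.
* **Consensus votes on the best allele only**, again pVAC-Seq-like; the
  five consensus predictors score the same peptide/allele pair the primary
  predictor selected.
* **Ranking ties** (equal fold change) break by lower MT IC50, then
  lexicographic MT peptide, making the order deterministic and
  permutation-invariant.

## The predictor interface

External binding predictors are consumed through a *prediction source*: a
function `(peptide, allele, predictor) -> IC50 nM`. Adapters for real
predictors should write the cache dialect
(`peptide<TAB>allele<TAB>predictor<TAB>ic50_nM`) consumed by
`cachePredictionSource()`, which guarantees each triple is resolved
identically on every query and errors on a missing triple rather than
imputing. For offline work, `toyPredict()` is a deterministic built-in
predictor: position weights w(allele, position, residue) in [0, 1] come from
a string hash keyed by predictor name, the peptide score is their mean, and
`IC50 = 50000^(1 - score)`, strictly decreasing in the score and spanning
the 1--50000 nM range predictors emit. It reproduces none of the biology of
a trained predictor — it exists so the pipeline's plumbing, caching, and
consensus logic are exercised with distinct, reproducible panel members.

## The synthetic cohort generator

`simulateCohort()` plants two kinds of variants. Passers clear every
criterion *with margin*: depth at least twice the threshold, VAF at least
threshold + 0.2, FPKM at least 10x, primary MT IC50 at most half of 500 nM
with 4 of 5 consensus predictors agreeing, and WT IC50 at least 4x the MT.
Each decoy violates exactly one criterion and clears the rest with the same
margins, and the violation is carried by a single field (the DNA depth, the
DNA alt count, the FPKM entry, or one cache entry), so restoring that field
restores the pass — a per-criterion sensitivity the test suite checks
directly. Margins are parameters (`margins =`), so boundary behavior can be
probed separately from recovery.

Design choices, made once:

* **Uniform amino-acid composition.** No proteome composition model is
  imposed; sequences are uniform over the 20 canonical letters, the
  simplest exchangeable null.
* **Real codon edits.** Each planted substitution is backed by an actual
  single-nucleotide codon change consistent with the amino-acid change, so
  the VCF round-trip and the annotation/codon consistency check are
  non-trivial.
* **One variant per gene.** Expression is per-gene, and a low-FPKM decoy
  sharing a gene with a passer would be contradictory.
* **Seeding.** Every generator derives a substream from its master seed and
  a component name (a deterministic string hash), so adding a new generator
  never perturbs existing streams, and every generator is a pure function
  of its arguments.
* **Cohort sizes are free parameters.** Real per-tumor mutation totals
  (thousands of somatic mutations funneling to hundreds of missense
  variants and a handful of candidates) depend on sequencing data that is
  not available at desk scale; the generator reproduces the *shape* of the
  funnel, not those counts. The suite and the acceptance script use 50
  variants per cohort (20 passers, 5 decoys per criterion) over 60
  proteins of 40--120 residues — large enough that every criterion and
  register length is exercised, small enough to screen in seconds.

What the generator does **not** emulate: read-level sequencing (no FASTQ,
no error model), germline variation, sub-clonal VAF structure, correlated
predictor errors, and real binding chemistry. Passing the recovery test
therefore demonstrates that the filtering, voting and ranking logic is
correct, not that the screen's thresholds are well-calibrated for any
particular tumor.

## Structural metrics

The structural module quantifies what published peptide--HLA figures report:
the P2--P9 anchor C-alpha distance (an extended binding pose in the class I
groove puts it in the 15--21 A range), inter-chain atom contacts, hydrogen
bonds, and the MM/GBSA binding free energy averaged over the equilibrated
window of a trajectory.

Conventions, configurable and recorded here because no single standard
exists:

* contacts: heavy-atom pairs at ≤ 4.5 Å (inclusive), hydrogens excluded by
  default;
* hydrogen bonds: donor N/O with a covalently attached H (attachment
  inferred by proximity, H within 1.3 Å in the same residue),
  acceptor N/O on the other chain, donor--acceptor ≤ 3.5 Å and D--H···A
  angle ≥ 120°; both donor directions counted. Hydrogen-free structures
  (most X-ray PDBs) are an error unless `distanceOnly = TRUE`, which counts
  N/O pairs by distance alone — a looser count, flagged rather than silent;
* the MM/GBSA window `[80, 100]` ns is closed on both ends ("from 80 to
  100 ns" reads inclusively); ΔG = G_complex − G_receptor − G_ligand per
  frame, summarized as mean, sample SD and frame count;
* the peptide chain is auto-detected as the shortest chain with 8--12
  residues unless named.

Anchor positions index residues in chain order (first residue = P1),
robust to PDB files whose author numbering does not start at 1.

The module computes geometry and window averages only: force-field
energies, minimization, solvation and MD integration are explicitly out of
scope, and published ΔG_MM/GBSA values for specific complexes are not
desk-reproducible targets. `simulateEnergySeries()` plants a known mean ΔG;
its receptor/ligand jitter is integer-valued so that the component
subtraction is exact in floating point and a noise-free series returns the
planted value bit-exactly.

## Assay statistics

`percentLysis()` implements
`100 − (OD_co-culture / OD_target) × 100`. Values below 0 or above 100 are
returned as-is and flagged, not clipped — a co-culture outgrowing the
target-alone wells is an assay problem the analyst should see.
`summarizeReplicates()` reports mean ± SEM (sample SD / √n; n = 1 yields a
flagged NA rather than an error). `compareGroups()` uses Student's t
(pooled variance) for two groups — chosen so the classical identity
F = t² against the one-way ANOVA holds, which the tests verify numerically —
and one-way ANOVA with Tukey HSD (Tukey--Kramer when unbalanced) for more,
at α = 0.05.

## Numerical and formatting choices

* Report tables print IC50s at three decimals and fold changes at two,
  rounded half-up (`2.125 → 2.13`), not banker's rounding. Published
  candidate tables mix rounding and truncation (e.g. 3646.31/118.433 =
  30.788 printed as 30.78), so recomputed fold changes are compared at
  ±0.02.
* `computeVAF()` treats zero depth as an error distinct from "below
  threshold"; a site with no reads has no defined VAF.
* Selenocysteine and ambiguity codes are rejected at enumeration, not
  silently skipped, since binding predictors accept only the 20 canonical
  letters.
* All identifiers, tie-breaks and output orders are deterministic, so
  golden tests and cache files are stable across runs and platforms.

## Known limitations

* Single-residue missense neoantigens only: no indels, frameshifts,
  fusions or splice-derived epitopes.
* No clonality/purity modeling, proteasomal-processing or TAP transport
  scores; RNA VAF proxies mutant-allele expression.
* The built-in predictor is a plumbing stand-in, not a binding model;
  conclusions about real peptides require external predictor adapters.
* The hydrogen-bond count depends on protonation; for structures without
  hydrogens the distance-only fallback overcounts.
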