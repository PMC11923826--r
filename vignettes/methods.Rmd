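---
title: "Methods: topology-driven palmitoylation-site inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-driven palmitoylation-site inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topopalm)
```

## The scientific problem

S-palmitoylation is the reversible thioester attachment of a C16 acyl
chain to a cysteine thiol. On transmembrane proteins (TMPs) it clusters
at juxtamembrane cysteines — residues a handful of positions away from
the cytoplasmic face of a membrane-spanning helix. Exactly those
residues are systematically hard to observe by the dominant discovery
technology, trypsin-based bottom-up proteomics: juxtamembrane tryptic
peptides tend to be either too hydrophobic (they drag a whole
transmembrane helix along) or vanishingly short (cysteines flanked by
Arg/Lys), so they fall outside the mass and hydropathy range that LC-MS
reliably recovers.

`topopalm` addresses this in two parts. First, `digest_trypsin()` and
the detectability census quantify the observation gap: a complete
in-silico tryptic digest, with each Cys-containing peptide classified by
whether it falls inside a detectability box of 700–3000 Da and mean
Kyte–Doolittle hydropathy −2 to +1 (both bounds inclusive — the
convention we adopted where the box definition leaves it open). Second,
a gradient-boosted-tree classifier predicts palmitoylation from
annotation-level topology alone, sidestepping the peptide-level bias
entirely.

## The feature model

Every inference-eligible cysteine is described by 28 features
(`feature_registry()`), grouped as:

* **Topological placement** — containing segment kind and (for
  transmembrane sites) helix orientation; segment length; absolute and
  relative offsets within the segment; protein length and distances to
  both termini.
* **Membrane-interface distance** — the residue count to the
  cytoplasmic–membrane boundary. For an inward-oriented helix
  (C-terminal side cytoplasmic) this is `end − position`; for outward,
  `position − start`; for a cytoplasmic head/tail segment the distance
  from its membrane-adjacent boundary, with the first residue of the
  segment at distance 0; internal loops take the smaller side. When a
  helix has unknown orientation we use the smaller of the two end
  distances rather than guessing an orientation; when a loop borders no
  helix directly (e.g. it follows a signal peptide) we fall back to the
  nearest transmembrane boundary in the protein.
* **Window physicochemistry** — five residues on each side of the
  cysteine (windows used in this field range from 5 to 16 residues; the
  small end minimizes noise given how close palmitoylation sites sit to
  the membrane). Per side: mean Kyte–Doolittle hydropathy, net formal
  charge (K/R +1, D/E −1, His 0 at the physiological-pH convention),
  Zimmerman polarity, Ikai aliphatic index, Zhao–London transmembrane
  tendency; plus the hydropathy sum and C-minus-N gradient, the charge
  gradient, and pooled basic-residue and asparagine counts.
* **Cysteine clustering** — a window Cys score awarding `(6 − d)/5`
  points for each additional cysteine at offset `d` (1–5) in either
  window. The published scheme states only that nearer window cysteines
  earn more points; the linear decay here is our concrete
  instantiation, and the weight vector (`CYS_SCORE_WEIGHTS`) is
  exposed so alternatives can be substituted.

Truncated windows near termini use means over the available residues
(no padding); counts stay raw. A window that is entirely empty
contributes `NA`, which the tree booster handles natively. Sites in
signal peptides, intramembrane segments (which do not traverse the
bilayer and are too rare to be represented in training data),
unannotated gaps, or windows touching a nonstandard residue (U, X, B,
Z) are excluded from inference with a logged reason — never given a
fabricated value.

Coordinates are 1-based inclusive throughout (the UniProt convention).
Orientation is inferred exactly as the annotation dialect implies: a
helix whose immediately preceding segment is extracellular/lumenal is
inward, cytoplasmic is outward, anything else (including an N-terminal
helix with no predecessor) stays unknown rather than guessed.

## Label curation

Positives come from a SwissPalm-style "Sites" export filtered on the
`site_techniques` text for the literal substrings `"Point mutation"`
or `"palmitate"` — i.e. sites backed by site-directed mutagenesis or
radiolabeling rather than large-scale proteomics (which is precisely
the biased technology under study). Matching is case-sensitive by
default because those are the literal database strings; a flag enables
case-insensitive matching for other dialects. Supplements (e.g.
database cross-references, or native-MS studies quantifying a
palmitoylated fraction, ingested at a strict `fraction > 0.25`) may
only add positives. Negatives are inferred as every other
inference-eligible cysteine *on a protein that carries at least one
positive*; proteins never studied for palmitoylation contribute no
negatives, which keeps unverified absence out of the negative class.
The class imbalance is reported as total:positive, the definition
consistent with both ratios this model family reports (6.75 for
446/2565 and 8.81 for 82/641).

## The classifier

The booster is `xgboost` configured to mirror the conventional
gradient-boosted-machine knobs: `max_depth` ↔ interaction depth (18),
`nrounds` ↔ number of trees (2000), `eta` ↔ shrinkage (0.08),
`min_child_weight` ↔ minimum node size (5), single-threaded exact tree
construction so training is bit-reproducible given the seed. The
shrinkage default is 0.08; this model family has also been described
with 0.008, and the value is a plain argument of
`palm_hyperparams()` so users can set either. No class re-weighting is
applied. Cross-validation is stratified by site with a fixed seed;
fold assignment is per site, not per protein, so reported CV AUC can
be slightly optimistic when sibling sites share a protein — the
held-out evaluations in this package therefore split at the protein
level. Tuning (`tune_palm_grid()`) ranks grid points by mean
cross-validated ROC AUC with folds shared across points.

Evaluation (`evaluate_scores()`) reports the rank-statistic ROC AUC, a
tie-grouped threshold-sweep precision–recall curve with trapezoidal
AUC (anchored at recall 0 with the first precision), F1 across the
sweep, and precision/recall/F1/Matthews correlation at the three named
cutoffs 0.25/0.50/0.75. A site counts as predicted positive at
`score >= threshold`; "above threshold" in rank summaries
(`rank_and_threshold()`) is strict, matching the "probability > 0.75"
reading of high-confidence counts. MCC is defined as 0 when any
confusion-matrix marginal is empty (the degenerate-predictor
convention). Ranks break score ties by accession then position so the
rank vector is always a permutation.

## The synthetic study conditions

The generator (`synth_params()`) emulates the statistical structure
the features assume — and nothing more. Defaults, chosen once as the
reference simulation conditions: 500 proteins; 1–4 transmembrane
helices of 18–25 residues alternating with loops of 10–80 residues;
5% of proteins carry an N-terminal signal peptide and 2% an
intramembrane segment; per-kind residue compositions give hydrophobic
(I/L/V/F/A-rich) helix cores and charged/polar loops; cysteine rates
of 2–5% per segment kind. Labels are planted by a latent rule that
uses *only* the membrane-interface distance: a cysteine within
`d_near = 10` residues of the interface is positive with probability
`p_near = 0.8`, any other eligible cysteine with `p_far = 0.02`.
Because the plant ignores hydrophobicity and clustering, feature
importance has an unambiguous expected answer (`interface_distance`
must dominate), which the recovery tests assert.

What passing these tests shows: the pipeline can learn a
distance-from-membrane rule from its own features at realistic signal
strength, end to end from files on disk. What it does not show:
performance on real proteomes, where annotation is incomplete,
composition is not multinomial, and palmitoylation depends on more
than distance. The synthetic generator makes no attempt at
evolutionary sequence structure.

## Numerical and design choices

* Masses are **average** (not monoisotopic) residue masses plus one
  water; the detectability window is a coarse heuristic for which
  average masses are conventional.
* Membrane proximity in the digest census counts residues from the
  nearest helix boundary (a residue immediately past the boundary is
  at distance 1) and is inclusive at the 20-residue cutoff; the
  interface-distance *feature* instead counts from the segment's first
  residue (distance 0 at the boundary residue itself), the convention
  consistent with a median distance of 1 for inward-helix sites.
* Complete digestion is modelled by default; `missed_cleavages` exists
  but defaults to 0.
* The amino-acid tables (Kyte–Doolittle, Zimmerman polarity,
  Zhao–London transmembrane tendency, average masses, formal charges)
  ship both as package constants and as substitutable TSVs under
  `inst/extdata/scales/`, kept in lockstep by a test.
* Degenerate cases: a length-1 segment has relative position 0; an
  empty sequence is an error everywhere; `net_charge("") == 0` by
  convention; duplicate accessions are hard errors rather than silent
  merges.

## Problem sizes used by the test-suite and acceptance script

The reference simulation (500 proteins, ≈3,700–3,900 eligible
cysteines, protein-level 3:1 train/test split) is trained once with
the default hyperparameters and reused across the recovery, null and
design-scan checks; unit tests use smaller simulations (20–60
proteins) and lighter boosters, sizes chosen to exercise every code
path while keeping the default suite quick to run.

## Known limitations

* No topology prediction: proteins without usable annotation are
  excluded, mirroring the annotation-completeness limitation inherent
  to this approach (about a quarter of murine TMPs).
* No structure-derived features by design — the model's premise is
  that annotation-level topology suffices.
* The exact 28-feature roster and the Cys-score weighting are faithful
  but not provably identical reconstructions of the original tool's
  appendix-documented choices; both are exposed in code
  (`feature_registry()`, `CYS_SCORE_WEIGHTS`) precisely so they are
  auditable.
* External score ingestion (`ingest_external_scores()`) supports
  benchmarking against other predictors but re-implements none of
  them.
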