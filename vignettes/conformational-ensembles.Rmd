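---
title: "Subsampled-alignment conformational ensembles: methods and design"
author: "ConformR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsampled-alignment conformational ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConformR)
```

## The problem and the model

Co-evolutionary structure predictors collapse a protein's conformational
landscape onto its best-supported state because a deep multiple sequence
alignment (MSA) over-determines one set of contacts. Thinning the alignment
re-opens the landscape: with fewer, more diverse sequences the predictor's
output varies from run to run, and across many seeded runs those outputs
sample alternative conformations. ConformR implements the two computational
halves of this workflow — preparing diversity-controlled MSA subsamples, and
quantifying the resulting structure ensembles — while treating the predictor
itself as an external black box that consumes A3M files and emits PDB models
with per-residue pLDDT in the B-factor column.

## Alignment subsampling

An `MSA` lives in the rectangular column space of its first record, the
target. A3M input is normalised at the boundary: lowercase letters are
insertions relative to the query and are deleted together with `.` padding,
because Hamming arithmetic requires a fixed column space; in aligned FASTA,
`.` and `*` are tolerated and normalised to `-`. Within that space the
Hamming distance treats `-` as an ordinary 21st character — the simplest
reading, and the one users can reproduce by eye. Duplicate rows are removed
before clustering by default (first occurrence kept, so the target always
survives); the subsampling size contracts are therefore stated over
*distinct* sequences.

Subsampling is controlled by the pair `max_seq` (*N*) and `extra_seq` (*M*):

1. *N* rows become cluster centres. The target is always centre one. The
   remaining centres default to greedy farthest-point selection in Hamming
   space — each new centre is the row farthest from all previous centres,
   ties broken randomly from the seed — which gives maximally diverse,
   reproducible centres; a uniform-random strategy is available where
   diversity maximisation is not wanted. Every non-centre row is assigned to
   its nearest centre, ties to the earlier centre.
2. *M* extra sequences are drawn from the non-centre rows: clusters are
   visited round-robin in descending size order and sampled uniformly
   without replacement, so every populated cluster contributes one sequence
   before any contributes two. The extras never contain the target and are
   disjoint from the centres by row identity.

Each `(N, M, seed)` triple owns a private Mersenne-Twister stream derived
from the triple, so jobs are byte-reproducible, independent of evaluation
order, and never touch the session's RNG state. Requests exceeding the
available distinct rows clamp with a warning rather than fail: a shallow
alignment should still produce its best-effort subsample.

## Ensemble geometry

All structural metrics are CA-only: the workflow's predicted models vary in
backbone geometry, and CA traces carry the conformational signal while
staying robust to side-chain noise. Superposition is the closed-form Kabsch
fit (SVD of the cross-covariance with reflection correction); RMSD is
measured after superposition unless explicitly disabled.

The RMSF reference is the *iterative mean structure*: superpose every frame
onto the current mean, recompute the per-CA mean, and repeat until the mean
moves by less than `tol` (default 1e-3 Å, unsuperposed RMSD between
successive means) or `maxIter` (default 10) is reached, which in practice
takes 2–3 iterations; non-convergence is a warning, not an error, because
the last iterate is still a serviceable reference. Using frame 1 instead
would bias the fluctuation profile toward whichever conformation happened to
be predicted first.

The TM-score is implemented natively so that it is unit-testable and free of
external binaries. For the same-sequence frames of an ensemble the residue
correspondence is fixed and *only the superposition is searched*: seeds are
the full chain, both halves, and sliding windows of length L/4 (step L/8);
each seed is refined by re-superposing on the residues within a d0-based
cutoff (growing the cutoff by 0.5 Å when fewer than three residues qualify)
until the included set is stable, and the best score over seeds is kept.
`d0 = 1.24 (L−15)^{1/3} − 1.8` Å requires L > 15, which is enforced with an
explicit error. `tmScoreFromDistances()` exposes the bare formula for
calibration — residues all at exactly d0 score 0.5. Pairwise TM matrices are
symmetrised by averaging the two orientations, since the seeded search is
not exactly symmetric.

## Flexibility profiles and peak calling

`computeRMSF()` pairs each residue's fluctuation with its mean pLDDT, since
mobile residues are expected to combine large RMSF with low predictor
confidence; the long-format condition table feeds the RMSF-vs-pLDDT scatter
used to compare `max_seq:extra_seq` settings.

Peak calling on a profile takes three thresholds, all user-specifiable:

- `width` — minimum number of positions a reported range must span;
- `height` — minimum profile value at the apex and at the range boundaries;
- `prominence` — minimum topographic prominence of the apex (height above
  the higher of the two saddles separating it from higher terrain).

Apexes are plateau-aware local maxima requiring a strictly lower neighbour
on both sides, so constant series and profile edges never yield peaks. A
range is the contiguous above-`height` region around an apex; apexes sharing
a region merge into one range, and below-threshold dips *shorter than
`width`* between above-threshold runs are bridged first, so a single
flexible segment briefly interrupted by sampling noise reports as one range
rather than two. Defaults are scale-free — `height` = profile mean + 1 SD,
`prominence` = 1 SD — because absolute Å thresholds do not transfer between
proteins. The same detector serves RMSD-versus-frame series.

## Conformational states and populations

Frames are embedded at their superposed RMSD to one or two reference
conformations, and k-means (25 restarts, seeded) partitions that 1D/2D
space. k-means matches the centroid-plus-populations presentation of the
analysis; both the number of restarts and the seed are fixed so repeated
runs agree exactly. Cluster 0 is always the most populated state, with ties
broken by centroid distance to the first reference. With `k = "auto"`, k in
2..5 is chosen by mean silhouette width; since the silhouette is undefined
at k = 1, the model falls back to a single state when the best silhouette is
below 0.25 (no real cluster structure) or fewer than four frames are
available. Populations are reported in percent and sum to 100 exactly.

The *ensemble variability score* printed with each model is this package's
own definition — the mean pairwise distance between state centroids divided
by the mean distance of frames to their own centroid, rounded to two
decimals (0 for one state, NA when the within spread is degenerate). It is
labelled as such in all outputs; it is a reproducible summary of how far
apart the states sit relative to their width, not a quantity with an
external reference value.

Kernel densities of RMSD values use a Gaussian KDE (Silverman bandwidth by
default) on a grid spanning [min − 3bw, max + 3bw]; a degenerate sample
falls back to a small positive bandwidth so an all-equal input still renders
as a single narrow peak.

## The synthetic world: what it emulates, and what it does not

The fixture generator replaces the two expensive stages — homology search
and predictor inference — with planted-truth analogues:

- **Alignments**: one random 20-letter ancestor per family, all families
  differing at the same `inter` columns (distinct letters per family, so
  ancestor pairs sit at Hamming distance ≈ `inter`), members mutated at up
  to `intra` random columns. Separability demands `inter > 2·intra`; the
  planted family labels are the oracle for centre-recovery tests.
- **Ensembles**: an idealised CA coil with exact 3.8 Å spacing (helix-like
  winding, so it is never degenerate for superposition) and one conformation
  per hinge angle, the C-terminal half rigidly rotated about the middle
  residue. Frames sample conformations by weight, add isotropic Gaussian
  noise (σ = 0.2 Å by default, tripled inside an 11-residue planted flexible
  segment placed in the static N-terminal half), receive a uniform random
  rigid motion, and carry pLDDT planted at mean 92 outside / 65 inside the
  flexible segment (SD 2), reproducing the mobility–confidence
  anticorrelation. Coordinates are rounded to the 0.001 Å PDB column
  precision at generation time so PDB round-trips are exact.

Default study conditions used by the tests and the acceptance script:
3 families × 20–40 members, 60 columns, `inter` = 20, `intra` = 2;
three-state ensembles at hinge angles 0/25/50° with weights 70/20/10 % and
N = 200 frames (state separation ≳ 2 Å against σ = 0.2 Å, i.e.
separation/noise ≥ 10); peak recovery on 20-frame single-state ensembles
(segment amplitude 3× baseline). These sizes keep the full suite under a
minute while leaving each recovery property far from its decision boundary.

What passing these tests shows — and does not. They demonstrate that the
algorithms are internally correct: clustering recovers planted families,
RMSF and peak calling recover planted segments, population estimates match
planted draws, and all I/O round-trips. They do not demonstrate that any
particular `max_seq:extra_seq` recovers the true conformational landscape of
a real protein; that depends on the predictor, the depth and bias of the
real alignment, and reference structures chosen by the user. Real predicted
ensembles also violate the generator's assumptions in known ways: noise is
neither isotropic nor Gaussian, states are not rigid-body hinges, and pLDDT
correlates with error non-linearly.

## Numerical choices and degenerate inputs

- Superposition requires ≥ 3 points and matched lengths; the rotation is
  orthonormal with det = +1 to 1e-8 by construction.
- A single-frame ensemble yields an all-zero RMSF with a warning rather
  than an error, and its pairwise matrix is the 1×1 zero/one matrix.
- pLDDT outside [0, 100] is a validation error at the class boundary —
  predicted-model conventions make out-of-range B-factors a sign of reading
  the wrong file, and silent clamping would hide that.
- Insertion codes in PDB input are rejected loudly (predicted models never
  contain them; misindexing would corrupt every downstream profile);
  altloc duplicates keep the highest-occupancy CA; multi-chain files
  analyse the first chain unless one is named.
- All outputs index residues by the deposited PDB residue number, never by
  0-based array position, so report files line up with structure viewers.
- Ties in farthest-point selection and k-means restarts are resolved from
  derived seeds; no code path consumes the caller's RNG state.

## Command-line surface

The `conformr` Rscript front end exposes the workflows as subcommands
(`fixtures`, `subsample`, `stage-predictions`, `analyze-flex`,
`analyze-states`, `matrix`) with a YAML-config alternative to flags.
`stage-predictions` deliberately stops at emitting a shell manifest of
predictor commands: running inference requires GPUs and model weights and is
out of scope, so the package prepares inputs for it and consumes its
outputs. Configuration errors abort before any file is written; successful
runs are byte-reproducible per seed in all CSV/JSON outputs.

## Known limitations

- The TM-score search is a heuristic maximisation; scores are lower bounds
  on the true maximum (observed to agree with the trivial global
  superposition or better on all test cases).
- Sequence-independent alignment (TM-align-style) is not provided; frames
  must share a residue numbering.
- Clustering is limited to the 1D/2D RMSD-to-reference space; ensembles
  whose states are not separable in that projection need different
  coordinates.
- mmCIF input, trajectory formats and full-atom analyses are out of scope.
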