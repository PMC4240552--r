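---
title: "Consensus ortholog groups by partition intersection and profile expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ortholog groups by partition intersection and profile expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaortho)
```

## The method

`metaortho` combines the ortholog-group predictions of N ≥ 2 independent
methods into one consensus clustering. The premise is that agreement
between methods with different failure modes (graph-based vs tree-based)
is strong evidence of true orthology, while the strict intersection of
many methods is too conservative for annotation transfer. The algorithm
therefore alternates a stringent step with a sensitive one:

1. With level counter i = N, form all cells of the common refinement of
   every size-i subset of the input partitions: two proteins share a
   cell iff every method of the subset groups them together. A protein
   absent from a method's predictions cannot enter any cell of a subset
   containing that method — absence is evidence of nothing, not a
   wildcard.
2. Cells of size ≥ `min_size` (default 4) become seed groups. Because a
   protein can fall in cells of different subsets when i < N, conflicts
   are resolved protein by protein: the largest cell wins, an exact size
   tie is decided uniformly at random from the run's seeded generator,
   and a cell that drops below `min_size` after a loss is demoted.
   Processing order is deterministic (descending cell size, then the
   lexicographically smallest member), so the random stream is consulted
   only for genuine ties, and every such draw is logged.
3. Each seed group's sequences are multiply aligned and summarised as a
   position-specific profile; every still-unassigned protein is compared
   to every profile. A protein joins a group when the comparison has
   E-value strictly below `evalue_threshold` (default 1e-10) and the
   local alignment covers at least `min_coverage` (default 0.40) of
   *both* the query sequence and the profile's match columns — the
   coverage condition names both lengths, so it is enforced as
   `min(seq_coverage, profile_coverage)`. Among qualifying profiles the
   lowest E-value wins, then the higher minimum coverage, then the
   lexicographically smallest group id; a protein joins at most one
   group per pass, and profiles are never updated within a pass.
4. The expanded groups are final: their members leave the pool. Then
   i ← i − 1 and the loop repeats while i > 2 and unassigned proteins
   remain. After the i = 2 pass, two-method cells of size 2 to
   `min_size` − 1 are appended as *leftover* final groups.

Defaults (1e-10, 0.40, 4) are the method's standard operating point; the
E-value bound is strict ("lower than") while the coverage bound is
non-strict ("at least"), and both boundaries are unit-tested.

### Design choices in the open corners

* **Leftover cells vs disjointness.** A leftover two-method cell may
  contain proteins already finalized at a higher level (its other
  members were recruited elsewhere). To keep the output a partition,
  leftover cells are restricted to still-unassigned proteins, dropped if
  fewer than 2 remain, and processed in canonical order so that
  overlapping leftovers cannot double-assign a protein.
* **Duplicate cells across subsets.** At level i < N the same member set
  can arise from different method subsets. One copy is kept; all
  contributing subsets are recorded in the group's provenance.
* **Database size for E-values.** D is the number of proteins that are
  unassigned at the start of the pass, reset each level — the quantity a
  search of the unassigned set would use.
* **Search direction and E-value flavour.** Each unassigned sequence is
  compared against each profile and the full-sequence E-value is
  thresholded (the external backend reads the full-sequence E-value and
  the best domain's coordinates from the domain table).
* **Overlapping input groups.** The algorithm needs per-method
  partitions. A protein listed in several groups of one file is kept in
  the largest (earliest on ties) with a warning; singleton groups carry
  no co-membership information and are dropped at load.
* **Isoforms.** One sequence per protein id is assumed; collapsing
  splice variants is upstream preprocessing.

## The builtin profile backend

The default backend is self-contained and exactly testable:

* **Alignment.** Center-star progressive alignment: the center is the
  sequence with the maximal summed pairwise global-alignment score
  (Gotoh affine gaps, BLOSUM62, gap open 11 / extend 1, a gap of length
  L costing open + (L−1)·extend); other rows are merged against the
  center under "once a gap, always a gap". Ties break on protein token
  order, so the alignment is invariant to input order.
* **Profile.** Columns with more than 50% gaps are excluded from the
  match states. Column frequencies use Henikoff position-based sequence
  weights and are mixed with the background by weight
  `2·w/(neff + 1)` (w = `pseudocount_weight`, default 0.5, giving a half
  background at one effective sequence and decaying as the effective
  count `neff` — the mean number of distinct residues per match column —
  grows). Match scores are `log2(freq/background)` in bits, clamped at
  −16; unknown residues score 0. The background defaults to the
  Robinson–Robinson amino-acid frequencies and is overridable.
* **Search.** Smith–Waterman-style local alignment of the sequence
  against the match columns (affine gaps, open 4 / extend 1 bits,
  deterministic traceback preference diagonal → profile-consuming gap →
  sequence-consuming gap), floored at score 0.
* **E-values.** Each profile is calibrated against `n_decoys` (default
  200) residue-shuffled sequences drawn with replacement from the
  current unassigned pool. A Gumbel is fitted by the method of moments
  (λ = π/(σ√6), μ = mean − γ/λ with γ ≈ 0.5772) and
  E(s) = D·(1 − exp(−exp(−λ(s − μ)))). True family members score
  hundreds of bits above the decoy distribution, so the recruitment
  decision is extremely robust to the moment-fit's tail error; the test
  suite nevertheless checks that an unrelated 1000-sequence decoy set
  yields at most a handful of hits at E ≤ 1.

The `external` backend swaps these pieces for an external multiple
aligner (any command with `{in}`/`{out}` placeholders; `mafft` by
default) and HMMER's `hmmbuild`/`hmmsearch` (with `-Z` set to D). It
exposes identical hit semantics — swapping backends changes scores, not
the control flow — and reproduces the method's original toolchain when
those binaries are present. The builtin profile is a position-specific
log-odds model with an empirical null, not a full Plan7 HMM; there is no
forward algorithm and no iterative profile refinement.

## The evaluation suite

* **Jaccard.** Clusterings are expanded to their sets of co-grouped
  protein pairs; similarity is |A∩B|/|A∪B| in [0,1]. Two empty pair
  sets score 1 by convention (documented; unreachable for any loaded
  group set, which holds groups of size ≥ 2 by construction).
* **Fusion/fission.** Predicted groups are restricted to the benchmark
  universe. A reference group overlapped by n predicted groups counts
  n − 1 fissions; the best-matching predicted group (largest overlap,
  ties to the larger group, then lexicographic) causes a fusion when it
  carries more than 3 proteins foreign to the reference group — so 4
  foreign proteins fuse and 3 do not. Fusion is judged on the best match
  only, per-reference-group and binary, and `total_fusions` counts
  affected reference groups. "Accurate" means no fission, no fusion,
  and at least one overlapping predicted group: a reference group the
  prediction missed entirely creates no events but is not accurate.
* **Annotation conservation.** Term information content is
  −ln p(term), with p the fraction of a namespace's annotations falling
  on the term or a descendant (so the root has p = 1, ic = 0, and p is
  monotone along every edge). Term-term similarity is the relevance
  measure: the maximum over common ancestors a of
  (2·ic(a)/(ic(c1)+ic(c2)))·(1 − p(a)) — specific *and* rare ancestors
  score high; a root-only relationship scores 0. Protein pairs are
  scored only when both sides are annotated (unannotated pairs are
  skipped, never zeroed), using the best-match average of the term
  matrix (mean of row maxima and of column maxima, averaged), computed
  per GO namespace annotated on both proteins and averaged over those
  namespaces. Of the published best-match variants we commit to the
  average, and to per-namespace exclusion rather than zeroing, as the
  benchmark's description does not pin either down. EC numbers are
  mapped onto a four-level prefix tree under a virtual root (wildcards
  like `1.2.-.-` annotate the internal node) and scored the same way.
  Only experimental GO evidence (EXP, IDA, IPI, IMP, IGI, IEP) enters
  the store; the filter is applied at load and is idempotent.
* **Sweep.** `parameter_sweep()` reruns the consensus on the cartesian
  grid of the three thresholds under one seed and tabulates the
  fusion/fission aggregates per point.

## The synthetic generator

Real benchmark corpora (multi-proteome downloads plus runs of several
external orthology tools) are out of reach for an offline test suite, so
the package ships a seeded generator that emulates their structure:

* each true group descends from an ancestor drawn i.i.d. from the
  background frequencies; members are per-site substituted copies at a
  per-group rate drawn from `divergence_range` (substitution-only by
  design, so the alignment oracles stay exact — there is an indel-free
  assumption here that real proteomes violate);
* decoy proteins are unrelated random sequences;
* each group carries a distinct leaf of a balanced three-level ontology
  and a synthetic EC serial under a shared prefix, inherited by members
  with probability `annotation_fidelity` (default 0.9);
* method predictions are perturbations of the truth: per group, a split
  at a uniform point with `p_fission` and a merge with a random partner
  with `p_fusion`; per protein, removal with `p_dropout` and relocation
  with `p_relocate`.

Default study conditions — 40 groups, 6 species, 1–2 members per
species per group, sequence length ~N(120, 15²) (a compact but
realistic protein length for desk-scale runs), divergence 0.05–0.5,
error rates (0.1, 0.1, 0.05, 0.02) — are the conditions the test suite
measures under; the acceptance study narrows divergence to 0.05–0.3 so
that within-group identity stays clearly above the twilight zone at
these short lengths. Passing these tests shows the algorithm recovers
planted structure under its own error model; it does not demonstrate
robustness to domain shuffling, fragmentary gene models, or
heterogeneous rates across sites, none of which the generator emulates.

## Numerical and degenerate-input behaviour

* E-values are computed via `expm1`, so scores far above μ underflow to
  E = 0 (assignable) rather than to NaN; scores far below give E = D.
* Calibration refuses decoy pools with zero score variance and pools
  smaller than one sequence; profiles refuse alignments whose every
  column is majority-gap, and backgrounds that do not sum to 1 within
  1e-9.
* `run_meta` stops the level loop early when no unassigned predicted
  protein remains; with a NULL proteome it degrades to pure
  intersection (no expansion stage).
* All tie-breaks (group ordering, assignment, clique choice) reduce to
  the total lexicographic order on (species, protein) tokens, computed
  in the C locale so results do not depend on the session locale.
* Group ids are regenerated on output (`G1…Gk`, descending size then
  smallest member), making write→read round trips canonical.

## Problem sizes used by the test suite

The oracle-equivalence tests run 200 random instances of ≤ 60 proteins
and 3–4 methods against an O(n²) brute-force oracle; the profile tests
check 100 random profile/sequence pairs against a plain-R dynamic
program and recover known Gumbel parameters at n = 5000; the end-to-end
study runs 20 replicates of the 40-group/6-species condition and asks
the consensus to beat every input method's exact-recovery fraction in
at least 18 and the best input's fusion+fission-affected percentage in
at least 15. These sizes keep the full suite around two minutes on one
CPU while leaving each property statistically meaningful.

## Known limitations

* The builtin E-value null is an empirical Gumbel fitted by moments;
  its far tail is approximate. This affects reported E-values, not the
  accept/reject decision at sensible thresholds (true hits sit orders
  of magnitude beyond the decoy range).
* The center-star aligner is O(k²) in group size and less accurate than
  a modern progressive aligner on large, gappy families; the external
  backend exists for exactly that case.
* The BRH input method's two filter thresholds (score ratio and
  alignment-length ratio, both defaulting to 0.5) have no published
  reference values and should be tuned per dataset; the length filter
  is taken relative to the shorter sequence.
* Fission counting ignores unassigned reference-group members: a member
  missing from the prediction creates no extra group and hence no
  fission; coverage is tracked separately through the accuracy flag.
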