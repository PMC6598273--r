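---
title: "Variant-aware off-target detection and activity scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-aware off-target detection and activity scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otvar)
```

## The problem

A CRISPR-Cas9 guide RNA programs the nuclease with a 20-nt spacer. Cleavage
requires (a) a genomic 20-bp *protospacer* sufficiently similar to the
spacer and (b) a 3-bp *PAM* motif (canonically NGG for SpCas9, with NGA as
the most active non-canonical alternative) immediately 3' of it. Sites that
differ from the guide by a handful of mismatches can still be cut —
*off-targets* — and enumerating and ranking them is the central safety
analysis for any genome-editing experiment.

Standard off-target screens scan the *reference* genome. An individual's
genome, however, differs from the reference at millions of positions, and a
variant can create an off-target that is invisible in the reference (by
removing a mismatch or creating a PAM) or destroy one the reference
predicts. `otvar` makes the scan *variant-aware*: it takes a reference
FASTA plus a per-individual VCF, reconstructs the variant-bearing sequence
context, searches both, and reconciles the two hit sets into the
individual's personal off-target landscape.

Throughout the package, protospacer positions are numbered 1..20 from the
PAM-distal end; the *seed region* is positions 9..20, the 12 bp immediately
PAM-proximal, where mismatches suppress activity most strongly. Genomic
intervals are 0-based half-open, as in BED.

## The variant genome

Scanning a whole personalised genome would duplicate almost all of the
reference scan. Instead, only the neighbourhoods that can differ are
materialised. A site spans 23 bp, so a variant can only affect windows
within 22 bp of its footprint:

* Variants whose footprints lie within 22 bp of each other (transitively)
  are chained into one *cluster* (`cluster_variants()`), because a single
  23-mer could co-overlap them.
* Each cluster becomes a *window*: the reference interval from the
  outermost footprints plus 22 bp flanks, clipped at contig edges
  (`build_windows()`).
* **Phased** genotypes (`gt1|gt2`) yield one allele sequence per
  haplotype; identical haplotypes collapse to one sequence.
* **Unphased** heterozygous variants have unknown co-occurrence, so every
  combination is enumerated: with *n* unphased het variants in a cluster
  (hom-alt variants fixed in all), exactly 2^n − 1 sequences are emitted —
  the all-reference combination is excluded because the reference scan
  already covers it (`expand_unphased()`). Clusters beyond `max_het`
  (default 10) heterozygous members would explode combinatorially and fall
  back, with a warning, to one window per variant.

Every allele sequence carries an *offset map* assigning each base a 0-based
reference coordinate; bases inserted relative to the reference lift to
their anchor position. This is what lets hits found in allele sequences be
reported in reference coordinates (`lift_exact` marks hits whose lifted
span is exactly 23 bp).

## Search

`search_guide()` finds every position, on both strands, where the 20-mer
protospacer matches with at most *k* Hamming mismatches (k ≤ 8) and the
adjacent 3-mer matches a PAM motif. Mismatches are counted on the
protospacer only; degenerate PAM positions (IUPAC `N` etc.) are never
counted. A genome `N` never matches a guide base and satisfies only the
PAM character `N`.

The implementation is a pigeonhole seed-and-extend search: the protospacer
is split into k + 1 contiguous near-equal pieces, so any hit with ≤ k
mismatches contains at least one piece exactly. Exact piece occurrences
(via `Biostrings::matchPattern`) seed candidate alignments, which are then
extended across the full 20-mer with vectorised mismatch counting and PAM
gating; candidates reached through several seeds are deduplicated. The
`extend_order` parameter ("lr"/"rl") exercises the contract that extension
direction cannot change the result. The same row-construction code is
driven exhaustively by `brute_force_search()`, a sliding-window scan with
no seeding, which serves as the correctness oracle: the test suite asserts
set-equality of the two outputs across genomes, budgets and PAM sets.

This is a deliberate simplification of bidirectional-index search schemes
used by FM-index tools: for the package's problem sizes (see below) an
in-memory scan over `DNAStringSet`s is simpler, transparent, and fast
enough, while preserving the defining semantics (all-hits enumeration with
≤ k errors, both strands, PAM-gated).

## Merging reference and variant hits

`merge_and_filter()` reconciles the two scans:

1. A reference hit is removed when *no haplotype* of the individual
   carries the reference allele at every variant the hit overlaps: hits
   overlapping a hom-alt variant, or phased heterozygous variants in
   trans, do not exist in that person. A hit overlapping a single het, or
   hets in cis, survives — one haplotype is still fully reference there.
   Unphased het variants have unknown co-occurrence, so the reference
   combination is treated as possible and the hit kept unless a variant is
   hom-alt. (A cruder reading would remove every reference hit in any
   variant region; that breaks the invariant that the merged output equals
   a brute-force scan of the reconstructed haplotypes, which the test
   suite enforces, so the haplotype-consistent rule is used.)
2. Variant hits are lifted through their window's offset map and tagged
   with the IDs of the variants their span overlaps; hits overlapping no
   variant merely duplicate the reference scan and are dropped.
3. Identical lifted hits found through several windows/combinations
   collapse, keeping the union of variant IDs.
4. A guide's declared on-target locus is removed when rediscovered with 0
   mismatches; other perfect matches are kept and flagged (`is_perfect`).

All removal/collapse counts are attached as the `filter_counts` attribute
and satisfy an exact bookkeeping identity checked in the tests.

## Scores

Three scores rank hits:

* **MIT score** (`score_mit()`): with mismatch positions `p1..pm` and the
  20 published position penalties `W`,
  `S = prod(1 − W_p) × 1 / (((19 − d)/19)·4 + 1) × 1/m²`, where `d` is the
  mean pairwise distance between mismatch positions (`d = 19` for a single
  mismatch, the convention of the reference implementations). A perfect
  match scores 1.
* **CFD-style score** (`score_cfd()`): product over mismatched positions
  of a (position, guide base, off-target base) penalty, times a penalty on
  the last two PAM bases. The bundled table
  (`inst/extdata/cfd_penalty_table_synthetic.tsv`) is a clearly labelled
  *synthetic stand-in* generated deterministically with the published
  table's structure (PAM-proximal mismatches penalised more, transversions
  more than transitions, GG PAM = 1): the published supplementary values
  are not redistributable here. Scoring with the published values is a
  drop-in: pass their TSV to `cfd_table(path)`. Missing entries raise an
  explicit error rather than silently scoring 0.
* **Random-Forest activity probability** (`predict_activity()`), below.

Scores always operate on guide-oriented 20-mers (protospacer read 5'→3'
with the PAM 3'), never on raw genome orientation.

## Feature schema and model training

`extract_features()` maps an (on-target 23-mer, off-target 23-mer) pair to
458 numeric features, in three families: mismatch descriptors (total,
seed/non-seed counts, mean pairwise distance, per-position mismatch /
transition / transversion indicators — 64 features), off-target sequence
context (position-specific mono- and dinucleotide one-hots plus GC
content — 385), and on-target relationship (first-PAM-base match and
one-hot of the off-target PAM's 2nd/3rd base — 9). The count differs from
any particular published model because the schema is defined by its
construction, versioned (`feature_schema("1")`), and enforced at
prediction time.

Training (`train_activity_model()`) follows a
detection-concentration-based protocol:

1. **Labelling**: a site is *active* iff its minimal detection
   concentration is ≤ 64 nM (`label_by_concentration()`); never-detected
   sites are inactive. The idea is that sites requiring high enzyme
   concentration in vitro are unlikely to matter in cells.
2. **Mismatch-weighted downsampling** (`sample_inactive()`): inactive
   sites vastly outnumber active ones and have systematically more
   mismatches; a naive sampler would teach the forest to read mismatch
   count alone. Each of 10 seeded repeats keeps all actives and samples,
   without replacement, an inactive subset whose per-mismatch-count
   histogram *equals* the actives'. Undersized bins are filled to
   availability with a warning and recorded shortfall.
3. **Forests**: one `randomForest` per repeat (500 trees,
   `mtry = floor(sqrt(p))`), Gini importance averaged across repeats
   (`average_importance()`).
4. **Backward selection** (`backward_select()`): following the averaged
   ranking, the least important feature is removed one at a time, refitting
   on a representative repeat and recording out-of-bag (OOB) error; the
   selected set minimises OOB error, ties resolved towards the smaller
   set. One feature per step (rather than blocks) is exact and affordable
   at this problem size.
5. **Final model** (`select_final_model()`): every repeat is refit on the
   selected features and the lowest-OOB repeat is packaged as the
   `ot_model` (tidy via `tidy()`/`glance()`, plotted via `autoplot()`).

`cv_auc()` (stratified k-fold, pROC) and `concentration_correlation()`
(mean predicted probability per concentration tier) quantify model
quality; `threshold_curve()`/`apply_cutoff()` implement probability
cut-off filtering of candidate sites.

## What the simulators emulate — and what they do not

All fixtures are synthetic (`sim_genome()`, `sim_plant_sites()`,
`sim_variants()`, `sim_training_table()`), so every ground truth is known
by construction: planted sites record their exact positions, strands and
realised mismatch positions; variants are genome-consistent and
round-trip through VCF; the training table's activity is a *planted rule*
(active iff seed mismatches ≤ 2 and total mismatches ≤ 5), with
concentration tiers derived deterministically from the rule margin.

This emulates the *structure* of real assay data (concentration-tiered
detection, mismatch-skewed class imbalance, canonical/non-canonical PAMs)
but none of its biology: real activity is not a threshold rule, real
genomes are not i.i.d. with fixed GC content, and the synthetic CFD table
is not the published one. Consequently the package's quantitative results
(AUCs near 1, clean tier separation) characterise *correct recovery of a
planted signal*, not expected performance on experimental data. Two
structural consequences show up honestly in the fixtures: with the default
activity rule, inactive sites with few mismatches *cannot exist*, so the
sampler necessarily reports shortfalls unless actives are restricted to
3–5 mismatches (`active_total_range`); and because the planted rule is
perfectly separable, predicted probabilities saturate within the active
tiers, so tier means are asserted to be monotone non-increasing with a
strict active/inactive gap rather than strictly ordered throughout.

## Problem sizes and numerical choices

The package's own choice of scale — genomes of 10–100 kb, tens of variants,
mismatch budgets to 8, training tables of a few hundred sites — keeps every
property checkable against brute force within minutes on one CPU. The
algorithms contain nothing scale-bound except time: the search is linear
in genome length, and windows/clusters are independent.

Determinism is explicit everywhere: all stochastic steps take a seed,
sub-seeds are derived arithmetically (never from consumed RNG state), and
`with_seed()` restores the caller's RNG state, so the same inputs always
produce byte-identical FASTA/VCF/BED/JSON outputs.

## Limitations

* Hamming mismatches only: DNA/RNA bulges (indel alignments between guide
  and target) are not searched.
* The bundled CFD table is synthetic (see above).
* Unphased clusters are capped at `max_het = 10` heterozygous variants
  before falling back to per-variant windows.
* One individual per VCF; multi-sample VCFs are not split.
* Activity labels in the fixtures come from a planted rule; no claim about
  real cleavage activity is made or testable offline.
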