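# otvar — variant-aware CRISPR-Cas9 off-target detection and scoring

CRISPR-Cas9 cuts where its guide RNA's 20-nt spacer pairs with a genomic
20-bp protospacer followed by a 3-bp PAM (canonically NGG, with NGA the
most active alternative). Sites matching the guide with up to ~8
mismatches can still be cleaved — *off-targets* — and enumerating them is
the core safety analysis of any editing experiment. Standard screens scan
the *reference* genome; but an individual's variants can **create**
off-targets the reference hides (removing a mismatch, creating a PAM) or
**destroy** ones it predicts. `otvar` performs the scan against an
individual: reference FASTA + per-individual VCF in, the personal
off-target landscape out, with analytical (MIT, CFD-style) and learned
(Random-Forest) activity scores.

The package is aimed at computational biologists studying guide
specificity and at method developers who need a transparent, fully
testable implementation: every component is exercised against an
independent brute-force oracle on synthetic fixtures whose ground truth is
known by construction.

## What it computes

* **Variant genome** (`build_windows()`): variants within 22 bp of each
  other cluster into windows (a site spans 23 bp, so only these
  neighbourhoods can differ from the reference). Phased genotypes give one
  sequence per haplotype; *n* unphased heterozygous variants give all
  2^n − 1 non-reference combinations. Offset maps lift every base back to
  reference coordinates.
* **Search** (`search_guide()`): all sites on both strands with ≤ k
  protospacer mismatches (k ≤ 8, Hamming) and a PAM from a chosen IUPAC
  motif set. Pigeonhole seed-and-extend over k + 1 exact pieces;
  `brute_force_search()` is the independent oracle.
* **Merge/filter** (`merge_and_filter()`): reference hits that exist on
  no haplotype (hom-alt variants, phased hets in trans) are removed,
  variant hits are lifted and tagged with
  the VCF IDs that created them, duplicates collapse, the declared
  on-target is excluded. The merged set equals a brute-force scan of the
  reconstructed haplotypes — an invariant the test suite enforces.
* **Scores**: MIT position-penalty score
  `S = ∏(1 − W_p) · 1/(((19 − d)/19)·4 + 1) · 1/m²`; CFD-style
  penalty-product score (the bundled penalty table is a labelled synthetic
  stand-in — supply the published TSV via `cfd_table(path)` to score with
  it); and a Random-Forest activity probability over a 458-dimensional
  versioned feature schema.
* **Training** (`train_activity_model()`): concentration-based labelling
  (active ⇔ detected at ≤ 64 nM), mismatch-histogram-matched downsampling
  of inactives in 10 seeded repeats, per-repeat forests, averaged Gini
  importance, backward feature selection by out-of-bag error, lowest-OOB
  final model.

## Worked example

Simulate a 20 kb genome with planted off-target sites, variants placed
near them, and run the pipeline end to end:

```r
library(otvar)
library(dplyr)

spec    <- sim_spec(genome_length = 20000, n_snv = 20, n_indel = 5, seed = 7)
genome  <- sim_genome(spec)
guide   <- sim_guide(8)                      # "TTGCGTGCGCAACGGCCTGT"
planted <- sim_plant_sites(genome, guide, mismatch_counts = c(0, 1, 2, 3),
                           strand_minus_frac = 0.5, seed = 9)
variants <- sim_variants(planted$genome, spec, near_sites = planted$sites$start)

guides_path <- tempfile(fileext = ".txt")
writeLines(paste0(guide, "AGG\tdemo_guide"), guides_path)

run <- run_pipeline(planted$genome, guides_path, vcf = variants,
                    pams = "NGG", max_mismatches = 4)
run
#> <ot_run> 7 hit(s) for 1 guide(s)
#>   reference hits: 4 (removed in variant regions: 1)
#>   variant hits: 4 raw, 4 retained

run$hits |>
  select(contig, start, strand, n_mismatches, source, variant_ids,
         score_mit, score_cfd)
#> # A tibble: 7 × 8
#>   contig start strand n_mismatches source    variant_ids score_mit score_cfd
#>   <chr>  <int> <chr>         <int> <chr>     <list>          <dbl>     <dbl>
#> 1 chr1      41 -                 2 reference <chr [0]>     0.0391      0.370
#> 2 chr1      41 -                 3 variant   <chr [1]>     0.00985     0.331
#> 3 chr1    7400 -                 3 reference <chr [0]>     0.0156      0.629
#> 4 chr1    8786 -                 0 reference <chr [0]>     1           1
#> 5 chr1    8786 -                 1 variant   <chr [1]>     0.385       0.303
#> 6 chr1    8786 -                 2 variant   <chr [2]>     0.0213      0.345
#> 7 chr1   11055 -                 3 variant   <chr [2]>     0.00755     0.220
```

The `variant` rows are this individual's private off-targets, each
carrying the VCF IDs that create it; one reference hit was removed because
a hom-alt variant means that site does not exist in this person. Passing
`out = "prefix"` additionally writes a BED6+ report and a JSON run
summary; `compare_individuals()` contrasts runs across several VCFs.

Training on a synthetic table with a planted activity rule (active ⇔ seed
mismatches ≤ 2 and total ≤ 5; concentration tiers follow the rule margin):

```r
table <- sim_training_table(n_active = 40, n_inactive_pool = 400,
                            active_total_range = c(3, 5), seed = 11)
model <- train_activity_model(table, n_repeats = 5, ntree = 200, seed = 12)
model
#> <ot_model> Random-Forest activity model
#>   features: 1 (schema 1)
#>   trees: 200, repeat 1 of 5, OOB error 0.0000

tidy(model)     # selected features with importance
#> # A tibble: 1 × 2
#>   feature importance
#>   <chr>        <dbl>
#> 1 mm_seed       39.5

concentration_correlation(model, table)
#> # A tibble: 5 × 3
#>   min_active_concentration     n mean_prob
#>                      <dbl> <int>     <dbl>
#> 1                        4     4     1
#> 2                       16    17     1
#> 3                       64    19     1
#> 4                      256    58     0.293
#> 5                       NA   342     0.102
```

Backward selection recovers exactly the feature the planted rule is built
on (`mm_seed`), and predicted activity falls with the concentration tier.
`autoplot(model)` draws the selection curve; `plot_tier_activity()`,
`plot_threshold_tradeoff()` and `plot_mismatch_distribution()` cover the
other diagnostics.

A command-line front end wraps the same pipeline:

```sh
exec/otvar simulate --out demo --length 20000 --seed 7
exec/otvar run --genome demo.fa --guides demo.guides.txt --vcf demo.vcf \
               --pams NGG --max-mm 4 --out demo_run
exec/otvar train --table sites.tsv --out model.rds
```

## Scope and limitations

Mismatch-only search (no DNA/RNA bulges), one individual per VCF, a
synthetic CFD table by default, and synthetic training fixtures whose
activity is a planted rule — the near-perfect AUCs here measure recovery
of that rule, not expected performance on experimental data. See the
methods vignette (`vignettes/variant-aware-offtargets.Rmd`) for the full
model description, parameter rationale and design decisions.
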