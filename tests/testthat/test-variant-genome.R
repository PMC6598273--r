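# Variant-genome construction: clustering, window arithmetic, phased and
# unphased allele expansion, and coordinate lifting.

mk_vars <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(contig = r$contig %||% "chr1", pos = r$pos,
                   id = r$id %||% paste0("v", i), ref = r$ref, alt = r$alt,
                   gt1 = r$gt1 %||% 0L, gt2 = r$gt2 %||% 1L,
                   phased = r$phased %||% TRUE)
  }))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("variants chain into clusters by 23-mer co-occupancy", {
  v <- mk_vars(list(pos = 100L, ref = "A", alt = "C"),
               list(pos = 110L, ref = "A", alt = "C"))
  # positions differ by 10 <= 22: both can sit in one 23-mer
  expect_equal(unique(cluster_variants(v)$cluster), 1L)

  v2 <- mk_vars(list(pos = 100L, ref = "A", alt = "C"),
                list(pos = 200L, ref = "A", alt = "C"))
  expect_equal(cluster_variants(v2)$cluster, c(1L, 2L))

  v3 <- mk_vars(list(pos = 100L, ref = "A", alt = "C"),
                list(pos = 120L, ref = "A", alt = "C"),
                list(pos = 140L, ref = "A", alt = "C"))
  # pairwise gaps of 20 chain transitively even though 100 and 140 are 40 apart
  expect_equal(unique(cluster_variants(v3)$cluster), 1L)

  expect_error(cluster_variants(v2[2:1, ]), "sorted")
})

test_that("windows take 22 bp flanks and insert alleles at the right offset", {
  chars <- rep("T", 1000)
  chars[500] <- "G"
  genome <- tibble::tibble(contig = "chr1", seq = str_of(chars))
  v <- mk_vars(list(pos = 500L, ref = "G", alt = "A", gt1 = 1L, gt2 = 1L))
  w <- build_windows(genome, v)
  expect_equal(w$ref_start, 477L)
  expect_equal(w$ref_end, 522L)
  al <- w$alleles[[1]]
  expect_equal(nrow(al), 1L)
  expect_equal(nchar(al$seq), 45L)
  expect_equal(substr(al$seq, 23, 23), "A")  # offset 22, 0-based
  expect_equal(al$offmap[[1]], 477:521)

  # left flank truncated at the contig edge
  v_edge <- mk_vars(list(pos = 10L, ref = "T", alt = "C"))
  w_edge <- build_windows(genome, v_edge)
  expect_equal(w_edge$ref_start, 0L)
  expect_equal(w_edge$ref_end, 32L)

  # genome/VCF disagreement is a consistency error
  v_bad <- mk_vars(list(pos = 500L, ref = "C", alt = "A"))
  expect_error(build_windows(genome, v_bad), "mismatch")
})

test_that("phased clusters yield one sequence per haplotype", {
  genome <- tibble::tibble(contig = "chr1",
                           seq = str_of(rep(c("A", "C", "G", "T"), 250)))
  v <- mk_vars(list(pos = 500L, ref = "T", alt = "A", gt1 = 0L, gt2 = 1L),
               list(pos = 510L, ref = "C", alt = "G", gt1 = 1L, gt2 = 0L))
  w <- build_windows(genome, v)
  expect_equal(nrow(w), 1L)
  al <- w$alleles[[1]]
  expect_equal(sort(al$label), c("hap1", "hap2"))
  expect_equal(sort(vapply(al$applied_ids, paste, character(1))),
               c("v1", "v2"))
  ref_sub <- substr(genome$seq, w$ref_start + 1, w$ref_end)
  # each haplotype sequence differs from the reference at exactly one position
  for (s in al$seq) {
    expect_equal(sum(chars_of(s) != chars_of(ref_sub)), 1L)
  }

  # identical haplotypes (hom-alt only) collapse to a single allele sequence
  v_hom <- mk_vars(list(pos = 500L, ref = "T", alt = "A", gt1 = 1L, gt2 = 1L))
  expect_equal(nrow(build_windows(genome, v_hom)$alleles[[1]]), 1L)
})

test_that("unphased expansion enumerates non-reference het combinations", {
  for (n in 1:6) {
    cv <- do.call(mk_vars, lapply(seq_len(n), function(i) {
      list(pos = 100L + 3L * i, ref = "A", alt = "C", gt1 = 0L, gt2 = 1L,
           phased = FALSE)
    }))
    expect_length(expand_unphased(cv), 2^n - 1)
  }

  # hom-alt is fixed in every combination, the het toggles
  cv <- mk_vars(list(pos = 100L, ref = "A", alt = "C", gt1 = 1L, gt2 = 1L),
                list(pos = 110L, ref = "A", alt = "G", gt1 = 0L, gt2 = 1L,
                     phased = FALSE))
  combos <- expand_unphased(cv)
  expect_length(combos, 2L)
  expect_true(all(vapply(combos, function(x) "v1" %in% x, logical(1))))
})

test_that("oversized unphased clusters fall back to per-variant windows", {
  genome <- tibble::tibble(contig = "chr1", seq = strrep("A", 400))
  cv <- do.call(mk_vars, lapply(1:5, function(i) {
    list(pos = 100L + 4L * i, ref = "A", alt = "C", gt1 = 0L, gt2 = 1L,
         phased = FALSE)
  }))
  expect_warning(w <- build_windows(genome, cv, max_het = 3), "cap")
  expect_equal(nrow(w$alleles[[1]]), 5L)
})

test_that("allele offset maps lift back to the reference correctly", {
  spec <- sim_spec(genome_length = 6000, n_snv = 12, n_indel = 6, seed = 21)
  genome <- sim_genome(spec)
  vars <- sim_variants(genome, spec)
  w <- build_windows(genome, vars)
  gchars <- chars_of(genome$seq[[1]])
  fp <- tibble::tibble(id = vars$id, s = vars$pos - 1L,
                       e = vars$pos - 1L + nchar(vars$ref))
  for (wi in seq_len(nrow(w))) {
    al <- w$alleles[[wi]]
    for (ai in seq_len(nrow(al))) {
      seq_ch <- chars_of(al$seq[[ai]])
      offmap <- al$offmap[[ai]]
      expect_length(offmap, length(seq_ch))
      applied <- fp[fp$id %in% al$applied_ids[[ai]], ]
      outside <- !vapply(offmap, function(p) {
        any(applied$s <= p & p < applied$e)
      }, logical(1))
      # every base outside an applied variant footprint lifts to a matching
      # reference base
      expect_identical(seq_ch[outside], gchars[offmap[outside] + 1L])
      # no spurious sequences: each allele differs from the reference subsequence
      ref_sub <- substr(genome$seq[[1]], w$ref_start[[wi]] + 1, w$ref_end[[wi]])
      expect_false(identical(al$seq[[ai]], ref_sub))
    }
  }
})

test_that("every variant-overlapping 23-mer of a haplotype occurs in a window", {
  spec <- sim_spec(genome_length = 4000, n_snv = 10, n_indel = 4, seed = 22)
  genome <- sim_genome(spec)
  vars <- sim_variants(genome, spec)
  w <- build_windows(genome, vars)
  all_allele_seqs <- unlist(lapply(w$alleles, function(a) a$seq))
  for (hap in 1:2) {
    ha <- hap_apply(genome$seq[[1]], vars, hap)
    fp <- tibble::tibble(s = vars$pos - 1L,
                         e = vars$pos - 1L + nchar(vars$ref))[
                           vars[[paste0("gt", hap)]] == 1L, ]
    if (nrow(fp) == 0) next
    L <- nchar(ha$seq)
    for (st in seq_len(L - 22L)) {
      span <- ha$offmap[st:(st + 22L)]
      if (!any(fp$s <= max(span) & min(span) < fp$e)) next
      kmer <- substr(ha$seq, st, st + 22L)
      expect_true(any(vapply(all_allele_seqs, grepl, logical(1), pattern = kmer,
                             fixed = TRUE)),
                  label = sprintf("23-mer at hap%d:%d covered", hap, st))
    }
  }
})

test_that("the variant genome writes as multi-FASTA with informative headers", {
  spec <- sim_spec(genome_length = 3000, n_snv = 6, n_indel = 2, seed = 23)
  genome <- sim_genome(spec)
  vars <- sim_variants(genome, spec)
  w <- build_windows(genome, vars)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_variant_genome(w, fa)
  back <- read_genome(fa)
  expect_equal(nrow(back), nrow(variant_genome_sequences(w)))
  expect_true(all(grepl("^chr1:", back$contig)))
})
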