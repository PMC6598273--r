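# Seed-and-extend search vs the brute-force oracle, strand and PAM
# semantics, and the merge/filter step.

mk_variants <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(contig = r$contig %||% "chr1", pos = r$pos,
                   id = r$id %||% paste0("v", i), ref = r$ref, alt = r$alt,
                   gt1 = r$gt1 %||% 1L, gt2 = r$gt2 %||% 1L,
                   phased = r$phased %||% TRUE)
  }))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

mk_hit <- function(start, strand = "+", proto, pam = "AGG", mm = 0L,
                   mpos = integer(0), seqname = "chr1") {
  tibble::tibble(seqname = seqname, start = as.integer(start),
                 end = as.integer(start + 23L), strand = strand,
                 protospacer = proto, pam = pam, n_mismatches = as.integer(mm),
                 mismatch_positions = list(as.integer(mpos)))
}

test_that("a planted site is found with exact coordinates on both strands", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  proto <- chars_of(guide)
  proto[3] <- "A"  # position 3, counted from the PAM-distal end
  site <- paste0(str_of(proto), "TGG")

  plus <- paste0(strrep("T", 50), site, strrep("T", 100))
  idx <- ot_index(c(chr1 = plus))
  for (ord in c("lr", "rl")) {
    h <- search_guide(idx, guide, "NGG", max_mismatches = 1,
                      extend_order = ord)
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, 50L)
    expect_equal(h$end, 73L)
    expect_equal(h$strand, "+")
    expect_equal(h$protospacer, str_of(proto))
    expect_equal(h$pam, "TGG")
    expect_equal(h$n_mismatches, 1L)
    expect_equal(h$mismatch_positions[[1]], 3L)
  }
  # 0 mismatches is too strict for this site
  expect_equal(nrow(search_guide(idx, guide, "NGG", max_mismatches = 0)), 0L)

  # the same site on the minus strand: the genome holds the reverse
  # complement; start stays the leftmost genomic coordinate and the
  # protospacer/mismatch positions are reported in guide orientation
  minus <- paste0(strrep("T", 50), revcomp(site), strrep("T", 100))
  hm <- search_guide(ot_index(c(chr1 = minus)), guide, "NGG",
                     max_mismatches = 1)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$start, 50L)
  expect_equal(hm$strand, "-")
  expect_equal(hm$protospacer, str_of(proto))
  expect_equal(hm$pam, "TGG")
  expect_equal(hm$mismatch_positions[[1]], 3L)
})

test_that("PAM motifs gate hits and an empty PAM set yields no hits", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  seq <- paste0(strrep("T", 40), guide, "CGA", strrep("T", 60))
  idx <- ot_index(c(chr1 = seq))
  expect_equal(nrow(search_guide(idx, guide, "NGG", 0)), 0L)
  h <- search_guide(idx, guide, c("NGG", "NGA"), 0)
  expect_equal(nrow(h), 1L)
  expect_equal(h$pam, "CGA")
  expect_equal(nrow(search_guide(idx, guide, character(0), 3)), 0L)
})

test_that("genome N never matches the guide and satisfies only PAM N", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  with_n <- chars_of(guide)
  with_n[7] <- "N"
  seq <- paste0(strrep("T", 30), str_of(with_n), "NGG", strrep("T", 30))
  idx <- ot_index(c(chr1 = seq))
  # N in the protospacer is a mismatch even against its own guide base
  expect_equal(nrow(search_guide(idx, guide, "NGG", 0)), 0L)
  h <- search_guide(idx, guide, "NGG", 1)
  expect_equal(h$n_mismatches, 1L)
  expect_equal(h$mismatch_positions[[1]], 7L)
  # genome N at a PAM position satisfies motif N but not motif G
  seq2 <- paste0(strrep("T", 30), guide, "TNG", strrep("T", 30))
  expect_equal(nrow(search_guide(ot_index(c(chr1 = seq2)), guide, "NGG", 0)),
               0L)
})

test_that("indexed search reproduces the brute-force oracle exactly", {
  for (seed in 1:4) {
    spec <- sim_spec(genome_length = 4000, seed = 100 + seed)
    guide <- sim_guide(200 + seed)
    pl <- sim_plant_sites(sim_genome(spec), guide,
                          mismatch_counts = c(0, 1, 3, 5, 8),
                          pams = "NGG", strand_minus_frac = 0.5,
                          seed = 300 + seed)
    idx <- ot_index(pl$genome)
    for (k in c(0L, 3L, 8L)) {
      oracle <- brute_force_search(pl$genome, guide, c("NGG", "NGA"), k)
      expect_identical(search_guide(idx, guide, c("NGG", "NGA"), k), oracle)
      expect_identical(search_guide(idx, guide, c("NGG", "NGA"), k,
                                    extend_order = "rl"), oracle)
    }
  }
})

test_that("hit sets grow monotonically with the mismatch budget", {
  spec <- sim_spec(genome_length = 6000, seed = 31)
  guide <- sim_guide(32)
  pl <- sim_plant_sites(sim_genome(spec), guide,
                        mismatch_counts = c(2, 4, 6, 8), seed = 33)
  idx <- ot_index(pl$genome)
  keys <- lapply(c(2L, 5L, 8L), function(k) {
    hit_set(search_guide(idx, guide, "NGG", k))
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})

test_that("reference hits in hom-alt regions are removed, het ones retained", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  vars <- mk_variants(
    list(pos = 110L, ref = "A", alt = "C", gt1 = 1L, gt2 = 1L),  # hom-alt
    list(pos = 310L, ref = "A", alt = "C", gt1 = 0L, gt2 = 1L))  # het
  ref_hits <- dplyr::bind_rows(
    mk_hit(100, proto = guide),   # overlaps hom-alt footprint: remove
    mk_hit(300, proto = guide),   # overlaps het footprint: keep
    mk_hit(500, proto = guide))   # no variant nearby: keep
  out <- merge_and_filter(ref_hits, NULL, NULL, vars)
  expect_equal(out$start, c(300L, 500L))
  expect_true(all(out$source == "reference"))
  counts <- attr(out, "filter_counts")
  expect_equal(counts$n_ref_in, 3L)
  expect_equal(counts$n_ref_removed_variant_region, 1L)
})

test_that("het pairs in trans remove a reference hit, cis pairs keep it", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  hit <- mk_hit(100, proto = guide)
  # trans: hap1 carries v1, hap2 carries v2 -- no haplotype is fully
  # reference across the hit, so the reference-allele site does not exist
  trans <- mk_variants(list(pos = 105L, ref = "A", alt = "C",
                            gt1 = 1L, gt2 = 0L),
                       list(pos = 115L, ref = "A", alt = "C",
                            gt1 = 0L, gt2 = 1L))
  out_trans <- merge_and_filter(hit, NULL, NULL, trans)
  expect_equal(nrow(out_trans), 0L)
  expect_equal(attr(out_trans, "filter_counts")$n_ref_removed_variant_region,
               1L)
  # cis: both variants sit on hap2, hap1 is reference throughout
  cis <- mk_variants(list(pos = 105L, ref = "A", alt = "C",
                          gt1 = 0L, gt2 = 1L),
                     list(pos = 115L, ref = "A", alt = "C",
                          gt1 = 0L, gt2 = 1L))
  expect_equal(nrow(merge_and_filter(hit, NULL, NULL, cis)), 1L)
  # unphased het pair: co-occurrence unknown, the reference combination is
  # possible, so the hit is retained
  unph <- mk_variants(list(pos = 105L, ref = "A", alt = "C",
                           gt1 = 1L, gt2 = 0L, phased = FALSE),
                      list(pos = 115L, ref = "A", alt = "C",
                           gt1 = 0L, gt2 = 1L, phased = FALSE))
  expect_equal(nrow(merge_and_filter(hit, NULL, NULL, unph)), 1L)
})

test_that("variant hits lift to reference coordinates through a real window", {
  set.seed(41)
  guide <- sim_guide(41)
  proto <- chars_of(guide)
  alt_base <- setdiff(c("A", "C", "G", "T"), proto[10])[[1]]
  site <- proto
  site[10] <- alt_base  # the reference carries a 1-mismatch site
  bg <- function(n) str_of(sample(c("A", "C", "T"), n, replace = TRUE))
  genome <- tibble::tibble(
    contig = "chr1",
    seq = paste0(bg(200), str_of(site), "AGG", bg(300)))
  # the SNV restores the guide base, creating a perfect site at start 200
  vars <- mk_variants(list(pos = 210L, ref = alt_base, alt = proto[10],
                           gt1 = 1L, gt2 = 1L))
  w <- build_windows(genome, vars)
  vg <- variant_genome_sequences(w)
  var_raw <- search_guide(ot_index(setNames(vg$seq, vg$name)), guide, "NGG", 0)
  var_hits <- dplyr::left_join(var_raw, vg[, c("name", "window_row",
                                               "allele_row")],
                               by = c(seqname = "name"))
  ref_hits <- search_guide(ot_index(genome), guide, "NGG", 1)
  expect_equal(ref_hits$start, 200L)  # reference scan sees the 1-mm site

  out <- merge_and_filter(ref_hits, var_hits, w, vars)
  # hom-alt: the reference-allele site does not exist in this individual
  expect_equal(nrow(out), 1L)
  expect_equal(out$source, "variant")
  expect_equal(out$start, 200L)
  expect_equal(out$end, 223L)
  expect_equal(out$n_mismatches, 0L)
  expect_true(out$is_perfect)
  expect_true(out$lift_exact)
  expect_equal(out$variant_ids[[1]], "v1")

  # with a het genotype the reference-allele site survives alongside
  vars_het <- mk_variants(list(pos = 210L, ref = alt_base, alt = proto[10],
                               gt1 = 0L, gt2 = 1L))
  w2 <- build_windows(genome, vars_het)
  vg2 <- variant_genome_sequences(w2)
  vr2 <- search_guide(ot_index(setNames(vg2$seq, vg2$name)), guide, "NGG", 0)
  vh2 <- dplyr::left_join(vr2, vg2[, c("name", "window_row", "allele_row")],
                          by = c(seqname = "name"))
  out2 <- merge_and_filter(ref_hits, vh2, w2, vars_het)
  expect_equal(nrow(out2), 2L)
  expect_setequal(out2$source, c("reference", "variant"))
  expect_equal(sort(out2$n_mismatches), c(0L, 1L))
})

test_that("variant hits that overlap no variant footprint are dropped", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  vars <- mk_variants(list(pos = 101L, ref = "A", alt = "C"))
  windows <- tibble::tibble(
    contig = "chr1", ref_start = 78L, ref_end = 160L,
    alleles = list(tibble::tibble(
      label = "hap1", seq = NA_character_, offmap = list(78:159),
      applied_ids = list("v1"))))
  hit_over <- mk_hit(10, proto = guide)    # offmap[11..33] = 88..110: overlaps
  hit_away <- mk_hit(40, proto = guide)    # offmap[41..63] = 118..140: no
  vh <- dplyr::bind_rows(hit_over, hit_away)
  vh$window_row <- 1L
  vh$allele_row <- 1L
  out <- merge_and_filter(empty_hits_tbl(), vh, windows, vars)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 88L)
  expect_equal(attr(out, "filter_counts")$n_var_dropped_no_variant, 1L)
})

test_that("duplicate variant hits collapse with the union of variant ids", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  vars <- mk_variants(list(pos = 101L, ref = "A", alt = "C"),
                      list(pos = 105L, ref = "T", alt = "G"))
  al1 <- tibble::tibble(label = "c1", seq = NA_character_,
                        offmap = list(78:160), applied_ids = list("v1"))
  al2 <- tibble::tibble(label = "c2", seq = NA_character_,
                        offmap = list(78:160), applied_ids = list(c("v1", "v2")))
  windows <- tibble::tibble(contig = "chr1", ref_start = 78L, ref_end = 161L,
                            alleles = list(dplyr::bind_rows(al1, al2)))
  # the same lifted locus found through two combinations
  vh <- dplyr::bind_rows(mk_hit(10, proto = guide), mk_hit(10, proto = guide))
  vh$window_row <- 1L
  vh$allele_row <- c(1L, 2L)
  out <- merge_and_filter(empty_hits_tbl(), vh, windows, vars)
  expect_equal(nrow(out), 1L)
  expect_equal(out$variant_ids[[1]], c("v1", "v2"))
  expect_equal(attr(out, "filter_counts")$n_var_collapsed, 1L)
})

test_that("the declared on-target locus is removed, other perfect hits flagged", {
  guide <- "ATGCCGGATTCAGACTGCAA"
  vars <- mk_variants(list(pos = 900L, ref = "A", alt = "C"))
  ref_hits <- dplyr::bind_rows(
    mk_hit(100, proto = guide, mm = 0L),
    mk_hit(400, proto = guide, mm = 0L),
    mk_hit(600, proto = guide, mm = 2L, mpos = c(3L, 9L)))
  ref_hits$guide_id <- "g1"
  on_targets <- tibble::tibble(guide_id = "g1", contig = "chr1",
                               start = 100L, strand = "+")
  out <- merge_and_filter(ref_hits, NULL, NULL, vars, on_targets = on_targets)
  expect_equal(out$start, c(400L, 600L))
  expect_equal(out$is_perfect, c(TRUE, FALSE))
  expect_equal(attr(out, "filter_counts")$n_on_target_removed, 1L)
})
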