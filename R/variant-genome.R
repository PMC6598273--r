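# Individualised "variant genome": variant-bearing subsequences with 22 bp
# flanks, one sequence per haplotype (phased) or per variant combination
# (unphased), each with an offset map back to reference coordinates.

FLANK <- 22L  # one base short of a full 23-mer site: any site overlapping a
              # variant lies entirely inside the window

#' Cluster variants that could share a single off-target site
#'
#' Two variants join the same cluster when the distance from the start of the
#' later one to the last reference base of the earlier one is at most
#' `max_gap` bases, chained transitively. With the default of 22 this is
#' exactly "co-occupiable by one 23-mer": two SNVs 22 bp apart can sit in one
#' site, 23 bp apart cannot.
#'
#' @param variants Variants tibble sorted by (`contig`, `pos`).
#' @param max_gap Maximum chaining distance in bases.
#' @return The input tibble with an integer `cluster` column.
#' @export
cluster_variants <- function(variants, max_gap = FLANK) {
  if (nrow(variants) == 0L) {
    return(dplyr::mutate(variants, cluster = integer(0)))
  }
  ord <- order(variants$contig, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    abort("variants must be sorted by (contig, pos)")
  }
  cluster <- integer(nrow(variants))
  cl <- 0L
  prev_contig <- ""
  prev_last <- -Inf
  for (i in seq_len(nrow(variants))) {
    start0 <- variants$pos[[i]] - 1L
    last0 <- start0 + nchar(variants$ref[[i]]) - 1L
    if (variants$contig[[i]] != prev_contig || start0 - prev_last > max_gap) {
      cl <- cl + 1L
      prev_last <- last0
    } else {
      prev_last <- max(prev_last, last0)
    }
    cluster[[i]] <- cl
    prev_contig <- variants$contig[[i]]
  }
  dplyr::mutate(variants, cluster = cluster)
}

# Apply a set of variants to the reference interval [start0, end0) of a
# contig. Returns the modified sequence, an offset map giving the 0-based
# reference coordinate of every emitted base (bases inside an insertion lift
# to their anchor, the last reference base of the REF allele), and a parallel
# variant-id map (NA for reference bases).
apply_variants_to_interval <- function(chars, start0, end0, vars) {
  out_chars <- character(0)
  out_map <- integer(0)
  out_ids <- character(0)
  cursor <- start0  # 0-based next reference position to copy
  if (nrow(vars) > 0L) {
    vars <- vars[order(vars$pos), , drop = FALSE]
    for (i in seq_len(nrow(vars))) {
      vstart0 <- vars$pos[[i]] - 1L
      reflen <- nchar(vars$ref[[i]])
      if (vstart0 < cursor) abort("overlapping variants in one combination")
      if (cursor < vstart0) {
        idx <- (cursor + 1L):vstart0  # 1-based into chars
        out_chars <- c(out_chars, chars[idx])
        out_map <- c(out_map, (cursor):(vstart0 - 1L))
        out_ids <- c(out_ids, rep(NA_character_, length(idx)))
      }
      ref_here <- c2s(chars[(vstart0 + 1L):(vstart0 + reflen)])
      if (!identical(ref_here, vars$ref[[i]])) {
        abort(sprintf("REF allele of %s (%s) does not match genome (%s): genome/VCF mismatch",
                      vars$id[[i]], vars$ref[[i]], ref_here))
      }
      alt_chars <- s2c(vars$alt[[i]])
      alt_map <- vstart0 + pmin(seq_along(alt_chars) - 1L, reflen - 1L)
      out_chars <- c(out_chars, alt_chars)
      out_map <- c(out_map, alt_map)
      out_ids <- c(out_ids, rep(vars$id[[i]], length(alt_chars)))
      cursor <- vstart0 + reflen
    }
  }
  if (cursor < end0) {
    out_chars <- c(out_chars, chars[(cursor + 1L):end0])
    out_map <- c(out_map, cursor:(end0 - 1L))
    out_ids <- c(out_ids, rep(NA_character_, end0 - cursor))
  }
  list(seq = c2s(out_chars), offmap = out_map, idmap = out_ids)
}

variant_footprints <- function(vars) {
  tibble::tibble(id = vars$id, start0 = vars$pos - 1L,
                 end0 = vars$pos - 1L + nchar(vars$ref))
}

# Non-empty-to-full subset enumeration of het variants; hom-alts are fixed in
# every combination; the all-reference combination is never emitted.
het_combinations <- function(het_ids, has_hom) {
  n <- length(het_ids)
  combos <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- het_ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(sel) == 0L && !has_hom) next  # all-reference: covered by the reference scan
    combos[[length(combos) + 1L]] <- sel
  }
  combos
}

#' Expand a cluster of unphased heterozygous variants
#'
#' Enumerates every combination of the cluster's heterozygous variants
#' (hom-alt variants fixed in all combinations); the all-reference
#' combination is not emitted because the reference-genome scan already
#' covers it. A window with `n` unphased het variants and no hom-alt member
#' therefore yields exactly `2^n - 1` combination sequences.
#'
#' @param cluster_vars Variants tibble for one cluster.
#' @return A list of character vectors of variant ids, one per combination.
#' @export
expand_unphased <- function(cluster_vars) {
  het <- cluster_vars$gt1 != cluster_vars$gt2
  hom <- cluster_vars$gt1 == 1L & cluster_vars$gt2 == 1L
  combos <- het_combinations(cluster_vars$id[het], any(hom))
  lapply(combos, function(sel) c(cluster_vars$id[hom], sel))
}

#' Build variant windows with allele sequences
#'
#' For each cluster of variants, extracts the reference interval spanning the
#' outermost variant footprints plus 22 bp flanks (clipped at contig edges)
#' and emits the variant-bearing allele sequences: one per haplotype when all
#' heterozygous members are phased, otherwise one per combination of
#' heterozygous variants (see [expand_unphased()]). Every allele sequence
#' carries an offset map lifting each of its bases to a 0-based reference
#' coordinate (insertion bases lift to their anchor) so hits can be reported
#' in reference coordinates.
#'
#' @param genome Genome tibble.
#' @param variants Variants tibble (clustered or not; clustering is applied
#'   with `max_gap` if the `cluster` column is absent).
#' @param max_gap Clustering gap, see [cluster_variants()].
#' @param max_het Combination cap: clusters with more unphased heterozygous
#'   variants than this are processed per single variant with a warning.
#' @return A windows tibble: `contig`, `ref_start`, `ref_end` (0-based
#'   half-open), `variant_ids` (list), and `alleles`, a list-column of
#'   tibbles with `label`, `seq`, `applied_ids` (list), `offmap` (list).
#' @export
build_windows <- function(genome, variants, max_gap = FLANK, max_het = 10L) {
  genome <- as_genome_tbl(genome)
  if (!"cluster" %in% names(variants)) {
    variants <- cluster_variants(variants, max_gap)
  }
  if (nrow(variants) == 0L) {
    return(tibble::tibble(contig = character(), ref_start = integer(),
                          ref_end = integer(), variant_ids = list(),
                          alleles = list()))
  }
  chars_by_contig <- setNames(lapply(genome$seq, s2c), genome$contig)
  recs <- lapply(split(variants, variants$cluster), function(cv) {
    contig <- cv$contig[[1]]
    chars <- chars_by_contig[[contig]]
    if (is.null(chars)) abort(sprintf("contig %s not found in genome", contig))
    clen <- length(chars)
    fp <- variant_footprints(cv)
    w_start <- max(0L, min(fp$start0) - FLANK)
    w_end <- min(clen, max(fp$end0) + FLANK)
    het <- cv$gt1 != cv$gt2
    unphased_het <- het & !cv$phased
    combo_sets <- list()
    labels <- character(0)
    if (any(unphased_het)) {
      if (sum(het) > max_het) {
        warn(sprintf("cluster at %s:%d has %d het variants (cap %d); processing per single variant",
                     contig, cv$pos[[1]], sum(het), max_het))
        combo_sets <- as.list(cv$id)
        labels <- cv$id
      } else {
        combo_sets <- expand_unphased(cv)
        labels <- vapply(combo_sets, paste, character(1), collapse = "+")
      }
    } else {
      for (h in 1:2) {
        ids <- cv$id[cv[[paste0("gt", h)]] == 1L]
        if (length(ids) == 0L) next
        combo_sets[[length(combo_sets) + 1L]] <- ids
        labels <- c(labels, paste0("hap", h))
      }
      # identical haplotypes (e.g. hom-alt only) collapse to one sequence
      keys <- vapply(combo_sets, paste, character(1), collapse = "+")
      keep <- !duplicated(keys)
      combo_sets <- combo_sets[keep]
      labels <- labels[keep]
      labels[keys[keep] %in% keys[!keep]] <-
        paste0(labels[keys[keep] %in% keys[!keep]], "+hap2")
    }
    alleles <- dplyr::bind_rows(lapply(seq_along(combo_sets), function(i) {
      sel <- cv[cv$id %in% combo_sets[[i]], , drop = FALSE]
      # overlapping variants are mutually exclusive within a combination
      fp_sel <- variant_footprints(sel)
      if (nrow(fp_sel) > 1L) {
        o <- order(fp_sel$start0)
        if (any(fp_sel$start0[o][-1L] < head(fp_sel$end0[o], -1L))) return(NULL)
      }
      ap <- apply_variants_to_interval(chars, w_start, w_end, sel)
      tibble::tibble(label = labels[[i]], seq = ap$seq,
                     applied_ids = list(sel$id), offmap = list(ap$offmap))
    }))
    ref_sub <- c2s(chars[(w_start + 1L):w_end])
    alleles <- alleles[alleles$seq != ref_sub, , drop = FALSE]
    tibble::tibble(contig = contig, ref_start = w_start, ref_end = w_end,
                   variant_ids = list(cv$id), alleles = list(alleles))
  })
  out <- dplyr::bind_rows(recs)
  dplyr::arrange(out, .data$contig, .data$ref_start)
}

#' Flatten variant windows into a searchable sequence table
#'
#' @param windows Windows tibble from [build_windows()].
#' @return A tibble with one row per allele sequence: `name`, `seq`,
#'   `window_row`, `allele_row`.
#' @export
variant_genome_sequences <- function(windows) {
  recs <- lapply(seq_len(nrow(windows)), function(w) {
    al <- windows$alleles[[w]]
    if (is.null(al) || nrow(al) == 0L) return(NULL)
    tibble::tibble(
      name = sprintf("%s:%d-%d|%s", windows$contig[[w]], windows$ref_start[[w]],
                     windows$ref_end[[w]], al$label),
      seq = al$seq, window_row = w, allele_row = seq_len(nrow(al)))
  })
  dplyr::bind_rows(recs)
}

#' Write the variant genome as multi-FASTA
#'
#' Headers encode contig, reference interval and the variant combination.
#'
#' @param windows Windows tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_genome <- function(windows, path) {
  vs <- variant_genome_sequences(windows)
  ids <- vapply(seq_len(nrow(vs)), function(i) {
    paste(windows$alleles[[vs$window_row[[i]]]]$applied_ids[[vs$allele_row[[i]]]],
          collapse = ";")
  }, character(1))
  ss <- Biostrings::DNAStringSet(setNames(vs$seq, paste0(vs$name, "|", ids)))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
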