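# Synthetic-data simulator: genomes, planted off-target sites, variants and
# labelled training tables. Everything downstream of this module is exercised
# against these fixtures, so generation is fully deterministic under a seed.

#' Simulation specification
#'
#' Bundles the knobs for the synthetic genome/variant generator and validates
#' them once.
#'
#' @param genome_length Genome length in bases (>= 100).
#' @param gc_content Target GC fraction in `[0, 1]`.
#' @param n_snv,n_indel Number of SNVs / short INDELs to simulate.
#' @param indel_max_len Maximum inserted/deleted length in bases (<= 5 by
#'   default; the search model is mismatch-only, so longer events are of no
#'   use to the fixtures).
#' @param phased Emit phased (`|`) or unphased (`/`) genotypes.
#' @param seed Integer RNG seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @return An object of class `ot_sim_spec`.
#' @export
sim_spec <- function(genome_length = 10000L, gc_content = 0.41, n_snv = 20L,
                     n_indel = 5L, indel_max_len = 5L, phased = TRUE,
                     seed = 1L) {
  if (genome_length < 100) abort("genome_length must be >= 100")
  if (gc_content < 0 || gc_content > 1) abort("gc_content must lie in [0, 1]")
  if (n_snv < 0 || n_indel < 0) abort("variant counts must be non-negative")
  if (indel_max_len < 1) abort("indel_max_len must be >= 1")
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_snv = as.integer(n_snv),
                 n_indel = as.integer(n_indel),
                 indel_max_len = as.integer(indel_max_len),
                 phased = isTRUE(phased), seed = as.integer(seed)),
            class = "ot_sim_spec")
}

#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_content / 2`.
#'
#' @param spec An [sim_spec()] object.
#' @param contig Contig name for the single simulated contig.
#' @return A genome tibble (`contig`, `seq`).
#' @export
sim_genome <- function(spec, contig = "chr1") {
  stopifnot(inherits(spec, "ot_sim_spec"))
  probs <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
             G = spec$gc_content / 2, T = (1 - spec$gc_content) / 2)
  seq <- with_seed(spec$seed, {
    c2s(sample(DNA_BASES, spec$genome_length, replace = TRUE, prob = probs))
  })
  tibble::tibble(contig = contig, seq = seq)
}

#' Generate a random 20-mer guide
#'
#' @param seed RNG seed.
#' @return A 20-character protospacer sequence.
#' @export
sim_guide <- function(seed = 1L) {
  with_seed(seed, c2s(sample(DNA_BASES, 20L, replace = TRUE)))
}

# Realise one concrete PAM from an IUPAC motif (never emits N).
realize_pam <- function(motif) {
  c2s(vapply(s2c(motif), function(ch) {
    opts <- setdiff(iupac_allowed(ch), "N")
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)))
}

#' Plant off-target sites for a guide into a genome
#'
#' Each planted site is a 23-mer (protospacer + PAM) written into the genome
#' at a random non-overlapping position, with exactly the requested number of
#' protospacer mismatches against the guide. Minus-strand sites are written
#' as the reverse complement so the site reads guide-like on the minus
#' strand. Windows containing `N` are never used.
#'
#' @param genome Genome tibble.
#' @param guide 20-mer protospacer.
#' @param mismatch_counts Integer vector, one entry per site, each in 0..8.
#' @param pams Character vector of IUPAC PAM motifs to draw from.
#' @param strand_minus_frac Fraction of sites planted on the minus strand.
#' @param seed RNG seed.
#' @return A list with `genome` (edited genome tibble) and `sites`, a tibble
#'   of planted-site records (`contig`, `start` 0-based, `strand`,
#'   `protospacer`, `pam`, `n_mismatches`, `mismatch_positions` list-column,
#'   1-based from the PAM-distal end).
#' @export
sim_plant_sites <- function(genome, guide, mismatch_counts, pams = "NGG",
                            strand_minus_frac = 0, seed = 1L) {
  genome <- as_genome_tbl(genome)
  assert_guide20(guide)
  if (any(mismatch_counts < 0 | mismatch_counts > 8)) {
    abort("mismatch_counts must lie in 0..8")
  }
  n <- length(mismatch_counts)
  gchars <- s2c(guide)
  with_seed(seed, {
    chars <- s2c(genome$seq[[1]])
    L <- length(chars)
    if (L < 23L * n * 2L) abort("genome too short to place requested sites")
    taken <- integer(0)
    recs <- vector("list", n)
    strands <- ifelse(runif(n) < strand_minus_frac, "-", "+")
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:2000) {
        st <- sample.int(L - 22L, 1L)  # 1-based start
        span <- st:(st + 22L)
        if (length(intersect(span, taken)) > 0L) next
        if (any(chars[span] == "N")) next
        placed <- TRUE
        break
      }
      if (!placed) abort("could not place non-overlapping sites; genome too crowded")
      m <- mismatch_counts[[i]]
      proto <- gchars
      mm_pos <- sort(sample.int(20L, m))
      for (p in mm_pos) proto[p] <- sample(setdiff(DNA_BASES, gchars[p]), 1L)
      pam <- realize_pam(sample(pams, 1L))
      site <- c2s(c(proto, s2c(pam)))
      written <- if (strands[[i]] == "-") revcomp(site) else site
      chars[span] <- s2c(written)
      taken <- c(taken, span)
      recs[[i]] <- tibble::tibble(contig = genome$contig[[1]], start = st - 1L,
                                  strand = strands[[i]], protospacer = c2s(proto),
                                  pam = pam, n_mismatches = as.integer(m),
                                  mismatch_positions = list(mm_pos))
    }
    list(genome = tibble::tibble(contig = genome$contig[[1]], seq = c2s(chars)),
         sites = dplyr::bind_rows(recs))
  })
}

#' Simulate variants over a genome
#'
#' Generates SNVs and short INDELs whose REF alleles are consistent with the
#' genome. When `near_sites` is given, `near_frac` of the variants are placed
#' within 22 bp of those positions so that variant windows intersect planted
#' off-target loci.
#'
#' @param genome Genome tibble.
#' @param spec [sim_spec()] controlling counts, INDEL length and phasing.
#' @param near_sites Optional integer vector of 0-based positions to place a
#'   fraction of variants near.
#' @param near_frac Fraction of variants placed near `near_sites`.
#' @return A variants tibble (`contig`, `pos` 1-based VCF convention, `id`,
#'   `ref`, `alt`, `gt1`, `gt2`, `phased`).
#' @export
sim_variants <- function(genome, spec, near_sites = NULL, near_frac = 0.5) {
  genome <- as_genome_tbl(genome)
  stopifnot(inherits(spec, "ot_sim_spec"))
  chars <- s2c(genome$seq[[1]])
  L <- length(chars)
  n_total <- spec$n_snv + spec$n_indel
  if (n_total == 0L) {
    return(empty_variants_tbl())
  }
  with_seed(derive_seed(spec$seed, 17L), {
    occupied <- integer(0)
    pick_pos <- function(width, near) {
      for (try in 1:5000) {
        if (near && length(near_sites) > 0L) {
          anchor <- near_sites[[sample.int(length(near_sites), 1L)]]
          pos <- anchor + sample(-22:22, 1L) + 1L  # 1-based
        } else {
          pos <- sample.int(L - width - 1L, 1L) + 1L
        }
        if (pos < 2L || pos + width > L) next
        span <- pos:(pos + width - 1L)
        if (length(intersect(span, occupied)) > 0L) next
        if (any(chars[span] == "N")) next
        occupied <<- c(occupied, span)
        return(pos)
      }
      abort("could not place variant without overlap")
    }
    kinds <- c(rep("snv", spec$n_snv), rep("indel", spec$n_indel))
    near_flags <- rep(FALSE, n_total)
    if (!is.null(near_sites) && length(near_sites) > 0L) {
      near_flags[seq_len(ceiling(near_frac * n_total))] <- TRUE
    }
    recs <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      if (kinds[[i]] == "snv") {
        pos <- pick_pos(1L, near_flags[[i]])
        ref <- chars[pos]
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
      } else {
        len <- sample.int(spec$indel_max_len, 1L)
        if (runif(1) < 0.5) {  # insertion
          pos <- pick_pos(1L, near_flags[[i]])
          ref <- chars[pos]
          alt <- c2s(c(ref, sample(DNA_BASES, len, replace = TRUE)))
        } else {               # deletion
          pos <- pick_pos(len + 1L, near_flags[[i]])
          ref <- c2s(chars[pos:(pos + len)])
          alt <- chars[pos]
        }
      }
      gt <- if (spec$phased) sample(c("0|1", "1|0", "1|1"), 1L)
            else sample(c("0/1", "1/1"), 1L)
      al <- as.integer(s2c(gsub("[|/]", "", gt)))
      recs[[i]] <- tibble::tibble(contig = genome$contig[[1]], pos = pos,
                                  id = NA_character_, ref = ref, alt = alt,
                                  gt1 = al[[1]], gt2 = al[[2]],
                                  phased = spec$phased)
    }
    out <- dplyr::arrange(dplyr::bind_rows(recs), .data$contig, .data$pos)
    out$id <- paste0("var", seq_len(nrow(out)))
    # consistency check against the genome
    ok <- vapply(seq_len(nrow(out)), function(i) {
      identical(c2s(chars[out$pos[[i]]:(out$pos[[i]] + nchar(out$ref[[i]]) - 1L)]),
                out$ref[[i]])
    }, logical(1))
    if (!all(ok)) abort("internal: simulated REF allele mismatches genome")
    out
  })
}

empty_variants_tbl <- function() {
  tibble::tibble(contig = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(), gt1 = integer(),
                 gt2 = integer(), phased = logical())
}

#' Write variants to a VCF v4.2 file
#'
#' @param variants Variants tibble as produced by [sim_variants()].
#' @param path Output path.
#' @param contig_lengths Named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=otvar-simulator",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "SAMPLE1", sep = "\t"))
  sep <- ifelse(variants$phased, "|", "/")
  gt <- paste0(variants$gt1, sep, variants$gt2)
  body <- paste(variants$contig, variants$pos, variants$id, variants$ref,
                variants$alt, ".", "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Parses the first sample's GT field, splits multi-allelic records into
#' bi-allelic variants, and drops hom-ref genotypes (they carry no sequence
#' change).
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A variants tibble (`contig`, `pos`, `id`, `ref`, `alt`, `gt1`,
#'   `gt2`, `phased`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variants_tbl())
  gt_raw <- if (ncol(v@gt) >= 2L) {
    vapply(strsplit(v@gt[, 2L], ":", fixed = TRUE), `[[`, character(1), 1L)
  } else rep("1|1", nrow(fix))
  recs <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[[i]], ",", fixed = TRUE)[[1]]
    phased <- grepl("|", gt_raw[[i]], fixed = TRUE)
    alleles <- suppressWarnings(as.integer(strsplit(gt_raw[[i]], "[|/]")[[1]]))
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    alleles[is.na(alleles)] <- 0L
    base_id <- if (!is.na(fix$ID[[i]]) && fix$ID[[i]] != ".") fix$ID[[i]]
               else paste0("line", i)
    sub <- lapply(seq_along(alts), function(j) {
      g1 <- as.integer(alleles[[1]] == j)
      g2 <- as.integer(alleles[[2]] == j)
      if (g1 == 0L && g2 == 0L) return(NULL)  # hom-ref for this allele
      tibble::tibble(contig = fix$CHROM[[i]], pos = as.integer(fix$POS[[i]]),
                     id = if (length(alts) > 1L) paste0(base_id, "_", j) else base_id,
                     ref = toupper(fix$REF[[i]]), alt = toupper(alts[[j]]),
                     gt1 = g1, gt2 = g2, phased = phased)
    })
    recs[[i]] <- dplyr::bind_rows(sub)
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) return(empty_variants_tbl())
  dplyr::arrange(out, .data$contig, .data$pos)
}

# training-table simulation ---------------------------------------------------

# Mutate `m_seed` seed positions (9..20) and `m_nonseed` non-seed positions
# (1..8) of a guide; returns the off-target protospacer.
mutate_protospacer <- function(gchars, m_seed, m_nonseed) {
  proto <- gchars
  pos <- c(if (m_seed > 0L) sample(9:20, m_seed),
           if (m_nonseed > 0L) sample(1:8, m_nonseed))
  for (p in pos) proto[p] <- sample(setdiff(DNA_BASES, gchars[p]), 1L)
  proto
}

#' Simulate a labelled off-target training table
#'
#' Emulates an assay-derived activity table with a planted, fully known
#' activity rule: a site is active iff it has at most `seed_mm_max`
#' mismatches in the 12 bp seed region (positions 9..20, PAM-proximal) and
#' at most `total_mm_max` mismatches in total. Active sites receive a
#' minimal active concentration tier from \{4, 16, 64\} nM, deterministically
#' from the rule margin `min(seed_mm_max - seed_mm, total_mm_max - total_mm)`
#' (larger margin, i.e. fewer mismatches, maps to a smaller minimal
#' concentration). Inactive sites one mismatch beyond the rule get 256 nM;
#' the rest are "not detected" (`NA`).
#'
#' Because every site obeying the rule is active by construction, the
#' inactive pool contains no site with fewer than `seed_mm_max + 1`
#' mismatches; `active_total_range` narrows the actives' total-mismatch
#' range when a pool sufficient in every occupied bin is needed (e.g. for
#' sampler-fidelity checks).
#'
#' @param n_active Number of active sites.
#' @param n_inactive_pool Size of the inactive candidate pool.
#' @param n_guides Number of distinct on-target guides.
#' @param seed_mm_max,total_mm_max The planted rule's thresholds.
#' @param active_total_range Range (low, high) the actives' total mismatch
#'   counts are drawn from, intersected with the rule.
#' @param seed RNG seed.
#' @return A tibble with columns `guide_id`, `on_target` (23-mer),
#'   `off_target` (23-mer), `n_mismatches`, `seed_mismatches`, `label`
#'   (`"active"`/`"inactive"`), `min_active_concentration` (nM, `NA` when
#'   never detected).
#' @export
sim_training_table <- function(n_active = 60L, n_inactive_pool = 600L,
                               n_guides = 3L, seed_mm_max = 2L,
                               total_mm_max = 5L,
                               active_total_range = c(0L, total_mm_max),
                               seed = 1L) {
  with_seed(seed, {
    guides <- vapply(seq_len(n_guides),
                     function(i) c2s(sample(DNA_BASES, 20L, replace = TRUE)),
                     character(1))
    on_pams <- vapply(seq_len(n_guides),
                      function(i) realize_pam("NGG"), character(1))
    make_rows <- function(n, active) {
      recs <- vector("list", n)
      for (i in seq_len(n)) {
        gi <- ((i - 1L) %% n_guides) + 1L
        gchars <- s2c(guides[[gi]])
        if (active) {
          lo <- max(active_total_range[[1]], 0L)
          hi <- min(active_total_range[[2]], total_mm_max)
          m_total <- sample(lo:hi, 1L)
          m_seed <- sample(max(0L, m_total - 8L):min(seed_mm_max, m_total), 1L)
        } else {
          repeat {
            m_seed <- sample(0:8, 1L)
            m_total <- sample(max(1L, m_seed):8L, 1L)
            if (m_seed > seed_mm_max || m_total > total_mm_max) break
          }
        }
        m_nonseed <- min(m_total - m_seed, 8L)
        m_total <- m_seed + m_nonseed
        proto <- mutate_protospacer(gchars, m_seed, m_nonseed)
        margin <- min(seed_mm_max - m_seed, total_mm_max - m_total)
        conc <- if (active) c(64, 16, 4)[[margin + 1L]]
                else if (margin == -1L) 256 else NA_real_
        recs[[i]] <- tibble::tibble(
          guide_id = paste0("g", gi),
          on_target = paste0(guides[[gi]], on_pams[[gi]]),
          off_target = paste0(c2s(proto), realize_pam("NGG")),
          n_mismatches = m_total, seed_mismatches = m_seed,
          label = if (active) "active" else "inactive",
          min_active_concentration = conc)
      }
      dplyr::bind_rows(recs)
    }
    dplyr::bind_rows(make_rows(n_active, TRUE),
                     make_rows(n_inactive_pool, FALSE))
  })
}

#' Write / read a training table as TSV
#'
#' @param table Training-table tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_training_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_training_table
#' @export
read_training_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    guide_id = "c", on_target = "c", off_target = "c",
                    n_mismatches = "i", seed_mismatches = "i", label = "c",
                    min_active_concentration = "d"))
}
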