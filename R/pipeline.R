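# End-to-end orchestration: guides + FASTA + optional VCF -> variant genome
# -> search -> merge/filter -> score -> BED6+ report, plus the
# multi-individual comparison.

#' Read a guides file
#'
#' One guide per line, tab-separated: 23-mer (protospacer + PAM), then
#' optionally an id, and optionally the origin locus as contig, 0-based
#' start and strand. The origin locus enables on-target self-match removal;
#' without it, perfect self-hits are flagged rather than removed.
#'
#' @param path Path to the guides file.
#' @return Tibble `guide_id`, `sequence` (23-mer), `protospacer`, `pam`,
#'   `contig`, `start`, `strand` (NA when no origin given).
#' @export
read_guides <- function(path) {
  if (!file.exists(path)) abort(sprintf("guides file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) abort(sprintf("guides file %s contains no guides", path))
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    seq <- toupper(trimws(f[[1]]))
    if (nchar(seq) != 23L) {
      abort(sprintf("%s line %d: guide must be 23 bases (20-mer + PAM), got %d",
                    path, i, nchar(seq)))
    }
    assert_dna(seq, sprintf("%s line %d", path, i))
    tibble::tibble(
      guide_id = if (length(f) >= 2L && nzchar(f[[2]])) f[[2]] else paste0("guide", i),
      sequence = seq, protospacer = substr(seq, 1L, 20L),
      pam = substr(seq, 21L, 23L),
      contig = if (length(f) >= 5L) f[[3]] else NA_character_,
      start = if (length(f) >= 5L) as.integer(f[[4]]) else NA_integer_,
      strand = if (length(f) >= 5L) f[[5]] else NA_character_)
  })
  dplyr::bind_rows(recs)
}

#' Write guides to file
#'
#' @param guides Guides tibble (see [read_guides()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(guides, path) {
  has_origin <- !is.na(guides$contig)
  lines <- vapply(seq_len(nrow(guides)), function(i) {
    base <- paste(guides$sequence[[i]], guides$guide_id[[i]], sep = "\t")
    if (has_origin[[i]]) {
      paste(base, guides$contig[[i]], guides$start[[i]], guides$strand[[i]],
            sep = "\t")
    } else base
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

search_all_guides <- function(index, guides, pams, max_mismatches) {
  out <- lapply(seq_len(nrow(guides)), function(i) {
    h <- search_guide(index, guides$protospacer[[i]], pams, max_mismatches)
    if (nrow(h) > 0L) h$guide_id <- guides$guide_id[[i]]
    h
  })
  dplyr::bind_rows(out)
}

#' Score merged hits
#'
#' Adds MIT and CFD scores and, when a model is supplied, the Random-Forest
#' activity probability, plus a BED `score` column (chosen score scaled to
#' 0..1000).
#'
#' @param hits Merged hits tibble with `guide_id`.
#' @param guides Guides tibble.
#' @param scorer Which score fills the BED score column: `"mit"`, `"cfd"`
#'   or `"rf"`.
#' @param model `ot_model`, required for `scorer = "rf"`.
#' @param table CFD penalty table.
#' @return `hits` with `score_mit`, `score_cfd`, `activity_prob` (if model)
#'   and `bed_score` columns.
#' @export
score_hits <- function(hits, guides, scorer = c("mit", "cfd", "rf"),
                       model = NULL, table = cfd_table()) {
  scorer <- match.arg(scorer)
  if (scorer == "rf" && is.null(model)) {
    abort("scorer = 'rf' requires a trained model")
  }
  if (nrow(hits) == 0L) {
    hits$score_mit <- numeric(0)
    hits$score_cfd <- numeric(0)
    if (!is.null(model)) hits$activity_prob <- numeric(0)
    hits$bed_score <- integer(0)
    return(hits)
  }
  g <- guides[match(hits$guide_id, guides$guide_id), , drop = FALSE]
  hits$score_mit <- score_mit(g$protospacer, hits$protospacer)
  hits$score_cfd <- score_cfd(g$protospacer, hits$protospacer, hits$pam, table)
  if (!is.null(model)) {
    feats <- extract_features(g$sequence, paste0(hits$protospacer, hits$pam))
    hits$activity_prob <- predict_activity(model, feats)
  }
  chosen <- switch(scorer, mit = hits$score_mit, cfd = hits$score_cfd,
                   rf = hits$activity_prob)
  hits$bed_score <- pmin(1000L, pmax(0L, as.integer(round(chosen * 1000))))
  hits
}

#' Write hits as a BED6+ TSV
#'
#' The first six columns form a BED6 record (chrom, start, end, name,
#' score, strand); extra columns carry the 23-mer target sequence, mismatch
#' count, colon-joined mismatch positions, the hit source and
#' semicolon-joined VCF back-references.
#'
#' @param hits Scored hits tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  mmstr <- vapply(hits$mismatch_positions, paste, character(1), collapse = ":")
  vidstr <- vapply(hits$variant_ids, paste, character(1), collapse = ";")
  df <- data.frame(
    chrom = hits$contig, start = hits$start, end = hits$end,
    name = if ("guide_id" %in% names(hits)) hits$guide_id else ".",
    score = if ("bed_score" %in% names(hits)) hits$bed_score else 0L,
    strand = hits$strand,
    target = paste0(hits$protospacer, hits$pam),
    n_mismatches = hits$n_mismatches,
    mismatches = ifelse(nzchar(mmstr), mmstr, "."),
    source = hits$source,
    variants = ifelse(nzchar(vidstr), vidstr, "."))
  extra <- intersect(c("score_mit", "score_cfd", "activity_prob"), names(hits))
  for (col in extra) df[[col]] <- hits[[col]]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Run the end-to-end off-target pipeline
#'
#' Reads the genome, guides and (optionally) a VCF, builds the variant
#' genome, searches reference and variant sequences, merges and filters,
#' scores, and optionally applies a probability cut-off and writes a BED6+
#' report plus a JSON run summary. Without a VCF the pipeline degrades to a
#' reference-only search.
#'
#' @param genome Genome tibble or path to a FASTA file.
#' @param guides Guides tibble or path to a guides file.
#' @param vcf Variants tibble, path to a VCF file, or `NULL`.
#' @param pams PAM motifs to search.
#' @param max_mismatches Mismatch budget (0..8).
#' @param scorer Score for the BED score column (`"mit"`, `"cfd"`, `"rf"`).
#' @param model Optional `ot_model` for RF scoring.
#' @param threshold Optional activity-probability cut-off in `[0, 1]`
#'   (requires a model).
#' @param out Optional output prefix; writes `<out>.bed` and
#'   `<out>.summary.json`.
#' @param seed Seed recorded in the run summary (the search itself is
#'   deterministic).
#' @return An object of class `ot_run`: list with `hits` (scored tibble),
#'   `summary` (counts), `guides`, `windows`.
#' @export
run_pipeline <- function(genome, guides, vcf = NULL,
                         pams = c("NGG", "NGA"), max_mismatches = 8L,
                         scorer = c("mit", "cfd", "rf"), model = NULL,
                         threshold = NULL, out = NULL, seed = 1L) {
  scorer <- match.arg(scorer)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
        threshold < 0 || threshold > 1) {
      abort("threshold must be a single probability in [0, 1]")
    }
    if (is.null(model)) abort("a probability threshold requires a model")
  }
  if (is.character(genome)) genome <- read_genome(genome)
  genome <- as_genome_tbl(genome)
  if (is.character(guides)) guides <- read_guides(guides)
  variants <- if (is.null(vcf)) empty_variants_tbl()
              else if (is.character(vcf)) read_vcf(vcf)
              else vcf

  windows <- build_windows(genome, variants)
  ref_index <- ot_index(genome)
  ref_hits <- search_all_guides(ref_index, guides, pams, max_mismatches)

  var_hits <- NULL
  vseqs <- variant_genome_sequences(windows)
  if (!is.null(vseqs) && nrow(vseqs) > 0L) {
    vindex <- ot_index(tibble::tibble(name = as.character(seq_len(nrow(vseqs))),
                                      seq = vseqs$seq))
    vh <- search_all_guides(vindex, guides, pams, max_mismatches)
    if (nrow(vh) > 0L) {
      row <- as.integer(vh$seqname)
      vh$window_row <- vseqs$window_row[row]
      vh$allele_row <- vseqs$allele_row[row]
    }
    var_hits <- vh
  }

  on_targets <- guides[!is.na(guides$contig),
                       c("guide_id", "contig", "start", "strand")]
  if (nrow(on_targets) == 0L) on_targets <- NULL
  hits <- merge_and_filter(ref_hits, var_hits, windows, variants, on_targets)
  counts <- attr(hits, "filter_counts")
  hits <- score_hits(hits, guides, scorer = scorer, model = model)

  n_before_threshold <- nrow(hits)
  if (!is.null(threshold)) {
    hits <- apply_cutoff(hits, threshold, column = "activity_prob")
  }
  summary <- c(counts, list(
    n_guides = nrow(guides), pams = paste(pams, collapse = ","),
    max_mismatches = as.integer(max_mismatches), scorer = scorer,
    threshold = threshold %||% NA, seed = as.integer(seed),
    n_windows = nrow(windows),
    n_merged = n_before_threshold,
    n_after_threshold = nrow(hits)))
  run <- structure(list(hits = hits, summary = summary, guides = guides,
                        windows = windows), class = "ot_run")
  if (!is.null(out)) {
    write_bed(hits, paste0(out, ".bed"))
    jsonlite::write_json(summary, paste0(out, ".summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  run
}

#' @export
print.ot_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<ot_run> %d hit(s) for %d guide(s)\n",
                     "  reference hits: %d (removed in variant regions: %d)\n",
                     "  variant hits: %d raw, %d retained\n"),
              nrow(x$hits), s$n_guides, s$n_ref_in,
              s$n_ref_removed_variant_region, s$n_var_in,
              sum(x$hits$source == "variant")))
  invisible(x)
}

hit_keys <- function(hits) {
  paste(hits$contig, hits$start, hits$strand,
        if ("guide_id" %in% names(hits)) hits$guide_id else "", sep = "\r")
}

#' Compare off-target landscapes across individuals
#'
#' Runs (or accepts) one pipeline result per individual over the same
#' genome and guides but different VCFs, and summarises the overlap of hit
#' loci: sites common to all individuals, unique to each, and shared with
#' the reference landscape (hits whose source is the reference scan).
#'
#' @param runs Named list of `ot_run` objects (or hit tibbles).
#' @return An object of class `ot_compare`: list with `per_individual`
#'   tibble (`individual`, `n_hits`, `n_unique`, `n_shared_reference`) and
#'   `n_common_all`.
#' @export
compare_individuals <- function(runs) {
  if (length(runs) < 2L) abort("need at least two individuals to compare")
  nm <- names(runs) %||% paste0("individual", seq_along(runs))
  hits <- lapply(runs, function(r) if (inherits(r, "ot_run")) r$hits else r)
  gsets <- lapply(hits, function(h) {
    if ("guide_id" %in% names(h)) sort(unique(h$guide_id)) else character(0)
  })
  if (length(unique(gsets)) > 1L) {
    abort("individuals were searched with different guide sets")
  }
  keys <- lapply(hits, hit_keys)
  common <- Reduce(intersect, keys)
  per <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    others <- unique(unlist(keys[-i]))
    tibble::tibble(
      individual = nm[[i]], n_hits = length(unique(keys[[i]])),
      n_unique = length(setdiff(keys[[i]], others)),
      n_shared_reference = length(unique(
        keys[[i]][hits[[i]]$source == "reference"])))
  }))
  structure(list(per_individual = per, n_common_all = length(common)),
            class = "ot_compare")
}

#' @export
print.ot_compare <- function(x, ...) {
  cat(sprintf("<ot_compare> %d site(s) common to all individuals\n",
              x$n_common_all))
  print(x$per_individual)
  invisible(x)
}
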