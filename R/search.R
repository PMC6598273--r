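# Off-target search: a pigeonhole seed-and-extend search over an index of
# sequences, plus an independent brute-force sliding-window oracle, and the
# merge/filter step combining reference and variant-genome hits.

as_seq_tbl <- function(sequences) {
  if (is.character(sequences)) {
    nm <- names(sequences) %||% paste0("seq", seq_along(sequences))
    return(tibble::tibble(name = nm, seq = unname(toupper(sequences))))
  }
  if (is.data.frame(sequences)) {
    if ("contig" %in% names(sequences)) {
      return(tibble::tibble(name = sequences$contig, seq = toupper(sequences$seq)))
    }
    stopifnot(all(c("name", "seq") %in% names(sequences)))
    return(tibble::tibble(name = sequences$name, seq = toupper(sequences$seq)))
  }
  abort("sequences must be a character vector or a tibble with name/seq or contig/seq")
}

#' Build a search index over a set of sequences
#'
#' The index stores each sequence together with its reverse complement and
#' supports seed location plus per-base extension of a candidate match to
#' the left or to the right in either order (the mismatch count is
#' independent of the extension order; see `extend_order` of
#' [search_guide()]).
#'
#' @param sequences Named character vector, genome tibble (`contig`/`seq`)
#'   or sequence tibble (`name`/`seq`). Alphabet \{A,C,G,T,N\}; `N` never
#'   matches a guide base.
#' @return An object of class `ot_index`.
#' @export
ot_index <- function(sequences) {
  tbl <- as_seq_tbl(sequences)
  if (nrow(tbl) == 0L) abort("cannot build an index over zero sequences")
  assert_dna(tbl$seq, "indexed sequence", allow_n = TRUE)
  rc <- revcomp(tbl$seq)
  structure(list(
    name = tbl$name,
    seq = tbl$seq,
    chars = lapply(tbl$seq, s2c),
    rc_chars = lapply(rc, s2c),
    fwd = Biostrings::DNAStringSet(tbl$seq),
    rc = Biostrings::DNAStringSet(rc),
    lens = nchar(tbl$seq)
  ), class = "ot_index")
}

#' @export
print.ot_index <- function(x, ...) {
  cat(sprintf("<ot_index> %d sequence(s), %s bases total\n",
              length(x$name), format(sum(x$lens), big.mark = ",")))
  invisible(x)
}

# Contiguous partition of the 20-mer into n near-equal pieces. With k
# mismatches allowed and k+1 pieces, at least one piece of any hit matches
# exactly (pigeonhole), so exact seed location enumerates every hit.
piece_partition <- function(n_pieces, width = 20L) {
  base <- width %/% n_pieces
  extra <- width %% n_pieces
  lens <- rep(base, n_pieces) + c(rep(1L, extra), rep(0L, n_pieces - extra))
  tibble::tibble(start = cumsum(c(1L, head(lens, -1L))), len = lens)
}

empty_hits_tbl <- function() {
  tibble::tibble(seqname = character(), start = integer(), end = integer(),
                 strand = character(), protospacer = character(),
                 pam = character(), n_mismatches = integer(),
                 mismatch_positions = list())
}

hit_rows <- function(seqname, chars, L, cand, strand, gchars, k, pam_sets) {
  if (length(cand) == 0L) return(NULL)
  mm <- rep(0L, length(cand))
  for (j in 1:20) mm <- mm + (chars[cand + j - 1L] != gchars[[j]])
  ok_pam <- rep(FALSE, length(cand))
  for (sets in pam_sets) {
    okm <- rep(TRUE, length(cand))
    for (p in 1:3) okm <- okm & chars[cand + 19L + p] %in% sets[[p]]
    ok_pam <- ok_pam | okm
  }
  keep <- which(mm <= k & ok_pam)
  if (length(keep) == 0L) return(NULL)
  cand <- cand[keep]
  mm <- mm[keep]
  proto <- vapply(cand, function(i) c2s(chars[i:(i + 19L)]), character(1))
  pam <- vapply(cand, function(i) c2s(chars[(i + 20L):(i + 22L)]), character(1))
  mpos <- lapply(cand, function(i) which(chars[i:(i + 19L)] != gchars))
  start0 <- if (strand == "+") cand - 1L else L - cand - 22L
  tibble::tibble(seqname = seqname, start = as.integer(start0),
                 end = as.integer(start0 + 23L), strand = strand,
                 protospacer = proto, pam = pam, n_mismatches = mm,
                 mismatch_positions = mpos)
}

#' Search for off-target sites of a guide (seed-and-extend)
#'
#' Finds every position on both strands of the indexed sequences where the
#' 20-mer protospacer matches with at most `max_mismatches` Hamming
#' mismatches and the adjacent 3-mer on the PAM side (3' of the protospacer)
#' matches one of the PAM motifs. Mismatches are counted on the protospacer
#' only; degenerate PAM positions (`N`) are never counted as mismatches.
#' `N` in the genome never matches a guide base and satisfies only the PAM
#' motif character `N`.
#'
#' The search partitions the protospacer into `max_mismatches + 1`
#' contiguous pieces; by pigeonhole at least one piece of every hit occurs
#' exactly, so exact seed location followed by bidirectional extension with
#' mismatch counting enumerates all hits. Candidate sites found through
#' several seeds are deduplicated.
#'
#' @param index An [ot_index()].
#' @param guide 20-mer protospacer over \{A,C,G,T\}.
#' @param pams Character vector of 3-base IUPAC PAM motifs (e.g.
#'   `c("NGG", "NGA")`). An empty set yields no hits.
#' @param max_mismatches Mismatch budget, 0..8.
#' @param extend_order Extend candidate seeds left-then-right (`"lr"`) or
#'   right-then-left (`"rl"`); results are identical, the parameter exists
#'   to exercise the bidirectional-extension contract.
#' @return A hits tibble: `seqname`, `start`, `end` (0-based half-open),
#'   `strand`, `protospacer` (as read 5'->3' on the target strand), `pam`,
#'   `n_mismatches`, `mismatch_positions` (list, 1-based from the PAM-distal
#'   end).
#' @export
search_guide <- function(index, guide, pams, max_mismatches = 8L,
                         extend_order = c("lr", "rl")) {
  stopifnot(inherits(index, "ot_index"))
  extend_order <- match.arg(extend_order)
  assert_guide20(guide)
  if (max_mismatches < 0L || max_mismatches > 8L) {
    abort("max_mismatches must lie in 0..8")
  }
  if (length(pams) == 0L) return(empty_hits_tbl())
  pam_sets <- lapply(pams, pam_allowed_sets)
  gchars <- s2c(guide)
  pieces <- piece_partition(max_mismatches + 1L)
  if (extend_order == "rl") pieces <- pieces[rev(seq_len(nrow(pieces))), ]
  out <- list()
  for (s in seq_along(index$name)) {
    L <- index$lens[[s]]
    if (L < 23L) next
    for (strand in c("+", "-")) {
      chars <- if (strand == "+") index$chars[[s]] else index$rc_chars[[s]]
      subject <- if (strand == "+") index$fwd[[s]] else index$rc[[s]]
      cand <- integer(0)
      for (p in seq_len(nrow(pieces))) {
        piece <- substr(guide, pieces$start[[p]],
                        pieces$start[[p]] + pieces$len[[p]] - 1L)
        m <- Biostrings::matchPattern(piece, subject, fixed = TRUE)
        st <- Biostrings::start(m) - (pieces$start[[p]] - 1L)
        cand <- c(cand, st[st >= 1L & st <= L - 22L])
      }
      cand <- sort(unique(cand))
      out[[length(out) + 1L]] <-
        hit_rows(index$name[[s]], chars, L, cand, strand, gchars,
                 max_mismatches, pam_sets)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_hits_tbl())
  dplyr::arrange(res, .data$seqname, .data$start, .data$strand)
}

#' Brute-force off-target scan (oracle)
#'
#' Sliding-window Hamming scan of both strands of every sequence, with the
#' same match semantics as [search_guide()] but no seeding or indexing. This
#' is the ground-truth oracle the indexed search is verified against.
#'
#' @inheritParams search_guide
#' @param sequences Sequences in any form accepted by [ot_index()].
#' @return A hits tibble with the same columns as [search_guide()].
#' @export
brute_force_search <- function(sequences, guide, pams, max_mismatches = 8L) {
  tbl <- as_seq_tbl(sequences)
  assert_guide20(guide)
  if (length(pams) == 0L) return(empty_hits_tbl())
  pam_sets <- lapply(pams, pam_allowed_sets)
  gchars <- s2c(guide)
  out <- list()
  for (s in seq_len(nrow(tbl))) {
    L <- nchar(tbl$seq[[s]])
    if (L < 23L) next
    for (strand in c("+", "-")) {
      chars <- s2c(if (strand == "+") tbl$seq[[s]] else revcomp(tbl$seq[[s]]))
      starts <- seq_len(L - 22L)
      out[[length(out) + 1L]] <-
        hit_rows(tbl$name[[s]], chars, L, starts, strand, gchars,
                 max_mismatches, pam_sets)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_hits_tbl())
  dplyr::arrange(res, .data$seqname, .data$start, .data$strand)
}

#' Merge and filter reference and variant-genome hits
#'
#' Combines the reference-genome scan with the variant-genome scan:
#' \enumerate{
#'   \item reference hits are removed when no haplotype of the individual
#'     carries the reference allele at every overlapped variant: hits
#'     overlapping a hom-alt variant, or phased heterozygous variants in
#'     trans, do not exist in that person. Hits overlapping only variants
#'     with a consistent reference haplotype (e.g. a single het, or cis
#'     hets) are retained;
#'   \item variant hits are lifted to reference coordinates through their
#'     window's offset map and tagged with the ids of the variants they
#'     overlap; hits overlapping no variant duplicate the reference scan and
#'     are dropped;
#'   \item duplicate variant hits (same lifted locus, strand and sequence
#'     found through several windows/combinations) are collapsed, keeping
#'     the union of variant ids;
#'   \item each guide's declared on-target locus is removed when found with
#'     0 mismatches; other perfect matches are retained and flagged
#'     (`is_perfect`);
#'   \item the result is sorted by (contig, start, strand).
#' }
#'
#' @param ref_hits Hits tibble from scanning the reference genome (`seqname`
#'   is the contig); may carry a `guide_id` column.
#' @param var_hits Hits tibble from scanning variant-genome allele
#'   sequences, with `window_row`/`allele_row` columns referring into
#'   `windows`.
#' @param windows Windows tibble from [build_windows()].
#' @param variants Variants tibble (for footprints and genotypes).
#' @param on_targets Optional tibble (`guide_id`, `contig`, `start`,
#'   `strand`) of declared guide origin loci.
#' @return A merged hits tibble with `contig`, `start`, `end`, `strand`,
#'   `protospacer`, `pam`, `n_mismatches`, `mismatch_positions`, `source`
#'   (`"reference"`/`"variant"`), `variant_ids` (list), `lift_exact`,
#'   `is_perfect` (and `guide_id` when present). Filtering counts are
#'   attached as attribute `filter_counts`.
#' @export
merge_and_filter <- function(ref_hits, var_hits, windows, variants,
                             on_targets = NULL) {
  has_guide <- "guide_id" %in% names(ref_hits) ||
    (!is.null(var_hits) && "guide_id" %in% names(var_hits))
  norm_ref <- function(h) {
    if (nrow(h) == 0L) return(NULL)
    out <- dplyr::rename(h, contig = "seqname")
    if (!"guide_id" %in% names(out)) out$guide_id <- NA_character_
    out$source <- "reference"
    out$variant_ids <- rep(list(character(0)), nrow(out))
    out$lift_exact <- TRUE
    out
  }
  counts <- list(n_ref_in = nrow(ref_hits),
                 n_var_in = if (is.null(var_hits)) 0L else nrow(var_hits),
                 n_ref_removed_variant_region = 0L,
                 n_var_dropped_no_variant = 0L,
                 n_var_collapsed = 0L,
                 n_on_target_removed = 0L)
  fp <- variant_footprints(variants)
  fp$contig <- variants$contig

  ref <- norm_ref(ref_hits)
  if (!is.null(ref) && nrow(fp) > 0L) {
    # a reference hit exists in the individual iff some haplotype carries
    # the reference allele at every variant the hit overlaps: phased
    # variants must share a reference haplotype; unphased variants only
    # need one reference allele (hom-alt never has one)
    drop <- vapply(seq_len(nrow(ref)), function(i) {
      ov <- which(fp$contig == ref$contig[[i]] & fp$start0 < ref$end[[i]] &
                    fp$end0 > ref$start[[i]])
      if (length(ov) == 0L) return(FALSE)
      ph <- ov[variants$phased[ov]]
      un <- ov[!variants$phased[ov]]
      hap_ok <- length(ph) == 0L || all(variants$gt1[ph] == 0L) ||
        all(variants$gt2[ph] == 0L)
      un_ok <- !any(variants$gt1[un] == 1L & variants$gt2[un] == 1L)
      !(hap_ok && un_ok)
    }, logical(1))
    counts$n_ref_removed_variant_region <- sum(drop)
    ref <- ref[!drop, , drop = FALSE]
  }

  var <- NULL
  if (!is.null(var_hits) && nrow(var_hits) > 0L) {
    lifted <- lapply(seq_len(nrow(var_hits)), function(i) {
      w <- var_hits$window_row[[i]]
      a <- var_hits$allele_row[[i]]
      al <- windows$alleles[[w]]
      offmap <- al$offmap[[a]]
      idx <- (var_hits$start[[i]] + 1L):(var_hits$start[[i]] + 23L)
      coords <- offmap[idx]
      lstart <- min(coords)
      lend <- max(coords) + 1L
      applied <- al$applied_ids[[a]]
      fpa <- fp[fp$id %in% applied, , drop = FALSE]
      vids <- fpa$id[fpa$start0 < lend & fpa$end0 > lstart]
      tibble::tibble(
        contig = windows$contig[[w]], start = lstart, end = lend,
        strand = var_hits$strand[[i]],
        protospacer = var_hits$protospacer[[i]], pam = var_hits$pam[[i]],
        n_mismatches = var_hits$n_mismatches[[i]],
        mismatch_positions = var_hits$mismatch_positions[i],
        guide_id = if ("guide_id" %in% names(var_hits))
          var_hits$guide_id[[i]] else NA_character_,
        source = "variant", variant_ids = list(sort(unique(vids))),
        lift_exact = (lend - lstart) == 23L)
    })
    var <- dplyr::bind_rows(lifted)
    no_var <- lengths(var$variant_ids) == 0L
    counts$n_var_dropped_no_variant <- sum(no_var)
    var <- var[!no_var, , drop = FALSE]
    if (nrow(var) > 0L) {
      key <- paste(var$contig, var$start, var$end, var$strand,
                   var$protospacer, var$pam, var$guide_id, sep = "\r")
      counts$n_var_collapsed <- sum(duplicated(key))
      merged_ids <- lapply(split(var$variant_ids, key), function(l) {
        sort(unique(unlist(l)))
      })
      var <- var[!duplicated(key), , drop = FALSE]
      var$variant_ids <- merged_ids[paste(var$contig, var$start, var$end,
                                          var$strand, var$protospacer,
                                          var$pam, var$guide_id,
                                          sep = "\r")]
      var$variant_ids <- unname(var$variant_ids)
    }
  }

  out <- dplyr::bind_rows(ref, var)
  if (is.null(out) || nrow(out) == 0L) {
    out <- dplyr::mutate(dplyr::rename(empty_hits_tbl(), contig = "seqname"),
                         guide_id = character(0), source = character(0),
                         variant_ids = list(), lift_exact = logical(0))
  }
  out$is_perfect <- out$n_mismatches == 0L
  if (!is.null(on_targets) && nrow(out) > 0L) {
    drop <- vapply(seq_len(nrow(out)), function(i) {
      out$is_perfect[[i]] && any(
        on_targets$contig == out$contig[[i]] &
          on_targets$start == out$start[[i]] &
          on_targets$strand == out$strand[[i]] &
          (is.na(out$guide_id[[i]]) | on_targets$guide_id == out$guide_id[[i]]))
    }, logical(1))
    counts$n_on_target_removed <- sum(drop)
    out <- out[!drop, , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$contig, .data$start, .data$strand)
  if (!has_guide) out$guide_id <- NULL
  attr(out, "filter_counts") <- counts
  out
}
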