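# Independent oracles used across tests. These deliberately re-derive
# results with simple, direct code rather than calling the implementation
# paths they check.

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
str_of <- function(ch) paste(ch, collapse = "")

# Apply phased variants to a whole contig for one haplotype, tracking for
# every emitted base its 0-based reference coordinate. Independent of the
# package's window construction.
hap_apply <- function(seq, variants, hap) {
  ch <- chars_of(seq)
  keep <- variants[variants[[paste0("gt", hap)]] == 1L, , drop = FALSE]
  keep <- keep[order(keep$pos), , drop = FALSE]
  out_ch <- character(0)
  out_map <- integer(0)
  cursor <- 0L
  for (i in seq_len(nrow(keep))) {
    v0 <- keep$pos[[i]] - 1L
    rl <- nchar(keep$ref[[i]])
    if (cursor < v0) {
      out_ch <- c(out_ch, ch[(cursor + 1L):v0])
      out_map <- c(out_map, cursor:(v0 - 1L))
    }
    ac <- chars_of(keep$alt[[i]])
    out_ch <- c(out_ch, ac)
    out_map <- c(out_map, v0 + pmin(seq_along(ac) - 1L, rl - 1L))
    cursor <- v0 + rl
  }
  L <- length(ch)
  if (cursor < L) {
    out_ch <- c(out_ch, ch[(cursor + 1L):L])
    out_map <- c(out_map, cursor:(L - 1L))
  }
  list(seq = str_of(out_ch), offmap = out_map)
}

# Ground-truth hit set of a phased individual: brute-force scan of both
# reconstructed haplotypes plus coordinate lifting, deduplicated on
# (contig, lifted start, strand, protospacer, pam, n_mismatches).
haplotype_truth <- function(genome, variants, guide, pams, max_mm) {
  keys <- character(0)
  for (hap in 1:2) {
    ha <- hap_apply(genome$seq[[1]], variants, hap)
    hits <- brute_force_search(setNames(ha$seq, genome$contig[[1]]),
                               guide, pams, max_mm)
    if (nrow(hits) == 0L) next
    for (i in seq_len(nrow(hits))) {
      span <- ha$offmap[(hits$start[[i]] + 1L):(hits$start[[i]] + 23L)]
      keys <- c(keys, paste(genome$contig[[1]], min(span), hits$strand[[i]],
                            hits$protospacer[[i]], hits$pam[[i]],
                            hits$n_mismatches[[i]], sep = "|"))
    }
  }
  sort(unique(keys))
}

run_keys <- function(hits) {
  sort(unique(paste(hits$contig, hits$start, hits$strand, hits$protospacer,
                    hits$pam, hits$n_mismatches, sep = "|")))
}

hit_set <- function(hits) {
  sort(paste(hits$seqname, hits$start, hits$strand, hits$n_mismatches,
             sep = "|"))
}

# Direct re-evaluation of the MIT formula, written independently of
# score_mit().
mit_oracle <- function(guide, offtarget) {
  g <- chars_of(guide)
  o <- chars_of(offtarget)
  W <- c(0, 0, 0.014, 0, 0, 0.395, 0.317, 0, 0.389, 0.079,
         0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804, 0.685, 0.583)
  pos <- which(g != o)
  m <- length(pos)
  if (m == 0) return(1)
  d <- if (m == 1) 19 else {
    s <- 0; np <- 0
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      s <- s + abs(pos[b] - pos[a]); np <- np + 1
    }
    s / np
  }
  prod(1 - W[pos]) / (((19 - d) / 19) * 4 + 1) / m^2
}

random_pair <- function(n_mm) {
  g <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
  o <- g
  for (p in sample.int(20, n_mm)) {
    o[p] <- sample(setdiff(c("A", "C", "G", "T"), g[p]), 1)
  }
  list(guide = str_of(g), off = str_of(o))
}

make_guides_tbl <- function(guide, pam = "AGG", id = "g1", contig = NA_character_,
                            start = NA_integer_, strand = NA_character_) {
  tibble::tibble(guide_id = id, sequence = paste0(guide, pam),
                 protospacer = guide, pam = pam, contig = contig,
                 start = start, strand = strand)
}
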