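# Low-level sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. `N` is its own complement; input may be upper case
#' A/C/G/T/N only.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) c2s(rev(s2c(chartr("ACGTN", "TGCAN", s)))), character(1),
         USE.NAMES = FALSE)
}

# Bases satisfying one IUPAC motif character. A genomic N satisfies only the
# motif character N; guide/motif characters other than N are never satisfied
# by N.
iupac_allowed <- function(ch) {
  base <- s2c(Biostrings::IUPAC_CODE_MAP[[ch]])
  if (ch == "N") c(base, "N") else base
}

# Per-position allowed-base sets for a 3-base PAM motif.
pam_allowed_sets <- function(motif) {
  chs <- s2c(motif)
  if (length(chs) != 3L) {
    abort(sprintf("PAM motif '%s' must have length 3", motif))
  }
  lapply(chs, iupac_allowed)
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s}", what,
                  if (allow_n) ",N" else ""))
  }
  invisible(x)
}

assert_guide20 <- function(guide) {
  if (length(guide) != 1L || nchar(guide) != 20L) {
    abort("guide must be a single 20-base protospacer sequence")
  }
  assert_dna(guide, "guide")
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Sub-seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

is_purine <- function(b) b %in% PURINES

# genome tibble helpers -------------------------------------------------------

as_genome_tbl <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(tibble::tibble(contig = names(genome),
                          seq = as.character(genome)))
  }
  if (is.character(genome)) {
    nm <- names(genome) %||% paste0("contig", seq_along(genome))
    return(tibble::tibble(contig = nm, seq = unname(genome)))
  }
  if (is.data.frame(genome)) {
    stopifnot(all(c("contig", "seq") %in% names(genome)))
    return(tibble::as_tibble(genome[, c("contig", "seq")]))
  }
  abort("genome must be a DNAStringSet, named character vector, or tibble with contig/seq")
}

#' Read a genome from FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A tibble with columns `contig` and `seq`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(contig = sub("\\s.*$", "", names(ss)),
                 seq = toupper(as.character(ss)))
}

#' Write a genome tibble to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome Tibble with `contig` and `seq` columns (or DNAStringSet).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  g <- as_genome_tbl(genome)
  ss <- Biostrings::DNAStringSet(setNames(g$seq, g$contig))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
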