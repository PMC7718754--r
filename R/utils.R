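# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

rs_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("repeatscape_", class), "repeatscape_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random DNA string
#'
#' Uniform i.i.d. bases; used by the simulator for backgrounds, genes and
#' repeat consensus sequences.
#'
#' @param n Length in nucleotides.
#' @return A single character string over A/C/G/T.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Per-site substitution mutation: each position independently replaced by
# one of the three other bases with probability p.
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

# Apply sequencing error (substitutions only) to a character vector of reads.
apply_seq_error <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, mutate_seq, character(1), p = error_rate, USE.NAMES = FALSE)
}

# Draw n integers uniformly from [lo, hi]; safe when lo == hi (avoids the
# sample(x, ...) scalar surprise).
sample_int_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Deterministic seed derivation for sub-streams, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

as_reads_df <- function(read_id, species_code, seq) {
  data.frame(read_id = as.character(read_id),
             species_code = as.character(species_code),
             seq = toupper(as.character(seq)),
             stringsAsFactors = FALSE)
}

# Fraction of N (or other ambiguous) characters per sequence.
n_fraction <- function(seqs) {
  total <- nchar(seqs)
  acgt <- nchar(gsub("[^ACGT]", "", seqs))
  ifelse(total == 0, 1, (total - acgt) / total)
}
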