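# shared internal helpers

# half-up rounding; base round() is round-half-even, which would print
# 92.395 as 92.39 where the retention tables print 92.40
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @keywords internal
abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# all k-mers over A<C<G<T in lexicographic order, matching the column order
# of Biostrings::oligonucleotideFrequency
kmer_names <- function(k) {
  stopifnot(k >= 1)
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, bases, paste0)))
    }
  }
  out
}

# reverse complement for plain character vectors of ACGTN strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase, U->T, anything outside ACGT -> N
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}
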