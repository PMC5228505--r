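# independent oracles and fixture builders, deliberately naive

# naive substring-scan k-mer counter: per sequence, slide a window and
# tally exact matches; windows containing N are skipped
oracle_count_kmers <- function(sequences, k) {
  kmers <- oudphylo:::kmer_names(k)
  counts <- stats::setNames(rep(0, 4^k), kmers)
  for (s in sequences) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      counts[w] <- counts[w] + 1
    }
  }
  counts
}

# direct-formula OUD oracle from naive counts and base tallies
oracle_oud <- function(sequences, k) {
  counts <- oracle_count_kmers(sequences, k)
  L <- sum(nchar(sequences))
  chars <- unlist(strsplit(sequences, ""))
  mono <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), 0)
  p <- mono / sum(mono)
  e0 <- (L - k) / 4^k
  kmers <- names(counts)
  e1 <- vapply(kmers, function(z) {
    (L - k) * prod(p[strsplit(z, "")[[1]]])
  }, 0)
  (counts - e1) / e0
}

# hypergeometric upper tail by explicit combinatorial summation
oracle_hyper_tail <- function(x, K, N_u, n) {
  xs <- x:min(n, K)
  sum(choose(K, xs) * choose(N_u - K, n - xs)) / choose(N_u, n)
}

# random transcript set over ACGT (optionally with N), fixed composition bias
random_sequences <- function(n_seq, len_range, p = rep(0.25, 4), n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n_seq), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    chars <- sample(alphabet, len, replace = TRUE, prob = p)
    if (n_prob > 0) {
      chars[runif(len) < n_prob] <- "N"
    }
    paste(chars, collapse = "")
  }, "")
}

random_transcript_tbl <- function(strain, n_seq, len_range, ...) {
  seqs <- random_sequences(n_seq, len_range, ...)
  oudphylo:::new_transcript_tbl(strain, paste0(strain, "_t", seq_len(n_seq), "_i1"),
                                seqs)
}

# bundled retention table (18 chrysophyte strains)
retention_fixture <- function() {
  read_retention(system.file("extdata", "chrysophyte_retention.tsv",
                             package = "oudphylo"))
}

# toy module definitions used by the completeness tests
toy_modules <- function() {
  tibble::tibble(
    module_id = c(rep("M_glyco", 10), rep("M_tca", 4), "CX_atp", "CX_atp"),
    kind = c(rep("pathway_module", 14), rep("structural_complex", 2)),
    member = c(paste0("e", 1:10), paste0("t", 1:4), "M_glyco", "M_tca"),
    is_core = c(rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 4),
                rep(FALSE, 4), rep(FALSE, 2))
  )
}
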