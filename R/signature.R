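#' Count overlapping k-mers of a transcriptome
#'
#' Counts every length-k window within each transcript separately (windows
#' never span transcript boundaries); windows containing `N` are skipped.
#' Under the `canonical` strand policy each window is attributed to the
#' lexicographically smaller of the window and its reverse complement; the
#' default is `forward` because assembled mRNA is stranded. Counts are
#' indexed in lexicographic k-mer order (`A < C < G < T`), the fixed index
#' convention used throughout — in particular by the bootstrap resampler.
#'
#' Alongside the counts the object records `L`, the total transcriptome
#' length in bases, and `n_windows`, the number of valid windows actually
#' counted. The deviation formulas deliberately use the whole-transcriptome
#' window factor `L - k` rather than `n_windows` (see [expected_uniform()]);
#' `n_windows` is kept for diagnostics.
#'
#' @param transcripts A transcript tibble for one strain, or a character
#'   vector of sequences.
#' @param k k-mer length, >= 1.
#' @param strand `"forward"` (default) or `"canonical"`.
#' @return An object of class `kmer_counts`: a list with `k`, `counts`
#'   (named vector of length 4^k), `n_windows`, `L`, `mono` (A/C/G/T
#'   counts), `dinuc` (16 dinucleotide counts, for the Markov null), and
#'   `strain`.
#' @examples
#' count_kmers(c("AAAA"), k = 2)$counts[["AA"]] # 3
#' @export
count_kmers <- function(transcripts, k, strand = c("forward", "canonical")) {
  strand <- match.arg(strand)
  abort_if(k < 1, "k must be >= 1")
  if (is.data.frame(transcripts)) {
    strain <- if (nrow(transcripts)) unique(transcripts$strain)[1] else NA_character_
    sequences <- transcripts$sequence
  } else {
    strain <- NA_character_
    sequences <- as.character(transcripts)
  }
  abort_if(length(sequences) == 0, "no sequences")
  abort_if(!any(nchar(sequences) >= k), "no countable windows")
  dss <- Biostrings::DNAStringSet(sequences)
  counts <- colSums(Biostrings::oligonucleotideFrequency(dss, width = k))
  if (strand == "canonical") {
    rc <- revcomp(names(counts))
    canon <- pmin(names(counts), rc)
    folded <- tapply(counts, canon, sum)
    counts <- stats::setNames(numeric(length(counts)), names(counts))
    counts[names(folded)] <- folded
  }
  mono <- colSums(Biostrings::letterFrequency(dss, c("A", "C", "G", "T")))
  dinuc <- colSums(Biostrings::oligonucleotideFrequency(dss, width = 2))
  structure(
    list(k = as.integer(k), counts = counts, n_windows = sum(counts),
         L = sum(nchar(sequences)), mono = mono, dinuc = dinuc,
         strand = strand, strain = strain),
    class = "kmer_counts"
  )
}

#' Expected k-mer counts under the uniform null
#'
#' Every k-mer gets the same expectation `(L - k) / 4^k` for a transcriptome
#' of `L` total bases — the normalizing denominator of the usage-deviation
#' signature.
#'
#' @param L Total transcriptome length in bases; must exceed `k`.
#' @param k k-mer length.
#' @return Named numeric vector of length 4^k.
#' @examples
#' expected_uniform(1028, 4)[1] # 4
#' @export
expected_uniform <- function(L, k) {
  abort_if(L <= k, "L must exceed k (uniform expectation would be <= 0)")
  stats::setNames(rep((L - k) / 4^k, 4^k), kmer_names(k))
}

#' Expected k-mer counts under the i.i.d. mononucleotide null
#'
#' `E1(z) = (L - k) * prod_j p(z_j)` with mononucleotide frequencies `p`
#' pooled over the whole transcriptome. The window factor matches
#' [expected_uniform()], so a transcriptome with uniform base composition
#' has `E1 = E0` exactly. A base with zero frequency gives `E1(z) = 0` for
#' every k-mer containing it; such k-mers also have observed count 0, so
#' the deviation is 0, never NaN.
#'
#' @param counts A `kmer_counts` object.
#' @return Named numeric vector of length 4^k.
#' @export
expected_iid <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  abort_if(sum(counts$mono) == 0, "no unambiguous bases for mononucleotide model")
  p <- counts$mono / sum(counts$mono)
  kmers <- names(counts$counts)
  base_mat <- kmer_base_matrix(kmers, counts$k)
  probs <- matrix(p[base_mat], nrow = length(kmers))
  stats::setNames((counts$L - counts$k) * apply(probs, 1, prod), kmers)
}

# rows = kmers, cols = positions, entries in {"A","C","G","T"}
kmer_base_matrix <- function(kmers, k) {
  matrix(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE),
         ncol = k, byrow = TRUE)
}

#' Expected k-mer counts under a first-order Markov (dinucleotide) null
#'
#' `E(z) = (L - k) * p(z_1) * prod_{j>=2} p(z_j | z_{j-1})` with transition
#' frequencies estimated from pooled dinucleotide counts. Offered as an
#' alternative null for the usage-deviation signature; dinucleotide
#' normalization is known not to improve the resulting phylogenies, but the
#' variant is kept for comparison.
#'
#' @param counts A `kmer_counts` object with `k >= 2`.
#' @return Named numeric vector of length 4^k.
#' @export
expected_markov1 <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  abort_if(counts$k < 2, "Markov null needs k >= 2")
  p <- counts$mono / sum(counts$mono)
  di <- counts$dinuc
  first <- substr(names(di), 1, 1)
  row_tot <- tapply(di, first, sum)[c("A", "C", "G", "T")]
  abort_if(any(row_tot == 0 & p > 0),
           "zero-count conditioning base in dinucleotide table")
  trans <- di # p(b | a) indexed by "ab"; keep dinucleotide names
  trans[] <- di / as.numeric(row_tot[first])
  trans[is.nan(trans)] <- 0
  kmers <- names(counts$counts)
  base_mat <- kmer_base_matrix(kmers, counts$k)
  e <- (counts$L - counts$k) * p[base_mat[, 1]]
  for (j in 2:counts$k) {
    e <- e * trans[paste0(base_mat[, j - 1], base_mat[, j])]
  }
  stats::setNames(as.numeric(e), kmers)
}

#' Oligonucleotide usage deviation signature
#'
#' The signature of a transcriptome is the vector, over all 4^k k-mers z,
#' of normalized usage deviations
#'
#' `OUD(z) = (N(z) - E1(z)) / E0(z)`
#'
#' where `N(z)` is the observed count, `E1(z)` the expectation under the
#' i.i.d. mononucleotide null (or the first-order Markov null when
#' `null = "markov1"`), and `E0(z) = (L - k)/4^k` the uniform expectation.
#' The signature has exactly 4^k components (256 for k = 4, 4,096 for
#' k = 6) and is the object all downstream distances and trees are built
#' from.
#'
#' @param counts A `kmer_counts` object (see [count_kmers()]), or a
#'   transcript tibble (then `k`/`strand` are used to count first).
#' @param null `"iid"` (default) or `"markov1"`.
#' @param k,strand Passed to [count_kmers()] when `counts` is a transcript
#'   table.
#' @return An `oud_signature`: a named numeric vector of length 4^k with
#'   attributes `k`, `null_model`, `strain`, `L`, `n_windows`.
#' @examples
#' sig <- oud_signature(count_kmers("AAAA", k = 2))
#' sig[["AA"]] # 8
#' @export
oud_signature <- function(counts, null = c("iid", "markov1"), k = 4L,
                          strand = "forward") {
  null <- match.arg(null)
  if (!inherits(counts, "kmer_counts")) {
    counts <- count_kmers(counts, k = k, strand = strand)
  }
  abort_if(counts$L <= counts$k, "L must exceed k")
  e0 <- expected_uniform(counts$L, counts$k)
  e1 <- switch(null, iid = expected_iid(counts),
               markov1 = expected_markov1(counts))
  values <- (counts$counts - e1) / e0
  abort_if(any(!is.finite(values)), "non-finite deviation value")
  structure(values, class = "oud_signature", k = counts$k, null_model = null,
            strain = counts$strain, L = counts$L, n_windows = counts$n_windows)
}

#' Signatures for a set of strains
#'
#' Convenience wrapper computing one usage-deviation signature per strain of
#' a multi-strain transcript table, returned as a strains x 4^k matrix — the
#' input of [signature_distances()] and [bootstrap_support()].
#'
#' @param transcripts Transcript tibble with a `strain` column.
#' @inheritParams oud_signature
#' @return A numeric matrix (rownames = strains, colnames = k-mers) of class
#'   `oud_signature_set` with attributes `k` and `null_model`.
#' @export
oud_signatures <- function(transcripts, k = 4L, null = c("iid", "markov1"),
                           strand = "forward") {
  null <- match.arg(null)
  strains <- unique(transcripts$strain)
  abort_if(length(strains) < 1, "no strains")
  rows <- lapply(strains, function(s) {
    oud_signature(count_kmers(transcripts[transcripts$strain == s, ],
                              k = k, strand = strand), null = null)
  })
  m <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(m) <- list(strains, kmer_names(k))
  structure(m, class = c("oud_signature_set", "matrix", "array"),
            k = as.integer(k), null_model = null)
}

#' @export
print.oud_signature <- function(x, ...) {
  cat(sprintf("<oud_signature> strain=%s k=%d null=%s (%d components)\n",
              attr(x, "strain"), attr(x, "k"), attr(x, "null_model"),
              length(x)))
  cat(sprintf("  mean %.4g, max |OUD| %.4g\n", mean(x), max(abs(x))))
  invisible(x)
}

#' Tidy a usage-deviation signature
#'
#' @param x An `oud_signature`.
#' @param ... Unused.
#' @return A tibble with columns `kmer` and `oud`.
#' @export
tidy.oud_signature <- function(x, ...) {
  tibble::tibble(kmer = names(x), oud = as.numeric(x))
}

#' @export
glance.oud_signature <- function(x, ...) {
  tibble::tibble(
    strain = attr(x, "strain"), k = attr(x, "k"),
    null_model = attr(x, "null_model"), n_components = length(x),
    L = attr(x, "L"), n_windows = attr(x, "n_windows"),
    mean_oud = mean(x), max_abs_oud = max(abs(x))
  )
}

#' Write / read a signature as TSV
#'
#' Two-column TSV `kmer<TAB>oud_value`; metadata (`k`, strain, null model)
#' travels in `#`-prefixed header lines.
#'
#' @param sig An `oud_signature`.
#' @param path File path.
#' @return `path` (write) or an `oud_signature` (read).
#' @export
write_signature <- function(sig, path) {
  meta <- sprintf("# k=%d strain=%s null=%s", attr(sig, "k"),
                  attr(sig, "strain"), attr(sig, "null_model"))
  writeLines(c(meta, paste(names(sig), format(as.numeric(sig), digits = 17),
                           sep = "\t")), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")][1]
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                          vapply(parts, `[`, "", 1))
  get_field <- function(f) sub(paste0(".*", f, "="), "",
                               regmatches(meta, regexpr(paste0(f, "=\\S+"), meta)))
  structure(vals, class = "oud_signature",
            k = as.integer(round(log(length(vals), 4))),
            null_model = get_field("null"), strain = get_field("strain"))
}
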