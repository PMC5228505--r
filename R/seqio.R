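#' Read a transcriptome FASTA into a transcript table
#'
#' Reads assembled transcripts (e.g. a Trinity assembly) into a tibble with
#' one row per transcript. Sequences are normalized at ingest: lowercase is
#' uppercased, `U` becomes `T`, and any other residue becomes `N`, so the
#' downstream k-mer machinery sees a closed `{A,C,G,T,N}` alphabet. The
#' record id is the FASTA header up to the first whitespace; the gene-level
#' `component_id` is derived from the id (see [parse_component_id()]).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param strain Strain label attached to every record.
#' @return A tibble with columns `strain`, `id`, `component_id`, `sequence`,
#'   `length`, of class `transcript_tbl`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1_i1", "ACGTACGT", ">t1_i2", "acgu"), fa)
#' read_transcripts(fa, strain = "s1")
#' @export
read_transcripts <- function(path, strain) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  # read as raw strings first: normalization (U->T, other->N) must see the
  # original characters, which a DNA-alphabet reader would reject or drop
  seqs <- Biostrings::readBStringSet(path)
  abort_if(length(seqs) == 0, paste0("no sequences in ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- unname(normalize_sequence(as.character(seqs)))
  new_transcript_tbl(strain, ids, sequences)
}

new_transcript_tbl <- function(strain, ids, sequences) {
  abort_if(anyDuplicated(ids) > 0, "duplicate transcript ids within strain")
  abort_if(any(nchar(sequences) < 1), "zero-length sequence")
  out <- tibble::tibble(
    strain = strain,
    id = ids,
    component_id = parse_component_id(ids),
    sequence = sequences,
    length = nchar(sequences)
  )
  class(out) <- c("transcript_tbl", class(out))
  out
}

#' Derive the gene-level component id from a transcript id
#'
#' Trinity groups transcripts into components ("genes") whose isoforms share
#' the component prefix. Two Trinity id dialects are recognized: a trailing
#' `_i<digits>` (e.g. `TRINITY_DN100_c0_g1_i1`) and a trailing `_seq<digits>`
#' (e.g. `comp17_c0_seq3`); the suffix is stripped. Any other id is its own
#' component.
#'
#' @param transcript_id Character vector of non-empty transcript ids.
#' @return Character vector of component ids, same length.
#' @examples
#' parse_component_id(c("TRINITY_DN100_c0_g1_i1", "comp17_c0_seq3", "geneX"))
#' @export
parse_component_id <- function(transcript_id) {
  abort_if(any(!nzchar(transcript_id)), "empty transcript id")
  sub("_(i|seq)[0-9]+$", "", transcript_id)
}

#' Write transcripts back to FASTA
#'
#' @param transcripts A transcript tibble (columns `id`, `sequence`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- transcripts$id
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Assembly statistics for one transcriptome
#'
#' Computes the descriptive statistics commonly reported for de novo
#' transcriptome assemblies: transcript and component counts, total bases,
#' GC content (over unambiguous bases only), and the N50 — the smallest
#' length N such that contigs of length >= N together contain at least half
#' of the assembly's bases.
#'
#' @param transcripts A transcript tibble for one strain (or several; stats
#'   are computed per strain).
#' @return A tibble with one row per strain: `strain`, `n_transcripts`,
#'   `n_components`, `total_bases`, `gc_content`, `n50`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a_i1", "GGCCGGCC", ">b_i1", "ATAT"), fa)
#' assembly_stats(read_transcripts(fa, "s1"))
#' @export
assembly_stats <- function(transcripts) {
  abort_if(nrow(transcripts) == 0, "empty transcript set")
  transcripts |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      n_transcripts = dplyr::n(),
      n_components = dplyr::n_distinct(.data$component_id),
      total_bases = sum(.data$length),
      gc_content = gc_fraction(.data$sequence),
      n50 = n50(.data$length),
      .groups = "drop"
    )
}

gc_fraction <- function(sequences) {
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(sequences), c("A", "C", "G", "T")
  )
  totals <- colSums(counts)
  denom <- sum(totals)
  abort_if(denom == 0, "GC content undefined: no unambiguous (non-N) bases")
  unname((totals["G"] + totals["C"]) / denom)
}

#' N50 of a set of contig lengths
#'
#' Smallest length N for which contigs of length >= N contain at least half
#' of the total bases (real-valued, inclusive comparison).
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The N50 length.
#' @examples
#' n50(c(7, 5, 3, 3, 2, 2, 2)) # 5
#' @export
n50 <- function(lengths) {
  abort_if(length(lengths) == 0, "no contigs")
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(sorted))
  sorted[which(cum >= sum(as.numeric(lengths)) / 2)[1]]
}

#' Read a read-retention table
#'
#' Expects a TSV with header `strain  raw_pairs  clean_pairs` giving raw and
#' quality-filtered read-pair counts per strain.
#'
#' @param path Path to the TSV.
#' @return A tibble with those three columns.
#' @export
read_retention <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(
    !all(c("strain", "raw_pairs", "clean_pairs") %in% names(tbl)),
    "retention table must have columns strain, raw_pairs, clean_pairs"
  )
  tibble::as_tibble(tbl)
}

#' Percent of read pairs retained after cleaning
#'
#' Adds a `percent_clean` column (100 x clean / raw, half-up rounded to two
#' decimals, matching how such tables are conventionally printed).
#'
#' @param retention Tibble with `raw_pairs` and `clean_pairs` columns.
#' @return The input with a `percent_clean` column appended.
#' @examples
#' percent_clean(tibble::tibble(
#'   strain = "s", raw_pairs = 13899445, clean_pairs = 12843053
#' ))
#' @export
percent_clean <- function(retention) {
  abort_if(any(retention$raw_pairs <= 0), "raw_pairs must be positive")
  abort_if(
    any(retention$clean_pairs < 0 | retention$clean_pairs > retention$raw_pairs),
    "clean_pairs must lie in [0, raw_pairs]"
  )
  dplyr::mutate(
    retention,
    percent_clean = round_half_up(100 * .data$clean_pairs / .data$raw_pairs, 2)
  )
}

#' Summary of per-strain retention percentages
#'
#' @param retention Tibble with `raw_pairs`/`clean_pairs` (or an existing
#'   `percent_clean` column).
#' @return One-row tibble with `mean`, `median`, `min`, `max` of the
#'   per-strain percentages, each half-up rounded to two decimals. The
#'   median of an even count is the midpoint of the two central values.
#' @export
summarize_retention <- function(retention) {
  abort_if(nrow(retention) == 0, "no retention records")
  if (!"percent_clean" %in% names(retention)) {
    retention <- percent_clean(retention)
  }
  p <- retention$percent_clean
  tibble::tibble(
    mean = round_half_up(mean(p), 2),
    median = round_half_up(stats::median(p), 2),
    min = round_half_up(min(p), 2),
    max = round_half_up(max(p), 2)
  )
}
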