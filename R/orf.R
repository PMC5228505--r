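#' Find open reading frames in all six frames
#'
#' Scans a nucleotide sequence for maximal stop-free codon runs
#' ("stop-to-stop" ORFs) in every reading frame of both strands, the same
#' definition TransDecoder's LongOrfs step uses. Runs are open at sequence
#' boundaries; a terminal stop codon belongs to the run's span, but the
#' reported CDS never contains an internal stop. Codons containing `N`
#' cannot be called and break a run like a stop. Set `require_start = TRUE`
#' to trim each run to begin at its first `ATG`.
#'
#' @param sequence A single nucleotide string over `{A,C,G,T,N}`.
#' @param min_len_nt Minimum CDS length in nucleotides; must be a positive
#'   multiple of 3. Default 300 (100 codons), the conventional long-ORF
#'   threshold.
#' @param require_start Require the CDS to begin with `ATG`?
#' @return A tibble with one row per ORF: `frame` (+1..+3, -1..-3), `start`,
#'   `end` (0-based half-open on the reported strand; for reverse frames the
#'   reported strand is the reverse complement), `length`, `cds_sequence`.
#'   Ordered by length descending, ties by frame preference (forward before
#'   reverse, lower |frame| first, then leftmost start).
#' @examples
#' find_orfs("ATGAAATAA", min_len_nt = 9)
#' @export
find_orfs <- function(sequence, min_len_nt = 300L, require_start = FALSE) {
  abort_if(length(sequence) != 1, "one sequence at a time")
  abort_if(min_len_nt < 3 || min_len_nt %% 3 != 0,
           "min_len_nt must be a positive multiple of 3")
  fwd <- sequence
  rev <- revcomp(sequence)
  rows <- vector("list", 6)
  i <- 0L
  for (f in 1:3) {
    rows[[i <- i + 1L]] <- frame_orfs(fwd, f, min_len_nt, require_start)
    rows[[i <- i + 1L]] <- frame_orfs(rev, -f, min_len_nt, require_start)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(tibble::tibble(
      frame = integer(), start = integer(), end = integer(),
      length = integer(), cds_sequence = character()
    ))
  }
  out <- tibble::tibble(
    frame = unlist(lapply(rows, `[[`, "frame")),
    start = unlist(lapply(rows, `[[`, "start")),
    end = unlist(lapply(rows, `[[`, "end")),
    length = unlist(lapply(rows, `[[`, "length")),
    cds_sequence = unlist(lapply(rows, `[[`, "cds_sequence"))
  )
  # tie-break: longest first, forward strand preferred, lower frame, leftmost
  out[order(-out$length, out$frame < 0, abs(out$frame), out$start), ]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# the single best ORF of one sequence under the documented tie-break,
# without the tabular assembly of find_orfs (hot path for per-gene CDS)
best_orf <- function(sequence, min_len_nt, require_start = FALSE) {
  rev <- NULL
  best <- NULL
  for (f in c(1:3, -(1:3))) {
    if (f < 0 && is.null(rev)) rev <- revcomp(sequence)
    hits <- frame_orfs(if (f > 0) sequence else rev, f, min_len_nt,
                       require_start)
    if (is.null(hits)) next
    j <- which.max(hits$length) # leftmost of the frame's maxima
    cand <- list(frame = f, length = hits$length[j],
                 cds_sequence = hits$cds_sequence[j])
    # frames are visited in preference order, so strict improvement only
    if (is.null(best) || cand$length > best$length) best <- cand
  }
  best
}

# one frame of one strand; returns a plain list of parallel vectors (hot path)
frame_orfs <- function(strand_seq, frame, min_len_nt, require_start) {
  offset <- abs(frame) - 1L # 0-based frame offset on this strand
  n <- nchar(strand_seq)
  n_codons <- (n - offset) %/% 3L
  if (n_codons < 1) return(NULL)
  starts <- offset + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(strand_seq, starts, starts + 2L)
  blocked <- codons %in% STOP_CODONS | grepl("N", codons, fixed = TRUE)
  runs <- rle(!blocked)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- which(runs$values)
  if (length(keep) == 0) return(NULL)
  s_vec <- integer(0); e_vec <- integer(0)
  for (i in keep) {
    s <- run_start[i]
    e <- run_end[i]
    if (require_start) {
      atg <- which(codons[s:e] == "ATG")
      if (length(atg) == 0) next
      s <- s + atg[1] - 1L
    }
    # a terminating stop codon (but not an uncallable N codon) belongs to
    # the ORF's span, as its final codon
    if (e < n_codons && codons[e + 1L] %in% STOP_CODONS) e <- e + 1L
    if (3L * (e - s + 1L) < min_len_nt) next
    s_vec <- c(s_vec, s); e_vec <- c(e_vec, e)
  }
  if (length(s_vec) == 0) return(NULL)
  len <- 3L * (e_vec - s_vec + 1L)
  start0 <- offset + 3L * (s_vec - 1L)
  list(frame = rep(frame, length(len)), start = start0, end = start0 + len,
       length = len,
       cds_sequence = substring(strand_seq, start0 + 1L, start0 + len))
}

#' Longest ORF per gene component
#'
#' For each component (gene) of a transcript table, scans every isoform with
#' [find_orfs()] and keeps the single longest CDS across all isoforms.
#' Components with no qualifying ORF are dropped. The result is itself a
#' transcript table (one CDS per component, id = component id), so it can be
#' fed straight into the signature machinery — this is how the
#' longest-ORF-per-gene signature mode is realized.
#'
#' @inheritParams find_orfs
#' @param transcripts A transcript tibble (possibly several strains).
#' @return A transcript tibble of CDS records with columns `strain`, `id`
#'   (= component id), `component_id`, `sequence`, `length`, plus `frame`
#'   and `source_transcript_id`.
#' @export
longest_orf_per_component <- function(transcripts, min_len_nt = 300L,
                                      require_start = FALSE) {
  best <- lapply(transcripts$sequence, best_orf, min_len_nt = min_len_nt,
                 require_start = require_start)
  hit <- !vapply(best, is.null, TRUE)
  cds <- tibble::tibble(
    strain = transcripts$strain[hit],
    source_transcript_id = transcripts$id[hit],
    component_id = transcripts$component_id[hit],
    frame = vapply(best[hit], `[[`, 1L, "frame"),
    sequence = vapply(best[hit], `[[`, "", "cds_sequence"),
    length = vapply(best[hit], `[[`, 1L, "length")
  )
  if (nrow(cds) == 0) {
    out <- tibble::tibble(
      strain = character(), id = character(), component_id = character(),
      sequence = character(), length = integer(),
      frame = integer(), source_transcript_id = character()
    )
    class(out) <- c("transcript_tbl", class(out))
    return(out)
  }
  out <- cds |>
    dplyr::group_by(.data$strain, .data$component_id) |>
    # within a component the per-isoform winners compete on the same rule
    dplyr::arrange(-.data$length, .data$frame < 0, abs(.data$frame),
                   .data$source_transcript_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(id = .data$component_id) |>
    dplyr::select("strain", "id", "component_id", "sequence", "length",
                  "frame", "source_transcript_id")
  class(out) <- c("transcript_tbl", class(out))
  out
}
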