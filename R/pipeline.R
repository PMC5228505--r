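#' Run the alignment-free phylogeny pipeline
#'
#' Orchestrates the full signature workflow: read (or accept) per-strain
#' transcript tables, optionally reduce them to the longest ORF per gene
#' component, compute usage-deviation signatures, pairwise Euclidean
#' distances, the UPGMA tree and bootstrap supports, and optionally re-root
#' on an outgroup. Three input modes are supported:
#' \describe{
#'   \item{`transcripts`}{signatures from all transcripts (mode A);}
#'   \item{`orf`}{signatures from the longest ORF per component (mode B,
#'     the default — per-gene CDS avoids over-weighting k-mers of genes
#'     with many isoforms);}
#'   \item{`shared-orf`}{mode B restricted to gene ids present in every
#'     strain of the membership table (mode C).}
#' }
#'
#' @param transcripts Either a pooled transcript tibble with a `strain`
#'   column, or a named character vector of FASTA paths (names = strains).
#' @param mode `"orf"` (default), `"transcripts"`, or `"shared-orf"`.
#' @param k k-mer length; 6 by default (4 and 6 give the same phylogeny on
#'   real chrysophyte data; 6 is the conventional choice).
#' @param null Null model for the signature (`"iid"` or `"markov1"`).
#' @param strand Strand policy for counting.
#' @param n_boot Bootstrap replicates (0 disables bootstrapping).
#' @param seed Integer seed for the bootstrap.
#' @param outgroup Optional leaf label to re-root on.
#' @param membership Long tibble `strain`, `gene_id`; required for
#'   `"shared-orf"`. Gene ids must match component ids of the ORF records.
#' @param min_orf_nt Minimum ORF length for the ORF modes.
#' @return A list of class `oud_pipeline`: `signatures`
#'   (`oud_signature_set`), `distances` (`oud_dist`), `tree`
#'   (`support_tree`), and `manifest` (parameters, input description,
#'   per-strain sequence counts).
#' @export
run_pipeline <- function(transcripts, mode = c("orf", "transcripts",
                                               "shared-orf"),
                         k = 6L, null = "iid", strand = "forward",
                         n_boot = 100L, seed = 1L, outgroup = NULL,
                         membership = NULL, min_orf_nt = 300L) {
  mode <- match.arg(mode)
  checksums <- NULL
  if (!is.data.frame(transcripts)) {
    paths <- transcripts
    abort_if(is.null(names(paths)) || any(!nzchar(names(paths))),
             "FASTA paths must be named by strain")
    checksums <- unname(tools::md5sum(paths))
    transcripts <- dplyr::bind_rows(
      purrr::imap(paths, function(p, s) read_transcripts(p, s))
    )
  }
  strains <- unique(transcripts$strain)
  abort_if(length(strains) < 2, "need at least two strains")

  input <- switch(
    mode,
    "transcripts" = transcripts,
    "orf" = longest_orf_per_component(transcripts, min_len_nt = min_orf_nt),
    "shared-orf" = {
      abort_if(is.null(membership), "shared-orf mode needs a membership table")
      shared <- membership |>
        dplyr::distinct(.data$strain, .data$gene_id) |>
        dplyr::count(.data$gene_id) |>
        dplyr::filter(.data$n == length(strains)) |>
        dplyr::pull(.data$gene_id)
      abort_if(length(shared) == 0, "no shared genes")
      orfs <- longest_orf_per_component(transcripts, min_len_nt = min_orf_nt)
      orfs[orfs$component_id %in% shared, ]
    }
  )
  abort_if(nrow(input) == 0, "no usable sequences after mode filtering")

  sigs <- oud_signatures(input, k = k, null = null, strand = strand)
  dm <- signature_distances(sigs)
  tree <- if (n_boot > 0) bootstrap_support(sigs, n_reps = n_boot, seed = seed)
          else upgma_tree(dm)
  if (!is.null(outgroup)) tree <- reroot_tree(tree, outgroup)

  counts_per_strain <- table(input$strain)
  manifest <- list(
    tool = "oudphylo", version = as.character(utils::packageVersion("oudphylo")),
    mode = mode, k = as.integer(k), null_model = null, strand = strand,
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    outgroup = outgroup, min_orf_nt = as.integer(min_orf_nt),
    strains = strains,
    sequences_per_strain = as.list(stats::setNames(as.integer(counts_per_strain),
                                                   names(counts_per_strain))),
    n_shared_genes = if (mode == "shared-orf")
      length(unique(input$component_id)) else NULL,
    input_md5 = checksums
  )
  structure(list(signatures = sigs, distances = dm, tree = tree,
                 manifest = manifest),
            class = "oud_pipeline")
}

#' @export
print.oud_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<oud_pipeline> mode=%s k=%d null=%s strains=%d boot=%d\n",
              m$mode, m$k, m$null_model, length(m$strains), m$n_boot))
  cat("tree:\n")
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Quality-control report: retention plus assembly statistics
#'
#' Joins per-strain read-retention percentages with per-strain assembly
#' statistics; strains present in only one of the two inputs keep `NA` in
#' the other's columns. A summary attribute carries the retention mean,
#' median, min and max.
#'
#' @param retention Retention tibble (`strain`, `raw_pairs`, `clean_pairs`)
#'   or path to such a TSV; may be `NULL`.
#' @param transcripts Pooled transcript tibble, named FASTA path vector, or
#'   `NULL`.
#' @return A tibble with one row per strain; retention summary in attribute
#'   `retention_summary`.
#' @export
qc_report <- function(retention = NULL, transcripts = NULL) {
  abort_if(is.null(retention) && is.null(transcripts),
           "need retention and/or transcripts")
  ret <- NULL
  if (!is.null(retention)) {
    if (is.character(retention)) retention <- read_retention(retention)
    ret <- percent_clean(retention)
  }
  stats_tbl <- NULL
  if (!is.null(transcripts)) {
    if (!is.data.frame(transcripts)) {
      transcripts <- dplyr::bind_rows(
        purrr::imap(transcripts, function(p, s) read_transcripts(p, s))
      )
    }
    stats_tbl <- assembly_stats(transcripts)
  }
  out <- if (is.null(ret)) stats_tbl
         else if (is.null(stats_tbl)) ret
         else dplyr::full_join(ret, stats_tbl, by = "strain")
  if (!is.null(ret)) attr(out, "retention_summary") <- summarize_retention(ret)
  out
}
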