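#' Read a gene membership table
#'
#' Accepts either the long form `strain<TAB>gene_id` (optionally with a
#' `present` column of 0/1 or TRUE/FALSE) or a wide boolean matrix whose
#' first column is `strain` and remaining columns are gene ids.
#'
#' @param path Path to the TSV.
#' @return A long tibble with columns `strain`, `gene_id` containing only
#'   present genes.
#' @export
read_membership <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  tbl <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                             check.names = FALSE))
  if (all(c("strain", "gene_id") %in% names(tbl))) {
    if ("present" %in% names(tbl)) {
      tbl <- tbl[as.logical(tbl$present), c("strain", "gene_id")]
    }
    return(dplyr::distinct(tbl[, c("strain", "gene_id")]))
  }
  abort_if(names(tbl)[1] != "strain",
           "membership table needs strain/gene_id columns or a wide strain matrix")
  tidyr::pivot_longer(tbl, -"strain", names_to = "gene_id",
                      values_to = "present") |>
    dplyr::filter(as.logical(.data$present)) |>
    dplyr::select("strain", "gene_id")
}

#' Partition genes by trophic-group presence
#'
#' A gene is present in a group if at least one strain of that group carries
#' it. Genes present in exactly one group are that group's exclusive genes;
#' genes present in every group form the core; the total counts genes
#' present in at least one strain. This is the gene-content comparison used
#' to contrast heterotrophic, mixotrophic and phototrophic strains.
#'
#' @param membership Long tibble `strain`, `gene_id` (present genes only).
#' @param groups Tibble `strain`, `group` assigning every strain to exactly
#'   one group.
#' @return A tibble `category`, `count` with one `exclusive_<group>` row per
#'   group plus `core` and `total` rows; the full gene-by-group presence
#'   matrix is attached as attribute `presence`.
#' @export
gene_content_partition <- function(membership, groups) {
  abort_if(anyDuplicated(groups$strain) > 0, "strain assigned to multiple groups")
  missing <- setdiff(unique(membership$strain), groups$strain)
  abort_if(length(missing) > 0,
           paste0("strains without group assignment: ",
                  paste(missing, collapse = ", ")))
  group_levels <- sort(unique(groups$group))
  pres <- membership |>
    dplyr::inner_join(groups, by = "strain") |>
    dplyr::distinct(.data$gene_id, .data$group) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "group", values_from = "present",
                       values_fill = FALSE)
  for (g in setdiff(group_levels, names(pres))) pres[[g]] <- FALSE
  pres_mat <- as.matrix(pres[, group_levels, drop = FALSE])
  n_groups_present <- rowSums(pres_mat)
  exclusive <- vapply(group_levels, function(g) {
    sum(pres_mat[, g] & n_groups_present == 1)
  }, 1L)
  out <- tibble::tibble(
    category = c(paste0("exclusive_", group_levels), "core", "total"),
    count = c(unname(exclusive),
              sum(n_groups_present == length(group_levels)),
              nrow(pres_mat))
  )
  attr(out, "presence") <- pres
  out
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway, tests whether the selected gene set over-represents the
#' pathway's members: with a universe of `N_u` genes of which `K` belong to
#' the pathway, and `n` selected genes of which `x` are pathway members, the
#' p-value is the hypergeometric upper tail `P(X >= x)`. Pathway member sets
#' are intersected with the universe before testing. Benjamini-Hochberg
#' adjusted p-values are reported alongside.
#'
#' @param selected Character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param universe Character vector of all detectable gene ids.
#' @param pathways Tibble `pathway_id`, `gene_id` (one row per member), or a
#'   named list of gene-id vectors.
#' @param alpha Raw-p significance threshold used for the `significant`
#'   flag; 0.1 by default, the customary threshold for expression-based
#'   enrichment (gene-content contrasts conventionally use 0.001).
#' @return A tibble with one row per pathway: `pathway_id`, `x`, `n`, `K`,
#'   `N_u`, `p_value`, `p_adjust`, `significant`, sorted by `p_value`.
#' @examples
#' hypergeom_pathway_enrichment(
#'   selected = c("g1", "g2"), universe = paste0("g", 1:10),
#'   pathways = list(pw1 = c("g1", "g2", "g3"))
#' )
#' @export
hypergeom_pathway_enrichment <- function(selected, universe, pathways,
                                         alpha = 0.1) {
  universe <- unique(universe)
  abort_if(length(universe) == 0, "empty gene universe")
  selected <- unique(selected)
  abort_if(!all(selected %in% universe), "selected genes outside the universe")
  if (is.data.frame(pathways)) {
    pathways <- split(pathways$gene_id, pathways$pathway_id)
  }
  n_u <- length(universe)
  n_sel <- length(selected)
  rows <- purrr::imap(pathways, function(members, id) {
    members <- intersect(unique(members), universe)
    k_path <- length(members)
    x <- length(intersect(selected, members))
    # upper tail P(X >= x); X ~ Hypergeometric(N_u, K, n)
    p <- stats::phyper(x - 1, k_path, n_u - k_path, n_sel, lower.tail = FALSE)
    tibble::tibble(pathway_id = id, x = x, n = n_sel, K = k_path, N_u = n_u,
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjust <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  dplyr::arrange(out, .data$p_value, .data$pathway_id)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment:
#' `adj_i = min_{j >= i} (m / rank_j) p_(j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(pvalues) {
  abort_if(any(pvalues < 0 | pvalues > 1 | is.na(pvalues)),
           "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read pathway definitions
#'
#' TSV with columns `pathway_id`, `gene_id`.
#' @param path Path to the TSV.
#' @return Tibble `pathway_id`, `gene_id`.
#' @export
read_pathways <- function(path) {
  tbl <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  abort_if(!all(c("pathway_id", "gene_id") %in% names(tbl)),
           "pathway table must have columns pathway_id, gene_id")
  tbl
}

#' Read module definitions
#'
#' TSV with columns `module_id`, `kind` (`pathway_module` or
#' `structural_complex`), `member` and `is_core`. For a pathway module the
#' `member` column holds required enzyme gene ids (`is_core` flags the core
#' subset); for a structural complex it holds constituent pathway-module
#' ids (`is_core` ignored).
#'
#' @param path Path to the TSV.
#' @return Tibble `module_id`, `kind`, `member`, `is_core`.
#' @export
read_modules <- function(path) {
  tbl <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  abort_if(!all(c("module_id", "kind", "member", "is_core") %in% names(tbl)),
           "module table must have columns module_id, kind, member, is_core")
  tbl$is_core <- as.logical(tbl$is_core)
  tbl
}

#' Classify module completeness for one strain
#'
#' Operational-module classification in the style used for essential
#' KEGG modules:
#' \itemize{
#'   \item A \emph{pathway module} is `complete` when at most one required
#'     enzyme is missing from the strain's gene set; `partial` when more
#'     than one is missing but all core enzymes are present; `missing`
#'     otherwise.
#'   \item A \emph{structural complex} is classified from its constituent
#'     pathway modules: `complete` when the majority (strictly more than
#'     half) of them are complete, `missing` when none is, `partial`
#'     otherwise (the exact-half case falls here).
#' }
#'
#' @param strain_genes Character vector of gene ids detected in the strain.
#' @param modules Module definition tibble (see [read_modules()]).
#' @return Tibble `module_id`, `kind`, `n_required`, `n_missing`, `status`.
#' @export
module_completeness <- function(strain_genes, modules) {
  pm <- modules[modules$kind == "pathway_module", ]
  sc <- modules[modules$kind == "structural_complex", ]
  abort_if(nrow(pm) + nrow(sc) == 0, "no module definitions")
  pm_rows <- pm |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(
      kind = "pathway_module",
      n_required = dplyr::n(),
      n_missing = sum(!.data$member %in% strain_genes),
      core_intact = all(.data$member[.data$is_core] %in% strain_genes),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_missing <= 1 ~ "complete",
      .data$core_intact ~ "partial",
      TRUE ~ "missing"
    ))
  pm_status <- stats::setNames(pm_rows$status, pm_rows$module_id)
  sc_rows <- sc |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(
      kind = "structural_complex",
      n_required = dplyr::n(),
      n_missing = {
        dangling <- setdiff(.data$member, names(pm_status))
        abort_if(length(dangling) > 0,
                 paste0("structural complex references unknown modules: ",
                        paste(dangling, collapse = ", ")))
        sum(pm_status[.data$member] != "complete")
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_functional = .data$n_required - .data$n_missing,
      status = dplyr::case_when(
        .data$n_functional > .data$n_required / 2 ~ "complete",
        .data$n_functional == 0 ~ "missing",
        TRUE ~ "partial"
      )
    ) |>
    dplyr::select(-"n_functional")
  dplyr::bind_rows(
    dplyr::select(pm_rows, -"core_intact"),
    sc_rows
  )
}
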