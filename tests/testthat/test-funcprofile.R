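toy_groups <- tibble::tibble(
  strain = paste0("s", 1:6),
  group = rep(c("hetero", "mixo", "photo"), each = 2)
)

test_that("gene-content partition matches exhaustive enumeration on a toy table", {
  # hand-built presence patterns over 6 genes
  membership <- tibble::tribble(
    ~strain, ~gene_id,
    "s1", "gAll", "s2", "gAll", "s3", "gAll", "s4", "gAll", "s5", "gAll",
    "s6", "gAll",
    "s1", "gHet",                       # hetero-exclusive (one strain)
    "s3", "gMix", "s4", "gMix",         # mixo-exclusive
    "s5", "gPho",                       # photo-exclusive
    "s1", "gHM", "s3", "gHM",           # hetero + mixo, no group exclusive
    "s2", "gCore2", "s4", "gCore2", "s6", "gCore2" # one strain per group
  )
  part <- gene_content_partition(membership, toy_groups)
  counts <- stats::setNames(part$count, part$category)
  expect_equal(unname(counts["exclusive_hetero"]), 1)
  expect_equal(unname(counts["exclusive_mixo"]), 1)
  expect_equal(unname(counts["exclusive_photo"]), 1)
  expect_equal(unname(counts["core"]), 2)
  expect_equal(unname(counts["total"]), 6)

  # brute force on random tables: exclusives + core + shared-by-two == total
  set.seed(55)
  for (rep in 1:10) {
    genes <- paste0("g", 1:40)
    mem <- tidyr::expand_grid(strain = toy_groups$strain, gene_id = genes) |>
      dplyr::filter(stats::runif(dplyr::n()) < 0.3)
    mem <- dplyr::bind_rows(
      mem, tibble::tibble(strain = "s1", gene_id = "g_anchor")
    )
    part <- gene_content_partition(mem, toy_groups)
    counts <- stats::setNames(part$count, part$category)
    pres <- attr(part, "presence")
    n_grp <- rowSums(as.matrix(pres[, c("hetero", "mixo", "photo")]))
    expect_equal(sum(counts[startsWith(names(counts), "exclusive_")]),
                 sum(n_grp == 1))
    expect_equal(unname(counts["core"]), sum(n_grp == 3))
    expect_equal(unname(counts["total"]),
                 sum(n_grp == 1) + sum(n_grp == 2) + sum(n_grp == 3))
  }

  expect_error(
    gene_content_partition(tibble::tibble(strain = "sX", gene_id = "g1"),
                           toy_groups),
    "without group"
  )
})

test_that("single-group-everywhere gene is core; all exclusives zero", {
  membership <- tidyr::expand_grid(strain = toy_groups$strain, gene_id = "g1")
  part <- gene_content_partition(membership, toy_groups)
  counts <- stats::setNames(part$count, part$category)
  expect_equal(unname(counts["core"]), 1)
  expect_true(all(counts[startsWith(names(counts), "exclusive_")] == 0))
})

test_that("hypergeometric enrichment is exact", {
  universe <- paste0("g", 1:10)
  # zero overlap: upper tail includes X >= 0, so p = 1 exactly
  res0 <- hypergeom_pathway_enrichment(
    selected = paste0("g", 1:5), universe = universe,
    pathways = list(pwEmpty = paste0("g", 6:10))
  )
  expect_equal(res0$x, 0)
  expect_equal(res0$p_value, 1)

  # N_u=10, K=5, n=5, x=5: p = C(5,5) C(5,0) / C(10,5) = 1/252
  res5 <- hypergeom_pathway_enrichment(
    selected = paste0("g", 1:5), universe = universe,
    pathways = list(pwFull = paste0("g", 1:5))
  )
  expect_equal(res5$p_value, 1 / 252, tolerance = 1e-12)

  # agreement with the combinatorial tail-sum oracle across configurations
  set.seed(66)
  for (rep in 1:30) {
    n_u <- sample(10:60, 1)
    universe <- paste0("g", seq_len(n_u))
    k_path <- sample(1:n_u, 1)
    n_sel <- sample(1:n_u, 1)
    path_genes <- sample(universe, k_path)
    sel <- sample(universe, n_sel)
    res <- hypergeom_pathway_enrichment(sel, universe,
                                        list(pw = path_genes))
    expect_equal(res$p_value,
                 oracle_hyper_tail(res$x, k_path, n_u, n_sel),
                 tolerance = 1e-12)
  }

  # members outside the universe are ignored before testing
  res <- hypergeom_pathway_enrichment(
    selected = "g1", universe = paste0("g", 1:4),
    pathways = list(pw = c("g1", "gZZ"))
  )
  expect_equal(res$K, 1)
  expect_error(hypergeom_pathway_enrichment("g1", character(0),
                                            list(pw = "g1")),
               "empty")
})

test_that("planted enrichment yields the planted pathway's minimal p", {
  set.seed(77)
  for (rep in 1:5) {
    universe <- paste0("g", 1:200)
    pathways <- lapply(1:8, function(i) sample(universe, 20))
    names(pathways) <- paste0("pw", 1:8)
    # selected set over-representing pw3
    selected <- unique(c(sample(pathways$pw3, 15), sample(universe, 10)))
    res <- hypergeom_pathway_enrichment(selected, universe, pathways)
    expect_equal(res$pathway_id[1], "pw3")
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.04), 0.04)
  set.seed(88)
  p <- runif(50)
  adj <- bh_adjust(p)
  # monotone in the raw order, bounded by [p, 1], step-up consistent
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12 & adj <= 1))
  m <- length(p)
  ord <- order(p)
  manual <- rev(cummin(rev(m / seq_len(m) * p[ord])))
  expect_equal(adj[ord], pmin(manual, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("module completeness implements the three-colour rules", {
  mods <- toy_modules()
  all_genes <- c(paste0("e", 1:10), paste0("t", 1:4))

  # all enzymes present -> complete (and the complex with both modules too)
  res <- module_completeness(all_genes, mods)
  expect_equal(res$status[res$module_id == "M_glyco"], "complete")
  expect_equal(res$status[res$module_id == "CX_atp"], "complete")

  # exactly one missing -> still complete
  res <- module_completeness(setdiff(all_genes, "e1"), mods)
  expect_equal(res$status[res$module_id == "M_glyco"], "complete")

  # two non-core missing, core (e4..e6) intact -> partial
  res <- module_completeness(setdiff(all_genes, c("e1", "e2")), mods)
  expect_equal(res$status[res$module_id == "M_glyco"], "partial")

  # two missing including a core enzyme -> missing
  res <- module_completeness(setdiff(all_genes, c("e1", "e4")), mods)
  expect_equal(res$status[res$module_id == "M_glyco"], "missing")

  # structural complex: one of two complete -> exact half -> partial
  res <- module_completeness(setdiff(all_genes, c("e1", "e2")), mods)
  expect_equal(res$status[res$module_id == "CX_atp"], "partial")

  # no constituent complete -> missing
  res <- module_completeness(character(0), mods)
  expect_equal(res$status[res$module_id == "CX_atp"], "missing")

  # dangling module reference errors
  bad <- dplyr::bind_rows(mods, tibble::tibble(
    module_id = "CX_bad", kind = "structural_complex",
    member = "M_nowhere", is_core = FALSE
  ))
  expect_error(module_completeness(all_genes, bad), "unknown modules")
})

test_that("tabular definition files load through their readers", {
  pw <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tgene_id", "pw1\tg1", "pw1\tg2", "pw2\tg3"), pw)
  expect_equal(nrow(read_pathways(pw)), 3)

  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("module_id\tkind\tmember\tis_core",
               "M1\tpathway_module\te1\tTRUE",
               "M1\tpathway_module\te2\tFALSE",
               "C1\tstructural_complex\tM1\tFALSE"), md)
  mods <- read_modules(md)
  expect_equal(mods$is_core, c(TRUE, FALSE, FALSE))
  expect_equal(module_completeness(c("e1", "e2"), mods)$status,
               c("complete", "complete"))

  mem_long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tgene_id\tpresent", "s1\tg1\t1", "s1\tg2\t0",
               "s2\tg1\t1"), mem_long)
  m <- read_membership(mem_long)
  expect_equal(nrow(m), 2)

  mem_wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tg1\tg2", "s1\tTRUE\tFALSE", "s2\tTRUE\tTRUE"),
             mem_wide)
  m <- read_membership(mem_wide)
  expect_equal(sort(m$gene_id[m$strain == "s2"]), c("g1", "g2"))
})
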