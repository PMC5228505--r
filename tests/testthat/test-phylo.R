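random_ultra <- function(n, seed) random_ultrametric_tree(n, depth = 1,
                                                          seed = seed)

test_that("Euclidean signature distance follows the formula", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(4)
  x <- rnorm(256); y <- rnorm(256)
  expect_equal(euclidean_distance(x, y), sqrt(sum((x - y)^2)))
  expect_equal(euclidean_distance(x, x), 0)
  expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))

  a <- structure(rnorm(16), k = 2L, null_model = "iid")
  b <- structure(rnorm(256), k = 4L, null_model = "iid")
  expect_error(euclidean_distance(a, b), "different k")
})

test_that("the distance matrix is symmetric with zero diagonal", {
  set.seed(8)
  m <- matrix(rnorm(4 * 64), 4, dimnames = list(paste0("s", 1:4), NULL))
  dm <- signature_distances(m)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(is.finite(dm)))
  # duplicated signature rows give zero distance and consistent columns
  m2 <- rbind(m, m[1, , drop = FALSE])
  rownames(m2) <- c(rownames(m), "s1b")
  dm2 <- signature_distances(m2)
  expect_equal(dm2["s1", "s1b"], 0)
  expect_equal(dm2["s1b", "s2"], dm2["s1", "s2"])
  rownames(m2)[5] <- "s1"
  expect_error(signature_distances(m2), "unique")
})

test_that("UPGMA reproduces the hand-worked 3-taxon case", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  h <- oudphylo:::tree_node_heights(tr)
  n <- length(tr$tip.label)
  expect_equal(sort(h[(n + 1):(n + tr$Nnode)]), c(1, 4))
  # topology ((A,B),C): the A-B cherry is a clade
  clades <- lapply(ape::prop.part(tr), function(i) sort(tr$tip.label[i]))
  expect_true(list(c("A", "B")) %in% clades)
  # two-label case: single root at height 3
  d2 <- matrix(c(0, 6, 6, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma_tree(d2)
  expect_equal(unname(tr2$edge.length), c(3, 3))
})

test_that("UPGMA recovers any ultrametric tree from its cophenetic distances", {
  for (seed in 1:25) {
    n <- sample(4:16, 1)
    truth <- random_ultra(n, seed)
    dm <- ape::cophenetic.phylo(truth)
    rec <- upgma_tree(dm)
    expect_equal(rf_distance(rec, truth), 0)
    # heights agree with the generating tree's
    expect_equal(max(oudphylo:::tree_node_heights(rec)),
                 max(ape::node.depth.edgelength(truth)), tolerance = 1e-9)
    # ultrametricity: all leaves at height 0
    h <- oudphylo:::tree_node_heights(rec)
    expect_lt(max(abs(h[seq_len(n)])), 1e-9)
  }
})

test_that("UPGMA agrees with the reference average-linkage implementation", {
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:12, 1)
    m <- matrix(rnorm(n * 50), n, dimnames = list(paste0("s", 1:n), NULL))
    dm <- signature_distances(m)
    mine <- upgma_tree(dm)
    ref <- phangorn::upgma(stats::as.dist(dm))
    expect_equal(rf_distance(mine, ref), 0)
    expect_equal(sort(ape::cophenetic.phylo(mine)[rownames(dm), rownames(dm)]),
                 sort(ape::cophenetic.phylo(ref)[rownames(dm), rownames(dm)]),
                 tolerance = 1e-9)
  }
})

test_that("equal-distance ties are broken lexicographically and deterministically", {
  labs <- c("d", "b", "a", "c")
  d <- matrix(2, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  tr <- upgma_tree(d)
  # first merge must join the lexicographically least pair (a, b)
  pairs <- ape::prop.part(tr)
  blocks <- lapply(pairs, function(i) sort(tr$tip.label[i]))
  expect_true(list(c("a", "b")) %in% blocks)
  expect_identical(ape::write.tree(tr), ape::write.tree(upgma_tree(d)))
})

test_that("bipartition sets are canonical and exclude trivial splits", {
  t_bal <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(bipartitions(t_bal), "A,B")
  t_cat <- ape::read.tree(text = "(((A,B),C),D);")
  expect_equal(bipartitions(t_cat), "A,B")
  t2 <- ape::read.tree(text = "(A,B);")
  expect_length(bipartitions(t2), 0)
})

test_that("Robinson-Foulds distance matches the reference implementation", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf labels")
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    a <- random_ultra(8, seed)
    b <- random_ultra(8, seed + 100)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(a, b, rooted = FALSE)))
    expect_equal(rf_distance(a, b), rf_distance(b, a))
  }
})

test_that("bootstrap support finds a planted two-block split with certainty", {
  set.seed(31)
  base <- matrix(rnorm(4 * 64, sd = 0.05), 4,
                 dimnames = list(c("s1", "s2", "s3", "s4"), NULL))
  base[c("s3", "s4"), ] <- base[c("s3", "s4"), ] + 5 # offset in every column
  tr <- bootstrap_support(base, n_reps = 100, seed = 99)
  support <- attr(tr, "support")
  expect_equal(length(support), 1) # one internal split in a 4-leaf tree
  expect_equal(unname(support[["s1,s2"]]), 100)

  # single replicate: supports can only be 0 or 100
  tr1 <- bootstrap_support(base, n_reps = 1, seed = 5)
  expect_true(all(attr(tr1, "support") %in% c(0, 100)))

  # bit-identical reproducibility for a fixed seed
  trA <- bootstrap_support(base, n_reps = 25, seed = 7)
  trB <- bootstrap_support(base, n_reps = 25, seed = 7)
  expect_identical(attr(trA, "support"), attr(trB, "support"))
  expect_identical(ape::write.tree(trA), ape::write.tree(trB))

  expect_error(bootstrap_support(base, n_reps = 0), "n_reps")
})

test_that("planted-split support concentrates as the effect grows", {
  supports <- vapply(c(0.2, 1, 5), function(effect) {
    vals <- vapply(1:5, function(seed) {
      set.seed(seed)
      m <- matrix(rnorm(4 * 64, sd = 1), 4,
                  dimnames = list(paste0("s", 1:4), NULL))
      m[3:4, ] <- m[3:4, ] + effect
      tr <- bootstrap_support(m, n_reps = 50, seed = seed)
      s <- attr(tr, "support")
      if ("s1,s2" %in% names(s)) s[["s1,s2"]] else 0
    }, 0)
    mean(vals)
  }, 0)
  expect_true(!is.unsorted(supports))
  expect_equal(supports[3], 100)
})

test_that("re-rooting preserves the unrooted topology", {
  tr <- random_ultra(8, 3)
  for (leaf in tr$tip.label[c(1, 4, 8)]) {
    rr <- reroot_tree(tr, leaf)
    expect_setequal(bipartitions(rr), bipartitions(tr))
    rr2 <- reroot_tree(rr, leaf)
    expect_setequal(bipartitions(rr2), bipartitions(rr))
  }
  expect_error(reroot_tree(tr, "nope"), "unknown leaf")
})

test_that("Newick round-trips preserve topology, heights and supports", {
  for (seed in 1:10) {
    tr <- random_ultra(sample(4:12, 1), seed)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(rf_distance(tr, back), 0)
    expect_equal(sort(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label]),
                 sort(ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]),
                 tolerance = 1e-9)
  }
  # supports travel as internal node labels
  set.seed(1)
  m <- matrix(rnorm(4 * 32), 4, dimnames = list(paste0("s", 1:4), NULL))
  m[3:4, ] <- m[3:4, ] + 4
  tr <- bootstrap_support(m, n_reps = 20, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_true("100" %in% back$node.label)
  # two-leaf serialization
  d2 <- matrix(c(0, 6, 6, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(upgma_tree(d2), f2)
  expect_match(readLines(f2), "^\\(A:3,B:3\\)?.*;$")
  # malformed input errors
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B,;", bad)
  expect_error(read_newick(bad))
})

test_that("PHYLIP distance serialization round-trips", {
  set.seed(14)
  m <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("s", 1:5), NULL))
  dm <- signature_distances(m)
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(dm, f)
  back <- read_phylip_dist(f)
  expect_equal(rownames(back), rownames(dm))
  expect_equal(unclass(back), unclass(dm), tolerance = 1e-9,
               ignore_attr = TRUE)
})
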