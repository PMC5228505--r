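#' Euclidean distance between two usage-deviation signatures
#'
#' `d(x, y) = sqrt( sum_z (OUD_x(z) - OUD_y(z))^2 )` over all 4^k k-mers z.
#'
#' @param x,y `oud_signature` objects (or plain numeric vectors) of equal
#'   length; when both carry a `k`/null-model attribute these must agree.
#' @return A nonnegative scalar.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(x, y) {
  kx <- attr(x, "k"); ky <- attr(y, "k")
  abort_if(!is.null(kx) && !is.null(ky) && kx != ky, "signatures have different k")
  nx <- attr(x, "null_model"); ny <- attr(y, "null_model")
  abort_if(!is.null(nx) && !is.null(ny) && nx != ny,
           "signatures use different null models")
  abort_if(length(x) != length(y), "signatures have different lengths")
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

#' All pairwise signature distances
#'
#' @param sigs An `oud_signature_set` matrix (strains x k-mers; see
#'   [oud_signatures()]), or any numeric matrix with strain rownames.
#' @return A symmetric matrix of class `oud_dist` with zero diagonal and
#'   strain labels.
#' @export
signature_distances <- function(sigs) {
  abort_if(nrow(sigs) < 2, "need at least two signatures")
  labels <- rownames(sigs)
  abort_if(is.null(labels) || anyDuplicated(labels) > 0,
           "signatures must carry unique strain labels")
  d <- as.matrix(stats::dist(unclass(sigs), method = "euclidean"))
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("oud_dist", "matrix", "array"))
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group average-linkage clustering: repeatedly
#' merge the pair of clusters at minimal average distance; the merged
#' cluster's distance to any other is the size-weighted average of its
#' parts; the new node sits at half the merge distance, so root-to-leaf
#' path lengths are all equal (ultrametric). Ties on the minimum are broken
#' deterministically: among equal-minimum pairs the pair whose (smaller
#' leaf-label, larger leaf-label) — each cluster represented by its
#' lexicographically smallest leaf — is lexicographically least wins.
#'
#' @param dm Symmetric distance matrix with labels (e.g. from
#'   [signature_distances()]), or a `dist`.
#' @return A rooted ultrametric `phylo` (class `support_tree`), node
#'   supports unset.
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_tree(d)
#' @export
upgma_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- unclass(dm)
  labels <- rownames(dm)
  n <- nrow(dm)
  abort_if(n < 2, "need at least two labels")
  abort_if(is.null(labels), "distance matrix must have labels")
  abort_if(any(!is.finite(dm)), "non-finite distance")
  abort_if(any(abs(dm - t(dm)) > 1e-12) || any(diag(dm) != 0),
           "distance matrix must be symmetric with zero diagonal")

  # active clusters: node id, size, height, representative (smallest leaf label)
  node_id <- seq_len(n)            # leaves 1..n; internals n+1..2n-1
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_label <- labels
  d <- dm
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  edge_len <- numeric(2L * (n - 1L))
  node_height <- numeric(2L * n - 1L)
  e <- 0L
  next_node <- n

  for (step in seq_len(n - 1L)) {
    m <- length(node_id)
    # find minimal pair with lexicographic tie-break on representatives
    best <- NULL
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- d[i, j]
        if (dij < best_d - 1e-15) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-15) {
          cand <- sort(c(rep_label[i], rep_label[j]))
          cur <- sort(c(rep_label[best[1]], rep_label[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best_d <- min(best_d, dij); best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    next_node <- next_node + 1L
    h <- best_d / 2
    node_height[next_node] <- h
    for (child in c(i, j)) {
      e <- e + 1L
      edges[e, ] <- c(next_node, node_id[child])
      edge_len[e] <- h - height[child]
    }
    # size-weighted average linkage update
    if (m > 2L) {
      others <- setdiff(seq_len(m), c(i, j))
      newd <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d <- d[others, others, drop = FALSE]
      d <- rbind(cbind(d, newd), c(newd, 0))
    } else {
      d <- matrix(0, 1, 1)
    }
    new_rep <- min(rep_label[i], rep_label[j])
    new_size <- size[i] + size[j]
    keep <- setdiff(seq_along(node_id), c(i, j))
    node_id <- c(node_id[keep], next_node)
    size <- c(size[keep], new_size)
    height <- c(height[keep], h)
    rep_label <- c(rep_label[keep], new_rep)
  }

  # internal nodes were numbered in merge order (root last); ape numbers the
  # root n+1, so reverse the internal numbering: n+s -> 2n-s
  internal <- edges > n
  edges[internal] <- 2L * n - (edges[internal] - n)
  tr <- structure(
    list(edge = edges, edge.length = edge_len, tip.label = labels,
         Nnode = n - 1L),
    class = "phylo"
  )
  tr <- ape::reorder.phylo(tr, "cladewise")
  class(tr) <- c("support_tree", "phylo")
  tr
}

#' Node heights of an ultrametric tree
#' @keywords internal
tree_node_heights <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Canonical bipartitions (splits) of a tree
#'
#' One bipartition per internal edge of the unrooted topology, identified by
#' its smaller block (ties by lexicographic order of the sorted,
#' comma-joined block). Trivial splits — single leaves, and the root split
#' of the rooted representation — are excluded.
#'
#' @param tree A `phylo`.
#' @return Character vector of canonical split keys (sorted block members
#'   joined by `","`); empty for trees of fewer than 4 leaves.
#' @export
bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  abort_if(n < 2, "need at least two leaves")
  if (n < 4) return(character(0))
  clades <- ape::prop.part(tree)
  keys <- vapply(clades, function(idx) {
    block <- sort(tips[idx])
    other <- sort(setdiff(tips, block))
    if (length(block) < length(other)) {
      paste(block, collapse = ",")
    } else if (length(other) < length(block)) {
      paste(other, collapse = ",")
    } else {
      min(paste(block, collapse = ","), paste(other, collapse = ","))
    }
  }, "")
  sizes <- vapply(strsplit(keys, ",", fixed = TRUE), length, 1L)
  unique(keys[sizes >= 2 & sizes <= n - 2])
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the trees' bipartition sets
#' (unrooted, non-trivial splits).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  abort_if(!setequal(t1$tip.label, t2$tip.label),
           "trees must share the same leaf labels")
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap bipartition support by resampling signature components
#'
#' The reference tree is the UPGMA tree of the full signature distance
#' matrix. Each bootstrap replicate draws 4^k signature component indices
#' with replacement — the same index multiset applied to every strain's
#' signature, so resampled columns stay comparable across strains — then
#' rebuilds distances and the UPGMA tree. The support of each internal
#' bipartition of the reference tree is the percentage of replicates whose
#' tree contains that split. Supports are written onto the reference tree's
#' internal node labels.
#'
#' @param sigs An `oud_signature_set` (strains x 4^k matrix).
#' @param n_reps Number of replicates (>= 1); 100 by default.
#' @param seed Integer seed making the resampling reproducible.
#' @return The reference tree (`support_tree`) with `node.label` holding
#'   integer percent supports (root and trivial splits: `NA`), plus a
#'   `support` attribute naming each scored split.
#' @export
bootstrap_support <- function(sigs, n_reps = 100L, seed = 1L) {
  abort_if(n_reps < 1, "n_reps must be >= 1")
  m <- unclass(sigs)
  ref <- upgma_tree(signature_distances(sigs))
  ref_splits <- bipartitions(ref)
  hits <- stats::setNames(rep(0L, length(ref_splits)), ref_splits)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      boot <- m[, idx, drop = FALSE]
      rownames(boot) <- rownames(m)
      bt <- upgma_tree(signature_distances(boot))
      found <- bipartitions(bt)
      present <- ref_splits %in% found
      hits[present] <- hits[present] + 1L
    }
  })
  support <- 100 * hits / n_reps
  annotate_support(ref, support)
}

# write per-split supports onto internal node labels of a rooted tree
annotate_support <- function(tree, support) {
  n <- length(tree$tip.label)
  tips <- tree$tip.label
  labs <- rep(NA_character_, tree$Nnode)
  clades <- ape::prop.part(tree)
  for (i in seq_along(clades)) {
    block <- sort(tips[clades[[i]]])
    other <- sort(setdiff(tips, block))
    key <- if (length(block) < length(other)) paste(block, collapse = ",")
           else if (length(other) < length(block)) paste(other, collapse = ",")
           else min(paste(block, collapse = ","), paste(other, collapse = ","))
    if (key %in% names(support)) labs[i] <- format(round(support[[key]]))
  }
  tree$node.label <- labs
  attr(tree, "support") <- support
  class(tree) <- c("support_tree", "phylo")
  tree
}

#' Re-root a tree on an outgroup leaf
#'
#' Roots the tree on the pendant edge of `outgroup_label` (the conventional
#' way signature trees are oriented against an independent marker-gene
#' phylogeny). The unrooted topology — hence the bipartition set — is
#' unchanged.
#'
#' @param tree A `phylo`.
#' @param outgroup_label A leaf label.
#' @return The re-rooted tree.
#' @export
reroot_tree <- function(tree, outgroup_label) {
  abort_if(!outgroup_label %in% tree$tip.label,
           paste0("unknown leaf: ", outgroup_label))
  out <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  class(out) <- c("support_tree", "phylo")
  out
}

#' Write / read trees as Newick
#'
#' Branch lengths come from node heights; bootstrap supports are stored as
#' internal node labels. Reading a tree without internal labels simply
#' leaves supports unset.
#'
#' @param tree A `phylo`.
#' @param path File path.
#' @return `path` (write) or a `support_tree` (read).
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$node.label)) {
    tree$node.label[is.na(tree$node.label)] <- ""
  }
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  abort_if(is.null(tr), paste0("malformed Newick in ", path))
  class(tr) <- c("support_tree", "phylo")
  tr
}

#' Distance matrix serialization
#'
#' Writes a labelled symmetric matrix as PHYLIP square format (and reads it
#' back).
#'
#' @param dm Matrix with labels.
#' @param path File path.
#' @return `path` (write) or an `oud_dist` matrix (read).
#' @export
write_phylip_dist <- function(dm, path) {
  dm <- as.matrix(dm)
  lines <- c(format(nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste(c(rownames(dm)[i],
                       format(dm[i, ], digits = 10)), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  parts <- strsplit(lines[1 + seq_len(n)], "\t", fixed = TRUE)
  labels <- vapply(parts, `[`, "", 1)
  d <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("oud_dist", "matrix", "array"))
}

#' @export
tidy.support_tree <- function(x, ...) {
  n <- length(x$tip.label)
  heights <- tree_node_heights(x)
  support <- attr(x, "support")
  internal <- n + seq_len(x$Nnode)
  tibble::tibble(
    node = internal,
    height = heights[internal],
    support = if (!is.null(x$node.label)) suppressWarnings(as.numeric(x$node.label))
              else NA_real_
  )
}

#' @export
glance.support_tree <- function(x, ...) {
  heights <- tree_node_heights(x)
  tibble::tibble(
    n_leaves = length(x$tip.label),
    n_internal = x$Nnode,
    tree_height = max(heights),
    n_supported = sum(!is.na(suppressWarnings(as.numeric(x$node.label))))
  )
}
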