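#' p-distance matrix from an alignment
#'
#' For each pair of equal-length aligned sequences, the proportion of
#' differing columns among columns where neither sequence has a gap.
#'
#' @param aligned A named character vector of equal-length aligned sequences,
#'   or a tibble with columns `id` and `sequence` (e.g. from
#'   [generate_clade_set()]).
#' @return A symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames.
#' @export
#' @examples
#' p_distance(c(a = "AAAA", b = "AAAT", c = "AATT"))
p_distance <- function(aligned) {
  if (is.data.frame(aligned)) {
    aligned <- setNames(aligned$sequence, aligned$id)
  }
  n <- length(aligned)
  if (n < 3L) abort("need at least 3 sequences")
  if (length(unique(nchar(aligned))) != 1L) abort("sequences must have equal length")
  ids <- names(aligned) %||% paste0("seq", seq_len(n))
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf("sequences '%s' and '%s' share no gap-free columns", ids[i], ids[j]))
      }
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix. Ties on the Q criterion are
#' broken by the lexicographically smallest pair of cluster labels (a
#' cluster's label is its alphabetically first member tip). Negative branch
#' lengths are clamped to zero with the deficit shifted to the sibling edge
#' (the final three-taxon star clamps without a shift).
#'
#' @param d Symmetric distance matrix with labels as dimnames (at least 3
#'   taxa), e.g. from [p_distance()].
#' @param clamp_negative Clamp negative branch lengths (default TRUE).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) abort("need at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    abort("distance matrix must be symmetric, non-negative, with zero diagonal")
  }

  # active clusters: node id (tips 1..n; the k-th join is node n+1+k), label =
  # alphabetically first member tip (used only for deterministic tie-breaks)
  active <- data.frame(node = seq_len(n), label = labels, stringsAsFactors = FALSE)
  D <- d
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  n_join <- 0L

  clamp_pair <- function(li, lj) {
    if (!clamp_negative) return(c(li, lj))
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }

  while (nrow(active) > 3L) {
    m <- nrow(active)
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        pair_lab <- sort(c(active$label[i], active$label[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair_lab[1] < best$lab[1] ||
              (pair_lab[1] == best$lab[1] && pair_lab[2] < best$lab[2])))) {
          best <- list(q = q, i = i, j = j, lab = pair_lab)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp_pair(li, lj)
    n_join <- n_join + 1L
    new_node <- n + 1L + n_join # n+1 is reserved for the final central node
    edges <- rbind(edges, c(new_node, active$node[i]), c(new_node, active$node[j]))
    lens <- c(lens, ll[1], ll[2])

    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd), c(newd, 0))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(node = new_node, label = min(best$lab)))
    dimnames(D2) <- list(active$label, active$label)
    D <- D2
  }

  # final three clusters join at the central node (three-point formulas)
  central <- n + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  trio <- c(l1, l2, l3)
  if (clamp_negative) trio <- pmax(trio, 0)
  edges <- rbind(edges, c(central, active$node[1]), c(central, active$node[2]),
                 c(central, active$node[3]))
  lens <- c(lens, trio)

  tree <- list(edge = unname(edges), edge.length = unname(lens),
               tip.label = labels, Nnode = n - 2L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# canonical bipartitions of the internal edges of an unrooted phylo tree:
# for each non-root internal node, the tip set of its clade, complemented if
# it contains the alphabetically first tip; returned as sorted "a|b|c" strings
# named by internal node number
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  all_tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    node <- n + k
    if (node == root) next
    side <- sort(tree$tip.label[parts[[k]]])
    if (all_tips[1] %in% side) side <- sort(setdiff(all_tips, side))
    if (length(side) < 2L || length(side) > n - 2L) next # trivial split
    out <- c(out, paste(side, collapse = "|"))
    nodes <- c(nodes, node)
  }
  setNames(out, nodes)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data tree
#' the fraction of replicates containing it. Replicate r uses RNG seed
#' `seed + r`, so runs are reproducible and independent of the number of
#' replicates requested.
#'
#' @param aligned Equal-length aligned sequences (named character vector or
#'   tibble with `id`/`sequence` columns).
#' @param replicates Number of bootstrap replicates (paper-scale default 500).
#' @param seed Integer root seed.
#' @param dist_fun Distance function, default [p_distance()].
#' @return A `hmwgs_boot` list: `tree` (the full-data NJ tree with
#'   `node.label` set to support fractions, empty for the root) and
#'   `supports` (tibble: `node`, `bipartition`, `support`).
#' @export
bootstrap_support <- function(aligned, replicates = 500L, seed = 1L,
                              dist_fun = p_distance) {
  stopifnot(replicates >= 1L)
  if (is.data.frame(aligned)) aligned <- setNames(aligned$sequence, aligned$id)
  main <- nj_tree(dist_fun(aligned))
  target <- tree_bipartitions(main)
  counts <- setNames(numeric(length(target)), target)

  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  L <- ncol(mat)
  for (r in seq_len(replicates)) {
    cols <- withr::with_seed(seed + r, sample.int(L, L, replace = TRUE))
    boot <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(boot) <- names(aligned)
    bt <- nj_tree(dist_fun(boot))
    seen <- unique(tree_bipartitions(bt))
    hit <- names(counts) %in% seen
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / replicates

  n <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  labels[as.integer(names(target)) - n] <- format(support, trim = TRUE)
  main$node.label <- labels
  structure(list(
    tree = main,
    supports = tibble(node = as.integer(names(target)),
                      bipartition = unname(target),
                      support = unname(support))
  ), class = "hmwgs_boot")
}

#' @export
tidy.hmwgs_boot <- function(x, ...) x$supports

#' @export
print.hmwgs_boot <- function(x, ...) {
  cat(sprintf("<hmwgs_boot> %d tips, %d internal bipartitions, support %s\n",
              length(x$tree$tip.label), nrow(x$supports),
              paste(format(x$supports$support), collapse = ", ")))
  invisible(x)
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept; when the tree carries bootstrap support fractions
#' as node labels they are written as integer percentages.
#'
#' @param tree A `phylo` tree or a [bootstrap_support()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (inherits(tree, "hmwgs_boot")) tree <- tree$tree
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(lab), "", as.character(round(100 * lab)))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Plot a phylogenetic tree
#'
#' Thin wrapper over ape's tree plotting, showing bootstrap percentages at
#' internal nodes when present.
#'
#' @param tree A `phylo` tree or a [bootstrap_support()] result.
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_tree <- function(tree, ...) {
  if (inherits(tree, "hmwgs_boot")) tree <- tree$tree
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    ape::nodelabels(ifelse(is.na(lab), "", as.character(round(100 * lab))),
                    frame = "none", adj = c(1.2, -0.3), cex = 0.8)
  }
  invisible(tree)
}
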