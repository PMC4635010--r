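test_that("p-distance matches direct column counting", {
  d <- p_distance(c(a = "AAAA", b = "AAAT", c = "AATT"))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0.5)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(d))

  seqs <- vapply(1:5, function(s) random_protein(40, seed = s + 300), character(1))
  # punch some gaps in
  seqs <- vapply(seq_along(seqs), function(k) {
    withr::with_seed(k, {
      v <- strsplit(seqs[k], "")[[1]]
      v[sample(40, 4)] <- "-"
      paste(v, collapse = "")
    })
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  d2 <- p_distance(seqs)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d2[i, j], pdist_pair(seqs[i], seqs[j]))
  }
})

test_that("p-distance rejects degenerate input", {
  expect_error(p_distance(c(a = "AA", b = "AAA", c = "AA")), "equal length")
  expect_error(p_distance(c(a = "AA")), "at least 3")
  expect_error(p_distance(c(a = "A--", b = "-A-", c = "AAA")),
               "no gap-free columns")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 1L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 4))
})

test_that("NJ recovers topology and lengths from a 4-taxon additive matrix", {
  true <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  d <- cophenetic(true)
  tr <- nj_tree(d)
  expect_equal(phangorn::RF.dist(ape::unroot(true), tr), 0)
  # unrooted: the two rooted internal edges (1 and 0) merge into one
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
})

test_that("NJ reproduces the generating tree on random additive matrices", {
  for (s in 1:20) {
    n <- 4 + (s %% 5)
    ref <- random_additive_matrix(n, seed = s + 400)
    tr <- nj_tree(ref$d)
    expect_equal(phangorn::RF.dist(ref$tree, tr), 0, info = paste("seed", s))
    # additive matrices are reproduced exactly by the recovered tree
    expect_equal(cophenetic(tr)[rownames(ref$d), colnames(ref$d)], ref$d,
                 tolerance = 1e-8)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  for (s in 1:10) {
    base <- random_additive_matrix(6, seed = s + 500)$d
    noise <- withr::with_seed(s, matrix(stats::runif(36, 0, 0.3), 6, 6))
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    d <- base + noise
    expect_equal(phangorn::RF.dist(nj_tree(d), ape::nj(as.dist(d))), 0,
                 info = paste("seed", s))
  }
})

test_that("negative branch lengths are clamped with the deficit shifted", {
  # a random non-additive matrix known to drive NJ branches negative
  d <- withr::with_seed(18, {
    m <- matrix(stats::runif(25, 0.05, 1), 5, 5)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:5], letters[1:5])
    m
  })
  tr_raw <- nj_tree(d, clamp_negative = FALSE)
  expect_true(any(tr_raw$edge.length < 0))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  # shifting the deficit to the sibling edge preserves topology and total length
  expect_equal(phangorn::RF.dist(tr, tr_raw), 0)
  expect_equal(sum(tr$edge.length), sum(tr_raw$edge.length), tolerance = 1e-9)
})

test_that("bootstrap supports are deterministic, bounded and permutation-invariant", {
  cl <- generate_clade_set(n_per_clade = 4, length = 120, within = 0.03,
                           between = 0.4, seed = 21)
  aligned <- setNames(cl$sequence, cl$id)

  one <- bootstrap_support(aligned, replicates = 1, seed = 5)
  expect_true(all(one$supports$support %in% c(0, 1)))

  b1 <- bootstrap_support(aligned, replicates = 25, seed = 7)
  b2 <- bootstrap_support(aligned, replicates = 25, seed = 7)
  expect_identical(b1$supports, b2$supports)

  # permuting the input order leaves bipartition supports unchanged
  perm <- withr::with_seed(3, sample(length(aligned)))
  b3 <- bootstrap_support(aligned[perm], replicates = 25, seed = 7)
  j <- dplyr::inner_join(b1$supports, b3$supports, by = "bipartition")
  expect_equal(nrow(j), nrow(b1$supports))
  expect_equal(j$support.x, j$support.y)
})

test_that("two synthetic clades separate with high bootstrap support", {
  cl <- generate_clade_set(n_per_clade = 5, length = 200, within = 0.01,
                           between = 0.3, seed = 2)
  bt <- bootstrap_support(cl, replicates = 100, seed = 3)
  clade_b <- sort(cl$id[cl$clade == "B"])
  split_b <- paste(clade_b, collapse = "|")
  sup <- bt$supports$support[bt$supports$bipartition == split_b]
  expect_length(sup, 1L)
  expect_gte(sup, 0.95)
  # NJ topology itself separates the clades (root outside clade B first)
  rooted <- ape::root(bt$tree, outgroup = "cladeA_1", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, clade_b))
})

test_that("newick export carries branch lengths and integer percent supports", {
  cl <- generate_clade_set(n_per_clade = 3, length = 100, within = 0.02,
                           between = 0.4, seed = 13)
  bt <- bootstrap_support(cl, replicates = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(bt, path)
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, cl$id)
  labs <- suppressWarnings(as.integer(reread$node.label))
  labs <- labs[!is.na(labs)]
  expect_true(all(labs >= 0 & labs <= 100))
})
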