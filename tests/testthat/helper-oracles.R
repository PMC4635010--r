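# Independent oracles used to check the package implementations on tiny
# inputs. They stay deliberately naive (enumeration / quadratic scans).

# exhaustive global alignment score under affine gaps: recursion over the
# three possible last operations, tracking whether the previous op opened a
# gap in a or in b; feasible for strings up to ~8 characters
brute_force_align_score <- function(a, b, match = 2, mismatch = -3,
                                    gap_open = -10, gap_extend = -0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, rec(i - 1, j - 1, "m") + s)
    }
    if (i > 0) {
      g <- if (identical(prev, "a")) gap_extend else gap_open
      best <- max(best, rec(i - 1, j, "a") + g)
    }
    if (j > 0) {
      g <- if (identical(prev, "b")) gap_extend else gap_open
      best <- max(best, rec(i, j - 1, "b") + g)
    }
    best
  }
  rec(length(av), length(bv), "m")
}

# simple linear-gap Needleman-Wunsch score (no affine machinery); the
# package aligner must reproduce it when gap_extend == gap_open
linear_gap_score <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
    }
  }
  D[n + 1, m + 1]
}

# brute-force p-distance for one pair
pdist_pair <- function(x, y) {
  xv <- strsplit(x, "")[[1]]
  yv <- strsplit(y, "")[[1]]
  ok <- xv != "-" & yv != "-"
  sum(xv[ok] != yv[ok]) / sum(ok)
}

# brute-force run enumeration for one secondary-structure state
count_runs <- function(ss, state) {
  v <- strsplit(ss, "")[[1]] == state
  sum(v & !c(FALSE, head(v, -1)))
}

# random DNA/protein helpers under a local seed
random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

random_protein <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, paste(sample(aa, n, TRUE), collapse = ""))
}

# additive distance matrix from a random tree with positive branch lengths
random_additive_matrix <- function(n_taxa, seed) {
  tr <- withr::with_seed(seed, ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.2, 2)))
  tr <- ape::unroot(tr)
  list(tree = tr, d = cophenetic(tr))
}

write_fasta_lines <- function(path, ids, seqs, width = 60) {
  lines <- character(0)
  for (k in seq_along(ids)) {
    lines <- c(lines, paste0(">", ids[k]),
               substring(seqs[k], seq(1, nchar(seqs[k]), width),
                         pmin(seq(1, nchar(seqs[k]), width) + width - 1, nchar(seqs[k]))))
  }
  writeLines(lines, path)
  path
}

# segmentation spans as a bare data frame (drops the protein/seed attributes)
seg_df <- function(x) {
  data.frame(domain = x$domain, start = x$start, end = x$end, length = x$length)
}

# small, fast generator spec used where the full-size architecture is not
# itself under test
small_spec <- function(seed, ...) {
  subunit_spec(nterm_length = 40L,
               unit_counts = c(hexa = 10L, nona = 4L, tetra = 2L),
               linker_tail = "", seed = seed, ...)
}
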