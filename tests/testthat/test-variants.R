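test_that("alignment score matches the exhaustive affine oracle on short strings", {
  set.seed(51)
  for (k in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE), collapse = "")
    got <- align_global(a, b)$score
    expect_equal(got, brute_force_align_score(a, b), info = paste(a, b))
  }
})

test_that("alignment degenerates to linear gaps when gap_extend equals gap_open", {
  set.seed(52)
  for (k in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE), collapse = "")
    got <- align_global(a, b, gap_open = -5, gap_extend = -5)$score
    expect_equal(got, linear_gap_score(a, b, gap = -5), info = paste(a, b))
  }
})

test_that("alignment basics: identity, simple insertion, left-aligned gaps", {
  aln <- align_global("ACGTACGT", "ACGTACGT")
  expect_equal(aln$aligned_a, aln$aligned_b)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))

  aln2 <- align_global("ACAAGT", "ACGT")
  expect_equal(nchar(aln2$aligned_a), 6L)
  expect_equal(sum(strsplit(aln2$aligned_b, "")[[1]] == "-"), 2L)
  # one contiguous gap run
  expect_match(aln2$aligned_b, "^[ACGT]+-{2}[ACGT]+$")

  # a gap inside a homopolymer tract must sit leftmost
  aln3 <- align_global("CCAAAAAGG", "CCAAAGG")
  gap_cols <- which(strsplit(aln3$aligned_b, "")[[1]] == "-")
  expect_equal(gap_cols, c(3L, 4L))
})

test_that("substitutions classify by purine/pyrimidine class", {
  bases <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  for (r in bases) for (a in setdiff(bases, r)) {
    expected <- if ((r %in% purine) == (a %in% purine)) "transition" else "transversion"
    expect_equal(classify_substitution(r, a), expected)
  }
  expect_equal(classify_substitution("T", "C"), "transition")
  expect_equal(classify_substitution("A", "C"), "transversion")
  expect_error(classify_substitution("A", "A"), "must differ")
})

test_that("codon effect arithmetic follows the ORF reading frame", {
  backbone <- comparator_backbone(seed = 2)
  eff <- codon_effect(368, backbone$dna, "T")
  expect_equal(eff$codon_index, 123L)
  expect_equal(eff$codon_pos, 2L)
  expect_equal(eff$ref_aa, "T")
  expect_equal(eff$alt_aa, "I")
  expect_equal(eff$effect, "nonsynonymous")

  # third-position change within a 4-fold degenerate codon is synonymous
  eff2 <- codon_effect(6, "ATGGGATAA", "G") # GGA -> GGG, both Gly
  expect_equal(eff2$effect, "synonymous")
  expect_true(is.na(eff2$aa_change))

  expect_error(codon_effect(10, "ATGTAA", "A"), "outside")
  expect_error(codon_effect(2, "ATGTA", "A"), "divisible by 3")
})

test_that("published 1Dy12.6 variant table is reproduced end to end", {
  backbone <- comparator_backbone(seed = 4)
  e <- dy12_6_edits()
  q <- apply_edits(backbone$dna, e$snps, e$indels)
  v <- call_variants(align_global(q$dna, backbone$dna), query = "a")

  expect_equal(v$snps$pos, c(368L, 1469L, 1687L))
  expect_equal(v$snps$alt, c("T", "G", "A"))
  expect_equal(v$snps$ref, c("C", "A", "C"))
  expect_equal(v$snps$klass, c("transition", "transition", "transversion"))
  expect_equal(v$snps$aa_change, c("T>I", "Q>R", "P>T"))

  expect_equal(nrow(v$indels), 1L)
  expect_equal(v$indels$kind, "insertion")
  expect_equal(c(v$indels$start, v$indels$end), c(958L, 1002L))
  expect_equal(v$indels$length, 45L)
  expect_equal(v$indels$peptide, "GHYPASQQQPGQGQQ")
})

test_that("published 1Dy12.7 variant table is reproduced end to end", {
  backbone <- comparator_backbone(seed = 4)
  e <- dy12_7_edits()
  q <- apply_edits(backbone$dna, e$snps, e$indels)
  v <- call_variants(align_global(q$dna, backbone$dna), query = "a")

  expect_equal(v$snps$pos, e$snps$pos)
  expect_equal(v$snps$ref, e$snps$ref)
  expect_equal(v$snps$alt, e$snps$alt)
  expect_equal(glance(v)$n_snps, 17L)
  expect_equal(glance(v)$n_indels, 2L)

  del <- v$indels[v$indels$kind == "deletion", ]
  expect_equal(c(del$start, del$end), c(540L, 541L))
  expect_equal(del$length, 18L)
  expect_equal(del$peptide, "QIGKGK")
  ins <- v$indels[v$indels$kind == "insertion", ]
  expect_equal(c(ins$start, ins$end), c(700L, 717L))
  expect_equal(ins$peptide, "RQIGQG")

  # two SNPs sharing a codon report one joint amino-acid change
  expect_equal(unique(v$snps$aa_change[v$snps$pos %in% c(482, 483)]), "P>L")
  expect_equal(unique(v$snps$aa_change[v$snps$pos %in% c(499, 500)]), "W>E")
  # nonsynonymous changes counted per codon
  expect_equal(glance(v)$n_nonsyn, 10L)
})

test_that("variant calling round-trips random synthetic edit sets", {
  for (s in 1:6) {
    gen <- generate_subunit(small_spec(s + 200))
    dna <- gen$record$dna
    n <- nchar(dna)
    edits <- withr::with_seed(s, {
      pos <- sort(sample(seq(10L, n %/% 2L - 30L), 4))
      ref <- vapply(pos, function(p) substr(dna, p, p), character(1))
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      ins_at <- n %/% 2L + 30L
      list(snps = tibble::tibble(pos = pos, ref = ref, alt = alt),
           indels = tibble::tibble(kind = "insertion", pos = ins_at, length = 9L,
                                   sequence = paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                                                    collapse = "")))
    })
    q <- apply_edits(dna, edits$snps, edits$indels)
    v <- call_variants(align_global(q$dna, dna), query = "a")
    expect_equal(v$snps[, c("pos", "ref", "alt")], q$truth$snps)
    expect_equal(v$indels[, c("kind", "start", "end", "length", "sequence")],
                 q$truth$indels)
    # ts/tv conservation and percentage
    sm <- glance(v)
    expect_equal(sm$n_ts + sm$n_tv, sm$n_snps)
    expect_equal(sm$ts_pct, 100 * sm$n_ts / sm$n_snps)
  }
})

test_that("identical sequences yield an empty variant table", {
  dna <- random_dna(300, seed = 61)
  v <- call_variants(align_global(dna, dna))
  expect_equal(nrow(v$snps), 0L)
  expect_equal(nrow(v$indels), 0L)
  expect_equal(glance(v)$n_snps, 0L)
})

test_that("identity matrix follows the declared gap-as-mismatch convention", {
  a <- random_dna(10, seed = 71)
  b <- a; substr(b, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(a, 4, 4))[1]
  recs <- subunit_records(c("x", "y", "z"), dna = c(a, b, a))
  m <- identity_matrix(recs, level = "dna")
  expect_equal(diag(unclass(m)), c(x = 100, y = 100, z = 100))
  expect_equal(m["x", "y"], 90)
  expect_equal(m["x", "z"], 100)
  expect_true(isSymmetric(unclass(m)))
})

test_that("a 2022-nt pair with six substitutions shows 99.70% identity", {
  recs <- reconstructed_alleles(seed = 8)
  dna <- recs$dna[recs$id == "1Dy12.6_syn"]
  edits <- withr::with_seed(8, {
    pos <- sort(sample(100:1900, 6))
    ref <- vapply(pos, function(p) substr(dna, p, p), character(1))
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    tibble::tibble(pos = pos, ref = ref, alt = alt)
  })
  mutated <- apply_edits(dna, edits)$dna
  m <- identity_matrix(subunit_records(c("a", "b"), dna = c(dna, mutated)))
  expect_equal(m["a", "b"], round(100 * (2022 - 6) / 2022, 2))
  expect_equal(m["a", "b"], 99.70)
})

test_that("variant tables export to minimal VCF and paper-style TSV", {
  backbone <- comparator_backbone(seed = 4)
  e <- dy12_7_edits()
  q <- apply_edits(backbone$dna, e$snps, e$indels)
  v <- call_variants(align_global(q$dna, backbone$dna))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, "JF_backbone", "dy12.7", vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 19L) # 17 SNPs + 2 indels
  del <- strsplit(body[grepl("CAGATAGGAAAAGGGAAA", body)], "\t")[[1]]
  expect_equal(as.integer(del[2]), 540L) # anchored at the preceding ref base
  expect_equal(nchar(del[4]), 19L)       # anchor base + 18 deleted
  expect_equal(nchar(del[5]), 1L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(v, "JF_backbone", "dy12.7", tsv)
  tab <- read.delim(tsv, check.names = FALSE)
  expect_equal(tab$gene, c("dy12.7", "JF_backbone"))
  expect_true("540-541" %in% names(tab))
  expect_equal(tab[["482"]], c("T(L)", "C(P)"))
})
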