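test_that("cysteines map to the y-type 5/1/1 layout on generated subunits", {
  for (s in c(2, 23)) {
    gen <- generate_subunit(subunit_spec(seed = s))
    seg <- segment_protein(gen$record$protein)
    mat <- mature_protein(gen$record$protein, seg)
    cys <- map_cysteines(mat, seg)
    expect_equal(cys$position, gen$truth$cys_positions)
    expect_true(all(diff(cys$position) > 0))
    counts <- glance(cys)
    expect_equal(as.integer(counts), c(5L, 1L, 1L, 7L))
  }
})

test_that("cysteine mapping handles degenerate layouts", {
  # no cysteines anywhere
  gen <- generate_subunit(subunit_spec(
    cysteine_layout = c(nterm = 0L, repetitive = 0L, cterm = 0L), seed = 4))
  seg <- segment_protein(gen$record$protein)
  cys <- map_cysteines(mature_protein(gen$record$protein, seg), seg)
  expect_equal(nrow(cys), 0L)
  expect_equal(glance(cys)$total, 0L)

  # three cysteines confined to the C-terminal domain
  gen3 <- generate_subunit(subunit_spec(
    cysteine_layout = c(nterm = 0L, repetitive = 0L, cterm = 3L), seed = 4))
  seg3 <- segment_protein(gen3$record$protein)
  counts <- glance(map_cysteines(mature_protein(gen3$record$protein, seg3), seg3))
  expect_equal(as.integer(counts), c(0L, 0L, 3L, 3L))
})

test_that("glutamine content counts Q residues", {
  expect_equal(as.numeric(glutamine_content("QQQ")), c(3, 1))
  expect_equal(as.numeric(glutamine_content("PGQGQQ")), c(3, 0.5))
  gen <- generate_subunit(small_spec(6))
  mat <- mature_protein(gen$record$protein)
  expect_equal(glutamine_content(mat)$count, gen$truth$q_count)
})

test_that("average mass uses average residue masses plus one water", {
  expect_equal(average_mass(""), 18.0153)
  expect_equal(average_mass("G"), 75.07, tolerance = 0.01 / 75.07)
  expect_error(average_mass("GXZ"), "invalid residue")
  # additivity: mass(a + b) == mass(a) + mass(b) - water
  for (s in 1:10) {
    a <- random_protein(25, seed = s)
    b <- random_protein(40, seed = s + 100)
    expect_equal(average_mass(paste0(a, b)),
                 average_mass(a) + average_mass(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("mass concordance reproduces the published deltas", {
  mc <- mass_concordance(c(70165, 68400, 1234.5), c(69985, 68407, 1234.5))
  expect_equal(mc$delta_da, c(180, -7, 0))
  expect_true(all(mc$consistent))
  expect_false(mass_concordance(70000, 69000)$consistent) # 1.4% off
})

test_that("secondary-structure summary matches brute-force run enumeration", {
  gen <- generate_subunit(small_spec(8))
  seg <- segment_protein(gen$record$protein)
  len <- nchar(mature_protein(gen$record$protein, seg))

  # uniform coil: 100% C, zero for everything else
  uni <- summarize_ss8(strrep("C", len), seg)
  expect_equal(uni$pct[uni$state == "C" & uni$region == "overall"], 100)
  expect_equal(uni$n_runs[uni$state == "C" & uni$region == "overall"], 1)
  expect_equal(sum(uni$pct[uni$region == "overall"]), 100, tolerance = 0.1)
  expect_true(all(uni$n_residues[uni$state != "C" & uni$region == "overall"] == 0))

  # toy with known runs, checked against an independent run counter
  ss <- withr::with_seed(99, paste(sample(c("H", "T", "C", "E"), len, TRUE,
                                          prob = c(.1, .2, .6, .1)), collapse = ""))
  out <- summarize_ss8(ss, seg)
  for (st in c("H", "T", "C", "E")) {
    expect_equal(out$n_runs[out$state == st & out$region == "overall"],
                 count_runs(ss, st))
    expect_equal(out$n_residues[out$state == st & out$region == "overall"],
                 sum(strsplit(ss, "")[[1]] == st))
  }
  # per-domain residues and runs sum to the overall figures
  for (st in c("H", "T", "C", "E")) {
    sub <- out[out$state == st, ]
    expect_equal(sum(sub$n_residues[sub$region != "overall"]),
                 sub$n_residues[sub$region == "overall"])
    expect_equal(sum(sub$n_runs[sub$region != "overall"]),
                 sub$n_runs[sub$region == "overall"])
  }
})

test_that("runs spanning a domain boundary are split half and half", {
  gen <- generate_subunit(small_spec(10))
  seg <- segment_protein(gen$record$protein)
  spans <- as.data.frame(seg)
  len <- sum(spans$length[spans$domain != "signal"])
  nterm_len <- spans$length[spans$domain == "nterm"]
  # one H run straddling the nterm/repetitive boundary, C elsewhere
  ss <- paste0(strrep("C", nterm_len - 2), strrep("H", 4), strrep("C", len - nterm_len - 2))
  out <- summarize_ss8(ss, seg)
  h <- out[out$state == "H", ]
  expect_equal(h$n_runs[h$region == "overall"], 1)
  expect_equal(h$n_runs[h$region == "nterm"], 0.5)
  expect_equal(h$n_runs[h$region == "repetitive"], 0.5)
})

test_that("secondary-structure input is validated", {
  gen <- generate_subunit(small_spec(12))
  seg <- segment_protein(gen$record$protein)
  expect_error(summarize_ss8("CCCC", seg), "does not match")
  len <- nchar(mature_protein(gen$record$protein, seg))
  expect_error(summarize_ss8(strrep("Z", len), seg), "invalid secondary-structure state")
})
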