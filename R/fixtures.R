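# Published pairwise variant sets for the two novel 1Dy alleles against their
# closest active comparator (GenBank JF736016), and a synthetic backbone that
# reproduces the comparator's local codon contexts at every edited site.

# deterministic reverse translation of the 15-residue repeat insertion
# GHYPASQQQPGQGQQ (one nonapeptide + one hexapeptide, 45 nt); the insertion's
# published nucleotide string is typographically truncated, so the amino-acid
# description is authoritative and is reverse-translated here
INSERTION_1DY12_6 <- "GGACATTATCCAGCATCACAACAACAACCAGGACAAGGACAACAA"

#' Published variant sets for the 1Dy12.6 and 1Dy12.7 alleles
#'
#' The SNP and indel edit lists of the two novel y-type alleles relative to
#' their closest active comparator allele (JF736016), in the coordinates of
#' the novel allele (the frame in which they are conventionally printed).
#' Suitable as input to [apply_edits()].
#'
#' @return A list with `snps` and `indels` tibbles (see [apply_edits()]).
#' @export
#' @examples
#' dy12_6_edits()$snps
dy12_6_edits <- function() {
  list(
    snps = tibble(
      pos = c(368L, 1469L, 1687L),
      ref = c("C", "A", "C"),
      alt = c("T", "G", "A")
    ),
    indels = tibble(
      kind = "insertion", pos = 958L, length = 45L,
      sequence = INSERTION_1DY12_6
    )
  )
}

#' @rdname dy12_6_edits
#' @export
dy12_7_edits <- function() {
  list(
    snps = tibble(
      pos = c(465L, 482L, 483L, 499L, 500L, 522L, 526L, 537L, 556L, 564L,
              571L, 634L, 656L, 666L, 692L, 1001L, 1227L),
      ref = c("T", "C", "A", "T", "G", "G", "C", "G", "A", "G",
              "C", "A", "T", "A", "A", "A", "A"),
      alt = c("A", "T", "G", "G", "A", "T", "T", "A", "T", "A",
              "T", "C", "G", "G", "G", "G", "G")
    ),
    indels = tibble(
      kind = c("deletion", "insertion"),
      pos = c(540L, 700L),
      length = c(18L, 18L),
      sequence = c("CAGATAGGAAAAGGGAAA", "CGGCAAATAGGACAAGGG")
    )
  )
}

# backbone codon patches, keyed by 1-based start of the codon (or longer
# segment) on the backbone ORF. They pin down: the reference base and amino
# acid at every published SNP site (mapped from the novel-allele frame to the
# backbone frame through the indels), the deleted hexapeptide QIGKGK at
# backbone 541-558, and anchor-guard codons that stop indel left-alignment
# from drifting off the published anchors.
BACKBONE_PATCHES <- c(
  `367` = "ACT",  # Thr; T>C SNP site 368 (novel-frame 368)
  `463` = "GCT",  # Ala; synonymous site 465
  `481` = "CCA",  # Pro; sites 482+483 share this codon (P -> L jointly)
  `499` = "TGG",  # Trp; sites 499+500 share this codon (W -> E jointly)
  `520` = "CAG",  # Gln; site 522
  `526` = "CCT",  # Pro; site 526
  `535` = "CCG",  # Pro; synonymous site 537
  `538` = "CAG",  # anchor guard: base 540 (G) differs from base 558 (A)
  `541` = "CAGATAGGAAAAGGGAAA", # QIGKGK, deleted in the 1977-nt allele
  `574` = "ACA",  # Thr; site 556 (novel frame) = backbone 574
  `580` = "GCG",  # Ala; synonymous site 564 = backbone 582
  `589` = "CCA",  # Pro; site 571 = backbone 589
  `652` = "ACA",  # Thr; site 634 = backbone 652
  `673` = "GTA",  # Val; site 656 = backbone 674
  `682` = "CAA",  # Gln; synonymous site 666 = backbone 684
  `709` = "GAA",  # Glu; site 692 = backbone 710
  `715` = "CAA",  # anchor guard: base 717 (A) differs from the 18-nt
                  # insertion's last base (G)
  `955` = "CAG",  # anchor guard: base 957 (G) differs from the 45-nt
                  # insertion's last base (A)
  `1000` = "CAA", # Gln; site 1001
  `1225` = "CAA", # Gln; synonymous site 1227
  `1423` = "CAA", # Gln; site 1469 (novel frame) = backbone 1424
  `1642` = "CCA"  # Pro; site 1687 (novel frame) = backbone 1642
)

#' Synthetic comparator backbone ORF
#'
#' A generated 1977-nt y-type ORF standing in for the closest active
#' comparator allele (JF736016, whose full sequence is not printed in the
#' characterization tables): architecture 21 + 104 + 491 + 42 residues with
#' 48 hexapeptide, 19 nonapeptide and 8 tetrapeptide units, with the local
#' codon contexts of every published variant site patched in so that the
#' published reference bases, amino acids, indel sequences and anchors all
#' hold. Applying [dy12_6_edits()] or [dy12_7_edits()] to this backbone and
#' re-calling variants reproduces the published variant tables; the backbone
#' asserts that round trip, not base-level identity with the real allele.
#'
#' @param seed Integer seed for the generated scaffold.
#' @return A one-row subunit record tibble (id `"backbone_1Dy"`).
#' @export
comparator_backbone <- function(seed = 1L) {
  spec <- subunit_spec(unit_counts = c(hexa = 48L, nona = 19L, tetra = 8L),
                       linker_tail = "", seed = seed)
  gen <- generate_subunit(spec, id = "backbone_1Dy")
  dna <- gen$record$dna
  for (k in seq_along(BACKBONE_PATCHES)) {
    at <- as.integer(names(BACKBONE_PATCHES)[k])
    piece <- BACKBONE_PATCHES[[k]]
    substr(dna, at, at + nchar(piece) - 1L) <- piece
  }
  subunit_records("backbone_1Dy", dna = dna, protein = translate_orf(dna),
                  source = sprintf("synthetic comparator backbone seed=%d", seed))
}

#' Reconstruct the two novel alleles from the backbone
#'
#' Convenience wrapper: applies the published edit sets to the synthetic
#' comparator backbone, returning a three-row record table (backbone plus the
#' two reconstructed alleles, 1977/2022/1977 nt).
#'
#' @param seed Seed for [comparator_backbone()].
#' @return A subunit record tibble with ids `backbone_1Dy`, `1Dy12.6_syn`,
#'   `1Dy12.7_syn`.
#' @export
reconstructed_alleles <- function(seed = 1L) {
  backbone <- comparator_backbone(seed)
  e6 <- dy12_6_edits()
  e7 <- dy12_7_edits()
  q6 <- apply_edits(backbone$dna, e6$snps, e6$indels)
  q7 <- apply_edits(backbone$dna, e7$snps, e7$indels)
  bind_rows(
    backbone,
    subunit_records("1Dy12.6_syn", dna = q6$dna, protein = translate_orf(q6$dna),
                    source = "backbone + published 1Dy12.6 edits"),
    subunit_records("1Dy12.7_syn", dna = q7$dna, protein = translate_orf(q7$dna),
                    source = "backbone + published 1Dy12.7 edits")
  )
}
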