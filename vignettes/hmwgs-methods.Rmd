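---
title: "Characterizing HMW glutenin subunit genes with hmwgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing HMW glutenin subunit genes with hmwgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmwgs)
```

## The biological setting

High molecular weight glutenin subunits (HMW-GS) are wheat seed storage
proteins encoded by intronless genes at the *Glu-1* loci. Each locus carries a
larger x-type and a smaller y-type gene; the y-type proteins carry seven
conserved cysteines and share a stereotyped primary structure: a 21-residue
signal peptide cleaved from the mature protein, a conserved non-repetitive
N-terminal region, a long central repetitive domain, and a conserved
42-residue C-terminal region. The central domain is a tandem array of short
glutamine-rich units -- hexapeptides (consensus `PGQGQQ`), nonapeptides
(consensus `GYYPTSLQQ`, with `GHYPASQQQ` a common variant consensus), `PGQQ`
tetrapeptides, and, in x-type subunits only, `GQQ` tripeptides. Allelic
variation in this domain (unit gains and losses, SNPs) is what breeders mine
for dough-quality improvement, so a characterization pipeline has to make the
domain arithmetic, the repeat bookkeeping and the variant calling exact and
reproducible.

`hmwgs` implements that pipeline end to end: ORF validation and translation,
four-domain segmentation, repeat-unit decomposition, cysteine / glutamine /
molecular-mass accounting, pairwise variant calling with
transition/transversion and codon-effect classification, identity matrices,
and neighbour-joining phylogeny with bootstrap support. A synthetic-subunit
generator emits architecture-faithful genes *with ground truth*, so every
stage is testable without any database download.

## Segmentation

The literature specifies the signal peptide (21 aa) and C-terminal domain
(42 aa) by length only, so `segment_protein()` locates them by fixed length
from the ends (both configurable through `domain_template()` for other
prolamins). No boundary sequence for the N-terminal/repetitive junction is
published either; the repetitive domain is taken to start at the first
position after the signal where a *repeat seed motif* matches with at most
one mismatch. The default seeds are the hexapeptide consensus and the
6-residue prefixes of the two nonapeptide consensuses (`PGQGQQ`, `GYYPTS`,
`GHYPAS`); ties at one position go to the longest seed, then list order. The
four spans always tile the protein exactly -- that invariant is
property-tested against generator truth.

On the two published y-type architectures the defaults recover the printed
lengths: a 673-residue subunit segments as 21 + 104 + 506 + 42 and a
658-residue subunit as 21 + 104 + 491 + 42.

## Repeat decomposition

`decompose_repeats()` scans the central domain greedily left to right; at
each cursor the longest unit kind whose consensus matches within its
allowance is consumed (nonapeptide before hexapeptide before tetrapeptide
before tripeptide), and residues matching nothing accumulate into explicit
linker runs, so concatenating the reported units always reconstructs the
domain exactly. The published unit counts call the motifs "consensus", i.e.
degenerate matches are intended; the default allowances are nona &le; 2,
hexa &le; 1, tetra = tri = 0. The greedy longest-first convention is the
package's own (no decomposition algorithm is published); it is deterministic
and documented rather than claimed canonical.

A point worth recording: the stated composition of the larger subunit's
506-residue domain -- 48 hexapeptides and 20 nonapeptides -- leaves
506 − 48×6 − 20×9 = 38 residues. Thirty-six are the unique consistent count
of `PGQQ` tetrapeptide separators (nine of them); the remaining two are a
linker tail. The 491-residue domain resolves exactly:
48×6 + 19×9 + 8×4 = 491. The generator's default layouts use those counts.

## Composition accounting

`map_cysteines()` assigns every cysteine of the mature protein to its domain;
y-type subunits are expected to show the conserved 5 (N-terminal) / 1
(repetitive, near the C-terminus) / 1 (C-terminal) layout. `average_mass()`
uses average (not monoisotopic) Expasy residue masses plus one water, the
correct scale for linear-mode MALDI-TOF measurements of intact subunits;
`mass_concordance()` calls a deduced/observed pair consistent below a default
0.5% relative difference (the published pairs differ by 0.26% and 0.01%,
i.e. 180 Da and −7 Da). Deduced masses are computed on the mature
(signal-removed) protein.

`summarize_ss8()` consumes an externally predicted 8-state secondary-structure
string -- prediction itself is out of scope -- and reports residue fractions
and maximal-run counts per state, overall and per domain. Published
per-domain run tables contain half counts; the package reproduces that
convention by crediting a run spanning a domain boundary 0.5 to each side
(runs starting + runs ending, divided by two), which keeps per-domain counts
summing exactly to the overall count.

## Alignment and variant calling

`align_global()` is a Gotoh affine-gap Needleman-Wunsch (C++ core). A gap of
length k costs `gap_open + (k−1)·gap_extend`, so `gap_extend = gap_open` is
the linear-gap score -- the brute-force oracle used in the tests. Defaults
(+2 match, −3 mismatch, −10 open, −0.5 extend) favour the long contiguous
indels typical of repeat-domain evolution. Traceback tie-breaks are fixed
(diagonal, then gap in the second sequence, then gap in the first) and a
post-pass left-aligns every gap run, which makes indel anchors deterministic
inside tandem repeats.

`call_variants()` reports SNP positions in the query frame (variant tables
for novel alleles are conventionally printed on the novel allele's
coordinates), anchors deletions between flanking query positions
("540–541" style), spans insertions in query coordinates, and translates
in-frame codon-aligned indels. Codon effects are computed in the reference
frame with all SNPs sharing a codon applied *jointly*: two substitutions in
one codon are one amino-acid change, reported on each participating SNP, and
the summary counts nonsynonymous codons. (Per-SNP naive effects would
overcount: a `TGG`&rarr;`GAG` codon carries two SNPs but one
tryptophan&rarr;glutamate change.)

`identity_matrix()` uses a declared convention -- matching columns over full
alignment length, gaps counting as mismatches, two decimals -- because the
metric behind published identity tables (produced by commercial software) is
not specified. Published identities are therefore treated as soft,
convention-dependent checks, not exact targets.

## The synthetic comparator backbone

The comparator allele used in the published variant tables is available only
as a GenBank accession, not as printed sequence. The package therefore ships
`comparator_backbone()`: a generated 1977-nt y-type ORF (21 + 104 + 491 + 42
architecture) with the local codon context of every published variant site
patched in, so that the printed reference bases, amino acids, the deleted
`QIGKGK` hexapeptide and both insertion anchors all hold. Anchor-guard codons
ensure gap left-alignment cannot drift off the printed anchors. It is a
synthetic stand-in: round trips through `apply_edits()` and
`call_variants()` assert recovery of the printed tables, never base-level
identity with the real allele. One printed insertion is 40 nt on paper yet
described as 45 bp encoding `GHYPASQQQPGQGQQ`; the amino-acid description is
arithmetically consistent (45 = 3×15) and is taken as authoritative, the
nucleotide string being a suspected truncation.

## Phylogeny

`p_distance()` computes the proportion of differing columns among mutually
ungapped columns; distance corrections (Poisson, JTT) are deliberately not
defaulted because the settings behind the published figure are unstated.
`nj_tree()` is a from-scratch Saitou-Nei implementation with two documented
conventions: Q-criterion ties break on the lexicographically smallest pair of
cluster labels (a cluster is labelled by its alphabetically first tip), and
negative branch lengths are clamped to zero with the deficit shifted to the
sibling edge (the final three-taxon star clamps without a shift). On additive
matrices it provably recovers the generating tree; the tests also cross-check
topology against an independent NJ implementation on noisy matrices.
`bootstrap_support()` resamples columns with replacement, derives replicate
seeds by counter from one root seed, and scores each internal bipartition of
the full-data tree by the fraction of replicates containing it.

Reproducing the published 26-taxon tree would require fetching the 24
comparator accessions, so the x/y-type separation on real alleles is a
qualitative claim outside the test suite; what the package verifies instead
is the method: exact recovery on random additive matrices (up to 8 taxa) and
&ge; 95% support at 100 replicates for the separating edge of a synthetic
two-clade set (5 + 5 taxa, 1% within-clade and 30% between-clade per-site
divergence, 200 residues).

## The generator, and what passing tests do not show

`generate_subunit()` assembles signal + N-terminal + unit layout + C-terminal
per spec, places cysteines (default 5/1/1; the repetitive-domain cysteine
sits at the domain's last residue, inside the linker tail when present,
otherwise as a one-mismatch variant of the final hexapeptide), and
reverse-translates with uniformly sampled codons -- codon usage realism is
irrelevant to the package's claims, determinism is not. Non-domain residues
are drawn uniformly from the 19 non-cysteine amino acids, and the N-terminal
region is resampled until no seed motif fires before the true boundary, so
generator truth is self-consistent by construction.

The generator emulates architecture, not evolution: no unequal-crossover
dynamics, no codon bias, no indel mutation process, and real N-terminal
regions are conserved sequence rather than uniform noise. Passing recovery
tests therefore demonstrates the pipeline's bookkeeping is exact on
architecture-faithful inputs; performance on real alleles still depends on
the published domain conventions holding, which the segmentation templates
encode but cannot guarantee for atypical subunits.

## Problem sizes and determinism

Test and acceptance runs use full-size molecules where the claim is about
published figures (2022/1977-nt ORFs, 506/491-residue domains) and reduced
sizes elsewhere (8-taxon additive matrices, 100 bootstrap replicates,
200-residue clade sets, ~200-residue subunits for property loops). Every
stochastic step -- generation, clade simulation, bootstrap -- takes an
explicit integer seed and is bit-reproducible; the published-table round
trips are deterministic for *any* backbone seed, because the patched codon
contexts, not the scaffold, carry the signal.
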