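#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment. A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`, so setting `gap_extend = gap_open`
#' recovers the linear-gap score. Traceback is deterministic (ties prefer the
#' diagonal, then a gap in `b`, then a gap in `a`), and by default indels are
#' subsequently left-aligned, which makes anchors reproducible inside tandem
#' repeat tracts.
#'
#' @param a,b Sequences to align (DNA or protein; uppercased).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. The defaults
#'   (+2/-3/-10/-0.5) favour long contiguous indels, appropriate for
#'   repeat-domain length variants.
#' @param left_align Left-align gaps after traceback (default TRUE).
#' @return A `hmwgs_alignment` list: `a`, `b` (inputs), `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`.
#' @export
align_global <- function(a, b, match = 2, mismatch = -3,
                         gap_open = -10, gap_extend = -0.5,
                         left_align = TRUE) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) abort("both sequences must be non-empty")
  res <- .nw_align_cpp(a, b, match, mismatch, gap_open, gap_extend)
  aln <- list(a = a, b = b,
              aligned_a = res$aligned_a, aligned_b = res$aligned_b,
              score = res$score,
              params = c(match = match, mismatch = mismatch,
                         gap_open = gap_open, gap_extend = gap_extend))
  if (left_align) aln <- left_align_gaps(aln)
  structure(aln, class = "hmwgs_alignment")
}

# shift every gap run as far left as the flanking sequence allows; shifting a
# gap left by one is valid when the base entering the right edge equals the
# base leaving the left edge, so match/mismatch status of columns is unchanged
left_align_gaps <- function(aln) {
  va <- seq_chars(aln$aligned_a)
  vb <- seq_chars(aln$aligned_b)
  shift_gaps <- function(gapped, other) {
    # gaps live in `gapped`; the run's residues are in `other`
    i <- 1L
    n <- length(gapped)
    while (i <= n) {
      if (gapped[i] != "-") { i <- i + 1L; next }
      s <- i
      e <- s
      while (e < n && gapped[e + 1L] == "-") e <- e + 1L
      while (s > 1L && gapped[s - 1L] != "-" && other[s - 1L] != "-" &&
             other[s - 1L] == other[e]) {
        gapped[e] <- gapped[s - 1L]
        gapped[s - 1L] <- "-"
        tmp <- other[s - 1L] # equal to other[e]; keep vectors aligned explicitly
        other[s - 1L] <- other[e]
        other[e] <- tmp
        s <- s - 1L; e <- e - 1L
      }
      i <- e + 1L
    }
    list(gapped = gapped, other = other)
  }
  r1 <- shift_gaps(va, vb)
  va <- r1$gapped; vb <- r1$other
  r2 <- shift_gaps(vb, va)
  vb <- r2$gapped; va <- r2$other
  aln$aligned_a <- paste(va, collapse = "")
  aln$aligned_b <- paste(vb, collapse = "")
  aln
}

#' @export
print.hmwgs_alignment <- function(x, ...) {
  cat(sprintf("<hmwgs_alignment> score %.1f, %d columns\n",
              x$score, nchar(x$aligned_a)))
  invisible(x)
}

#' Classify a nucleotide substitution
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) changes are
#' transitions; purine-pyrimidine changes are transversions.
#'
#' @param ref,alt Single bases (vectorized).
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
#' @examples
#' classify_substitution("T", "C") # transition
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T"))) {
    abort("bases must be A, C, G or T")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Codon effect of a single substitution
#'
#' @param snp_position 1-based position on the reference ORF (the A of ATG
#'   is position 1).
#' @param ref_orf Reference ORF (length divisible by 3).
#' @param alt_base Substituted base.
#' @return One-row tibble: `codon_index`, `codon_pos`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `effect`
#'   (synonymous/nonsynonymous), `aa_change` (`NA` when synonymous).
#' @export
#' @examples
#' codon_effect(6, "ATGGGA", "G") # GGA -> GGG, synonymous
codon_effect <- function(snp_position, ref_orf, alt_base) {
  ref_orf <- check_dna(ref_orf, "ref_orf")
  if (nchar(ref_orf) %% 3L != 0L) abort("ref_orf length must be divisible by 3")
  if (snp_position < 1L || snp_position > nchar(ref_orf)) {
    abort("snp_position is outside the ORF")
  }
  alt_base <- toupper(alt_base)
  stopifnot(alt_base %in% c("A", "C", "G", "T"))
  ci <- ceiling(snp_position / 3)
  cp <- (snp_position - 1L) %% 3L + 1L
  ref_codon <- substr(ref_orf, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt_base
  ref_aa <- codon_to_aa(ref_codon)
  alt_aa <- codon_to_aa(alt_codon)
  eff <- if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
  tibble(
    codon_index = as.integer(ci), codon_pos = as.integer(cp),
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa, effect = eff,
    aa_change = if (eff == "nonsynonymous") paste0(ref_aa, ">", alt_aa) else NA_character_
  )
}

codon_to_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Call SNPs and indels from a pairwise global alignment
#'
#' Mismatch columns become SNP records with 1-based positions in the *query*
#' frame (the field's convention: variant positions are printed on the novel
#' allele).
#' Contiguous gap runs become one indel each: a gap run in the query row is a
#' deletion, anchored between the two flanking query coordinates
#' ("540-541" style); a gap run in the reference row is an insertion, spanning
#' query coordinates. In-frame, codon-aligned indels are translated to a
#' peptide.
#'
#' Codon effects are computed in the reference frame with all SNPs sharing a
#' reference codon applied jointly (two substitutions in one codon produce a
#' single amino-acid change, which all SNPs of that codon report); the
#' summary consequently counts nonsynonymous *codon* changes.
#'
#' @param aln A [align_global()] result.
#' @param query Which input is the query, `"a"` (default) or `"b"`.
#' @return A `hmwgs_variants` list: `snps` (tibble: `pos`, `ref_pos`, `ref`,
#'   `alt`, `klass`, `codon_index`, `codon_pos`, `ref_aa`, `alt_aa`, `effect`,
#'   `aa_change`), `indels` (tibble: `kind`, `start`, `end`, `length`,
#'   `sequence`, `peptide`, `ref_anchor`), and `summary` (one row: `n_snps`,
#'   `n_indels`, `n_ts`, `n_tv`, `ts_pct`, `n_nonsyn`).
#'   [tidy()] returns the SNP table, [glance()] the summary.
#' @export
call_variants <- function(aln, query = c("a", "b")) {
  query <- match.arg(query)
  qrow <- seq_chars(if (query == "a") aln$aligned_a else aln$aligned_b)
  rrow <- seq_chars(if (query == "a") aln$aligned_b else aln$aligned_a)
  qseq <- if (query == "a") aln$a else aln$b
  rseq <- if (query == "a") aln$b else aln$a

  ncol <- length(qrow)
  qpos <- cumsum(qrow != "-")
  rpos <- cumsum(rrow != "-")

  # SNPs
  snp_cols <- which(qrow != "-" & rrow != "-" & qrow != rrow)
  snps <- tibble(
    pos = as.integer(qpos[snp_cols]),
    ref_pos = as.integer(rpos[snp_cols]),
    ref = rrow[snp_cols],
    alt = qrow[snp_cols]
  )
  if (nrow(snps) > 0) {
    snps$klass <- classify_substitution(snps$ref, snps$alt)
    snps <- annotate_codon_effects(snps, rseq)
  } else {
    snps <- tibble(pos = integer(0), ref_pos = integer(0), ref = character(0),
                   alt = character(0), klass = character(0),
                   codon_index = integer(0), codon_pos = integer(0),
                   ref_aa = character(0), alt_aa = character(0),
                   effect = character(0), aa_change = character(0))
  }

  # indels: contiguous gap runs per row
  indel_rows <- list()
  gap_runs <- function(row) {
    r <- rle(row == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  for (run in split_rows(gap_runs(qrow))) {
    s <- run[1]; e <- run[2]
    seqn <- paste(rrow[s:e], collapse = "")
    anchor <- as.integer(qpos[s]) # query coordinate before the gap (0 if leading)
    first_ref <- as.integer(rpos[s])
    indel_rows[[length(indel_rows) + 1L]] <- tibble(
      kind = "deletion", start = anchor, end = anchor + 1L,
      length = nchar(seqn), sequence = seqn,
      peptide = indel_peptide(seqn, first_ref),
      ref_anchor = first_ref - 1L
    )
  }
  for (run in split_rows(gap_runs(rrow))) {
    s <- run[1]; e <- run[2]
    seqn <- paste(qrow[s:e], collapse = "")
    first_q <- as.integer(qpos[s])
    indel_rows[[length(indel_rows) + 1L]] <- tibble(
      kind = "insertion", start = first_q, end = as.integer(qpos[e]),
      length = nchar(seqn), sequence = seqn,
      peptide = indel_peptide(seqn, first_q),
      ref_anchor = as.integer(rpos[s])
    )
  }
  indels <- if (length(indel_rows)) {
    arrange(bind_rows(indel_rows), .data$start)
  } else {
    tibble(kind = character(0), start = integer(0), end = integer(0),
           length = integer(0), sequence = character(0), peptide = character(0),
           ref_anchor = integer(0))
  }

  n_ts <- sum(snps$klass == "transition")
  n_tv <- sum(snps$klass == "transversion")
  n_nonsyn <- length(unique(snps$codon_index[snps$effect == "nonsynonymous" &
                                               !is.na(snps$effect)]))
  summary <- tibble(
    n_snps = nrow(snps), n_indels = nrow(indels),
    n_ts = n_ts, n_tv = n_tv,
    ts_pct = if (nrow(snps) > 0) 100 * n_ts / nrow(snps) else NA_real_,
    n_nonsyn = n_nonsyn
  )
  structure(list(snps = snps, indels = indels, summary = summary),
            class = "hmwgs_variants", query = qseq, ref = rseq)
}

split_rows <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(list())
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

# translate an indel sequence when it is an in-frame, codon-aligned event in
# its carrier sequence (first base at carrier position `first_pos`)
indel_peptide <- function(seqn, first_pos) {
  if (nchar(seqn) %% 3L == 0L && (first_pos - 1L) %% 3L == 0L) {
    translate_orf(seqn)
  } else {
    NA_character_
  }
}

# joint per-reference-codon effects; effects are NA when the reference frame
# is not codon-sized
annotate_codon_effects <- function(snps, rseq) {
  snps$codon_index <- as.integer(ceiling(snps$pos / 3))
  snps$codon_pos <- as.integer((snps$pos - 1L) %% 3L + 1L)
  if (nchar(rseq) %% 3L != 0L) {
    snps$ref_aa <- NA_character_; snps$alt_aa <- NA_character_
    snps$effect <- NA_character_; snps$aa_change <- NA_character_
    return(snps)
  }
  ref_ci <- ceiling(snps$ref_pos / 3)
  snps$ref_aa <- NA_character_; snps$alt_aa <- NA_character_
  snps$effect <- NA_character_; snps$aa_change <- NA_character_
  for (ci in unique(ref_ci)) {
    rows <- which(ref_ci == ci)
    ref_codon <- substr(rseq, 3L * ci - 2L, 3L * ci)
    alt_codon <- ref_codon
    for (r in rows) {
      cp <- (snps$ref_pos[r] - 1L) %% 3L + 1L
      substr(alt_codon, cp, cp) <- snps$alt[r]
    }
    ref_aa <- codon_to_aa(ref_codon)
    alt_aa <- codon_to_aa(alt_codon)
    eff <- if (identical(ref_aa, alt_aa)) "synonymous" else "nonsynonymous"
    snps$ref_aa[rows] <- ref_aa
    snps$alt_aa[rows] <- alt_aa
    snps$effect[rows] <- eff
    if (eff == "nonsynonymous") snps$aa_change[rows] <- paste0(ref_aa, ">", alt_aa)
  }
  snps
}

#' @export
tidy.hmwgs_variants <- function(x, ...) x$snps

#' @export
glance.hmwgs_variants <- function(x, ...) x$summary

#' @export
print.hmwgs_variants <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hmwgs_variants> %d SNPs (%d ts / %d tv), %d indels, %d nonsynonymous codons\n",
              s$n_snps, s$n_ts, s$n_tv, s$n_indels, s$n_nonsyn))
  invisible(x)
}

#' @export
autoplot.hmwgs_variants <- function(object, ...) {
  snps <- object$snps
  indels <- object$indels
  df <- bind_rows(
    if (nrow(snps)) tibble(pos = snps$pos, type = snps$klass),
    if (nrow(indels)) tibble(pos = indels$start, type = indels$kind)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = 1, colour = .data$type)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(0, 1.2)) +
    ggplot2::labs(x = "ORF position (query frame)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pairwise identity matrix
#'
#' Identity of each pair under global alignment: matching columns divided by
#' the full alignment length, gap columns counting as non-matching, reported
#' as a percentage to two decimals. This metric is a declared convention of
#' the package (alignment tools differ in how they score gaps into identity).
#'
#' @param records Subunit record tibble (at least two rows).
#' @param level `"dna"` or `"protein"`.
#' @param ... Scoring parameters passed to [align_global()].
#' @return A symmetric `hmwgs_identity` percentage matrix with a 100.00
#'   diagonal and record ids as dimnames. [tidy()] returns the long form.
#' @export
identity_matrix <- function(records, level = c("dna", "protein"), ...) {
  level <- match.arg(level)
  seqs <- records[[level]]
  ids <- records$id
  if (length(seqs) < 2L || anyNA(seqs)) {
    abort(sprintf("need at least two records with a %s sequence", level))
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      aln <- align_global(seqs[i], seqs[j], ...)
      va <- seq_chars(aln$aligned_a)
      vb <- seq_chars(aln$aligned_b)
      ident <- 100 * sum(va == vb & va != "-") / length(va)
      m[i, j] <- m[j, i] <- round(ident, 2)
    }
  }
  structure(m, class = c("hmwgs_identity", "matrix"))
}

#' @export
tidy.hmwgs_identity <- function(x, ...) {
  ids <- rownames(x)
  out <- expand.grid(id1 = ids, id2 = ids, stringsAsFactors = FALSE)
  out$identity <- as.vector(unclass(x))
  as_tibble(out)
}

#' @export
autoplot.hmwgs_identity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2, fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$identity)), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write an identity matrix as TSV
#' @param m A `hmwgs_identity` matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a variant table as minimal VCF 4.2
#'
#' SNPs are written at their reference-frame position; indels are anchored at
#' the preceding reference base, with that base prefixed to REF and ALT as
#' VCF requires.
#'
#' @param variants A [call_variants()] result.
#' @param ref_id,query_id Identifiers for the reference (CHROM column) and
#'   the query (sample name in the header).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, ref_id, query_id, path) {
  rseq <- attr(variants, "ref")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref_id, nchar(rseq)),
    sprintf("##source=hmwgs; query=%s", query_id),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  s <- variants$snps
  if (nrow(s)) {
    body <- c(body, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", ref_id, s$ref_pos, s$ref, s$alt))
  }
  ind <- variants$indels
  for (k in seq_len(nrow(ind))) {
    anchor_pos <- ind$ref_anchor[k]
    if (anchor_pos < 1L) next # indel at the very start cannot be VCF-anchored
    anchor <- substr(rseq, anchor_pos, anchor_pos)
    if (ind$kind[k] == "deletion") {
      ref <- paste0(anchor, ind$sequence[k]); alt <- anchor
    } else {
      ref <- anchor; alt <- paste0(anchor, ind$sequence[k])
    }
    body <- c(body, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", ref_id, anchor_pos, ref, alt))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Paper-style variant TSV
#'
#' One column per variant position (query frame), with the query and
#' reference bases and the amino-acid annotation in parentheses for
#' nonsynonymous changes; indel columns carry the anchor range.
#'
#' @inheritParams write_variants_vcf
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, ref_id, query_id, path) {
  s <- variants$snps
  ind <- variants$indels
  cols <- c(
    if (nrow(s)) setNames(
      lapply(seq_len(nrow(s)), function(k) {
        q <- if (!is.na(s$aa_change[k])) sprintf("%s(%s)", s$alt[k], s$alt_aa[k]) else s$alt[k]
        r <- if (!is.na(s$aa_change[k])) sprintf("%s(%s)", s$ref[k], s$ref_aa[k]) else s$ref[k]
        c(q, r)
      }), s$pos),
    if (nrow(ind)) setNames(
      lapply(seq_len(nrow(ind)), function(k) {
        if (ind$kind[k] == "insertion") c(ind$sequence[k], "***(*)") else c("***(*)", ind$sequence[k])
      }), paste0(ind$start, "-", ind$end))
  )
  ord <- order(as.numeric(sub("-.*$", "", names(cols))))
  cols <- cols[ord]
  tab <- do.call(cbind, cols)
  df <- data.frame(gene = c(query_id, ref_id), tab, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
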