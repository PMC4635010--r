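# codons per amino acid for reverse translation (standard code, no stops)
CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specification of a synthetic HMW-GS subunit
#'
#' Defaults describe the y-type architecture of the largest known 1Dy
#' subunit: a 21-residue signal peptide, a 104-residue N-terminal region, a
#' central repetitive domain of 48 hexapeptide and 20 nonapeptide units with
#' 9 PGQQ tetrapeptide separators plus a 2-residue linker tail (506 residues
#' in all), a 42-residue C-terminal region, and 5/1/1 cysteines in the
#' N-terminal/repetitive/C-terminal regions -- 673 residues in total. Set
#' `unit_counts = c(hexa = 48, nona = 19, tetra = 8)` and `linker_tail = ""`
#' for the 658-residue (491-residue repetitive domain) architecture.
#'
#' @param signal_length,nterm_length,cterm_length Domain lengths in residues.
#' @param unit_counts Named counts of repeat units (`hexa`, `nona`, `tetra`);
#'   tetrapeptides are used as nonapeptide separators, so `tetra` must not
#'   exceed `nona`.
#' @param linker_tail Residues appended after the last unit (still inside the
#'   repetitive domain), e.g. `"QQ"`.
#' @param cysteine_layout Named counts of cysteines per mature region.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `hmwgs_spec` list.
#' @export
subunit_spec <- function(signal_length = 21L, nterm_length = 104L,
                         cterm_length = 42L,
                         unit_counts = c(hexa = 48L, nona = 20L, tetra = 9L),
                         linker_tail = "QQ",
                         cysteine_layout = c(nterm = 5L, repetitive = 1L, cterm = 1L),
                         seed = 1L) {
  unit_counts <- unit_counts[c("hexa", "nona", "tetra")]
  unit_counts[is.na(unit_counts)] <- 0L
  names(unit_counts) <- c("hexa", "nona", "tetra")
  if (unit_counts[["tetra"]] > max(unit_counts[["nona"]], 0L)) {
    abort("tetrapeptides separate nonapeptides: `tetra` count must not exceed `nona`")
  }
  if (sum(unit_counts) == 0L) abort("at least one repeat unit is required")
  if (unit_counts[["nona"]] > 0L && unit_counts[["hexa"]] < unit_counts[["nona"]] - unit_counts[["tetra"]] + 1L) {
    abort("not enough hexapeptides to separate all nonapeptides and end the domain")
  }
  cysteine_layout <- cysteine_layout[c("nterm", "repetitive", "cterm")]
  cysteine_layout[is.na(cysteine_layout)] <- 0L
  names(cysteine_layout) <- c("nterm", "repetitive", "cterm")
  if (cysteine_layout[["nterm"]] > nterm_length || cysteine_layout[["cterm"]] > cterm_length) {
    abort("cysteine layout exceeds region lengths")
  }
  if (cysteine_layout[["repetitive"]] > 1L) {
    abort("at most one repetitive-domain cysteine is supported")
  }
  structure(list(
    signal_length = as.integer(signal_length),
    nterm_length = as.integer(nterm_length),
    cterm_length = as.integer(cterm_length),
    unit_counts = vapply(unit_counts, as.integer, integer(1)),
    linker_tail = toupper(linker_tail),
    cysteine_layout = vapply(cysteine_layout, as.integer, integer(1)),
    seed = as.integer(seed)
  ), class = "hmwgs_spec")
}

# deterministic unit layout honouring the published arrangement rules:
# hexapeptide runs, each nonapeptide followed by a hexapeptide or PGQQ
# separator, domain ends with a hexapeptide run (or the linker tail)
build_unit_layout <- function(counts, config) {
  n_nona <- counts[["nona"]]
  n_tetra <- counts[["tetra"]]
  n_hexa <- counts[["hexa"]]
  if (n_nona == 0L) {
    kinds <- rep("hexa", n_hexa)
  } else {
    sep_kinds <- sample(c(rep("tetra", n_tetra), rep("hexa", n_nona - n_tetra)))
    spare <- n_hexa - sum(sep_kinds == "hexa") - 1L # one hexa reserved for the tail run
    slots <- n_nona + 1L # before each nona block and a final run
    extra <- tabulate(sample.int(slots, spare, replace = TRUE), nbins = slots)
    kinds <- character(0)
    for (k in seq_len(n_nona)) {
      kinds <- c(kinds, rep("hexa", extra[k]), "nona", sep_kinds[k])
    }
    kinds <- c(kinds, rep("hexa", extra[slots] + 1L))
  }
  seqs <- vapply(kinds, function(kind) {
    opts <- config$motifs[[kind]]
    if (length(opts) > 1L) opts[sample.int(length(opts), 1L)] else opts
  }, character(1), USE.NAMES = FALSE)
  tibble(kind = kinds, sequence = seqs)
}

random_residues <- function(n, exclude = "C") {
  pool <- setdiff(AA20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

place_cysteines <- function(region, n_cys) {
  if (n_cys == 0L) return(list(seq = region, pos = integer(0)))
  pos <- sort(sample.int(nchar(region), n_cys))
  for (p in pos) substr(region, p, p) <- "C"
  list(seq = region, pos = pos)
}

reverse_translate <- function(protein) {
  codons <- vapply(seq_chars(protein), function(aa) {
    opts <- CODONS_BY_AA[[aa]]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

#' Generate a synthetic HMW-GS subunit with ground truth
#'
#' Assembles signal + N-terminal + repetitive domain (unit layout per the
#' published arrangement rules) + C-terminal, places cysteines, and
#' reverse-translates with uniformly sampled codons into an ORF with an ATG
#' start and a single terminal stop. The N-terminal and signal sequences are
#' resampled until no repeat seed motif occurs before the true repetitive
#' boundary, so the stated truth is always recoverable. Fully deterministic
#' given the spec (including its seed).
#'
#' @param spec A [subunit_spec()].
#' @param id Record identifier.
#' @param config Repeat-motif set used for unit sequences.
#' @param template Segmentation template used for the self-consistency screen.
#' @return A list with `record` (one-row subunit tibble) and `truth`: a list
#'   with `boundaries` (domain tibble as [segment_protein()] returns),
#'   `layout` (unit tibble with domain coordinates), `cys_positions` (mature
#'   coordinates), `q_count` (glutamines in the mature protein), `protein`,
#'   and `dna`.
#' @export
generate_subunit <- function(spec, id = sprintf("syn_%d", spec$seed),
                             config = repeat_config(),
                             template = domain_template(
                               signal_length = spec$signal_length,
                               cterm_length = spec$cterm_length)) {
  withr::with_seed(spec$seed, {
    layout <- build_unit_layout(spec$unit_counts, config)
    repetitive <- paste(layout$sequence, collapse = "")
    if (nzchar(spec$linker_tail)) repetitive <- paste0(repetitive, spec$linker_tail)

    # repetitive-domain cysteine sits at the domain's last residue (the
    # published position is "close to the C-terminus"); inside the linker
    # tail when present, else as a 1-mismatch variant of the final unit
    rep_cys <- integer(0)
    if (spec$cysteine_layout[["repetitive"]] == 1L) {
      substr(repetitive, nchar(repetitive), nchar(repetitive)) <- "C"
      rep_cys <- nchar(repetitive)
      if (!nzchar(spec$linker_tail)) {
        layout$sequence[nrow(layout)] <- sub(".$", "C", layout$sequence[nrow(layout)])
      }
    }

    signal <- paste0("M", random_residues(spec$signal_length - 1L))
    nt <- place_cysteines(random_residues(spec$nterm_length), spec$cysteine_layout[["nterm"]])
    ct <- place_cysteines(random_residues(spec$cterm_length), spec$cysteine_layout[["cterm"]])

    protein <- paste0(signal, nt$seq, repetitive, ct$seq)
    true_start <- spec$signal_length + spec$nterm_length + 1L

    # self-consistency screen: no seed motif may fire before the true boundary
    tries <- 0L
    repeat {
      hit <- find_repeat_start(protein, template$repeat_seeds,
                               template$max_seed_mismatch,
                               from = spec$signal_length + 1L,
                               last = nchar(protein) - spec$cterm_length)
      if (!is.null(hit) && hit$pos == true_start) break
      tries <- tries + 1L
      if (tries > 100L) abort("could not realize a self-consistent N-terminal region")
      signal <- paste0("M", random_residues(spec$signal_length - 1L))
      nt <- place_cysteines(random_residues(spec$nterm_length), spec$cysteine_layout[["nterm"]])
      protein <- paste0(signal, nt$seq, repetitive, ct$seq)
    }

    dna <- paste0(reverse_translate(protein), STOP_CODONS[sample.int(3L, 1L)])

    rep_start <- true_start
    rep_end <- rep_start + nchar(repetitive) - 1L
    boundaries <- tibble(
      domain = c("signal", "nterm", "repetitive", "cterm"),
      start = c(1L, spec$signal_length + 1L, rep_start, rep_end + 1L),
      end = c(spec$signal_length, rep_start - 1L, rep_end, nchar(protein))
    )
    boundaries$length <- boundaries$end - boundaries$start + 1L

    unit_start <- cumsum(c(1L, head(nchar(layout$sequence), -1L)))
    layout$start <- unit_start
    layout$end <- unit_start + nchar(layout$sequence) - 1L

    mature <- substr(protein, spec$signal_length + 1L, nchar(protein))
    cys_positions <- sort(c(
      nt$pos,
      spec$nterm_length + rep_cys,
      spec$nterm_length + nchar(repetitive) + ct$pos
    ))

    list(
      record = subunit_records(id, dna = dna, protein = protein,
                               source = sprintf("synthetic seed=%d", spec$seed)),
      truth = list(
        boundaries = boundaries,
        layout = layout,
        cys_positions = as.integer(cys_positions),
        q_count = stringr::str_count(mature, stringr::fixed("Q")),
        protein = protein,
        dna = dna
      )
    )
  })
}

#' Apply SNP and indel edits to a backbone ORF
#'
#' Edits are given in the coordinates of the *edited* (query) sequence -- the
#' frame in which variant tables print positions -- and applied in ascending
#' position. Each SNP's `ref` base is checked against the backbone at the
#' mapped position and a mismatch is an error naming the position.
#'
#' @param dna Backbone (reference) DNA string.
#' @param snps Tibble/data frame with columns `pos`, `ref`, `alt`, or NULL.
#' @param indels Tibble/data frame with columns `kind`
#'   (`"insertion"`/`"deletion"`), `pos` (insertion: first inserted base;
#'   deletion: query base after which the gap sits), `length`, `sequence`
#'   (inserted sequence; for deletions the expected deleted backbone
#'   sequence, checked when given), or NULL.
#' @return A list: `dna` (the edited sequence) and `truth`, a list of `snps`
#'   and `indels` tibbles in the same conventions as [call_variants()]
#'   (positions and spans in the query frame).
#' @export
apply_edits <- function(dna, snps = NULL, indels = NULL) {
  dna <- check_dna(dna)
  empty_snps <- tibble(pos = integer(0), ref = character(0), alt = character(0))
  snps <- if (is.null(snps) || nrow(snps) == 0L) empty_snps else
    tibble(pos = unname(as.integer(snps$pos)),
           ref = unname(toupper(snps$ref)),
           alt = unname(toupper(snps$alt)))
  empty_ind <- tibble(kind = character(0), pos = integer(0), length = integer(0),
                      sequence = character(0))
  indels <- if (is.null(indels) || nrow(indels) == 0L) empty_ind else
    tibble(kind = indels$kind, pos = as.integer(indels$pos),
           length = as.integer(indels$length),
           sequence = toupper(indels$sequence %||% NA_character_))

  events <- bind_rows(
    if (nrow(snps)) tibble(type = "snp", pos = snps$pos, ord = snps$pos + 0,
                           ref = snps$ref, alt = snps$alt,
                           length = 1L, sequence = NA_character_),
    if (nrow(indels)) tibble(type = indels$kind, pos = indels$pos,
                             ord = indels$pos + ifelse(indels$kind == "insertion", -0.5, 0.5),
                             ref = NA_character_, alt = NA_character_,
                             length = indels$length, sequence = indels$sequence)
  )
  if (nrow(events) == 0L) {
    return(list(dna = dna, truth = list(snps = empty_snps,
                                        indels = tibble(kind = character(0), start = integer(0),
                                                        end = integer(0), length = integer(0),
                                                        sequence = character(0)))))
  }
  events <- arrange(events, .data$ord)

  out <- character(0)
  qcur <- 1L # next query position to emit
  rcur <- 1L # next backbone position to consume
  truth_ind <- list()
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    if (ev$type == "snp") {
      gap <- ev$pos - qcur
      if (gap < 0L) abort("edits overlap or are out of order")
      if (gap > 0L) out <- c(out, substr(dna, rcur, rcur + gap - 1L))
      have <- substr(dna, rcur + gap, rcur + gap)
      if (have != ev$ref) {
        abort(sprintf("reference mismatch at query position %d (backbone %d): expected %s, found %s",
                      ev$pos, rcur + gap, ev$ref, have))
      }
      out <- c(out, ev$alt)
      qcur <- ev$pos + 1L
      rcur <- rcur + gap + 1L
    } else if (ev$type == "insertion") {
      gap <- ev$pos - qcur
      if (gap < 0L) abort("edits overlap or are out of order")
      if (gap > 0L) out <- c(out, substr(dna, rcur, rcur + gap - 1L))
      if (is.na(ev$sequence) || nchar(ev$sequence) != ev$length) {
        abort("insertions require `sequence` of length `length`")
      }
      out <- c(out, ev$sequence)
      truth_ind[[length(truth_ind) + 1L]] <- tibble(
        kind = "insertion", start = ev$pos, end = ev$pos + ev$length - 1L,
        length = ev$length, sequence = ev$sequence
      )
      qcur <- ev$pos + ev$length
      rcur <- rcur + gap
    } else { # deletion anchored after query position ev$pos
      gap <- ev$pos + 1L - qcur
      if (gap < 0L) abort("edits overlap or are out of order")
      if (gap > 0L) out <- c(out, substr(dna, rcur, rcur + gap - 1L))
      rcur <- rcur + gap
      deleted <- substr(dna, rcur, rcur + ev$length - 1L)
      if (!is.na(ev$sequence) && deleted != ev$sequence) {
        abort(sprintf("deletion after query position %d: backbone has %s, expected %s",
                      ev$pos, deleted, ev$sequence))
      }
      truth_ind[[length(truth_ind) + 1L]] <- tibble(
        kind = "deletion", start = ev$pos, end = ev$pos + 1L,
        length = ev$length, sequence = deleted
      )
      rcur <- rcur + ev$length
      qcur <- ev$pos + 1L
    }
  }
  if (rcur <= nchar(dna)) out <- c(out, substr(dna, rcur, nchar(dna)))

  truth_ind <- if (length(truth_ind)) arrange(bind_rows(truth_ind), .data$start) else
    tibble(kind = character(0), start = integer(0), end = integer(0),
           length = integer(0), sequence = character(0))
  list(dna = paste(out, collapse = ""), truth = list(snps = snps, indels = truth_ind))
}

#' Generate two diverged clades of aligned protein sequences
#'
#' Mutates two ancestor sequences (the second derived from the first at the
#' between-clade rate) at the within-clade rate per tip. No indels are
#' introduced, so the sequences are trivially aligned.
#'
#' @param n_per_clade Tips per clade.
#' @param length Sequence length in residues.
#' @param within,between Per-site substitution probabilities (between must
#'   exceed within).
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `clade` (`"A"`/`"B"`), `sequence`.
#' @export
generate_clade_set <- function(n_per_clade = 5L, length = 200L,
                               within = 0.01, between = 0.3, seed = 1L) {
  stopifnot(within >= 0, within <= 1, between >= 0, between <= 1)
  if (between < within) abort("`between` must be at least `within`")
  withr::with_seed(seed, {
    mutate_seq <- function(chars, rate) {
      hit <- which(stats::runif(length(chars)) < rate)
      for (p in hit) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
      chars
    }
    anc1 <- seq_chars(random_residues(length, exclude = character(0)))
    anc2 <- mutate_seq(anc1, between)
    rows <- list()
    for (clade in c("A", "B")) {
      anc <- if (clade == "A") anc1 else anc2
      for (k in seq_len(n_per_clade)) {
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("clade%s_%d", clade, k), clade = clade,
          sequence = paste(mutate_seq(anc, within), collapse = "")
        )
      }
    }
    bind_rows(rows)
  })
}
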