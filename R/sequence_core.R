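#' Build a subunit record table
#'
#' The central container used throughout the package: one row per HMW-GS
#' gene/protein, with the DNA open reading frame and/or the deduced protein.
#'
#' @param id Character vector of record identifiers (e.g. GenBank accessions).
#' @param dna Optional character vector of ORF sequences (A/C/G/T).
#' @param protein Optional character vector of amino-acid sequences.
#' @param source Free-text provenance (accession, synthetic seed, ...).
#'
#' @return A tibble with columns `id`, `dna`, `protein`, `source`.
#' @export
#' @examples
#' subunit_records("toy", dna = "ATGGGTTGA")
subunit_records <- function(id, dna = NA_character_, protein = NA_character_,
                            source = NA_character_) {
  stopifnot(length(id) >= 1L)
  rec <- tibble(
    id = as.character(id),
    dna = toupper(as.character(dna)),
    protein = toupper(as.character(protein)),
    source = as.character(source)
  )
  for (k in seq_len(nrow(rec))) {
    if (!is.na(rec$dna[k])) rec$dna[k] <- check_dna(rec$dna[k], paste0("dna[", rec$id[k], "]"))
    if (!is.na(rec$protein[k])) {
      rec$protein[k] <- check_protein(rec$protein[k], paste0("protein[", rec$id[k], "]"))
    }
    if (!is.na(rec$dna[k]) && !is.na(rec$protein[k])) {
      tr <- translate_orf(rec$dna[k])
      if (!identical(tr, rec$protein[k])) {
        abort(sprintf("record '%s': translate(dna) does not equal protein", rec$id[k]))
      }
    }
  }
  rec
}

#' Read HMW-GS sequences from a FASTA file
#'
#' @param path Path to a FASTA file (multi-record, wrapped or single-line).
#' @param type `"dna"` or `"protein"`; sequences are uppercased and validated
#'   against the corresponding alphabet. For DNA, IUPAC ambiguity codes and
#'   `U` are rejected: cloned Sanger ORFs are unambiguous.
#'
#' @return A subunit record tibble (see [subunit_records()]) with the FASTA
#'   description preserved in `source`.
#' @export
read_subunit_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records found in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) abort(sprintf("record '%s' has an empty sequence", ids[k]))
    if (type == "dna") check_dna(seqs[k], ids[k]) else check_protein(seqs[k], ids[k])
  }
  if (type == "dna") {
    subunit_records(ids, dna = unname(seqs), source = unname(names(set)))
  } else {
    subunit_records(ids, protein = unname(seqs), source = unname(names(set)))
  }
}

#' Write subunit records to FASTA
#'
#' @param records Subunit record tibble.
#' @param path Output file.
#' @param what Which sequence column to write.
#' @return `path`, invisibly.
#' @export
write_subunit_fasta <- function(records, path, what = c("dna", "protein")) {
  what <- match.arg(what)
  seqs <- records[[what]]
  if (anyNA(seqs)) abort(sprintf("some records have no %s sequence", what))
  lines <- character(0)
  for (k in seq_len(nrow(records))) {
    body <- gsub("(.{60})", "\\1\n", seqs[k])
    lines <- c(lines, paste0(">", records$id[k]), strsplit(body, "\n")[[1]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Translate a DNA open reading frame
#'
#' Standard genetic code (translation table 1). A single terminal stop codon
#' is stripped; internal stops are rendered as `*`.
#'
#' @param dna DNA string (A/C/G/T; lowercase accepted).
#' @param frame 0-based frame offset.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_orf("CAGATAGGAAAAGGGAAA") # "QIGKGK"
translate_orf <- function(dna, frame = 0L) {
  dna <- check_dna(dna)
  if (nchar(dna) - frame < 3L) abort("fewer than 3 bases available in the requested frame")
  sub <- substr(dna, frame + 1L, nchar(dna))
  sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
  sub("\\*$", "", aa)
}

#' Validate an open reading frame
#'
#' All problems are reported via flags, never as errors: HMW-GS genes are
#' intronless, so the genomic amplicon is expected to be a complete ORF
#' running from the A of ATG through a single terminal stop.
#'
#' @param x A DNA string, a character vector of DNA strings, or a subunit
#'   record tibble (column `dna` is used).
#' @return A tibble with one row per sequence: `id`, `starts_with_atg`,
#'   `ends_with_stop`, `length_nt`, `divisible_by_3`, `internal_stops`
#'   (list-column of 1-based codon indices), `n_internal_stops`, `valid` and
#'   `residue_count` (`length_nt/3 - 1` when all checks pass, otherwise `NA`).
#' @export
#' @examples
#' validate_orf("ATGTGA") # minimal ORF, residue_count 1... encodes M only
validate_orf <- function(x) {
  if (is.data.frame(x)) {
    ids <- x$id
    seqs <- x$dna
  } else {
    seqs <- x
    ids <- if (!is.null(names(x))) names(x) else paste0("seq", seq_along(x))
  }
  stops <- c("TAA", "TAG", "TGA")
  rows <- purrr::map2(seqs, ids, function(dna, id) {
    dna <- check_dna(dna, id)
    len <- nchar(dna)
    div3 <- len %% 3L == 0L
    n_codon <- len %/% 3L
    codons <- if (n_codon > 0) {
      substring(dna, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    } else character(0)
    starts <- substr(dna, 1L, 3L) == "ATG"
    ends <- div3 && n_codon >= 1L && codons[n_codon] %in% stops
    internal <- if (n_codon > 1L) which(codons[-n_codon] %in% stops) else integer(0)
    valid <- starts && ends && div3 && length(internal) == 0L && n_codon >= 2L
    tibble(
      id = id, starts_with_atg = starts, ends_with_stop = ends,
      length_nt = len, divisible_by_3 = div3,
      internal_stops = list(internal), n_internal_stops = length(internal),
      valid = valid,
      residue_count = if (valid) len %/% 3L - 1L else NA_integer_
    )
  })
  bind_rows(rows)
}

#' Deduce missing protein sequences from valid ORFs
#'
#' @param records Subunit record tibble.
#' @return The records tibble with `protein` filled in wherever it was absent
#'   and the ORF validates.
#' @export
deduce_proteins <- function(records) {
  for (k in seq_len(nrow(records))) {
    if (is.na(records$protein[k]) && !is.na(records$dna[k])) {
      chk <- validate_orf(records$dna[k])
      if (isTRUE(chk$valid)) records$protein[k] <- translate_orf(records$dna[k])
    }
  }
  records
}
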