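#' Run the full characterization pipeline
#'
#' Orchestrates ORF validation, translation, segmentation, repeat
#' decomposition, cysteine/glutamine/mass accounting and (optionally)
#' pairwise variant calling, identity and secondary-structure summaries over
#' a table of subunit records. Any stage that cannot run for a record is
#' marked skipped with its reason rather than failing the whole report.
#'
#' @param records Subunit record tibble (see [subunit_records()],
#'   [read_subunit_fasta()]); proteins are deduced from valid ORFs when
#'   absent.
#' @param template Segmentation [domain_template()].
#' @param config Repeat-motif [repeat_config()].
#' @param pairs Optional two-column data frame/tibble (`query`, `ref`) of
#'   record ids to compare; when NULL no variant section is produced.
#' @param observed_masses Optional named numeric vector of MALDI-TOF masses
#'   (Da) keyed by record id.
#' @param ss8 Optional named character vector of externally predicted 8-state
#'   secondary-structure strings (one letter per mature residue), keyed by id.
#' @param mass_threshold_pct Concordance threshold for [mass_concordance()].
#' @return A `hmwgs_report` list with tibble sections: `orf`, `segmentation`,
#'   `repeats`, `arrangement`, `cysteines`, `glutamine`, `mass`, `variants`
#'   (+ `variant_summaries`), `identity`, `ss8`, and `skipped`
#'   (`id`, `stage`, `reason`).
#' @export
characterize <- function(records, template = domain_template(),
                         config = repeat_config(), pairs = NULL,
                         observed_masses = NULL, ss8 = NULL,
                         mass_threshold_pct = 0.5) {
  if (nrow(records) < 1L) abort("need at least one record")
  records <- deduce_proteins(records)
  skipped <- list()
  skip <- function(id, stage, reason) {
    skipped[[length(skipped) + 1L]] <<- tibble(id = id, stage = stage, reason = reason)
  }

  orf <- if (all(is.na(records$dna))) NULL else
    validate_orf(records[!is.na(records$dna), ])

  seg_rows <- list(); rep_rows <- list(); arr_rows <- list()
  cys_rows <- list(); q_rows <- list(); mass_rows <- list(); ss8_rows <- list()
  segs <- list()
  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    protein <- records$protein[k]
    if (is.na(protein)) {
      skip(id, "segmentation", "no protein sequence (missing or invalid ORF)")
      next
    }
    seg <- tryCatch(segment_protein(protein, template), error = function(e) e)
    if (inherits(seg, "error")) {
      skip(id, "segmentation", conditionMessage(seg))
      next
    }
    segs[[id]] <- seg
    seg_rows[[id]] <- mutate(as_tibble(seg), id = id, .before = 1L)

    ann <- decompose_repeats(domain_sequence(protein, seg), config)
    rep_rows[[id]] <- mutate(glance(ann), id = id, .before = 1L)
    arr_rows[[id]] <- mutate(check_arrangement(ann), id = id, .before = 1L)

    mature <- mature_protein(protein, seg)
    cys_rows[[id]] <- mutate(glance(map_cysteines(mature, seg)), id = id, .before = 1L)
    q_rows[[id]] <- mutate(glutamine_content(mature), id = id, .before = 1L)

    deduced <- average_mass(mature)
    obs <- if (!is.null(observed_masses) && id %in% names(observed_masses)) {
      observed_masses[[id]]
    } else {
      NA_real_
    }
    mrow <- if (is.na(obs)) {
      tibble(deduced_da = deduced, observed_da = NA_real_, delta_da = NA_real_,
             delta_pct = NA_real_, consistent = NA)
    } else {
      mass_concordance(deduced, obs, mass_threshold_pct)
    }
    mass_rows[[id]] <- mutate(mrow, id = id, .before = 1L)

    if (!is.null(ss8) && id %in% names(ss8)) {
      s <- tryCatch(summarize_ss8(ss8[[id]], seg), error = function(e) e)
      if (inherits(s, "error")) skip(id, "ss8", conditionMessage(s)) else
        ss8_rows[[id]] <- mutate(s, id = id, .before = 1L)
    }
  }

  variants <- NULL; variant_summaries <- NULL; indels <- NULL
  if (!is.null(pairs)) {
    vt <- list(); vs <- list(); vi <- list()
    for (k in seq_len(nrow(pairs))) {
      qid <- pairs$query[k]; rid <- pairs$ref[k]
      qdna <- records$dna[records$id == qid]
      rdna <- records$dna[records$id == rid]
      if (length(qdna) != 1L || length(rdna) != 1L || is.na(qdna) || is.na(rdna)) {
        skip(paste(qid, rid, sep = " vs "), "variants", "missing DNA sequence")
        next
      }
      v <- call_variants(align_global(qdna, rdna), query = "a")
      key <- paste(qid, rid, sep = " vs ")
      vt[[key]] <- mutate(v$snps, pair = key, .before = 1L)
      vs[[key]] <- mutate(v$summary, pair = key, .before = 1L)
      vi[[key]] <- mutate(v$indels, pair = key, .before = 1L)
    }
    variants <- bind_rows(vt)
    variant_summaries <- bind_rows(vs)
    indels <- bind_rows(vi)
  }

  identity <- NULL
  with_dna <- records[!is.na(records$dna), ]
  if (nrow(with_dna) >= 2L) identity <- identity_matrix(with_dna, level = "dna")

  structure(list(
    records = records,
    orf = orf,
    segmentation = bind_rows(seg_rows),
    repeats = bind_rows(rep_rows),
    arrangement = bind_rows(arr_rows),
    cysteines = bind_rows(cys_rows),
    glutamine = bind_rows(q_rows),
    mass = bind_rows(mass_rows),
    ss8 = if (length(ss8_rows)) bind_rows(ss8_rows) else NULL,
    variants = variants,
    variant_summaries = variant_summaries,
    indels = indels,
    identity = identity,
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(id = character(0), stage = character(0), reason = character(0)),
    segmentations = segs
  ), class = "hmwgs_report")
}

#' @export
print.hmwgs_report <- function(x, ...) {
  cat(sprintf("<hmwgs_report> %d records", nrow(x$records)))
  if (!is.null(x$variants)) cat(sprintf(", %d compared pairs", nrow(x$variant_summaries)))
  if (nrow(x$skipped)) cat(sprintf(", %d skipped stages", nrow(x$skipped)))
  cat("\n")
  invisible(x)
}

#' Write a characterization report to disk
#'
#' Writes `report.json` (all sections) plus one TSV per tabular section.
#'
#' @param report A [characterize()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sections <- c("orf", "segmentation", "repeats", "arrangement", "cysteines",
                "glutamine", "mass", "ss8", "variants", "variant_summaries",
                "indels", "skipped")
  out <- list(schema = "hmwgs_report/1")
  for (s in sections) {
    tab <- report[[s]]
    if (is.null(tab) || nrow(tab) == 0L) next
    tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
    out[[s]] <- tab
    write.table(tab, file.path(dir, paste0(s, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$identity)) {
    out$identity <- as.data.frame(unclass(report$identity))
    write_identity_tsv(report$identity, file.path(dir, "identity.tsv"))
  }
  jsonlite::write_json(out, file.path(dir, "report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a YAML configuration into template/config objects
#'
#' Recognized keys: `signal_length`, `cterm_length`, `repeat_seeds`,
#' `max_seed_mismatch` (template); `nona`, `hexa`, `tetra`, `tri`,
#' `allowance` (repeat config); `mass_threshold_pct`.
#'
#' @param path Path to a YAML file.
#' @return A list with `template`, `config` and `mass_threshold_pct`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tmpl_args <- y[intersect(names(y), c("signal_length", "cterm_length",
                                       "repeat_seeds", "max_seed_mismatch"))]
  cfg_args <- y[intersect(names(y), c("nona", "hexa", "tetra", "tri"))]
  if (!is.null(y$allowance)) cfg_args$allowance <- unlist(y$allowance)
  list(
    template = do.call(domain_template, tmpl_args),
    config = do.call(repeat_config, cfg_args),
    mass_threshold_pct = y$mass_threshold_pct %||% 0.5
  )
}
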