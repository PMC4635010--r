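#' Repeat-motif configuration
#'
#' The central repetitive domain of HMW-GS proteins is a tandem array of
#' short glutamine-rich units: nonapeptides (consensus GYYPTSLQQ, with
#' GHYPASQQQ as a common second consensus), hexapeptides (PGQGQQ), PGQQ
#' tetrapeptides, and -- in x-type subunits only -- GQQ tripeptides. The
#' published consensuses are degenerate, so each kind carries a mismatch
#' allowance.
#'
#' @param nona,hexa,tetra,tri Character vectors of consensus motifs per kind.
#' @param allowance Named integer vector of per-kind mismatch allowances.
#' @return A `hmwgs_repeat_config` list.
#' @export
repeat_config <- function(nona = c("GYYPTSLQQ", "GHYPASQQQ"),
                          hexa = "PGQGQQ",
                          tetra = "PGQQ",
                          tri = "GQQ",
                          allowance = c(nona = 2L, hexa = 1L, tetra = 0L, tri = 0L)) {
  motifs <- list(nona = toupper(nona), hexa = toupper(hexa),
                 tetra = toupper(tetra), tri = toupper(tri))
  motifs <- motifs[lengths(motifs) > 0L]
  lens <- c(nona = 9L, hexa = 6L, tetra = 4L, tri = 3L)
  for (kind in names(motifs)) {
    if (any(nchar(motifs[[kind]]) != lens[[kind]])) {
      abort(sprintf("all '%s' motifs must have length %d", kind, lens[[kind]]))
    }
  }
  structure(list(motifs = motifs, allowance = allowance, unit_length = lens),
            class = "hmwgs_repeat_config")
}

UNIT_LETTER <- c(nona = "N", hexa = "H", tetra = "T", tri = "G", linker = "-")

#' Decompose a repetitive domain into repeat units
#'
#' Greedy left-to-right scan: at each cursor position the longest motif kind
#' matching within its mismatch allowance is consumed (nonapeptide before
#' hexapeptide before tetrapeptide before tripeptide); among consensuses of
#' the same kind, the one with fewest mismatches wins (ties: list order).
#' Residues matching no motif are collected into linker runs, so the unit
#' sequences always reconstruct the domain exactly.
#'
#' @param domain Amino-acid string (the central repetitive domain).
#' @param config A [repeat_config()].
#' @return A `hmwgs_repeats` tibble of units in domain order with columns
#'   `kind` (nona/hexa/tetra/tri/linker), `start`, `end` (1-based within the
#'   domain), `sequence` and `mismatches` (`NA` for linkers). Attributes:
#'   `domain`, `counts` (named vector, linkers excluded), `layout` (compact
#'   string, e.g. `"H H N H"`).
#' @export
#' @examples
#' decompose_repeats("PGQGQQGYYPTSLQQPGQGQQ")
decompose_repeats <- function(domain, config = repeat_config()) {
  domain <- check_protein(domain, "domain")
  chars <- seq_chars(domain)
  n <- length(chars)
  kinds_by_len <- names(sort(config$unit_length[names(config$motifs)], decreasing = TRUE))

  kind_v <- character(0); start_v <- integer(0); seq_v <- character(0); mm_v <- integer(0)
  linker_start <- NA_integer_
  i <- 1L
  flush_linker <- function(upto) {
    if (!is.na(linker_start)) {
      kind_v <<- c(kind_v, "linker"); start_v <<- c(start_v, linker_start)
      seq_v <<- c(seq_v, paste(chars[linker_start:(upto - 1L)], collapse = ""))
      mm_v <<- c(mm_v, NA_integer_)
      linker_start <<- NA_integer_
    }
  }
  while (i <= n) {
    hit <- NULL
    for (kind in kinds_by_len) {
      L <- config$unit_length[[kind]]
      if (i + L - 1L > n) next
      window <- chars[i:(i + L - 1L)]
      best_mm <- NA_integer_; best_seq <- NA_character_
      for (m in config$motifs[[kind]]) {
        mm <- sum(window != seq_chars(m))
        if (mm <= config$allowance[[kind]] && (is.na(best_mm) || mm < best_mm)) {
          best_mm <- mm; best_seq <- m
        }
      }
      if (!is.na(best_mm)) {
        hit <- list(kind = kind, len = L, mm = best_mm)
        break
      }
    }
    if (is.null(hit)) {
      if (is.na(linker_start)) linker_start <- i
      i <- i + 1L
    } else {
      flush_linker(i)
      kind_v <- c(kind_v, hit$kind); start_v <- c(start_v, i)
      seq_v <- c(seq_v, paste(chars[i:(i + hit$len - 1L)], collapse = ""))
      mm_v <- c(mm_v, hit$mm)
      i <- i + hit$len
    }
  }
  flush_linker(n + 1L)

  units <- tibble(kind = kind_v, start = start_v,
                  end = start_v + nchar(seq_v) - 1L,
                  sequence = seq_v, mismatches = mm_v)
  counts <- table(factor(units$kind[units$kind != "linker"],
                         levels = names(config$motifs)))
  structure(units, class = c("hmwgs_repeats", class(tibble())),
            domain = domain,
            counts = setNames(as.integer(counts), names(counts)),
            layout = paste(UNIT_LETTER[units$kind], collapse = " "))
}

#' Repeat-unit counts
#' @param annotation A `hmwgs_repeats` annotation.
#' @return Named integer vector of unit counts per kind (linkers excluded).
#' @export
repeat_counts <- function(annotation) attr(annotation, "counts")

#' @export
tidy.hmwgs_repeats <- function(x, ...) as_tibble(x)

#' @export
glance.hmwgs_repeats <- function(x, ...) {
  counts <- attr(x, "counts")
  out <- as_tibble(as.list(counts))
  out$n_linker_residues <- sum(nchar(x$sequence[x$kind == "linker"]))
  out$domain_length <- nchar(attr(x, "domain"))
  out
}

#' Check repeat arrangement rules
#'
#' Two published arrangement rules for y-type subunits: (a) nonapeptide units
#' are never adjacent -- each pair is separated by a hexapeptide or a PGQQ
#' tetrapeptide; (b) tripeptide (GQQ) units occur only in x-type subunits.
#'
#' @param annotation A `hmwgs_repeats` annotation.
#' @param subunit_type `"y"` (default) or `"x"`; rule (b) is only an
#'   expectation for y-type subunits.
#' @return A tibble with columns `rule`, `pass`, `note`.
#' @export
check_arrangement <- function(annotation, subunit_type = c("y", "x")) {
  subunit_type <- match.arg(subunit_type)
  kinds <- annotation$kind
  adjacent_nona <- any(kinds[-length(kinds)] == "nona" & kinds[-1] == "nona")
  has_tri <- any(kinds == "tri")
  tibble(
    rule = c("nona_separated", "no_tripeptide"),
    pass = c(!adjacent_nona, !(has_tri && subunit_type == "y")),
    note = c(
      if (adjacent_nona) "two nonapeptide units are adjacent" else
        "all nonapeptide units separated by another unit",
      if (has_tri && subunit_type == "y") "tripeptide present (unexpected for y-type)" else
        if (has_tri) "tripeptide present (x-type)" else "no tripeptide units"
    )
  )
}

#' Unit-level differences between two repeat annotations
#'
#' Aligns the two unit layouts by longest common subsequence on
#' (kind, sequence) and reports runs of whole units present in only one
#' annotation -- the unit-level view of repeat-domain indels such as a
#' nonapeptide+hexapeptide (15-residue) insertion.
#'
#' @param annotation_a,annotation_b `hmwgs_repeats` annotations of two
#'   comparable subunits.
#' @return A tibble with one row per inserted/deleted unit run: `op`
#'   (`"insertion"` = present only in a, `"deletion"` = present only in b),
#'   `kinds`, `sequence`, `length` (residues), `start_a`, `start_b` (domain
#'   coordinates of the run, `NA` in the annotation lacking it).
#' @export
insertion_motif_report <- function(annotation_a, annotation_b) {
  ka <- paste(annotation_a$kind, annotation_a$sequence)
  kb <- paste(annotation_b$kind, annotation_b$sequence)
  n <- length(ka); m <- length(kb)
  # LCS dynamic program
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (ka[i] == kb[j]) L[i, j] + 1L else max(L[i, j + 1L], L[i + 1L, j])
    }
  }
  ops <- character(0); idx <- integer(0) # per unit: "A" only-in-a, "B" only-in-b, "=" shared
  ia <- n; ib <- m
  path <- list()
  while (ia > 0L || ib > 0L) {
    if (ia > 0L && ib > 0L && ka[ia] == kb[ib] && L[ia + 1L, ib + 1L] == L[ia, ib] + 1L) {
      path[[length(path) + 1L]] <- c("=", ia, ib); ia <- ia - 1L; ib <- ib - 1L
    } else if (ib > 0L && (ia == 0L || L[ia + 1L, ib] >= L[ia, ib + 1L])) {
      path[[length(path) + 1L]] <- c("B", NA, ib); ib <- ib - 1L
    } else {
      path[[length(path) + 1L]] <- c("A", ia, NA); ia <- ia - 1L
    }
  }
  path <- rev(path)
  out <- list()
  k <- 1L
  while (k <= length(path)) {
    op <- path[[k]][1]
    if (op == "=") { k <- k + 1L; next }
    run <- k
    while (run < length(path) && path[[run + 1L]][1] == op) run <- run + 1L
    members <- path[k:run]
    if (op == "A") {
      rows <- as.integer(vapply(members, function(p) p[2], character(1)))
      units <- annotation_a[rows, ]
      out[[length(out) + 1L]] <- tibble(
        op = "insertion", kinds = paste(units$kind, collapse = "+"),
        sequence = paste(units$sequence, collapse = ""),
        length = sum(nchar(units$sequence)),
        start_a = units$start[1], start_b = NA_integer_
      )
    } else {
      rows <- as.integer(vapply(members, function(p) p[3], character(1)))
      units <- annotation_b[rows, ]
      out[[length(out) + 1L]] <- tibble(
        op = "deletion", kinds = paste(units$kind, collapse = "+"),
        sequence = paste(units$sequence, collapse = ""),
        length = sum(nchar(units$sequence)),
        start_a = NA_integer_, start_b = units$start[1]
      )
    }
    k <- run + 1L
  }
  if (length(out) == 0L) {
    tibble(op = character(0), kinds = character(0), sequence = character(0),
           length = integer(0), start_a = integer(0), start_b = integer(0))
  } else {
    bind_rows(out)
  }
}

#' Write a repeat annotation as GFF3-like TSV over protein coordinates
#'
#' @param annotation A `hmwgs_repeats` annotation.
#' @param seqid Sequence identifier for column 1.
#' @param path Output file.
#' @param offset 0-based offset to add to unit coordinates (e.g. the start of
#'   the repetitive domain within the full protein, minus one).
#' @return `path`, invisibly.
#' @export
write_repeats_gff <- function(annotation, seqid, path, offset = 0L) {
  out <- data.frame(
    seqid = seqid, source = "hmwgs", type = annotation$kind,
    start = annotation$start + offset, end = annotation$end + offset,
    score = ifelse(is.na(annotation$mismatches), ".", annotation$mismatches),
    strand = ".", phase = ".",
    attributes = paste0("sequence=", annotation$sequence)
  )
  writeLines(c("##gff-version 3",
               apply(out, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' @export
autoplot.hmwgs_repeats <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                               ymin = 0, ymax = 1, fill = .data$kind)) +
    ggplot2::geom_rect(colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position in repetitive domain", y = NULL, fill = "unit") +
    ggplot2::theme_minimal()
}
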