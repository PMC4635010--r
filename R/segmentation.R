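#' Domain template for HMW-GS segmentation
#'
#' HMW-GS proteins tile into four domains: a 21-residue signal peptide, a
#' conserved non-repetitive N-terminal region, a long central repetitive
#' domain, and a conserved 42-residue C-terminal region. The signal peptide
#' and C-terminal domain are located by fixed length (the literature gives
#' lengths, not boundary sequences); the repetitive domain starts at the
#' first near-match of a repeat seed motif.
#'
#' @param signal_length Signal peptide length in residues (default 21).
#' @param cterm_length C-terminal domain length in residues (default 42).
#' @param repeat_seeds Short amino-acid motifs whose first occurrence (allowing
#'   `max_seed_mismatch` mismatches) marks the repetitive-domain start. The
#'   defaults are the hexapeptide consensus and the 6-residue prefixes of the
#'   two nonapeptide consensuses.
#' @param max_seed_mismatch Mismatches tolerated when scanning for a seed.
#' @return A `hmwgs_template` list.
#' @export
domain_template <- function(signal_length = 21L, cterm_length = 42L,
                            repeat_seeds = c("PGQGQQ", "GYYPTS", "GHYPAS"),
                            max_seed_mismatch = 1L) {
  stopifnot(signal_length >= 0L, cterm_length >= 0L, length(repeat_seeds) >= 1L)
  structure(
    list(signal_length = as.integer(signal_length),
         cterm_length = as.integer(cterm_length),
         repeat_seeds = toupper(repeat_seeds),
         max_seed_mismatch = as.integer(max_seed_mismatch)),
    class = "hmwgs_template"
  )
}

# first position in [from, last] where any seed matches within the allowance
# and fits before `last`; ties at the same position: longest motif wins, then
# list order
find_repeat_start <- function(protein, seeds, allowance, from, last) {
  chars <- seq_chars(protein)
  ord <- order(-nchar(seeds), seq_along(seeds))
  seeds <- seeds[ord]
  if (from > last) return(NULL)
  for (pos in seq(from, last)) {
    for (s in seeds) {
      L <- nchar(s)
      if (pos + L - 1L > last) next
      window <- chars[pos:(pos + L - 1L)]
      if (sum(window != seq_chars(s)) <= allowance) {
        return(list(pos = pos, seed = s))
      }
    }
  }
  NULL
}

#' Segment an HMW-GS protein into its four domains
#'
#' @param protein Full deduced protein (signal peptide included).
#' @param template A [domain_template()].
#' @return A `hmwgs_segmentation` tibble with columns `domain`
#'   (signal/nterm/repetitive/cterm), `start`, `end` (1-based inclusive, on
#'   the full protein) and `length`; the four spans tile the protein exactly.
#' @export
segment_protein <- function(protein, template = domain_template()) {
  protein <- check_protein(protein)
  n <- nchar(protein)
  sl <- template$signal_length
  cl <- template$cterm_length
  if (n <= sl + cl + 1L) {
    abort(sprintf("protein too short to segment (%d residues <= %d + %d + 1)", n, sl, cl))
  }
  # the repetitive domain must start after the signal and fit before the cterm
  hit <- find_repeat_start(protein, template$repeat_seeds,
                           template$max_seed_mismatch,
                           from = sl + 1L, last = n - cl)
  if (is.null(hit)) {
    abort("repetitive domain not found: no repeat seed motif matches")
  }
  rep_start <- hit$pos
  seg <- tibble(
    domain = c("signal", "nterm", "repetitive", "cterm"),
    start = c(1L, sl + 1L, rep_start, n - cl + 1L),
    end = c(sl, rep_start - 1L, n - cl, n)
  )
  seg$length <- seg$end - seg$start + 1L
  structure(seg, class = c("hmwgs_segmentation", class(tibble())),
            protein = protein, seed = hit$seed)
}

#' Remove the signal peptide
#'
#' @param protein Full protein string.
#' @param seg Its [segment_protein()] result (defaults to segmenting with the
#'   standard template).
#' @return The mature protein (signal span removed).
#' @export
mature_protein <- function(protein, seg = segment_protein(protein)) {
  protein <- check_protein(protein)
  stopifnot(inherits(seg, "hmwgs_segmentation"))
  if (max(seg$end) != nchar(protein)) {
    abort("segmentation does not match the protein length")
  }
  substr(protein, seg$end[seg$domain == "signal"] + 1L, nchar(protein))
}

# segmentation spans shifted onto mature-protein coordinates
mature_spans <- function(seg) {
  sl <- seg$length[seg$domain == "signal"]
  out <- seg[seg$domain != "signal", ]
  out$start <- out$start - sl
  out$end <- out$end - sl
  out
}

#' Extract one domain's sequence
#'
#' @param protein Full protein string.
#' @param seg Segmentation of `protein`.
#' @param domain One of `"signal"`, `"nterm"`, `"repetitive"`, `"cterm"`.
#' @return The domain subsequence.
#' @export
domain_sequence <- function(protein, seg, domain = "repetitive") {
  row <- seg[seg$domain == domain, ]
  if (nrow(row) != 1L) abort(sprintf("unknown domain '%s'", domain))
  substr(protein, row$start, row$end)
}

#' Write a segmentation as BED-like TSV
#'
#' Columns: name, start, end (both 1-based inclusive), domain label.
#'
#' @param seg A `hmwgs_segmentation`.
#' @param name Sequence name for the first column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(seg, name, path) {
  out <- data.frame(name = name, start = seg$start, end = seg$end, domain = seg$domain)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.hmwgs_segmentation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                               ymin = 0, ymax = 1, fill = .data$domain)) +
    ggplot2::geom_rect(colour = "grey20") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "residue", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}
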