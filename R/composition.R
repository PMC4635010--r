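#' Map cysteine residues onto domains
#'
#' y-type HMW-GS carry seven conserved cysteines: five in the N-terminal
#' region, one in the central repetitive region close to the C-terminus, and
#' one in the C-terminal region. This locates every `C` of the mature protein
#' and assigns it to its domain.
#'
#' @param mature Mature protein string (signal peptide removed).
#' @param seg Segmentation of the *full* protein (see [segment_protein()]);
#'   spans are shifted internally onto mature coordinates.
#' @return A `hmwgs_cysmap` tibble with columns `position` (1-based mature
#'   coordinate, strictly increasing) and `region`
#'   (nterm/repetitive/cterm). Use [glance()] for the per-region counts.
#' @export
map_cysteines <- function(mature, seg) {
  mature <- check_protein(mature, "mature")
  spans <- mature_spans(seg)
  if (max(spans$end) != nchar(mature)) {
    abort("segmentation is not consistent with the mature protein (was the signal removed?)")
  }
  pos <- which(seq_chars(mature) == "C")
  region <- vapply(pos, function(p) {
    spans$domain[spans$start <= p & p <= spans$end][1]
  }, character(1))
  structure(tibble(position = as.integer(pos), region = region),
            class = c("hmwgs_cysmap", class(tibble())))
}

#' @export
glance.hmwgs_cysmap <- function(x, ...) {
  tibble(
    nterm = sum(x$region == "nterm"),
    repetitive = sum(x$region == "repetitive"),
    cterm = sum(x$region == "cterm"),
    total = nrow(x)
  )
}

#' Glutamine content
#'
#' @param seq Character vector of amino-acid sequences.
#' @return A tibble with one row per sequence: `count` of Q residues and
#'   `fraction` (count / length).
#' @export
#' @examples
#' glutamine_content("PGQGQQ") # 3 Q, fraction 0.5
glutamine_content <- function(seq) {
  rows <- purrr::map(seq, function(s) {
    s <- check_protein(s)
    q <- stringr::str_count(s, stringr::fixed("Q"))
    tibble(count = q, fraction = q / nchar(s))
  })
  bind_rows(rows)
}

#' Average molecular mass of a peptide
#'
#' Sum of average (not monoisotopic) residue masses plus one water
#' (18.0153 Da). Average masses are the appropriate scale for linear-mode
#' MALDI-TOF measurements of intact HMW-GS proteins. The residue mass table
#' is the Expasy ProtParam set.
#'
#' @param seq Character vector of amino-acid sequences over the standard
#'   20-letter alphabet. The empty string returns the mass of water.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' average_mass("G") # about 75.07
average_mass <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s)) return(NA_real_)
    if (!nzchar(s)) return(WATER_MASS)
    s <- check_protein(s)
    sum(AA_RESIDUE_MASS[seq_chars(s)]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Concordance between deduced and observed masses
#'
#' @param deduced Sequence-deduced average masses (Da).
#' @param observed MALDI-TOF observed masses (Da).
#' @param threshold_pct Relative difference (percent of the observed mass)
#'   below which the pair is called consistent. Default 0.5%.
#' @return A tibble: `deduced_da`, `observed_da`, `delta_da`
#'   (deduced - observed), `delta_pct`, `consistent`.
#' @export
#' @examples
#' mass_concordance(70165, 69985) # delta 180 Da
mass_concordance <- function(deduced, observed, threshold_pct = 0.5) {
  stopifnot(all(deduced > 0, na.rm = TRUE), all(observed > 0, na.rm = TRUE))
  delta <- deduced - observed
  pct <- 100 * delta / observed
  tibble(
    deduced_da = deduced, observed_da = observed,
    delta_da = delta, delta_pct = pct,
    consistent = abs(pct) <= threshold_pct
  )
}

#' Summarize an 8-state secondary-structure string per domain
#'
#' Consumes an externally predicted 8-state string (one letter per mature
#' residue, alphabet H/G/I/E/B/T/S/C) and reports, per state: the residue
#' fraction of the whole mature protein ("content") and the number of maximal
#' runs ("no."), both overall and within the N-terminal, central repetitive
#' and C-terminal domains. A run spanning a domain boundary contributes 0.5
#' to each side, so per-domain run counts sum to the overall count.
#'
#' @param ss 8-state secondary-structure string, same length as the mature
#'   protein.
#' @param seg Segmentation of the full protein (shifted internally).
#' @return A tibble in long form: `state`, `region` (overall/nterm/
#'   repetitive/cterm), `n_residues`, `pct` (percent of all mature residues),
#'   `n_runs`.
#' @export
summarize_ss8 <- function(ss, seg) {
  ss <- toupper(ss)
  bad <- regexpr(paste0("[^", paste(SS8_STATES, collapse = ""), "]"), ss)
  if (bad > 0) abort(sprintf("invalid secondary-structure state '%s' at position %d",
                             substr(ss, bad, bad), bad))
  spans <- mature_spans(seg)
  len <- sum(spans$end - spans$start + 1L)
  if (nchar(ss) != len) {
    abort(sprintf("secondary-structure string length (%d) does not match the mature protein (%d)",
                  nchar(ss), len))
  }
  chars <- seq_chars(ss)
  runs <- rle(chars)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  region_of <- function(p) spans$domain[spans$start <= p & p <= spans$end][1]

  regions <- c("overall", spans$domain)
  rows <- list()
  for (st in SS8_STATES) {
    in_state <- chars == st
    run_sel <- runs$values == st
    for (rg in regions) {
      if (rg == "overall") {
        n_res <- sum(in_state)
        n_runs <- sum(run_sel)
      } else {
        span <- spans[spans$domain == rg, ]
        idx <- seq(span$start, span$end)
        n_res <- sum(in_state[idx])
        starts_in <- vapply(run_start[run_sel], region_of, character(1)) == rg
        ends_in <- vapply(run_end[run_sel], region_of, character(1)) == rg
        n_runs <- (sum(starts_in) + sum(ends_in)) / 2
      }
      rows[[length(rows) + 1L]] <- tibble(
        state = st, region = rg, n_residues = n_res,
        pct = 100 * n_res / len, n_runs = n_runs
      )
    }
  }
  bind_rows(rows)
}
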