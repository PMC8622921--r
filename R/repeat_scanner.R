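# repeat_scanner: locate and frame the tripeptide-repeat coding tract.
#
# AFGP coding regions are imperfect tandem repeats of a 9-nt unit encoding
# [Thr/Arg/Lys]-[Ala/Pro]-Ala.  The scanner tiles the CDS into 9-nt units at
# every phase offset (0..8 nt) — the tract defines its own codon register,
# which need not agree with the annotated reading frame (frameshift
# pseudogenes break the register upstream of an intact tract) — classifies
# every unit, and returns the highest-scoring contiguous run of units whose
# fraction of unclassifiable (OTHER) units stays within tolerance.  Whether
# the tract register agrees with the gene's reading frame is judged
# downstream by the classifier.

UNIT_CLASSES <- c("TAA", "TPA", "RAA", "KAA", "OTHER")
REPEAT_CLASSES <- c("TAA", "TPA")   # Thr-led units: one glycosylated Thr each
SPACER_CLASSES <- c("RAA", "KAA")   # Arg/Lys-led units: cleavage linkers

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons become `*` (no trimming); codons
#' containing `N` translate to `X`.
#'
#' @param cds DNA string whose length is a multiple of 3.
#' @return amino-acid string.
#' @export
#' @examples
#' translate_cds("ACAGCAGCA")  # "TAA" = Thr-Ala-Ala
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("CDS length %d is not divisible by 3", nchar(cds)),
         call. = FALSE)
  }
  paste(translate_codons(split_codons(toupper(cds))), collapse = "")
}

#' Classify a tripeptide unit by its residues
#'
#' Thr-led units with Ala/Pro at position 2 and Ala at position 3 are the
#' glycosylated repeats (`TAA`, `TPA`); Arg/Lys-Ala-Ala units are the spacer
#' / cleavage units (`RAA`, `KAA`); anything else is `OTHER`.
#'
#' @param residues character vector of 3-letter amino-acid strings.
#' @return character vector drawn from
#'   `c("TAA", "TPA", "RAA", "KAA", "OTHER")`.
#' @export
#' @examples
#' classify_unit(c("TAA", "TPA", "RAA", "KAA", "GAA"))
classify_unit <- function(residues) {
  stopifnot(all(nchar(residues) == 3L | is.na(residues)))
  p1 <- substr(residues, 1, 1)
  p2 <- substr(residues, 2, 2)
  p3 <- substr(residues, 3, 3)
  out <- rep("OTHER", length(residues))
  thr <- p1 == "T" & p2 %in% c("A", "P") & p3 == "A"
  spc <- p1 %in% c("R", "K") & p2 == "A" & p3 == "A"
  out[thr] <- paste0("T", p2[thr], "A")
  out[spc] <- paste0(p1[spc], "AA")
  out
}

# Tile the CDS into 9-nt units starting at nt offset `phase` (0..8).
# Returns a tibble of all complete units at that phase.
tile_units <- function(cds, phase) {
  n <- nchar(cds)
  m <- (n - phase) %/% 9L
  if (m <= 0L) {
    return(tibble(index = integer(0), codons = character(0),
                  residues = character(0), class = character(0)))
  }
  starts <- phase + 9L * (seq_len(m) - 1L)
  codons9 <- substring(cds, starts + 1L, starts + 9L)
  cod_starts <- phase + 3L * (seq_len(3L * m) - 1L)
  aa <- translate_codons(substring(cds, cod_starts + 1L, cod_starts + 3L))
  res <- paste0(aa[seq(1L, 3L * m, by = 3L)],
                aa[seq(2L, 3L * m, by = 3L)],
                aa[seq(3L, 3L * m, by = 3L)])
  tibble(index = seq_len(m) - 1L, codons = codons9, residues = res,
         class = classify_unit(res))
}

empty_repeat_region <- function() {
  structure(
    list(cds_offset_start = NA_integer_, cds_offset_end = NA_integer_,
         frame = NA_integer_,
         units = tibble(index = integer(0), codons = character(0),
                        residues = character(0), class = character(0)),
         n_units = 0L, n_repeat_units = 0L, n_spacer_units = 0L),
    class = "repeat_region")
}

#' Is a repeat region empty?
#' @param region a `repeat_region`.
#' @return logical.
#' @export
is_empty_region <- function(region) {
  stopifnot(inherits(region, "repeat_region"))
  region$n_units == 0L
}

# Best run of consecutive units at one phase: maximise the number of
# non-OTHER units subject to (i) at least `min_units` units, (ii) fraction of
# OTHER units <= max_other_frac, (iii) non-OTHER units at both ends (leading/
# trailing OTHER trimmed).  Returns list(i, j, score) in unit indices
# (1-based, inclusive) or NULL.
best_run <- function(is_other, min_units, max_other_frac) {
  m <- length(is_other)
  if (m < min_units) return(NULL)
  cum <- c(0L, cumsum(is_other))
  good <- which(!is_other)
  if (length(good) == 0L) return(NULL)
  best <- NULL
  for (i in good) {
    j <- good[good >= i]                        # candidate run ends
    len <- j - i + 1L
    oth <- cum[j + 1L] - cum[i]
    ok <- len >= min_units & oth <= max_other_frac * len
    if (!any(ok)) next
    score <- len[ok] - oth[ok]
    # prefer higher score, then longer run (ties within a start position)
    k <- which(score == max(score))
    k <- k[length(k)]                           # longest among equal scores
    cand <- list(i = i, j = j[ok][k], score = score[k])
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Locate the tripeptide-repeat tract in a CDS
#'
#' Scans every 9-nt tiling phase (the tract defines its own codon register,
#' which an upstream frameshift may decouple from the annotated reading
#' frame) and every unit start, and returns
#' the highest-scoring run of consecutive 9-nt units whose OTHER fraction is
#' at most `max_other_frac` and whose length is at least `min_units`.  The
#' score is the number of classifiable (non-OTHER) units; leading and
#' trailing OTHER units are trimmed.  Ties are broken by leftmost start, then
#' by longest run.
#'
#' @param cds DNA string (coding orientation).
#' @param min_units minimum run length in units.
#' @param max_other_frac maximum tolerated fraction of OTHER units within the
#'   run.  The tract is "imperfect" in real genes; 0.1 is a pragmatic default.
#' @return a `repeat_region`: list with `cds_offset_start`/`cds_offset_end`
#'   (0-based half-open nt offsets into the CDS), `frame` (phase offset in
#'   nt), `units` (tibble: `index`, `codons`, `residues`, `class`),
#'   `n_units`, `n_repeat_units` (Thr-led), `n_spacer_units` (Arg/Lys-led).
#'   An empty region (no qualifying run) has `n_units == 0`.
#' @export
#' @examples
#' cds <- strrep("ACACCAGCA", 12)
#' find_repeat_region(cds)$n_repeat_units
find_repeat_region <- function(cds, min_units = 4L, max_other_frac = 0.1) {
  cds <- toupper(cds)
  check_dna(cds, "CDS")
  best <- NULL
  for (phase in 0L:8L) {
    units <- tile_units(cds, phase)
    if (nrow(units) == 0L) next
    run <- best_run(units$class == "OTHER", min_units, max_other_frac)
    if (is.null(run)) next
    start_nt <- phase + 9L * (run$i - 1L)
    cand <- list(phase = phase, i = run$i, j = run$j, score = run$score,
                 start_nt = start_nt, units = units)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$start_nt < best$start_nt) ||
        (cand$score == best$score && cand$start_nt == best$start_nt &&
         (cand$j - cand$i) > (best$j - best$i))) {
      best <- cand
    }
  }
  if (is.null(best)) return(empty_repeat_region())
  u <- best$units[best$i:best$j, , drop = FALSE]
  u$index <- seq_len(nrow(u)) - 1L
  structure(
    list(cds_offset_start = best$start_nt,
         cds_offset_end = best$start_nt + 9L * nrow(u),
         frame = best$phase,
         units = u,
         n_units = nrow(u),
         n_repeat_units = sum(u$class %in% REPEAT_CLASSES),
         n_spacer_units = sum(u$class %in% SPACER_CLASSES)),
    class = "repeat_region")
}

#' @export
print.repeat_region <- function(x, ...) {
  if (is_empty_region(x)) {
    cat("<repeat_region> empty (no qualifying run)\n")
  } else {
    cat(sprintf(
      "<repeat_region> CDS offsets [%d, %d), %d units (%d repeat, %d spacer, %d other)\n",
      x$cds_offset_start, x$cds_offset_end, x$n_units, x$n_repeat_units,
      x$n_spacer_units, x$n_units - x$n_repeat_units - x$n_spacer_units))
  }
  invisible(x)
}

#' Per-unit table of a repeat region
#'
#' Flat tibble view (one row per unit, codons split out) suitable for TSV
#' export.
#'
#' @param region a `repeat_region`.
#' @param gene_id optional id column value.
#' @return tibble with columns `gene`, `index`, `codon1..3`, `residues`,
#'   `class`.
#' @export
unit_table <- function(region, gene_id = NA_character_) {
  stopifnot(inherits(region, "repeat_region"))
  u <- region$units
  tibble(gene = rep(gene_id, nrow(u)), index = u$index,
         codon1 = substr(u$codons, 1, 3), codon2 = substr(u$codons, 4, 6),
         codon3 = substr(u$codons, 7, 9),
         residues = u$residues, class = u$class)
}
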