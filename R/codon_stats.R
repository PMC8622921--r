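# codon_stats: per-position codon usage across the tripeptide repeats,
# bias flags, and a usage-pattern distance between genes.

#' Codon counts and frequencies at tripeptide positions 1-3
#'
#' Accumulates, over all units of a repeat region, the codon observed at each
#' of the three residue positions.  Frequencies are conditional on position
#' (they sum to 1 at every position with at least one codon).  OTHER units
#' are excluded by default so that degraded units do not distort the
#' repeat-codon statistics.
#'
#' @param region a `repeat_region` with at least one unit.
#' @param gene_id optional gene id recorded on the table.
#' @param include_other include codons from OTHER-class units.
#' @return a `codon_usage` tibble: `position` (1-3), `codon`, `amino_acid`,
#'   `count`, `freq`; attribute `gene_id`.
#' @export
#' @examples
#' r <- find_repeat_region(strrep("ACAGCAGCA", 10))
#' position_codon_counts(r)
position_codon_counts <- function(region, gene_id = NA_character_,
                                  include_other = FALSE) {
  stopifnot(inherits(region, "repeat_region"))
  u <- region$units
  if (!include_other) u <- u[u$class != "OTHER", , drop = FALSE]
  if (nrow(u) == 0L) {
    stop("empty repeat region: no units to count", call. = FALSE)
  }
  long <- tibble(
    position = rep(1:3, each = nrow(u)),
    codon = c(substr(u$codons, 1, 3), substr(u$codons, 4, 6),
              substr(u$codons, 7, 9)))
  tab <- long |>
    count(.data$position, .data$codon, name = "count") |>
    group_by(.data$position) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup() |>
    mutate(amino_acid = translate_codons(.data$codon)) |>
    select("position", "codon", "amino_acid", "count", "freq") |>
    arrange(.data$position, .data$codon)
  attr(tab, "gene_id") <- gene_id
  class(tab) <- c("codon_usage", class(tab))
  tab
}

# All codons of the standard code for one amino acid.
synonymous_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

#' Flag absent and depleted synonymous codons
#'
#' For every amino acid observed at a position, a synonymous codon with zero
#' occurrences is flagged `absent`, and one used at a frequency (among that
#' amino acid's codons at that position) below `depleted_threshold` is
#' flagged `depleted`.  AFGP repeat tracts characteristically lack ACG (Thr,
#' position 1) and CCC (Pro, position 2) and select against GCT (Ala) and
#' CCT (Pro) at position 2; those patterns surface here as ordinary flags.
#'
#' @param table a [position_codon_counts()] result.
#' @param depleted_threshold synonymous-frequency threshold below which a
#'   used codon is called depleted.
#' @return tibble: `flag`, `position`, `codon`, `amino_acid`, `syn_freq`.
#' @export
codon_bias_flags <- function(table, depleted_threshold = 0.02) {
  stopifnot(inherits(table, "codon_usage"))
  out <- list()
  for (pos in unique(table$position)) {
    sub <- table[table$position == pos, , drop = FALSE]
    for (aa in unique(sub$amino_acid)) {
      syn <- synonymous_codons(aa)
      obs <- sub[sub$amino_acid == aa, , drop = FALSE]
      total <- sum(obs$count)
      for (cod in syn) {
        cnt <- if (cod %in% obs$codon) obs$count[obs$codon == cod] else 0L
        f <- cnt / total
        if (cnt == 0L) {
          out[[length(out) + 1L]] <- tibble(
            flag = "absent", position = pos, codon = cod, amino_acid = aa,
            syn_freq = 0)
        } else if (f < depleted_threshold) {
          out[[length(out) + 1L]] <- tibble(
            flag = "depleted", position = pos, codon = cod, amino_acid = aa,
            syn_freq = f)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(flag = character(0), position = integer(0),
                  codon = character(0), amino_acid = character(0),
                  syn_freq = numeric(0)))
  }
  bind_rows(out) |> arrange(.data$position, .data$amino_acid, .data$codon)
}

#' Total-variation distance between two codon-usage tables
#'
#' Mean, over the three tripeptide positions, of the total-variation distance
#' between the position-conditional codon frequency distributions.  Symmetric,
#' zero iff the frequencies are identical, and bounded by 1 (attained when
#' the codon sets are disjoint at every position).  A position with no data
#' in either table contributes 0; one with data in only one table counts as
#' maximally different.
#'
#' @param a,b [position_codon_counts()] results.
#' @return distance in `[0, 1]`.
#' @export
usage_distance <- function(a, b) {
  stopifnot(inherits(a, "codon_usage"), inherits(b, "codon_usage"))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("usage_distance requires non-empty tables", call. = FALSE)
  }
  tv <- vapply(1:3, function(pos) {
    fa <- a[a$position == pos, c("codon", "freq")]
    fb <- b[b$position == pos, c("codon", "freq")]
    if (nrow(fa) == 0L && nrow(fb) == 0L) return(0)
    if (nrow(fa) == 0L || nrow(fb) == 0L) return(1)
    codons <- union(fa$codon, fb$codon)
    pa <- setNames(rep(0, length(codons)), codons)
    pb <- pa
    pa[fa$codon] <- fa$freq
    pb[fb$codon] <- fb$freq
    sum(abs(pa - pb)) / 2
  }, numeric(1))
  mean(tv)
}

#' Wide per-gene codon usage table
#'
#' Binds several per-gene usage tables into one wide tibble
#' (gene x position:codon frequency), convenient for TSV export and
#' clustering.
#'
#' @param tables list of [position_codon_counts()] results.
#' @return tibble; first column `gene`, remaining columns named
#'   `p<position>_<codon>`.
#' @export
usage_wide <- function(tables) {
  rows <- lapply(tables, function(t) {
    g <- attr(t, "gene_id") %||% NA_character_
    vals <- setNames(t$freq, sprintf("p%d_%s", t$position, t$codon))
    c(list(gene = g), as.list(vals))
  })
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    r[miss] <- 0
    as_tibble(r[cols])
  })
  bind_rows(filled)
}
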