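# gene_models: gene/pseudogene classification, cleavage-site enumeration,
# polyprotein digestion, glycopeptide mass prediction, size binning, and
# family summaries.

#' Average-mass model for glycosylated AFGPs
#'
#' Standard average residue masses (Da), one water per peptide, and one
#' dehydrated galactosyl-N-acetylgalactosamine disaccharide adduct per
#' glycosylated Thr.
#'
#' @param residue_avg_mass named numeric, Da per residue.
#' @param water terminal water, Da.
#' @param disaccharide_adduct glycan mass added per Thr, Da.
#' @return a `mass_model` list.
#' @export
#' @examples
#' m <- mass_model()
#' peptide_mass(strrep("TAA", 4), m)  # smallest isoform, ~2.5 kDa
mass_model <- function(residue_avg_mass = c(T = 101.10, A = 71.08, P = 97.12,
                                            R = 156.19, K = 128.17),
                       water = 18.02,
                       disaccharide_adduct = 365.33) {
  stopifnot(all(residue_avg_mass > 0), water > 0, disaccharide_adduct > 0)
  structure(list(residue_avg_mass = residue_avg_mass, water = water,
                 disaccharide_adduct = disaccharide_adduct),
            class = "mass_model")
}

#' Predicted average mass of a glycosylated peptide
#'
#' `mass = sum(residue masses) + water + n_Thr * disaccharide_adduct`, i.e.
#' every Thr is assumed to carry one O-linked disaccharide.
#'
#' @param residues amino-acid string (e.g. `"TAATAA"`), or a row of the
#'   [digest_polyprotein()] table (its `residues` column is used).
#' @param model a [mass_model()].
#' @return mass in Da.  The empty peptide weighs one water.
#' @export
peptide_mass <- function(residues, model = mass_model()) {
  if (is.list(residues) && !is.null(residues$residues)) {
    residues <- residues$residues
  }
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) return(model$water)
  aa <- strsplit(residues, "")[[1]]
  unknown <- setdiff(aa, names(model$residue_avg_mass))
  if (length(unknown)) {
    stop(sprintf("residue(s) outside the mass model: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sum(model$residue_avg_mass[aa]) + model$water +
    sum(aa == "T") * model$disaccharide_adduct
}

#' Historical AFGP size bin of a predicted isoform
#'
#' AFGP8 and AFGP7 are defined by repeat count (four and five tripeptide
#' repeats); fragments below four repeats are `sub_AFGP`.  Larger products
#' are binned by mass against the historical gel ranges: the AFGP6 group up
#' to the midpoint (9.2 kDa) of the gap between its upper edge (7.9 kDa) and
#' the lower edge of the AFGP1-5 group (10.5 kDa); everything heavier is
#' `AFGP1_5_group`.  Six-repeat products fall slightly below the nominal
#' 4.2 kDa lower edge of the AFGP6 gel range and are assigned to the AFGP6
#' group (the 6-8 repeat ladder is continuous on gels).
#'
#' @param mass_da predicted glycosylated mass, Da (may be `NA` when
#'   `n_repeats` alone decides the bin).
#' @param n_repeats number of Thr-led tripeptide repeats.
#' @return one of `"sub_AFGP"`, `"AFGP8"`, `"AFGP7"`, `"AFGP6_group"`,
#'   `"AFGP1_5_group"`.
#' @export
assign_isoform_bin <- function(mass_da, n_repeats) {
  stopifnot(length(mass_da) == length(n_repeats))
  out <- character(length(n_repeats))
  out[n_repeats < 4L] <- "sub_AFGP"
  out[n_repeats == 4L] <- "AFGP8"
  out[n_repeats == 5L] <- "AFGP7"
  big <- n_repeats >= 6L
  out[big & (is.na(mass_da) | mass_da < 9200)] <- "AFGP6_group"
  out[big & !is.na(mass_da) & mass_da >= 9200] <- "AFGP1_5_group"
  out
}

#' Enumerate polyprotein cleavage sites in a repeat region
#'
#' Trypsin-like proteases cleave at the carboxyl side of Arg and Lys.  Every
#' Lys-Ala-Ala unit yields a `single_Lys` site; an Arg-Ala-Ala unit yields an
#' `RAAR` site when the following unit begins with Arg (the 4-residue
#' Arg-Ala-Ala-Arg motif spans the unit boundary), otherwise a `single_Arg`
#' site.  Overlapping RAAR motifs are resolved leftmost-first: an Arg already
#' consumed as the fourth residue of an RAAR cannot seed another site.
#'
#' @param region a `repeat_region`.
#' @return tibble with columns `unit_index` (0-based), `site_type`
#'   (`single_Arg`/`single_Lys`/`RAAR`), `residue_span` (3 or 4), ordered by
#'   `unit_index`.
#' @export
find_cleavage_sites <- function(region) {
  stopifnot(inherits(region, "repeat_region"))
  u <- region$units
  empty <- tibble(unit_index = integer(0), site_type = character(0),
                  residue_span = integer(0))
  if (nrow(u) == 0L) return(empty)
  p1 <- substr(u$residues, 1, 1)
  rows <- list()
  r_consumed <- logical(nrow(u))
  for (i in seq_len(nrow(u))) {
    if (u$class[i] == "KAA") {
      rows[[length(rows) + 1L]] <-
        list(unit_index = u$index[i], site_type = "single_Lys",
             residue_span = 3L)
    } else if (u$class[i] == "RAA" && !r_consumed[i]) {
      if (i < nrow(u) && p1[i + 1L] == "R") {
        rows[[length(rows) + 1L]] <-
          list(unit_index = u$index[i], site_type = "RAAR",
               residue_span = 4L)
        r_consumed[i + 1L] <- TRUE
      } else {
        rows[[length(rows) + 1L]] <-
          list(unit_index = u$index[i], site_type = "single_Arg",
               residue_span = 3L)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  bind_rows(lapply(rows, as_tibble))
}

#' Exhaustively digest a polyprotein repeat region into mature isoforms
#'
#' Assumes every potential cleavage site is cleaved.  Spacer units (Arg/Lys
#' led) are treated as excised linkers: products are the maximal runs of
#' non-spacer units between them, and a product's repeat count is its number
#' of Thr-led units.  Products with at least one repeat are reported;
#' all-OTHER fragments are counted in the unit accounting but not listed.
#' Unit conservation (`product units + linker units + dropped units = total`)
#' is recorded in the `unit_accounting` attribute and checked on every call.
#'
#' @param region a `repeat_region`.
#' @param sites cleavage sites from [find_cleavage_sites()]; recomputed when
#'   missing.
#' @param model [mass_model()] used for `mass_da`.
#' @param gene_id optional source gene id.
#' @param retain_linkers keep spacer units attached to the upstream product
#'   (cut-only mode) instead of excising them.  The default (excision)
#'   reproduces the repeat arithmetic of purified isoforms, in which Lys is
#'   essentially absent.
#' @return tibble with one row per mature isoform: `gene`, `ordinal`,
#'   `n_units`, `n_repeats`, `n_thr`, `n_T`, `n_A`, `n_P`, `residues`,
#'   `mass_da` (NA when a residue falls outside the mass model), `size_bin`.
#' @export
digest_polyprotein <- function(region, sites = NULL, model = mass_model(),
                               gene_id = NA_character_,
                               retain_linkers = FALSE) {
  stopifnot(inherits(region, "repeat_region"))
  u <- region$units
  if (is.null(sites)) sites <- find_cleavage_sites(region)
  empty <- tibble(gene = character(0), ordinal = integer(0),
                  n_units = integer(0), n_repeats = integer(0),
                  n_thr = integer(0), n_T = integer(0), n_A = integer(0),
                  n_P = integer(0), residues = character(0),
                  mass_da = numeric(0), size_bin = character(0))
  if (nrow(u) == 0L) {
    attr(empty, "unit_accounting") <-
      list(product_units = 0L, linker_units = 0L, dropped_units = 0L,
           total_units = 0L)
    return(empty)
  }
  is_linker <- u$class %in% SPACER_CLASSES
  if (retain_linkers) {
    # cut after each linker unit; linkers stay on the upstream product
    grp <- cumsum(c(0L, head(is_linker, -1L)))
  } else {
    grp <- cumsum(is_linker)
    grp[is_linker] <- NA_integer_    # excised
  }
  keep <- !is.na(grp)
  prods <- split(which(keep), grp[keep])
  rows <- lapply(prods, function(idx) {
    res <- paste(u$residues[idx], collapse = "")
    n_rep <- sum(u$class[idx] %in% REPEAT_CLASSES)
    aa <- strsplit(res, "")[[1]]
    mass <- tryCatch(peptide_mass(res, model), error = function(e) NA_real_)
    tibble(gene = gene_id, ordinal = NA_integer_,
           n_units = length(idx), n_repeats = n_rep,
           n_thr = sum(aa == "T"),
           n_T = sum(aa == "T"), n_A = sum(aa == "A"), n_P = sum(aa == "P"),
           residues = res, mass_da = mass,
           size_bin = assign_isoform_bin(mass, n_rep))
  })
  out <- bind_rows(rows)
  dropped_units <- 0L
  if (nrow(out) > 0L) {
    out <- out[order(vapply(prods, min, 0L)), , drop = FALSE]
    reported <- out$n_repeats >= 1L
    dropped_units <- sum(out$n_units[!reported])
    out <- out[reported, , drop = FALSE]
    out$ordinal <- seq_len(nrow(out))
  }
  if (nrow(out) == 0L) out <- empty
  acct <- list(product_units = sum(out$n_units),
               linker_units = if (retain_linkers) 0L else sum(is_linker),
               dropped_units = dropped_units,
               total_units = nrow(u))
  if (acct$product_units + acct$linker_units + acct$dropped_units !=
      acct$total_units) {
    stop("internal error: digestion does not conserve units", call. = FALSE)
  }
  attr(out, "unit_accounting") <- acct
  out
}

#' Classify a gene record as functional, pseudogene, or non-AFGP
#'
#' A record is functional when an uninterrupted reading frame runs from a
#' start codon, through an intact 5' non-repetitive coding segment of at
#' least `min_leader_nt`, across the whole repeat region, to a stop codon
#' downstream of it.  Otherwise the lesion is named:
#'
#' * `coding_insertion` — a second qualifying repeat run lies at least
#'   `insertion_min_nt` away from the main one (a long tract interrupting the
#'   CDS, as in 6.5-kbp insertion pseudogenes);
#' * `five_prime_truncated` — no start codon with a sufficient leader exists
#'   upstream of the repeats;
#' * `frameshift_indel` — a start codon exists but the frame is broken (the
#'   repeats are out of register with it) or a premature stop intervenes.
#'
#' Records whose CDS contains no repeat region at all are reported as
#' `non_AFGP` rather than as an error.
#'
#' @param record a [gene_record()].
#' @param region the [find_repeat_region()] result for the record's CDS;
#'   recomputed when missing.
#' @param min_leader_nt minimum length (nt) of the non-repetitive coding
#'   segment between the start codon and the repeat tract.
#' @param insertion_min_nt minimum length (nt) of an interrupting tract to
#'   call `coding_insertion`.
#' @param min_units,max_other_frac scanner settings used when `region` must
#'   be recomputed and for the secondary (insertion) scan.
#' @return list with `status` (`functional` / `pseudogene` / `non_AFGP`),
#'   `pseudogene_reason`, and `orf_start` (0-based CDS offset of the
#'   supporting start codon, or `NA`).
#' @export
classify_gene <- function(record, region = NULL, min_leader_nt = 30L,
                          insertion_min_nt = 500L,
                          min_units = 4L, max_other_frac = 0.1) {
  stopifnot(inherits(record, "gene_record"))
  cds <- extract_cds(record)
  if (is.null(region)) {
    region <- find_repeat_region(cds, min_units, max_other_frac)
  }
  if (is_empty_region(region)) {
    return(list(status = "non_AFGP", pseudogene_reason = "none",
                orf_start = NA_integer_))
  }
  rs <- region$cds_offset_start
  re <- region$cds_offset_end

  # (1) long interrupting tract: mask the main region and rescan
  masked <- paste0(substr(cds, 1L, rs),
                   strrep("N", re - rs),
                   substr(cds, re + 1L, nchar(cds)))
  second <- find_repeat_region(masked, min_units, max_other_frac)
  if (!is_empty_region(second)) {
    gap <- if (second$cds_offset_start >= re) second$cds_offset_start - re
           else rs - second$cds_offset_end
    if (gap >= insertion_min_nt) {
      return(list(status = "pseudogene",
                  pseudogene_reason = "coding_insertion",
                  orf_start = NA_integer_))
    }
  }

  # (2) start codons upstream of the repeats with a sufficient leader
  upstream <- substr(cds, 1L, rs)
  atg <- gregexpr("ATG", upstream, fixed = TRUE)[[1]]
  atg <- atg[atg > 0L] - 1L                       # 0-based offsets
  atg <- atg[rs - atg >= min_leader_nt]
  if (length(atg) == 0L) {
    return(list(status = "pseudogene",
                pseudogene_reason = "five_prime_truncated",
                orf_start = NA_integer_))
  }
  in_frame <- atg[(rs - atg) %% 3L == 0L]
  for (s in in_frame) {
    span_end <- s + 3L * ((re - s) %/% 3L)
    aa <- translate_cds(substr(cds, s + 1L, span_end))
    if (grepl("*", aa, fixed = TRUE)) next       # premature stop
    # require an in-frame stop codon downstream of the repeat region
    tail_start <- span_end
    tail_len <- 3L * ((nchar(cds) - tail_start) %/% 3L)
    if (tail_len <= 0L) next
    tail_aa <- translate_cds(substr(cds, tail_start + 1L,
                                    tail_start + tail_len))
    if (!grepl("*", tail_aa, fixed = TRUE)) next
    return(list(status = "functional", pseudogene_reason = "none",
                orf_start = as.integer(s)))
  }
  list(status = "pseudogene", pseudogene_reason = "frameshift_indel",
       orf_start = NA_integer_)
}

#' Summarise an analysed gene family per species
#'
#' @param results a list of per-gene results as produced by
#'   [process_gene()] (each has `record`, `region`, `classification`,
#'   `isoforms`).
#' @return tibble with one row per species: gene counts, pseudogene counts
#'   by reason, isoform totals, repeat-count range over predicted isoforms,
#'   and the amino-acid composition (percent) of Thr/Ala/Pro/Arg/Lys over
#'   repeat-region translations.  Zero genes give zero rows.
#' @export
family_summary <- function(results) {
  if (length(results) == 0L) {
    return(tibble(species = character(0), n_genes = integer(0),
                  n_functional = integer(0), n_pseudogenes = integer(0),
                  n_five_prime_truncated = integer(0),
                  n_frameshift_indel = integer(0),
                  n_coding_insertion = integer(0), n_non_afgp = integer(0),
                  n_isoforms = integer(0),
                  repeats_min = integer(0), repeats_max = integer(0),
                  pct_T = numeric(0), pct_A = numeric(0), pct_P = numeric(0),
                  pct_R = numeric(0), pct_K = numeric(0)))
  }
  per_gene <- lapply(results, function(r) {
    tibble(species = r$record$species,
           status = r$classification$status,
           reason = r$classification$pseudogene_reason,
           n_isoforms = nrow(r$isoforms),
           repeats_min = if (nrow(r$isoforms)) min(r$isoforms$n_repeats) else NA_integer_,
           repeats_max = if (nrow(r$isoforms)) max(r$isoforms$n_repeats) else NA_integer_,
           residues = paste(r$region$units$residues, collapse = ""))
  })
  d <- bind_rows(per_gene)
  res <- lapply(split(d, d$species), function(g) {
    aa <- strsplit(paste(g$residues, collapse = ""), "")[[1]]
    n_aa <- max(length(aa), 1L)
    tibble(species = g$species[1],
           n_genes = nrow(g),
           n_functional = sum(g$status == "functional"),
           n_pseudogenes = sum(g$status == "pseudogene"),
           n_five_prime_truncated = sum(g$reason == "five_prime_truncated"),
           n_frameshift_indel = sum(g$reason == "frameshift_indel"),
           n_coding_insertion = sum(g$reason == "coding_insertion"),
           n_non_afgp = sum(g$status == "non_AFGP"),
           n_isoforms = sum(g$n_isoforms),
           repeats_min = if (all(is.na(g$repeats_min))) NA_integer_
                         else min(g$repeats_min, na.rm = TRUE),
           repeats_max = if (all(is.na(g$repeats_max))) NA_integer_
                         else max(g$repeats_max, na.rm = TRUE),
           pct_T = 100 * sum(aa == "T") / n_aa,
           pct_A = 100 * sum(aa == "A") / n_aa,
           pct_P = 100 * sum(aa == "P") / n_aa,
           pct_R = 100 * sum(aa == "R") / n_aa,
           pct_K = 100 * sum(aa == "K") / n_aa)
  })
  out <- bind_rows(res)
  out[order(out$species), , drop = FALSE]
}

#' Run the full per-gene analysis
#'
#' Scan, classify, enumerate cleavage sites, digest, and tabulate codon
#' usage for one record.
#'
#' @param record a [gene_record()].
#' @param min_units,max_other_frac scanner settings.
#' @param min_leader_nt,insertion_min_nt classifier settings.
#' @param model [mass_model()].
#' @return list with `record`, `cds`, `region`, `classification`, `sites`,
#'   `isoforms`, `codon_usage`.
#' @export
process_gene <- function(record, min_units = 4L, max_other_frac = 0.1,
                         min_leader_nt = 30L, insertion_min_nt = 500L,
                         model = mass_model()) {
  cds <- extract_cds(record)
  region <- find_repeat_region(cds, min_units, max_other_frac)
  cls <- classify_gene(record, region, min_leader_nt, insertion_min_nt,
                       min_units, max_other_frac)
  sites <- find_cleavage_sites(region)
  isoforms <- digest_polyprotein(region, sites, model, gene_id = record$id)
  usage <- if (is_empty_region(region)) NULL else
    position_codon_counts(region, gene_id = record$id)
  list(record = record, cds = cds, region = region, classification = cls,
       sites = sites, isoforms = isoforms, codon_usage = usage)
}
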