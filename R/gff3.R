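# GFF3 output for gene, CDS, repeat-region, tripeptide-unit and
# cleavage-site annotations.  The writer and reader are deliberately plain:
# nine tab-separated columns, attributes in a fixed builder-determined order,
# so that a write -> read -> write cycle is byte-identical.

GFF3_COLS <- c("seqid", "source", "type", "start", "end",
               "score", "strand", "phase", "attributes")

# Map a 0-based half-open CDS-offset interval to 0-based half-open genomic
# coordinates on the record's forward axis.
cds_to_genomic <- function(record, off_start, off_end) {
  if (record$strand == "+") {
    c(record$cds_start + off_start, record$cds_start + off_end)
  } else {
    c(record$cds_end - off_end, record$cds_end - off_start)
  }
}

#' Build a GFF3 feature table for an annotated gene record
#'
#' Assembles `gene`, `CDS`, `repeat_region`, optional `tripeptide_unit`, and
#' `cleavage_site` features in internal 0-based half-open coordinates on the
#' record's forward axis.  Pass the result to [write_gff3()].
#'
#' @param record a [gene_record()].
#' @param region the [find_repeat_region()] result for the record's CDS; an
#'   unannotated record (missing region) is an error.
#' @param sites optional [find_cleavage_sites()] tibble.
#' @param include_units emit one `tripeptide_unit` feature per unit.
#' @param source value for the GFF3 source column.
#' @return tibble with columns `r GFF3_COLS` (coordinates 0-based half-open).
#' @export
gff3_features <- function(record, region, sites = NULL,
                          include_units = FALSE, source = "afgpkit") {
  stopifnot(inherits(record, "gene_record"))
  if (missing(region) || is.null(region)) {
    stop(sprintf("record '%s' is unannotated: a repeat region is required",
                 record$id), call. = FALSE)
  }
  rows <- list(
    tibble(seqid = record$id, source = source, type = "gene",
           start = 0L, end = nchar(record$seq), score = ".",
           strand = record$strand, phase = ".",
           attributes = sprintf("ID=%s;status=%s;pseudogene_reason=%s",
                                record$id, record$status,
                                record$pseudogene_reason)),
    tibble(seqid = record$id, source = source, type = "CDS",
           start = record$cds_start, end = record$cds_end, score = ".",
           strand = record$strand, phase = "0",
           attributes = sprintf("ID=%s.cds;Parent=%s", record$id, record$id)))
  if (!is_empty_region(region)) {
    g <- cds_to_genomic(record, region$cds_offset_start, region$cds_offset_end)
    rows <- c(rows, list(
      tibble(seqid = record$id, source = source, type = "repeat_region",
             start = g[1], end = g[2], score = ".",
             strand = record$strand, phase = ".",
             attributes = sprintf(
               "ID=%s.repeats;Parent=%s.cds;n_units=%d;n_repeat_units=%d;n_spacer_units=%d",
               record$id, record$id, region$n_units,
               region$n_repeat_units, region$n_spacer_units))))
    if (include_units && region$n_units > 0) {
      u <- region$units
      off0 <- region$cds_offset_start + 9L * u$index
      gs <- t(vapply(seq_len(nrow(u)), function(i)
        cds_to_genomic(record, off0[i], off0[i] + 9L), numeric(2)))
      rows <- c(rows, list(
        tibble(seqid = record$id, source = source, type = "tripeptide_unit",
               start = as.integer(gs[, 1]), end = as.integer(gs[, 2]),
               score = ".", strand = record$strand, phase = ".",
               attributes = sprintf(
                 "ID=%s.unit%03d;Parent=%s.repeats;residues=%s;class=%s",
                 record$id, u$index, record$id, u$residues, u$class))))
    }
    if (!is.null(sites) && nrow(sites) > 0) {
      off0 <- region$cds_offset_start + 9L * sites$unit_index
      span_nt <- 3L * sites$residue_span
      gs <- t(vapply(seq_len(nrow(sites)), function(i)
        cds_to_genomic(record, off0[i], off0[i] + span_nt[i]), numeric(2)))
      rows <- c(rows, list(
        tibble(seqid = record$id, source = source, type = "cleavage_site",
               start = as.integer(gs[, 1]), end = as.integer(gs[, 2]),
               score = ".", strand = record$strand, phase = ".",
               attributes = sprintf(
                 "ID=%s.site%03d;Parent=%s.repeats;site_type=%s;unit_index=%d",
                 record$id, sites$unit_index, record$id, sites$site_type,
                 sites$unit_index))))
    }
  }
  bind_rows(rows)
}

#' Write a feature table as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive coordinates the format requires.  Feature order and attribute
#' order are emitted as given, so canonical input round-trips byte-identically
#' through [read_gff3()].
#'
#' @param features tibble as produced by [gff3_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(all(GFF3_COLS %in% names(features)))
  out <- features
  out$start <- out$start + 1L          # 0-based half-open -> 1-based inclusive
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     out$seqid, out$source, out$type, out$start, out$end,
                     out$score, out$strand, out$phase, out$attributes))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 file.
#' @return tibble with columns `r GFF3_COLS`, coordinates converted back to
#'   0-based half-open.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(seqid = character(0), source = character(0),
                  type = character(0), start = integer(0), end = integer(0),
                  score = character(0), strand = character(0),
                  phase = character(0), attributes = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) {
    stop(sprintf("GFF3 parse error in '%s': line %d does not have 9 columns",
                 path, bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  tibble(seqid = m[, 1], source = m[, 2], type = m[, 3],
         start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
         score = m[, 6], strand = m[, 7], phase = m[, 8],
         attributes = m[, 9])
}
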