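# seqio: the core gene record model plus FASTA input/output.
#
# Coordinate convention: all internal coordinates are 0-based, half-open
# ([start, end) offsets into the record sequence).  Emitted GFF3 is 1-based
# inclusive, per the format.

#' Construct a gene record
#'
#' A `gene_record` holds one AFGP gene or pseudogene: its full sequence
#' (flanks included), the CDS coordinates within it, strand, and its
#' functional status.  Minus-strand records keep `seq` as supplied; CDS
#' extraction reverse-complements so downstream stages always see the coding
#' strand.
#'
#' @param id unique gene identifier; by convention `species_gene`
#'   (e.g. `"Bs_AFGP4"`).
#' @param seq DNA string, A/C/G/T/N (lowercase accepted, uppercased).
#' @param cds_start,cds_end 0-based half-open CDS offsets into `seq`.
#' @param strand `"+"` or `"-"`.
#' @param species species tag; defaults to the part of `id` before the first
#'   underscore.
#' @param status `"functional"` or `"pseudogene"`.
#' @param pseudogene_reason one of `"none"`, `"five_prime_truncated"`,
#'   `"frameshift_indel"`, `"coding_insertion"`.  Must be `"none"` when
#'   `status` is `"functional"`.
#' @return an object of class `gene_record`: a list with fields `id`,
#'   `species`, `seq`, `cds_start`, `cds_end`, `strand`, `flank5`, `flank3`,
#'   `status`, `pseudogene_reason`.
#' @export
#' @examples
#' g <- gene_record("sp_g1", "AAACGTTT", cds_start = 3, cds_end = 6)
#' extract_cds(g)
gene_record <- function(id, seq, cds_start, cds_end, strand = "+",
                        species = NULL,
                        status = "functional",
                        pseudogene_reason = "none") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  check_dna(seq, sprintf("sequence of '%s'", id))
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!(cds_start >= 0L && cds_start < cds_end && cds_end <= nchar(seq))) {
    stop(sprintf("invalid CDS coordinates [%d, %d) for '%s' (sequence length %d)",
                 cds_start, cds_end, id, nchar(seq)), call. = FALSE)
  }
  strand <- match.arg(strand, c("+", "-"))
  status <- match.arg(status, c("functional", "pseudogene"))
  pseudogene_reason <- match.arg(
    pseudogene_reason,
    c("none", "five_prime_truncated", "frameshift_indel", "coding_insertion"))
  if (status == "functional" && pseudogene_reason != "none") {
    stop("a functional record must have pseudogene_reason = 'none'",
         call. = FALSE)
  }
  if (is.null(species)) {
    species <- if (grepl("_", id)) sub("_.*$", "", id) else "unknown"
  }
  # flank5/flank3 are defined on the coding orientation of the record
  up <- substr(seq, 1L, cds_start)
  down <- substr(seq, cds_end + 1L, nchar(seq))
  if (strand == "+") {
    flank5 <- up; flank3 <- down
  } else {
    flank5 <- revcomp_dna(down); flank3 <- revcomp_dna(up)
  }
  structure(
    list(id = id, species = species, seq = seq,
         cds_start = cds_start, cds_end = cds_end, strand = strand,
         flank5 = flank5, flank3 = flank3,
         status = status, pseudogene_reason = pseudogene_reason),
    class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (%s, %s strand)\n", x$id, x$species, x$strand))
  cat(sprintf("  seq %d nt; CDS [%d, %d); status %s%s\n",
              nchar(x$seq), x$cds_start, x$cds_end, x$status,
              if (x$status == "pseudogene")
                paste0(" (", x$pseudogene_reason, ")") else ""))
  invisible(x)
}

#' Extract the coding sequence of a gene record
#'
#' Returns `seq[cds_start, cds_end)`, reverse-complemented for minus-strand
#' records so the result is always in coding orientation.
#'
#' @param record a [gene_record()].
#' @return DNA string.
#' @export
extract_cds <- function(record) {
  stopifnot(inherits(record, "gene_record"))
  s <- substr(record$seq, record$cds_start + 1L, record$cds_end)
  if (record$strand == "-") s <- revcomp_dna(s)
  s
}

# Light line-level syntax check so parse errors can name the offending line;
# the actual parsing is delegated to Biostrings.
validate_fasta_lines <- function(lines, path) {
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(invisible(TRUE))  # empty file: 0 records
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA parse error in '%s': line %d does not start with '>'",
                 path, nonblank[1]), call. = FALSE)
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    if (!nzchar(trimws(sub("^>", "", trimws(lines[h]))))) {
      stop(sprintf("FASTA parse error in '%s': empty header at line %d",
                   path, h), call. = FALSE)
    }
    nxt <- h + 1L
    has_seq <- nxt <= length(lines) && !startsWith(trimws(lines[nxt]), ">") &&
      nzchar(trimws(lines[nxt]))
    if (!has_seq) {
      stop(sprintf("FASTA parse error in '%s': record at line %d has an empty sequence",
                   path, h), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Order is preserved, sequences are uppercased, duplicate identifiers and
#' letters outside A/C/G/T/N are rejected (the repeat scanner is codon-exact,
#' so ambiguity codes other than N are refused at the door).  Identifiers are
#' the header text up to the first whitespace.
#'
#' @param path FASTA file.
#' @return a tibble with columns `id`, `seq`; zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  validate_fasta_lines(readLines(path, warn = FALSE), path)
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, warn = FALSE, n = 1L)) == 0L) {
    return(tibble(id = character(0), seq = character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  check_dna(seqs, "FASTA sequence")
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x a tibble/data.frame with columns `id` and `seq`, a named character
#'   vector, or a list of [gene_record()]s.
#' @param path output file.
#' @param width line wrap width (nt).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.list(x) && length(x) && inherits(x[[1]], "gene_record")) {
    x <- tibble(id = vapply(x, `[[`, "", "id"),
                seq = vapply(x, `[[`, "", "seq"))
  }
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x))
  stopifnot(all(c("id", "seq") %in% names(x)))
  if (anyDuplicated(x$id)) stop("duplicate ids in FASTA output", call. = FALSE)
  ss <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
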