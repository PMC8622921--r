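# pipeline: scan -> classify -> digest -> codon -> tree -> report as one
# reproducible run.  Every artefact is deterministic given (inputs, config);
# the archived config makes a run replayable.

#' Build gene records from a FASTA table and optional coordinate table
#'
#' Without coordinates the whole sequence is treated as CDS (no flanks, so
#' no trees).  The coordinate table uses internal 0-based half-open CDS
#' offsets, as written by [sim_write()].
#'
#' @param fasta tibble from [read_fasta()].
#' @param coords optional tibble/path with columns `id`, `cds_start`,
#'   `cds_end` and optionally `strand`, `species`.
#' @return list of [gene_record()]s.
#' @export
records_from_fasta <- function(fasta, coords = NULL) {
  if (is.character(coords)) {
    coords <- as_tibble(read.delim(coords, sep = "\t",
                                   stringsAsFactors = FALSE))
  }
  lapply(seq_len(nrow(fasta)), function(i) {
    id <- fasta$id[i]; seq <- fasta$seq[i]
    if (!is.null(coords) && id %in% coords$id) {
      row <- coords[coords$id == id, ][1, ]
      gene_record(id, seq, row$cds_start, row$cds_end,
                  strand = row$strand %||% "+",
                  species = row$species %||% NULL)
    } else {
      gene_record(id, seq, 0L, nchar(seq))
    }
  })
}

# Characteristic C-terminus residue signature: translation of the CDS from
# the end of the repeat region to (not including) the first stop codon.
cterm_signature <- function(cds, region) {
  if (is_empty_region(region)) return(NA_character_)
  tail_start <- region$cds_offset_end
  len <- 3L * ((nchar(cds) - tail_start) %/% 3L)
  if (len <= 0L) return("")
  aa <- translate_cds(substr(cds, tail_start + 1L, tail_start + len))
  sub("\\*.*$", "", aa)
}

# 5' analysis segment: flank + non-repetitive coding region up to the start
# of the repeats (UTR + signal/propeptide equivalent).
segment5 <- function(record, region, cds) {
  lead_len <- if (is_empty_region(region)) 0L else region$cds_offset_start
  paste0(record$flank5, substr(cds, 1L, lead_len))
}

# Keep the modal-length subset of a sequence vector (the gap-free tree mode
# requires equal lengths); returns the named subset.
modal_length_subset <- function(seqs) {
  if (length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  tab <- table(lens)
  keep <- lens == as.integer(names(tab)[which.max(tab)])
  seqs[keep]
}

# Exclude pseudogene sequences with <60% identity to every other sequence
# (mirrors the exclusion of dissimilar pseudogene 3' flanks from the 3' tree).
drop_dissimilar <- function(seqs, pseudo_ids, min_identity = 0.6) {
  if (length(seqs) < 3L) return(seqs)
  d <- pairwise_distance(seqs, model = "p")
  diag(d) <- Inf
  dissim <- apply(d, 1, min) > (1 - min_identity)
  keep <- !(names(seqs) %in% pseudo_ids & dissim)
  seqs[keep]
}

#' Run the full AFGP annotation pipeline
#'
#' Executes, in fixed order: repeat scan, gene classification, cleavage-site
#' enumeration and exhaustive digestion, codon-usage tabulation, flank-based
#' tree inference (when flanking sequence is available for at least three
#' genes), ortholog assignment (when two or more species are present), and a
#' machine-readable report.
#'
#' @param fasta path to a FASTA file or a tibble from [read_fasta()].
#' @param out_dir output directory; created if needed.  `NULL` skips all
#'   file output and returns results only.
#' @param coords optional coordinate table or TSV path (see
#'   [records_from_fasta()]).
#' @param min_units,max_other_frac scanner parameters.
#' @param min_leader_nt,insertion_min_nt classifier parameters.
#' @param model [mass_model()].
#' @param distance_model `"JC69"` or `"p"` for flank distances.
#' @param include_units write per-unit `tripeptide_unit` GFF3 features.
#' @return (invisibly) a list: `results` (per-gene [process_gene()] output),
#'   `genes` (summary tibble), `isoforms`, `family` (per-species summary),
#'   `tree5`, `tree3` (possibly `NULL`), `orthologs`, `report`.
#' @export
run_pipeline <- function(fasta, out_dir = NULL, coords = NULL,
                         min_units = 4L, max_other_frac = 0.1,
                         min_leader_nt = 30L, insertion_min_nt = 500L,
                         model = mass_model(), distance_model = "JC69",
                         include_units = FALSE) {
  if (is.character(fasta)) {
    if (!file.exists(fasta)) {
      stop(sprintf("input FASTA not found: '%s'", fasta), call. = FALSE)
    }
    fasta <- read_fasta(fasta)
  }
  stopifnot(all(c("id", "seq") %in% names(fasta)))
  config <- list(min_units = min_units, max_other_frac = max_other_frac,
                 min_leader_nt = min_leader_nt,
                 insertion_min_nt = insertion_min_nt,
                 mass_model = unclass(model),
                 distance_model = distance_model)

  records <- records_from_fasta(fasta, coords)
  results <- lapply(records, function(r)
    tryCatch(
      process_gene(r, min_units, max_other_frac, min_leader_nt,
                   insertion_min_nt, model),
      error = function(e) stop(sprintf("stage scan/classify, gene '%s': %s",
                                       r$id, conditionMessage(e)),
                               call. = FALSE)))
  names(results) <- vapply(records, `[[`, "", "id")

  genes_tbl <- bind_rows(lapply(results, function(r) {
    tibble(id = r$record$id, species = r$record$species,
           status = r$classification$status,
           pseudogene_reason = r$classification$pseudogene_reason,
           region_start = r$region$cds_offset_start,
           region_end = r$region$cds_offset_end,
           n_units = r$region$n_units,
           n_repeat_units = r$region$n_repeat_units,
           n_spacer_units = r$region$n_spacer_units,
           n_sites = nrow(r$sites), n_isoforms = nrow(r$isoforms),
           cterm = cterm_signature(r$cds, r$region))
  }))
  if (nrow(genes_tbl) == 0L) {
    genes_tbl <- tibble(id = character(0), species = character(0),
                        status = character(0),
                        pseudogene_reason = character(0),
                        region_start = integer(0), region_end = integer(0),
                        n_units = integer(0), n_repeat_units = integer(0),
                        n_spacer_units = integer(0), n_sites = integer(0),
                        n_isoforms = integer(0), cterm = character(0))
  }
  isoforms_tbl <- bind_rows(lapply(results, `[[`, "isoforms"))
  family_tbl <- family_summary(results)

  # trees from flanking segments (gap-free equal-length mode)
  tree5 <- tree3 <- NULL
  orthologs <- NULL
  seqs5 <- vapply(results, function(r) segment5(r$record, r$region, r$cds), "")
  seqs3 <- vapply(results, function(r) r$record$flank3, "")
  seqs5 <- modal_length_subset(seqs5[nchar(seqs5) > 0L])
  seqs3 <- seqs3[nchar(seqs3) > 0L]
  if (length(seqs3) >= 3L) {
    pse <- genes_tbl$id[genes_tbl$status == "pseudogene"]
    seqs3 <- drop_dissimilar(modal_length_subset(seqs3), pse)
  }
  if (length(seqs5) >= 3L) {
    tree5 <- nj_tree(pairwise_distance(seqs5, model = distance_model))
  }
  if (length(seqs3) >= 3L) {
    tree3 <- nj_tree(pairwise_distance(seqs3, model = distance_model))
  }
  if (!is.null(tree5) && !is.null(tree3) &&
      length(unique(genes_tbl$species)) >= 2L) {
    cterm <- setNames(genes_tbl$cterm, genes_tbl$id)
    orthologs <- assign_orthologs(tree5, tree3, cterm)
  }

  report <- list(
    tool = "afgpkit",
    version = as.character(utils::packageVersion("afgpkit")),
    config = config,
    config_hash = content_hash(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                digits = NA)),
    n_genes = nrow(genes_tbl),
    n_functional = sum(genes_tbl$status == "functional"),
    n_pseudogenes = sum(genes_tbl$status == "pseudogene"),
    n_non_afgp = sum(genes_tbl$status == "non_AFGP"),
    n_isoforms = nrow(isoforms_tbl),
    species = family_tbl)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(x, name) write.table(
      x, file.path(out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    tsv(genes_tbl, "genes.tsv")
    tsv(isoforms_tbl, "isoforms.tsv")
    tsv(family_tbl, "family_summary.tsv")
    sites_tbl <- bind_rows(lapply(results, function(r) {
      if (nrow(r$sites)) cbind(tibble(gene = r$record$id), r$sites)
      else NULL
    }))
    if (is.null(sites_tbl) || nrow(sites_tbl) == 0L) {
      sites_tbl <- tibble(gene = character(0), unit_index = integer(0),
                          site_type = character(0), residue_span = integer(0))
    }
    tsv(sites_tbl, "cleavage_sites.tsv")
    usage <- Filter(Negate(is.null), lapply(results, `[[`, "codon_usage"))
    if (length(usage)) {
      tsv(usage_wide(usage), "codon_usage.tsv")
      flags <- bind_rows(lapply(usage, function(u) {
        f <- codon_bias_flags(u)
        if (nrow(f)) cbind(tibble(gene = attr(u, "gene_id")), f) else NULL
      }))
      if (!is.null(flags) && nrow(flags)) tsv(flags, "codon_flags.tsv")
    }
    feats <- bind_rows(lapply(results, function(r)
      gff3_features(r$record, r$region, r$sites,
                    include_units = include_units)))
    if (nrow(feats)) write_gff3(feats, file.path(out_dir, "features.gff3"))
    if (!is.null(tree5)) write_newick(tree5, file.path(out_dir, "tree5.nwk"))
    if (!is.null(tree3)) write_newick(tree3, file.path(out_dir, "tree3.nwk"))
    if (!is.null(orthologs)) tsv(orthologs, "orthologs.tsv")
    cfg_out <- config
    cfg_out$mass_model$residue_avg_mass <-
      as.list(cfg_out$mass_model$residue_avg_mass)
    yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(results = results, genes = genes_tbl,
                 isoforms = isoforms_tbl, family = family_tbl,
                 tree5 = tree5, tree3 = tree3, orthologs = orthologs,
                 report = report))
}

#' Shape pipeline output for [truth_compare()]
#'
#' @param run result of [run_pipeline()].
#' @return list with `genes`, `sites`, `tree` in the form
#'   [truth_compare()] expects.  Predicted status collapses `non_AFGP`
#'   into `pseudogene` is *not* done; labels are passed through.
#' @export
pipeline_predictions <- function(run) {
  sites <- bind_rows(lapply(run$results, function(r) {
    if (nrow(r$sites)) tibble(gene = r$record$id,
                              unit_index = r$sites$unit_index,
                              site_type = r$sites$site_type)
    else NULL
  }))
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- tibble(gene = character(0), unit_index = integer(0),
                    site_type = character(0))
  }
  list(genes = tibble(id = run$genes$id,
                      n_repeat_units = run$genes$n_repeat_units,
                      status = run$genes$status),
       sites = sites,
       tree = run$tree5)
}
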