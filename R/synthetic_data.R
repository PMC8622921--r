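# synthetic_data: ground-truthed simulator of AFGP gene-family evolution.
#
# One ancestral gene (5' flank + start + non-repetitive leader + ACA-GCA-GCA
# repeat units + C-terminus + stop + 3' flank) evolves for a fixed number of
# generations under four event types applied in a fixed order within each
# generation: slipped-strand mispairing (in-place duplication of a contiguous
# block of units), nucleotide substitution with transition bias (position-1
# ACA codons mutating at their middle base preferentially yield AGA/AAA,
# the genesis of cleavage spacers), whole-gene duplication (bifurcating the
# true gene tree), and pseudogenization (one of the three observed lesion
# types).  An optional speciation event copies the whole family into a
# second species.  Every sequence is emitted together with machine-readable
# ground truth regenerable from (seed, config).

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.BASES <- c("A", "C", "G", "T")

# Codons used for the non-repetitive leader (signal/propeptide-like:
# hydrophobic and small residues, deliberately excluding Met, stops, and any
# residue that could extend or seed a tripeptide unit next to the tract).
.LEADER_CODONS <- c("CTG", "CTC", "TTG", "TTC", "ATC", "GTG", "GTC",
                    "TCC", "TCG", "AGC", "TGG", "TTT")

#' Simulator configuration
#'
#' All rates are per generation.  The defaults describe a gadid-like family:
#' flank lengths match the 5' (1140 nt) and 3' (325 nt) analysis segments,
#' the duplication rate yields expected family sizes in the observed 4-16
#' gene range over the default 100 generations, the pseudogenization reason
#' mix reflects the observed lesion spectrum (2:2:1 truncation : frameshift :
#' insertion), and `cleavage_genesis = 10` makes spacer-creating ACA -> AGA
#' transversions ten times likelier than ACA -> AAA, mirroring the ~10:1
#' Arg:Lys ratio in real repeat regions.
#'
#' @param seed integer RNG seed; the same (seed, config) regenerates
#'   byte-identical output.
#' @param n_initial_units repeat units in the ancestral gene.
#' @param generations number of generations to simulate.
#' @param slippage_rate expected slippage events per gene per generation.
#' @param slippage_block_mean mean duplicated block size (geometric on
#'   1, 2, ...).
#' @param substitution_rate per-site substitutions per generation in the
#'   coding sequence (repeat tract, C-terminus, leader).
#' @param flank_substitution_rate per-site substitutions per generation in
#'   the non-coding 5' and 3' flanks (the tree-building segments).
#' @param ts_tv_ratio transition:transversion weight.
#' @param cleavage_genesis odds of AGA vs AAA when the middle base of a
#'   position-1 ACA codon is substituted.
#' @param gene_duplication_rate expected whole-gene duplications per gene
#'   per generation.
#' @param pseudogenization_rate probability per (functional) gene per
#'   generation of acquiring a lesion.
#' @param pseudogene_reason_mix named probabilities over the three lesions.
#' @param insertion_length length (nt) of a `coding_insertion` tract.
#' @param flank_length_5,flank_length_3 flank lengths (nt).
#' @param leader_codons codons in the leader, start codon included.
#' @param species species tag for the founding lineage.
#' @param speciation_time generation at which the whole family is copied
#'   into a second species (`NA` = never).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_initial_units = 12L,
                       generations = 100L,
                       slippage_rate = 0.05,
                       slippage_block_mean = 2,
                       substitution_rate = 1e-4,
                       flank_substitution_rate = 1e-4,
                       ts_tv_ratio = 2,
                       cleavage_genesis = 10,
                       gene_duplication_rate = 0.02,
                       pseudogenization_rate = 0.002,
                       pseudogene_reason_mix = c(five_prime_truncated = 0.4,
                                                 frameshift_indel = 0.4,
                                                 coding_insertion = 0.2),
                       insertion_length = 800L,
                       flank_length_5 = 1140L,
                       flank_length_3 = 325L,
                       leader_codons = 20L,
                       species = "simA",
                       speciation_time = NA_integer_) {
  cfg <- list(seed = as.integer(seed),
              n_initial_units = as.integer(n_initial_units),
              generations = as.integer(generations),
              slippage_rate = slippage_rate,
              slippage_block_mean = slippage_block_mean,
              substitution_rate = substitution_rate,
              flank_substitution_rate = flank_substitution_rate,
              ts_tv_ratio = ts_tv_ratio,
              cleavage_genesis = cleavage_genesis,
              gene_duplication_rate = gene_duplication_rate,
              pseudogenization_rate = pseudogenization_rate,
              pseudogene_reason_mix = pseudogene_reason_mix,
              insertion_length = as.integer(insertion_length),
              flank_length_5 = as.integer(flank_length_5),
              flank_length_3 = as.integer(flank_length_3),
              leader_codons = as.integer(leader_codons),
              species = species,
              speciation_time = as.integer(speciation_time))
  rates <- c(cfg$slippage_rate, cfg$substitution_rate,
             cfg$flank_substitution_rate, cfg$gene_duplication_rate,
             cfg$pseudogenization_rate)
  stopifnot(all(rates >= 0), cfg$n_initial_units >= 1L,
            cfg$generations >= 0L, cfg$slippage_block_mean >= 1,
            cfg$ts_tv_ratio > 0, cfg$cleavage_genesis >= 0,
            cfg$insertion_length > 0L, cfg$leader_codons >= 2L)
  mix <- cfg$pseudogene_reason_mix
  stopifnot(setequal(names(mix),
                     c("five_prime_truncated", "frameshift_indel",
                       "coding_insertion")),
            all(mix >= 0), sum(mix) > 0)
  cfg$pseudogene_reason_mix <- mix / sum(mix)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# Substitute one site of `s` at 1-based position `pos`; returns the string.
# Target base weights: transition = kappa, each transversion = 1, unless
# `weights` overrides.
substitute_base <- function(s, pos, kappa, weights = NULL) {
  b <- substr(s, pos, pos)
  if (!b %in% .BASES) return(s)       # never mutate N
  alts <- setdiff(.BASES, b)
  w <- if (is.null(weights)) {
    ifelse(alts == .TRANSITION[[b]], kappa, 1)
  } else weights[alts]
  nb <- sample(alts, 1L, prob = w)
  substr(s, pos, pos) <- nb
  s
}

new_sim_gene <- function(id, species, cfg) {
  leader <- paste0("ATG", paste(sample(.LEADER_CODONS,
                                       cfg$leader_codons - 1L,
                                       replace = TRUE), collapse = ""))
  list(id = id, species = species, birth_time = 0L,
       status = "functional", reason = "none",
       flank5 = random_dna(cfg$flank_length_5),
       leader = leader,
       units = rep("ACAGCAGCA", cfg$n_initial_units),
       insertion_after = NA_integer_, insertion_seq = "",
       cterm = "GGATTATTC",           # Gly-Leu-Phe: inert C-terminal tag
       stop = "TGA",
       flank3 = random_dna(cfg$flank_length_3))
}

# Assemble the emitted sequence and CDS coordinates of a simulated gene.
sim_gene_seq <- function(g) {
  units <- g$units
  body <- if (!is.na(g$insertion_after)) {
    paste0(paste(units[seq_len(g$insertion_after)], collapse = ""),
           g$insertion_seq,
           paste(units[-seq_len(g$insertion_after)], collapse = ""))
  } else {
    paste(units, collapse = "")
  }
  cds <- paste0(g$leader, body, g$cterm, g$stop)
  seq <- paste0(g$flank5, cds, g$flank3)
  list(seq = seq, cds_start = nchar(g$flank5),
       cds_end = nchar(g$flank5) + nchar(cds))
}

# Apply `k` coding substitutions to units + cterm + leader of gene `g`.
mutate_coding <- function(g, k, cfg) {
  for (i in seq_len(k)) {
    lens <- c(9L * length(g$units), nchar(g$cterm), nchar(g$leader))
    pos <- sample.int(sum(lens), 1L)
    if (pos <= lens[1]) {
      u <- (pos - 1L) %/% 9L + 1L
      off <- (pos - 1L) %% 9L + 1L
      unit <- g$units[u]
      if (off == 2L && substr(unit, 1, 3) == "ACA") {
        # spacer genesis: middle base of a position-1 Thr codon
        w <- setNames(c(0, 0, cfg$cleavage_genesis, cfg$ts_tv_ratio), .BASES)
        w["A"] <- 1
        g$units[u] <- substitute_base(unit, off, cfg$ts_tv_ratio, weights = w)
      } else {
        g$units[u] <- substitute_base(unit, off, cfg$ts_tv_ratio)
      }
    } else if (pos <= lens[1] + lens[2]) {
      g$cterm <- substitute_base(g$cterm, pos - lens[1], cfg$ts_tv_ratio)
    } else {
      g$leader <- substitute_base(g$leader, pos - lens[1] - lens[2],
                                  cfg$ts_tv_ratio)
    }
  }
  g
}

mutate_flanks <- function(g, k, cfg) {
  for (i in seq_len(k)) {
    lens <- c(nchar(g$flank5), nchar(g$flank3))
    if (sum(lens) == 0L) break
    pos <- sample.int(sum(lens), 1L)
    if (pos <= lens[1]) {
      g$flank5 <- substitute_base(g$flank5, pos, cfg$ts_tv_ratio)
    } else {
      g$flank3 <- substitute_base(g$flank3, pos - lens[1],
                                  cfg$ts_tv_ratio)
    }
  }
  g
}

apply_slippage <- function(g, cfg, log_event) {
  b <- 1L + rgeom(1L, prob = 1 / cfg$slippage_block_mean)
  len <- length(g$units)
  u <- sample.int(len, 1L)
  b <- min(b, len - u + 1L)
  g$units <- append(g$units, g$units[u:(u + b - 1L)], after = u + b - 1L)
  if (!is.na(g$insertion_after) && g$insertion_after >= u) {
    g$insertion_after <- g$insertion_after + b
  }
  log_event("slippage", sprintf("start_unit=%d;block=%d", u, b))
  g
}

apply_pseudogenization <- function(g, cfg, log_event) {
  reason <- sample(names(cfg$pseudogene_reason_mix), 1L,
                   prob = cfg$pseudogene_reason_mix)
  if (reason == "coding_insertion" && length(g$units) < 8L) {
    reason <- "frameshift_indel"   # no room for a detectable split tract
  }
  if (reason == "five_prime_truncated") {
    g$leader <- ""
    g$flank5 <- substr(g$flank5, 1L, max(0L, nchar(g$flank5) - 200L))
  } else if (reason == "frameshift_indel") {
    sz <- sample(1:2, 1L)
    at <- nchar(g$leader) - 3L
    if (runif(1) < 0.5) {
      g$leader <- paste0(substr(g$leader, 1L, at),
                         random_dna(sz),
                         substr(g$leader, at + 1L, nchar(g$leader)))
    } else {
      g$leader <- paste0(substr(g$leader, 1L, at - sz),
                         substr(g$leader, at + 1L, nchar(g$leader)))
    }
  } else {
    lo <- 4L
    hi <- length(g$units) - 4L
    g$insertion_after <- if (hi <= lo) lo else sample(lo:hi, 1L)
    g$insertion_seq <- random_dna(cfg$insertion_length)
  }
  g$status <- "pseudogene"
  g$reason <- reason
  log_event("pseudogenization", reason)
  g
}

#' Simulate an AFGP gene family with ground truth
#'
#' See [sim_config()] for the event model.  The emitted truth reflects the
#' *final* state of every gene: unit classes after mutation, the cleavage
#' sites implied by them, status labels from the pseudogenization events,
#' the true gene tree (duplication/speciation splits, branch lengths in
#' generations), and a replayable event log.
#'
#' @param config a [sim_config()].
#' @return list with `records` (list of [gene_record()]), `truth`
#'   (an `afgp_truth` list: `genes`, `sites`, `tree_newick`,
#'   `ortholog_pairs`, `cterm`, `event_log`), and `config`.
#' @export
#' @examples
#' sim <- simulate_family(sim_config(seed = 7, generations = 10))
#' sim$truth$genes
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    counter <- 1L
    gene_id <- function(species, k) sprintf("%s_g%03d", species, k)
    genes <- list(new_sim_gene(gene_id(cfg$species, 1L), cfg$species, cfg))
    names(genes) <- genes[[1]]$id
    gene_number <- c(1L)
    names(gene_number) <- genes[[1]]$id
    splits <- list()     # (time, parent, child) lineage bifurcations
    log <- list()
    speciation_pairs <- list()
    add_log <- function(gen, gene, event, detail) {
      log[[length(log) + 1L]] <<- tibble(generation = gen, gene = gene,
                                         event = event, detail = detail)
    }

    for (gen in seq_len(cfg$generations)) {
      if (!is.na(cfg$speciation_time) && gen == cfg$speciation_time) {
        sp2 <- paste0(cfg$species, "2")
        for (gid in names(genes)) {
          g2 <- genes[[gid]]
          g2$species <- sp2
          g2$id <- gene_id(sp2, gene_number[[gid]])
          g2$birth_time <- gen
          genes[[g2$id]] <- g2
          gene_number[g2$id] <- gene_number[[gid]]
          splits[[length(splits) + 1L]] <-
            list(time = gen, parent = gid, child = g2$id,
                 type = "speciation")
          speciation_pairs[[length(speciation_pairs) + 1L]] <-
            c(gid, g2$id)
          add_log(gen, g2$id, "speciation_copy", gid)
        }
      }
      for (gid in names(genes)) {
        g <- genes[[gid]]
        # slippage
        for (e in seq_len(rpois(1L, cfg$slippage_rate))) {
          g <- apply_slippage(g, cfg, function(ev, det) add_log(gen, gid, ev, det))
        }
        # substitution: coding (repeat tract + C-terminus + leader)
        L <- 9L * length(g$units) + nchar(g$cterm) + nchar(g$leader)
        g <- mutate_coding(g, rpois(1L, L * cfg$substitution_rate), cfg)
        # substitution: non-coding flanks
        L2 <- nchar(g$flank5) + nchar(g$flank3)
        g <- mutate_flanks(g, rpois(1L, L2 * cfg$flank_substitution_rate), cfg)
        genes[[gid]] <- g
        # whole-gene duplication
        for (e in seq_len(rpois(1L, cfg$gene_duplication_rate))) {
          counter <- max(gene_number) + 1L
          child <- g
          child$id <- gene_id(g$species, counter)
          child$birth_time <- gen
          genes[[child$id]] <- child
          gene_number[child$id] <- counter
          splits[[length(splits) + 1L]] <-
            list(time = gen, parent = gid, child = child$id,
                 type = "duplication")
          add_log(gen, child$id, "duplication", gid)
          g <- genes[[gid]]
        }
        # pseudogenization
        if (g$status == "functional" &&
            runif(1) < cfg$pseudogenization_rate) {
          g <- apply_pseudogenization(
            g, cfg, function(ev, det) add_log(gen, gid, ev, det))
          genes[[gid]] <- g
        }
      }
    }
    if (length(genes) == 0L) stop("simulation produced zero genes",
                                  call. = FALSE)

    records <- lapply(genes, function(g) {
      s <- sim_gene_seq(g)
      gene_record(g$id, s$seq, s$cds_start, s$cds_end, strand = "+",
                  species = g$species, status = g$status,
                  pseudogene_reason = g$reason)
    })

    truth <- build_truth(genes, splits, cfg,
                         if (length(log)) bind_rows(log) else
                           tibble(generation = integer(0), gene = character(0),
                                  event = character(0), detail = character(0)),
                         speciation_pairs)
    list(records = unname(records), truth = truth, config = cfg)
  })
}

# Construct a repeat_region object directly from a unit vector (ground truth
# framing, no scanning).
units_as_region <- function(units) {
  res <- vapply(units, function(u)
    paste(translate_codons(split_codons(u)), collapse = ""), "",
    USE.NAMES = FALSE)
  u <- tibble(index = seq_along(units) - 1L, codons = units,
              residues = res, class = classify_unit(res))
  structure(
    list(cds_offset_start = 0L, cds_offset_end = 9L * length(units),
         frame = 0L, units = u, n_units = nrow(u),
         n_repeat_units = sum(u$class %in% REPEAT_CLASSES),
         n_spacer_units = sum(u$class %in% SPACER_CLASSES)),
    class = "repeat_region")
}

build_truth <- function(genes, splits, cfg, event_log, speciation_pairs) {
  gene_rows <- lapply(genes, function(g) {
    reg <- units_as_region(g$units)
    tibble(id = g$id, species = g$species, status = g$status,
           reason = g$reason, n_units = reg$n_units,
           n_repeat_units = reg$n_repeat_units,
           n_spacer_units = reg$n_spacer_units,
           unit_classes = paste(reg$units$class, collapse = ","))
  })
  site_rows <- lapply(genes, function(g) {
    s <- find_cleavage_sites(units_as_region(g$units))
    if (nrow(s)) tibble(gene = g$id, unit_index = s$unit_index,
                        site_type = s$site_type)
    else tibble(gene = character(0), unit_index = integer(0),
                site_type = character(0))
  })
  cterm <- vapply(genes, function(g)
    paste(translate_codons(split_codons(g$cterm)), collapse = ""), "")
  names(cterm) <- names(genes)

  # true tree from the recorded splits; splits are appended in time order, so
  # recursion advances through them by sequence index (handles several events
  # on one lineage within a generation)
  end_t <- cfg$generations
  next_split <- function(gid, after_idx) {
    idx <- which(vapply(splits, function(s) s$parent == gid, TRUE))
    idx <- idx[idx > after_idx]
    if (length(idx) == 0L) NULL else idx[1]
  }
  build <- function(gid, t0, after_idx) {
    k <- next_split(gid, after_idx)
    if (is.null(k)) {
      sprintf("%s:%d", gid, end_t - t0)
    } else {
      ev <- splits[[k]]
      sprintf("(%s,%s):%d", build(gid, ev$time, k),
              build(ev$child, ev$time, k), ev$time - t0)
    }
  }
  root <- names(genes)[1]
  tree_newick <- paste0(build(root, 0L, 0L), ";")

  # speciation-derived ortholog pairs whose two lineages stayed single-copy
  # and functional; any duplication at or after the speciation makes the
  # correspondence one-to-many
  post_dup <- vapply(splits, function(s)
    if (s$type == "duplication" && !is.na(cfg$speciation_time) &&
        s$time >= cfg$speciation_time)
      s$parent else NA_character_, "")
  post_dup <- post_dup[!is.na(post_dup)]
  ortho <- lapply(speciation_pairs, function(p) {
    if (any(p %in% post_dup)) return(NULL)
    if (genes[[p[1]]]$status != "functional" ||
        genes[[p[2]]]$status != "functional") return(NULL)
    tibble(gene_a = p[1], gene_b = p[2])
  })
  ortho <- bind_rows(Filter(Negate(is.null), ortho))
  if (nrow(ortho) == 0L) {
    ortho <- tibble(gene_a = character(0), gene_b = character(0))
  }

  structure(list(genes = bind_rows(gene_rows),
                 sites = bind_rows(site_rows),
                 tree_newick = tree_newick,
                 ortholog_pairs = ortho,
                 cterm = cterm,
                 event_log = event_log),
            class = "afgp_truth")
}

#' Write a simulated family to disk
#'
#' Emits `genes.fasta`, `coords.tsv` (id, species, 0-based half-open CDS
#' coordinates, strand, status), `truth.json`, and `config.yaml`.
#'
#' @param sim result of [simulate_family()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$records, file.path(dir, "genes.fasta"))
  coords <- bind_rows(lapply(sim$records, function(r)
    tibble(id = r$id, species = r$species, cds_start = r$cds_start,
           cds_end = r$cds_end, strand = r$strand, status = r$status,
           pseudogene_reason = r$pseudogene_reason)))
  write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(genes = tr$genes, sites = tr$sites, tree_newick = tr$tree_newick,
         ortholog_pairs = tr$ortholog_pairs,
         cterm = as.list(tr$cterm), event_log = tr$event_log),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(sim$config)
  cfg$pseudogene_reason_mix <- as.list(cfg$pseudogene_reason_mix)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Score pipeline output against simulator ground truth
#'
#' @param truth an `afgp_truth` (from [simulate_family()]).
#' @param predicted a list with `genes` (tibble: `id`, `n_repeat_units`,
#'   `status`), optional `sites` (tibble: `gene`, `unit_index`,
#'   `site_type`), and optional `tree` (a `family_tree` to compare with the
#'   true tree).
#' @return list: `repeat_count_exact_match` (fraction of genes whose Thr-led
#'   unit count is recovered exactly), `site_precision`, `site_recall`
#'   (matched by gene, unit index, and type), `status_accuracy`,
#'   `status_confusion` (table), `rf_distance` (NA when no tree supplied).
#' @export
truth_compare <- function(truth, predicted) {
  stopifnot(inherits(truth, "afgp_truth"), is.list(predicted),
            !is.null(predicted$genes))
  tg <- truth$genes
  pg <- predicted$genes
  missing_ids <- setdiff(tg$id, pg$id)
  extra_ids <- setdiff(pg$id, tg$id)
  if (length(missing_ids) || length(extra_ids)) {
    stop(sprintf(
      "gene id mismatch between truth and prediction; missing: [%s]; unexpected: [%s]",
      paste(missing_ids, collapse = ", "),
      paste(extra_ids, collapse = ", ")), call. = FALSE)
  }
  m <- match(tg$id, pg$id)
  exact <- mean(tg$n_repeat_units == pg$n_repeat_units[m])

  prec <- rec <- NA_real_
  if (!is.null(predicted$sites)) {
    key <- function(s) paste(s$gene, s$unit_index, s$site_type, sep = ":")
    tk <- key(truth$sites)
    pk <- key(predicted$sites)
    prec <- if (length(pk)) mean(pk %in% tk) else
      (if (length(tk)) 0 else 1)
    rec <- if (length(tk)) mean(tk %in% pk) else 1
  }

  ts <- tg$status
  ps <- pg$status[m]
  confusion <- table(truth = ts, predicted = ps)
  acc <- mean(ts == ps)

  rf <- NA_integer_
  if (!is.null(predicted$tree)) {
    true_tree <- ape::read.tree(text = truth$tree_newick)
    rf <- rf_distance(true_tree, predicted$tree)
  }
  list(repeat_count_exact_match = exact,
       site_precision = prec, site_recall = rec,
       status_accuracy = acc, status_confusion = confusion,
       rf_distance = rf)
}
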