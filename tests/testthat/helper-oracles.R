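# Independent oracles and fixture builders used across the suite.
# These deliberately do not share code paths with the package internals:
# translation goes through Biostrings::translate on whole frames, repeat
# runs are enumerated exhaustively, ORFs are found by regex on translated
# frames.

# --- fixture builders -------------------------------------------------------

UNIT_TAA <- "ACAGCAGCA"   # Thr-Ala-Ala
UNIT_TPA <- "ACACCAGCA"   # Thr-Pro-Ala
UNIT_RAA <- "AGAGCAGCA"   # Arg-Ala-Ala
UNIT_KAA <- "AAAGCAGCA"   # Lys-Ala-Ala

# random DNA free of any 9-nt window (in any codon phase) that would form a
# classifiable tripeptide unit; used to embed planted tracts
random_nonrepeat_dna <- function(n, seed_offset = 0L) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (!has_unit_window(s)) return(s)
  }
}

has_unit_window <- function(s) {
  n <- nchar(s)
  if (n < 9L) return(FALSE)
  for (start in 1:(n - 8L)) {
    aa <- oracle_translate(substr(s, start, start + 8L))
    if (grepl("^T[AP]A$", aa) || grepl("^[RK]AA$", aa)) return(TRUE)
  }
  FALSE
}

# an intact synthetic AFGP gene CDS: ATG + stop-free leader + units + C-term
# + stop.  Leader is built from hydrophobic codons that cannot extend the
# repeat tract.
make_cds <- function(units, leader_codons = 12L) {
  leader <- paste(rep(c("CTG", "TTC", "GTC"), length.out = leader_codons - 1L),
                  collapse = "")
  paste0("ATG", leader, paste(units, collapse = ""), "GGATTATTC", "TGA")
}

random_gene_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      len <- sample(60:300, 1)
      seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                          prob = c(.24, .24, .24, .24, .04)), collapse = "")
      a <- sort(sample(0:(len - 3), 2))
      while ((a[2] - a[1]) %% 3 != 0 || a[2] == a[1]) {
        a <- sort(sample(0:(len - 3), 2))
      }
      gene_record(sprintf("sp%d_g%d", i %% 3, i), seq, a[1], a[2],
                  strand = sample(c("+", "-"), 1))
    })
  })
}

# --- translation / repeat-region oracle -------------------------------------

oracle_translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# unit class vectors for all nine phases from three whole-frame
# translations (phase = frame + 3 * codon_offset)
oracle_unit_classes_all <- function(cds) {
  n <- nchar(cds)
  out <- vector("list", 9L)
  mcs <- (n - 0:2) %/% 3L
  frames_nt <- substr(rep(cds, 3), 1:3, 0:2 + 3L * pmax(mcs, 0L))
  keep <- mcs > 0L
  aa_all <- rep("", 3L)
  if (any(keep)) {
    aa_all[keep] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(frames_nt[keep]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  for (frame in 0:2) {
    mc <- mcs[frame + 1L]
    if (mc <= 0L) next
    aa <- strsplit(aa_all[frame + 1L], "")[[1]]
    for (off in 0:2) {
      phase <- frame + 3L * off
      m <- (mc - off) %/% 3L
      if (m <= 0L) { out[[phase + 1L]] <- character(0); next }
      k <- seq_len(m)
      res <- paste0(aa[off + 3L * k - 2L], aa[off + 3L * k - 1L],
                    aa[off + 3L * k])
      out[[phase + 1L]] <-
        ifelse(grepl("^T[AP]A$", res), "REPEAT",
               ifelse(grepl("^[RK]AA$", res), "SPACER", "OTHER"))
    }
  }
  out
}

oracle_unit_classes <- function(cds, phase) {
  cls <- oracle_unit_classes_all(cds)[[phase + 1L]]
  if (is.null(cls)) character(0) else cls
}

# exhaustive enumeration of every (phase, start, end) run satisfying the
# min-length / impurity / trimmed-end constraints, in matrix form: every
# (i, j) pair is materialised and filtered at once.  Global selection by
# (max score, min start_nt, max length).
oracle_region <- function(cds, min_units = 4L, max_other_frac = 0.1) {
  best <- NULL
  all_cls <- oracle_unit_classes_all(cds)
  for (phase in 0L:8L) {
    cls <- all_cls[[phase + 1L]]
    if (is.null(cls)) next
    m <- length(cls)
    if (m < min_units) next
    is_oth <- cls == "OTHER"
    cum <- c(0L, cumsum(is_oth))
    i_idx <- rep(seq_len(m), times = m)
    j_idx <- rep(seq_len(m), each = m)
    len <- j_idx - i_idx + 1L
    oth <- cum[j_idx + 1L] - cum[i_idx]
    ok <- len >= min_units & !is_oth[i_idx] & !is_oth[j_idx] &
      oth <= max_other_frac * len
    if (!any(ok)) next
    i_ok <- i_idx[ok]; j_ok <- j_idx[ok]
    score <- len[ok] - oth[ok]
    start_nt <- phase + 9L * (i_ok - 1L)
    ord <- order(-score, start_nt, -len[ok])[1]
    i <- i_ok[ord]; j <- j_ok[ord]
    cand <- list(score = score[ord], start_nt = start_nt[ord],
                 len = len[ok][ord], phase = phase, i = i, j = j,
                 n_repeat = sum(cls[i:j] == "REPEAT"),
                 n_spacer = sum(cls[i:j] == "SPACER"))
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$start_nt < best$start_nt) ||
        (cand$score == best$score && cand$start_nt == best$start_nt &&
         cand$len > best$len)) {
      best <- cand
    }
  }
  best
}

# --- ORF oracle -------------------------------------------------------------

# does any forward-frame ORF (ATG..stop) cover [rs, re) with a leader of at
# least min_leader_nt before the repeats?
oracle_orf_covers <- function(cds, rs, re, min_leader_nt = 30L) {
  n <- nchar(cds)
  for (frame in 0:2) {
    m <- (n - frame) %/% 3L
    if (m <= 0L) next
    aa <- oracle_translate(substr(cds, frame + 1L, frame + 3L * m))
    starts <- gregexpr("M", aa, fixed = TRUE)[[1]]
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    if (starts[1] == -1L) next
    for (s_aa in starts) {
      s_nt <- frame + 3L * (s_aa - 1L)
      stop_after <- stops[stops > s_aa]
      if (length(stop_after) == 0L || stop_after[1] == -1L) next
      e_nt <- frame + 3L * stop_after[1]       # end of stop codon
      if (s_nt <= rs - min_leader_nt && e_nt >= re &&
          (rs - s_nt) %% 3L == 0L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# --- misc -------------------------------------------------------------------

# region object built directly from class strings (ground-truth framing,
# no scanning/trimming), for digestion tests
region_from_classes <- function(classes) {
  codon_of <- c(TAA = UNIT_TAA, TPA = UNIT_TPA, RAA = UNIT_RAA,
                KAA = UNIT_KAA, OTHER = "GGAGGAGGA")
  afgpkit:::units_as_region(unname(codon_of[classes]))
}

sim_to_pipeline <- function(sim, out_dir = NULL) {
  fasta <- tibble::tibble(
    id = vapply(sim$records, `[[`, "", "id"),
    seq = vapply(sim$records, `[[`, "", "seq"))
  coords <- dplyr::bind_rows(lapply(sim$records, function(r)
    tibble::tibble(id = r$id, cds_start = r$cds_start, cds_end = r$cds_end,
                   strand = r$strand, species = r$species)))
  run_pipeline(fasta, out_dir = out_dir, coords = coords)
}
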