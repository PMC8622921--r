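test_that("cleavage sites: Lys, lone Arg, and boundary-spanning RAAR motifs", {
  r <- region_from_classes(c(rep("TAA", 4), "KAA", rep("TAA", 5)))
  s <- find_cleavage_sites(r)
  expect_identical(nrow(s), 1L)
  expect_identical(s$unit_index, 4L)
  expect_identical(s$site_type, "single_Lys")
  expect_identical(s$residue_span, 3L)

  # RAA followed by an R-initial unit -> one RAAR; residue string contains R-A-A-R
  r2 <- region_from_classes(c(rep("TAA", 3), "RAA", "RAA", rep("TAA", 2)))
  expect_match(paste(r2$units$residues, collapse = ""), "RAAR")
  s2 <- find_cleavage_sites(r2)
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$site_type, "RAAR")
  expect_identical(s2$residue_span, 4L)
  expect_identical(s2$unit_index, 3L)

  # isolated RAA -> single_Arg
  r3 <- region_from_classes(c(rep("TAA", 3), "RAA", rep("TAA", 3)))
  expect_identical(find_cleavage_sites(r3)$site_type, "single_Arg")

  # all-Thr region has no sites
  expect_identical(nrow(find_cleavage_sites(region_from_classes(rep("TAA", 6)))), 0L)
})

test_that("every KAA maps to one site and overlapping RAARs resolve leftmost-first", {
  withr::with_seed(42, {
    for (i in 1:50) {
      classes <- sample(c("TAA", "TPA", "RAA", "KAA"), sample(5:40, 1),
                        replace = TRUE, prob = c(.5, .2, .2, .1))
      r <- region_from_classes(classes)
      s <- find_cleavage_sites(r)
      expect_identical(sum(s$site_type == "single_Lys"), sum(classes == "KAA"))
      expect_false(is.unsorted(s$unit_index))
      # an RAAR consumes the following unit's Arg: no site may start there
      raar_next <- s$unit_index[s$site_type == "RAAR"] + 1L
      expect_length(intersect(raar_next, s$unit_index), 0L)
    }
  })
})

test_that("digestion splits products at excised linkers and conserves units", {
  r <- region_from_classes(c(rep("TAA", 4), "KAA", rep("TAA", 5)))
  d <- digest_polyprotein(r, gene_id = "g1")
  expect_identical(d$n_repeats, c(4L, 5L))
  expect_identical(d$size_bin, c("AFGP8", "AFGP7"))
  acct <- attr(d, "unit_accounting")
  expect_identical(acct$product_units + acct$linker_units + acct$dropped_units,
                   acct$total_units)

  # no sites: a single product carrying every repeat unit
  r2 <- region_from_classes(rep("TAA", 7))
  d2 <- digest_polyprotein(r2)
  expect_identical(nrow(d2), 1L)
  expect_identical(d2$n_repeats, r2$n_repeat_units)

  # sub-repeat fragments are reported, binned sub_AFGP
  r3 <- region_from_classes(c("TAA", "TAA", "KAA", rep("TAA", 6)))
  d3 <- digest_polyprotein(r3)
  expect_identical(d3$size_bin[1], "sub_AFGP")
  expect_identical(d3$n_repeats, c(2L, 6L))
})

test_that("digestion conserves units and spacer-free regions yield one product", {
  withr::with_seed(17, {
    for (i in 1:60) {
      classes <- sample(c("TAA", "TPA", "RAA", "KAA", "OTHER"),
                        sample(4:50, 1), replace = TRUE,
                        prob = c(.45, .2, .15, .1, .1))
      r <- region_from_classes(classes)
      d <- digest_polyprotein(r)
      acct <- attr(d, "unit_accounting")
      expect_identical(
        acct$product_units + acct$linker_units + acct$dropped_units,
        acct$total_units)
      expect_identical(acct$linker_units,
                       sum(classes %in% c("RAA", "KAA")))
      # removing all R/K-led units collapses digestion to a single product
      pure <- classes[!classes %in% c("RAA", "KAA")]
      if (sum(pure %in% c("TAA", "TPA")) >= 1) {
        dp <- digest_polyprotein(region_from_classes(pure))
        expect_identical(nrow(dp), 1L)
      }
    }
  })
})

test_that("retain-linkers mode keeps spacers on the upstream product", {
  r <- region_from_classes(c(rep("TAA", 4), "KAA", rep("TAA", 5)))
  d <- digest_polyprotein(r, retain_linkers = TRUE)
  expect_identical(d$n_units, c(5L, 5L))
  expect_identical(d$n_repeats, c(4L, 5L))
  expect_match(d$residues[1], "KAA$")
})

test_that("peptide_mass matches an independent sum of standard average masses", {
  m <- mass_model()
  # frozen expectations: n*(T+A+A) + water + n*adduct
  oracle <- function(n) n * (101.10 + 71.08 + 71.08) + 18.02 + n * 365.33
  expect_equal(peptide_mass(strrep("TAA", 4), m), 2452.38, tolerance = 1e-9)
  expect_equal(peptide_mass(strrep("TAA", 4), m), oracle(4))
  expect_equal(peptide_mass(strrep("TAA", 33), m), oracle(33))
  expect_equal(peptide_mass(strrep("TAA", 53), m), oracle(53))
  expect_identical(peptide_mass("", m), 18.02)
  expect_error(peptide_mass("TAZ", m), "outside the mass model")
})

test_that("peptide_mass is additive up to one water", {
  m <- mass_model()
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- paste(sample(c("T", "A", "P", "R", "K"), sample(1:30, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(c("T", "A", "P", "R", "K"), sample(1:30, 1),
                        replace = TRUE), collapse = "")
      expect_equal(peptide_mass(paste0(a, b), m),
                   peptide_mass(a, m) + peptide_mass(b, m) - m$water)
    }
  })
})

test_that("mass increases strictly with repeat count", {
  m <- mass_model()
  masses <- vapply(1:60, function(n) peptide_mass(strrep("TAA", n), m), 0)
  expect_true(all(diff(masses) > 0))
})

test_that("isoform bins follow repeat count first, then mass", {
  expect_identical(assign_isoform_bin(2452, 4), "AFGP8")
  expect_identical(assign_isoform_bin(3061, 5), "AFGP7")
  expect_identical(assign_isoform_bin(1235, 2), "sub_AFGP")
  expect_identical(assign_isoform_bin(5495, 9), "AFGP6_group")
  expect_identical(assign_isoform_bin(20101, 33), "AFGP1_5_group")
  expect_identical(assign_isoform_bin(32273, 53), "AFGP1_5_group")
  # boundary: the 9.2 kDa midpoint of the gel gap separates the groups
  expect_identical(assign_isoform_bin(9199, 14), "AFGP6_group")
  expect_identical(assign_isoform_bin(9200, 14), "AFGP1_5_group")
})

test_that("gene classification separates intact genes from the three lesion types", {
  units <- rep(UNIT_TAA, 20)
  cds <- make_cds(units)
  seq0 <- paste0(strrep("ACGT", 10), cds, strrep("GGCC", 8))
  g <- gene_record("sp_ok", seq0, 40, 40 + nchar(cds))
  expect_identical(classify_gene(g)$status, "functional")

  # 1-nt deletion 10 nt upstream of the repeats: frameshift
  cut <- 40 + nchar(cds) - nchar("GGATTATTCTGA") - 9 * 20 - 10
  seq_fs <- paste0(substr(seq0, 1, cut - 1), substr(seq0, cut + 1, nchar(seq0)))
  g_fs <- gene_record("sp_fs", seq_fs, 40, 40 + nchar(cds) - 1)
  cls_fs <- classify_gene(g_fs)
  expect_identical(cls_fs$status, "pseudogene")
  expect_identical(cls_fs$pseudogene_reason, "frameshift_indel")

  # start codon and leader removed: 5' truncated
  cds_tr <- sub("^ATG", "", cds)
  cds_tr <- substr(cds_tr, 34, nchar(cds_tr))
  seq_tr <- paste0(strrep("ACGT", 10), cds_tr, strrep("GGCC", 8))
  g_tr <- gene_record("sp_tr", seq_tr, 40, 40 + nchar(cds_tr))
  cls_tr <- classify_gene(g_tr)
  expect_identical(cls_tr$status, "pseudogene")
  expect_identical(cls_tr$pseudogene_reason, "five_prime_truncated")

  # long insertion splitting the tract
  ins <- withr::with_seed(8, random_nonrepeat_dna(60))
  ins <- strrep(ins, 12)                       # 720 nt > 500 nt threshold
  mid <- 40 + nchar(cds) - nchar("GGATTATTCTGA") - 9 * 10
  seq_in <- paste0(substr(seq0, 1, mid), ins,
                   substr(seq0, mid + 1, nchar(seq0)))
  g_in <- gene_record("sp_in", seq_in, 40, 40 + nchar(cds) + nchar(ins))
  cls_in <- classify_gene(g_in)
  expect_identical(cls_in$status, "pseudogene")
  expect_identical(cls_in$pseudogene_reason, "coding_insertion")

  # no repeats at all: reported non-AFGP, not an error
  g_no <- withr::with_seed(12, gene_record("sp_no", random_nonrepeat_dna(200), 0, 198))
  expect_identical(classify_gene(g_no)$status, "non_AFGP")
})

test_that("functional calls agree with a brute-force ORF scanner on small fixtures", {
  withr::with_seed(23, {
    for (i in 1:40) {
      n_units <- sample(4:30, 1)
      cds <- make_cds(rep(UNIT_TAA, n_units))
      # randomly corrupt: maybe delete 1 nt, maybe drop the start codon
      lesion <- sample(c("none", "del", "nostart"), 1)
      if (lesion == "del") {
        p <- sample(10:30, 1)
        cds <- paste0(substr(cds, 1, p - 1), substr(cds, p + 1, nchar(cds)))
      } else if (lesion == "nostart") {
        cds <- substr(cds, 4, nchar(cds))
      }
      g <- gene_record("sp_x", cds, 0, nchar(cds))
      region <- find_repeat_region(cds)
      got <- classify_gene(g, region)
      want <- oracle_orf_covers(cds, region$cds_offset_start,
                                region$cds_offset_end)
      expect_identical(got$status == "functional", want,
                       info = paste("case", i, lesion))
    }
  })
})

test_that("family_summary aggregates per species with composition percentages", {
  cds <- make_cds(c(rep(UNIT_TAA, 10), UNIT_KAA, rep(UNIT_TAA, 6)))
  g <- gene_record("Bs_g1", cds, 0, nchar(cds))
  res <- list(process_gene(g))
  fam <- family_summary(res)
  expect_identical(nrow(fam), 1L)
  expect_identical(fam$n_genes, 1L)
  expect_identical(fam$n_functional, 1L)
  expect_identical(fam$n_isoforms, 2L)
  expect_identical(fam$repeats_min, 6L)
  expect_identical(fam$repeats_max, 10L)
  # 17 units, 16 Thr + 1 Lys at position 1, rest Ala
  expect_equal(fam$pct_T, 100 * 16 / 51)
  expect_equal(fam$pct_K, 100 * 1 / 51)
  expect_equal(fam$pct_A, 100 * 34 / 51)

  expect_identical(nrow(family_summary(list())), 0L)
})
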