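test_that("p and JC69 distances match their closed forms", {
  a <- strrep("ACGT", 25)                       # 100 nt
  b <- a
  # introduce exactly 10 mismatches
  for (p in seq(1, 100, by = 10)) {
    substr(b, p, p) <- if (substr(a, p, p) == "A") "C" else "A"
  }
  d <- pairwise_distance(c(x = a, y = b), model = "p")
  expect_equal(d["x", "y"], 0.10)
  expect_equal(d["x", "x"], 0)
  dj <- pairwise_distance(c(x = a, y = b), model = "JC69")
  expect_equal(dj["x", "y"], -0.75 * log(1 - 0.4 / 3))
  expect_lt(abs(dj["x", "y"] - 0.1073), 1e-4)
})

test_that("gap/N columns are pairwise-deleted and saturation is capped with warning", {
  d <- pairwise_distance(c(x = "ACGTACGTNN", y = "ACGAACG-AA"), model = "p")
  # 7 comparable sites, 1 mismatch
  expect_equal(d["x", "y"], 1 / 7)
  expect_warning(
    ds <- pairwise_distance(c(x = "AAAAAAAAAA", y = "CCCCCCCCCC"),
                            model = "JC69", cap = 4),
    "capped")
  expect_equal(ds["x", "y"], 4)
})

test_that("distances agree with ape::dist.dna under pairwise deletion", {
  seqs <- withr::with_seed(61, {
    base <- paste(sample(c("a", "c", "g", "t"), 300, replace = TRUE),
                  collapse = "")
    vapply(1:5, function(i) {
      s <- base
      for (p in sample(300, 25)) {
        substr(s, p, p) <- sample(c("a", "c", "g", "t"), 1)
      }
      s
    }, "")
  })
  names(seqs) <- paste0("s", 1:5)
  ours <- pairwise_distance(toupper(seqs), model = "JC69")
  bin <- ape::as.DNAbin(t(sapply(strsplit(seqs, ""), identity)))
  theirs <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                    pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(theirs[rownames(ours), colnames(ours)]),
               tolerance = 1e-10)
})

test_that("neighbor joining recovers additive distances exactly", {
  withr::with_seed(71, {
    for (n in 4:8) {
      for (rep in 1:4) {
        true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
        true$tip.label <- sprintf("t%02d", seq_len(n))
        dm <- ape::cophenetic.phylo(true)
        dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
        got <- nj_tree(dm)
        # additive matrices determine a unique tree: the induced path
        # distances of the reconstruction must reproduce the input...
        induced <- ape::cophenetic.phylo(got$phylo)
        expect_equal(unname(induced[rownames(dm), colnames(dm)]),
                     unname(dm), tolerance = 1e-8)
        # ...and the topology must match the generating tree
        expect_identical(rf_distance(got, true), 0L)
        # independent implementation cross-check
        expect_identical(rf_distance(got$phylo, ape::nj(as.dist(dm))), 0L)
      }
    }
  })
})

test_that("four-leaf NJ picks the right topology among the three possible", {
  # additive on ((a,b),(c,d)): a-b = 2, c-d = 2, across = 6
  dm <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4, 4,
               dimnames = list(c("a", "b", "c", "d"),
                               c("a", "b", "c", "d")))
  got <- nj_tree(dm)$phylo
  candidates <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  rfs <- vapply(candidates, function(nwk)
    rf_distance(got, ape::read.tree(text = nwk)), 0L)
  expect_identical(unname(rfs), c(0L, 2L, 2L))
})

test_that("degenerate trees for fewer than four leaves are well-formed", {
  dm3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(dm3)
  expect_identical(sort(t3$phylo$tip.label), c("a", "b", "c"))
  # closed-form branch lengths of the star resolution:
  # b_a = (2+4-4)/2 = 1, b_b = 1, b_c = 3
  expect_equal(sort(t3$phylo$edge.length), c(1, 1, 3))

  dm2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(dm2)
  expect_identical(sort(t2$phylo$tip.label), c("a", "b"))
})

test_that("NJ output is deterministic under label-order permutations", {
  withr::with_seed(81, {
    true <- ape::rtree(6)
    dm <- ape::cophenetic.phylo(true)
    base <- nj_tree(dm)$newick
    for (i in 1:5) {
      perm <- sample(rownames(dm))
      expect_identical(nj_tree(dm[perm, perm])$newick, base)
    }
  })
})

test_that("simulated families with divergent flanks yield the true topology", {
  sim <- simulate_family(sim_config(seed = 7, generations = 100,
                                    gene_duplication_rate = 0.025,
                                    flank_substitution_rate = 2e-3,
                                    substitution_rate = 0,
                                    pseudogenization_rate = 0))
  expect_gte(length(sim$records), 4)
  run <- sim_to_pipeline(sim)
  true_tree <- ape::read.tree(text = sim$truth$tree_newick)
  expect_identical(rf_distance(true_tree, run$tree5), 0L)
})

test_that("ortholog assignment follows cherries plus C-terminus agreement", {
  t5 <- structure(list(newick = "((spA_g1:1,spB_g1:1):2,(spA_g2:1,spB_g2:1):2,spA_g3:4);",
                       phylo = ape::read.tree(
                         text = "((spA_g1:1,spB_g1:1):2,(spA_g2:1,spB_g2:1):2,spA_g3:4);")),
                  class = "family_tree")
  t3 <- t5
  cterm <- c(spA_g1 = "GLF", spB_g1 = "GLF", spA_g2 = "GLF", spB_g2 = "GVF",
             spA_g3 = "GLF")
  pairs <- assign_orthologs(t5, t3, cterm)
  # g2 pair is a cherry in both trees but the C-termini differ
  expect_identical(pairs$gene_a, "spA_g1")
  expect_identical(pairs$gene_b, "spB_g1")
  expect_identical(pairs$evidence, "both_trees")

  # one leaf missing from the 3' tree: 5' cherry + matching C-terminus suffices
  t3b <- structure(list(phylo = ape::read.tree(
    text = "((spA_g2:1,spB_g2:1):2,spA_g3:4,spB_g1:1);")),
    class = "family_tree")
  t3b$newick <- ape::write.tree(t3b$phylo)
  expect_warning(pairs2 <- assign_orthologs(t5, t3b, cterm), "leaf sets")
  expect_true(any(pairs2$gene_a == "spA_g1" & pairs2$gene_b == "spB_g1"))
  expect_identical(pairs2$evidence[pairs2$gene_a == "spA_g1"], "tree5")

  # a contradicting cross-species cherry in the other tree vetoes the pair
  t3c <- structure(list(phylo = ape::read.tree(
    text = "((spA_g1:1,spB_g2:1):2,(spA_g2:1,spB_g1:1):2,spA_g3:4);")),
    class = "family_tree")
  t3c$newick <- ape::write.tree(t3c$phylo)
  cterm_all <- c(spA_g1 = "GLF", spB_g1 = "GLF", spA_g2 = "GLF",
                 spB_g2 = "GLF", spA_g3 = "GLF")
  pairs3 <- assign_orthologs(t5, t3c, cterm_all)
  expect_false(any(pairs3$gene_a == "spA_g1" & pairs3$gene_b == "spB_g1" &
                     pairs3$evidence == "both_trees"))
})

test_that("ortholog assignment is symmetric and order-invariant on simulated families", {
  sim <- simulate_family(sim_config(seed = 31, generations = 65,
                                    speciation_time = 55,
                                    gene_duplication_rate = 0.03,
                                    flank_substitution_rate = 2e-3,
                                    substitution_rate = 0,
                                    pseudogenization_rate = 0))
  run <- sim_to_pipeline(sim)
  truth_pairs <- sim$truth$ortholog_pairs
  expect_gte(nrow(truth_pairs), 1)
  got <- run$orthologs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  gk <- key(got$gene_a, got$gene_b)
  tk <- key(truth_pairs$gene_a, truth_pairs$gene_b)
  # every truth pair recovered; every reported pair real
  expect_true(all(tk %in% gk))
  expect_true(all(gk %in% tk))
})

test_that("ortholog recall degrades once flank divergence saturates", {
  # replicates too small to build a tree (fewer than 3 genes) or with no
  # surviving one-to-one ortholog pair carry no information about recall
  recall_at <- function(rate, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_family(sim_config(seed = s, generations = 65,
                                        speciation_time = 55,
                                        gene_duplication_rate = 0.03,
                                        flank_substitution_rate = rate,
                                        substitution_rate = 0,
                                        pseudogenization_rate = 0))
      truth_pairs <- sim$truth$ortholog_pairs
      if (nrow(truth_pairs) == 0 || length(sim$records) < 4) {
        return(NA_real_)
      }
      run <- suppressWarnings(sim_to_pipeline(sim))
      got <- run$orthologs
      if (is.null(got) || nrow(got) == 0) return(0)
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      mean(key(truth_pairs$gene_a, truth_pairs$gene_b) %in%
             key(got$gene_a, got$gene_b))
    }, 0), na.rm = TRUE)
  }
  seeds <- 301:306
  lo <- recall_at(5e-3, seeds)    # clear signal, far from saturation
  hi <- recall_at(0.3, seeds)     # ortholog flanks themselves saturate
  expect_gte(lo, hi)
  expect_lt(hi, 1)
})

test_that("expansion order flags basal pseudogenes and unique duplicon edges", {
  # one pseudogene with a 3x terminal branch
  nwk <- "((g1:6,g2:1):1,(g3:1,g4:1):1,g5:1);"
  tree <- structure(list(newick = nwk, phylo = ape::read.tree(text = nwk)),
                    class = "family_tree")
  genes <- paste0("g", 1:5)
  clusters <- setNames(c("I", "I", "II", "II", "I"), genes)
  flank <- matrix(0.2, 5, 5, dimnames = list(genes, genes))
  flank["g2", "g3"] <- flank["g3", "g2"] <- 1.3
  ev <- expansion_order(tree, pseudogenes = "g1", clusters = clusters,
                        shared_flank = flank)
  expect_identical(ev$type, c("basal_candidate", "duplicon"))
  expect_identical(ev$to[ev$type == "basal_candidate"], "g1")
  dup <- ev[ev$type == "duplicon", ]
  expect_identical(dup$from, "g2")   # cluster I holds the basal pseudogene
  expect_identical(dup$to, "g3")

  # star tree with uniform flanks: nothing resolvable
  star <- ape::read.tree(text = "(g1:1,g2:1,g3:1,g4:1,g5:1);")
  ev0 <- expansion_order(star, pseudogenes = "g1", clusters = clusters,
                         shared_flank = matrix(0.2, 5, 5,
                                               dimnames = list(genes, genes)))
  expect_identical(nrow(ev0), 0L)

  dot <- expansion_dot(ev)
  expect_match(dot[1], "digraph")
  expect_true(any(grepl("g2.*->.*g3", dot)))
})
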