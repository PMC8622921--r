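# family_evolution: gene-family trees from non-repetitive 5'/3' flanking
# sequence, ortholog assignment across species, and duplication-order
# inference.
#
# The repetitive coding tract cannot be aligned with confidence, so the
# family history is read from the flanks.  Distance-based neighbor joining is
# used for tree inference; it is implemented here (rather than delegated)
# because downstream results must be deterministic given input order, with
# Q-criterion ties broken by lexicographic label pair.  ape::nj serves as an
# independent cross-check in the test suite.

#' Pairwise distances between equal-length flank sequences
#'
#' Computes p-distances (mismatches / valid sites) or Jukes-Cantor 1969
#' distances (`-3/4 * log(1 - 4p/3)`) under pairwise deletion: positions
#' where either sequence has a gap (`-`) or `N` are ignored for that pair.
#' Saturated JC distances (p >= 0.75) are reported as `cap` with a warning.
#'
#' @param seqs named character vector of aligned (equal-length) sequences.
#' @param model `"p"` or `"JC69"`.
#' @param cap value substituted for undefined (saturated) JC distances.
#' @return symmetric numeric matrix with zero diagonal, labelled by sequence
#'   name.
#' @export
#' @examples
#' pairwise_distance(c(a = "ACGTACGTAC", b = "ACGTACGTAA"), model = "p")
pairwise_distance <- function(seqs, model = c("p", "JC69"), cap = 5) {
  model <- match.arg(model)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be pre-aligned to equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  valid <- !(mat == "-" | mat == "N" | mat == ".")
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      ns <- sum(ok)
      p <- if (ns == 0L) NA_real_ else sum(mat[i, ok] != mat[j, ok]) / ns
      if (is.na(p)) p <- 0
      dij <- if (model == "p") p else if (p < 0.75) -0.75 * log(1 - 4 * p / 3)
             else { saturated <- TRUE; cap }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (saturated) {
    warning(sprintf("saturated JC69 distance(s) capped at %g", cap),
            call. = FALSE)
  }
  d
}

# Deterministic neighbor joining.  Active nodes carry a sort key = the
# lexicographically smallest leaf label in their clade (radix order, locale
# independent); Q-ties pick the smallest (key_i, key_j) pair.
nj_build <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  frag <- labels                # newick fragment per active node
  key <- labels
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- cbind(pmin(key[cand[, 1]], key[cand[, 2]]),
                       pmax(key[cand[, 1]], key[cand[, 2]]))
    o <- order(pair_keys[, 1], pair_keys[, 2], method = "radix")[1]
    i <- cand[o, 1]; j <- cand[o, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    kids <- if (key[i] <= key[j]) {
      sprintf("%s:%s,%s:%s", frag[i], fmt(bi), frag[j], fmt(bj))
    } else {
      sprintf("%s:%s,%s:%s", frag[j], fmt(bj), frag[i], fmt(bi))
    }
    new_frag <- sprintf("(%s)", kids)
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    rownames(d2) <- colnames(d2) <- key
    d <- d2
    n <- n - 1L
  }
  if (n == 3L) {
    b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    o <- order(key, method = "radix")
    b <- c(b1, b2, b3)[o]
    sprintf("(%s:%s,%s:%s,%s:%s);",
            frag[o[1]], fmt(b[1]), frag[o[2]], fmt(b[2]),
            frag[o[3]], fmt(b[3]))
  } else if (n == 2L) {
    o <- order(key, method = "radix")
    sprintf("(%s:%s,%s:%s);", frag[o[1]], fmt(d[1, 2] / 2),
            frag[o[2]], fmt(d[1, 2] / 2))
  } else {
    sprintf("%s;", frag[1])
  }
}

#' Neighbor-joining gene-family tree
#'
#' Standard neighbor joining on a distance matrix, deterministic given the
#' input: ties in the Q criterion are broken by the lexicographically
#' smallest pair of clade labels.  Fewer than 3 leaves yield a degenerate
#' (but valid) tree rather than an error.
#'
#' @param d symmetric distance matrix with unique row/column names, e.g.
#'   from [pairwise_distance()].
#' @return a `family_tree`: list with `newick` (string) and `phylo`
#'   (an [ape::read.tree()] object).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 1L,
            !is.null(rownames(d)))
  if (anyDuplicated(rownames(d))) stop("duplicate leaf labels", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric",
                                      call. = FALSE)
  nwk <- nj_build(d)
  structure(list(newick = nwk, phylo = ape::read.tree(text = nwk)),
            class = "family_tree")
}

#' @export
print.family_tree <- function(x, ...) {
  cat(sprintf("<family_tree> %d leaves\n", length(x$phylo$tip.label)))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Write a family tree to a newick file
#' @param tree a `family_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "family_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Nonparametric bootstrap over alignment columns: columns are resampled
#' with replacement, distances and the NJ tree recomputed, and clade
#' frequencies counted on the original topology.
#'
#' @param seqs named character vector of aligned sequences.
#' @param model distance model, see [pairwise_distance()].
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed (restores the caller's RNG state).
#' @return a `family_tree` whose `phylo` carries node labels with bootstrap
#'   percentages and an extra `support` element.
#' @export
nj_bootstrap <- function(seqs, model = "JC69", replicates = 100L, seed = 1L) {
  base <- nj_tree(pairwise_distance(seqs, model))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      s <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      nj_tree(pairwise_distance(s, model))$phylo
    })
  })
  counts <- ape::prop.clades(base$phylo, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base$phylo$node.label <- round(100 * counts / replicates)
  base$support <- base$phylo$node.label
  base
}

#' Robinson-Foulds distance between two trees
#'
#' Computed on the shared leaf set after unrooting; trees with fewer than 4
#' shared leaves have a single unrooted topology and distance 0.
#'
#' @param a,b `family_tree` objects or `phylo` objects.
#' @return non-negative integer.
#' @export
rf_distance <- function(a, b) {
  pa <- if (inherits(a, "family_tree")) a$phylo else a
  pb <- if (inherits(b, "family_tree")) b$phylo else b
  common <- intersect(pa$tip.label, pb$tip.label)
  if (length(common) < 4L) return(0L)
  pa <- ape::keep.tip(pa, common)
  pb <- ape::keep.tip(pb, common)
  as.integer(round(ape::dist.topo(ape::unroot(pa), ape::unroot(pb),
                                  method = "PH85")))
}

# Leaf pairs forming cherries (two-tip clades) of a phylo tree.
tree_cherries <- function(phylo) {
  if (length(phylo$tip.label) < 2L) {
    return(tibble(tip_a = character(0), tip_b = character(0)))
  }
  if (length(phylo$tip.label) == 2L) {
    t <- sort(phylo$tip.label, method = "radix")
    return(tibble(tip_a = t[1], tip_b = t[2]))
  }
  ntip <- length(phylo$tip.label)
  edge <- phylo$edge
  out <- list()
  for (node in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == node, 2]
    tipkids <- kids[kids <= ntip]
    if (length(kids) == 2L && length(tipkids) == 2L) {
      t <- sort(phylo$tip.label[tipkids], method = "radix")
      out[[length(out) + 1L]] <- tibble(tip_a = t[1], tip_b = t[2])
    }
  }
  if (length(out) == 0L) {
    return(tibble(tip_a = character(0), tip_b = character(0)))
  }
  bind_rows(out)
}

leaf_species <- function(leaf, sep = "_") sub(paste0(sep, ".*$"), "", leaf)

#' Assign cross-species orthologs from 5' and 3' gene trees
#'
#' A cross-species pair is called orthologous when (a) the two genes are
#' sisters (form a cherry) in at least one tree and are not contradicted in
#' the other — contradicted meaning the other tree places either gene in a
#' cross-species cherry with a different partner — and (b) their
#' characteristic C-terminus signatures match exactly.  Genes missing from
#' one tree (e.g. pseudogenes whose flank was excluded) are evaluated on the
#' tree that contains them.
#'
#' @param tree5,tree3 `family_tree`s built from the 5' and 3' non-repetitive
#'   regions; leaves named `species_gene`.
#' @param cterm named character vector, gene id -> C-terminus residue string.
#' @param sep separator between species tag and gene name in leaf labels.
#' @return tibble: `gene_a`, `gene_b`, `species_a`, `species_b`, `evidence`
#'   (`both_trees` / `tree5` / `tree3`), sorted by gene pair.
#' @export
assign_orthologs <- function(tree5, tree3, cterm, sep = "_") {
  p5 <- if (inherits(tree5, "family_tree")) tree5$phylo else tree5
  p3 <- if (inherits(tree3, "family_tree")) tree3$phylo else tree3
  if (!setequal(p5$tip.label, p3$tip.label)) {
    warning("leaf sets differ between the 5' and 3' trees; ",
            "pairs are evaluated where evidence exists", call. = FALSE)
  }
  ch5 <- tree_cherries(p5)
  ch3 <- tree_cherries(p3)
  cross <- function(ch) {
    ch[leaf_species(ch$tip_a, sep) != leaf_species(ch$tip_b, sep), ,
       drop = FALSE]
  }
  x5 <- cross(ch5); x3 <- cross(ch3)
  pair_key <- function(ch) paste(ch$tip_a, ch$tip_b, sep = "\r")
  # contradiction: the other tree pairs either gene with a different
  # cross-species partner
  contradicted <- function(a, b, other_cross, other_leaves) {
    if (!(a %in% other_leaves) || !(b %in% other_leaves)) return(FALSE)
    inv <- (other_cross$tip_a == a | other_cross$tip_b == a |
            other_cross$tip_a == b | other_cross$tip_b == b) &
      !(other_cross$tip_a == a & other_cross$tip_b == b)
    any(inv)
  }
  cand <- unique(rbind(x5, x3))
  if (nrow(cand) == 0L) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  species_a = character(0), species_b = character(0),
                  evidence = character(0)))
  }
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand$tip_a[k]; b <- cand$tip_b[k]
    in5 <- pair_key(cand[k, ]) %in% pair_key(x5)
    in3 <- pair_key(cand[k, ]) %in% pair_key(x3)
    ok5 <- in5 && !contradicted(a, b, x3, p3$tip.label)
    ok3 <- in3 && !contradicted(a, b, x5, p5$tip.label)
    if (!(ok5 || ok3)) next
    ca <- cterm[a]; cb <- cterm[b]
    if (is.na(ca) || is.na(cb) || ca != cb) next
    rows[[length(rows) + 1L]] <- tibble(
      gene_a = a, gene_b = b,
      species_a = leaf_species(a, sep), species_b = leaf_species(b, sep),
      evidence = if (in5 && in3) "both_trees" else if (in5) "tree5" else "tree3")
  }
  if (length(rows) == 0L) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  species_a = character(0), species_b = character(0),
                  evidence = character(0)))
  }
  out <- bind_rows(rows)
  out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
}

# Terminal branch length of every tip.
tip_lengths <- function(phylo) {
  ntip <- length(phylo$tip.label)
  idx <- match(seq_len(ntip), phylo$edge[, 2])
  setNames(phylo$edge.length[idx], phylo$tip.label)
}

#' Order of gene-family duplication events
#'
#' Applies two deterministic rules to a gene tree and per-pair shared-flank
#' lengths:
#'
#' 1. *Basal candidates*: pseudogene leaves whose terminal branch length
#'    exceeds `basal_factor` times the median of all other terminal branches
#'    — selective release lets the oldest (pre-duplication) copies accumulate
#'    substitutions fastest.
#' 2. *Immediate duplicon edges*: for each pair of gene clusters, the unique
#'    cross-cluster gene pair with strictly maximal shared flanking-sequence
#'    length marks the duplication that seeded the younger cluster.  No edge
#'    is emitted when the maximum is not unique (unresolvable).
#'
#' @param tree a `family_tree` (or `phylo`).
#' @param pseudogenes character vector of pseudogene leaf ids.
#' @param clusters named character/integer vector mapping gene id -> cluster.
#' @param shared_flank symmetric named matrix of shared flank lengths (nt).
#' @param basal_factor branch-length multiple above which a pseudogene is
#'   called basal.
#' @return tibble of events: `type` (`basal_candidate` / `duplicon`),
#'   `from`, `to`, `rationale`; zero rows when nothing is resolvable.
#' @export
expansion_order <- function(tree, pseudogenes = character(0),
                            clusters = NULL, shared_flank = NULL,
                            basal_factor = 2) {
  phylo <- if (inherits(tree, "family_tree")) tree$phylo else tree
  events <- list()
  tl <- tip_lengths(phylo)
  basal <- character(0)
  for (g in intersect(pseudogenes, names(tl))) {
    others <- tl[setdiff(names(tl), g)]
    if (length(others) && !is.na(tl[g]) &&
        tl[g] > basal_factor * median(others, na.rm = TRUE)) {
      basal <- c(basal, g)
      events[[length(events) + 1L]] <- tibble(
        type = "basal_candidate", from = NA_character_, to = g,
        rationale = sprintf(
          "pseudogene terminal branch %.4g > %g x median (%.4g) of other leaves",
          tl[g], basal_factor, median(others, na.rm = TRUE)))
    }
  }
  if (!is.null(clusters) && !is.null(shared_flank)) {
    ids <- intersect(names(clusters), rownames(shared_flank))
    cl <- clusters[ids]
    for (pair in utils::combn(sort(unique(as.character(cl)), method = "radix"),
                              2, simplify = FALSE)) {
      a_ids <- ids[cl == pair[1]]
      b_ids <- ids[cl == pair[2]]
      sub <- shared_flank[a_ids, b_ids, drop = FALSE]
      m <- max(sub)
      if (!is.finite(m) || m <= 0 || sum(sub == m) != 1L) next
      w <- which(sub == m, arr.ind = TRUE)
      ga <- a_ids[w[1, 1]]; gb <- b_ids[w[1, 2]]
      # direct the edge out of the cluster holding a basal candidate (the
      # older cluster); fall back to lexicographic order
      a_basal <- any(basal %in% a_ids)
      b_basal <- any(basal %in% b_ids)
      if (a_basal && !b_basal) { from <- ga; to <- gb }
      else if (b_basal && !a_basal) { from <- gb; to <- ga }
      else { ord <- sort(c(ga, gb), method = "radix"); from <- ord[1]; to <- ord[2] }
      events[[length(events) + 1L]] <- tibble(
        type = "duplicon", from = from, to = to,
        rationale = sprintf(
          "unique maximal shared flank (%g nt) between clusters %s and %s",
          m, pair[1], pair[2]))
    }
  }
  if (length(events) == 0L) {
    return(tibble(type = character(0), from = character(0),
                  to = character(0), rationale = character(0)))
  }
  bind_rows(events)
}

#' DOT export of an expansion-event table
#' @param events tibble from [expansion_order()].
#' @return character vector of DOT lines.
#' @export
expansion_dot <- function(events) {
  body <- vapply(seq_len(nrow(events)), function(i) {
    if (events$type[i] == "basal_candidate") {
      sprintf('  "%s" [shape=box,label="%s (basal)"];',
              events$to[i], events$to[i])
    } else {
      sprintf('  "%s" -> "%s";', events$from[i], events$to[i])
    }
  }, "")
  c("digraph expansion {", body, "}")
}
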