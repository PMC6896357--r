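test_that("internal aligner agrees with the exhaustive gap-enumeration DP on random pairs", {
  set.seed(101)
  aa <- rownames(.blosum62)[1:20]
  for (r in 1:5) {
    s1 <- random_protein(30); s2 <- random_protein(30)
    pw <- compute_pairwise(c(a = s1, b = s2), mode = "internal")
    ab <- pw[pw$query_id == "a" & pw$subject_id == "b", ]
    # invert the bitscore transform to recover the raw alignment score
    raw <- (ab$bitscore * log(2) + log(0.041)) / 0.267
    expect_equal(raw, brute_sw_score(s1, s2), tolerance = 1e-8)
  }
})

test_that("pairwise scores are symmetric and self-pairs have identity 100", {
  set.seed(7)
  seqs <- setNames(vapply(1:4, function(i) random_protein(60), character(1)),
                   paste0("g", 1:4))
  pw <- compute_pairwise(seqs, mode = "internal")
  for (i in names(seqs)) for (j in names(seqs)) {
    sij <- pw$bitscore[pw$query_id == i & pw$subject_id == j]
    sji <- pw$bitscore[pw$query_id == j & pw$subject_id == i]
    expect_equal(sij, sji)
  }
  selfs <- pw[pw$query_id == pw$subject_id, ]
  expect_equal(nrow(selfs), 4)
  expect_true(all(selfs$percent_identity == 100))
  # identical sequences align at identity 100
  pw2 <- compute_pairwise(c(x = "MKVLAWGHE", y = "MKVLAWGHE"), mode = "internal")
  expect_equal(pw2$percent_identity[pw2$query_id == "x" & pw2$subject_id == "y"], 100)
})

test_that("homology filter is strictly 'more than' the identity threshold", {
  p <- data.frame(query_id = c("a", "a", "a"), subject_id = c("b", "c", "d"),
                  bitscore = 1, evalue = 0,
                  percent_identity = c(30.0, 30.1, 12), alignment_length = 100L)
  e <- homology_filter(p)
  expect_equal(nrow(e), 1)
  expect_equal(e$b, "c")
  expect_equal(nrow(homology_filter(p, min_identity = 99)), 0)
})

test_that("H-score is the bitscore normalized by the smaller self-score", {
  p <- data.frame(query_id = c("a", "b", "a"), subject_id = c("a", "b", "b"),
                  bitscore = c(500, 400, 200), evalue = 0,
                  percent_identity = 100, alignment_length = 100L)
  H <- h_score(p)
  expect_equal(H["a", "b"], 0.5)       # 200 / min(500, 400)
  expect_equal(H["b", "a"], 0.5)
  expect_equal(diag(H), c(a = 1, b = 1))
  # absent pair -> 0
  p2 <- rbind(p[1:2, ], data.frame(query_id = "c", subject_id = "c",
                                   bitscore = 300, evalue = 0,
                                   percent_identity = 100, alignment_length = 100L))
  expect_equal(h_score(p2)["a", "c"], 0)
  expect_error(h_score(p[3, ]), "self-score")
})

test_that("family clustering matches brute-force average-linkage recomputation", {
  set.seed(33)
  for (r in 1:5) {
    n <- 8
    ids <- paste0("g", 1:n)
    H <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    H <- (H + t(H)) / 2; diag(H) <- 1
    for (cutoff in c(0.3, 0.5, 0.7)) {
      fam <- cluster_families(H, cutoff)$family
      oracle <- brute_average_linkage(1 - H, h = 1 - cutoff)
      # same partition up to label renaming
      expect_equal(length(unique(fam)), length(unique(oracle)))
      agree <- outer(fam[ids], fam[ids], "==") == outer(oracle, oracle, "==")
      expect_true(all(agree))
    }
  }
})

test_that("clustering limits: cutoff 1 isolates every gene, cutoff 0 joins connected components", {
  ids <- c("a", "b", "c")
  H <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3, dimnames = list(ids, ids))
  expect_equal(unname(cluster_families(H, 0.5)$family), c(1, 1, 2))
  expect_equal(length(unique(cluster_families(H, 1.0)$family)), 3)
  # cutoff 0: one family per connected component with H > 0; c is isolated
  expect_equal(unname(cluster_families(H, 0)$family), c(1, 1, 2))
  expect_equal(length(cluster_families(matrix(numeric(0), 0, 0))$family), 0)
})

test_that("family assignment is invariant to gene input order", {
  set.seed(12)
  n <- 10; ids <- paste0("g", sprintf("%02d", 1:n))
  H <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  H <- (H + t(H)) / 2; diag(H) <- 1
  f1 <- cluster_families(H, 0.5)$family
  perm <- sample(n)
  f2 <- cluster_families(H[perm, perm], 0.5)$family
  expect_identical(f1[sort(ids)], f2[sort(ids)])
})

test_that("NJ recovers the closed-form three-taxon branch lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)   # (d_AB + d_AC - d_BC)/2
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers additive matrices from random trees", {
  set.seed(55)
  for (r in 1:50) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D[tr$tip.label, tr$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[tr$tip.label, tr$tip.label], D,
                 tolerance = 1e-8)
  }
})

test_that("on ultrametric distances the NJ topology matches UPGMA's", {
  set.seed(77)
  for (r in 1:10) {
    tr <- ape::rcoal(6)
    D <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(D)
    up <- ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
    expect_equal(ape::dist.topo(nj, ape::unroot(up)), 0, ignore_attr = TRUE)
  }
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister edge", {
  # deliberately non-additive, near-degenerate matrix that drives ape's NJ negative
  set.seed(3)
  found <- FALSE
  for (r in 1:50) {
    n <- 5
    D <- matrix(runif(n * n, 0.1, 1), n, n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    raw <- ape::nj(stats::as.dist(D))
    if (any(raw$edge.length < 0)) {
      found <- TRUE
      tr <- nj_tree(D)
      expect_true(all(tr$edge.length >= 0))
      expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
    }
  }
  expect_true(found)
})

test_that("bootstrap support is deterministic, 100 for universally supported splits, and stable in reps", {
  # every column carries the same AB|CD pattern
  aln <- c(A = strrep("AR", 20), B = strrep("AR", 20),
           C = strrep("ND", 20), D = strrep("ND", 20))
  bs <- bootstrap_support(aln, n_reps = 50, seed = 5)
  expect_equal(unname(bs$support), 100)

  set.seed(99)
  fam <- replicate(6, random_protein(80))
  names(fam) <- paste0("t", 1:6)
  b1 <- bootstrap_support(fam, n_reps = 100, seed = 42)
  b2 <- bootstrap_support(fam, n_reps = 100, seed = 42)
  expect_identical(b1$support, b2$support)
  b3 <- bootstrap_support(fam, n_reps = 1000, seed = 42)
  expect_true(all(abs(b1$support - b3$support) <= 10))
  expect_error(bootstrap_support(c(A = "M", B = "M", C = "M")), "2 columns")
})

test_that("Wagner parsimony reproduces the hand-checked example and labels expansions", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  ac <- ancestral_counts(tr, c(A = 3, B = 1, C = 1))
  ntip <- 3
  root <- ntip + 1
  expect_equal(ac$total_cost, 2)
  expect_equal(ac$node_counts[root], 1)
  inner <- setdiff(unique(ac$events$parent_node), root)
  expect_equal(ac$node_counts[inner], 1)

  # all-equal leaves: zero cost, all ancestors equal
  ac2 <- ancestral_counts(tr, c(A = 4, B = 4, C = 4))
  expect_equal(ac2$total_cost, 0)
  expect_true(all(ac2$node_counts[(ntip + 1):(ntip + 2)] == 4))
  expect_true(all(ac2$events$event == "stable"))

  # a 17 -> 47 branch is an expansion of +30
  ac3 <- ancestral_counts(tr, c(A = 47, B = 47, C = 17))
  ev <- ac3$events
  e <- ev[ev$parent_count == 17 & ev$child_count == 47, ][1, ]
  expect_equal(e$event, "expansion")
  expect_equal(e$change, 30)
  expect_error(ancestral_counts(tr, c(A = 1, B = 1)), "missing leaf")
})

test_that("Wagner parsimony cost equals exhaustive enumeration on small trees", {
  set.seed(21)
  for (r in 1:20) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    counts <- setNames(sample(0:6, n, replace = TRUE), tr$tip.label)
    ac <- ancestral_counts(tr, counts)
    expect_equal(ac$total_cost, brute_wagner_cost(tr, counts))
    # the reported assignment realizes the reported cost
    realized <- sum(abs(ac$node_counts[ac$events$parent_node] -
                        ac$node_counts[ac$events$child_node]))
    expect_equal(realized, ac$total_cost)
    expect_equal(unname(ac$node_counts[seq_len(n)]),
                 unname(counts[tr$tip.label]))
  }
})

test_that("lineage specificity separates within-species clustering from interleaving", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  expect_equal(lineage_specificity(t1, sp), 1.0)
  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(lineage_specificity(t2, sp), 0.0)
  t3 <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:1):1,b2:1);")
  expect_equal(lineage_specificity(t3, sp), 0.5)
})

test_that("expansion fixtures score high lineage specificity; no-expansion cohorts score zero", {
  pooled <- numeric(0); base <- numeric(0)
  for (s in 1:3) {
    p <- sim_params(
      species_tree = ape::read.tree(text = "((cgigas:1,pfmartensii:1):0.5,outgroup:1.5);"),
      tandem_dup_rate = 0.5, retroposition_rate = 0.4,
      rate_multipliers = c(cgigas = 1, pfmartensii = 1, outgroup = 0), seed = s)
    sim <- simulate_cohort(p)
    t <- sim$truth; tot <- 0; cov <- 0
    for (f in unique(t$family_id)) {
      ids <- t$gene_id[t$family_id == f]
      if (length(ids) < 4 || length(unique(t$species[t$family_id == f])) < 2) next
      tr <- nj_tree(protein_distance(sim$proteins[ids]))
      stat <- lineage_specificity(tr, setNames(t$species, t$gene_id))
      tot <- tot + length(ids); cov <- cov + stat * length(ids)
    }
    pooled <- c(pooled, cov / tot)
    sim0 <- simulate_cohort(sim_params(tandem_dup_rate = 0, retroposition_rate = 0,
                                       gene_loss_rate = 0, seed = s))
    t0 <- sim0$truth; tot0 <- 0; cov0 <- 0
    for (f in unique(t0$family_id)) {
      ids <- t0$gene_id[t0$family_id == f]
      if (length(ids) < 4) next
      tr <- nj_tree(protein_distance(sim0$proteins[ids]))
      st <- lineage_specificity(tr, setNames(t0$species, t0$gene_id))
      tot0 <- tot0 + length(ids); cov0 <- cov0 + st * length(ids)
    }
    base <- c(base, cov0 / tot0)
  }
  expect_true(all(pooled > 0.4))
  expect_true(all(pooled > base))
  expect_true(all(base == 0))
})
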