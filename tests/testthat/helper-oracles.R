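# Independent oracles and toy-data builders shared across tests.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Brute-force local alignment with affine gaps, scored by trying every gap
# length explicitly (O(n^2 m^2)); independent of the Gotoh-style recursion
# used by library aligners. Gap of length k costs open + k * ext.
brute_sw_score <- function(s1, s2, open = 11, ext = 1, mat = .blosum62) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1); best <- 0
  for (i in 1:n) for (j in 1:m) {
    v <- S[i, j] + mat[x[i], y[j]]
    for (k in 1:i) v <- max(v, S[i - k + 1, j + 1] - (open + k * ext))
    for (k in 1:j) v <- max(v, S[i + 1, j - k + 1] - (open + k * ext))
    v <- max(v, 0)
    S[i + 1, j + 1] <- v
    best <- max(best, v)
  }
  best
}

# Brute-force average-linkage agglomeration on a distance matrix: recompute
# every inter-cluster mean at every step, merge the closest pair while the
# minimum is <= h. Returns cluster membership (integer vector).
brute_average_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < bd) { bd <- d; best <- c(a, b) }
    }
    if (bd >= h) break   # strict: merge only below the cut height
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  mem <- integer(n)
  for (k in seq_along(clusters)) mem[clusters[[k]]] <- k
  mem
}

# Exhaustive Wagner parsimony: enumerate every assignment of integer states
# to the internal nodes, sum |parent - child| over branches, return the
# minimum total cost.
brute_wagner_cost <- function(tree, leaf_counts) {
  ntip <- length(tree$tip.label)
  states <- 0:max(leaf_counts)
  internals <- (ntip + 1):(ntip + tree$Nnode)
  grid <- do.call(expand.grid, rep(list(states), length(internals)))
  node_val <- function(v, assign) {
    if (v <= ntip) leaf_counts[tree$tip.label[v]]
    else assign[[match(v, internals)]]
  }
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- as.list(grid[r, ])
    cost <- sum(apply(tree$edge, 1, function(e)
      abs(node_val(e[1], assign) - node_val(e[2], assign))))
    best <- min(best, cost)
  }
  best
}

# Build a gene-model table from a compact per-gene spec:
# data.frame(gene_id, scaffold, n_introns); genes laid out left to right on
# each scaffold in row order, exons of `exon` bp separated by `intron` bp.
build_toy_genes <- function(spec, species = "toy", exon = 120, intron = 90,
                            gap = 2000) {
  cds <- vector("list", nrow(spec))
  pos <- setNames(rep(1, length(unique(spec$scaffold))), unique(spec$scaffold))
  for (i in seq_len(nrow(spec))) {
    sc <- spec$scaffold[i]
    n_seg <- spec$n_introns[i] + 1
    starts <- pos[sc] + (0:(n_seg - 1)) * (exon + intron)
    cds[[i]] <- cbind(start = starts, end = starts + exon - 1)
    pos[sc] <- max(cds[[i]][, 2]) + gap
  }
  gene_models(spec$gene_id, species, spec$scaffold, "+", cds)
}

# Toy genome with a prescribed tandem-array composition: `composition` is a
# named vector size -> number of arrays; each array occupies its own
# scaffold as consecutive candidate genes; `n_singletons` isolated
# candidates go one per scaffold. Returns list(genes, candidate_ids).
build_array_genome <- function(composition, n_singletons,
                               introns_arrayed = NULL, introns_single = NULL) {
  rows <- list(); k <- 0; sc <- 0
  for (size in as.integer(names(composition))) {
    for (a in seq_len(composition[[as.character(size)]])) {
      sc <- sc + 1
      for (g in seq_len(size)) {
        k <- k + 1
        rows[[k]] <- data.frame(gene_id = sprintf("arr%03d", k),
                                scaffold = sprintf("scf%03d", sc),
                                n_introns = 0)
      }
    }
  }
  n_arrayed <- k
  for (s in seq_len(n_singletons)) {
    sc <- sc + 1; k <- k + 1
    rows[[k]] <- data.frame(gene_id = sprintf("sng%03d", s),
                            scaffold = sprintf("scf%03d", sc),
                            n_introns = 0)
  }
  spec <- do.call(rbind, rows)
  if (!is.null(introns_arrayed))
    spec$n_introns[seq_len(n_arrayed)] <- introns_arrayed
  if (!is.null(introns_single))
    spec$n_introns[n_arrayed + seq_len(n_singletons)] <- introns_single
  list(genes = build_toy_genes(spec), candidate_ids = spec$gene_id,
       arrayed_ids = spec$gene_id[seq_len(n_arrayed)],
       singleton_ids = spec$gene_id[n_arrayed + seq_len(n_singletons)])
}

# intron-count vector with exactly k values <= 2 among n genes
intron_counts_with_poor <- function(n, k) {
  c(rep(1, k), rep(5, n - k))
}

random_protein <- function(n, alphabet = rownames(.blosum62)[1:20]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
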