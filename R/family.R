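# Gene-family evolution: all-vs-all protein similarity, the H-score
# (self-score-normalized bitscore), average-linkage family clustering,
# neighbor-joining gene trees with bootstrap, Wagner-parsimony ancestral
# family counts, and a lineage-specificity statistic for gene trees.

# BLAST-style bitscore from a raw gapped BLOSUM62 score
# (standard gapped Karlin-Altschul parameters for BLOSUM62 11/1)
.bitscore <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

#' All-vs-all pairwise protein similarity
#'
#' In `internal` mode, computes Smith-Waterman local alignments (BLOSUM62,
#' affine gap open 11 / extend 1) for every unordered pair, reporting a
#' BLAST-style bitscore, percent identity and alignment length; self-pairs
#' are always present with identity 100. In `external` mode, reads a
#' precomputed BLAST tabular file via [read_pair_scores()].
#'
#' @param proteins named character vector of amino-acid sequences
#'   (internal mode), or a file path (external mode).
#' @param mode `"internal"` or `"external"`.
#' @param score_floor drop pairs with bitscore below this (self-pairs kept).
#' @return data.frame in [read_pair_scores()] layout, both orientations of
#'   each pair present.
#' @export
compute_pairwise <- function(proteins, mode = c("internal", "external"),
                             score_floor = 0) {
  mode <- match.arg(mode)
  if (mode == "external") return(read_pair_scores(proteins))
  ids <- names(proteins)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  subj <- Biostrings::AAStringSet(proteins)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    aln <- Biostrings::pairwiseAlignment(
      subj[seq(i, length(ids))], subj[[i]], type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    raw <- Biostrings::score(aln)
    alen <- nchar(as.character(Biostrings::pattern(aln)))
    nm <- Biostrings::nmatch(aln)
    rows[[i]] <- data.frame(
      query_id = ids[i], subject_id = ids[seq(i, length(ids))],
      bitscore = .bitscore(raw), evalue = 0,
      percent_identity = round(100 * nm / pmax(alen, 1), 2),
      alignment_length = alen, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d$percent_identity[d$query_id == d$subject_id] <- 100
  keep <- d$bitscore >= score_floor | d$query_id == d$subject_id
  d <- d[keep, , drop = FALSE]
  rev <- d[d$query_id != d$subject_id, , drop = FALSE]
  tmp <- rev$query_id; rev$query_id <- rev$subject_id; rev$subject_id <- tmp
  out <- rbind(d, rev)
  rownames(out) <- NULL
  out
}

#' Homology edges from pairwise identities
#'
#' Two genes are considered homologous when their percent identity is
#' strictly greater than the threshold (default 30, i.e. "more than 30%").
#'
#' @param pairs pairwise-score data.frame.
#' @param min_identity strict lower bound on percent identity.
#' @return data.frame of undirected edges (`a`, `b`, `percent_identity`),
#'   each unordered pair once, no self edges.
#' @export
homology_filter <- function(pairs, min_identity = 30.0) {
  p <- pairs[pairs$query_id != pairs$subject_id &
             pairs$percent_identity > min_identity, , drop = FALSE]
  if (nrow(p) == 0)
    return(data.frame(a = character(0), b = character(0),
                      percent_identity = numeric(0), stringsAsFactors = FALSE))
  a <- pmin(p$query_id, p$subject_id)
  b <- pmax(p$query_id, p$subject_id)
  d <- data.frame(a = a, b = b, percent_identity = p$percent_identity,
                  stringsAsFactors = FALSE)
  d <- d[order(d$a, d$b, -d$percent_identity), ]
  d <- d[!duplicated(d[c("a", "b")]), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' H-score matrix from pairwise bitscores
#'
#' The H-score between genes a and b is the Treefam-style normalized
#' bitscore `S(a,b) / min(S(a,a), S(b,b))`, symmetrized by taking the
#' larger of the two alignment directions and clipped to `[0, 1]`. Missing
#' pairs score 0; the diagonal is 1.
#'
#' @param pairs pairwise-score data.frame; self-pairs must be present for
#'   every gene.
#' @return symmetric numeric matrix with entries in `[0, 1]`, dimnames =
#'   sorted gene ids.
#' @export
h_score <- function(pairs) {
  selfs <- pairs[pairs$query_id == pairs$subject_id, , drop = FALSE]
  ids <- sort(unique(c(pairs$query_id, pairs$subject_id)))
  self_s <- setNames(selfs$bitscore[match(ids, selfs$query_id)], ids)
  if (any(is.na(self_s)))
    stop("missing self-score for: ",
         paste(ids[is.na(self_s)], collapse = ", "))
  if (any(self_s <= 0)) stop("zero or negative self-score")
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$query_id, ids); j <- match(pairs$subject_id, ids)
  h <- pairs$bitscore / pmin(self_s[i], self_s[j])
  # max over the two directions
  for (k in seq_along(i)) {
    v <- max(H[i[k], j[k]], h[k])
    H[i[k], j[k]] <- v; H[j[k], i[k]] <- v
  }
  H[H < 0] <- 0; H[H > 1] <- 1
  diag(H) <- 1
  H
}

#' Cluster genes into families by average linkage on H-scores
#'
#' Agglomerative average-linkage (UPGMA-style) clustering on the distance
#' `d = 1 - H`, cut at height `1 - cutoff`; the resulting groups are the
#' gene families. Gene ids are sorted before clustering so the assignment
#' is invariant to input order.
#'
#' @param H H-score matrix from [h_score()].
#' @param cutoff similarity cutoff in `[0, 1]` (default 0.5).
#' @return list with `family` (named integer vector gene -> family id,
#'   dense 1..k, numbered by first gene id in the family), `cutoff`.
#' @export
cluster_families <- function(H, cutoff = 0.5) {
  if (length(H) == 0) return(list(family = setNames(integer(0), character(0)),
                                  cutoff = cutoff))
  ids <- sort(rownames(H))
  H <- H[ids, ids, drop = FALSE]
  if (length(ids) == 1) {
    fam <- setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - H), method = "average")
    # strict cut: only merges at distance < 1 - cutoff form a family, so
    # cutoff 1 isolates every gene even when sequences are identical
    m <- sum(hc$height < 1 - cutoff)
    fam <- stats::cutree(hc, k = length(ids) - m)
  }
  # renumber densely by order of first appearance over sorted ids
  fam <- setNames(match(fam, unique(fam)), ids)
  list(family = fam, cutoff = cutoff)
}

#' Pairwise distances from a protein alignment
#'
#' p-distance (fraction of differing columns among pairwise non-gap
#' columns), optionally Poisson-corrected (`-log(1 - p)`).
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param correction `"p"` (default) or `"poisson"`.
#' @return symmetric distance matrix.
#' @export
protein_distance <- function(alignment, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    d <- if (correction == "poisson") -log(max(1 - p, 1e-10)) else p
    D[i, j] <- D[j, i] <- d
  }
  D
}

# clamp negative branch lengths to zero, moving the deficit to the sister
# edge so that path lengths through the parent are preserved
.clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    tr$edge.length[e] <- 0
    if (length(sisters))
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
    else break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree
#'
#' Classical Saitou-Nei neighbor joining on a distance matrix. Negative
#' branch lengths (possible on non-additive input) are clamped to zero with
#' the deficit transferred to the sister edge, preserving path lengths.
#'
#' @param distances symmetric matrix, zero diagonal, finite non-negative.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  if (nrow(distances) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative")
  tr <- ape::nj(stats::as.dist(distances))
  .clamp_negative_edges(tr)
}

# leaf-set bipartitions of the internal edges of an unrooted tree,
# canonicalized so each split is the side not containing the first tip
.splits <- function(tr) {
  tips <- sort(tr$tip.label)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- sort(labs[cl])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate from p-distances, and reports the percentage of replicates
#' containing each internal bipartition of the original tree.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed; identical seeds give identical supports.
#' @return list with `tree` (the original NJ tree) and `support` (named
#'   numeric vector, one entry per internal bipartition, in `[0, 100]`).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1) {
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  if (w < 2) stop("alignment must have at least 2 columns")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  tree0 <- nj_tree(protein_distance(alignment))
  splits0 <- .splits(tree0)
  counts <- setNames(numeric(length(splits0)), splits0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(w, w, replace = TRUE)
    bmat <- mat[, cols, drop = FALSE]
    aln <- setNames(apply(bmat, 1, paste, collapse = ""), rownames(mat))
    btree <- tryCatch(nj_tree(protein_distance(aln)), error = function(e) NULL)
    if (is.null(btree)) next
    bs <- .splits(btree)
    hit <- splits0 %in% bs
    counts[hit] <- counts[hit] + 1
  }
  list(tree = tree0, support = 100 * counts / n_reps)
}

#' Ancestral gene-family counts by Wagner parsimony
#'
#' Reconstructs integer family sizes at the internal nodes of a rooted
#' species tree by Sankoff dynamic programming over states
#' `0..max(leaf count)` with per-branch cost `|parent - child|` (linear
#' Wagner parsimony); ties are broken toward the smallest count. Each
#' branch is labeled `expansion` (+k), `contraction` (-k) or `stable`.
#'
#' @param tree rooted `phylo` species tree.
#' @param leaf_counts named integer vector, one count per species.
#' @return list with `tree`, `node_counts` (vector over ape node numbers,
#'   tips first), `total_cost`, and `events` (data.frame: `parent_node`,
#'   `child_node`, `child_label`, `parent_count`, `child_count`, `change`,
#'   `event`).
#' @export
ancestral_counts <- function(tree, leaf_counts) {
  miss <- setdiff(tree$tip.label, names(leaf_counts))
  if (length(miss)) stop("missing leaf count for: ", paste(miss, collapse = ", "))
  if (any(leaf_counts < 0)) stop("leaf counts must be >= 0")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- 0:max(leaf_counts[tree$tip.label])
  ns <- length(states)
  cost <- matrix(Inf, nnode, ns)
  for (i in seq_len(ntip))
    cost[i, match(leaf_counts[tree$tip.label[i]], states)] <- 0
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # child's contribution to parent state s: min over t of |s-t| + cost[child,t]
  contrib <- function(child_cost) {
    vapply(states, function(s) min(abs(s - states) + child_cost), numeric(1))
  }
  po_edge <- stats::reorder(tree, "postorder")$edge
  post <- unique(po_edge[, 1])  # internal nodes, children-first order
  for (v in post) {
    cc <- vapply(children[[as.character(v)]],
                 function(ch) contrib(cost[ch, ]), numeric(ns))
    cost[v, ] <- rowSums(cc)
  }
  root <- post[length(post)]
  node_counts <- integer(nnode)
  best <- which(cost[root, ] == min(cost[root, ]))
  node_counts[root] <- states[min(best)]  # smallest-count tie-break
  for (v in rev(post)) {
    s <- node_counts[v]
    for (ch in children[[as.character(v)]]) {
      tot <- abs(s - states) + cost[ch, ]
      t <- states[min(which(tot == min(tot)))]
      node_counts[ch] <- t
    }
  }
  ev <- data.frame(parent_node = tree$edge[, 1], child_node = tree$edge[, 2])
  ev$child_label <- ifelse(ev$child_node <= ntip,
                           tree$tip.label[ev$child_node],
                           paste0("node", ev$child_node))
  ev$parent_count <- node_counts[ev$parent_node]
  ev$child_count <- node_counts[ev$child_node]
  ev$change <- ev$child_count - ev$parent_count
  ev$event <- ifelse(ev$change > 0, "expansion",
                     ifelse(ev$change < 0, "contraction", "stable"))
  list(tree = tree, node_counts = node_counts,
       total_cost = min(cost[root, ]), events = ev)
}

#' Lineage specificity of a gene tree
#'
#' Fraction of genes that sit inside maximal monophyletic same-species
#' clades of size at least 2. Near 1 when paralogs cluster within species
#' (expansion after speciation); near 0 when orthologs interleave.
#'
#' @param gene_tree rooted `phylo` tree over genes.
#' @param species_of named character vector gene -> species.
#' @return numeric in `[0, 1]`.
#' @export
lineage_specificity <- function(gene_tree, species_of) {
  tips <- gene_tree$tip.label
  miss <- setdiff(tips, names(species_of))
  if (length(miss)) stop("missing species for: ", paste(miss, collapse = ", "))
  ntip <- length(tips)
  sp <- species_of[tips]
  # species composition per node, postorder
  nnode <- ntip + gene_tree$Nnode
  mono <- rep(NA_character_, nnode)  # species if clade monospecific, else NA
  size <- integer(nnode)
  mono[seq_len(ntip)] <- sp
  size[seq_len(ntip)] <- 1L
  children <- split(gene_tree$edge[, 2], gene_tree$edge[, 1])
  po <- unique(stats::reorder(gene_tree, "postorder")$edge[, 1])
  for (v in po) {
    ch <- children[[as.character(v)]]
    s <- unique(mono[ch])
    mono[v] <- if (length(s) == 1 && !anyNA(s)) s else NA_character_
    size[v] <- sum(size[ch])
  }
  parent_of <- setNames(gene_tree$edge[, 1], gene_tree$edge[, 2])
  root <- po[length(po)]
  covered <- 0L
  for (v in seq_len(nnode)) {
    if (is.na(mono[v]) || size[v] < 2) next
    p <- if (v == root) NA else parent_of[as.character(v)]
    if (is.na(p) || is.na(mono[p])) covered <- covered + size[v]  # maximal
  }
  covered / ntip
}
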