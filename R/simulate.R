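# Synthetic genome-cohort simulator. Gene families evolve along a species
# tree by tandem duplication (intron structure preserved, placed adjacent),
# retroposition (intronless copy at a random genomic position, possibly
# pseudogenized), intron gain on retrocopy lineages, and gene loss.
# Proteins evolve by i.i.d. per-site substitution, so percent identity is a
# clean monotone proxy for divergence. Every run returns a ground-truth
# event table, making the simulator the reference against which annotation,
# clustering, intron classing, tandem detection and expression calls are
# validated.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' Simulation parameters
#'
#' Rates are expected events per gene per unit branch length. Defaults
#' describe a modest bivalve-like cohort: few ancestral families seeded
#' with intron-rich genes (3-9 introns), active tandem duplication and
#' retroposition, occasional intron gain on retrocopies, and a fraction of
#' retrocopies born dead (pseudogenized, below 1 RPKM everywhere).
#'
#' @param species_tree rooted `phylo` with branch lengths; default a
#'   three-species tree with two sister ingroups and an outgroup.
#' @param n_ancestral_families families at the root.
#' @param genes_per_family_at_root genes per family at the root.
#' @param tandem_dup_rate,retroposition_rate,intron_gain_rate,gene_loss_rate
#'   per-gene per-branch-length event rates.
#' @param ancestral_intron_count_range inclusive integer range for root
#'   gene intron counts.
#' @param subst_prob per-site substitution probability per unit branch
#'   length.
#' @param protein_length amino acids per protein (fixed; no indels).
#' @param scaffold_count scaffolds per species genome.
#' @param intervening_gene_fraction probability of inserting an unrelated
#'   filler gene at each gene-gene junction of the final genome.
#' @param pseudogene_fraction fraction of retrocopies assigned near-zero
#'   expression (below 1 RPKM in all samples).
#' @param domain_loss_fraction fraction of genes losing one of the two
#'   receptor domains (populates minority architectures).
#' @param intron_gain_on_ancestral also allow intron gain on intron-rich
#'   (non-retrocopy) lineages? Default `FALSE`.
#' @param rate_multipliers optional named vector (per species) scaling the
#'   tandem/retro/intron-gain rates on each branch; a branch uses the mean
#'   multiplier of its descendant species. Used to contrast expanding
#'   ingroups with a quiet outgroup.
#' @param n_samples expression samples (developmental stages).
#' @param library_size total mapped reads per sample.
#' @param max_genes hard cap on cohort size; exceeding it is an error
#'   advising smaller rates.
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(species_tree = ape::read.tree(text = "((speciesA:1,speciesB:1):0.5,speciesC:1.5);"),
                       n_ancestral_families = 8,
                       genes_per_family_at_root = 2,
                       tandem_dup_rate = 0.3,
                       retroposition_rate = 0.25,
                       intron_gain_rate = 0.08,
                       gene_loss_rate = 0.03,
                       ancestral_intron_count_range = c(3, 9),
                       subst_prob = 0.06,
                       protein_length = 150,
                       scaffold_count = 4,
                       intervening_gene_fraction = 0,
                       pseudogene_fraction = 0.3,
                       domain_loss_fraction = 0,
                       intron_gain_on_ancestral = FALSE,
                       rate_multipliers = NULL,
                       n_samples = 6,
                       library_size = 5e6,
                       max_genes = 5000,
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(all(c(tandem_dup_rate, retroposition_rate, intron_gain_rate,
                  gene_loss_rate) >= 0),
            subst_prob >= 0, subst_prob <= 1,
            diff(ancestral_intron_count_range) >= 0,
            ancestral_intron_count_range[1] >= 0,
            scaffold_count >= 1, n_ancestral_families >= 1,
            genes_per_family_at_root >= 1)
  class(p) <- "sim_params"
  p
}

# split a CDS of length len with 0-based intron offsets into translation-
# order segment lengths
.seg_lengths <- function(len, offsets) {
  diff(c(0, sort(offsets), len))
}

.mutate_protein <- function(aa, p_sub) {
  if (p_sub <= 0) return(aa)
  hit <- stats::runif(length(aa)) < p_sub
  if (any(hit)) {
    n <- sum(hit)
    repl <- .AA20[ceiling(stats::runif(n) * 20)]
    same <- repl == aa[hit]
    while (any(same)) {
      repl[same] <- .AA20[ceiling(stats::runif(sum(same)) * 20)]
      same <- repl == aa[hit]
    }
    aa[hit] <- repl
  }
  aa
}

#' Simulate a genome cohort with known evolutionary events
#'
#' Runs gene birth-death along each branch of the species tree. A tandem
#' duplicate copies its parent's intron structure and is inserted
#' immediately after the parent on the same scaffold; a retrocopy starts
#' with zero introns at a uniformly random genome position and is
#' pseudogenized with probability `pseudogene_fraction`; intron gain
#' inserts an intron at a uniformly random CDS offset (phase = offset mod
#' 3), by default only on retrocopy lineages. Same seed, same output.
#'
#' @param params a [sim_params()] object.
#' @return list with `genes` (a `gene_models` table including unrelated
#'   filler genes), `proteins` (named character vector), `domain_hits`
#'   (data.frame), `expression` (list: `counts`, `gene_length`,
#'   `library_sizes`), `truth` (per family gene: `gene_id`, `species`,
#'   `family_id`, `parent_gene_id`, `origin`, `true_intron_count`,
#'   `array_id`, `is_retro_lineage`, `is_pseudogene`), `species_tree`,
#'   `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  tr <- params$species_tree
  ntip <- length(tr$tip.label)
  cds_len <- 3 * params$protein_length
  counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("g%05d", counter) }

  # gene registry: one list per gene
  genes <- list()
  mk_gene <- function(family, protein, offsets, origin, parent,
                      retro_lineage, pseudo) {
    id <- new_id()
    if (counter > params$max_genes)
      stop("cohort exceeded max_genes = ", params$max_genes,
           "; reduce duplication/retroposition rates")
    genes[[id]] <<- list(id = id, family = family, protein = protein,
                         offsets = offsets, origin = origin, parent = parent,
                         retro_lineage = retro_lineage, pseudo = pseudo)
    id
  }

  # root genome: families laid out consecutively over scaffolds
  irange <- params$ancestral_intron_count_range
  root_ids <- character(0)
  for (f in seq_len(params$n_ancestral_families)) {
    fam_protein <- .AA20[ceiling(stats::runif(params$protein_length) * 20)]
    for (g in seq_len(params$genes_per_family_at_root)) {
      n_introns <- irange[1] + floor(stats::runif(1) * (diff(irange) + 1))
      offsets <- sort(sample.int(cds_len - 1, n_introns))
      prot <- .mutate_protein(fam_protein, 0.02)  # slight within-family spread
      root_ids <- c(root_ids, mk_gene(f, prot, offsets, "speciation", NA_character_,
                                      FALSE, FALSE))
    }
  }
  per_scaffold <- ceiling(length(root_ids) / params$scaffold_count)
  scaffold_of <- rep(seq_len(params$scaffold_count),
                     each = per_scaffold)[seq_along(root_ids)]
  root_genome <- lapply(seq_len(params$scaffold_count),
                        function(s) root_ids[scaffold_of == s])

  # per-branch rate multiplier = mean multiplier of descendant species
  branch_mult <- function(child) {
    if (is.null(params$rate_multipliers)) return(1)
    tips <- if (child <= ntip) tr$tip.label[child] else
      ape::extract.clade(tr, child)$tip.label
    mean(params$rate_multipliers[tips])
  }

  evolve_branch <- function(genome, blen, mult) {
    # 1. substitutions on every resident gene
    p_sub <- min(1, params$subst_prob * blen)
    for (sc in seq_along(genome)) for (id in genome[[sc]])
      genes[[id]]$protein <<- .mutate_protein(genes[[id]]$protein, p_sub)
    # 2. birth-death events, scaffold order (new copies not re-processed)
    for (sc in seq_along(genome)) {
      for (id in genome[[sc]]) {
        g <- genes[[id]]
        if (stats::runif(1) < 1 - exp(-params$gene_loss_rate * blen)) {
          genome[[sc]] <- setdiff(genome[[sc]], id)
          next
        }
        n_td <- stats::rpois(1, params$tandem_dup_rate * mult * blen)
        for (k in seq_len(n_td)) {
          nid <- mk_gene(g$family, g$protein, g$offsets, "tandem_duplication",
                         id, g$retro_lineage, FALSE)
          pos <- match(id, genome[[sc]])
          genome[[sc]] <- append(genome[[sc]], nid, after = pos)
        }
        n_re <- stats::rpois(1, params$retroposition_rate * mult * blen)
        for (k in seq_len(n_re)) {
          pseudo <- stats::runif(1) < params$pseudogene_fraction
          nid <- mk_gene(g$family, g$protein, numeric(0), "retroposition",
                         id, TRUE, pseudo)
          dst <- ceiling(stats::runif(1) * length(genome))
          at <- floor(stats::runif(1) * (length(genome[[dst]]) + 1))
          genome[[dst]] <- append(genome[[dst]], nid, after = at)
        }
        if (g$retro_lineage || params$intron_gain_on_ancestral) {
          n_gain <- stats::rpois(1, params$intron_gain_rate * mult * blen)
          for (k in seq_len(n_gain)) {
            off <- sample(setdiff(seq_len(cds_len - 1), genes[[id]]$offsets), 1)
            genes[[id]]$offsets <<- sort(c(genes[[id]]$offsets, off))
            if (genes[[id]]$origin == "retroposition")
              genes[[id]]$origin <<- "intron_gain_on_retrocopy"
          }
        }
      }
    }
    genome
  }

  copy_genome <- function(genome) {
    lapply(genome, function(sc) vapply(sc, function(id) {
      g <- genes[[id]]
      mk_gene(g$family, g$protein, g$offsets, "speciation", id,
              g$retro_lineage, g$pseudo)
    }, character(1), USE.NAMES = FALSE))
  }

  # recurse down the tree
  leaf_genomes <- vector("list", ntip)
  recurse <- function(node, genome) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    for (ch in kids) {
      blen <- tr$edge.length[which(tr$edge[, 1] == node & tr$edge[, 2] == ch)]
      gm <- evolve_branch(copy_genome(genome), blen, branch_mult(ch))
      if (ch <= ntip) leaf_genomes[[ch]] <<- gm else recurse(ch, gm)
    }
  }
  root <- ntip + 1L
  recurse(root, root_genome)

  # ---- materialize the extant cohort ----
  intron_len <- 300; intergenic <- 5000
  rows_id <- character(0); rows_sp <- character(0); rows_sc <- character(0)
  rows_strand <- character(0); rows_cds <- list()
  truth <- list()
  proteins <- character(0)
  dom <- list()
  filler_n <- 0L

  for (sp_i in seq_len(ntip)) {
    sp <- tr$tip.label[sp_i]
    gm <- leaf_genomes[[sp_i]]
    for (sc_i in seq_along(gm)) {
      ids <- gm[[sc_i]]
      # optional unrelated filler genes at junctions
      layout <- list()
      for (k in seq_along(ids)) {
        layout[[length(layout) + 1]] <- ids[k]
        if (k < length(ids) &&
            stats::runif(1) < params$intervening_gene_fraction) {
          filler_n <- filler_n + 1L
          layout[[length(layout) + 1]] <- sprintf("filler%04d", filler_n)
        }
      }
      pos <- 1
      scaff <- paste0(sp, "_scf", sc_i)
      for (id in unlist(layout)) {
        is_filler <- startsWith(id, "filler")
        if (is_filler) {
          offsets <- sort(sample.int(cds_len - 1, 2))
          prot <- .AA20[ceiling(stats::runif(params$protein_length) * 20)]
        } else {
          g <- genes[[id]]
          offsets <- g$offsets
          prot <- g$protein
        }
        seg <- .seg_lengths(cds_len, offsets)
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        if (strand == "-") seg <- rev(seg)  # genomic order
        starts <- pos + cumsum(c(0, head(seg, -1) + intron_len))
        ends <- starts + seg - 1
        gid <- paste0(sp, "_", id)
        rows_id <- c(rows_id, gid); rows_sp <- c(rows_sp, sp)
        rows_sc <- c(rows_sc, scaff); rows_strand <- c(rows_strand, strand)
        rows_cds[[length(rows_cds) + 1]] <- cbind(start = starts, end = ends)
        pos <- max(ends) + intergenic
        proteins[gid] <- paste(prot, collapse = "")
        if (!is_filler) {
          g <- genes[[id]]
          lbd <- c(10, min(10 + floor(params$protein_length / 2),
                           params$protein_length - 10))
          ntm <- c(lbd[2] + 5, params$protein_length)
          hits <- data.frame(gene_id = gid, label = c("LBD", "NTM"),
                             start = c(lbd[1], ntm[1]), end = c(lbd[2], ntm[2]),
                             evalue = 1e-30, stringsAsFactors = FALSE)
          if (params$domain_loss_fraction > 0 &&
              stats::runif(1) < params$domain_loss_fraction)
            hits <- hits[-(1 + (stats::runif(1) < 0.5)), , drop = FALSE]
          dom[[length(dom) + 1]] <- hits
          truth[[length(truth) + 1]] <- data.frame(
            gene_id = gid, species = sp, family_id = g$family,
            parent_gene_id = if (is.na(g$parent)) NA_character_ else g$parent,
            origin = g$origin, true_intron_count = length(g$offsets),
            array_id = NA_character_,
            is_retro_lineage = g$retro_lineage, is_pseudogene = g$pseudo,
            stringsAsFactors = FALSE)
        }
      }
      # ground-truth tandem arrays: maximal runs of >= 2 consecutive
      # same-family genes in the laid-out order (fillers break runs only
      # beyond the detector's tolerance; truth uses the unfilled order)
      if (length(ids) >= 2) {
        fam <- vapply(ids, function(i) genes[[i]]$family, numeric(1))
        run <- cumsum(c(1, diff(fam) != 0))
        for (r in unique(run)) {
          members <- ids[run == r]
          if (length(members) >= 2) {
            aid <- paste0(sp, ".", sc_i, ".", r)
            for (m in members) {
              gid <- paste0(sp, "_", m)
              i <- which(vapply(truth, function(t) t$gene_id == gid, logical(1)))
              truth[[i]]$array_id <- aid
            }
          }
        }
      }
    }
  }

  gm_tab <- gene_models(rows_id, rows_sp, rows_sc, rows_strand, rows_cds)
  truth <- do.call(rbind, truth)
  dom <- do.call(rbind, dom)

  # expression: lognormal baseline with a random "on" sample set;
  # pseudogenes guaranteed below 1 RPKM in every sample
  fam_ids <- truth$gene_id
  glen <- setNames(gm_tab$cds_length[match(fam_ids, gm_tab$gene_id)], fam_ids)
  samples <- paste0("S", seq_len(params$n_samples))
  lib <- setNames(rep(params$library_size, params$n_samples), samples)
  counts <- matrix(0L, length(fam_ids), params$n_samples,
                   dimnames = list(fam_ids, samples))
  for (i in seq_along(fam_ids)) {
    thr <- glen[i] * params$library_size / 1e9  # count at exactly 1 RPKM
    if (truth$is_pseudogene[i]) {
      counts[i, ] <- as.integer(stats::runif(params$n_samples) < 0.3)
      counts[i, counts[i, ] >= thr] <- 0L
    } else {
      n_on <- 1 + floor(stats::runif(1) * 3)
      on <- sample.int(params$n_samples, n_on)
      base <- stats::rlnorm(1, log(50), 0.8)
      counts[i, on] <- as.integer(ceiling(pmax(base * stats::rlnorm(n_on, 0, 0.3),
                                               thr + 1)))
      counts[i, -on] <- stats::rpois(params$n_samples - n_on, 2)
    }
  }

  list(genes = gm_tab, proteins = proteins, domain_hits = dom,
       expression = list(counts = counts, gene_length = glen,
                         library_sizes = lib),
       truth = truth, species_tree = tr, params = params)
}

#' Write a named simulation scenario to disk
#'
#' The `"bivalve_expansion"` scenario contrasts two sister ingroup species
#' with active tandem duplication and retroposition against an outgroup
#' with neither, under a fixed built-in seed; re-running produces identical
#' files.
#'
#' @param name scenario name (currently `"bivalve_expansion"`).
#' @param dir output directory (created if needed).
#' @param seed override the scenario's built-in seed.
#' @return invisibly, the named character vector of written files
#'   (`genome.gff3`, `proteins.fasta`, `domains.tsv`, `tree.nwk`,
#'   `expression.tsv`, `libsizes.tsv`, `truth.tsv`).
#' @export
emit_fixture <- function(name, dir, seed = NULL) {
  params <- switch(name,
    bivalve_expansion = sim_params(
      species_tree = ape::read.tree(
        text = "((cgigas:1,pfmartensii:1):0.5,outgroup:1.5);"),
      tandem_dup_rate = 0.5, retroposition_rate = 0.4,
      rate_multipliers = c(cgigas = 1, pfmartensii = 1, outgroup = 0),
      seed = 20240817),
    stop("unknown scenario: ", name))
  if (!is.null(seed)) params$seed <- seed
  sim <- simulate_cohort(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genome = file.path(dir, "genome.gff3"),
             proteins = file.path(dir, "proteins.fasta"),
             domains = file.path(dir, "domains.tsv"),
             tree = file.path(dir, "tree.nwk"),
             expression = file.path(dir, "expression.tsv"),
             libsizes = file.path(dir, "libsizes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_gff3(sim$genes, files["genome"])
  write_proteins(sim$proteins, files["proteins"])
  write_domain_tsv(sim$domain_hits, files["domains"])
  write_newick(sim$species_tree, files["tree"])
  write_expression(sim$expression$counts, sim$expression$gene_length,
                   files["expression"])
  write_library_sizes(sim$expression$library_sizes, files["libsizes"])
  write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(files)
}
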