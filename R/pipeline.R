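# End-to-end orchestration: simulate (or load) -> annotate -> structure ->
# cluster -> tandem -> ancestral -> express, with every stage reading and
# writing core-io formats so each is independently invocable, plus a
# consolidated report.

#' Default pipeline configuration
#'
#' Flat key-value configuration grouped by stage; every parameter defaults
#' to the module default. `simulate = TRUE` generates the input cohort with
#' [simulate_cohort()]; otherwise `gff`, `proteins`, `domains`, `tree`,
#' `expression`, `libsizes` must point at input files.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    scenario = "bivalve_expansion",
    seed = 1,
    gff = NULL, proteins = NULL, domains = NULL, tree = NULL,
    expression = NULL, libsizes = NULL,
    evalue_threshold = 1e-5,
    min_identity = 30.0,
    h_cutoff = 0.5,
    max_intervening = 1,
    target_mode = "geneset",
    bootstrap_reps = 0,
    out_dir = "nachrex_run"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration
#'
#' Plain `key = value` file; round-trips [run_config()] objects.
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @return `path` invisibly / a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  ks <- names(cfg)
  vals <- vapply(ks, function(k)
    if (is.null(cfg[[k]])) "" else as.character(cfg[[k]]), character(1))
  writeLines(paste(ks, "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  defaults <- run_config()
  cfg <- defaults
  for (m in kv) {
    k <- m[2]; v <- m[3]
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    d <- defaults[[k]]
    cfg[k] <- list(if (!nzchar(v)) NULL
      else if (is.logical(d)) as.logical(v)
      else if (is.numeric(d)) as.numeric(v)
      else v)
  }
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full expansion-analysis pipeline
#'
#' Stages run in order, each writing its outputs under `cfg$out_dir` before
#' the next stage reads; a stage failure halts the run naming the stage,
#' retaining earlier outputs. The run is deterministic given the
#' configuration (including seeds).
#'
#' @param cfg a [run_config()].
#' @return a report list: `candidates_per_species`, `architecture_census`,
#'   `intron_class_counts`, `tandem_summary`, `family_sizes`,
#'   `ancestral_events`, `expression_summary`, `files` (paths of all
#'   artifacts).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- inputs --
  inputs <- stage("simulate", {
    if (isTRUE(cfg$simulate)) {
      d <- file.path(cfg$out_dir, "inputs")
      fs <- emit_fixture(cfg$scenario, d, seed = cfg$seed)
      files <- c(files, fs)
      list(gff = fs[["genome"]], proteins = fs[["proteins"]],
           domains = fs[["domains"]], tree = fs[["tree"]],
           expression = fs[["expression"]], libsizes = fs[["libsizes"]])
    } else {
      cfg[c("gff", "proteins", "domains", "tree", "expression", "libsizes")]
    }
  })
  genes <- stage("load", read_gff3(inputs$gff))
  proteins <- stage("load", read_proteins(inputs$proteins))
  hits <- stage("load", read_domain_tsv(inputs$domains))
  sp_tree <- stage("load", read_newick(inputs$tree))
  expr_in <- stage("load", read_expression(inputs$expression))
  libsizes <- stage("load", read_library_sizes(inputs$libsizes))

  # -- annotate: architectures + candidate calls --
  ann <- stage("annotate", {
    by_gene <- split(hits, hits$gene_id)
    arches <- lapply(by_gene, architecture_string)
    # best homology e-value: the best domain-hit e-value stands in when no
    # reference-set score table is provided
    best_ev <- vapply(by_gene, function(h) min(h$evalue), numeric(1))
    calls <- lapply(names(arches), function(g)
      call_candidate(g, best_ev[[g]], arches[[g]], cfg$evalue_threshold))
    cand <- vapply(calls, `[[`, logical(1), "is_candidate")
    tab <- data.frame(
      gene_id = names(arches),
      species = genes$species[match(names(arches), genes$gene_id)],
      architecture = vapply(arches, `[[`, character(1), "string"),
      is_candidate = cand,
      reason = vapply(calls, `[[`, character(1), "reason"),
      stringsAsFactors = FALSE)
    files <- c(files, .write_tsv(tab, file.path(cfg$out_dir, "calls.tsv")))
    tab
  })
  cand_tab <- ann[ann$is_candidate, , drop = FALSE]
  census <- architecture_census(cand_tab$architecture, cand_tab$species)
  stage("annotate", .write_tsv(
    data.frame(species = rownames(census), census, check.names = FALSE),
    file.path(cfg$out_dir, "architecture_census.tsv")))

  # -- structure --
  cand_genes <- genes[genes$gene_id %in% cand_tab$gene_id, , drop = FALSE]
  classes <- stage("structure", {
    cl <- classify_introns(cand_genes)
    files <- c(files, .write_tsv(cl, file.path(cfg$out_dir, "intron_classes.tsv")))
    cl
  })

  # -- cluster --
  fam <- stage("cluster", {
    pw <- compute_pairwise(proteins[cand_tab$gene_id], mode = "internal")
    H <- h_score(pw)
    fa <- cluster_families(H, cutoff = cfg$h_cutoff)
    files <- c(files, .write_tsv(
      data.frame(gene_id = names(fa$family), family_id = fa$family),
      file.path(cfg$out_dir, "families.tsv")))
    fa
  })

  # -- tandem --
  tandem <- stage("tandem", {
    arrays <- find_tandem_arrays(
      cand_tab$gene_id, genes, max_intervening = cfg$max_intervening,
      same_family_only = identical(cfg$target_mode, "family"),
      family = fam$family)
    smry <- summarize_arrays(arrays, nrow(cand_tab))
    files <- c(files, .write_tsv(arrays, file.path(cfg$out_dir, "arrays.tsv")),
               .write_tsv(smry$by_size, file.path(cfg$out_dir, "tandem_summary.tsv")))
    list(arrays = arrays, summary = smry)
  })

  # -- ancestral counts per family --
  ancestral <- stage("ancestral", {
    fam_sp <- table(fam$family[cand_tab$gene_id], cand_tab$species)
    ev <- do.call(rbind, lapply(rownames(fam_sp), function(f) {
      counts <- setNames(rep(0L, length(sp_tree$tip.label)), sp_tree$tip.label)
      counts[colnames(fam_sp)] <- as.integer(fam_sp[f, ])
      ac <- ancestral_counts(sp_tree, counts)
      cbind(family_id = f, ac$events)
    }))
    files <- c(files, .write_tsv(ev, file.path(cfg$out_dir, "ancestral_events.tsv")))
    ev
  })

  # -- expression --
  expr <- stage("express", {
    rk <- rpkm(expr_in$counts, expr_in$gene_length, libsizes)
    keep <- intersect(rownames(rk), cand_tab$gene_id)
    rk <- rk[keep, , drop = FALSE]
    lowfrac <- low_expression_fraction(rk, classes)
    cls <- expression_classes(rk)
    files <- c(files,
               .write_tsv(cls, file.path(cfg$out_dir, "expression_classes.tsv")),
               .write_tsv(lowfrac, file.path(cfg$out_dir, "expression_summary.tsv")))
    list(rpkm = rk, low_fraction = lowfrac, classes = cls)
  })

  report <- list(
    candidates_per_species = table(cand_tab$species),
    architecture_census = census,
    intron_class_counts = intron_class_counts(classes),
    tandem_summary = tandem$summary,
    family_sizes = table(fam$family),
    ancestral_events = ancestral,
    expression_summary = expr$low_fraction,
    files = files)
  saveRDS_free <- file.path(cfg$out_dir, "report.tsv")
  stage("report", .write_tsv(
    data.frame(metric = c("n_candidates", "n_families", "n_arrays",
                          "n_genes_in_arrays", "percent_in_arrays"),
               value = c(nrow(cand_tab), length(unique(fam$family)),
                         tandem$summary$n_arrays_total,
                         tandem$summary$n_genes_total,
                         tandem$summary$percent_in_arrays)),
    saveRDS_free))
  report
}

#' Tandem-array summary in receptor-inventory layout
#'
#' Runs the tandem detector in geneset mode (the whole candidate set as one
#' pool) and summarizes by array size -- the layout used when reporting how
#' much of a receptor repertoire sits in tandem arrays.
#'
#' @param genes full `gene_models` table (targets and non-targets).
#' @param candidate_ids the candidate gene set.
#' @param max_intervening tolerated intervening genes (default 0).
#' @return [summarize_arrays()] output.
#' @export
table2_mode <- function(genes, candidate_ids, max_intervening = 0) {
  arrays <- find_tandem_arrays(candidate_ids, genes,
                               max_intervening = max_intervening,
                               same_family_only = FALSE)
  summarize_arrays(arrays, length(candidate_ids))
}
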