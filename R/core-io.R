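#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames
NULL

# Coordinate conventions used throughout the package:
#  * genomic coordinates: 1-based inclusive (GFF3 standard)
#  * protein coordinates: 1-based inclusive
#  * intron CDS offsets:  0-based nucleotide offsets from the CDS start,
#    counted in translation order (see extract_introns)

#' Construct a table of gene models
#'
#' A gene-model table is the package's central genomic container: one row per
#' gene, with the CDS segments kept as a list column of two-column matrices
#' (start, end; genomic, 1-based inclusive, stored in ascending genomic order
#' regardless of strand).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param species character vector (recycled) of species labels.
#' @param scaffold character vector of scaffold/chromosome names.
#' @param strand character vector of "+" or "-".
#' @param cds list of two-column numeric matrices, one per gene, each row a
#'   CDS segment (start, end).
#' @return A `data.frame` of class `gene_models` with columns `gene_id`,
#'   `species`, `scaffold`, `strand`, `start`, `end`, `cds` (list column),
#'   `n_cds`, `cds_length`, `complete_cds` (is the total CDS length divisible
#'   by 3 -- a flag, never an error) and `rank_on_scaffold` (1-based order of
#'   the gene among all genes on its scaffold, by ascending start).
#' @export
gene_models <- function(gene_id, species, scaffold, strand, cds) {
  stopifnot(length(gene_id) == length(scaffold),
            length(gene_id) == length(cds),
            all(strand %in% c("+", "-")))
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  cds <- lapply(cds, function(m) {
    m <- matrix(as.numeric(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[, 1] > m[, 2])) stop("CDS segment with start > end")
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("overlapping CDS segments")
    m
  })
  df <- data.frame(
    gene_id = as.character(gene_id),
    species = rep_len(as.character(species), length(gene_id)),
    scaffold = as.character(scaffold),
    strand = rep_len(as.character(strand), length(gene_id)),
    start = vapply(cds, function(m) min(m[, 1]), numeric(1)),
    end = vapply(cds, function(m) max(m[, 2]), numeric(1)),
    stringsAsFactors = FALSE
  )
  df$cds <- cds
  df$n_cds <- vapply(cds, nrow, integer(1))
  df$cds_length <- vapply(cds, function(m) sum(m[, 2] - m[, 1] + 1), numeric(1))
  df$complete_cds <- df$cds_length %% 3 == 0
  df <- assign_ranks(df)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Assign scaffold ranks to a gene-model table
#'
#' Ranks are 1-based order indices among all genes sharing a (species,
#' scaffold) pair, by ascending genomic start. File order never matters.
#'
#' @param genes a `gene_models` data.frame.
#' @return the same table with `rank_on_scaffold` (re)computed.
#' @export
assign_ranks <- function(genes) {
  key <- paste(genes$species, genes$scaffold, sep = "\r")
  genes$rank_on_scaffold <- stats::ave(genes$start, key,
                                       FUN = function(x) rank(x, ties.method = "first"))
  genes$rank_on_scaffold <- as.integer(genes$rank_on_scaffold)
  genes
}

# parse the ID= / Parent= fields of a GFF3 attribute string
.gff_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) >= 3) utils::URLdecode(x[3]) else NA_character_,
         character(1))
}

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA / CDS features with standard `ID` and `Parent`
#' attributes. Multi-transcript genes are collapsed to the transcript with
#' the longest total CDS (analyses count genes, not transcripts). CDS
#' features attached directly to a gene (no mRNA level) are also accepted.
#'
#' @param path GFF3 file.
#' @param species species label for all genes; if `NULL`, the `source`
#'   column (field 2) of the gene feature is used.
#' @return a `gene_models` data.frame; see [gene_models()].
#' @export
read_gff3 <- function(path, species = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(gene_models(character(0), character(0), character(0), character(0), list()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9))
    stop("GFF3 parse error: line ", lineno[which(nf != 9)[1]], " does not have 9 fields")
  f <- do.call(rbind, f)
  start <- as.numeric(f[, 4]); end <- as.numeric(f[, 5])
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop("GFF3 parse error: malformed coordinates (start > end or non-numeric) at line ",
         lineno[bad[1]])
  type <- f[, 3]
  id <- .gff_attr(f[, 9], "ID")
  parent <- .gff_attr(f[, 9], "Parent")

  gi <- type == "gene"
  mi <- type == "mRNA"
  ci <- type == "CDS"
  gene_ids <- id[gi]
  mrna_parent <- setNames(parent[mi], id[mi])
  if (any(ci & is.na(parent)))
    stop("GFF3 parse error: orphan CDS (no Parent) at line ",
         lineno[which(ci & is.na(parent))[1]])
  unknown <- ci & !(parent %in% c(id[mi], gene_ids))
  if (any(unknown))
    stop("GFF3 parse error: CDS with unknown Parent '",
         parent[which(unknown)[1]], "' at line ", lineno[which(unknown)[1]])

  # group CDS by transcript (or by gene when attached directly)
  cds_parent <- parent[ci]
  cds_tab <- data.frame(parent = cds_parent, start = start[ci], end = end[ci],
                        stringsAsFactors = FALSE)
  by_tx <- split(cds_tab[c("start", "end")], cds_tab$parent)
  tx_gene <- ifelse(names(by_tx) %in% gene_ids, names(by_tx),
                    unname(mrna_parent[names(by_tx)]))
  tx_len <- vapply(by_tx, function(d) sum(d$end - d$start + 1), numeric(1))
  # longest-CDS transcript per gene; ties broken by transcript id for determinism
  ord <- order(tx_gene, -tx_len, names(by_tx))
  pick <- ord[!duplicated(tx_gene[ord])]
  chosen <- setNames(names(by_tx)[pick], tx_gene[pick])

  gsub_ids <- gene_ids[gene_ids %in% names(chosen)]
  g_row <- match(gsub_ids, id)
  sp <- if (is.null(species)) f[g_row, 2] else rep_len(species, length(gsub_ids))
  cds_list <- lapply(chosen[gsub_ids], function(tx) as.matrix(by_tx[[tx]]))
  gene_models(gene_id = gsub_ids, species = sp, scaffold = f[g_row, 1],
              strand = f[g_row, 7], cds = cds_list)
}

#' Write gene models to a GFF3 file
#'
#' Emits one gene, one mRNA and its CDS features per gene model. The species
#' label is stored in the `source` column so that [read_gff3()] round-trips.
#'
#' @param genes a `gene_models` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    m <- g$cds[[1]]
    line <- function(type, s, e, attr)
      paste(g$scaffold, g$species, type, s, e, ".", g$strand, ".", attr, sep = "\t")
    writeLines(line("gene", g$start, g$end, paste0("ID=", g$gene_id)), con)
    writeLines(line("mRNA", g$start, g$end,
                    paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id)), con)
    for (j in seq_len(nrow(m)))
      writeLines(line("CDS", m[j, 1], m[j, 2], paste0("Parent=", g$gene_id, ".t1")), con)
  }
  invisible(path)
}

.known_domain_labels <- c("LBD", "NTM", "TM")

#' Read a protein domain-hit table
#'
#' Tab-separated columns `gene_id`, `label`, `start`, `end`, `evalue`
#' (protein coordinates, 1-based inclusive), in the style of an
#' InterProScan/SMART export reduced to located hits. Labels other than
#' `LBD`, `NTM`, `TM` are mapped to `OTHER:<name>` -- never rejected, since
#' extra functional domains (e.g. dynamin) are themselves informative.
#'
#' @param path TSV file with a header row.
#' @param protein_lengths optional named vector of protein lengths; when
#'   given, hits extending past the protein end raise a validation error
#'   listing the offending gene ids.
#' @return data.frame with columns `gene_id`, `label`, `start`, `end`,
#'   `evalue`, sorted by gene then hit start.
#' @export
read_domain_tsv <- function(path, protein_lengths = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "label", "start", "end", "evalue")
  if (!all(need %in% names(d)))
    stop("domain TSV must have columns: ", paste(need, collapse = ", "))
  d <- d[need]
  d$label <- ifelse(d$label %in% .known_domain_labels, d$label,
                    ifelse(startsWith(d$label, "OTHER:"), d$label,
                           paste0("OTHER:", d$label)))
  if (any(d$start > d$end)) stop("domain hit with start > end")
  if (any(d$evalue < 0)) stop("negative e-value in domain table")
  if (!is.null(protein_lengths)) {
    len <- protein_lengths[d$gene_id]
    bad <- !is.na(len) & d$end > len
    if (any(bad))
      stop("domain hits exceed protein length for: ",
           paste(unique(d$gene_id[bad]), collapse = ", "))
  }
  d[order(d$gene_id, d$start, d$end), , drop = FALSE]
}

#' Write a domain-hit table
#' @param hits data.frame as returned by [read_domain_tsv()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pairwise alignment scores (BLAST tabular, outfmt 6)
#'
#' Twelve columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Duplicate (query, subject) rows keep the row
#' with the best (largest) bitscore.
#'
#' @param path tabular file, no header.
#' @return data.frame with columns `query_id`, `subject_id`, `bitscore`,
#'   `evalue`, `percent_identity`, `alignment_length`.
#' @export
read_pair_scores <- function(path) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      percent_identity = numeric(0), alignment_length = integer(0),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12)
    stop("pair-score parse error: expected 12 tab-separated columns, found ", ncol(d))
  out <- data.frame(query_id = as.character(d[[1]]), subject_id = as.character(d[[2]]),
                    bitscore = as.numeric(d[[12]]), evalue = as.numeric(d[[11]]),
                    percent_identity = as.numeric(d[[3]]),
                    alignment_length = as.integer(d[[4]]),
                    stringsAsFactors = FALSE)
  if (any(out$percent_identity < 0 | out$percent_identity > 100))
    stop("percent identity outside [0,100]")
  ord <- order(out$query_id, out$subject_id, -out$bitscore)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[c("query_id", "subject_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pairwise scores in BLAST outfmt-6 layout
#'
#' Columns not tracked internally (mismatches, gap opens, coordinates) are
#' written as zeros; [read_pair_scores()] round-trips the tracked fields.
#'
#' @param pairs data.frame as returned by [read_pair_scores()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(pairs, path) {
  d <- data.frame(pairs$query_id, pairs$subject_id, pairs$percent_identity,
                  pairs$alignment_length, 0L, 0L, 0L, 0L, 0L, 0L,
                  pairs$evalue, pairs$bitscore)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a species (or gene) tree in Newick format
#'
#' A thin validating wrapper around [ape::read.tree()]: leaf labels must be
#' unique and parentheses balanced.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  no <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  nc <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (no != nc) stop("Newick parse error: unbalanced parentheses")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("Newick parse error")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  if (any(!nzchar(seqs))) stop("empty protein sequence in FASTA")
  seqs
}

#' Write protein sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Read an expression count matrix with gene lengths
#'
#' TSV layout: header row `gene_id`, `length_bp`, then one column per sample;
#' values are raw read counts.
#'
#' @param path TSV file.
#' @return list with `counts` (integer matrix, genes x samples),
#'   `gene_length` (named vector, bp).
#' @export
read_expression <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(d)))
    stop("expression TSV must have gene_id and length_bp columns")
  counts <- as.matrix(d[, setdiff(names(d), c("gene_id", "length_bp")), drop = FALSE])
  rownames(counts) <- d$gene_id
  if (any(counts < 0)) stop("negative read count")
  list(counts = counts, gene_length = setNames(d$length_bp, d$gene_id))
}

#' Write an expression count matrix
#' @param counts genes x samples count matrix.
#' @param gene_length named vector of gene lengths (bp).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(counts, gene_length, path) {
  d <- data.frame(gene_id = rownames(counts),
                  length_bp = gene_length[rownames(counts)],
                  counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample library sizes
#' @param path TSV with columns `sample`, `library_size`.
#' @return named numeric vector of total mapped reads per sample.
#' @export
read_library_sizes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(d$library_size, d$sample)
}

#' Write per-sample library sizes
#' @param libsizes named numeric vector.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_library_sizes <- function(libsizes, path) {
  write.table(data.frame(sample = names(libsizes), library_size = libsizes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
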