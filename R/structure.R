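# Exon-intron structure: intron extraction from CDS segments, the
# intronless / intron-poor (1-2) / intron-rich (>2) classification used to
# separate putative retrogenes from ancestral intron-rich receptor genes,
# projection of intron positions onto protein alignments, and
# conserved-vs-novel intron calls.

#' Extract introns from a gene model
#'
#' Introns are the gaps between consecutive CDS segments, walked in
#' translation order ("+" strand: ascending genomic; "-" strand: descending).
#' Each intron gets a 0-based nucleotide offset from the CDS start
#' (`cds_offset`), a phase (`cds_offset %% 3`: 0 = between codons, 1 =
#' between first and second codon position, 2 = between second and third),
#' and the 1-based protein position of the last complete residue before the
#' intron (`preceding_residue`; 0 when the intron interrupts codon 1).
#' Only CDS-interrupting introns are counted; UTR introns are invisible to
#' a CDS-segment representation.
#'
#' @param gene one row of a `gene_models` table (or a list with `gene_id`,
#'   `strand` and `cds`).
#' @return data.frame with columns `gene_id`, `index`, `cds_offset`,
#'   `phase`, `preceding_residue`; zero rows for a single-segment gene.
#' @export
extract_introns <- function(gene) {
  m <- if (is.data.frame(gene)) gene$cds[[1]] else gene$cds
  strand <- if (is.data.frame(gene)) gene$strand else gene$strand
  gid <- if (is.data.frame(gene)) gene$gene_id else gene$gene_id
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
    stop("overlapping CDS segments in ", gid)
  empty <- data.frame(gene_id = character(0), index = integer(0),
                      cds_offset = numeric(0), phase = integer(0),
                      preceding_residue = numeric(0), stringsAsFactors = FALSE)
  if (nrow(m) < 2) return(empty)
  seg_len <- m[, 2] - m[, 1] + 1
  if (strand == "-") seg_len <- rev(seg_len)  # translation order
  off <- cumsum(seg_len)[-length(seg_len)]
  data.frame(gene_id = gid,
             index = seq_along(off),
             cds_offset = off,
             phase = as.integer(off %% 3),
             preceding_residue = off %/% 3,
             stringsAsFactors = FALSE)
}

#' Extract introns for every gene in a table
#' @param genes a `gene_models` data.frame.
#' @return row-bound data.frame of [extract_introns()] results.
#' @export
extract_introns_all <- function(genes) {
  out <- lapply(seq_len(nrow(genes)), function(i) extract_introns(genes[i, ]))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify genes by intron count
#'
#' Classes: `intronless` (0 introns), `intron-poor` (1-2), `intron-rich`
#' (more than 2).
#'
#' @param genes a `gene_models` data.frame.
#' @return data.frame with `gene_id`, `species`, `n_introns`, `klass`.
#' @export
classify_introns <- function(genes) {
  n <- genes$n_cds - 1L
  data.frame(gene_id = genes$gene_id,
             species = genes$species,
             n_introns = n,
             klass = ifelse(n == 0, "intronless",
                            ifelse(n <= 2, "intron-poor", "intron-rich")),
             stringsAsFactors = FALSE)
}

#' Per-species intron-class counts
#' @param classes output of [classify_introns()].
#' @return integer matrix species x class (intronless, intron-poor,
#'   intron-rich).
#' @export
intron_class_counts <- function(classes) {
  lev <- c("intronless", "intron-poor", "intron-rich")
  tab <- table(factor(classes$species), factor(classes$klass, levels = lev))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Project an intron position onto a protein alignment
#'
#' Maps an intron to the 1-based alignment column of its anchor residue:
#' for phase-0 introns the residue immediately preceding the intron, for
#' phase-1/2 introns the residue whose codon the intron interrupts.
#'
#' @param intron one row of [extract_introns()] output.
#' @param aligned_seq the gene's aligned (gapped) protein string.
#' @return integer alignment column.
#' @export
project_intron_to_alignment <- function(intron, aligned_seq) {
  residue <- if (intron$phase == 0) intron$preceding_residue
             else intron$preceding_residue + 1L
  chars <- strsplit(aligned_seq, "")[[1]]
  res_cols <- which(chars != "-")
  if (residue > length(res_cols))
    stop("residue index ", residue, " exceeds ungapped length ", length(res_cols))
  if (residue < 1)
    stop("intron precedes the first complete codon; no anchor residue")
  res_cols[residue]
}

#' Call conserved vs. novel intron positions on a shared alignment
#'
#' An intron position, identified by its (alignment column, phase) pair, is
#' conserved when at least two distinct genes share it exactly; all other
#' positions are novel. Equal column with different phase does not count as
#' shared.
#'
#' @param projected data.frame with columns `gene_id`, `column`, `phase`
#'   (all projections on one alignment).
#' @return the input with an added `status` column (`conserved` / `novel`).
#' @export
call_conserved_introns <- function(projected) {
  key <- paste(projected$column, projected$phase, sep = "/")
  n_genes <- vapply(split(projected$gene_id, key),
                    function(g) length(unique(g)), integer(1))
  projected$status <- ifelse(n_genes[key] >= 2, "conserved", "novel")
  projected
}

#' Intron-poor fractions within tandem-arrayed vs. single-copy genes
#'
#' Cross-tabulates an intron-count labeling against a copy-type labeling
#' (tandem-arrayed vs. single-copy) and reports, per stratum, the count and
#' percentage of intron-poor genes. For this contrast "intron-poor" means
#' at most 2 introns (i.e. intronless genes included), matching how
#' retrogene-derived copies are bulked in receptor inventories.
#'
#' @param classes output of [classify_introns()] (needs `gene_id`,
#'   `n_introns`).
#' @param copy_type named character vector over the same gene set with
#'   values `tandem-arrayed` or `single-copy`.
#' @return data.frame with one row per stratum: `copy_type`, `n_genes`,
#'   `n_intron_poor`, `percent_intron_poor` (1 decimal).
#' @export
intron_class_by_copy_type <- function(classes, copy_type) {
  missing <- setdiff(classes$gene_id, names(copy_type))
  extra <- setdiff(names(copy_type), classes$gene_id)
  if (length(missing) || length(extra))
    stop("copy-type labels do not cover the gene set; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  ct <- copy_type[classes$gene_id]
  poor <- classes$n_introns <= 2
  out <- do.call(rbind, lapply(c("tandem-arrayed", "single-copy"), function(s) {
    i <- ct == s
    n <- sum(i); k <- sum(poor & i)
    data.frame(copy_type = s, n_genes = n, n_intron_poor = k,
               percent_intron_poor = if (n > 0) round(100 * k / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
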