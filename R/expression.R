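# Expression summaries: RPKM, the <1-RPKM low-expression rule used to flag
# putative pseudogenes, a tau specificity index, and heat-map-ready matrix
# export.

#' RPKM matrix from raw counts
#'
#' `RPKM = count * 1e9 / (gene_length_bp * library_size)` (reads per
#' kilobase of transcript per million mapped reads).
#'
#' @param counts genes x samples matrix of raw read counts.
#' @param gene_lengths named vector, bp, covering all rows.
#' @param library_sizes named vector of total mapped reads per sample,
#'   covering all columns.
#' @return numeric matrix of RPKM values, same dimnames as `counts`.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes) {
  len <- gene_lengths[rownames(counts)]
  lib <- library_sizes[colnames(counts)]
  if (anyNA(len)) stop("missing gene length")
  if (anyNA(lib)) stop("missing library size")
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (any(lib <= 0)) stop("library sizes must be positive")
  counts * 1e9 / outer(len, lib)
}

#' Fraction of low-expressed genes per intron class
#'
#' A gene is low-expressed when its RPKM is below 1 in every sample -- the
#' signature of a pseudogenized retrocopy. Reported per intron-count class,
#' with `intron-poor` here meaning at most 2 introns (intronless included)
#' and `intron-rich` more than 2.
#'
#' @param rpkm_mat RPKM matrix from [rpkm()].
#' @param classes [classify_introns()] output covering all matrix rows.
#' @return data.frame: `klass`, `n_genes`, `n_low`, `percent_low`
#'   (1 decimal; `NA` for an empty class).
#' @export
low_expression_fraction <- function(rpkm_mat, classes) {
  miss <- setdiff(rownames(rpkm_mat), classes$gene_id)
  if (length(miss)) stop("intron class missing for: ", paste(miss, collapse = ", "))
  low <- apply(rpkm_mat < 1, 1, all)
  grp <- ifelse(classes$n_introns[match(rownames(rpkm_mat), classes$gene_id)] <= 2,
                "intron-poor", "intron-rich")
  out <- do.call(rbind, lapply(c("intron-poor", "intron-rich"), function(k) {
    i <- grp == k
    n <- sum(i); nl <- sum(low & i)
    data.frame(klass = k, n_genes = n, n_low = nl,
               percent_low = if (n > 0) round(100 * nl / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genes low-expressed in every sample
#' @param rpkm_mat RPKM matrix.
#' @return named logical vector (`TRUE` = all samples below 1 RPKM).
#' @export
low_expressed <- function(rpkm_mat) {
  apply(rpkm_mat < 1, 1, all)
}

#' Tissue/stage specificity index (tau)
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` on the raw RPKM profile:
#' 0 for a uniform profile, 1 for expression in a single sample. Invariant
#' to positive rescaling.
#'
#' @param profile numeric vector of per-sample RPKM, length >= 2.
#' @return tau in `[0, 1]`, or `NA` for an all-zero profile.
#' @export
specificity_index <- function(profile) {
  if (length(profile) < 2) stop("need at least 2 samples")
  m <- max(profile)
  if (m == 0) return(NA_real_)
  sum(1 - profile / m) / (length(profile) - 1)
}

#' Per-gene expression class summary
#'
#' @param rpkm_mat RPKM matrix.
#' @return data.frame: `gene_id`, `low_expressed`, `peak_sample`,
#'   `specificity` (tau).
#' @export
expression_classes <- function(rpkm_mat) {
  data.frame(
    gene_id = rownames(rpkm_mat),
    low_expressed = apply(rpkm_mat < 1, 1, all),
    peak_sample = colnames(rpkm_mat)[apply(rpkm_mat, 1, which.max)],
    specificity = apply(rpkm_mat, 1, function(x)
      if (max(x) == 0) NA_real_ else specificity_index(x)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Heat-map-ready expression table
#'
#' `log2(RPKM + 1)`, columns reordered to the requested sample order,
#' optionally z-scored per row (constant rows left at 0). Matrix export
#' only; no plotting.
#'
#' @param rpkm_mat RPKM matrix.
#' @param sample_order permutation of the column names.
#' @param zscore z-score rows? (default `FALSE`).
#' @return numeric matrix.
#' @export
stage_profile_table <- function(rpkm_mat, sample_order = colnames(rpkm_mat),
                                zscore = FALSE) {
  unknown <- setdiff(sample_order, colnames(rpkm_mat))
  if (length(unknown)) stop("unknown sample: ", paste(unknown, collapse = ", "))
  if (!setequal(sample_order, colnames(rpkm_mat)))
    stop("sample_order must be a permutation of the matrix columns")
  m <- log2(rpkm_mat[, sample_order, drop = FALSE] + 1)
  if (zscore) {
    m <- t(apply(m, 1, function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }))
    colnames(m) <- sample_order
  }
  m
}

#' Fold change relative to the first time point
#'
#' Reduces a challenge/stress time course to per-gene fold changes relative
#' to time 0 (the first column of `sample_order`), on RPKM + a pseudocount.
#'
#' @param rpkm_mat RPKM matrix.
#' @param sample_order time-ordered column names; first = baseline.
#' @param pseudocount added before the ratio (default 0.1).
#' @return matrix of fold changes, baseline column = 1.
#' @export
fold_change_vs_baseline <- function(rpkm_mat, sample_order, pseudocount = 0.1) {
  m <- rpkm_mat[, sample_order, drop = FALSE] + pseudocount
  m / m[, 1]
}
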