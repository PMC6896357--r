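# Receptor candidate calling and sequence characterization.
#
# nAChR subunits carry an extracellular neurotransmitter-gated ion-channel
# ligand-binding domain (LBD) and a four-helix transmembrane channel domain
# (NTM). The LBD contains the Cys-loop signature: two cysteines separated by
# exactly 13 residues. Alpha subunits additionally carry vicinal cysteines
# (an adjacent CC dipeptide, loop C) downstream of the Cys-loop.

# merge same-label hits whose overlap is >= 50% of the shorter hit
.merge_hits <- function(hits) {
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  out <- list()
  for (lab in unique(hits$label)) {
    h <- hits[hits$label == lab, , drop = FALSE]
    i <- 1
    while (i <= nrow(h)) {
      cur <- h[i, ]
      j <- i + 1
      while (j <= nrow(h)) {
        ov <- min(cur$end, h$end[j]) - max(cur$start, h$start[j]) + 1
        shorter <- min(cur$end - cur$start, h$end[j] - h$start[j]) + 1
        if (ov >= 0.5 * shorter) {
          cur$start <- min(cur$start, h$start[j])
          cur$end <- max(cur$end, h$end[j])
          cur$evalue <- min(cur$evalue, h$evalue[j])
          h <- h[-j, , drop = FALSE]
        } else j <- j + 1
      }
      out[[length(out) + 1]] <- cur
      i <- i + 1
    }
  }
  do.call(rbind, out)
}

#' Domain architecture of one protein
#'
#' Orders a gene's domain hits along the protein (by start, ties by end then
#' label) and joins the labels with "-" into an architecture string such as
#' `"LBD-NTM"` or `"TM-LBD-NTM-TM"`. Overlapping hits with the same label are
#' merged when the overlap covers at least half of the shorter hit, so that
#' redundant calls from overlapping domain databases are not double-counted.
#'
#' @param hits data.frame of domain hits for one gene (columns `label`,
#'   `start`, `end`, `evalue`); may be empty.
#' @return list with `labels` (ordered character vector), `string` (labels
#'   joined by "-"), and `has_other_functional_domain` (any `OTHER:` label).
#' @export
architecture_string <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(labels = character(0), string = "",
                has_other_functional_domain = FALSE))
  m <- .merge_hits(hits)
  m <- m[order(m$start, m$end, m$label), , drop = FALSE]
  list(labels = m$label,
       string = paste(m$label, collapse = "-"),
       has_other_functional_domain = any(startsWith(m$label, "OTHER:")))
}

#' Call a gene as a receptor candidate
#'
#' A gene is accepted as an nAChR candidate when it is homologous to a
#' receptor reference set (best e-value at or below the threshold) and its
#' architecture contains at least one LBD or one NTM domain. The reason
#' records whether both domains or only one were present, preserving the
#' distinction reported in receptor inventories.
#'
#' @param gene_id gene identifier.
#' @param best_homology_evalue best e-value against the receptor reference
#'   set, or `NA`/`NULL` when no hit was found.
#' @param arch architecture as returned by [architecture_string()].
#' @param evalue_threshold acceptance threshold (default `1e-5`).
#' @return list with `gene_id`, `is_candidate` and `reason`, one of
#'   `homology+both-domains`, `homology+one-domain`, `rejected-no-domain`,
#'   `rejected-no-homology`.
#' @export
call_candidate <- function(gene_id, best_homology_evalue, arch,
                           evalue_threshold = 1e-5) {
  ev <- best_homology_evalue
  if (is.null(ev)) ev <- NA_real_
  if (!is.na(ev) && ev < 0) stop("negative e-value")
  has_lbd <- "LBD" %in% arch$labels
  has_ntm <- "NTM" %in% arch$labels
  if (is.na(ev) || ev > evalue_threshold) {
    reason <- "rejected-no-homology"
  } else if (has_lbd && has_ntm) {
    reason <- "homology+both-domains"
  } else if (has_lbd || has_ntm) {
    reason <- "homology+one-domain"
  } else {
    reason <- "rejected-no-domain"
  }
  list(gene_id = gene_id,
       is_candidate = reason %in% c("homology+both-domains", "homology+one-domain"),
       reason = reason)
}

#' Locate the Cys-loop motif
#'
#' Finds the leftmost occurrence of the Cys-loop signature `C-X{13}-C`
#' (two cysteines separated by exactly 13 residues; 15 residues inclusive),
#' restricted to the LBD interval when one is supplied.
#'
#' @param seq amino-acid string.
#' @param lbd optional `c(start, end)` protein interval (1-based inclusive).
#' @return `c(start, end)` of the motif span (positions of the two
#'   cysteines), or `NULL` when absent.
#' @export
find_cys_loop <- function(seq, lbd = NULL) {
  lo <- 1L; hi <- nchar(seq)
  if (!is.null(lbd)) { lo <- as.integer(lbd[1]); hi <- as.integer(min(lbd[2], hi)) }
  if (hi - lo + 1 < 15) return(NULL)
  window <- substr(seq, lo, hi)
  m <- regexpr("C.{13}C", window, perl = TRUE)
  if (m == -1) return(NULL)
  s <- lo + as.integer(m) - 1L
  c(start = s, end = s + 14L)
}

#' Classify a subunit as alpha
#'
#' Alpha subunits carry vicinal cysteines (an adjacent `CC` dipeptide, the
#' loop-C signature) within the LBD, downstream of the Cys-loop.
#'
#' @param seq amino-acid string.
#' @param lbd `c(start, end)` LBD interval.
#' @param cys_loop Cys-loop span from [find_cys_loop()], or `NULL`.
#' @return `TRUE` for alpha subunits.
#' @export
call_alpha <- function(seq, lbd, cys_loop) {
  if (is.null(cys_loop)) return(FALSE)
  from <- cys_loop[2] + 1L
  to <- min(lbd[2], nchar(seq))
  if (to - from + 1 < 2) return(FALSE)
  gregexpr("CC", substr(seq, from, to), fixed = TRUE)[[1]][1] != -1
}

#' Check conservation of principal binding-site residues
#'
#' Given a multiple alignment and the alignment columns that hold the
#' reference's principal acetylcholine binding sites, reports per gene
#' whether every listed column matches the reference residue exactly. Gaps
#' count as mismatches.
#'
#' @param alignment named character vector of aligned (gapped) sequences of
#'   equal length.
#' @param reference_id name of the reference sequence in `alignment`.
#' @param reference_columns integer vector of 1-based alignment columns.
#' @return named logical vector over the non-reference genes.
#' @export
check_binding_sites <- function(alignment, reference_id, reference_columns) {
  if (!reference_id %in% names(alignment)) stop("reference_id not in alignment")
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  if (any(reference_columns < 1 | reference_columns > w))
    stop("alignment column out of range")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  ref <- mat[reference_id, reference_columns, drop = TRUE]
  ids <- setdiff(names(alignment), reference_id)
  vapply(ids, function(g) {
    res <- mat[g, reference_columns, drop = TRUE]
    all(res == ref & res != "-")
  }, logical(1))
}

#' Tabulate domain architectures per species
#'
#' @param arch_strings character vector of architecture strings, one per gene.
#' @param species character vector of species labels, parallel to
#'   `arch_strings`.
#' @return integer matrix, species x architecture string; margins sum to the
#'   number of input genes.
#' @export
architecture_census <- function(arch_strings, species) {
  stopifnot(length(arch_strings) == length(species))
  if (length(species) == 0) return(matrix(integer(0), 0, 0))
  tab <- table(factor(species), factor(arch_strings))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
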