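# Tandem-array detection: maximal runs of target genes along a scaffold,
# allowing a bounded number of intervening non-target genes. Strand is
# ignored for membership, since tandem duplicates commonly invert.

#' Detect tandem arrays of target genes
#'
#' Scans each scaffold in rank order and chains target genes into maximal
#' runs where every adjacent member pair is separated by at most
#' `max_intervening` non-member genes. With `same_family_only = TRUE`
#' members must additionally share a family (a target gene of another
#' family counts as intervening); with `FALSE` ("geneset" mode) the whole
#' target set is one pool, as when counting arrays of all receptor
#' candidates. Runs of a single gene are discarded.
#'
#' @param target_ids character vector of target gene ids.
#' @param all_genes `gene_models` table covering targets and non-targets,
#'   with ranks assigned (see [assign_ranks()]).
#' @param max_intervening maximum non-member genes between adjacent members
#'   (default 1).
#' @param same_family_only cluster within families? (default `TRUE`).
#' @param family named vector gene -> family id; required when
#'   `same_family_only`.
#' @return data.frame with one row per array member: `array_id`, `scaffold`,
#'   `gene_id`, `position_in_array`; attribute `n_intervening` on the
#'   result gives total intervening genes per array.
#' @export
find_tandem_arrays <- function(target_ids, all_genes, max_intervening = 1,
                               same_family_only = TRUE, family = NULL) {
  if (same_family_only) {
    if (is.null(family)) stop("family assignment required when same_family_only")
    miss <- setdiff(target_ids, names(family))
    if (length(miss))
      stop("family missing for target genes: ", paste(miss, collapse = ", "))
  }
  g <- all_genes[order(all_genes$species, all_genes$scaffold,
                       all_genes$rank_on_scaffold), , drop = FALSE]
  is_target <- g$gene_id %in% target_ids
  pool <- if (same_family_only) as.character(family[g$gene_id]) else
    ifelse(is_target, "all", NA_character_)
  pool[!is_target] <- NA_character_

  rows <- list(); n_int <- integer(0); aid <- 0L
  key <- paste(g$species, g$scaffold, sep = "\r")
  for (sc in unique(key)) {
    i <- which(key == sc & is_target)
    if (!length(i)) next
    for (p in unique(pool[i])) {
      m <- i[pool[i] == p]                     # candidate members, rank order
      runs <- split(m, cumsum(c(1, diff(g$rank_on_scaffold[m]) - 1 > max_intervening)))
      for (run in runs) {
        if (length(run) < 2) next
        aid <- aid + 1L
        rows[[aid]] <- data.frame(
          array_id = aid, scaffold = g$scaffold[run[1]],
          gene_id = g$gene_id[run], position_in_array = seq_along(run),
          stringsAsFactors = FALSE)
        n_int[aid] <- g$rank_on_scaffold[run[length(run)]] -
          g$rank_on_scaffold[run[1]] + 1L - length(run)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(array_id = integer(0), scaffold = character(0),
               gene_id = character(0), position_in_array = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_intervening") <- n_int
  attr(out, "max_intervening") <- max_intervening
  out
}

#' Summarize tandem arrays by size
#'
#' @param arrays output of [find_tandem_arrays()].
#' @param target_set_size size of the candidate gene set the percentage is
#'   relative to.
#' @return list with `by_size` (data.frame: `size`, `n_arrays`, `n_genes`),
#'   `n_arrays_total`, `n_genes_total`, `percent_in_arrays` (1 decimal).
#' @export
summarize_arrays <- function(arrays, target_set_size) {
  sizes <- if (nrow(arrays)) as.integer(table(arrays$array_id)) else integer(0)
  tab <- table(sizes)
  by_size <- data.frame(size = as.integer(names(tab)),
                        n_arrays = as.integer(tab))
  by_size$n_genes <- by_size$size * by_size$n_arrays
  n_genes_total <- sum(by_size$n_genes)
  stopifnot(n_genes_total == nrow(arrays))  # conservation
  if (target_set_size < n_genes_total)
    stop("target_set_size (", target_set_size,
         ") smaller than genes in arrays (", n_genes_total, ")")
  list(by_size = by_size,
       n_arrays_total = sum(by_size$n_arrays),
       n_genes_total = n_genes_total,
       percent_in_arrays = round(100 * n_genes_total / target_set_size, 1))
}

#' Copy-type labels from an array partition
#'
#' @param arrays output of [find_tandem_arrays()].
#' @param target_ids full candidate gene set.
#' @return named character vector over `target_ids` with values
#'   `tandem-arrayed` / `single-copy`, suitable for
#'   [intron_class_by_copy_type()].
#' @export
copy_type_labels <- function(arrays, target_ids) {
  setNames(ifelse(target_ids %in% arrays$gene_id, "tandem-arrayed", "single-copy"),
           target_ids)
}
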