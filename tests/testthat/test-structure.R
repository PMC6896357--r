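mk_gene <- function(cds, strand = "+", id = "g1")
  gene_models(id, "toy", "s1", strand, list(cds))[1, ]

test_that("intron offsets and phases follow translation order", {
  g0 <- mk_gene(cbind(c(1, 401), c(300, 700)))
  i0 <- extract_introns(g0)
  expect_equal(nrow(i0), 1)
  expect_equal(i0$cds_offset, 300)
  expect_equal(i0$phase, 0L)           # between two consecutive codons
  expect_equal(i0$preceding_residue, 100)

  g1 <- mk_gene(cbind(c(1, 401), c(301, 700)))
  i1 <- extract_introns(g1)
  expect_equal(i1$cds_offset, 301)
  expect_equal(i1$phase, 1L)           # between first and second codon position

  g2 <- mk_gene(cbind(c(1, 401), c(302, 700)))
  expect_equal(extract_introns(g2)$phase, 2L)

  expect_equal(nrow(extract_introns(mk_gene(cbind(1, 300)))), 0)
})

test_that("minus-strand genes count offsets from the downstream (translation-start) segment", {
  # on "-", translation starts at the rightmost segment
  g <- mk_gene(cbind(c(1, 401), c(100, 700)), strand = "-")
  i <- extract_introns(g)
  expect_equal(i$cds_offset, 300)      # first segment in translation order is 300 bp
  expect_equal(i$phase, 0L)
})

test_that("reverse-complementing a locus leaves every intron offset and phase unchanged", {
  set.seed(42)
  for (r in 1:10) {
    n_seg <- sample(2:6, 1)
    starts <- cumsum(c(1, sample(200:500, n_seg - 1, TRUE)))
    lens <- sample(30:200, n_seg, TRUE)
    cds <- cbind(starts, starts + lens - 1)
    fwd <- mk_gene(cds, "+")
    L <- max(cds) + 100
    rc <- cbind(L - cds[, 2] + 1, L - cds[, 1] + 1)  # mirrored coordinates
    rev_g <- mk_gene(rc[order(rc[, 1]), , drop = FALSE], "-")
    fi <- extract_introns(fwd); ri <- extract_introns(rev_g)
    expect_equal(ri$cds_offset, fi$cds_offset)
    expect_equal(ri$phase, fi$phase)
  }
})

test_that("intron classes partition genes: 0 / 1-2 / >2 introns", {
  spec <- data.frame(gene_id = paste0("g", 1:6), scaffold = "s1",
                     n_introns = c(0, 1, 2, 3, 7, 0))
  cl <- classify_introns(build_toy_genes(spec))
  expect_equal(cl$klass, c("intronless", "intron-poor", "intron-poor",
                           "intron-rich", "intron-rich", "intronless"))
  counts <- intron_class_counts(cl)
  expect_equal(sum(counts), nrow(spec))  # conservation
  expect_equal(counts["toy", ], c(intronless = 2L, `intron-poor` = 2L,
                                  `intron-rich` = 2L))
})

test_that("intron projection walks gaps correctly and anchors phase-1/2 introns on the interrupted codon", {
  ir <- function(phase, prec) data.frame(gene_id = "g", index = 1L,
                                         cds_offset = prec * 3 + phase,
                                         phase = phase, preceding_residue = prec)
  # no gaps: identity mapping
  expect_equal(project_intron_to_alignment(ir(0, 10), strrep("A", 20)), 10)
  # "AB--CD": residue 3 (C) sits at column 5
  expect_equal(project_intron_to_alignment(ir(0, 3), "AB--CD"), 5)
  # phase-1 intron interrupting residue 4 of "A-BCD": D is residue 4, column 5
  expect_equal(project_intron_to_alignment(ir(1, 3), "A-BCD"), 5)
  expect_error(project_intron_to_alignment(ir(0, 9), "AB--CD"), "exceeds")
})

test_that("conserved introns need both equal column and equal phase in 2+ genes", {
  proj <- data.frame(
    gene_id = c("a", "b", "c", "a", "b"),
    column = c(57, 57, 80, 91, 91),
    phase = c(0, 0, 2, 0, 1))
  got <- call_conserved_introns(proj)
  expect_equal(got$status, c("conserved", "conserved", "novel", "novel", "novel"))
})

test_that("tandem-family conserved-intron calls: inherited positions conserved, fresh gains novel", {
  sim <- simulate_cohort(sim_params(seed = 9, intron_gain_rate = 0.3))
  truth <- sim$truth
  # pick a family with a tandem pair plus a retro-lineage gene with gains
  fams <- split(truth, truth$family_id)
  for (fam in fams) {
    td <- fam[fam$origin == "tandem_duplication" & !fam$is_retro_lineage, ]
    if (nrow(td) == 0) next
    parent_row <- match(paste0(td$species[1], "_", td$parent_gene_id[1]),
                        fam$gene_id)
    if (is.na(parent_row)) next
    ids <- c(fam$gene_id[parent_row], td$gene_id[1])
    g <- sim$genes[match(ids, sim$genes$gene_id), ]
    proj <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      ii <- extract_introns(g[i, ])
      # proteins are unaligned but equal length (no indels): identity columns
      ii$column <- vapply(seq_len(nrow(ii)), function(k)
        project_intron_to_alignment(ii[k, ], sim$proteins[[g$gene_id[i]]]),
        numeric(1))
      ii[c("gene_id", "column", "phase")]
    }))
    got <- call_conserved_introns(proj)
    # the tandem copy inherited every parental intron position exactly
    expect_true(all(got$status == "conserved"))
    break
  }
})

test_that("arrayed vs single-copy intron-poor contrast counts <=2-intron genes per stratum", {
  spec <- data.frame(gene_id = paste0("g", 1:10), scaffold = "s1",
                     n_introns = c(0, 1, 2, 3, 4, 0, 2, 5, 6, 1))
  cl <- classify_introns(build_toy_genes(spec))
  ct <- setNames(rep(c("tandem-arrayed", "single-copy"), each = 5), spec$gene_id)
  got <- intron_class_by_copy_type(cl, ct)
  arr <- got[got$copy_type == "tandem-arrayed", ]
  sng <- got[got$copy_type == "single-copy", ]
  expect_equal(arr$n_intron_poor, 3L)            # 0,1,2 introns
  expect_equal(arr$percent_intron_poor, 60.0)
  expect_equal(sng$n_intron_poor, 3L)            # 0,2,1 introns
  expect_equal(sng$percent_intron_poor, 60.0)
  expect_error(intron_class_by_copy_type(cl, ct[-1]), "missing")

  # all intron-rich: 0% in both strata
  spec2 <- data.frame(gene_id = paste0("h", 1:4), scaffold = "s1", n_introns = 5)
  cl2 <- classify_introns(build_toy_genes(spec2))
  ct2 <- setNames(rep(c("tandem-arrayed", "single-copy"), 2), spec2$gene_id)
  expect_equal(intron_class_by_copy_type(cl2, ct2)$percent_intron_poor, c(0, 0))
})

test_that("retro-lineage genes are recovered by the intronless-or-intron-poor classes", {
  diffs <- vapply(1:10, function(s) {
    sim <- simulate_cohort(sim_params(seed = s))
    cl <- classify_introns(sim$genes[sim$genes$gene_id %in% sim$truth$gene_id, ])
    mean(cl$n_introns <= 2) - mean(sim$truth$is_retro_lineage)
  }, numeric(1))
  expect_true(all(abs(diffs) <= 0.02))
})
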