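# Generator determinism, planted structure, and count/read simulation.

test_that("genome generation is deterministic under seed and varies across seeds", {
  cfg <- sim_config(seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$exons, g2$exons)
  g3 <- generate_genome(sim_config(seed = 2))
  expect_false(identical(g1$genes$start, g3$genes$start))
})

test_that("n_genes = 0 still emits a genome with an empty annotation", {
  cfg <- sim_config(seed = 1, n_genes = 0, n_coding = 0, n_circ = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$exons), 0)
  expect_equal(length(g$contigs), cfg$n_contigs)
})

test_that("genome annotation is internally consistent", {
  g <- generate_genome(sim_config(seed = 3))
  for (i in seq_len(nrow(g$genes))) {
    ex <- g$exons[g$exons$gene_id == g$genes$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    expect_true(all(ex$start >= g$genes$start[i]))
    expect_true(all(ex$end <= g$genes$end[i]))
    if (nrow(ex) > 1)
      expect_true(all(ex$start[-1] > ex$end[-nrow(ex)])) # non-overlapping
  }
  host <- g$genes[g$genes$coding_host, ][1, ]
  hex <- g$exons[g$exons$gene_id == host$gene_id &
                   g$exons$rank == host$host_exon_rank, ]
  expect_gte(hex$end - hex$start + 1, 900)  # the analog host exon
})

test_that("an over-packed contig raises a configuration error", {
  expect_error(generate_genome(sim_config(seed = 1, contig_length = 8000,
                                          n_genes = 30)),
               "too short")
})

test_that("planted categories hit the configured mix and survive annotation", {
  cfg <- sim_config(seed = 5)
  g <- generate_genome(cfg)
  p <- plant_circrnas(g, cfg)
  tab <- table(factor(p$truth$category,
                      levels = names(cfg$category_mix)))
  target <- cfg$n_circ * cfg$category_mix[names(tab)]
  expect_true(all(abs(as.integer(tab) - target) <= 2))
  expect_equal(sum(p$truth$coding), cfg$n_coding)
  # the downstream classifier recovers every planted category
  catalog <- annotate_bsj(p$bsj, g)
  expect_identical(catalog$category, p$truth$category)
})

test_that("a pure-exonic mix yields only exonic records", {
  cfg <- sim_config(seed = 2, n_circ = 20, n_coding = 2,
                    category_mix = c(exonic = 1, intronic = 0,
                                     intergenic = 0, sense_overlapping = 0,
                                     antisense = 0))
  p <- plant_circrnas(generate_genome(cfg), cfg)
  expect_true(all(p$truth$category == "exonic"))
})

test_that("realized proportions track the mix at larger N (goodness of fit)", {
  cfg <- sim_config(seed = 11, n_circ = 500, n_genes = 120,
                    exons_per_gene = c(2, 5), n_contigs = 4,
                    contig_length = 250000, n_coding = 6)
  p <- plant_circrnas(generate_genome(cfg), cfg)
  tab <- table(factor(p$truth$category, levels = names(cfg$category_mix)))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(tab), p = cfg$category_mix[names(tab)]))
  expect_gt(gof$p.value, 0.01)
})

test_that("the planted coding circle mirrors the analog's ORF geometry", {
  cfg <- sim_config(seed = 1)
  g <- generate_genome(cfg)
  p <- plant_circrnas(g, cfg)
  catalog <- annotate_bsj(p$bsj, g)
  for (i in which(p$truth$coding)) {
    orfs <- find_circular_orfs(catalog$sequence[i])
    top <- orfs[1, ]
    # ORF starts at the annotated start codon, spans the junction, and the
    # coding screen recovers the designed protein exactly
    expect_identical(top$protein, p$truth$protein[i])
    expect_equal(top$start, p$truth$orf_start[i])
    expect_true(top$spans_junction)
    # exactly two novel C-terminal residues relative to the linear protein
    parent <- parental_protein(g, p$truth$gene_id[i])
    jp <- junction_peptide(top$protein, parent)
    expect_identical(jp$novel_suffix, "TD")
    expect_identical(jp$divergence_positions,
                     c(nchar(top$protein) - 1L, nchar(top$protein)))
    # the ORF terminates within 30 nt of crossing the junction
    expect_lte((top$start + top$nt_length) %% catalog$length[i], 30)
  }
})

test_that("count simulation honors depth, seed and the planted fold change", {
  cfg <- sim_config(seed = 4)
  tr <- null_truth(50, cfg)
  zero <- simulate_counts(tr, sim_config(seed = 4, depth = 0))
  expect_true(all(zero$circ == 0))
  c1 <- simulate_counts(tr, cfg)
  c2 <- simulate_counts(tr, cfg)
  expect_identical(c1$circ, c2$circ)
  bad <- cfg; bad$nb_dispersion <- -1
  expect_error(simulate_counts(tr, bad), "dispersion")
})

test_that("planted fold change is recovered by the empirical pair ratio", {
  # Monte-Carlo oracle: with fc = 4 planted in every pair, the median raw
  # tumor/normal pair ratio sits at ~4 (the mean is Jensen-inflated by the
  # NB noise, so the median is the stable location summary)
  cfg <- sim_config(seed = 8, planted_fc = 4)
  tr <- null_truth(2000, cfg)
  tr[, grep("fc_pair", names(tr))] <- 4
  cc <- simulate_counts(tr, cfg)
  tumor <- cc$circ[, cc$design$sample[cc$design$condition == "tumor"]]
  normal <- cc$circ[, cc$design$sample[cc$design$condition == "normal"]]
  ratio <- (tumor + 0.5) / (normal + 0.5)
  expect_gt(median(ratio), 3.6)
  expect_lt(median(ratio), 4.4)
})

test_that("junction reads span the BSJ and RNase R removes only linear reads", {
  cfg <- sim_config(seed = 6, n_circ = 30, n_coding = 3)
  g <- generate_genome(cfg)
  p <- plant_circrnas(g, cfg)
  catalog <- annotate_bsj(p$bsj, g)
  reads <- simulate_junction_reads(catalog, g, p$truth, cfg)
  origin <- sub("^([^|]+)\\|(circ|linear)\\|.*$", "\\2",
                names(reads$untreated))
  expect_true(all(c("circ", "linear") %in% origin))
  treated_origin <- sub("^([^|]+)\\|(circ|linear)\\|.*$", "\\2",
                        names(reads$treated))
  expect_true(all(treated_origin == "circ"))          # 0% linear retained
  expect_equal(sum(origin == "circ"), length(reads$treated)) # >=99% kept
  # every circular read contains its circle's junction with >= anchor overlap
  idx <- which(origin == "circ")[1:20]
  for (j in idx) {
    id <- sub("\\|.*$", "", names(reads$untreated)[j])
    km <- junction_kmer(catalog$sequence[catalog$circ_id == id],
                        anchor = cfg$anchor)
    expect_true(grepl(km, as.character(reads$untreated[[j]]), fixed = TRUE))
  }
  expect_error(
    simulate_junction_reads(catalog, g, p$truth,
                            sim_config(seed = 6, read_length = 5000)),
    "read_length")
})
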