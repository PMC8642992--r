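# BSJ classification, sequence reconstruction and catalog summaries on a
# hand-built annotation.

g <- tiny_genome()
ctg <- as.character(g$contigs[["ctgT"]])

test_that("classification follows the five-category precedence", {
  # both ends on exon boundaries of the + gene -> exonic
  expect_equal(classify_circ(list(chrom = "ctgT", start = 1000, end = 1200,
                                  strand = "+"), g)$category, "exonic")
  # spanning both exons, boundary to boundary -> exonic
  expect_equal(classify_circ(list(chrom = "ctgT", start = 1000, end = 1800,
                                  strand = "+"), g)$category, "exonic")
  # strictly inside the intron, same strand -> intronic
  expect_equal(classify_circ(list(chrom = "ctgT", start = 1250, end = 1400,
                                  strand = "+"), g)$category, "intronic")
  # inside an exon without boundary match -> sense_overlapping
  expect_equal(classify_circ(list(chrom = "ctgT", start = 1010, end = 1150,
                                  strand = "+"), g)$category,
               "sense_overlapping")
  # same span, opposite strand -> antisense
  expect_equal(classify_circ(list(chrom = "ctgT", start = 1010, end = 1150,
                                  strand = "-"), g)$category, "antisense")
  # no gene at all -> intergenic
  expect_equal(classify_circ(list(chrom = "ctgT", start = 3200, end = 3400,
                                  strand = "+"), g)$category, "intergenic")
  expect_error(classify_circ(list(chrom = "ctgT", start = 500, end = 500,
                                  strand = "+"), g), "malformed")
  expect_error(classify_circ(list(chrom = "nope", start = 1, end = 2,
                                  strand = "+"), g), "contig")
})

test_that("reconstruction is a plain substring on a single-exon + circle", {
  rc <- reconstruct_sequence(list(chrom = "ctgT", start = 1000, end = 1200,
                                  strand = "+"), g)
  expect_identical(rc$sequence, substr(ctg, 1001, 1200))
  expect_equal(rc$length, 200)
})

test_that("minus-strand reconstruction is the reverse complement", {
  rc <- reconstruct_sequence(list(chrom = "ctgT", start = 2500, end = 2900,
                                  strand = "-"), g)
  rc_ind <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ctg, 2501, 2900))))
  expect_identical(rc$sequence, rc_ind)
})

test_that("two-exon circles splice out the intron", {
  rc <- reconstruct_sequence(list(chrom = "ctgT", start = 1000, end = 1800,
                                  strand = "+"), g)
  expect_equal(rc$length, 200 + 300)
  expect_identical(rc$sequence,
                   paste0(substr(ctg, 1001, 1200), substr(ctg, 1501, 1800)))
  expect_false(grepl(substr(ctg, 1201, 1500), rc$sequence, fixed = TRUE))
})

test_that("reconstruction commutes with strand mirroring", {
  # mirrored fixture: same exon, annotated on the other strand
  g2 <- g
  g2$genes$strand <- c("-", "+")
  g2$exons$strand <- c("-", "-", "+")
  plus <- reconstruct_sequence(list(chrom = "ctgT", start = 1000,
                                    end = 1200, strand = "+"), g)
  minus <- reconstruct_sequence(list(chrom = "ctgT", start = 1000,
                                     end = 1200, strand = "-"), g2)
  expect_identical(minus$sequence,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(plus$sequence))))
})

test_that("circle length follows the half-open coordinate convention", {
  expect_equal(circ_length(data.frame(start = 396147, end = 397106)), 959L)
  expect_equal(circ_length(data.frame(start = 0, end = 1)), 1L)
  df <- data.frame(start = 0, end = 250)
  df$blocks <- list(cbind(start = c(1L, 201L), end = c(100L, 250L)))
  expect_equal(circ_length(df), 150L)
  expect_error(circ_length(data.frame(start = 10, end = 10)), "malformed")
  # length always equals the reconstructed sequence length
  for (span in list(c(1000, 1200), c(1000, 1800), c(1250, 1400))) {
    rec <- list(chrom = "ctgT", start = span[1], end = span[2],
                strand = "+")
    rc <- reconstruct_sequence(rec, g)
    expect_equal(rc$length, nchar(rc$sequence))
  }
})

test_that("category percentages reproduce printed-report rounding", {
  counts <- c(exonic = 36218, intronic = 462, intergenic = 1848,
              sense_overlapping = 6744, antisense = 511)
  expect_equal(category_percentages(counts),
               c(exonic = 79L, intronic = 1L, intergenic = 4L,
                 sense_overlapping = 15L, antisense = 1L))
  expect_equal(unname(category_percentages(c(a = 1))), 100L)
  expect_equal(unname(category_percentages(c(a = 2, b = 1))), c(67L, 33L))
})

test_that("catalog summary handles regular and empty input", {
  cat_df <- data.frame(category = c("exonic", "exonic", "intronic"),
                       length = c(300, 1700, 900))
  s <- summarize_catalog(cat_df)
  expect_false(s$empty)
  expect_equal(sum(s$categories$count), 3)
  expect_equal(s$frac_below_1500, 2 / 3)
  e <- summarize_catalog(cat_df[0, ])
  expect_true(e$empty)
})
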