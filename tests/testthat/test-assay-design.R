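# Tagged constructs, start mutants, primers, junction siRNAs, tryptic
# peptides and TCF motif scans.

test_that("tagging inserts before the stop and appends the tag residues", {
  s <- "AAATAGATG"
  orf <- find_circular_orfs(s)[1, ]
  cs <- tag_orf(s, orf, "GATGAT")
  expect_identical(cs$sequence, "AAAGATGATTAGATG")
  new_orf <- find_circular_orfs(cs$sequence)
  new_orf <- new_orf[new_orf$spans_junction, ][1, ]
  expect_identical(new_orf$protein, "MKDD")
  expect_identical(cs$expected_protein, "MKDD")
  # empty tag is the identity
  expect_identical(tag_orf(s, orf, "")$sequence, s)
  # non-codon-multiple tags are rejected
  expect_error(tag_orf(s, orf, "GATGATGA"), "codon multiple")
  roll <- find_circular_orfs("ATGCCCCCCC")[1, ]
  expect_error(tag_orf("ATGCCCCCCC", roll, "GATGAT"), "rolling")
})

test_that("start-codon mutation abolishes the ORF unless another start remains", {
  s <- "AAATAGATG"
  orf <- find_circular_orfs(s)[1, ]
  m <- mutate_start(s, orf)
  expect_identical(m$sequence, "AAATAGCTG")
  expect_equal(nrow(find_circular_orfs(m$sequence)), 0L)
  # two ATGs sharing a stop: mutating the first leaves the second
  s2 <- "ATGATGAAATAGCCC"
  orf2 <- find_circular_orfs(s2)[1, ]
  expect_warning(mutate_start(s2, orf2), "alternative start")
  # refusing a non-ATG start
  fake <- orf; fake$start <- 1L
  expect_error(mutate_start(s, fake), "not an ATG")
})

test_that("divergent primers amplify across the junction, deterministically", {
  set.seed(51)
  s <- random_dna(600)
  p1 <- design_divergent_primers(s)
  p2 <- design_divergent_primers(s)
  expect_identical(p1, p2)
  expect_true(grepl(junction_kmer(s, 10), p1$amplicon, fixed = TRUE))
  expect_gte(p1$amplicon_length, 80)
  expect_lte(p1$amplicon_length, 200)
  for (pr in c(p1$forward, p1$reverse)) {
    expect_gte(nchar(pr), 18); expect_lte(nchar(pr), 24)
    gc <- 100 * lengths(regmatches(pr, gregexpr("[GC]", pr))) / nchar(pr)
    expect_gte(gc, 40); expect_lte(gc, 60)
  }
  expect_error(design_divergent_primers(random_dna(60)), "shorter")
})

test_that("primer orientation is read off the linear transcript", {
  set.seed(52)
  circle <- random_dna(500)
  downstream <- random_dna(200)
  tx <- paste0(circle, downstream)   # linear context: exon then next exon
  dp <- design_divergent_primers(circle)
  expect_identical(classify_primer_orientation(dp, tx), "divergent")
  # a conventional pair pointing inward is convergent
  conv <- list(forward = substr(tx, 21, 40),
               reverse = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(tx, 301, 320)))))
  expect_identical(classify_primer_orientation(conv, tx), "convergent")
  off <- list(forward = strrep("ACGT", 5), reverse = dp$reverse)
  expect_error(classify_primer_orientation(off, tx), "uniquely")
})

test_that("junction siRNAs straddle the BSJ and miss the linear transcript", {
  cfg <- sim_config(seed = 13)
  g <- generate_genome(cfg)
  p <- plant_circrnas(g, cfg)
  catalog <- annotate_bsj(p$bsj, g)
  i <- which(p$truth$coding)[1]
  s <- catalog$sequence[i]; L <- nchar(s)
  tx <- transcript_sequence(g, p$truth$gene_id[i])
  si <- paste0(substr(s, L - 9, L), substr(s, 1, 9))
  chk <- check_sirna_junction(si, s, tx)
  expect_true(chk$junction_overlap)
  expect_false(chk$linear_offtarget)
  # a body siRNA is off-target on the transcript, not junction-specific
  body <- substr(s, 300, 318)
  chk2 <- check_sirna_junction(body, s, tx)
  expect_false(chk2$junction_overlap)
  expect_true(chk2$linear_offtarget)
  expect_error(check_sirna_junction("ACGTACGTACGTACGTACN", s), "unambiguous")
  expect_error(check_sirna_junction("ACGT", s), "length")
})

test_that("the three published junction siRNAs tile the junction at 1-2 nt offsets", {
  si01 <- "AGAGAGTTCAGGACAGATT"
  si02 <- "GAGAGTTCAGGACAGATTG"
  si03 <- "AGAGTTCAGGACAGATTGA"
  expect_identical(substr(si01, 2, 19), substr(si02, 1, 18))  # +1 shift
  expect_identical(substr(si01, 3, 19), substr(si03, 1, 17))  # +2 shift
  expect_identical(substr(si02, 2, 19), substr(si03, 1, 18))
})

test_that("tryptic digestion reproduces the worked junction peptide", {
  d <- tryptic_digest("SSRRYSEGREFRTD", missed = 0)
  expect_identical(d$peptide, c("SSR", "R", "YSEGR", "EFR", "TD"))
  expect_identical(paste(d$peptide, collapse = ""), "SSRRYSEGREFRTD")
  # K/R before P is protected
  expect_identical(tryptic_digest("AKPLR", 0)$peptide, c("AKPLR"))
  # missed cleavages concatenate adjacent fragments
  d1 <- tryptic_digest("SSRRYSEGREFRTD", missed = 1)
  m1 <- d1$peptide[d1$missed == 1]
  expect_identical(m1, c("SSRR", "RYSEGR", "YSEGREFR", "EFRTD"))
})

test_that("digestion with 0 missed cleavages reassembles random proteins", {
  set.seed(53)
  for (i in 1:100) {
    pr <- random_protein(sample(5:80, 1))
    d <- tryptic_digest(pr, 0)
    expect_identical(paste(d$peptide, collapse = ""), pr)
  }
})

test_that("peptide evidence localizes the circle-specific residues", {
  jp <- junction_peptide("MAAARTD", "MAAARSS")
  expect_identical(jp$divergence_positions, 6:7)
  expect_identical(jp$novel_suffix, "TD")
  expect_true("TD" %in% jp$distinguishing$peptide)
  # identical prefix: nothing distinguishes the circle protein
  jp2 <- junction_peptide("MAAAR", "MAAARSS")
  expect_length(jp2$divergence_positions, 0)
  expect_equal(nrow(jp2$distinguishing), 0)
  expect_identical(jp2$novel_suffix, "")
})

test_that("TCF motif scanning is strand-complete and N-safe", {
  hits <- scan_tcf_sites("ATCAAAG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 1)
  expect_equal(hits$strand, "+")
  expect_equal(nrow(scan_tcf_sites("GGCAAAG")), 0)
  rev_hit <- scan_tcf_sites("CTTTGAT")   # revcomp is ATCAAAG
  expect_equal(nrow(rev_hit), 1)
  expect_equal(rev_hit$strand, "-")
  expect_equal(rev_hit$position, 1)
  expect_equal(nrow(scan_tcf_sites("NNCAAAG")), 0)
  # mirror property under reverse complement
  set.seed(54)
  s <- paste0(random_dna(50), "TTCAAAG", random_dna(50))
  h_fwd <- scan_tcf_sites(s)
  h_rev <- scan_tcf_sites(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))
  expect_equal(nrow(h_fwd), nrow(h_rev))
  expect_setequal(nchar(s) - (h_fwd$position + 6) + 1, h_rev$position)
})
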