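# Circular translation, ORF enumeration (vs exhaustive oracle), IRES
# scanning and candidate ranking.

test_that("circular translation handles wrap, rolling and ambiguity", {
  t1 <- translate_circular("ATGAAATAG", 0)
  expect_equal(t1$protein, "MK")
  expect_equal(t1$nt_length, 9L)
  expect_equal(t1$stop_pos, 6L)
  expect_false(t1$spans_junction)

  t2 <- translate_circular("AAATAGATG", 6)   # wraps: codons 6-8, 0-2, 3-5
  expect_equal(t2$protein, "MK")
  expect_equal(t2$stop_pos, 3L)
  expect_true(t2$spans_junction)
  expect_equal(t2$cycles_crossed, 1L)

  t3 <- translate_circular("ATGAAAAAA", 0)   # stop-free, L %% 3 == 0
  expect_true(t3$rolling)
  expect_equal(t3$nt_length, 27L)            # capped at max_cycles = 3

  t4 <- translate_circular("ATGNAATAG", 0)
  expect_true(t4$ambiguous)
  expect_equal(t4$protein, "M")

  expect_error(translate_circular("AT", 0), "shorter")
  expect_error(translate_circular("ATGAAATAG", 9), "start")
})

test_that("ORF enumeration matches the hand-worked examples", {
  o1 <- find_circular_orfs("ATGAAATAG")
  expect_equal(nrow(o1), 1L)
  expect_equal(o1$aa_length, 2L)
  expect_false(o1$spans_junction)

  o2 <- find_circular_orfs("AAATAGATG")
  expect_equal(nrow(o2), 1L)
  expect_equal(o2$aa_length, 2L)
  expect_true(o2$spans_junction)

  # nested starts sharing a stop are deduplicated to the longest
  o3 <- find_circular_orfs("ATGATGAAATAGCCC")
  expect_equal(sum(o3$stop_pos == 9, na.rm = TRUE), 1L)
  expect_equal(o3$start[which(o3$stop_pos == 9)], 0L)
})

test_that("ORF sets equal the exhaustive modular-walk oracle on random circles", {
  set.seed(101)
  cols <- c("start", "nt_length", "aa_length", "spans_junction",
            "rolling", "stop_pos", "protein")
  for (i in 1:120) {
    L <- sample(3:30, 1)
    s <- random_dna(L)
    mine <- find_circular_orfs(s)[, cols]
    orc <- oracle_orfs(s)[, cols]
    rownames(mine) <- rownames(orc) <- NULL
    expect_identical(mine, orc)
  }
})

test_that("ORF detection is rotation covariant", {
  set.seed(102)
  for (i in 1:40) {
    L <- sample(9:30, 1)
    s <- random_dna(L)
    base <- find_circular_orfs(s)
    r <- sample(L - 1, 1)
    rot <- paste0(substr(s, r + 1, L), substr(s, 1, r))
    rotated <- find_circular_orfs(rot)
    expect_equal(nrow(base), nrow(rotated))
    if (!nrow(base)) next
    key <- function(o) o[order(o$start), c("aa_length", "rolling",
                                           "protein")]
    base$start <- (base$start - r) %% L
    expect_equal(key(base), key(rotated), ignore_attr = TRUE)
  }
})

test_that("stop-free walks terminate or flag per circle-length arithmetic", {
  # L %% 3 == 0 and a stop-free frame: rolling flagged
  roll <- find_circular_orfs("ATGAAAAAA")
  expect_true(roll$rolling[1])
  # L %% 3 != 0: the walk visits every position within 3 cycles, so any
  # stop anywhere terminates every ORF
  withstop <- find_circular_orfs("ATGAAAAATAG")  # L = 11
  expect_true(all(!withstop$rolling))
  expect_true(all(withstop$cycles_crossed <= 3))
  # L %% 3 != 0 and not a single reachable stop: flagged at max_cycles
  nostop <- find_circular_orfs("ATGCCCCCCC")     # L = 10, stop-free
  expect_true(all(nostop$rolling))
})

test_that("junction-spanning proteins re-translate from the doubled linear sequence", {
  set.seed(103)
  for (i in 1:30) {
    s <- random_dna(sample(12:40, 1))
    orfs <- find_circular_orfs(s)
    orfs <- orfs[orfs$spans_junction & !orfs$rolling, , drop = FALSE]
    for (j in seq_len(nrow(orfs))) {
      lin <- strrep(s, 4)
      cds <- substr(lin, orfs$start[j] + 1,
                    orfs$start[j] + orfs$nt_length[j] - 3)
      n <- nchar(cds) / 3
      aa <- paste(seqinr::translate(seqinr::s2c(cds)), collapse = "")
      expect_identical(aa, orfs$protein[j])
    }
  }
})

test_that("IRES scanning reports imported intervals verbatim", {
  s <- random_dna(959)
  h <- scan_ires(s, intervals = data.frame(start = c(115, 689),
                                           end = c(257, 838)))
  expect_equal(h$span, c(143L, 150L))
  expect_equal(h$start, c(115L, 689L))
  expect_error(scan_ires(s, intervals = data.frame(start = 0, end = 10)),
               "intervals")
})

test_that("the IRES heuristic finds planted tracts and ignores poly-A", {
  expect_equal(nrow(scan_ires(strrep("A", 400))), 0L)
  set.seed(104)
  # 60-nt polypyrimidine tract ending 10 nt before an ATG at position 161
  s <- paste0(random_dna(90), paste(sample(c("C", "T"), 60, TRUE),
                                    collapse = ""),
              paste(sample(c("C", "T"), 10, TRUE), collapse = ""),
              "ATG", random_dna(300))
  h <- scan_ires(s)
  expect_gt(nrow(h), 0)
  expect_true(any(h$start <= 91 & h$end >= 150))  # hit covers the tract
  expect_warning(scan_ires(random_dna(100)), "clipped")
})

test_that("candidate ranking applies the funnel filters in order", {
  cfg <- sim_config(seed = 12)
  g <- generate_genome(cfg)
  p <- plant_circrnas(g, cfg)
  catalog <- annotate_bsj(p$bsj, g)
  cc <- simulate_counts(p$truth, cfg)
  tpm <- tpm_normalize(cc$circ, cc$lengths)
  screen <- screen_circrnas(tpm, cc$design)
  orfs <- find_catalog_orfs(catalog)
  ires <- lapply(catalog$sequence, function(s)
    suppressWarnings(scan_ires(s)))
  names(ires) <- catalog$circ_id
  cand <- rank_candidates(catalog, screen, orfs, ires)
  finals <- cand$circ_id[cand$passes_all]
  expect_setequal(finals, p$truth$circ_id[p$truth$coding])
  # the analog (longest ORF) ranks first
  expect_equal(cand$circ_id[which(cand$rank == 1)],
               p$truth$circ_id[p$truth$coding & p$truth$length >= 900])
  # every filter flag is present and rank is defined only for full passes
  expect_true(all(is.na(cand$rank[!cand$passes_all])))
  # a circle without an ATG fails the ORF filter specifically
  no_atg <- gsub("ATG", "ACG",
                 paste0(strrep("GCC", 100), strrep("GTT", 100)))
  cat2 <- catalog[1, ]
  cat2$sequence <- no_atg; cat2$length <- nchar(no_atg)
  sc2 <- screen[screen$circ_id == cat2$circ_id, ]
  sc2$passes_de <- TRUE; sc2$passes_recurrence <- TRUE
  cand2 <- rank_candidates(cat2, sc2, find_catalog_orfs(cat2),
                           setNames(list(suppressWarnings(
                             scan_ires(no_atg))), cat2$circ_id))
  expect_true(cand2$pass_de && cand2$pass_length)
  expect_false(cand2$pass_orf)
})
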