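# Independent oracles and hand-built fixtures used across the suite.

# --- exhaustive circular-ORF oracle -------------------------------------
# Walks every ATG start on a linearized repeat of the circle (string
# mechanics + seqinr translation), applies the published deduplication
# rule, and sorts. Shares no code with find_circular_orfs().
oracle_orfs <- function(sequence, max_cycles = 3L) {
  L <- nchar(sequence)
  rep_seq <- strrep(sequence, max_cycles + 1L)
  n_max <- (max_cycles * L) %/% 3L
  rows <- list()
  for (p in 0:(L - 1L)) {
    if (substr(rep_seq, p + 1L, p + 3L) != "ATG") next
    aa <- character(0); stopped <- FALSE; nt <- 0L
    for (k in seq_len(n_max)) {
      codon <- substr(rep_seq, p + 3L * (k - 1L) + 1L, p + 3L * k)
      res <- seqinr::translate(seqinr::s2c(codon))
      nt <- nt + 3L
      if (res == "*") { stopped <- TRUE; break }
      aa <- c(aa, res)
    }
    crossings <- if (nt == 0L) 0L else (p + nt - 1L) %/% L
    rows[[length(rows) + 1L]] <- data.frame(
      start = p, nt_length = nt, aa_length = length(aa),
      spans_junction = crossings >= 1L, rolling = !stopped,
      stop_pos = if (stopped) (p + nt - 3L) %% L else NA_integer_,
      protein = paste(aa, collapse = ""), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), nt_length = integer(0),
                      aa_length = integer(0), spans_junction = logical(0),
                      rolling = logical(0), stop_pos = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  orf <- do.call(rbind, rows)
  key <- ifelse(orf$rolling, paste0("r", orf$start),
                paste0("s", orf$stop_pos))
  ord <- order(-orf$nt_length, orf$start)
  orf <- orf[ord, , drop = FALSE]
  orf <- orf[!duplicated(key[ord]), , drop = FALSE]
  orf <- orf[order(-orf$aa_length, orf$start), , drop = FALSE]
  rownames(orf) <- NULL
  orf
}

# --- brute-force AUC over all positive/negative pairs -------------------
oracle_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]; neg <- values[!as.logical(labels)]
  s <- 0
  for (vp in pos) for (vn in neg)
    s <- s + (vp > vn) + 0.5 * (vp == vn)
  s / (length(pos) * length(neg))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_protein <- function(n) {
  paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""), n,
               replace = TRUE), collapse = "")
}

# --- minimal hand-built annotation fixture ------------------------------
# One 4000-nt contig with two genes:
#   geneA (+): exons 1001-1200 and 1501-1800 (intron 1201-1500)
#   geneB (-): single exon 2501-2900
tiny_genome <- function(seed = 42) {
  set.seed(seed)
  ctg <- random_dna(4000)
  genes <- data.frame(
    gene_id = c("geneA", "geneB"), contig = "ctgT",
    strand = c("+", "-"), start = c(1001L, 2501L), end = c(1800L, 2900L),
    n_exons = c(2L, 1L), cds_offset = NA_integer_, coding_host = FALSE,
    host_exon_rank = NA_integer_, orf_start = NA_integer_,
    ires_start = NA_integer_, ires_end = NA_integer_,
    protein = NA_character_, parent_protein = NA_character_,
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB"),
    rank = c(1L, 2L, 1L), contig = "ctgT",
    strand = c("+", "+", "-"),
    start = c(1001L, 1501L, 2501L), end = c(1200L, 1800L, 2900L),
    stringsAsFactors = FALSE)
  g <- list(contigs = Biostrings::DNAStringSet(c(ctgT = ctg)),
            genes = genes, exons = exons)
  class(g) <- "GenomeBundle"
  g
}

# truth table for pure count simulations (no genome needed)
null_truth <- function(n, cfg, length = 500L) {
  fc <- matrix(1, n, cfg$n_pairs,
               dimnames = list(NULL, sprintf("fc_pair%d",
                                             seq_len(cfg$n_pairs))))
  data.frame(circ_id = sprintf("c%04d", seq_len(n)),
             gene_id = NA_character_, length = length,
             linear_length = NA_integer_, fc, stringsAsFactors = FALSE)
}
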