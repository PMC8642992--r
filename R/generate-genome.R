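# Synthetic genome and annotation generator.
#
# Coding-circle cassette geometry (0-based circle coordinates, length L,
# ORF start s with (L - s) %% 3 == 2):
#
#   [0,7)    "GCTCAGA"   acceptor-side prefix, shared with the downstream
#                        exon's first 7 nt so the junction-proximal codons
#                        reproduce the linear (parental) protein
#   [7,13)   "ACTGAT"    the two novel C-terminal codons (Thr, Asp)
#   [13,16)  "TAA"       the ORF's stop, >= 10 nt past the junction so a
#                        tag inserted before it leaves the junction 20-mer
#                        intact
#   [s-70,s-10) 60 nt C/T polypyrimidine tract (the IRES-like element)
#   [s-3,s)  "TAA"       in-frame upstream stop: no upstream ATG can extend
#                        the planted ORF
#   [s,s+3)  "ATG"       the annotated start codon
#   [s+3,L-2) stop-free, ATG-free codons
#   [L-2,L)  "GA"        donor-side bases; junction-spanning codon "GAG"
#
# The downstream exon shares only 7 nt with the circle's acceptor end
# (< the 10-nt counting anchor), so the junction 20-mer never occurs in
# the linear transcript: BSJ read counting and junction siRNAs stay
# junction-specific.

CASSETTE_PREFIX <- "GCTCAGA"      # codons L, R after the spanning codon
CASSETTE_NOVEL <- "ACTGAT"        # novel residues T, D
CASSETTE_DONOR <- "GA"            # completes spanning codon GAG (Glu)
DOWNSTREAM_EXON_LEN <- 90L

# choose the ORF start for a host exon of length L: s in {158,159,160}
# with (L - s) %% 3 == 2
cassette_orf_start <- function(L) {
  s <- 158L + ((L - 2L - 158L) %% 3L)
  stopifnot((L - s) %% 3L == 2L, s >= 86L)
  s
}

# Build one engineered host-exon (circle) sequence plus its downstream exon
# and the resulting circular / parental proteins.
design_coding_cassette <- function(L) {
  s <- cassette_orf_start(L)
  tab <- codon_table()
  n_body <- (L - s - 5L) / 3L  # stop-free codons between ATG and donor bases
  body <- sample(safe_codons(), n_body, replace = TRUE)
  filler <- rand_dna(s - 70L - 16L)
  tract <- paste(sample(c("C", "T"), 60L, replace = TRUE), collapse = "")
  spacer <- paste(sample(c("C", "T"), 7L, replace = TRUE), collapse = "")
  circle <- paste0(CASSETTE_PREFIX, CASSETTE_NOVEL, "TAA", filler, tract,
                   spacer, "TAA", "ATG", paste(body, collapse = ""),
                   CASSETTE_DONOR)
  stopifnot(nchar(circle) == L)
  protein <- paste0("M", paste(tab[body], collapse = ""), "E", "L", "R",
                    "T", "D")
  downstream <- paste0(CASSETTE_PREFIX, "TCC", "AGC", "GGC", "TGC", "TAA",
                       rand_dna(DOWNSTREAM_EXON_LEN - 22L))
  parent_tail <- "SSGC"  # residues the linear protein has where the circle
                         # reads T, D and stops
  parent <- paste0(substr(protein, 1L, nchar(protein) - 2L), parent_tail)
  list(circle = circle, downstream = downstream, orf_start = s,
       ires_start = s - 69L, ires_end = s - 10L,  # 1-based on the circle
       protein = protein, parent_protein = parent)
}

#' Generate a toy genome with annotation
#'
#' Places `n_genes` multi-exon genes on both strands of `n_contigs` random
#' contigs. The first `n_coding` genes are engineered coding-circRNA hosts:
#' gene 1 is the "hot" analog (a 959-nt second exon hosting a single-exon
#' circle, mirroring a circle formed from one large internal exon), the
#' others carry a 600-nt host exon. Each host exon contains a complete
#' coding cassette (see the package vignette): an IRES-like polypyrimidine
#' element, an annotated ATG, a stop-free body, and a junction-spanning
#' termination such that exactly two novel residues precede the stop.
#'
#' Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `GenomeBundle`: list with `contigs` (a
#'   [Biostrings::DNAStringSet]), `genes` and `exons` data frames
#'   (1-based inclusive coordinates; exon `rank` is transcript order).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  contig_names <- sprintf("ctg%02d", seq_len(config$n_contigs))
  contig_chr <- vapply(seq_len(config$n_contigs),
                       function(i) rand_dna(config$contig_length),
                       character(1))
  names(contig_chr) <- contig_names

  genes <- list(); exons <- list()
  cursor <- setNames(rep(1500L, config$n_contigs), contig_names)

  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("gene%03d", i)
    ctg <- contig_names[((i - 1L) %% config$n_contigs) + 1L]
    is_host <- i <= config$n_coding
    if (is_host) {
      strand <- if (i == 1L) "+" else c("+", "-")[(i %% 2L) + 1L]
      host_len <- if (i == 1L) 959L else 600L
      cassette <- design_coding_cassette(host_len)
      if (i == 1L) {
        ex_len <- c(100L, host_len, DOWNSTREAM_EXON_LEN)
        ex_seq <- c(rand_dna(100L), cassette$circle, cassette$downstream)
        host_rank <- 2L
      } else {
        ex_len <- c(host_len, DOWNSTREAM_EXON_LEN)
        ex_seq <- c(cassette$circle, cassette$downstream)
        host_rank <- 1L
      }
      cds_offset <- sum(ex_len[seq_len(host_rank - 1L)]) + cassette$orf_start
    } else {
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      ex_seq <- NULL
      cds_offset <- NA_integer_
      cassette <- NULL
      host_rank <- NA_integer_
    }
    n_ex <- length(ex_len)
    intron_len <- if (n_ex > 1L) sample(200:600, n_ex - 1L, replace = TRUE)
                  else integer(0)
    span <- sum(ex_len) + sum(intron_len)
    gstart <- cursor[ctg] + sample(800:1500, 1L)
    gend <- gstart + span - 1L
    if (gend > config$contig_length - 500L)
      stopf(paste("contig %s too short for gene %s (need %d nt):",
                  "increase contig_length or reduce n_genes"),
            ctg, gid, gend + 500L)
    cursor[ctg] <- gend

    # genomic exon order: transcript order on '+', reversed on '-'
    tx_order <- seq_len(n_ex)
    genomic_order <- if (strand == "+") tx_order else rev(tx_order)
    len_genomic <- ex_len[genomic_order]
    starts <- gstart + cumsum(c(0L, head(len_genomic, -1L) +
                                  intron_len))
    ends <- starts + len_genomic - 1L

    if (is_host) {
      for (k in seq_len(n_ex)) {   # k indexes genomic order
        rank_k <- genomic_order[k]
        s_tx <- ex_seq[rank_k]
        seg <- if (strand == "+") s_tx else revcomp(s_tx)
        substr(contig_chr[ctg], starts[k], ends[k]) <- seg
      }
    }

    genes[[i]] <- data.frame(
      gene_id = gid, contig = ctg, strand = strand,
      start = gstart, end = gend, n_exons = n_ex,
      cds_offset = cds_offset,
      coding_host = is_host,
      host_exon_rank = if (is_host) host_rank else NA_integer_,
      orf_start = if (is_host) cassette$orf_start else NA_integer_,
      ires_start = if (is_host) cassette$ires_start else NA_integer_,
      ires_end = if (is_host) cassette$ires_end else NA_integer_,
      protein = if (is_host) cassette$protein else NA_character_,
      parent_protein = if (is_host) cassette$parent_protein
                       else NA_character_,
      stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(
      gene_id = gid, rank = genomic_order, contig = ctg, strand = strand,
      start = starts, end = ends, stringsAsFactors = FALSE)
  }

  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), contig = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               n_exons = integer(0), cds_offset = integer(0),
               coding_host = logical(0), host_exon_rank = integer(0),
               orf_start = integer(0), ires_start = integer(0),
               ires_end = integer(0), protein = character(0),
               parent_protein = character(0), stringsAsFactors = FALSE)
  exons_df <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(0), rank = integer(0),
               contig = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  rownames(genes_df) <- NULL; rownames(exons_df) <- NULL

  bundle <- list(contigs = Biostrings::DNAStringSet(contig_chr),
                 genes = genes_df, exons = exons_df)
  class(bundle) <- "GenomeBundle"
  bundle
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf("GenomeBundle: %d contig(s), %d gene(s), %d exon(s)\n",
              length(x$contigs), nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Spliced, strand-oriented transcript sequence of a gene
#'
#' Concatenates the gene's exons in genomic order and reverse-complements
#' the result for minus-strand genes, yielding the 5'->3' representative
#' transcript.
#'
#' @param genome A `GenomeBundle`.
#' @param gene_id Gene identifier.
#' @return A character scalar (DNA).
#' @export
transcript_sequence <- function(genome, gene_id) {
  ex <- genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stopf("unknown gene_id: %s", gene_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  ctg <- as.character(genome$contigs[[ex$contig[1]]])
  parts <- substring(ctg, ex$start, ex$end)
  s <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") s <- revcomp(s)
  s
}

#' Parental protein of a gene
#'
#' Translates the representative transcript from the annotated CDS offset to
#' the first stop (or transcript end when no stop occurs before it).
#'
#' @param genome A `GenomeBundle`.
#' @param gene_id Gene identifier.
#' @return Amino-acid string (stop excluded), or `NA` when the gene has no
#'   annotated CDS.
#' @export
parental_protein <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stopf("unknown gene_id: %s", gene_id)
  if (is.na(g$cds_offset)) return(NA_character_)
  tx <- transcript_sequence(genome, gene_id)
  cds <- substr(tx, g$cds_offset + 1L, nchar(tx))
  n_cod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  aa <- codon_table()[codons]
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}
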