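# Readers and writers for the standard formats the pipeline exchanges.

#' Write a GenomeBundle to FASTA + GFF3
#'
#' The annotation is written as gene/mRNA/exon features (1-based
#' inclusive, per GFF3); the CDS offset of engineered genes travels in a
#' `cds_offset` gene attribute.
#'
#' @param genome A `GenomeBundle`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome_bundle <- function(genome, fasta, gff3) {
  Biostrings::writeXStringSet(genome$contigs, fasta)
  g <- genome$genes; e <- genome$exons
  feats <- c(
    if (nrow(g)) GenomicRanges::GRanges(g$contig,
      IRanges::IRanges(g$start, g$end), strand = g$strand,
      type = "gene", ID = g$gene_id, Parent = NA_character_,
      cds_offset = g$cds_offset),
    if (nrow(g)) GenomicRanges::GRanges(g$contig,
      IRanges::IRanges(g$start, g$end), strand = g$strand,
      type = "mRNA", ID = paste0(g$gene_id, ".t1"), Parent = g$gene_id,
      cds_offset = NA_integer_),
    if (nrow(e)) GenomicRanges::GRanges(e$contig,
      IRanges::IRanges(e$start, e$end), strand = e$strand,
      type = "exon", ID = sprintf("%s.e%d", e$gene_id, e$rank),
      Parent = paste0(e$gene_id, ".t1"), cds_offset = NA_integer_))
  if (is.null(feats)) {
    writeLines("##gff-version 3", gff3)
  } else {
    rtracklayer::export(feats, gff3, format = "gff3")
  }
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Read a GenomeBundle from FASTA + GFF3
#'
#' Inverse of [write_genome_bundle()] (generator-specific design columns
#' such as planted proteins are not round-tripped; they live in the truth
#' table).
#'
#' @param fasta,gff3 Input paths.
#' @return A `GenomeBundle`.
#' @export
read_genome_bundle <- function(fasta, gff3) {
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- tryCatch(rtracklayer::import(gff3, format = "gff3"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0L) {
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), n_exons = integer(0),
                        cds_offset = integer(0), coding_host = logical(0),
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = character(0), rank = integer(0),
                        contig = character(0), strand = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  } else {
    md <- S4Vectors::mcols(gr)
    is_gene <- md$type == "gene"
    is_exon <- md$type == "exon"
    cds <- if ("cds_offset" %in% names(md))
      suppressWarnings(as.integer(md$cds_offset[is_gene]))
    else rep(NA_integer_, sum(is_gene))
    genes <- data.frame(
      gene_id = as.character(md$ID[is_gene]),
      contig = as.character(GenomicRanges::seqnames(gr[is_gene])),
      strand = as.character(GenomicRanges::strand(gr[is_gene])),
      start = GenomicRanges::start(gr[is_gene]),
      end = GenomicRanges::end(gr[is_gene]),
      cds_offset = cds, stringsAsFactors = FALSE)
    parent_tx <- as.character(unlist(md$Parent[is_exon]))
    exons <- data.frame(
      gene_id = sub("\\.t1$", "", parent_tx),
      rank = suppressWarnings(as.integer(sub("^.*\\.e", "",
                                             md$ID[is_exon]))),
      contig = as.character(GenomicRanges::seqnames(gr[is_exon])),
      strand = as.character(GenomicRanges::strand(gr[is_exon])),
      start = GenomicRanges::start(gr[is_exon]),
      end = GenomicRanges::end(gr[is_exon]),
      stringsAsFactors = FALSE)
    genes$n_exons <- as.integer(table(exons$gene_id)[genes$gene_id])
    genes$coding_host <- !is.na(genes$cds_offset)
  }
  bundle <- list(contigs = contigs, genes = genes, exons = exons)
  class(bundle) <- "GenomeBundle"
  bundle
}

#' Write BSJ calls as BED6
#'
#' @param bsj BED-like data frame (`chrom`, `start` 0-based, `end`,
#'   `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bsj_bed <- function(bsj, path) {
  gr <- GenomicRanges::GRanges(bsj$chrom,
                               IRanges::IRanges(bsj$start + 1L, bsj$end),
                               strand = bsj$strand,
                               name = bsj$name, score = bsj$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BSJ calls from BED
#'
#' BED is 0-based half-open; an optional `one_based` flag converts
#' 1-based inclusive input (GFF-style intervals) on the fly.
#'
#' @param path BED file.
#' @param one_based Set TRUE when the file carries 1-based inclusive
#'   coordinates.
#' @return BED-like data frame (0-based half-open).
#' @export
read_bsj_bed <- function(path, one_based = FALSE) {
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  if (one_based) { start0 <- start0 - 1L }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end,
             name = if (!is.null(gr$name)) as.character(gr$name)
                    else sprintf("circ_%03d", seq_along(gr)),
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write circular sequences as FASTA
#'
#' Headers carry id, coordinates and category.
#'
#' @param catalog Catalog from [annotate_bsj()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- sprintf("%s %s:%d-%d(%s) %s", catalog$circ_id,
                         catalog$contig, catalog$start, catalog$end,
                         catalog$strand, catalog$category)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
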