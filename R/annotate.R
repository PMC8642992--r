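# BSJ classification against the annotation and circular-sequence
# reconstruction.
#
# Coordinate conventions: BSJ input is BED-like 0-based half-open (so the
# printed span 396,147-397,106 has length end - start = 959);
# the annotation is 1-based inclusive. The reconstructed circular sequence
# is oriented 5'->3' on the transcribed strand and registered with
# position 0 immediately downstream of the back-splice junction (the
# splice-acceptor side), so the junction sits between the last and first
# nucleotide.

#' Classify one BSJ event into the five genomic categories
#'
#' Applies the category rules in precedence order: (1) *exonic* when both
#' BSJ ends coincide with annotated exon boundaries of a same-strand gene;
#' (2) *intronic* when the span lies entirely within one intron of a
#' same-strand gene; (3) *sense_overlapping* when it overlaps a same-strand
#' gene but neither rule applies; (4) *antisense* when it overlaps only
#' opposite-strand gene(s); (5) *intergenic* otherwise. The precedence
#' makes the categories mutually exclusive and the call total.
#'
#' @param bsj A list/one-row data frame with `chrom`, `start` (0-based),
#'   `end`, `strand`.
#' @param genome A `GenomeBundle`.
#' @return List with `category` and, for gene-linked calls, `gene_id`.
#' @export
classify_circ <- function(bsj, genome) {
  if (bsj$start >= bsj$end)
    stopf("malformed BSJ interval (start >= end) in record %s:%d-%d",
          bsj$chrom, bsj$start, bsj$end)
  if (!bsj$chrom %in% names(genome$contigs))
    stopf("unknown contig '%s' in BSJ record", bsj$chrom)
  first <- bsj$start + 1L; last <- bsj$end  # 1-based inclusive
  g <- genome$genes[genome$genes$contig == bsj$chrom, , drop = FALSE]
  overlapping <- g[g$start <= last & g$end >= first, , drop = FALSE]
  same <- overlapping[overlapping$strand == bsj$strand, , drop = FALSE]

  for (k in seq_len(nrow(same))) {
    ex <- genome$exons[genome$exons$gene_id == same$gene_id[k], ]
    if (any(ex$start == first) && any(ex$end == last))
      return(list(category = "exonic", gene_id = same$gene_id[k]))
  }
  for (k in seq_len(nrow(same))) {
    ex <- genome$exons[genome$exons$gene_id == same$gene_id[k], ]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    for (j in seq_len(nrow(ex) - 1L)) {
      if (first > ex$end[j] && last < ex$start[j + 1L])
        return(list(category = "intronic", gene_id = same$gene_id[k]))
    }
  }
  if (nrow(same) > 0L)
    return(list(category = "sense_overlapping", gene_id = same$gene_id[1]))
  if (nrow(overlapping) > 0L)
    return(list(category = "antisense", gene_id = NA_character_))
  list(category = "intergenic", gene_id = NA_character_)
}

#' Reconstruct the circular sequence of a BSJ event
#'
#' Exonic events are spliced: the exon blocks of the matched gene within
#' the BSJ span are concatenated (introns removed). Other categories take
#' the genomic span as one block. Minus-strand events are
#' reverse-complemented (block order reversed) so the sequence reads
#' 5'->3'; position 0 is the acceptor-side base.
#'
#' @param bsj A list/one-row data frame with `chrom`, `start` (0-based),
#'   `end`, `strand`, plus `category`/`gene_id` from [classify_circ()]
#'   (computed when absent).
#' @param genome A `GenomeBundle`.
#' @return List with `sequence`, `blocks` (matrix of 1-based inclusive
#'   block coordinates), `length`, `category`, `gene_id`.
#' @export
reconstruct_sequence <- function(bsj, genome) {
  if (is.null(bsj$category)) {
    cls <- classify_circ(bsj, genome)
    bsj$category <- cls$category; bsj$gene_id <- cls$gene_id
  }
  first <- bsj$start + 1L; last <- bsj$end
  ctg <- as.character(genome$contigs[[bsj$chrom]])
  if (last > nchar(ctg))
    stopf("BSJ span %s:%d-%d exceeds contig length %d", bsj$chrom,
          bsj$start, bsj$end, nchar(ctg))
  if (bsj$category == "exonic") {
    ex <- genome$exons[genome$exons$gene_id == bsj$gene_id, , drop = FALSE]
    ex <- ex[ex$start >= first & ex$end <= last, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    blocks <- cbind(start = ex$start, end = ex$end)
  } else {
    blocks <- cbind(start = first, end = last)
  }
  parts <- substring(ctg, blocks[, "start"], blocks[, "end"])
  s <- paste(parts, collapse = "")
  if (bsj$strand == "-") s <- revcomp(s)
  list(sequence = s, blocks = blocks, length = nchar(s),
       category = bsj$category, gene_id = bsj$gene_id)
}

#' Circle length from BSJ coordinates
#'
#' Single-block circles have length `end - start` (0-based half-open
#' input); spliced circles sum their exon block lengths.
#'
#' @param bsj Data frame with `start` and `end` columns (0-based
#'   half-open), optionally a `blocks` list column of 1-based inclusive
#'   block matrices.
#' @return Integer vector of lengths (nt).
#' @export
#' @examples
#' circ_length(data.frame(start = 396147, end = 397106))  # 959
circ_length <- function(bsj) {
  if (any(bsj$start >= bsj$end))
    stopf("malformed BSJ interval (start >= end)")
  if (!is.null(bsj$blocks)) {
    vapply(seq_len(nrow(bsj)), function(i) {
      b <- bsj$blocks[[i]]
      if (is.null(b)) as.integer(bsj$end[i] - bsj$start[i])
      else as.integer(sum(b[, "end"] - b[, "start"] + 1L))
    }, integer(1))
  } else {
    as.integer(bsj$end - bsj$start)
  }
}

#' Annotate a table of BSJ calls
#'
#' Vectorized driver: classifies every BSJ record, reconstructs its
#' circular sequence and returns the annotated catalog.
#'
#' @param bsj BED-like data frame (`chrom`, `start`, `end`, `name`
#'   (optional), `strand`), 0-based half-open.
#' @param genome A `GenomeBundle`.
#' @return Catalog data frame: `circ_id`, coordinates, `strand`,
#'   `category`, `gene_id`, `n_blocks`, `length`, `sequence`, plus a
#'   `blocks` list column.
#' @export
annotate_bsj <- function(bsj, genome) {
  ids <- if (!is.null(bsj$name)) as.character(bsj$name)
         else sprintf("circ_%03d", seq_len(nrow(bsj)))
  out <- vector("list", nrow(bsj))
  for (i in seq_len(nrow(bsj))) {
    rec <- as.list(bsj[i, ])
    cls <- classify_circ(rec, genome)
    rec$category <- cls$category; rec$gene_id <- cls$gene_id
    rc <- reconstruct_sequence(rec, genome)
    out[[i]] <- list(row = data.frame(
      circ_id = ids[i], contig = rec$chrom, start = rec$start,
      end = rec$end, strand = rec$strand, category = rec$category,
      gene_id = rec$gene_id, n_blocks = nrow(rc$blocks),
      length = rc$length, sequence = rc$sequence,
      stringsAsFactors = FALSE), blocks = rc$blocks)
  }
  catalog <- do.call(rbind, lapply(out, `[[`, "row"))
  catalog$blocks <- lapply(out, `[[`, "blocks")
  rownames(catalog) <- NULL
  catalog
}

#' Category percentages, printed-report style
#'
#' Percentages of category counts rounded half away from zero to whole
#' percent (the convention under which 36,218 / 462 / 1,848 / 6,744 / 511
#' of 45,783 print as 79 / 1 / 4 / 15 / 1).
#'
#' @param counts Named integer vector of category counts.
#' @return Named integer vector of percentages.
#' @export
category_percentages <- function(counts) {
  if (sum(counts) == 0) return(setNames(integer(length(counts)),
                                        names(counts)))
  setNames(as.integer(round_half_up(100 * counts / sum(counts))),
           names(counts))
}

#' Summarize an annotated catalog
#'
#' Category counts with rounded percentages and a length histogram using
#' the conventional sub-1500-nt emphasis bin.
#'
#' @param catalog Catalog from [annotate_bsj()] (needs `category` and
#'   `length` columns).
#' @param length_breaks Histogram breaks (nt).
#' @return List with `categories` (count + percent per category),
#'   `length_hist` (counts per bin) and `frac_below_1500`; an
#'   `empty = TRUE` marker when the catalog has no rows.
#' @export
summarize_catalog <- function(catalog,
                              length_breaks = c(0, 500, 1000, 1500, Inf)) {
  if (nrow(catalog) == 0L)
    return(list(empty = TRUE, categories = NULL, length_hist = NULL))
  counts <- table(factor(catalog$category, levels = CATEGORIES))
  counts <- setNames(as.integer(counts), names(counts))
  pct <- category_percentages(counts)
  lh <- table(cut(catalog$length, breaks = length_breaks, right = FALSE))
  list(empty = FALSE,
       categories = data.frame(category = names(counts), count = counts,
                               percent = pct, row.names = NULL,
                               stringsAsFactors = FALSE),
       length_hist = setNames(as.integer(lh), names(lh)),
       frac_below_1500 = mean(catalog$length < 1500))
}
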