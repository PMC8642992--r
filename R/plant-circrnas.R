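# Planting BSJ events of the five genomic categories, with truth records.

CATEGORIES <- c("exonic", "intronic", "intergenic", "sense_overlapping",
                "antisense")

# deterministic largest-remainder apportionment of n over fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Plant back-splice junction events on a synthetic genome
#'
#' Chooses `config$n_circ` BSJ events whose realized category proportions
#' follow `config$category_mix` (largest-remainder apportionment, so within
#' one count of the target). The `config$n_coding` engineered host exons
#' become single-exon coding circles, planted up `planted_fc`-fold in
#' every pair (the analog-like pattern, comfortably clear of the FC > 2
#' rule); `config$n_de_extra` further non-coding
#' circles are planted down-regulated (`1/planted_fc`) in 3, 4 or 5 of the
#' pairs (cycling). The symmetric up/down planting keeps the library
#' composition balanced, so planted fold changes are recoverable on the
#' relative (TPM) scale the screen measures, and the recurrence rule
#' ("up in >= 3 of n pairs", strict FC > 2) separates the coding plants
#' from the down-regulated extras in the funnel.
#'
#' @param genome A `GenomeBundle` from [generate_genome()] built with the
#'   same `config`.
#' @param config The [sim_config()] used for the genome.
#' @return A list with `truth` (one row per circle: identity, category,
#'   coding flag, planted protein/IRES interval, lengths, per-pair planted
#'   fold changes `fc_pair*`) and `bsj` (BED-like data frame, 0-based
#'   half-open, columns chrom/start/end/name/score/strand).
#' @export
plant_circrnas <- function(genome, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  counts <- apportion(config$n_circ, config$category_mix[CATEGORIES])
  names(counts) <- CATEGORIES
  if (counts["exonic"] < config$n_coding)
    stopf(paste("no room for %d coding plants among %d exonic circles:",
                "raise category_mix['exonic'] or n_circ"),
          config$n_coding, counts["exonic"])
  hosts <- genome$genes[genome$genes$coding_host, , drop = FALSE]
  if (nrow(hosts) < config$n_coding)
    stopf(paste("no eligible host exon for a coding plant:",
                "generate the genome with the same config (n_coding=%d)"),
          config$n_coding)

  rows <- list()
  seen <- character(0)
  add_row <- function(contig, start0, end, strand, category, gene_id,
                      coding = FALSE, host = NULL, blocks_len = NULL) {
    key <- paste(contig, start0, end, strand)
    if (key %in% seen) return(FALSE)
    seen <<- c(seen, key)
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, start = start0, end = end, strand = strand,
      category = category, gene_id = gene_id, coding = coding,
      protein = if (coding) host$protein else NA_character_,
      parent_protein = if (coding) host$parent_protein else NA_character_,
      orf_start = if (coding) host$orf_start else NA_integer_,
      ires_start = if (coding) host$ires_start else NA_integer_,
      ires_end = if (coding) host$ires_end else NA_integer_,
      length = if (is.null(blocks_len)) end - start0 else blocks_len,
      stringsAsFactors = FALSE)
    TRUE
  }

  # --- coding plants: the engineered host exons, as single-exon circles
  for (i in seq_len(config$n_coding)) {
    h <- hosts[i, ]
    ex <- genome$exons[genome$exons$gene_id == h$gene_id &
                         genome$exons$rank == h$host_exon_rank, ]
    add_row(ex$contig, ex$start - 1L, ex$end, h$strand, "exonic",
            h$gene_id, coding = TRUE, host = h)
  }

  # non-coding plants are never placed on the engineered host genes: an
  # interval carved from a designed cassette would inherit its IRES and
  # junction ORF and confound the negative set
  gene_pool <- genome$genes[!genome$genes$coding_host, , drop = FALSE]
  if (nrow(gene_pool) == 0L)
    stopf("no non-host genes available for non-coding circRNA plants")
  pick_gene <- function(min_exons = 1L) {
    ok <- gene_pool[gene_pool$n_exons >= min_exons, , drop = FALSE]
    ok[sample(nrow(ok), 1L), ]
  }
  exons_of <- function(gid) {
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    ex[order(ex$start), , drop = FALSE]
  }

  n_target <- counts
  n_target["exonic"] <- n_target["exonic"] - config$n_coding
  tries <- 0L
  while (n_target["exonic"] > 0L && tries < 10000L) {
    tries <- tries + 1L
    g <- pick_gene()
    ex <- exons_of(g$gene_id)
    ij <- sort(sample(nrow(ex), 2L, replace = TRUE))
    blocks_len <- sum(ex$end[ij[1]:ij[2]] - ex$start[ij[1]:ij[2]] + 1L)
    if (add_row(g$contig, ex$start[ij[1]] - 1L, ex$end[ij[2]], g$strand,
                "exonic", g$gene_id, blocks_len = blocks_len))
      n_target["exonic"] <- n_target["exonic"] - 1L
  }
  while (n_target["intronic"] > 0L && tries < 20000L) {
    tries <- tries + 1L
    g <- pick_gene(min_exons = 2L)
    ex <- exons_of(g$gene_id)
    k <- sample(nrow(ex) - 1L, 1L)
    istart <- ex$end[k] + 1L; iend <- ex$start[k + 1L] - 1L
    ilen <- iend - istart + 1L
    if (ilen < 140L) next
    clen <- sample(120:min(400L, ilen - 12L), 1L)
    off <- sample(5:(ilen - clen - 5L), 1L)
    if (add_row(g$contig, istart - 1L + off, istart - 1L + off + clen,
                g$strand, "intronic", g$gene_id))
      n_target["intronic"] <- n_target["intronic"] - 1L
  }
  for (cat in c("sense_overlapping", "antisense")) {
    while (n_target[cat] > 0L && tries < 30000L) {
      tries <- tries + 1L
      g <- pick_gene()
      ex <- exons_of(g$gene_id)
      wide <- which(ex$end - ex$start + 1L >= 160L)
      if (!length(wide)) next
      k <- if (length(wide) == 1L) wide else sample(wide, 1L)
      strand <- if (cat == "antisense") setdiff(c("+", "-"), g$strand)
                else g$strand
      if (add_row(g$contig, ex$start[k] + 4L, ex$end[k] - 5L, strand, cat,
                  if (cat == "antisense") NA_character_ else g$gene_id))
        n_target[cat] <- n_target[cat] - 1L
    }
  }
  if (n_target["intergenic"] > 0L) {
    for (ctg in names(genome$contigs)) {
      if (n_target["intergenic"] <= 0L) break
      occ <- genome$genes[genome$genes$contig == ctg, , drop = FALSE]
      occ <- occ[order(occ$start), , drop = FALSE]
      bounds <- c(500L, if (nrow(occ)) as.vector(rbind(occ$start - 200L,
                                                       occ$end + 200L)),
                  length(genome$contigs[[ctg]]) - 500L)
      gap_start <- bounds[seq(1, length(bounds), by = 2)]
      gap_end <- bounds[seq(2, length(bounds), by = 2)]
      for (gi in seq_along(gap_start)) {
        if (n_target["intergenic"] <= 0L) break
        if (gap_end[gi] - gap_start[gi] < 500L) next
        clen <- sample(200:400, 1L)
        s0 <- gap_start[gi] + sample(0:50, 1L)
        if (add_row(ctg, s0, s0 + clen, sample(c("+", "-"), 1L),
                    "intergenic", NA_character_))
          n_target["intergenic"] <- n_target["intergenic"] - 1L
      }
    }
  }
  if (any(n_target > 0L))
    stopf("could not place all planted circRNAs (%s left): enlarge the genome",
          paste(sprintf("%s=%d", names(n_target)[n_target > 0],
                        n_target[n_target > 0]), collapse = ", "))

  truth <- do.call(rbind, rows)
  truth <- truth[order(!truth$coding), , drop = FALSE]  # coding first
  truth$circ_id <- sprintf("circ_%03d", seq_len(nrow(truth)))
  rownames(truth) <- NULL

  # linear context: representative transcript length of the host gene
  truth$linear_length <- NA_integer_
  has_gene <- !is.na(truth$gene_id)
  truth$linear_length[has_gene] <- vapply(truth$gene_id[has_gene],
    function(gid) {
      ex <- genome$exons[genome$exons$gene_id == gid, ]
      as.integer(sum(ex$end - ex$start + 1L))
    }, integer(1))

  # planted per-pair fold changes: coding up in every pair, extras down
  # (symmetric planting keeps per-sample totals balanced)
  fc <- matrix(1, nrow = nrow(truth), ncol = config$n_pairs)
  fc[truth$coding, ] <- config$planted_fc  # up in all pairs (analog-like)
  noncoding <- which(!truth$coding & truth$category != "intergenic")
  n_extra <- min(config$n_de_extra, length(noncoding))
  if (n_extra > 0L) {
    extra <- sample(noncoding, n_extra)
    k_cycle <- rep(3:min(5, config$n_pairs), length.out = n_extra)
    for (j in seq_len(n_extra))
      fc[extra[j], seq_len(k_cycle[j])] <- 1 / config$planted_fc
  }
  colnames(fc) <- sprintf("fc_pair%d", seq_len(config$n_pairs))
  truth <- cbind(truth, fc)

  bsj <- data.frame(chrom = truth$contig, start = truth$start,
                    end = truth$end, name = truth$circ_id, score = 0L,
                    strand = truth$strand, stringsAsFactors = FALSE)
  list(truth = truth, bsj = bsj)
}
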