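# Negative-binomial count simulation and junction-read simulation.

#' Simulate paired tumor/normal BSJ and linear counts
#'
#' Draws negative-binomial counts (shared dispersion; variance
#' `mu + dispersion * mu^2`) for every planted circle in every sample of a
#' paired design. A circle's normal-tissue expectation is
#' `depth * exp(N(0, 0.5))` (a log-normal abundance spread); its tumor
#' expectation in pair `j` is that baseline times the planted
#' `fc_pair<j>`. Parental linear transcripts are simulated so that the
#' expected circle/linear TPM ratio per circle is uniform on
#' \[0.01, 0.06\] (the regime reported for highly expressed coding
#' circles relative to their host mRNA); circles without a
#' parental gene (intergenic/antisense) get `NA` linear rows.
#'
#' @param truth Truth table from [plant_circrnas()].
#' @param config The matching [sim_config()].
#' @return An object of class `bsj_counts`: list with `circ` and `linear`
#'   count matrices (features x samples), `lengths`, `linear_lengths`,
#'   `design` (sample/condition/pair) and `ratio_truth` (the drawn target
#'   TPM ratios).
#' @export
simulate_counts <- function(truth, config) {
  validate_sim_config(config)
  if (config$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  set.seed(config$seed + 2L)
  n <- nrow(truth); np <- config$n_pairs
  samples <- c(sprintf("T%d", seq_len(np)), sprintf("N%d", seq_len(np)))
  design <- data.frame(sample = samples,
                       condition = rep(c("tumor", "normal"), each = np),
                       pair = rep(seq_len(np), 2L),
                       stringsAsFactors = FALSE)
  fc <- as.matrix(truth[, sprintf("fc_pair%d", seq_len(np)), drop = FALSE])

  base <- config$depth * exp(rnorm(n, 0, 0.5))
  mu <- cbind(base * fc, matrix(base, n, np))  # tumor cols then normal cols
  colnames(mu) <- samples
  size <- 1 / config$nb_dispersion
  draw <- function(m) {
    out <- matrix(rnbinom(length(m), mu = as.vector(m), size = size),
                  nrow = nrow(m), dimnames = dimnames(m))
    if (config$depth == 0) out[] <- 0L
    out
  }
  circ <- draw(mu)
  rownames(circ) <- truth$circ_id

  # linear parental counts: length-normalized rate ratio circle:linear
  # = r with r ~ U[0.01, 0.06], so on a shared TPM scale
  # (combined_circ_linear_tpm) the expected circle/linear TPM ratio is r
  ratio <- runif(n, 0.01, 0.06)
  has_gene <- !is.na(truth$gene_id)
  lin_len <- truth$linear_length
  linear <- mu * NA_real_
  if (any(has_gene)) {
    mu_lin <- mu * NA_real_
    mu_lin[has_gene, ] <- mu[has_gene, ] *
      (lin_len[has_gene] / truth$length[has_gene]) / ratio[has_gene]
    linear[has_gene, ] <- draw(mu_lin[has_gene, , drop = FALSE])
  }
  rownames(linear) <- truth$circ_id

  out <- list(circ = circ, linear = linear,
              lengths = setNames(truth$length, truth$circ_id),
              linear_lengths = setNames(lin_len, truth$circ_id),
              design = design,
              ratio_truth = setNames(ifelse(has_gene, ratio, NA_real_),
                                     truth$circ_id))
  class(out) <- "bsj_counts"
  out
}

#' @export
print.bsj_counts <- function(x, ...) {
  cat(sprintf("bsj_counts: %d circRNAs x %d samples (%d pairs)\n",
              nrow(x$circ), ncol(x$circ), max(x$design$pair)))
  invisible(x)
}

#' Simulate junction-spanning reads (with an in-silico RNase R arm)
#'
#' For each circle, draws `Poisson(depth)` reads positioned so that every
#' read overlaps the back-splice junction by at least `config$anchor` nt on
#' each side (sampled from the doubled circular sequence). For each circle
#' with a parental gene, the same number of linear-transcript reads is
#' drawn from random transcript windows. The "treated" set models RNase R
#' digestion: it retains every circular read and no linear read.
#'
#' @param events Annotated catalog from [annotate_bsj()] (provides circular
#'   sequences).
#' @param genome The `GenomeBundle` (provides linear transcripts).
#' @param truth Truth table from [plant_circrnas()].
#' @param config The matching [sim_config()].
#' @return List of two named [Biostrings::DNAStringSet]s: `untreated` and
#'   `treated`. Read names carry their origin (`<id>|circ|i` or
#'   `<gene>|linear|i`).
#' @export
simulate_junction_reads <- function(events, genome, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  rl <- config$read_length; anc <- config$anchor
  if (any(events$length <= rl))
    stopf("read_length (%d) must be below the shortest circle (%d nt)",
          rl, min(events$length))
  circ_reads <- character(0)
  for (i in seq_len(nrow(events))) {
    L <- events$length[i]
    n <- rpois(1L, config$depth)
    if (n == 0L) next
    starts <- sample(seq(L + anc - rl, L - anc), n, replace = TRUE)
    doubled <- paste0(events$sequence[i], events$sequence[i])
    rd <- substring(doubled, starts + 1L, starts + rl)
    names(rd) <- sprintf("%s|circ|%d", events$circ_id[i], seq_len(n))
    circ_reads <- c(circ_reads, rd)
  }
  lin_reads <- character(0)
  for (i in which(!is.na(truth$gene_id))) {
    tx <- transcript_sequence(genome, truth$gene_id[i])
    if (nchar(tx) <= rl) next
    n <- rpois(1L, config$depth)
    if (n == 0L) next
    starts <- sample(seq_len(nchar(tx) - rl), n, replace = TRUE)
    rd <- substring(tx, starts, starts + rl - 1L)
    names(rd) <- sprintf("%s|linear|%d", truth$gene_id[i], seq_len(n))
    lin_reads <- c(lin_reads, rd)
  }
  list(untreated = Biostrings::DNAStringSet(c(circ_reads, lin_reads)),
       treated = Biostrings::DNAStringSet(circ_reads))
}

#' Write reads as FASTQ
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output path (plain text FASTQ).
#' @param quality Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
    function(w) strrep(quality, w), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}
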