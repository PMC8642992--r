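# Junction-spanning read counting, TPM normalization, circle/linear
# ratios and in-silico RNase R resistance.

#' Junction k-mer of a circular sequence
#'
#' The `2 * anchor`-mer formed by the last `anchor` and first `anchor`
#' nucleotides of the junction-registered circular sequence; a read
#' containing it necessarily spans the back-splice junction by at least
#' `anchor` nt on each side.
#'
#' @param sequence Circular sequence (character), position 0 at the
#'   acceptor side.
#' @param anchor Anchor length per side (nt).
#' @return Character scalar of length `2 * anchor`.
#' @export
junction_kmer <- function(sequence, anchor = 10L) {
  L <- nchar(sequence)
  if (anchor < 1L) stopf("anchor must be >= 1")
  if (L < 2L * anchor)
    stopf("circle shorter than 2 * anchor (%d < %d)", L, 2L * anchor)
  paste0(substr(sequence, L - anchor + 1L, L),
         substr(sequence, 1L, anchor))
}

#' Count junction-spanning reads per circle
#'
#' A read is counted for a circle iff it contains that circle's junction
#' `2 * anchor`-mer as an exact substring; each read counts at most once
#' per circle. Counting is therefore invariant to read order. Circles with
#' identical junction k-mers are reported in a warning (their counts are
#' then indistinguishable).
#'
#' @param reads A [Biostrings::DNAStringSet], or a path to a FASTQ file.
#' @param events Catalog from [annotate_bsj()] (needs `circ_id`,
#'   `sequence`).
#' @param anchor Anchor length per side (nt); reads must be longer than
#'   `2 * anchor`.
#' @return Named integer vector of counts per `circ_id`.
#' @export
count_bsj_reads <- function(reads, events, anchor = 10L) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  if (anchor < 1L) stopf("anchor must be >= 1")
  kmers <- vapply(events$sequence, junction_kmer, character(1),
                  anchor = anchor, USE.NAMES = FALSE)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  if (any(dup))
    warnf("ambiguous junction k-mers shared by: %s",
          paste(events$circ_id[dup], collapse = ", "))
  if (length(reads) == 0L)
    return(setNames(integer(nrow(events)), events$circ_id))
  if (min(Biostrings::width(reads)) <= 2L * anchor)
    stopf("read length must exceed 2 * anchor (%d)", 2L * anchor)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  hits <- Biostrings::vcountPDict(pd, reads)  # patterns x reads
  setNames(as.integer(rowSums(hits > 0L)), events$circ_id)
}

#' TPM normalization
#'
#' `tpm_i = (c_i / L_i[kb]) / sum_j (c_j / L_j[kb]) * 1e6` per sample.
#' A sample whose counts are all zero stays all zero (no division by
#' zero). Per-sample TPM sums to 1e6 whenever any count is positive, and
#' scaling a sample's counts by a constant leaves its TPM unchanged.
#'
#' @param counts Feature x sample count matrix (or vector).
#' @param lengths Feature lengths in nt.
#' @return TPM matrix with the dimensions of `counts`.
#' @export
tpm_normalize <- function(counts, lengths) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L,
                                          dimnames = list(names(counts),
                                                          NULL))
  if (any(counts < 0, na.rm = TRUE)) stopf("negative counts are invalid")
  if (any(lengths <= 0)) stopf("feature lengths must be positive")
  if (length(lengths) != nrow(counts))
    stopf("lengths must match the number of features")
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate, na.rm = TRUE)
  tpm <- sweep(rate, 2L, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  tpm
}

#' Combined-denominator TPM for circle/linear comparison
#'
#' Normalizes the circular and parental linear counts of a
#' [simulate_counts()] object in one table (shared per-sample
#' denominator), so their TPM values are directly comparable - the scale
#' on which a circle/linear TPM ratio of 0.01-0.06 is meaningful. (Two
#' tables separately normalized to one million each cannot both sum to
#' 1e6 and keep every circle below its parent; a shared denominator is
#' how a joint quantification reports both features.)
#'
#' @param counts A `bsj_counts` object (or a list with `circ`, `linear`,
#'   `lengths`, `linear_lengths`).
#' @return List with `circ_tpm` and `linear_tpm` matrices on the shared
#'   scale (NA rows kept for circles without a parental gene).
#' @export
combined_circ_linear_tpm <- function(counts) {
  has <- !is.na(counts$linear[, 1])
  n <- nrow(counts$circ)
  stacked <- rbind(counts$circ, counts$linear[has, , drop = FALSE])
  lens <- c(counts$lengths, counts$linear_lengths[has])
  tpm_all <- tpm_normalize(stacked, lens)
  circ_tpm <- tpm_all[seq_len(n), , drop = FALSE]
  linear_tpm <- counts$linear * NA_real_
  linear_tpm[has, ] <- tpm_all[n + seq_len(sum(has)), , drop = FALSE]
  rownames(linear_tpm) <- rownames(circ_tpm)
  list(circ_tpm = circ_tpm, linear_tpm = linear_tpm)
}

#' Per-sample circle/linear TPM ratio
#'
#' Ratio of circular to parental linear TPM, matched by feature name;
#' the inputs should share a normalization scale (see
#' [combined_circ_linear_tpm()]). Samples where the linear TPM is zero
#' (or either value is missing) give `NA` - reported as an undefined
#' sentinel, never as 0 - and are excluded from summaries.
#'
#' @param circ_tpm,linear_tpm TPM matrices with identical dimnames.
#' @return Matrix of ratios (NA where undefined).
#' @export
circ_linear_ratio <- function(circ_tpm, linear_tpm) {
  if (!identical(dim(circ_tpm), dim(linear_tpm)) ||
      !identical(rownames(circ_tpm), rownames(linear_tpm)))
    stopf("circ and linear TPM tables must be matched feature-by-feature")
  ratio <- circ_tpm / linear_tpm
  ratio[!is.finite(ratio)] <- NA_real_
  ratio[linear_tpm == 0] <- NA_real_
  ratio
}

#' In-silico RNase R resistance
#'
#' Retained fraction `treated / untreated` per feature; undefined
#' (`NA`) when the untreated count is zero. Features at or above
#' `threshold` are flagged resistant - the signature of a covalently
#' closed circle, whose junction reads survive the exonuclease.
#'
#' @param counts_untreated,counts_treated Matched named count vectors.
#' @param threshold Retained fraction at or above which a feature is
#'   called resistant.
#' @return Data frame: `feature`, `fraction`, `resistant`.
#' @export
rnase_r_resistance <- function(counts_untreated, counts_treated,
                               threshold = 0.5) {
  if (length(counts_untreated) != length(counts_treated))
    stopf("treated and untreated features must be matched")
  if (!is.null(names(counts_untreated)) &&
      !identical(names(counts_untreated), names(counts_treated)))
    stopf("treated and untreated feature names must be matched")
  frac <- ifelse(counts_untreated > 0,
                 counts_treated / counts_untreated, NA_real_)
  data.frame(feature = if (is.null(names(counts_untreated)))
               as.character(seq_along(counts_untreated))
             else names(counts_untreated),
             fraction = frac,
             resistant = !is.na(frac) & frac >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
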