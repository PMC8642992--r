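# Junction-specific validation designs: tagged constructs, start-codon
# mutants, divergent primers, junction siRNAs, distinguishing tryptic
# peptides, TCF motif scans.

#' Default 3xFLAG tag (nucleotide sequence)
#'
#' Encodes DYKDDDDK three times with codons free of stop triplets in the
#' reading frame.
#'
#' @return Character scalar (72 nt).
#' @export
flag_tag_3x <- function() {
  flag1 <- "GACTACAAGGACGACGACGACAAG"  # D Y K D D D D K
  paste0(flag1, flag1, flag1)
}

#' Insert a tag before an ORF's stop codon
#'
#' Builds the tagged overexpression construct: the tag is inserted
#' immediately before the first base of the ORF's stop codon, so the
#' back-splice junction and the ORF stay intact and the construct's
#' protein is the wild-type protein plus the tag residues.
#'
#' @param sequence Wild-type circular sequence.
#' @param orf One ORF row from [find_circular_orfs()] on this sequence
#'   (list or one-row data frame with `start`, `nt_length`, `stop_pos`,
#'   `rolling`, `protein`).
#' @param tag_nt Tag nucleotides; length must be a codon multiple. Empty
#'   tag returns the wild type.
#' @return A `construct_spec` list: `sequence` (the construct circle),
#'   `variant = "tagged"`, `insert_at` (0-based), `expected_protein`.
#' @export
tag_orf <- function(sequence, orf, tag_nt = flag_tag_3x()) {
  if (isTRUE(orf$rolling) || is.na(orf$stop_pos))
    stopf("cannot tag a rolling-circle ORF: it has no stop codon")
  if (nchar(tag_nt) %% 3L != 0L)
    stopf("tag length (%d nt) must be a codon multiple", nchar(tag_nt))
  if (nchar(tag_nt) > 0L && !is_dna(tag_nt))
    stopf("tag must be plain A/C/G/T")
  L <- nchar(sequence)
  p <- orf$stop_pos  # 0-based first base of the stop codon
  construct <- paste0(substr(sequence, 1L, p), tag_nt,
                      substr(sequence, p + 1L, L))
  tag_aa <- if (nchar(tag_nt) == 0L) "" else {
    n <- nchar(tag_nt) / 3L
    paste(codon_table()[substring(tag_nt, 3L * seq_len(n) - 2L,
                                  3L * seq_len(n))], collapse = "")
  }
  structure(list(sequence = construct, variant = "tagged",
                 insert_at = p, tag_nt = tag_nt,
                 expected_protein = paste0(orf$protein, tag_aa)),
            class = "construct_spec")
}

#' Mutate an ORF's start codon
#'
#' Replaces the ATG at the ORF start with `to` (CTG by default: one
#' transversion that abolishes initiation without creating a new ATG).
#' Warns when another in-frame ATG can still reach the original stop, i.e.
#' when the mutation does not abolish the product.
#'
#' @param sequence Wild-type circular sequence.
#' @param orf ORF row (needs `start`, `stop_pos`); its codon at `start`
#'   must be ATG.
#' @param to Replacement codon (must not be ATG).
#' @param max_cycles Passed to the re-screen used for the warning check.
#' @return A `construct_spec` list: `sequence`, `variant =
#'   "start_mutant"`, `mutated_at`.
#' @export
mutate_start <- function(sequence, orf, to = "CTG", max_cycles = 3L) {
  L <- nchar(sequence)
  s <- orf$start
  if (circ_substr(sequence, s, 3L) != "ATG")
    stopf("ORF start at %d is not an ATG", s)
  if (to == "ATG" || nchar(to) != 3L)
    stopf("replacement codon must be a non-ATG triplet")
  chars <- strsplit(sequence, "")[[1]]
  idx <- (s + 0:2) %% L + 1L
  chars[idx] <- strsplit(to, "")[[1]]
  mutant <- paste(chars, collapse = "")
  remaining <- find_circular_orfs(mutant, max_cycles = max_cycles)
  same_stop <- remaining[!remaining$rolling &
                           remaining$stop_pos == orf$stop_pos, ,
                         drop = FALSE]
  if (nrow(same_stop))
    warnf("start-codon mutation leaves alternative start(s) at %s reaching the original stop",
          paste(same_stop$start, collapse = ", "))
  structure(list(sequence = mutant, variant = "start_mutant",
                 mutated_at = s, replacement = to),
            class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("construct_spec (%s): %d nt\n", x$variant,
              nchar(x$sequence)))
  invisible(x)
}

#' Design a divergent primer pair across the back-splice junction
#'
#' The forward primer anneals in the final region of the
#' junction-registered circular sequence and the reverse primer in the
#' initial region, so the PCR product crosses the BSJ - on the linear
#' gene the two primers point away from each other (divergent) and
#' amplify nothing. Constraints: primer length 18-24 nt, GC 40-60
#' percent, amplicon 80-200 nt containing the junction. Among feasible
#' pairs the (deterministic) best minimizes GC distance from 50 percent
#' plus a mild penalty for off-center amplicon lengths.
#'
#' @param sequence Circular sequence.
#' @param primer_len Allowed primer lengths (range).
#' @param gc_range Allowed GC percentage window.
#' @param amplicon_range Allowed amplicon length window (nt).
#' @return A `primer_pair` list: `forward`, `reverse`, `orientation`,
#'   `amplicon_length`, `amplicon`, `spans_junction`, plus 0-based
#'   annealing coordinates.
#' @export
design_divergent_primers <- function(sequence, primer_len = c(18L, 24L),
                                     gc_range = c(40, 60),
                                     amplicon_range = c(80L, 200L)) {
  L <- nchar(sequence)
  if (L < amplicon_range[1])
    stopf("circle (%d nt) shorter than the minimum amplicon (%d nt)",
          L, amplicon_range[1])
  max_arm <- min(amplicon_range[2], L)
  lens <- primer_len[1]:primer_len[2]
  # forward candidates: [f_start, f_start + len) with f_start >= L - max_arm
  fwd <- do.call(rbind, lapply(lens, function(w) {
    starts <- seq(max(0L, L - max_arm), L - w)
    if (!length(starts)) return(NULL)
    data.frame(start = starts, len = w,
               seq = substring(sequence, starts + 1L, starts + w),
               stringsAsFactors = FALSE)
  }))
  rev_ <- do.call(rbind, lapply(lens, function(w) {
    ends <- seq(w, min(max_arm, L))  # site [end - w, end), 0-based end
    data.frame(end = ends, len = w,
               seq = substring(sequence, ends - w + 1L, ends),
               stringsAsFactors = FALSE)
  }))
  gc_of <- function(s) vapply(s, gc_percent, numeric(1), USE.NAMES = FALSE)
  fwd$gc <- gc_of(fwd$seq); rev_$gc <- gc_of(rev_$seq)
  fwd <- fwd[fwd$gc >= gc_range[1] & fwd$gc <= gc_range[2], , drop = FALSE]
  rev_ <- rev_[rev_$gc >= gc_range[1] & rev_$gc <= gc_range[2], ,
               drop = FALSE]
  if (!nrow(fwd) || !nrow(rev_))
    stopf("no primer satisfies the GC window %g-%g%%", gc_range[1],
          gc_range[2])
  best <- NULL; best_score <- Inf
  mid <- mean(amplicon_range)
  for (i in seq_len(nrow(fwd))) {
    arm_f <- L - fwd$start[i]
    amp <- arm_f + rev_$end
    ok <- which(amp >= amplicon_range[1] & amp <= amplicon_range[2])
    if (!length(ok)) next
    score <- abs(fwd$gc[i] - 50) + abs(rev_$gc[ok] - 50) +
      0.1 * abs(amp[ok] - mid)
    j <- ok[which.min(score)]
    if (min(score) < best_score) {
      best_score <- min(score)
      best <- list(f = i, r = j)
    }
  }
  if (is.null(best))
    stopf("no pair satisfies the amplicon window %d-%d nt",
          amplicon_range[1], amplicon_range[2])
  f <- fwd[best$f, ]; r <- rev_[best$r, ]
  amp_len <- (L - f$start) + r$end
  amplicon <- circ_substr(sequence, f$start, amp_len)
  structure(list(forward = f$seq, reverse = revcomp(r$seq),
                 orientation = "divergent",
                 f_start = f$start, r_end = r$end,
                 amplicon_length = amp_len, amplicon = amplicon,
                 spans_junction = TRUE),
            class = "primer_pair")
}

#' Classify a primer pair's orientation on the linear transcript
#'
#' Maps both primers onto the gene's representative transcript (forward
#' as-is, reverse via its reverse complement). Primers pointing toward
#' each other (forward site upstream of the reverse site) are convergent
#' - they amplify the linear transcript; primers pointing away are
#' divergent - on the linear template they amplify nothing, and only a
#' circular template brings them face to face across the junction.
#'
#' @param pair A `primer_pair` (or list with `forward`, `reverse`).
#' @param transcript Linear transcript sequence (5'->3').
#' @return `"convergent"` or `"divergent"`.
#' @export
classify_primer_orientation <- function(pair, transcript) {
  fpos <- str_positions(pair$forward, transcript)
  rpos <- str_positions(revcomp(pair$reverse), transcript)
  if (length(fpos) != 1L || length(rpos) != 1L)
    stopf("both primers must map uniquely to the transcript (forward: %d hit(s), reverse: %d hit(s))",
          length(fpos), length(rpos))
  if (fpos < rpos) "convergent" else "divergent"
}

#' Check a siRNA for junction overlap and linear off-targets
#'
#' The siRNA is junction-specific iff it occurs in the circularized
#' sequence at an offset straddling the back-splice junction with at
#' least `min_overhang` nt on each side, and does not occur in the
#' linear parental transcript.
#'
#' @param sirna siRNA sense sequence (19-23 nt, plain A/C/G/T).
#' @param sequence Junction-registered circular sequence.
#' @param linear_transcript Parental transcript to screen for
#'   off-targets (optional).
#' @param min_overhang Minimum nt on each side of the junction.
#' @return List: `junction_overlap`, `linear_offtarget`, `offsets`
#'   (0-based circle offsets of junction-straddling matches).
#' @export
check_sirna_junction <- function(sirna, sequence, linear_transcript = NULL,
                                 min_overhang = 4L) {
  w <- nchar(sirna)
  if (w < 19L || w > 23L) stopf("siRNA length must be 19-23 nt (got %d)", w)
  if (!is_dna(sirna) || grepl("N", sirna))
    stopf("siRNA must be unambiguous A/C/G/T")
  L <- nchar(sequence)
  doubled <- paste0(sequence, sequence)
  pos <- str_positions(sirna, doubled) - 1L  # 0-based
  # straddles the junction at L iff it starts before L and ends at/after it
  straddle <- pos[pos <= L - min_overhang & pos + w >= L + min_overhang]
  lin <- if (is.null(linear_transcript)) FALSE
         else length(str_positions(sirna, linear_transcript)) > 0L
  list(junction_overlap = length(straddle) > 0L,
       linear_offtarget = lin,
       offsets = straddle)
}

#' Tryptic digest of a protein
#'
#' Cleaves after K or R except when the next residue is P; peptides with
#' `m` missed cleavages are the concatenations of `m + 1` adjacent fully
#' cleaved fragments. With 0 missed cleavages the peptides concatenate
#' back to the input.
#'
#' @param protein Amino-acid string.
#' @param missed Maximum number of missed cleavages to report.
#' @return Data frame: `peptide`, `start` (1-based residue), `end`,
#'   `missed`.
#' @export
tryptic_digest <- function(protein, missed = 0L) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n == 0L) return(data.frame(peptide = character(0), start = integer(0),
                                 end = integer(0), missed = integer(0),
                                 stringsAsFactors = FALSE))
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  starts0 <- head(bounds, -1L) + 1L
  ends0 <- bounds[-1L]
  out <- list()
  for (m in 0:missed) {
    k <- length(starts0) - m
    if (k < 1L) break
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(aa[starts0[i]:ends0[i + m]], collapse = ""),
        start = starts0[i], end = ends0[i + m], missed = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Junction-distinguishing peptide evidence
#'
#' Compares the circle-encoded protein with the parental protein:
#' divergence positions are the residues where the circle protein differs
#' from the parent's N-terminal prefix, plus every circle residue beyond
#' the parent's length. Tryptic peptides (see [tryptic_digest()])
#' covering at least one divergence position are the distinguishing
#' peptides - the mass-spectrometry evidence that the circle, not the
#' linear gene, encoded the protein.
#'
#' @param protein Circle-encoded protein.
#' @param parent_protein Parental (linear) protein.
#' @param missed Maximum missed cleavages.
#' @return List: `divergence_positions` (1-based), `novel_suffix` (the
#'   C-terminal run of divergent residues, possibly empty), `peptides`,
#'   `distinguishing`.
#' @export
junction_peptide <- function(protein, parent_protein, missed = 1L) {
  if (!nchar(protein) || !nchar(parent_protein))
    stopf("both proteins must be non-empty")
  pa <- strsplit(protein, "")[[1]]
  qa <- strsplit(parent_protein, "")[[1]]
  k <- min(length(pa), length(qa))
  div <- which(pa[seq_len(k)] != qa[seq_len(k)])
  if (length(pa) > k) div <- c(div, (k + 1L):length(pa))
  peps <- tryptic_digest(protein, missed = missed)
  covers <- vapply(seq_len(nrow(peps)), function(i)
    any(div >= peps$start[i] & div <= peps$end[i]), logical(1))
  suffix <- if (length(div) && max(div) == length(pa)) {
    run_start <- max(div)
    while ((run_start - 1L) %in% div) run_start <- run_start - 1L
    paste(pa[run_start:length(pa)], collapse = "")
  } else ""
  list(divergence_positions = div, novel_suffix = suffix,
       peptides = peps,
       distinguishing = peps[covers, , drop = FALSE])
}

#' Scan a promoter for TCF consensus sites
#'
#' Matches the degenerate beta-catenin/TCF motif 5'-(A/T)(A/T)CAAAG-3' on
#' both strands; positions are 1-based on the input and N never matches.
#'
#' @param sequence Promoter sequence (A/C/G/T/N).
#' @return Data frame: `position` (1-based start of the 7-mer on the
#'   input), `strand`, `site`.
#' @export
scan_tcf_sites <- function(sequence) {
  if (!is_dna(sequence)) stopf("sequence must be A/C/G/T/N")
  pat <- "[AT][AT]CAAAG"
  fwd <- gregexpr(pat, sequence)[[1]]
  fwd <- if (fwd[1] == -1L) integer(0) else as.integer(fwd)
  rc <- revcomp(sequence)
  L <- nchar(sequence)
  rev_hits <- gregexpr(pat, rc)[[1]]
  rev_hits <- if (rev_hits[1] == -1L) integer(0) else as.integer(rev_hits)
  rev_pos <- L - (rev_hits + 7L - 1L) + 1L  # map back to input coordinates
  out <- rbind(
    if (length(fwd)) data.frame(position = fwd, strand = "+",
                                site = substring(sequence, fwd, fwd + 6L),
                                stringsAsFactors = FALSE),
    if (length(rev_pos)) data.frame(position = rev_pos, strand = "-",
                                    site = substring(sequence, rev_pos,
                                                     rev_pos + 6L),
                                    stringsAsFactors = FALSE))
  if (is.null(out)) out <- data.frame(position = integer(0),
                                      strand = character(0),
                                      site = character(0),
                                      stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
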