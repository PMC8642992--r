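# Circular ORF enumeration, rolling-circle translation, IRES-like element
# scanning, and the coding-potential candidate funnel.

# Per-position codon/amino-acid lookup for a circular sequence: element p+1
# is the amino acid of the codon starting at 0-based position p (wrapping).
# NA where the codon contains an ambiguity code.
circle_codon_aa <- function(sequence) {
  L <- nchar(sequence)
  ext <- paste0(sequence, substr(sequence, 1L, 2L))
  codons <- substring(ext, seq_len(L), seq_len(L) + 2L)
  unname(codon_table()[codons])
}

#' Translate a circular template from a given start
#'
#' Reads codons modulo the circle length from `start` (standard nuclear
#' code) until the first in-frame stop, or until `max_cycles` full turns
#' have been consumed, in which case the walk is flagged `rolling` (a
#' rolling-circle ORF) and the protein is truncated at the cap. A codon
#' containing an ambiguity code aborts the walk with `ambiguous = TRUE`.
#'
#' `nt_length` runs from the start codon through the stop codon inclusive;
#' the protein excludes the stop. `cycles_crossed` counts junction
#' crossings of the codon walk; an ORF spans the back-splice junction iff
#' it crosses at least once.
#'
#' @param sequence Circular sequence (junction-registered, position 0 just
#'   downstream of the BSJ).
#' @param start 0-based start offset on the circle.
#' @param max_cycles Cap on full turns for stop-free walks.
#' @return List: `protein`, `nt_length`, `stop_pos` (0-based offset of the
#'   stop codon's first base, NA when rolling), `rolling`,
#'   `cycles_crossed`, `spans_junction`, `ambiguous`.
#' @export
translate_circular <- function(sequence, start, max_cycles = 3L) {
  L <- nchar(sequence)
  if (L < 3L) stopf("circular template shorter than one codon (L=%d)", L)
  if (start < 0L || start >= L) stopf("start must satisfy 0 <= start < L")
  if (max_cycles < 1L) stopf("max_cycles must be >= 1")
  aa_at <- circle_codon_aa(sequence)
  n_max <- (max_cycles * L) %/% 3L  # codons fitting in max_cycles turns
  orbit <- (start + 3L * (seq_len(n_max) - 1L)) %% L
  aa <- aa_at[orbit + 1L]
  amb <- match(TRUE, is.na(aa))
  stop_at <- match("*", aa)
  if (!is.na(amb) && (is.na(stop_at) || amb < stop_at)) {
    n <- amb - 1L
    prot <- paste(aa[seq_len(n)], collapse = "")
    nt <- 3L * n
    return(list(protein = prot, nt_length = nt, stop_pos = NA_integer_,
                rolling = FALSE,
                cycles_crossed = cycles_crossed(start, nt, L),
                spans_junction = cycles_crossed(start, nt, L) >= 1L,
                ambiguous = TRUE))
  }
  if (is.na(stop_at)) {
    nt <- 3L * n_max
    return(list(protein = paste(aa, collapse = ""), nt_length = nt,
                stop_pos = NA_integer_, rolling = TRUE,
                cycles_crossed = cycles_crossed(start, nt, L),
                spans_junction = cycles_crossed(start, nt, L) >= 1L,
                ambiguous = FALSE))
  }
  nt <- 3L * stop_at
  list(protein = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
       nt_length = nt, stop_pos = orbit[stop_at],
       rolling = FALSE, cycles_crossed = cycles_crossed(start, nt, L),
       spans_junction = cycles_crossed(start, nt, L) >= 1L,
       ambiguous = FALSE)
}

# junction crossings of a codon walk covering absolute offsets
# [start, start + nt): one crossing per multiple of L passed strictly
# inside the covered span
cycles_crossed <- function(start, nt, L) {
  if (nt <= 0L) return(0L)
  as.integer((start + nt - 1L) %/% L)
}

#' Enumerate ORFs on a circular sequence
#'
#' Every ATG on the circle (including start codons that themselves span
#' the junction) opens a candidate walk via [translate_circular()].
#' Stopped ORFs are deduplicated to the longest per stop-codon position
#' (nested later starts on the same walk are dropped); rolling-circle
#' walks have no stop, so each initiating ATG is kept. Results are sorted
#' by `aa_length` descending, ties by smaller start.
#'
#' @param sequence Circular sequence, or a catalog row's sequence.
#' @param max_cycles Cap on full turns for stop-free walks.
#' @param min_aa Minimum protein length to report.
#' @return Data frame: `start`, `frame`, `nt_length`, `aa_length`,
#'   `spans_junction`, `rolling`, `cycles_crossed`, `stop_pos`,
#'   `protein`.
#' @export
find_circular_orfs <- function(sequence, max_cycles = 3L, min_aa = 0L) {
  L <- nchar(sequence)
  empty <- data.frame(start = integer(0), frame = integer(0),
                      nt_length = integer(0), aa_length = integer(0),
                      spans_junction = logical(0), rolling = logical(0),
                      cycles_crossed = integer(0), stop_pos = integer(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (L < 3L) return(empty)
  doubled <- paste0(sequence, sequence)
  starts <- str_positions("ATG", doubled) - 1L  # 0-based
  starts <- starts[starts < L]
  if (!length(starts)) return(empty)
  walks <- lapply(starts, function(s)
    translate_circular(sequence, s, max_cycles = max_cycles))
  keep <- !vapply(walks, `[[`, logical(1), "ambiguous")
  starts <- starts[keep]; walks <- walks[keep]
  if (!length(starts)) return(empty)
  orf <- data.frame(
    start = starts,
    frame = starts %% 3L,
    nt_length = vapply(walks, `[[`, integer(1), "nt_length"),
    aa_length = vapply(walks, function(w) nchar(w$protein), integer(1)),
    spans_junction = vapply(walks, `[[`, logical(1), "spans_junction"),
    rolling = vapply(walks, `[[`, logical(1), "rolling"),
    cycles_crossed = vapply(walks, `[[`, integer(1), "cycles_crossed"),
    stop_pos = vapply(walks, `[[`, integer(1), "stop_pos"),
    protein = vapply(walks, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)
  orf$dedup_key <- ifelse(orf$rolling,
                          paste0("roll", orf$start),
                          paste0("stop", orf$stop_pos))
  orf <- orf[order(-orf$nt_length, orf$start), , drop = FALSE]
  orf <- orf[!duplicated(orf$dedup_key), , drop = FALSE]
  orf$dedup_key <- NULL
  orf <- orf[orf$aa_length >= min_aa, , drop = FALSE]
  orf <- orf[order(-orf$aa_length, orf$start), , drop = FALSE]
  rownames(orf) <- NULL
  orf
}

#' Enumerate ORFs for every circle of a catalog
#'
#' @param catalog Catalog from [annotate_bsj()].
#' @inheritParams find_circular_orfs
#' @return Data frame of ORFs with a `circ_id` column.
#' @export
find_catalog_orfs <- function(catalog, max_cycles = 3L, min_aa = 0L) {
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    o <- find_circular_orfs(catalog$sequence[i], max_cycles = max_cycles,
                            min_aa = min_aa)
    if (nrow(o)) cbind(circ_id = catalog$circ_id[i], o,
                       stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(circ_id = character(0), start = integer(0),
                      frame = integer(0), nt_length = integer(0),
                      aa_length = integer(0), spans_junction = logical(0),
                      rolling = logical(0), cycles_crossed = integer(0),
                      stop_pos = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scan a circular sequence for IRES-like regions
#'
#' Default heuristic: sliding windows (`window` nt wide, `step` nt apart)
#' scored as
#' `pyrimidine fraction + longest C/T run / window + 0.2 * [ATG within
#' 20 nt downstream of the window]`; windows at or above `threshold` are
#' reported, overlapping windows merged (keeping the best score). The ATG
#' look-ahead wraps around the junction. This is an explicit proxy for an
#' IRES predictor, not a thermodynamic model; externally predicted
#' intervals can be supplied via `intervals` and are returned verbatim.
#' Output coordinates are 1-based inclusive on the circle.
#'
#' @param sequence Circular sequence.
#' @param window Window width (nt); clipped to the circle length with a
#'   warning when longer.
#' @param step Window step (nt).
#' @param threshold Minimum score.
#' @param intervals Optional data frame (`start`, `end`, 1-based
#'   inclusive) of imported IRES predictions; bypasses the heuristic.
#' @return Data frame: `start`, `end`, `score` (NA for imported
#'   intervals), `span` (= end - start + 1).
#' @export
scan_ires <- function(sequence, window = 150L, step = 10L,
                      threshold = 1.0, intervals = NULL) {
  L <- nchar(sequence)
  if (!is.null(intervals)) {
    if (any(intervals$start < 1L) || any(intervals$end > L) ||
        any(intervals$start > intervals$end))
      stopf("imported IRES intervals must satisfy 1 <= start <= end <= L")
    return(data.frame(start = intervals$start, end = intervals$end,
                      score = NA_real_,
                      span = intervals$end - intervals$start + 1L,
                      stringsAsFactors = FALSE))
  }
  if (window > L) {
    warnf("IRES window (%d) longer than circle (%d): clipped", window, L)
    window <- L
  }
  starts <- seq(1L, L - window + 1L, by = step)
  chars <- strsplit(sequence, "")[[1]]
  pyr <- chars %in% c("C", "T")
  doubled <- paste0(sequence, sequence)
  scores <- vapply(starts, function(s) {
    w <- pyr[s:(s + window - 1L)]
    frac <- mean(w)
    runs <- rle(w)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    down <- substr(doubled, s + window, min(s + window + 21L, 2L * L))
    has_atg <- grepl("ATG", down, fixed = TRUE) &&
      str_positions("ATG", down)[1] <= 20L
    frac + longest / window + 0.2 * has_atg
  }, numeric(1))
  hit <- scores >= threshold
  if (!any(hit))
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), span = integer(0),
                      stringsAsFactors = FALSE))
  hs <- starts[hit]; he <- starts[hit] + window - 1L; sc <- scores[hit]
  merged <- list(); cur <- c(hs[1], he[1], sc[1])
  for (i in seq_along(hs)[-1]) {
    if (hs[i] <= cur[2] + 1) {
      cur[2] <- max(cur[2], he[i]); cur[3] <- max(cur[3], sc[i])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- c(hs[i], he[i], sc[i])
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             score = m[, 3], span = as.integer(m[, 2] - m[, 1] + 1L),
             stringsAsFactors = FALSE)
}

# 0-based circle positions occupied by the final `n` nt of an ORF
orf_tail_positions <- function(orf_start, nt_length, L, n = 30L) {
  endpos <- orf_start + nt_length  # absolute, exclusive
  (seq(endpos - n, endpos - 1L)) %% L
}

#' Rank coding-potential candidates (the discovery funnel)
#'
#' Applies the mandatory filters in funnel order to every circle:
#' expression (passes the DE thresholds and the recurrence rule), circle
#' length within `[min_len, max_len]`, a junction-spanning ORF of at
#' least `min_aa` residues, ORF position (a qualifying ORF starting
#' within the first `start_window` fraction of the circle), and an
#' IRES-like hit that is not wholly inside the ORF's final 30 nt. Final
#' candidates are ranked by ORF length (ties by IRES score).
#'
#' @param catalog Catalog from [annotate_bsj()].
#' @param screen Screen table from [screen_circrnas()] (needs
#'   `circ_id`, `passes_de`, `passes_recurrence`).
#' @param orfs ORF table from [find_catalog_orfs()].
#' @param ires Named list of IRES hit tables from [scan_ires()], keyed
#'   by `circ_id`.
#' @param min_len,max_len Circle length window (nt).
#' @param min_aa Minimum junction-spanning ORF length (aa).
#' @param start_window ORF start must lie within this leading fraction of
#'   the circle.
#' @return Candidate table: per-filter pass flags, best ORF columns,
#'   best IRES columns, `passes_all` and `rank` (NA for non-candidates).
#' @export
rank_candidates <- function(catalog, screen, orfs, ires,
                            min_len = 200L, max_len = 3000L,
                            min_aa = 50L, start_window = 0.5) {
  if (is.null(screen$passes_de) || is.null(screen$passes_recurrence))
    stopf("screen table lacks pass flags: run screen_circrnas() first")
  n <- nrow(catalog)
  res <- data.frame(circ_id = catalog$circ_id, length = catalog$length,
                    stringsAsFactors = FALSE)
  si <- match(res$circ_id, screen$circ_id)
  if (anyNA(si)) stopf("screen results missing for some circles")
  res$pass_de <- screen$passes_de[si] & screen$passes_recurrence[si]
  res$pass_length <- res$length >= min_len & res$length <= max_len
  res$orf_start <- NA_integer_; res$orf_aa <- NA_integer_
  res$orf_nt <- NA_integer_; res$orf_protein <- NA_character_
  res$pass_orf <- FALSE; res$pass_orf_position <- FALSE
  res$ires_start <- NA_integer_; res$ires_end <- NA_integer_
  res$ires_score <- NA_real_; res$pass_ires <- FALSE
  for (i in seq_len(n)) {
    id <- res$circ_id[i]; L <- res$length[i]
    o <- orfs[orfs$circ_id == id & orfs$spans_junction & !orfs$rolling &
                orfs$aa_length >= min_aa, , drop = FALSE]
    res$pass_orf[i] <- nrow(o) > 0L
    o <- o[o$start <= start_window * L, , drop = FALSE]
    res$pass_orf_position[i] <- nrow(o) > 0L
    if (nrow(o) == 0L) next
    o <- o[order(-o$aa_length, o$start), , drop = FALSE][1L, ]
    res$orf_start[i] <- o$start; res$orf_aa[i] <- o$aa_length
    res$orf_nt[i] <- o$nt_length; res$orf_protein[i] <- o$protein
    h <- ires[[id]]
    if (is.null(h) || nrow(h) == 0L) next
    tail_pos <- orf_tail_positions(o$start, o$nt_length, L)
    inside_tail <- vapply(seq_len(nrow(h)), function(j)
      all(((h$start[j]:h$end[j]) - 1L) %in% tail_pos), logical(1))
    h <- h[!inside_tail, , drop = FALSE]
    if (nrow(h) == 0L) next
    res$pass_ires[i] <- TRUE
    hb <- h[order(-replace(h$score, is.na(h$score), Inf)), , drop = FALSE][1L, ]
    res$ires_start[i] <- hb$start; res$ires_end[i] <- hb$end
    res$ires_score[i] <- hb$score
  }
  res$passes_all <- res$pass_de & res$pass_length & res$pass_orf &
    res$pass_orf_position & res$pass_ires
  res$rank <- NA_integer_
  idx <- which(res$passes_all)
  if (length(idx)) {
    sc <- replace(res$ires_score[idx], is.na(res$ires_score[idx]), 0)
    ord <- idx[order(-res$orf_aa[idx], -sc)]
    res$rank[ord] <- seq_along(ord)
  }
  res
}
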