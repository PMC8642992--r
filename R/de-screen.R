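# Paired tumor/normal expression screen: per-pair fold changes, paired
# test with fold-change/p thresholds, recurrence filter, ROC biomarker.

check_design <- function(tpm, design) {
  if (!all(c("sample", "condition", "pair") %in% names(design)))
    stopf("design needs columns sample, condition, pair")
  if (!setequal(design$condition, c("tumor", "normal")))
    stopf("design conditions must be 'tumor' and 'normal'")
  if (!all(design$sample %in% colnames(tpm)))
    stopf("design samples missing from the TPM table: %s",
          paste(setdiff(design$sample, colnames(tpm)), collapse = ", "))
  pairs <- sort(unique(design$pair))
  for (p in pairs) {
    d <- design[design$pair == p, ]
    if (sum(d$condition == "tumor") != 1L ||
        sum(d$condition == "normal") != 1L)
      stopf("pair %s must contain exactly one tumor and one normal sample",
            p)
  }
  pairs
}

#' Per-pair fold changes
#'
#' `FC_pair = (tumor + eps) / (normal + eps)` on TPM, with pseudocount
#' `eps` guarding zeros.
#'
#' @param tpm Feature x sample TPM matrix.
#' @param design Data frame with `sample`, `condition`
#'   (tumor/normal), `pair`.
#' @param pseudocount Pseudocount `eps`.
#' @return Feature x pair matrix of fold changes.
#' @export
per_pair_fold_change <- function(tpm, design, pseudocount = 0.5) {
  pairs <- check_design(tpm, design)
  fc <- sapply(pairs, function(p) {
    d <- design[design$pair == p, ]
    t_col <- d$sample[d$condition == "tumor"]
    n_col <- d$sample[d$condition == "normal"]
    (tpm[, t_col] + pseudocount) / (tpm[, n_col] + pseudocount)
  })
  fc <- matrix(fc, nrow = nrow(tpm),
               dimnames = list(rownames(tpm),
                               sprintf("pair%s", pairs)))
  fc
}

#' Paired differential-expression test with the screen's thresholds
#'
#' Two-sided paired t-test on `log2(tpm + pseudocount)` per feature. A
#' feature passes (`passes_de`) iff its fold-change magnitude exceeds
#' `fc_threshold` (i.e. `FC > 2` or `FC < 1/2` at the default) and
#' `p < p_threshold` - the fold-change > 2, p < 0.05 decision rule. Zero
#' variance across pairs gives p = 1 with a degenerate-variance flag.
#'
#' @param tpm Feature x sample TPM matrix.
#' @param design Paired design (see [per_pair_fold_change()]).
#' @param pseudocount Pseudocount added before log2.
#' @param fc_threshold Fold-change threshold (strict `>` on the
#'   magnitude `max(FC, 1/FC)`).
#' @param p_threshold Significance threshold (strict `<`).
#' @param adjust Multiple-testing adjustment for an optional `p_adj`
#'   column (`"none"` by default: the screen applies raw p-values;
#'   `"BH"` available).
#' @return Data frame sorted by p: `circ_id`, `log2fc`, `fc`, `p_value`,
#'   `p_adj`, `degenerate`, `passes_de`.
#' @export
de_test <- function(tpm, design, pseudocount = 0.5, fc_threshold = 2,
                    p_threshold = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pairs <- check_design(tpm, design)
  if (length(pairs) < 2L) stopf("at least 2 pairs are required")
  t_cols <- vapply(pairs, function(p) design$sample[design$pair == p &
                     design$condition == "tumor"], character(1))
  n_cols <- vapply(pairs, function(p) design$sample[design$pair == p &
                     design$condition == "normal"], character(1))
  diffs <- log2(tpm[, t_cols, drop = FALSE] + pseudocount) -
    log2(tpm[, n_cols, drop = FALSE] + pseudocount)
  res <- t(apply(diffs, 1L, function(d) {
    m <- mean(d)
    if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0)
      return(c(log2fc = m, p = 1, degenerate = 1))
    c(log2fc = m, p = t.test(d)$p.value, degenerate = 0)
  }))
  out <- data.frame(circ_id = rownames(tpm), log2fc = res[, "log2fc"],
                    fc = 2^res[, "log2fc"], p_value = res[, "p"],
                    degenerate = res[, "degenerate"] == 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- if (adjust == "BH") p.adjust(out$p_value, "BH")
               else out$p_value
  fc_mag <- pmax(out$fc, 1 / out$fc)
  out$passes_de <- fc_mag > fc_threshold & out$p_value < p_threshold
  out[order(out$p_value), , drop = FALSE]
}

#' Recurrence filter across pairs
#'
#' A feature passes iff its per-pair fold change strictly exceeds
#' `threshold` in at least `k` pairs - the "highly expressed in at least
#' three of five pairs" rule (strict `>`, so FCs exactly at the threshold
#' do not count).
#'
#' @param per_pair_fc Feature x pair fold-change matrix from
#'   [per_pair_fold_change()].
#' @param k Minimum number of qualifying pairs.
#' @param threshold Per-pair fold-change threshold (strict `>`).
#' @return Data frame: `circ_id`, `recurrence` (qualifying pair count),
#'   `passes_recurrence`.
#' @export
recurrence_filter <- function(per_pair_fc, k = 3L, threshold = 2) {
  if (k > ncol(per_pair_fc))
    stopf("k (%d) cannot exceed the number of pairs (%d)", k,
          ncol(per_pair_fc))
  rec <- rowSums(per_pair_fc > threshold)
  data.frame(circ_id = rownames(per_pair_fc), recurrence = as.integer(rec),
             passes_recurrence = rec >= k, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full expression screen
#'
#' Convenience wrapper combining [de_test()], [per_pair_fold_change()] and
#' [recurrence_filter()] into one result table (rows in catalog order).
#'
#' @inheritParams de_test
#' @inheritParams recurrence_filter
#' @return Data frame with the DE statistics, per-pair fold changes,
#'   recurrence counts and all pass flags.
#' @export
screen_circrnas <- function(tpm, design, pseudocount = 0.5,
                            fc_threshold = 2, p_threshold = 0.05,
                            k = 3L, adjust = c("none", "BH")) {
  de <- de_test(tpm, design, pseudocount, fc_threshold, p_threshold,
                adjust)
  fc <- per_pair_fold_change(tpm, design, pseudocount)
  rec <- recurrence_filter(fc, k = k, threshold = fc_threshold)
  de <- de[match(rownames(tpm), de$circ_id), , drop = FALSE]
  rec <- rec[match(rownames(tpm), rec$circ_id), , drop = FALSE]
  out <- cbind(de, rec[, c("recurrence", "passes_recurrence")],
               as.data.frame(fc))
  rownames(out) <- NULL
  out
}

#' ROC curve, AUC and Youden cutoff for a single biomarker
#'
#' AUC by the rank (Mann-Whitney) statistic with tie correction; the
#' reported cutoff is the observed value maximizing Youden's J
#' (sensitivity + specificity - 1) under the rule "positive iff
#' value >= cutoff", with J ties broken toward higher specificity (the
#' larger cutoff). The returned `curve` contains one point per candidate
#' cutoff so the trapezoidal area can be checked against the rank AUC.
#'
#' @param values Numeric biomarker values.
#' @param labels Binary labels (logical, or coercible 0/1); `TRUE`/1 is
#'   the positive class, expected to have the higher values.
#' @return List with `auc`, `cutoff`, `sensitivity`, `specificity` and a
#'   `curve` data frame (`cutoff`, `tpr`, `fpr`).
#' @export
roc_biomarker <- function(values, labels) {
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stopf("values/labels must not be NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stopf("both label classes must be present")
  r <- rank(values)  # midranks: tie-corrected Mann-Whitney
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(values))
  tpr <- vapply(cuts, function(c) mean(values[labels] >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(values[!labels] >= c), numeric(1))
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[length(best)]  # larger cutoff -> higher specificity
  list(auc = auc, cutoff = cuts[best], sensitivity = tpr[best],
       specificity = 1 - fpr[best],
       curve = data.frame(cutoff = c(-Inf, cuts, Inf), tpr = c(1, tpr, 0),
                          fpr = c(1, fpr, 0)))
}
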