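#' Evaluation of BrdU calls and origin calls
#'
#' Confusion counts, balanced accuracy, specificity, ROC sweeps, the
#' primer-extension median profile, origin distance distributions and
#' chromosome pileups.
#'
#' @name evaluation
NULL

#' Confusion counts at a probability threshold
#'
#' @param probabilities Numeric vector of per-thymidine BrdU probabilities.
#' @param truths Logical/0-1 vector of the same length (TRUE = BrdU).
#' @param threshold Calls are positive when probability > threshold.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(probabilities, truths, threshold = 0.5) {
  if (length(probabilities) != length(truths)) {
    stopf("probabilities and truths differ in length")
  }
  truths <- as.logical(truths)
  call <- probabilities > threshold
  structure(list(TP = sum(call & truths), FP = sum(call & !truths),
                 TN = sum(!call & !truths), FN = sum(!call & truths)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Balanced accuracy: mean of sensitivity and specificity
#' @param counts A `confusion_counts`.
#' @return Fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts) {
  if (counts$TP + counts$FN == 0) stopf("balanced accuracy undefined: no positive truths")
  if (counts$TN + counts$FP == 0) stopf("balanced accuracy undefined: no negative truths")
  tpr <- counts$TP / (counts$TP + counts$FN)
  tnr <- counts$TN / (counts$TN + counts$FP)
  (tpr + tnr) / 2
}

#' Specificity: true-negative rate
#' @param counts A `confusion_counts`.
#' @return Fraction in `[0, 1]`.
#' @export
specificity <- function(counts) {
  if (counts$TN + counts$FP == 0) stopf("specificity undefined: no negative truths")
  counts$TN / (counts$TN + counts$FP)
}

#' ROC curve over a threshold sweep
#'
#' Thresholds are 101 evenly spaced values on `[0, 1]`, augmented with the
#' empirical probability set when there are at most 10^4 distinct values, so
#' that small cohorts are swept exactly.
#'
#' @param probabilities,truths As in [confusion_at_threshold()].
#' @param n_thresholds Number of evenly spaced thresholds.
#' @return Data frame `threshold`, `FPR`, `TPR`, sorted by threshold; the
#'   `auc` attribute holds the trapezoidal area under the curve.
#' @export
roc_curve <- function(probabilities, truths, n_thresholds = 101L) {
  truths <- as.logical(truths)
  if (length(unique(truths)) < 2L) stopf("ROC needs both truth classes")
  th <- seq(0, 1, length.out = n_thresholds)
  uq <- unique(probabilities)
  if (length(uq) <= 1e4) th <- sort(unique(c(th, uq)))
  # counting via sorted probabilities: positives/negatives above each threshold
  ord <- order(probabilities)
  ps <- probabilities[ord]; ts <- truths[ord]
  n_pos <- sum(truths); n_neg <- sum(!truths)
  cum_pos <- cumsum(ts); cum_neg <- cumsum(!ts)
  # number with probability > t  =  n - (index of last prob <= t)
  k <- findInterval(th, ps)
  tp <- n_pos - ifelse(k == 0, 0, cum_pos[pmax(k, 1)] * (k > 0))
  fp <- n_neg - ifelse(k == 0, 0, cum_neg[pmax(k, 1)] * (k > 0))
  out <- data.frame(threshold = th, FPR = fp / n_neg, TPR = tp / n_pos)
  o <- order(out$FPR, out$TPR)
  auc <- sum(diff(out$FPR[o]) * (head(out$TPR[o], -1) + tail(out$TPR[o], -1)) / 2)
  attr(out, "auc") <- auc
  out
}

#' Median BrdU probability per construct position
#'
#' For a primer-extension cohort (all records on the same construct), the
#' per-position median probability across reads, reported against 1-based
#' construct positions.
#'
#' @param records List of `detect_record` sharing one contig.
#' @return Data frame `position` (1-based), `median_probability`, `n_reads`.
#' @export
median_profile <- function(records) {
  if (length(records) == 0L) stopf("empty cohort")
  contigs <- unique(vapply(records, function(r) r$contig, character(1)))
  if (length(contigs) != 1L) stopf("records span multiple constructs: %s",
                                   paste(contigs, collapse = ", "))
  pos <- sort(unique(unlist(lapply(records, function(r) r$rows$position))))
  med <- vapply(pos, function(p) {
    v <- unlist(lapply(records, function(r) {
      r$rows$probability[r$rows$position == p]
    }))
    median(v)
  }, numeric(1))
  nr <- vapply(pos, function(p) {
    sum(vapply(records, function(r) p %in% r$rows$position, logical(1)))
  }, integer(1))
  data.frame(position = pos + 1L, median_probability = med, n_reads = nr)
}

#' Distances from origin calls to the nearest known origin
#'
#' For each call, the signed distance (bp) from the call interval's midpoint
#' to the nearest known-origin interval; 0 when the midpoint lies inside an
#' origin. Positive distances are to the right of the nearest origin.
#'
#' @param calls Feature-call data frame (kind `origin`).
#' @param known_origins Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @return List with `distances` (numeric) and `n_skipped` (calls on contigs
#'   absent from `known_origins`).
#' @export
origin_distance_distribution <- function(calls, known_origins) {
  if (nrow(known_origins) == 0L) stopf("known origin set is empty")
  calls <- calls[calls$kind == "origin", , drop = FALSE]
  distances <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(calls))) {
    kn <- known_origins[known_origins$contig == calls$contig[i], , drop = FALSE]
    if (nrow(kn) == 0L) {
      warning(sprintf("origin call on contig '%s' has no known origins; skipped",
                      calls$contig[i]), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    mid <- (calls$start[i] + calls$end[i]) / 2
    d_each <- ifelse(mid >= kn$start & mid < kn$end, 0,
                     ifelse(mid < kn$start, kn$start - mid, mid - (kn$end - 1)))
    j <- which.min(abs(d_each))
    signed <- if (d_each[j] == 0) 0 else if (mid < kn$start[j]) -d_each[j] else d_each[j]
    distances <- c(distances, signed)
  }
  list(distances = distances, n_skipped = n_skipped)
}

#' Binned pileup of feature calls along a contig
#'
#' @param calls Feature-call data frame (one contig).
#' @param contig_length Contig length in bp.
#' @param bin_bp Bin width (>= 1).
#' @return Data frame `start`, `end`, `count`: the number of call intervals
#'   overlapping each bin.
#' @export
pileup <- function(calls, contig_length, bin_bp = 1000L) {
  if (bin_bp < 1) stopf("bin_bp must be >= 1")
  n_bins <- ceiling(contig_length / bin_bp)
  counts <- integer(n_bins)
  for (i in seq_len(nrow(calls))) {
    b0 <- calls$start[i] %/% bin_bp + 1L
    b1 <- (calls$end[i] - 1L) %/% bin_bp + 1L
    b0 <- max(1L, b0); b1 <- min(n_bins, b1)
    if (b1 >= b0) counts[b0:b1] <- counts[b0:b1] + 1L
  }
  data.frame(start = (seq_len(n_bins) - 1L) * bin_bp,
             end = pmin(seq_len(n_bins) * bin_bp, contig_length),
             count = counts)
}

#' Origin recovery against simulator truth
#'
#' Fraction of truth origin intervals (on the supplied reads) overlapped by
#' an origin call of the same read, plus the fraction of calls whose
#' interval contains the true origin midpoint.
#'
#' @param calls Feature-call data frame.
#' @param sim_reads The simulated molecules the calls came from.
#' @return List `n_truth`, `n_recovered`, `sensitivity`,
#'   `midpoint_contained`.
#' @export
origin_recovery <- function(calls, sim_reads) {
  oc <- calls[calls$kind == "origin", , drop = FALSE]
  n_truth <- 0L; n_rec <- 0L; n_mid <- 0L
  for (rd in sim_reads) {
    tr <- rd$truth_origins
    if (is.null(tr) || nrow(tr) == 0L) next
    my <- oc[oc$read_id == rd$read_id, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      n_truth <- n_truth + 1L
      if (nrow(my) == 0L) next
      ov <- my$start < tr[j, 2] & my$end > tr[j, 1]
      if (any(ov)) {
        n_rec <- n_rec + 1L
        mid <- (tr[j, 1] + tr[j, 2]) / 2
        if (any(my$start[ov] <= mid & my$end[ov] > mid)) n_mid <- n_mid + 1L
      }
    }
  }
  list(n_truth = n_truth, n_recovered = n_rec,
       sensitivity = if (n_truth > 0) n_rec / n_truth else NA_real_,
       midpoint_contained = if (n_rec > 0) n_mid / n_rec else NA_real_)
}
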