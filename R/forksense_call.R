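#' Fork, origin and termination calling
#'
#' Thresholded fork-probability runs become fork segments; a leftward-fork
#' segment followed by a rightward-fork segment (diverging forks) brackets a
#' replication origin, and a rightward-fork segment followed by a
#' leftward-fork segment (converging forks) brackets a termination site. The
#' gap between the two segments is reported as the call's confidence
#' interval.
#'
#' The defaults (threshold 0.5, minimum segment span 1 kb, gap tolerance
#' 500 bp) are deliberately frozen: fork and origin calling needs no tuning.
#'
#' @name feature_calling
NULL

new_feature_call <- function(kind, contig, start, end, read_id, score) {
  data.frame(kind = kind, contig = contig, start = as.integer(start),
             end = as.integer(end), read_id = read_id, score = score,
             stringsAsFactors = FALSE)
}

empty_feature_calls <- function() {
  data.frame(kind = character(0), contig = character(0), start = integer(0),
             end = integer(0), read_id = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Maximal runs of above-threshold positions, closed over sub-tolerance gaps.
prob_runs <- function(positions, p, threshold, gap_tolerance) {
  hit <- which(p > threshold)
  if (length(hit) == 0L) return(NULL)
  hp <- positions[hit]
  brk <- which(diff(hp) > gap_tolerance)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(hp))
  cbind(start = hp[starts], end = hp[ends] + 1L,
        score = vapply(seq_along(starts),
                       function(i) mean(p[hit[starts[i]:ends[i]]]), numeric(1)))
}

#' Call fork segments on one read's fork track
#'
#' @param track A `fork_track`.
#' @param threshold Fork probability threshold in `(0, 1)`.
#' @param min_length_bp Minimum segment span.
#' @param gap_tolerance Runs separated by at most this many bp are merged.
#' @return Feature-call data frame with kinds `fork_left` / `fork_right`,
#'   sorted by start.
#' @export
call_fork_segments <- function(track, threshold = 0.5, min_length_bp = 1000L,
                               gap_tolerance = 500L) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  out <- empty_feature_calls()
  for (kind in c("fork_left", "fork_right")) {
    p <- if (kind == "fork_left") track$p_left else track$p_right
    runs <- prob_runs(track$positions, p, threshold, gap_tolerance)
    if (is.null(runs)) next
    keep <- runs[, "end"] - runs[, "start"] >= min_length_bp
    if (!any(keep)) next
    out <- rbind(out, new_feature_call(kind, track$contig,
                                       runs[keep, "start"], runs[keep, "end"],
                                       track$read_id, runs[keep, "score"]))
  }
  out[order(out$start), , drop = FALSE]
}

#' Match diverging and converging forks into origin and termination calls
#'
#' For each adjacent pair of fork segments on a read: a leftward-fork segment
#' whose right edge precedes a rightward-fork segment (diverging) yields an
#' origin call on the gap between them; a rightward-fork segment followed by
#' a leftward-fork segment (converging) yields a termination call on the gap.
#' Overlapping segments of a matching pair yield the overlap midpoint +/- 1
#' as a minimal interval. Unmatched single forks produce no origin or
#' termination calls.
#'
#' @param segments Fork-segment calls of a single read (from
#'   [call_fork_segments()]), sorted by start.
#' @return Feature-call data frame with kinds `origin` / `termination`.
#' @export
match_forks <- function(segments) {
  out <- empty_feature_calls()
  n <- nrow(segments)
  if (n < 2L) return(out)
  segments <- segments[order(segments$start), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    a <- segments[i, ]; b <- segments[i + 1L, ]
    kind <- if (a$kind == "fork_left" && b$kind == "fork_right") {
      "origin"
    } else if (a$kind == "fork_right" && b$kind == "fork_left") {
      "termination"
    } else {
      next
    }
    score <- mean(c(a$score, b$score))
    if (a$end <= b$start) {
      iv <- c(a$end, max(b$start, a$end + 1L))
    } else {
      mid <- floor((b$start + min(a$end, b$end)) / 2)
      iv <- c(mid - 1L, mid + 1L)
    }
    out <- rbind(out, new_feature_call(kind, a$contig, iv[1], iv[2],
                                       a$read_id, score))
  }
  out
}

#' Filter reads eligible for origin/termination calling
#'
#' Keeps reads whose mapped span is at least `min_length` bp with mapping
#' quality at least `min_mapq`. Records with unknown MAPQ pass the quality
#' criterion.
#'
#' @param records List of `detect_record` (or `fork_track`).
#' @param min_length Minimum mapped length in bp (inclusive).
#' @param min_mapq Minimum mapping quality (inclusive).
#' @return The passing subset of `records`.
#' @export
filter_reads_for_calling <- function(records, min_length = 20000L,
                                     min_mapq = 20L) {
  keep <- vapply(records, function(r) {
    len_ok <- (r$ref_end - r$ref_start) >= min_length
    mapq_ok <- is.na(r$mapq) || r$mapq >= min_mapq
    len_ok && mapq_ok
  }, logical(1))
  records[keep]
}

#' Call all replication features on a set of reads
#'
#' Applies the read filter, scores each passing read with the fork-sense
#' network, calls fork segments and matches them into origins and
#' terminations.
#'
#' @param model A trained `forksense_model`.
#' @param records List of `detect_record`.
#' @param apply_filter Apply [filter_reads_for_calling()] first.
#' @param threshold,min_length_bp,gap_tolerance Segment-calling controls.
#' @return List with `calls` (one feature-call data frame over all reads)
#'   and `tracks` (the per-read `fork_track`s, named by read id).
#' @export
call_replication_features <- function(model, records, apply_filter = TRUE,
                                      threshold = 0.5, min_length_bp = 1000L,
                                      gap_tolerance = 500L) {
  if (apply_filter) records <- filter_reads_for_calling(records)
  calls <- empty_feature_calls()
  tracks <- list()
  for (rec in records) {
    tr <- predict_forksense(model, rec)
    tracks[[rec$read_id]] <- tr
    segs <- call_fork_segments(tr, threshold, min_length_bp, gap_tolerance)
    calls <- rbind(calls, segs, match_forks(segs))
  }
  list(calls = calls, tracks = tracks)
}
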