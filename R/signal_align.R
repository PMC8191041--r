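#' Event segmentation of a raw current trace
#'
#' Partitions the signal into contiguous events (pore translocation states)
#' by placing boundaries where a sliding two-window mean-shift statistic
#' exceeds a threshold and is a local maximum.
#'
#' @param signal Numeric vector of current samples (pA).
#' @param window Half-window size (samples) of the shift statistic.
#' @param threshold Minimum absolute mean shift (pA) to open a new event.
#' @param jump_threshold Single-sample jump (pA) that also opens an event
#'   (catches one-sample dwells); 0 disables the fine scale.
#' @return Data frame with columns `start`, `end` (0-based half-open sample
#'   indices), `duration`, `mean`, `sd`; events partition the signal.
#' @export
segment_events <- function(signal, window = 2L, threshold = 2,
                           jump_threshold = 4) {
  if (length(signal) < 2L) stopf("signal must have at least 2 samples")
  .segment_events_cpp(as.numeric(signal), as.integer(window), threshold,
                      jump_threshold)
}

# Emission parameters for the alignment HMM: for every reference k-mer, the
# candidate levels it may emit (canonical plus analogue variants, CSR) and
# the k-mer's spread. The HMM scores an event against the best candidate, so
# it localises events at any substitution rate without discriminating BrdU.
hmm_emission_levels <- function(ref_seq, model) {
  codes <- seq_codes(ref_seq, allow_analogue = FALSE)
  idx <- kmer_indices(codes, model$k)
  ranks <- model$can_rank[idx]
  lens <- model$cand_ptr[ranks + 1L] - model$cand_ptr[ranks]
  take <- sequence(lens, from = model$cand_ptr[ranks] + 1L)
  list(cand_means = model$cand_means[take],
       cand_ptr = c(0L, cumsum(lens)),
       sd = model$sd[idx])
}

#' Hidden Markov signal alignment of events to a reference span
#'
#' Aligns segmented events to the reference k-mer sequence with a banded
#' Viterbi pass through a linear profile HMM (match / insert-extra-event /
#' skip-missed-k-mer states). The match emission of a k-mer scores the event
#' against the best of the k-mer's candidate levels — canonical or any
#' analogue variant — at the k-mer's own spread, so alignment stays accurate
#' at any substitution rate while remaining agnostic about which candidate
#' was present: discrimination of BrdU is left entirely to the detection
#' network.
#'
#' @param events Event table from [segment_events()].
#' @param ref_seq Reference sequence of the read's aligned span (ACGT).
#' @param model A `pore_model`.
#' @param band_width Band half-width in k-mers around the event/k-mer
#'   diagonal (or around `centres` when given).
#' @param transitions Named probabilities `match`, `insert`, `skip`, `stay`;
#'   `stay` is folded into the insert self-transition.
#' @param centres Optional 1-based anchor k-mer per event (monotone); the
#'   band then follows this path instead of the linear diagonal.
#' @return List of class `event_alignment`: `pairs` (data frame `event`,
#'   `kmer`, both 1-based, monotone), `skipped` (k-mer indices with no
#'   event), `score` (Viterbi log-probability), `n_kmers`.
#' @export
align_events <- function(events, ref_seq, model, band_width = 100L,
                         transitions = c(match = 0.89, insert = 0.05,
                                         skip = 0.05, stay = 0.01),
                         centres = NULL) {
  if (nchar(ref_seq) < model$k) stopf("reference span shorter than one k-mer")
  if (nrow(events) < 1L) stopf("need at least one event")
  lev <- hmm_emission_levels(ref_seq, model)
  res <- .viterbi_align_cpp(events$mean, lev$cand_means,
                            as.integer(lev$cand_ptr), lev$sd,
                            as.integer(band_width),
                            log(transitions[["match"]]),
                            log(transitions[["insert"]] + transitions[["stay"]]),
                            log(transitions[["skip"]]),
                            as.integer(centres %||% integer(0)))
  if (!isTRUE(res$ok)) stopf("read is unalignable: banded Viterbi found no valid path")
  assignment <- res$assignment
  structure(list(pairs = data.frame(event = seq_along(assignment),
                                    kmer = assignment),
                 skipped = setdiff(seq_along(lev$sd), assignment),
                 score = res$score,
                 n_kmers = length(lev$sd)),
            class = "event_alignment")
}

#' @export
print.event_alignment <- function(x, ...) {
  cat(sprintf("<event_alignment> %d events over %d k-mers, %d skipped, score %.1f\n",
              nrow(x$pairs), x$n_kmers, length(x$skipped), x$score))
  invisible(x)
}

# Feature layout of one k-mer row of an input tensor. Levels are standardised
# around the pore's operating range (~60-120 pA); the observed level
# difference is the discriminative channel for the analogue shift. Columns
# 31 carries the matched filter (the shift the pore model predicts for this
# row's k-mer if the tensor's centre thymidine carried the analogue) and
# columns 32-37 the row's full local shift design: the predicted shift for a
# single analogue at each offset of the row's k-mer, so the network can
# solve for which thymidines in the window are substituted.
N_TENSOR_FEATURES <- 37L

# Per-k-mer expected analogue shift for a single substitution at offset o
# (0-based within the k-mer); 0 where the offset base is not thymidine.
centre_shift_table <- function(codes, idx, model) {
  K <- length(idx)
  S <- matrix(0, K, model$k)
  for (o in 0:(model$k - 1L)) {
    is_t <- codes[(1L + o):(K + o)] == 3L
    vi <- idx[is_t] + 5L^(model$k - 1L - o)
    S[is_t, o + 1L] <- model$mean[vi] - model$mean[idx[is_t]]
  }
  S
}

tensor_feature_matrix <- function(alignment, events, ref_seq, model, S) {
  K <- alignment$n_kmers
  j <- alignment$pairs$kmer
  dur <- events$duration
  wsum <- rowsum(events$mean * dur, j)
  dsum <- rowsum(dur + 0, j)
  sqsum <- rowsum((events$sd^2 + events$mean^2) * dur, j)
  jj <- as.integer(rownames(wsum))
  ev_mean <- rep(NA_real_, K); ev_sd <- rep(NA_real_, K); ev_dwell <- rep(0, K)
  ev_mean[jj] <- wsum / dsum
  ev_sd[jj] <- sqrt(pmax(sqsum / dsum - (wsum / dsum)^2, 0))
  ev_dwell[jj] <- dsum
  codes <- seq_codes(ref_seq, allow_analogue = FALSE)
  idx <- kmer_indices(codes, model$k)
  exp_mean <- model$mean[idx]
  miss <- is.na(ev_mean)
  fm <- matrix(0, K, N_TENSOR_FEATURES)
  fm[!miss, 1] <- (ev_mean[!miss] - 90) / 30
  fm[!miss, 2] <- ev_sd[!miss] / 2
  fm[!miss, 3] <- log1p(ev_dwell[!miss]) / 3
  fm[!miss, 4] <- (exp_mean[!miss] - 90) / 30
  fm[!miss, 5] <- (ev_mean[!miss] - exp_mean[!miss]) / 5
  fm[miss, 6] <- 1                            # sentinel: skipped k-mer
  # one-hot of the k-mer's six bases (columns 7..30)
  onehot_base <- matrix(0, K, 4L * model$k)
  for (p in seq_len(model$k)) {
    b <- codes[p:(K + p - 1L)]
    onehot_base[cbind(seq_len(K), (p - 1L) * 4L + b + 1L)] <- 1
  }
  fm[, 7:30] <- onehot_base
  fm[, 32:37] <- S / 5
  fm
}

#' Build per-thymidine input tensors for the detection network
#'
#' One tensor is produced per candidate thymidine whose full window of
#' `window_W` k-mers (centred on the k-mer starting at the thymidine) lies
#' inside the aligned span. Multiple events mapped to one k-mer are
#' summarised (duration-weighted mean, pooled sd, summed dwell); skipped
#' k-mers contribute an all-zero sentinel row with a missing flag.
#'
#' @param alignment An `event_alignment` from [align_events()].
#' @param events The event table the alignment was computed from.
#' @param ref_seq Reference sequence of the aligned span.
#' @param candidate_positions 0-based reference positions of the thymidines
#'   to evaluate (absolute coordinates; see `ref_start`).
#' @param model A `pore_model`.
#' @param window_W Odd window width in k-mers.
#' @param ref_start 0-based reference coordinate of `ref_seq`'s first base.
#' @return List with `x` (array `n` x `window_W` x 30), `positions` (kept
#'   absolute positions), `n_excluded` (windows overhanging the span).
#' @export
build_input_tensors <- function(alignment, events, ref_seq, candidate_positions,
                                model, window_W = 15L, ref_start = 0L) {
  if (window_W %% 2L != 1L) stopf("window_W must be odd")
  K <- alignment$n_kmers
  half <- (window_W - 1L) %/% 2L
  centre <- as.integer(candidate_positions) - as.integer(ref_start) + 1L
  keep <- centre - half >= 1L & centre + half <= K
  kept <- centre[keep]
  n <- length(kept)
  if (n == 0L) {
    return(list(x = array(0, c(0L, window_W, N_TENSOR_FEATURES)),
                positions = integer(0),
                n_excluded = sum(!keep)))
  }
  codes <- seq_codes(ref_seq, allow_analogue = FALSE)
  idx <- kmer_indices(codes, model$k)
  S <- centre_shift_table(codes, idx, model)
  fm <- tensor_feature_matrix(alignment, events, ref_seq, model, S)
  x <- array(0, c(n, window_W, N_TENSOR_FEATURES))
  for (w in seq_len(window_W)) {
    rows_w <- kept + (w - 1L - half)
    block <- fm[rows_w, , drop = FALSE]
    # matched-filter column: predicted shift of this row's k-mer were the
    # centre thymidine substituted (rows whose k-mer covers the centre)
    off <- kept - rows_w
    covers <- off >= 0L & off <= model$k - 1L
    block[covers, N_TENSOR_FEATURES] <-
      S[cbind(rows_w[covers], off[covers] + 1L)] / 5
    x[, w, ] <- block
  }
  list(x = x, positions = candidate_positions[keep], n_excluded = sum(!keep))
}

#' Sample-level alignment refinement
#'
#' Re-aligns every raw current sample to a reference k-mer with a banded
#' Viterbi pass anchored on the coarse event-level alignment ("resquiggle").
#' Event boundaries that the mean-shift segmentation smeared — in
#' particular one-sample dwells — are recovered because each k-mer may
#' consume any geometric run of samples. The refined occupancy is returned
#' as a fresh event table (one event per occupied k-mer) plus its (insert-
#' free) alignment.
#'
#' @param signal Raw current samples.
#' @param events,alignment Output of [segment_events()] / [align_events()].
#' @param ref_seq Reference sequence of the aligned span.
#' @param model A `pore_model`.
#' @param band Band half-width in k-mers around the anchor path.
#' @param dwell_mean Expected samples per k-mer (sets the stay/advance
#'   transition odds).
#' @return List with `events` and `alignment` in the same shapes as
#'   [segment_events()] and [align_events()].
#' @export
refine_alignment <- function(signal, events, alignment, ref_seq, model,
                             band = 6L, dwell_mean = 8) {
  lev <- hmm_emission_levels(ref_seq, model)
  K <- length(lev$sd)
  # anchor: per-sample k-mer interpolated from the event alignment
  anchor <- integer(length(signal))
  ev_kmer <- alignment$pairs$kmer
  for (i in seq_len(nrow(events))) {
    anchor[(events$start[i] + 1L):events$end[i]] <- ev_kmer[i]
  }
  anchor <- cummax(pmax(anchor, 1L))
  p_adv <- 1 / dwell_mean
  occ <- .sample_viterbi_cpp(as.numeric(signal), lev$cand_means,
                             as.integer(lev$cand_ptr), lev$sd, anchor,
                             as.integer(band),
                             log(1 - p_adv), log(p_adv * 0.95),
                             log(p_adv * 0.05))
  run_ends <- c(which(diff(occ) != 0L), length(occ))
  run_starts <- c(0L, run_ends[-length(run_ends)])
  kmer_of_run <- occ[run_ends]
  cs <- c(0, cumsum(signal)); cs2 <- c(0, cumsum(signal^2))
  dur <- run_ends - run_starts
  mean_run <- (cs[run_ends + 1L] - cs[run_starts + 1L]) / dur
  var_run <- (cs2[run_ends + 1L] - cs2[run_starts + 1L]) / dur - mean_run^2
  sd_run <- sqrt(pmax(var_run, 0))
  ev2 <- data.frame(start = run_starts, end = run_ends,
                    duration = run_ends - run_starts,
                    mean = mean_run, sd = sd_run)
  al2 <- structure(list(pairs = data.frame(event = seq_along(kmer_of_run),
                                           kmer = kmer_of_run),
                        skipped = setdiff(seq_len(K), kmer_of_run),
                        score = alignment$score,
                        n_kmers = K),
                   class = "event_alignment")
  list(events = ev2, alignment = al2)
}

# Full per-read tensor pipeline: segment, align, refine, window. Returns
# NULL if the read is unalignable. The coarse band grows with the square
# root of the span length because the true alignment path drifts from the
# linear diagonal like a random walk in the per-k-mer dwell.
read_tensors <- function(signal, ref_seq, t_positions, model, window_W = 15L,
                         ref_start = 0L, band_width = NULL,
                         seg_window = 2L, seg_threshold = 2,
                         refine = TRUE) {
  if (is.null(band_width)) {
    band_width <- max(100L, as.integer(ceiling(2.2 * sqrt(nchar(ref_seq)))))
  }
  ev <- segment_events(signal, seg_window, seg_threshold)
  al <- tryCatch({
    E <- nrow(ev)
    if (E > 20000L) {
      # coarse-to-fine: anchor on a decimated event subsequence so the wide
      # sqrt-scaled band is only paid on E/6 events; if the coarse path hugs
      # its band edge (alignment drift beyond the sqrt law), retry wider
      dec <- seq(1L, E, by = 6L)
      bw <- band_width
      repeat {
        coarse <- align_events(ev[dec, ], ref_seq, model, band_width = bw)
        lin <- round((seq_along(dec) - 1) * (coarse$n_kmers - 1) /
                       max(1L, length(dec) - 1L)) + 1L
        if (max(abs(coarse$pairs$kmer - lin)) < bw - 5L || bw >= 4L * band_width) break
        bw <- bw * 2L
      }
      centres <- round(approx(dec, coarse$pairs$kmer, xout = seq_len(E),
                              rule = 2)$y)
      centres <- cummax(pmin(pmax(centres, 1L), coarse$n_kmers))
      align_events(ev, ref_seq, model, band_width = 32L, centres = centres)
    } else {
      align_events(ev, ref_seq, model, band_width = band_width)
    }
  }, error = function(e) NULL)
  if (is.null(al)) return(NULL)
  if (refine) {
    rf <- tryCatch(refine_alignment(signal, ev, al, ref_seq, model),
                   error = function(e) NULL)
    if (!is.null(rf)) { ev <- rf$events; al <- rf$alignment }
  }
  tb <- build_input_tensors(al, ev, ref_seq, t_positions, model,
                            window_W = window_W, ref_start = ref_start)
  tb$alignment <- al
  tb
}

#' Dump an event alignment as a TSV table (debug aid)
#'
#' @param alignment An `event_alignment`.
#' @param events The matching event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_alignment <- function(alignment, events, path) {
  tab <- data.frame(event = alignment$pairs$event,
                    kmer = alignment$pairs$kmer,
                    event_mean = sprintf("%.3f", events$mean[alignment$pairs$event]),
                    duration = events$duration[alignment$pairs$event])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
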