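#' Detect records: per-read BrdU probability tables
#'
#' A detect record holds, for one read, the 0-based reference position of
#' every evaluated thymidine, the network's BrdU probability at that
#' position, and the reference 6-mer starting there. Records are the sole
#' input of the fork-sense stage and serialise to the package's detect-table
#' dialect (see [write_detect_table()]).
#'
#' @name detect_record
NULL

new_detect_record <- function(read_id, contig, ref_start, ref_end, strand,
                              rows, mapq = NA_integer_) {
  if (nrow(rows) && any(diff(rows$position) <= 0)) {
    stopf("detect record positions must be strictly increasing")
  }
  if (nrow(rows) && (any(rows$probability < 0) || any(rows$probability > 1))) {
    stopf("detect record probabilities must be in [0, 1]")
  }
  structure(list(read_id = read_id, contig = contig,
                 ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
                 strand = strand, mapq = as.integer(mapq), rows = rows),
            class = "detect_record")
}

#' @export
print.detect_record <- function(x, ...) {
  cat(sprintf("<detect_record> %s %s:%d-%d(%s) mapq=%s, %d thymidines\n",
              x$read_id, x$contig, x$ref_start, x$ref_end, x$strand,
              ifelse(is.na(x$mapq), "NA", x$mapq), nrow(x$rows)))
  invisible(x)
}

#' Score one read's tensors into a detect record
#'
#' @param model A trained `detect_model`.
#' @param tensors Output of [build_input_tensors()] (fields `x`,
#'   `positions`).
#' @param read_id,contig,ref_start,ref_end,strand,mapq Read metadata.
#' @param ref_seq Reference sequence of the aligned span (used for the 6-mer
#'   column).
#' @return A `detect_record`; empty tensor input yields a record with zero
#'   rows.
#' @export
detect_read <- function(model, tensors, read_id, contig, ref_start, ref_end,
                        strand, ref_seq, mapq = NA_integer_) {
  pos <- tensors$positions
  if (length(pos) == 0L) {
    rows <- data.frame(position = integer(0), probability = numeric(0),
                       sixmer = character(0), stringsAsFactors = FALSE)
  } else {
    prob <- predict_detect(model, tensors$x)
    rel <- pos - as.integer(ref_start)
    sixmer <- substring(ref_seq, rel + 1L, rel + 6L)
    rows <- data.frame(position = as.integer(pos), probability = prob,
                       sixmer = sixmer, stringsAsFactors = FALSE)
  }
  new_detect_record(read_id, contig, ref_start, ref_end, strand, rows,
                    mapq = mapq)
}

#' Threshold a detect record into boolean BrdU calls
#'
#' A position is called BrdU-positive when its probability strictly exceeds
#' the threshold.
#'
#' @param record A `detect_record`.
#' @param threshold Probability threshold in `[0, 1]`.
#' @return Logical vector, one entry per record row.
#' @export
classify_at_threshold <- function(record, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  record$rows$probability > threshold
}

#' Run the full detection pipeline on simulated reads
#'
#' For each read: event segmentation, banded HMM signal alignment, tensor
#' construction and network scoring. Unalignable reads are dropped and
#' counted.
#'
#' @param model A trained `detect_model`.
#' @param reads List of `sim_read`.
#' @param pore_model A `pore_model`.
#' @param window_W Tensor window width.
#' @param band_width HMM band half-width.
#' @return List with `records` (list of `detect_record`) and `n_failed`.
#' @export
detect_sim_reads <- function(model, reads, pore_model, window_W = 15L,
                             band_width = NULL) {
  records <- vector("list", length(reads))
  failed <- 0L
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    tb <- read_tensors(rd$signal, rd$sequence, rd$t_positions, pore_model,
                       window_W = window_W, ref_start = rd$ref_start,
                       band_width = band_width)
    if (is.null(tb)) { failed <- failed + 1L; next }
    records[[i]] <- detect_read(model, tb, rd$read_id, rd$contig, rd$ref_start,
                                rd$ref_end, rd$strand, rd$sequence,
                                mapq = rd$mapq)
  }
  list(records = Filter(Negate(is.null), records), n_failed = failed)
}

# Truth lookup: per evaluated record row, was the thymidine substituted?
# Positions absent from the simulated truth are an error.
truth_labels_for_record <- function(record, sim_read) {
  m <- match(record$rows$position, sim_read$t_positions)
  if (anyNA(m)) stopf("record position not found in simulated truth")
  sim_read$truth_brdu[m]
}
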