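#' On-disk formats
#'
#' Readers and writers for everything the pipeline touches: FASTA references,
#' BAM alignments, the plain-text signal container, the detect-table dialect,
#' BED feature files and genome-browser bedgraphs. All writers are
#' deterministic byte-for-byte given identical inputs; all interval formats
#' are 0-based half-open.
#'
#' @name io_formats
NULL

#' Load a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase contig sequences.
#' @export
load_reference <- function(path) {
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stopf("reference contains non-nucleotide characters: %s", path)
      }
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) stopf("reference FASTA '%s' contains no sequences", path)
  nm <- sub("\\s.*$", "", names(set))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) stopf("duplicate contig name(s) in reference: %s",
                         paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("contig(s) with non-ACGTN characters: %s",
                      paste(nm[bad], collapse = ", "))
  names(seqs) <- nm
  seqs
}

#' Write a reference genome to FASTA
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(contigs)) {
    writeLines(paste0(">", nm), con)
    seqc <- contigs[[nm]]
    starts <- seq(1L, nchar(seqc), by = 70L)
    writeLines(substring(seqc, starts, pmin(starts + 69L, nchar(seqc))), con)
  }
  invisible(path)
}

# ---- plain-text signal container ------------------------------------------
# One block per read:
#   >read_id<TAB>contig<TAB>ref_start<TAB>ref_end<TAB>strand<TAB>mapq
#   sequence line
#   signal line (space-separated pA values, 3 decimals)

#' Write simulated reads to a signal container
#' @param reads List of `sim_read`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_container <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rd in reads) {
    writeLines(sprintf(">%s\t%s\t%d\t%d\t%s\t%d", rd$read_id, rd$contig,
                       rd$ref_start, rd$ref_end, rd$strand, rd$mapq), con)
    writeLines(rd$sequence, con)
    writeLines(paste(sprintf("%.3f", rd$signal), collapse = " "), con)
  }
  invisible(path)
}

#' Read a signal container
#' @param path Container path.
#' @return List of `sim_read` (without truth labels).
#' @export
read_signal_container <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 3L != 0L) stopf("malformed signal container '%s'", path)
  n <- length(lines) %/% 3L
  lapply(seq_len(n), function(i) {
    hdr <- strsplit(lines[3L * i - 2L], "\t", fixed = TRUE)[[1]]
    if (length(hdr) != 6L || !startsWith(hdr[1], ">")) {
      stopf("malformed read header at line %d", 3L * i - 2L)
    }
    sequence <- lines[3L * i - 1L]
    signal <- as.numeric(strsplit(lines[3L * i], " ", fixed = TRUE)[[1]])
    codes <- seq_codes(sequence, allow_analogue = FALSE)
    t_pos <- as.integer(hdr[3]) + which(codes == 3L) - 1L
    new_sim_read(sub("^>", "", hdr[1]), hdr[2], as.integer(hdr[3]),
                 as.integer(hdr[4]), hdr[5], sequence, signal, t_pos,
                 truth_brdu = rep(NA, length(t_pos)), mapq = as.integer(hdr[6]))
  })
}

# ---- BAM ------------------------------------------------------------------

#' Write perfect alignments of simulated reads as an indexed BAM
#'
#' The simulator's reads map end-to-end, so each record carries a single
#' match-run CIGAR.
#'
#' @param reads List of `sim_read`.
#' @param contigs Named character vector of reference sequences (for header
#'   lengths).
#' @param path Output BAM path (an index is created alongside).
#' @return The BAM path, invisibly.
#' @export
write_sim_bam <- function(reads, contigs, path) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(contigs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(contigs[[nm]])), con)
  }
  ord <- order(vapply(reads, function(r) r$contig, character(1)),
               vapply(reads, function(r) r$ref_start, integer(1)))
  for (rd in reads[ord]) {
    flag <- if (rd$strand == "+") 0L else 16L
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                       rd$read_id, flag, rd$contig, rd$ref_start + 1L, rd$mapq,
                       nchar(rd$sequence), rd$sequence), con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(bam)
}

#' Join a signal container with BAM alignments
#'
#' Yields one bundle per primary, mapped alignment whose query name has
#' signal in the container; secondary/supplementary and unmapped records are
#' skipped and unmatched ids counted.
#'
#' @param container_path Signal container path.
#' @param bam_path Indexed BAM path.
#' @param reference Named character vector from [load_reference()].
#' @return List with `bundles` (list of `sim_read` carrying BAM coordinates)
#'   and `n_unmatched`.
#' @export
load_read_bundles <- function(container_path, bam_path, reference) {
  reads <- read_signal_container(container_path)
  names(reads) <- vapply(reads, function(r) r$read_id, character(1))
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  bam <- Rsamtools::scanBam(bam_path,
                            param = Rsamtools::ScanBamParam(
                              flag = flags,
                              what = c("qname", "rname", "pos", "mapq", "strand", "qwidth")))[[1]]
  bundles <- list()
  n_unmatched <- 0L
  for (i in seq_along(bam$qname)) {
    qn <- bam$qname[i]
    if (!qn %in% names(reads)) { n_unmatched <- n_unmatched + 1L; next }
    rd <- reads[[qn]]
    contig <- as.character(bam$rname[i])
    if (!contig %in% names(reference)) stopf("BAM contig '%s' absent from reference", contig)
    rd$contig <- contig
    rd$ref_start <- bam$pos[i] - 1L
    rd$ref_end <- rd$ref_start + bam$qwidth[i]
    rd$strand <- as.character(bam$strand[i])
    rd$mapq <- bam$mapq[i]
    bundles[[qn]] <- rd
  }
  n_unmatched <- n_unmatched + sum(!names(reads) %in% bam$qname)
  if (length(bundles) == 0L) stopf("no reads joined between container and BAM")
  list(bundles = unname(bundles), n_unmatched = n_unmatched)
}

# ---- detect table ---------------------------------------------------------

#' Write detect records to the detect-table dialect
#'
#' Header lines start with `#`; each read contributes a line
#' `>read_id<TAB>contig<TAB>ref_start<TAB>ref_end<TAB>strand<TAB>mapq`
#' followed by rows `position<TAB>probability<TAB>sixmer` with probabilities
#' printed to 6 decimal places. This file is the only input the fork-sense
#' stage needs.
#'
#' @param records List of `detect_record`.
#' @param path Output path.
#' @param header Named character vector of extra header keys.
#' @return `path`, invisibly.
#' @export
write_detect_table <- function(records, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# forktrace detect v%s",
                     as.character(utils::packageVersion("forktrace"))), con)
  for (nm in names(header)) writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
  for (rec in records) {
    writeLines(sprintf(">%s\t%s\t%d\t%d\t%s\t%d", rec$read_id, rec$contig,
                       rec$ref_start, rec$ref_end, rec$strand,
                       ifelse(is.na(rec$mapq), -1L, rec$mapq)), con)
    if (nrow(rec$rows)) {
      writeLines(sprintf("%d\t%s\t%s", rec$rows$position,
                         format_prob(rec$rows$probability), rec$rows$sixmer), con)
    }
  }
  invisible(path)
}

#' Parse a detect table
#'
#' Exact inverse of [write_detect_table()]; unknown header keys are
#' preserved in the `header` attribute. Malformed rows raise an error with
#' their line number.
#'
#' @param path Detect-table path.
#' @return List of `detect_record` with a `header` attribute.
#' @export
parse_detect_table <- function(path) {
  lines <- readLines(path)
  header <- character(0)
  records <- list()
  cur <- NULL
  pos <- integer(0); prob <- numeric(0); six <- character(0)
  flush <- function() {
    if (is.null(cur)) return()
    rows <- data.frame(position = pos, probability = prob, sixmer = six,
                       stringsAsFactors = FALSE)
    records[[length(records) + 1L]] <<- new_detect_record(
      cur$read_id, cur$contig, cur$ref_start, cur$ref_end, cur$strand, rows,
      mapq = cur$mapq)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "#")) {
      header <- c(header, sub("^#\\s*", "", line))
    } else if (startsWith(line, ">")) {
      flush()
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (!length(f) %in% c(5L, 6L)) stopf("malformed read header at line %d", ln)
      mapq <- if (length(f) == 6L) as.integer(f[6]) else NA_integer_
      if (!is.na(mapq) && mapq < 0L) mapq <- NA_integer_
      cur <- list(read_id = sub("^>", "", f[1]), contig = f[2],
                  ref_start = as.integer(f[3]), ref_end = as.integer(f[4]),
                  strand = f[5], mapq = mapq)
      pos <- integer(0); prob <- numeric(0); six <- character(0)
    } else if (nzchar(line)) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) != 3L || is.null(cur)) stopf("malformed row at line %d", ln)
      p <- suppressWarnings(as.numeric(f[2]))
      q <- suppressWarnings(as.integer(f[1]))
      if (is.na(p) || is.na(q) || p < 0 || p > 1) {
        stopf("malformed row at line %d: bad position or probability", ln)
      }
      pos <- c(pos, q); prob <- c(prob, p); six <- c(six, f[3])
    }
  }
  flush()
  structure(records, header = header)
}

# ---- BED and bedgraph -----------------------------------------------------

#' Write feature calls as a BED4+ file
#'
#' Columns: chrom, start, end, read_id, score (0-based half-open).
#'
#' @param calls Feature-call data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", calls$contig, calls$start,
                       calls$end, calls$read_id, format_prob(calls$score)), con)
  }
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path.
#' @return Data frame `contig`, `start`, `end` (plus `name`, `score` when
#'   present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(contig = vapply(f, `[`, character(1), 1),
                    start = as.integer(vapply(f, `[`, character(1), 2)),
                    end = as.integer(vapply(f, `[`, character(1), 3)),
                    stringsAsFactors = FALSE)
  if (all(lengths(f) >= 4L)) out$name <- vapply(f, `[`, character(1), 4)
  if (all(lengths(f) >= 5L)) out$score <- as.numeric(vapply(f, `[`, character(1), 5))
  out
}

bedgraph_lines <- function(contig, positions, values) {
  sprintf("%s\t%d\t%d\t%s", contig, positions, positions + 1L,
          format_prob(values))
}

#' Write per-read bedgraphs of BrdU and fork probabilities
#'
#' One bedgraph per read per channel, each with a track line naming the read
#' and channel; intervals are `[position, position + 1)` with the
#' probability as value, ready for a genome browser.
#'
#' @param x A `detect_record` or `fork_track` (or a list of them).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_bedgraphs <- function(x, out_dir) {
  if (inherits(x, c("detect_record", "fork_track"))) x <- list(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (obj in x) {
    if (inherits(obj, "detect_record")) {
      channels <- list(brdu = list(pos = obj$rows$position,
                                   val = obj$rows$probability))
    } else {
      channels <- list(leftFork = list(pos = obj$positions, val = obj$p_left),
                       rightFork = list(pos = obj$positions, val = obj$p_right))
    }
    for (ch in names(channels)) {
      f <- file.path(out_dir, sprintf("%s.%s.bedgraph", obj$read_id, ch))
      con <- file(f, "w")
      writeLines(sprintf('track type=bedGraph name="%s %s" viewLimits=0:1',
                         obj$read_id, ch), con)
      if (length(channels[[ch]]$pos)) {
        writeLines(bedgraph_lines(obj$contig, channels[[ch]]$pos,
                                  channels[[ch]]$val), con)
      }
      close(con)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Parse a bedgraph written by [write_bedgraphs()]
#' @param path Bedgraph path.
#' @return Data frame `contig`, `position`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), position = integer(0),
                      value = numeric(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(contig = vapply(f, `[`, character(1), 1),
             position = as.integer(vapply(f, `[`, character(1), 2)),
             value = as.numeric(vapply(f, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}
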