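#' Pore models: expected current levels per 6-mer
#'
#' A pore model maps each 6-mer occupying the nanopore to the mean and spread
#' (standard deviation) of the ionic current observed while that 6-mer is in
#' the pore, in picoamperes. BrdU-for-thymidine substitution shifts the
#' current of the k-mers that contain the analogue; those variants are spelled
#' with `B` in place of the substituted `T` (e.g. `ACGBAT` is `ACGTAT` with
#' its first thymidine carrying BrdU).
#'
#' Internally the model is a dense lookup over all base-5 strings of length 6
#' (alphabet A,C,G,T,B); only canonical k-mers and valid analogue variants
#' (where every `B` sits at a `T` position of the canonical counterpart) have
#' defined levels.
#'
#' @name pore_model
NULL

new_pore_model <- function(mean, sd, k = 6L, source = "unknown") {
  idx <- pore_model_index()
  # per canonical k-mer: the set of candidate levels the pore can emit there
  # (canonical plus every defined analogue variant), stored CSR-style; the
  # signal-alignment HMM takes the best candidate per event so alignment
  # stays sharp at any substitution rate without calling the substitution
  can_rank <- integer(idx$n)
  can_rank[idx$canonical] <- seq_along(idx$canonical)
  ok <- !is.na(mean[idx$variant])
  vs <- split(mean[idx$variant][ok],
              can_rank[idx$counterpart_of_variant[ok]])
  cand <- as.list(mean[idx$canonical])
  for (nm in names(vs)) {
    r <- as.integer(nm)
    cand[[r]] <- c(cand[[r]], vs[[nm]])
  }
  lens <- lengths(cand)
  structure(list(k = k, mean = mean, sd = sd,
                 can_rank = can_rank,
                 cand_means = unlist(cand, use.names = FALSE),
                 cand_ptr = c(0L, cumsum(lens)),
                 source = source),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  n_def <- sum(!is.na(x$mean))
  cat(sprintf("<pore_model> k=%d, %d defined k-mers (%d canonical), source=%s\n",
              x$k, n_def, 4L^x$k, x$source))
  invisible(x)
}

# Indices of all 4096 canonical 6-mers and all valid analogue variants within
# the dense 5^6 table, plus the canonical counterpart of every variant.
pore_model_index <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    k <- 6L
    n <- 5L^k
    digits <- matrix(0L, n, k)
    x <- 0:(n - 1)
    for (j in k:1) {
      digits[, j] <- x %% 5L
      x <- x %/% 5L
    }
    has_b <- rowSums(digits == 4L) > 0L
    canonical_idx <- which(!has_b)
    # canonical counterpart: replace code 4 (B) by 3 (T)
    repl <- digits
    repl[repl == 4L] <- 3L
    mult <- 5^((k - 1L):0L)
    counterpart <- as.integer(repl %*% mult + 1)
    # a variant is valid if it contains at least one B (all Bs sit at positions
    # that are T in the counterpart by construction)
    variant_idx <- which(has_b)
    cache <<- list(canonical = canonical_idx,
                   variant = variant_idx,
                   counterpart_of_variant = counterpart[variant_idx],
                   n = n, k = k)
    cache
  }
})

#' Build the bundled synthetic 6-mer pore model
#'
#' Constructs the package's reference pore model deterministically from a
#' fixed internal seed: canonical 6-mer means are drawn uniformly on
#' 60--120 pA with spreads on 1--2 pA. The analogue current shift is
#' *systematic in sequence context*, as halogenated-base shifts are in a
#' real pore: a BrdU at pore position `p` of the 6-mer contributes a fixed
#' positional shift (drawn once, magnitudes 5--9 pA with mixed signs),
#' shifts of multiple analogues add, and each variant k-mer carries a small
#' k-mer-specific perturbation (N(0, 0.7 pA)). Variant shifts are floored at
#' 1.5 pA in magnitude so every analogue k-mer stays detectable; the spread
#' of a variant equals the spread of its canonical counterpart.
#'
#' The same table is returned on every call, in every session.
#'
#' @return A `pore_model` object.
#' @export
default_pore_model <- function() {
  idx <- pore_model_index()
  k <- idx$k
  with_seed(104729L, {
    mean <- rep(NA_real_, idx$n)
    sd <- rep(NA_real_, idx$n)
    mean[idx$canonical] <- runif(length(idx$canonical), 60, 120)
    sd[idx$canonical] <- runif(length(idx$canonical), 1, 2)
    pos_shift <- runif(k, 5, 9) * sample(c(-1, 1), k, replace = TRUE)
    # which positions of each variant carry the analogue
    digits <- matrix(0L, idx$n, k)
    x <- 0:(idx$n - 1)
    for (j in k:1) { digits[, j] <- x %% 5L; x <- x %/% 5L }
    b_at <- digits[idx$variant, , drop = FALSE] == 4L
    shift <- as.numeric(b_at %*% pos_shift) +
      rnorm(length(idx$variant), 0, 0.7)
    shift <- sign(shift + (shift == 0)) * pmax(abs(shift), 1.5)
    mean[idx$variant] <- mean[idx$counterpart_of_variant] + shift
    sd[idx$variant] <- sd[idx$counterpart_of_variant]
    new_pore_model(mean, sd, source = "bundled-synthetic")
  })
}

#' Load a pore model from a TSV table
#'
#' The table has columns `kmer`, `mean`, `sd`, one row per k-mer; analogue
#' variants are spelled with `B` replacing the substituted `T`. The table must
#' contain every canonical 6-mer over ACGT, and every thymidine-containing
#' 6-mer must have at least one analogue variant.
#'
#' @param path Path to a tab-separated table with a header row.
#' @return A `pore_model`.
#' @export
load_pore_model <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("kmer", "mean", "sd")
  if (!all(need %in% names(tab))) {
    stopf("pore model table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(nchar(tab$kmer) != 6L)) stopf("pore model table contains non-6-mer rows")
  if (any(!is.finite(tab$mean)) || any(!is.finite(tab$sd))) {
    stopf("pore model table contains non-finite levels")
  }
  bad_sd <- tab$sd <= 0
  if (any(bad_sd)) {
    stopf("non-positive sd for k-mer(s): %s",
          paste(head(tab$kmer[bad_sd], 5), collapse = ", "))
  }
  idx <- pore_model_index()
  mean <- rep(NA_real_, idx$n)
  sd <- rep(NA_real_, idx$n)
  ki <- vapply(tab$kmer, kmer_index_one, integer(1), USE.NAMES = FALSE)
  if (anyDuplicated(ki)) {
    stopf("duplicate k-mer rows: %s", paste(head(unique(tab$kmer[duplicated(ki)]), 5), collapse = ", "))
  }
  mean[ki] <- tab$mean
  sd[ki] <- tab$sd
  missing_can <- idx$canonical[is.na(mean[idx$canonical])]
  if (length(missing_can)) {
    stopf("pore model table is missing canonical k-mer(s): %s",
          paste(vapply(head(missing_can, 5), decode_kmer, character(1)), collapse = ", "))
  }
  # every T-containing canonical k-mer needs at least one analogue variant
  have_variant <- tapply(!is.na(mean[idx$variant]), idx$counterpart_of_variant, any)
  t_kmers <- unique(idx$counterpart_of_variant)
  no_var <- t_kmers[!have_variant[as.character(t_kmers)]]
  if (length(no_var)) {
    stopf("no analogue variant for thymidine-containing k-mer(s): %s",
          paste(vapply(head(no_var, 5), decode_kmer, character(1)), collapse = ", "))
  }
  new_pore_model(mean, sd, source = path)
}

#' Write a pore model to a TSV table
#'
#' Inverse of [load_pore_model()]: deterministic, rows sorted by k-mer with
#' canonical k-mers first.
#'
#' @param model A `pore_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pore_model <- function(model, path) {
  def <- which(!is.na(model$mean))
  kmers <- vapply(def, decode_kmer, character(1))
  has_b <- grepl("B", kmers, fixed = TRUE)
  ord <- order(has_b, kmers)
  tab <- data.frame(kmer = kmers[ord],
                    mean = sprintf("%.4f", model$mean[def][ord]),
                    sd = sprintf("%.4f", model$sd[def][ord]),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected current levels along a (partially substituted) sequence
#'
#' Computes the per-window expected signal level for each of the
#' `nchar(sequence) - 5` 6-mer positions of `sequence`, substituting analogue
#' (`B`) levels in every window that covers a thymidine marked in `brdu_mask`.
#'
#' @param sequence Nucleotide string over ACGT.
#' @param brdu_mask Logical vector with one entry per `T` in `sequence`
#'   (in order of appearance); marked thymidines carry BrdU.
#' @param model A `pore_model`.
#' @return A data frame with columns `mean` and `sd`, one row per k-mer
#'   position.
#' @export
expected_levels <- function(sequence, brdu_mask, model) {
  codes <- seq_codes(sequence, allow_analogue = FALSE)
  t_pos <- which(codes == 3L)
  if (length(brdu_mask) != length(t_pos)) {
    stopf("brdu_mask has length %d but sequence has %d thymidines",
          length(brdu_mask), length(t_pos))
  }
  codes[t_pos[as.logical(brdu_mask)]] <- 4L
  idx <- kmer_indices(codes, model$k)
  mean <- model$mean[idx]
  if (anyNA(mean)) stopf("pore model has no level for k-mer '%s'",
                         decode_kmer(idx[which(is.na(mean))[1]]))
  data.frame(mean = mean, sd = model$sd[idx])
}
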