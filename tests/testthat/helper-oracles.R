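# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package's own algorithms.

# Exhaustive (unbanded) Viterbi over the full event x k-mer lattice, written
# as a plain dynamic program in R. `cands` is a list with one vector of
# candidate levels per k-mer; the emission takes the best candidate.
viterbi_reference <- function(ev_mean, cands, km_sd,
                              lp_match = log(0.89), lp_insert = log(0.06),
                              lp_skip = log(0.05)) {
  E <- length(ev_mean); K <- length(cands)
  emis <- matrix(-Inf, E, K)
  for (j in seq_len(K)) {
    for (m in cands[[j]]) {
      emis[, j] <- pmax(emis[, j], dnorm(ev_mean, m, km_sd[j], log = TRUE))
    }
  }
  V <- matrix(-Inf, E, K)
  V[1, ] <- emis[1, ] + (seq_len(K) - 1) * lp_skip
  for (i in 2:E) {
    prev <- V[i - 1, ]
    M <- cummax(prev - lp_skip * seq_len(K)) + lp_skip * seq_len(K)
    V[i, ] <- emis[i, ] + pmax(prev + lp_insert,
                               c(-Inf, M[-K] + lp_match))
  }
  fin <- V[E, ] + (K - seq_len(K)) * lp_skip
  j <- which.max(fin)
  score <- fin[j]
  assign <- integer(E)
  tol <- 1e-9
  for (i in E:2) {
    assign[i] <- j
    target <- V[i, j] - emis[i, j]
    if (is.finite(V[i - 1, j]) && abs(V[i - 1, j] + lp_insert - target) < tol) next
    found <- FALSE
    for (jp in (j - 1):1) {
      cand <- V[i - 1, jp] + (j - 1 - jp) * lp_skip + lp_match
      if (is.finite(cand) && abs(cand - target) < tol) { j <- jp; found <- TRUE; break }
    }
    if (!found) stop("reference traceback failed")
  }
  assign[1] <- j
  list(score = score, assignment = assign)
}

# Emission parameters matching the package's HMM setup, recomputed
# independently from the pore model: per k-mer, the candidate levels
# (canonical plus all analogue variants, enumerated by hand) and the k-mer
# spread.
reference_emissions <- function(ref_seq, pm) {
  n <- nchar(ref_seq)
  kmers <- substring(ref_seq, 1:(n - 5), 6:n)
  cands <- vector("list", length(kmers))
  sd <- numeric(length(kmers))
  for (i in seq_along(kmers)) {
    idx <- forktrace:::kmer_index_one(kmers[i])
    sd[i] <- pm$sd[idx]
    chars <- strsplit(kmers[i], "")[[1]]
    t_at <- which(chars == "T")
    cc <- pm$mean[idx]
    if (length(t_at)) {
      for (mask in 1:(2^length(t_at) - 1)) {
        v <- chars
        sel <- t_at[bitwAnd(mask, 2^(seq_along(t_at) - 1)) > 0]
        v[sel] <- "B"
        vi <- forktrace:::kmer_index_one(paste(v, collapse = ""))
        cc <- c(cc, pm$mean[vi])
      }
    }
    cands[[i]] <- cc
  }
  list(cands = cands, sd = sd)
}

# Brute-force confusion recount from raw (probability, truth) pairs.
confusion_bruteforce <- function(prob, truth, threshold) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(prob)) {
    call <- prob[i] > threshold
    if (call && truth[i]) tp <- tp + 1L
    else if (call && !truth[i]) fp <- fp + 1L
    else if (!call && !truth[i]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Exhaustive nearest-origin scan for one call midpoint.
nearest_origin_bruteforce <- function(mid, origins) {
  best <- Inf
  for (i in seq_len(nrow(origins))) {
    d <- if (mid >= origins$start[i] && mid < origins$end[i]) 0
         else min(abs(mid - origins$start[i]), abs(mid - (origins$end[i] - 1)))
    best <- min(best, d)
  }
  best
}

# Brute-force run merging: positions above threshold, closed over gaps.
runs_bruteforce <- function(positions, p, threshold, gap_tol) {
  hit <- positions[p > threshold]
  if (!length(hit)) return(NULL)
  runs <- list()
  s <- hit[1]; e <- hit[1]
  for (x in hit[-1]) {
    if (x - e <= gap_tol) e <- x
    else { runs[[length(runs) + 1]] <- c(s, e + 1); s <- x; e <- x }
  }
  runs[[length(runs) + 1]] <- c(s, e + 1)
  do.call(rbind, runs)
}
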