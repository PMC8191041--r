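# Shared lightweight fixtures. The pore model is deterministic, so one copy
# serves every test file.
pm_fixture <- default_pore_model()

random_contig <- function(n, seed = 1) {
  forktrace:::with_seed(seed, forktrace:::random_dna(n))
}

# A tiny noise-free "perfect events" setup: one event per k-mer, event mean
# equal to the expected canonical level.
perfect_events <- function(ref_seq, pm, brdu_mask = NULL, dwell = 5L) {
  n_t <- sum(strsplit(ref_seq, "")[[1]] == "T")
  if (is.null(brdu_mask)) brdu_mask <- rep(FALSE, n_t)
  lev <- expected_levels(ref_seq, brdu_mask, pm)
  K <- nrow(lev)
  data.frame(start = (seq_len(K) - 1L) * dwell,
             end = seq_len(K) * dwell,
             duration = dwell,
             mean = lev$mean,
             sd = 0)
}
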