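#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-read generator. Defaults describe
#' the study conditions the rest of the package is trained and evaluated
#' under: an 80% plateau substitution rate (matching the substitution level of
#' the BrdU-rich training material), fork speed 1800 bp/min, a 4-minute
#' analogue pulse for the pulse-chase protocol, and nanopore-like dwell of 8
#' samples per base.
#'
#' @param substitution_rate Fraction of thymidines replaced by BrdU under the
#'   `uniform` protocol, in `[0, 1]`.
#' @param protocol One of `"uniform"`, `"g1_release"`, `"pulse_chase"`,
#'   `"primer_extension"`.
#' @param fork_speed Replication fork speed in bp/min.
#' @param pulse_duration BrdU pulse length in minutes (pulse-chase protocol).
#' @param chase_decay_length Characteristic decay length (bp) of the analogue
#'   gradient along the fork direction after the chase begins.
#' @param noise_sd_scale Multiplier on the pore-model level spread used as the
#'   per-sample Gaussian noise sd; 0 gives noise-free signal.
#' @param dwell_mean Mean dwell per k-mer position in samples (geometric with
#'   minimum 1 sample).
#' @param seed Integer seed; every simulation routine is bit-reproducible
#'   given the same config.
#' @param p_max Plateau substitution probability inside a fork footprint.
#' @param rise_length Length (bp) over which incorporation ramps from 0 to
#'   `p_max` after origin firing (G1-release protocol).
#' @param depletion_length Characteristic length (bp) of the gentle decline
#'   in incorporation along a fork's path as the intracellular BrdU pool
#'   depletes (G1-release protocol); gives every footprint an oriented
#'   gradient.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(substitution_rate = 0,
                       protocol = c("uniform", "g1_release", "pulse_chase", "primer_extension"),
                       fork_speed = 1800,
                       pulse_duration = 4,
                       chase_decay_length = 3000,
                       noise_sd_scale = 1,
                       dwell_mean = 8,
                       seed = 1L,
                       p_max = 0.8,
                       rise_length = 2000,
                       depletion_length = 20000) {
  protocol <- match.arg(protocol)
  if (!is.numeric(substitution_rate) || substitution_rate < 0 || substitution_rate > 1) {
    stopf("substitution_rate must be in [0, 1]")
  }
  if (fork_speed <= 0) stopf("fork_speed must be > 0")
  if (dwell_mean < 1) stopf("dwell_mean must be >= 1")
  if (noise_sd_scale < 0) stopf("noise_sd_scale must be >= 0")
  if (pulse_duration <= 0) stopf("pulse_duration must be > 0")
  if (chase_decay_length <= 0) stopf("chase_decay_length must be > 0")
  if (p_max <= 0 || p_max > 1) stopf("p_max must be in (0, 1]")
  if (depletion_length <= 0) stopf("depletion_length must be > 0")
  structure(list(substitution_rate = substitution_rate, protocol = protocol,
                 fork_speed = fork_speed, pulse_duration = pulse_duration,
                 chase_decay_length = chase_decay_length,
                 noise_sd_scale = noise_sd_scale, dwell_mean = dwell_mean,
                 seed = as.integer(seed), p_max = p_max,
                 rise_length = rise_length,
                 depletion_length = depletion_length),
            class = "sim_config")
}

new_sim_read <- function(read_id, contig, ref_start, ref_end, strand, sequence,
                         signal, t_positions, truth_brdu, truth_dwell = NULL,
                         truth_forks = NULL, truth_origins = NULL,
                         truth_terms = NULL, mapq = 60L) {
  structure(list(read_id = read_id, contig = contig,
                 ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
                 strand = strand, sequence = sequence, signal = signal,
                 t_positions = as.integer(t_positions), truth_brdu = truth_brdu,
                 truth_dwell = truth_dwell, truth_forks = truth_forks,
                 truth_origins = truth_origins, truth_terms = truth_terms,
                 mapq = as.integer(mapq)),
            class = "sim_read")
}

#' @export
print.sim_read <- function(x, ...) {
  cat(sprintf("<sim_read> %s %s:%d-%d(%s) %d bp, %d thymidines (%d BrdU), %d samples\n",
              x$read_id, x$contig, x$ref_start, x$ref_end, x$strand,
              x$ref_end - x$ref_start, length(x$truth_brdu),
              sum(x$truth_brdu), length(x$signal)))
  invisible(x)
}

# Raw-signal synthesis: each k-mer level repeated for a geometric dwell
# (minimum 1 sample) plus Gaussian noise scaled from the level spread.
# Draw order (dwell, then noise) is fixed so seeded runs are reproducible.
synth_signal <- function(levels, config) {
  n <- nrow(levels)
  dwell <- if (config$dwell_mean > 1) {
    1L + rgeom(n, 1 / config$dwell_mean)
  } else {
    rep(1L, n)
  }
  signal <- rep(levels$mean, dwell)
  if (config$noise_sd_scale > 0) {
    signal <- signal + rnorm(length(signal), 0,
                             rep(levels$sd, dwell) * config$noise_sd_scale)
  }
  list(signal = signal, dwell = dwell)
}

sim_read_from_labels <- function(sequence, brdu, config, model, contig,
                                 ref_start, read_id, emit_signal = TRUE, ...) {
  lev <- expected_levels(sequence, brdu, model)
  if (emit_signal) {
    sig <- synth_signal(lev, config)
  } else {
    sig <- list(signal = numeric(0), dwell = NULL)
  }
  codes <- seq_codes(sequence, allow_analogue = FALSE)
  t_pos <- ref_start + which(codes == 3L) - 1L
  new_sim_read(read_id, contig, ref_start, ref_start + nchar(sequence), "+",
               sequence, sig$signal, t_pos, brdu, truth_dwell = sig$dwell, ...)
}

#' Simulate a single read with uniform BrdU-for-thymidine substitution
#'
#' Draws per-thymidine Bernoulli(`substitution_rate`) BrdU labels over the
#' reference window, then synthesises a raw current trace from the pore model
#' (analogue-shifted levels at substituted positions, geometric dwell,
#' Gaussian noise). Runs with the same config are bit-identical.
#'
#' @param contig_seq Reference contig sequence (ACGT string).
#' @param window Integer pair `c(start, end)`, 0-based half-open, within the
#'   contig.
#' @param config A [sim_config()]; the `seed` field fully determines the read.
#' @param model A `pore_model`.
#' @param contig Contig name recorded in the read.
#' @param read_id Read identifier (default derived from the seed).
#' @param emit_signal If `FALSE`, only labels are generated (used by
#'   large-scale label statistics); the signal array is empty.
#' @return A `sim_read`.
#' @export
simulate_read <- function(contig_seq, window, config, model,
                          contig = "sim", read_id = NULL, emit_signal = TRUE) {
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (end - start < 6L) stopf("window shorter than 6 bp")
  if (start < 0L || end > nchar(contig_seq)) stopf("window outside contig")
  sequence <- substr(contig_seq, start + 1L, end)
  read_id <- read_id %||% sprintf("read_u%010d", config$seed)
  with_seed(config$seed, {
    n_t <- sum(seq_codes(sequence, allow_analogue = FALSE) == 3L)
    brdu <- if (config$substitution_rate > 0) {
      rbinom(n_t, 1L, config$substitution_rate) == 1L
    } else {
      rep(FALSE, n_t)
    }
    sim_read_from_labels(sequence, brdu, config, model, contig, start, read_id,
                         emit_signal = emit_signal)
  })
}

#' Simulate a cohort of uniformly substituted reads
#'
#' Convenience wrapper drawing `n_reads` windows of random length over a
#' contig and simulating each with [simulate_read()] under per-read derived
#' seeds.
#'
#' @param contig_seq Reference contig sequence.
#' @param n_reads Number of reads.
#' @param config A [sim_config()] (protocol `uniform`).
#' @param model A `pore_model`.
#' @param length_range Read length range in bp, drawn uniformly.
#' @param contig Contig name.
#' @param id_prefix Prefix for read identifiers.
#' @param emit_signal Passed to [simulate_read()].
#' @return List of `sim_read`.
#' @export
simulate_cohort <- function(contig_seq, n_reads, config, model,
                            length_range = c(5000, 20000), contig = "sim",
                            id_prefix = "read", emit_signal = TRUE) {
  L <- nchar(contig_seq)
  if (max(length_range) > L) stopf("contig shorter than maximum read length")
  windows <- with_seed(config$seed, {
    len <- round(runif(n_reads, length_range[1], length_range[2]))
    start <- floor(runif(n_reads, 0, L - len + 1))
    cbind(start, start + len)
  })
  lapply(seq_len(n_reads), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    simulate_read(contig_seq, windows[i, ], cfg, model, contig = contig,
                  read_id = sprintf("%s_%05d", id_prefix, i),
                  emit_signal = emit_signal)
  })
}

#' The bundled primer-extension construct
#'
#' An 80 bp forward-strand substrate whose thymidines at 1-based positions 30
#' and 36 always carry BrdU while every other position never does, used to
#' probe single-nucleotide resolution of the caller.
#'
#' @return The construct sequence as a character scalar.
#' @export
primer_construct <- function() {
  path <- system.file("extdata", "primer_construct.fa", package = "forktrace")
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

#' Simulate a primer-extension cohort
#'
#' Every read is an independent signal realisation of the fixed construct of
#' [primer_construct()], with BrdU at construct positions 30 and 36 (1-based)
#' and thymidine everywhere else.
#'
#' @param n_reads Number of reads (>= 1).
#' @param config A [sim_config()].
#' @param model A `pore_model`.
#' @return List of `sim_read` on contig `"primer_construct"`.
#' @export
simulate_primer_extension <- function(n_reads, config, model) {
  if (n_reads < 1) stopf("n_reads must be >= 1")
  seqc <- primer_construct()
  codes <- seq_codes(seqc, allow_analogue = FALSE)
  t_pos0 <- which(codes == 3L) - 1L        # 0-based construct coordinates
  brdu_at <- c(29L, 35L)                   # construct positions 30 and 36, 1-based
  if (!all(brdu_at %in% t_pos0)) stopf("construct lacks thymidines at the BrdU positions")
  brdu <- t_pos0 %in% brdu_at
  lapply(seq_len(n_reads), function(i) {
    with_seed(derive_seed(config$seed, i), {
      sim_read_from_labels(seqc, brdu, config, model, "primer_construct", 0L,
                           sprintf("primer_%04d", i))
    })
  })
}

# Local substitution probability at distance d (bp) from the assigned
# origin. G1 release: uptake ramp to the plateau, then a gentle decline as
# the analogue pool depletes, which orients every footprint. Pulse-chase:
# plateau during the pulse, exponential decay along the chase.
fork_substitution_profile <- function(d, config) {
  pulse_len <- config$fork_speed * config$pulse_duration
  switch(config$protocol,
         g1_release = config$p_max * pmin(1, d / config$rise_length) *
           exp(-d / config$depletion_length),
         pulse_chase = ifelse(d <= pulse_len, config$p_max,
                              config$p_max * exp(-(d - pulse_len) / config$chase_decay_length)),
         stopf("protocol '%s' has no fork footprint profile", config$protocol))
}

# How far from its origin a fork's footprint remains observable (and hence
# carries a truth direction label): the whole path under G1 release, the
# pulse plus the detectable part of the chase tail under pulse-chase.
fork_label_reach <- function(config) {
  if (config$protocol == "g1_release") return(Inf)
  round(config$fork_speed * config$pulse_duration +
          config$chase_decay_length * log(10))
}

#' Simulate molecules carrying replication-fork BrdU footprints
#'
#' Each origin fires at the start of the BrdU pulse and launches a
#' leftward-moving and a rightward-moving fork at `fork_speed`; converging
#' forks from adjacent origins stop where they meet (the midpoint, with equal
#' speeds). The local BrdU substitution probability at a position replicated
#' `t` minutes after firing is protocol dependent: under `g1_release` it
#' ramps from 0 to `p_max` over `rise_length` bp and stays at the plateau
#' (the pulse never ends); under `pulse_chase` it is `p_max` while the fork
#' is inside the pulse window and decays exponentially with characteristic
#' length `chase_decay_length` afterwards; under `g1_release` the plateau
#' also declines gently (`depletion_length`) as the analogue pool is
#' consumed, so every footprint carries an oriented gradient. Truth fork
#' labels mark positions where the footprint is observable (the whole path
#' under G1 release; the pulse plus the detectable chase tail under
#' pulse-chase); origin and termination truth intervals (1 kb, centred) are
#' recorded per molecule.
#'
#' Molecules containing no origin are traversed by a single fork entering
#' from a uniformly chosen end when the pulse starts; they carry fork truth
#' but no origin or termination truth.
#'
#' @param contig_seq Reference contig sequence.
#' @param molecule_windows List (or 2-column matrix) of 0-based half-open
#'   `c(start, end)` windows, one per molecule.
#' @param origin_sites Integer positions of replication origins; every origin
#'   must fall inside at least one molecule.
#' @param config A [sim_config()] with protocol `g1_release` or `pulse_chase`.
#' @param model A `pore_model`.
#' @param contig Contig name.
#' @param id_prefix Prefix for read identifiers.
#' @return List of `sim_read` with `truth_forks`, `truth_origins` and
#'   `truth_terms` populated.
#' @export
simulate_fork_footprints <- function(contig_seq, molecule_windows, origin_sites,
                                     config, model, contig = "sim",
                                     id_prefix = "mol") {
  if (!config$protocol %in% c("g1_release", "pulse_chase")) {
    stopf("protocol must be g1_release or pulse_chase")
  }
  if (is.matrix(molecule_windows)) {
    molecule_windows <- lapply(seq_len(nrow(molecule_windows)),
                               function(i) molecule_windows[i, ])
  }
  origin_sites <- sort(as.integer(origin_sites))
  covered <- vapply(origin_sites, function(o) {
    any(vapply(molecule_windows, function(w) o >= w[1] && o < w[2], logical(1)))
  }, logical(1))
  if (any(!covered)) {
    stopf("origin(s) outside every molecule: %s",
          paste(origin_sites[!covered], collapse = ", "))
  }
  pulse_len <- config$fork_speed * config$pulse_duration
  lapply(seq_along(molecule_windows), function(i) {
    w <- as.integer(molecule_windows[[i]])
    s <- w[1]; e <- w[2]
    if (e - s < 6L) stopf("molecule window shorter than 6 bp")
    with_seed(derive_seed(config$seed, i), {
      ori <- origin_sites[origin_sites >= s & origin_sites < e]
      passthrough <- length(ori) == 0L
      if (passthrough) {
        # single fork entering from a random end at pulse start
        from_left <- runif(1) < 0.5
        ori_eff <- if (from_left) s else e - 1L
      } else {
        ori_eff <- ori
      }
      pos <- s:(e - 1L)
      # assign each position to the nearest firing origin (segment boundaries
      # halfway between adjacent origins = where converging forks meet)
      if (length(ori_eff) == 1L) {
        assign_idx <- rep(1L, length(pos))
      } else {
        bounds <- floor((head(ori_eff, -1) + tail(ori_eff, -1)) / 2)
        assign_idx <- findInterval(pos, bounds + 1L) + 1L
      }
      o_of <- ori_eff[assign_idx]
      d <- abs(pos - o_of)
      p_sub <- fork_substitution_profile(d, config)
      sequence <- substr(contig_seq, s + 1L, e)
      codes <- seq_codes(sequence, allow_analogue = FALSE)
      t_rel <- which(codes == 3L)
      brdu <- rbinom(length(t_rel), 1L, p_sub[t_rel]) == 1L
      # truth fork intervals: fork passage during the pulse only
      reach <- fork_label_reach(config)
      left_iv <- NULL; right_iv <- NULL
      if (passthrough) {
        if (from_left) {
          right_iv <- rbind(right_iv, c(s, min(e, s + reach)))
        } else {
          left_iv <- rbind(left_iv, c(max(s, e - reach), e))
        }
        truth_origins <- matrix(numeric(0), 0, 2)
        truth_terms <- matrix(numeric(0), 0, 2)
      } else {
        segs <- if (length(ori_eff) == 1L) {
          cbind(s, e)
        } else {
          bounds <- floor((head(ori_eff, -1) + tail(ori_eff, -1)) / 2)
          cbind(c(s, bounds + 1L), c(bounds + 1L, e))
        }
        for (j in seq_along(ori_eff)) {
          o <- ori_eff[j]
          lo <- max(segs[j, 1], o - reach)
          hi <- min(segs[j, 2], o + 1L + reach)
          if (o > lo) left_iv <- rbind(left_iv, c(lo, o))
          if (hi > o + 1L) right_iv <- rbind(right_iv, c(o + 1L, hi))
        }
        half <- 500L
        truth_origins <- cbind(pmax(s, ori_eff - half), pmin(e, ori_eff + half))
        if (length(ori_eff) >= 2L) {
          mids <- floor((head(ori_eff, -1) + tail(ori_eff, -1)) / 2)
          truth_terms <- cbind(pmax(s, mids - half), pmin(e, mids + half))
        } else {
          truth_terms <- matrix(numeric(0), 0, 2)
        }
      }
      truth_forks <- list(left = left_iv %||% matrix(numeric(0), 0, 2),
                          right = right_iv %||% matrix(numeric(0), 0, 2))
      sim_read_from_labels(sequence, brdu, config, model, contig, s,
                           sprintf("%s_%05d", id_prefix, i),
                           truth_forks = truth_forks,
                           truth_origins = truth_origins,
                           truth_terms = truth_terms)
    })
  })
}

#' Per-position truth fork-direction labels
#'
#' Projects a simulated molecule's truth fork intervals onto a set of
#' reference positions (typically the thymidine positions of a detect
#' record).
#'
#' @param sim_read A `sim_read` from [simulate_fork_footprints()].
#' @param positions Integer reference positions (0-based).
#' @return Character vector over `"left"`, `"right"`, `"none"`.
#' @export
truth_fork_labels <- function(sim_read, positions) {
  lab <- rep("none", length(positions))
  in_iv <- function(iv) {
    hit <- rep(FALSE, length(positions))
    if (nrow(iv)) for (j in seq_len(nrow(iv))) {
      hit <- hit | (positions >= iv[j, 1] & positions < iv[j, 2])
    }
    hit
  }
  if (!is.null(sim_read$truth_forks)) {
    lab[in_iv(sim_read$truth_forks$left)] <- "left"
    lab[in_iv(sim_read$truth_forks$right)] <- "right"
  }
  lab
}
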