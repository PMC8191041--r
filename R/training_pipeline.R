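#' Standard training recipes
#'
#' End-to-end recipes tying the simulator, the signal-alignment stage and
#' the two networks together under fixed seeds: the detection network is
#' trained on unsubstituted and 80%-substituted cohorts, the fork-sense
#' network on G1-release and pulse-chase fork cohorts (plus origin-free
#' molecules). These are the exact procedures the package's evaluation and
#' worked examples use.
#'
#' @name training_recipes
NULL

#' Tensors + labels for detection training from simulated reads
#'
#' Runs the signal-alignment pipeline on each read and keeps a random
#' subsample of thymidine tensors per read (training does not need every
#' thymidine of every read; subsampling keeps memory and time proportional
#' to the cohort size).
#'
#' @param reads List of `sim_read`.
#' @param pore_model A `pore_model`.
#' @param tensors_per_read Maximum tensors kept per read.
#' @param seed Subsampling seed.
#' @param window_W,band_width Pipeline controls.
#' @return List `x` (tensor array), `y` (integer labels, 1 = BrdU),
#'   `n_failed`.
#' @export
detect_training_tensors <- function(reads, pore_model, tensors_per_read = 30L,
                                    seed = 1L, window_W = 15L,
                                    band_width = NULL) {
  xs <- list(); ys <- list(); failed <- 0L
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    tb <- read_tensors(rd$signal, rd$sequence, rd$t_positions, pore_model,
                       window_W = window_W, ref_start = rd$ref_start,
                       band_width = band_width)
    if (is.null(tb) || length(tb$positions) == 0L) { failed <- failed + 1L; next }
    lab <- rd$truth_brdu[match(tb$positions, rd$t_positions)]
    keep <- with_seed(derive_seed(seed, i), {
      sample.int(length(tb$positions), min(tensors_per_read, length(tb$positions)))
    })
    xs[[length(xs) + 1L]] <- tb$x[keep, , , drop = FALSE]
    ys[[length(ys) + 1L]] <- as.integer(lab[keep])
  }
  if (!length(xs)) stopf("no usable reads for training")
  n <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  x <- array(0, c(n, window_W, N_TENSOR_FEATURES))
  at <- 1L
  for (a in xs) {
    k <- dim(a)[1]
    x[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  list(x = x, y = unlist(ys), n_failed = failed)
}

#' Simulate the standard 0% / 80% detection training material
#'
#' @param n_reads Total reads (half unsubstituted, half 80%-substituted).
#' @param seed Cohort seed.
#' @param pore_model A `pore_model`.
#' @param contig_length Length of the random reference contig.
#' @param length_range Read length range in bp.
#' @return List `reads`, `contig_seq`.
#' @export
simulate_detect_training_cohort <- function(n_reads = 2000L, seed = 1L,
                                            pore_model = default_pore_model(),
                                            contig_length = 50000L,
                                            length_range = c(5000, 12000)) {
  contig_seq <- with_seed(derive_seed(seed, 0L), random_dna(contig_length))
  half <- n_reads %/% 2L
  r0 <- simulate_cohort(contig_seq, half,
                        sim_config(substitution_rate = 0, seed = derive_seed(seed, 101L)),
                        pore_model, length_range = length_range,
                        id_prefix = "t0")
  r80 <- simulate_cohort(contig_seq, n_reads - half,
                         sim_config(substitution_rate = 0.8, seed = derive_seed(seed, 202L)),
                         pore_model, length_range = length_range,
                         id_prefix = "t80")
  list(reads = c(r0, r80), contig_seq = contig_seq)
}

#' Train the detection network on the standard simulated cohorts
#'
#' @param n_reads Training cohort size.
#' @param seed Master seed (cohort, subsampling, initialisation, data
#'   order).
#' @param pore_model A `pore_model`.
#' @param epochs,tensors_per_read Training scale controls.
#' @param verbose Print progress.
#' @return A trained `detect_model`.
#' @export
train_detect_standard <- function(n_reads = 2000L, seed = 1L,
                                  pore_model = default_pore_model(),
                                  epochs = 8L, tensors_per_read = 24L,
                                  verbose = FALSE) {
  # reads are simulated and tensorised in chunks so raw signal never
  # accumulates in memory; each chunk draws a fresh reference contig so the
  # network sees diverse sequence context instead of memorising one contig
  chunk_size <- 250L
  n_half <- n_reads %/% 2L
  plan <- list(list(n = n_half, rate = 0, tag = "t0", sub_seed = 101L),
               list(n = n_reads - n_half, rate = 0.8, tag = "t80", sub_seed = 202L))
  xs <- list(); ys <- list()
  for (p in plan) {
    done <- 0L; ci <- 0L
    while (done < p$n) {
      ci <- ci + 1L
      n_now <- min(chunk_size, p$n - done)
      cfg <- sim_config(substitution_rate = p$rate,
                        seed = derive_seed(derive_seed(seed, p$sub_seed), ci))
      contig_seq <- with_seed(derive_seed(seed, 7L * p$sub_seed + ci),
                              random_dna(50000L))
      reads <- simulate_cohort(contig_seq, n_now, cfg, pore_model,
                               length_range = c(3000, 7000),
                               id_prefix = sprintf("%s_c%02d", p$tag, ci))
      td <- detect_training_tensors(reads, pore_model,
                                    tensors_per_read = tensors_per_read,
                                    seed = derive_seed(seed, 303L + ci))
      xs[[length(xs) + 1L]] <- td$x
      ys[[length(ys) + 1L]] <- td$y
      rm(reads, td)
      done <- done + n_now
    }
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  W <- dim(xs[[1]])[2]
  x <- array(0, c(n, W, N_TENSOR_FEATURES))
  at <- 1L
  for (i in seq_along(xs)) {
    k <- dim(xs[[i]])[1]
    x[at:(at + k - 1L), , ] <- xs[[i]]
    xs[[i]] <- 0
    at <- at + k
  }
  y <- unlist(ys)
  model <- build_detect_model(seed = derive_seed(seed, 404L))
  train_detect(model, x, y, epochs = epochs, batch_size = 512L,
               seed = derive_seed(seed, 505L), verbose = verbose)
}

#' Simulate a standard fork cohort (both protocols + origin-free molecules)
#'
#' Molecules are 50 kb with three origins 15 kb apart; a fraction of
#' molecules carry no origin and are traversed by a single fork.
#'
#' @param n_molecules Molecules per protocol.
#' @param seed Cohort seed.
#' @param pore_model A `pore_model`.
#' @param protocols Protocols to simulate.
#' @param origin_free_fraction Fraction of origin-free molecules.
#' @param molecule_length,origin_spacing Geometry in bp.
#' @return List `reads` (all molecules), `contig_seq`.
#' @export
simulate_fork_cohort <- function(n_molecules = 100L, seed = 1L,
                                 pore_model = default_pore_model(),
                                 protocols = c("g1_release", "pulse_chase"),
                                 origin_free_fraction = 0.2,
                                 molecule_length = 50000L,
                                 origin_spacing = 15000L) {
  contig_len <- as.integer(molecule_length + 10000L)
  contig_seq <- with_seed(derive_seed(seed, 0L), random_dna(contig_len))
  n_free <- round(n_molecules * origin_free_fraction)
  n_ori <- n_molecules - n_free
  reads <- list()
  for (pi in seq_along(protocols)) {
    proto <- protocols[pi]
    offs <- with_seed(derive_seed(seed, 1000L + pi), {
      floor(runif(n_molecules, 0, contig_len - molecule_length))
    })
    # origin-bearing molecules: three origins 15 kb apart around the centre
    if (n_ori > 0L) {
      windows <- lapply(seq_len(n_ori), function(i) {
        c(offs[i], offs[i] + molecule_length)
      })
      origins <- unlist(lapply(seq_len(n_ori), function(i) {
        centre <- offs[i] + molecule_length / 2
        round(centre + c(-1, 0, 1) * origin_spacing)
      }))
      cfg <- sim_config(protocol = proto, seed = derive_seed(seed, 2000L + pi))
      # simulate each molecule with its own origins so molecules stay independent
      for (i in seq_len(n_ori)) {
        ors <- origins[(3L * i - 2L):(3L * i)]
        cfg_i <- cfg
        cfg_i$seed <- derive_seed(cfg$seed, i)
        rd <- simulate_fork_footprints(contig_seq, list(windows[[i]]), ors,
                                       cfg_i, pore_model,
                                       id_prefix = sprintf("%s_ori%03d", proto, i))[[1]]
        reads[[length(reads) + 1L]] <- rd
      }
    }
    if (n_free > 0L) {
      cfg <- sim_config(protocol = proto, seed = derive_seed(seed, 3000L + pi))
      for (i in seq_len(n_free)) {
        w <- c(offs[n_ori + i], offs[n_ori + i] + molecule_length)
        cfg_i <- cfg
        cfg_i$seed <- derive_seed(cfg$seed, i)
        rd <- simulate_fork_footprints(contig_seq, list(w), integer(0), cfg_i,
                                       pore_model,
                                       id_prefix = sprintf("%s_free%03d", proto, i))[[1]]
        reads[[length(reads) + 1L]] <- rd
      }
    }
  }
  list(reads = reads, contig_seq = contig_seq)
}

#' Train the fork-sense network on a standard simulated fork cohort
#'
#' The cohort is processed end-to-end (detection network included) so the
#' fork-sense network trains on realistic BrdU probability tracks.
#'
#' @param detect_model A trained `detect_model`.
#' @param n_molecules Training molecules per protocol (each cohort also
#'   includes its origin-free fraction).
#' @param seed Master seed.
#' @param pore_model A `pore_model`.
#' @param epochs Training epochs.
#' @param geometry Per-protocol `c(molecule_length, origin_spacing)`, see
#'   [fork_cohort_geometry()].
#' @param verbose Print progress.
#' @return List `model` (trained `forksense_model`), `records`, `reads`.
#' @export
train_forksense_standard <- function(detect_model, n_molecules = 40L, seed = 1L,
                                     pore_model = default_pore_model(),
                                     epochs = 25L,
                                     geometry = fork_cohort_geometry(),
                                     verbose = FALSE) {
  reads <- list()
  for (proto in names(geometry)) {
    g <- geometry[[proto]]
    cohort <- simulate_fork_cohort(n_molecules,
                                   seed = derive_seed(seed, 11L + nchar(proto)),
                                   pore_model = pore_model, protocols = proto,
                                   molecule_length = g[1], origin_spacing = g[2])
    reads <- c(reads, cohort$reads)
  }
  det <- detect_sim_reads(detect_model, reads, pore_model)
  sim_by_id <- stats::setNames(reads,
                               vapply(reads, function(r) r$read_id, character(1)))
  labels <- lapply(det$records, function(rec) {
    truth_fork_labels(sim_by_id[[rec$read_id]], rec$rows$position)
  })
  model <- build_forksense_model(seed = derive_seed(seed, 22L))
  model <- train_forksense(model, det$records, labels, epochs = epochs,
                           seed = derive_seed(seed, 33L), verbose = verbose)
  list(model = model, records = det$records, reads = reads)
}

#' Default fork-cohort geometry per protocol
#'
#' Origin spacing must respect the footprint scale of each protocol: under
#' pulse-chase the 4-minute pulse at 1800 bp/min covers 7.2 kb per fork, so
#' origins closer than ~2x (pulse + visible chase tail) replicate the whole
#' span during the pulse and leave no orienting gradient; G1-release
#' footprints carry the pool-depletion gradient everywhere and can be
#' compact.
#'
#' @return Named list of `c(molecule_length, origin_spacing)` in bp.
#' @export
fork_cohort_geometry <- function() {
  list(g1_release = c(26000L, 8000L),
       pulse_chase = c(48000L, 19000L))
}

#' Train and checkpoint the detection network
#' @param out_model Checkpoint path.
#' @param n_reads,seed,epochs As in [train_detect_standard()].
#' @return The checkpoint path, invisibly.
#' @export
cmd_train_detect <- function(out_model, n_reads = 2000L, seed = 1L,
                             epochs = 30L) {
  model <- train_detect_standard(n_reads = n_reads, seed = seed,
                                 epochs = epochs)
  save_model(model, out_model)
  write_manifest(dirname(out_model), "train-detect",
                 list(n_reads = n_reads, seed = seed, epochs = epochs))
  invisible(out_model)
}

#' Train and checkpoint the fork-sense network
#' @param detect_model_path Trained detect checkpoint.
#' @param out_model Checkpoint path.
#' @param n_molecules,seed,epochs As in [train_forksense_standard()].
#' @return The checkpoint path, invisibly.
#' @export
cmd_train_forksense <- function(detect_model_path, out_model,
                                n_molecules = 60L, seed = 1L, epochs = 20L) {
  dm <- load_model(detect_model_path)
  res <- train_forksense_standard(dm, n_molecules = n_molecules, seed = seed,
                                  epochs = epochs)
  save_model(res$model, out_model)
  write_manifest(dirname(out_model), "train-forksense",
                 list(n_molecules = n_molecules, seed = seed, epochs = epochs))
  invisible(out_model)
}
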