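#' Coupling specification for a synthetic multichannel recording
#'
#' Describes one subject's ground truth: a spanning tree of phase-coupled
#' narrowband oscillators. Coupled neighbours attract each other's phase with
#' a fixed nonzero lag, so downstream phase-lag-index estimation sees a
#' consistent signed phase relation along every tree edge. Zero-lag
#' interactions are deliberately *not* part of the source model — those enter
#' only through the instantaneous mixing of [apply_volume_conduction()].
#'
#' @param n_channels number of channels (>= 2).
#' @param tree_edges two-column matrix of 1-based channel index pairs forming
#'   a spanning tree (`n_channels - 1` rows).
#' @param coupling_strength dimensionless in `[0, 1]`; 0 = independent sources.
#' @param phase_lag radians, not 0 or pi (PLI is blind there). Default pi/3:
#'   lags accumulated over k tree edges, k*pi/3 mod 2pi, stay a full pi/3
#'   away from the blind points 0 and pi (or land exactly on them), so the
#'   expected PLI is strictly largest on true edges and decays with tree
#'   distance as phase jitter accumulates.
#' @param carrier_band numeric length-2, oscillator frequency interval in Hz.
#' @param noise_sd additive white measurement-noise SD in signal units
#'   (oscillator amplitude is 1).
#' @param phase_noise_sd per-sample phase-diffusion SD in radians. This is
#'   what makes synchronization imperfect: the phase offset along an edge
#'   fluctuates around `phase_lag`, and the fluctuation accumulates with
#'   tree distance, so PLI decays away from the true edges instead of
#'   saturating at 1 across the whole locked network.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_channels, tree_edges,
                          coupling_strength = 0.9,
                          phase_lag = pi / 3,
                          carrier_band = c(16, 24),
                          noise_sd = 0.1,
                          phase_noise_sd = 0.25) {
  tree <- spanning_tree(tree_edges, n_channels)  # validates connected/acyclic
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  lag_mod <- phase_lag %% (2 * pi)
  if (isTRUE(all.equal(lag_mod, 0)) || isTRUE(all.equal(lag_mod, pi)) ||
      isTRUE(all.equal(lag_mod, 2 * pi)))
    stop("phase_lag must not be 0 or pi: PLI cannot see those lags")
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1])
    stop("carrier_band must be an increasing positive frequency interval")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (phase_noise_sd < 0) stop("phase_noise_sd must be nonnegative")
  structure(list(n_channels = as.integer(n_channels), tree = tree,
                 coupling_strength = coupling_strength, phase_lag = phase_lag,
                 carrier_band = carrier_band, noise_sd = noise_sd,
                 phase_noise_sd = phase_noise_sd),
            class = "coupling_spec")
}

#' Spanning tree interpolating between a star and a path
#'
#' `shift = 0` returns the star with hub 1; `shift = 1` the path
#' `1-2-...-n`. Intermediate shifts detach the fraction `shift` of the star's
#' re-chainable leaves (the highest-indexed ones) and re-chain them in index
#' order, so the family moves monotonically from a centralized toward a
#' decentralized (line-like) topology. Deterministic: the seed is accepted
#' for interface symmetry but the construction is purely index-based.
#'
#' @param n_channels number of nodes (>= 3).
#' @param shift interpolation position in `[0, 1]`.
#' @param seed unused (construction is deterministic); kept so callers can
#'   treat all generator entry points uniformly.
#' @return Two-column integer edge matrix of the `n_channels - 1` tree edges.
#' @export
make_interpolated_tree <- function(n_channels, shift, seed = NULL) {
  n <- as.integer(n_channels)
  if (n < 3L) stop("need at least 3 channels to interpolate star -> path")
  if (shift < 0 || shift > 1) stop("shift must lie in [0, 1]")
  # star: hub 1, leaves 2..n.  Re-chain the last k leaves: node m attaches to
  # m - 1 instead of the hub.  k = n - 2 turns the star into the full path.
  k <- as.integer(round(shift * (n - 2L)))
  parent <- if (k == 0L) rep.int(1L, n - 1L)
            else c(rep.int(1L, n - 1L - k), (n - k):(n - 1L))
  cbind(parent, 2:n, deparse.level = 0)
}

#' Synthesize one multichannel recording from a coupling specification
#'
#' Source model: each channel is a unit-amplitude oscillator
#' `cos(theta_i(t))` whose instantaneous frequency wanders inside the carrier
#' band (AR(1) drift around a channel-specific centre frequency), plus white
#' measurement noise. Along every tree edge the two phases are pulled
#' diffusively toward an offset of `phase_lag` (the node nearer the tree root,
#' channel 1, leads), so coupled pairs lock with a consistent signed lag while
#' uncoupled pairs drift freely — PLI values land strictly inside (0, 1) as in
#' real EEG.
#'
#' @param spec a [coupling_spec()].
#' @param n_samples samples to emit (after an internal 256-sample burn-in).
#' @param fs sampling rate in Hz; must exceed twice the carrier band's top.
#' @param seed integer RNG seed.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(spec, n_samples, fs, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (fs <= 2 * spec$carrier_band[2])
    stop(sprintf("fs = %g Hz violates Nyquist for carrier band top %g Hz",
                 fs, spec$carrier_band[2]))
  n <- spec$n_channels
  burn <- 256L
  total <- n_samples + burn
  withr_seed <- set_local_seed(seed)
  on.exit(withr_seed())

  # centre frequencies in the central half of the carrier band: keeps the
  # wandering instantaneous frequency inside the band and the pairwise
  # detuning within the pull range of the coupling
  bw <- diff(spec$carrier_band)
  f0 <- stats::runif(n, spec$carrier_band[1] + 0.25 * bw,
                     spec$carrier_band[2] - 0.25 * bw)
  # AR(1) frequency wander: stationary SD 5% of the carrier bandwidth
  rho <- 0.99
  wsd <- 0.05 * bw * sqrt(1 - rho^2)
  # orient the tree away from the root so every edge has a leader
  adj <- tree_adjacency_list(spec$tree)
  parent <- rep.int(0L, n)
  order_ <- integer(n); order_[1L] <- 1L
  seen <- rep.int(FALSE, n); seen[1L] <- TRUE
  head_ <- 1L; len <- 1L
  while (head_ <= len) {
    v <- order_[head_]; head_ <- head_ + 1L
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; len <- len + 1L; order_[len] <- w; parent[w] <- v
    }
  }
  child <- which(parent > 0L)
  par <- parent[child]
  K <- spec$coupling_strength * 0.5   # max phase pull, rad/sample
  lag <- spec$phase_lag
  # degree-normalized pulls (Kuramoto convention): a hub is steered by the
  # mean of its neighbours' demands, not their sum, so high-degree nodes
  # stay numerically and dynamically stable
  deg <- tree_degrees(spec$tree)

  theta0 <- stats::runif(n, -pi, pi)
  wander0 <- stats::runif(n, -0.05 * bw, 0.05 * bw)
  noise_steps <- matrix(stats::rnorm((total - 1L) * n, sd = wsd), n, total - 1L)
  # AR(1) wander unrolled in one recursive pass (channels as columns)
  wander <- stats::filter(t(noise_steps), rho, method = "recursive",
                          init = matrix(wander0, 1L, n))
  attributes(wander) <- list(dim = dim(wander))   # drop ts attributes
  wander <- t(wander)
  det_step <- 2 * pi * (f0 + wander) / fs
  if (spec$phase_noise_sd > 0)
    det_step <- det_step +
      matrix(stats::rnorm((total - 1L) * n, sd = spec$phase_noise_sd), n, total - 1L)
  # child is pulled to lag the parent; the parent feels the opposite pull
  theta <- evolve_phases_cpp(theta0, det_step,
                             child - 1L, par - 1L,
                             K / deg[child], K / deg[par], lag)
  x <- cos(theta[, (burn + 1L):total, drop = FALSE])
  if (spec$noise_sd > 0)
    x <- x + matrix(stats::rnorm(n * n_samples, sd = spec$noise_sd), n, n_samples)
  eeg_recording(x, fs = fs)
}

#' Exponential volume-conduction mixing matrix
#'
#' Instantaneous leakage falling off exponentially with channel-index
#' distance: `M[i,j] = exp(-|i-j| / spread)`, identity when `spread = 0`. A
#' geometry-free surrogate for field spread: real (zero-lag) gains only, so
#' a phase-lag-based connectivity measure should be unaffected.
#'
#' @param n_channels matrix dimension.
#' @param spread leakage scale in channel-index units (>= 0).
#' @return `n_channels` x `n_channels` mixing matrix.
#' @export
exponential_mixing <- function(n_channels, spread = 0.5) {
  if (spread < 0) stop("spread must be nonnegative")
  if (spread == 0) return(diag(n_channels))
  d <- abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  exp(-d / spread)
}

#' Apply instantaneous (zero-lag) mixing to a recording
#'
#' Every output sample is a linear combination of the same-time input
#' samples: `data_out = mixing %*% data_in`. No temporal mixing, so any phase
#' relations it creates are exactly 0 or pi — the regime PLI discards.
#'
#' @param recording an [eeg_recording()].
#' @param mixing square numeric matrix, `n_channels` x `n_channels`, with
#'   nonnegative entries and a dominant diagonal.
#' @return The mixed [eeg_recording()].
#' @export
apply_volume_conduction <- function(recording, mixing) {
  stopifnot(inherits(recording, "eeg_recording"))
  mixing <- as.matrix(mixing)
  n <- nrow(recording$data)
  if (!all(dim(mixing) == c(n, n)))
    stop(sprintf("mixing must be %d x %d, got %d x %d",
                 n, n, nrow(mixing), ncol(mixing)))
  if (any(mixing < 0)) stop("mixing gains must be nonnegative")
  if (any(diag(mixing) < apply(mixing, 1L, max)))
    stop("mixing must be diagonally dominant (diagonal is each row's maximum)")
  recording$data <- mixing %*% recording$data
  rownames(recording$data) <- recording$labels
  recording
}

#' Cohort specification
#'
#' Study-level ground truth for a two-group synthetic cohort: controls share
#' a near-star coupling topology; each patient's topology is shifted toward a
#' path in proportion to a disability covariate (`48 - ALSFRS-R`, integers),
#' `shift = patient_shift + disability_slope * disability / 48`, clipped to
#' `[0, 1]`. Defaults mirror the emulated study: 21 patients vs 16 controls,
#' 61 channels at 256 Hz, recordings long enough for 4 epochs of 2048
#' samples, beta-band carrier oscillators.
#'
#' @param n_patients,n_controls group sizes (> 0).
#' @param n_channels channels per recording.
#' @param fs sampling rate in Hz.
#' @param n_epochs,epoch_length sizing of the emitted recordings
#'   (`n_epochs * epoch_length` samples each).
#' @param control_shift star-to-path position of the control topology.
#' @param patient_shift base star-to-path position of patient topologies.
#' @param disability_slope added topology shift per unit of `disability / 48`.
#' @param disability_range integer range the patients' disability scores are
#'   drawn from (uniform), within `1..48`; controls score 0.
#' @param coupling_strength,phase_lag,carrier_band,noise_sd,phase_noise_sd
#'   passed to [coupling_spec()].
#' @param mixing_spread volume-conduction leakage scale
#'   ([exponential_mixing()]); 0 disables mixing.
#' @param seed integer master seed; the cohort is a deterministic function of
#'   the full specification.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 21L, n_controls = 16L,
                        n_channels = 61L, fs = 256,
                        n_epochs = 4L, epoch_length = 2048L,
                        control_shift = 0.1,
                        patient_shift = 0.3,
                        disability_slope = 0.6,
                        disability_range = c(4L, 40L),
                        coupling_strength = 0.9,
                        phase_lag = pi / 3,
                        carrier_band = c(16, 24),
                        noise_sd = 0.1,
                        phase_noise_sd = 0.25,
                        mixing_spread = 0.5,
                        seed = 1L) {
  if (n_patients < 1L || n_controls < 1L) stop("group sizes must be positive")
  if (disability_range[1] < 1L || disability_range[2] > 48L ||
      disability_range[2] < disability_range[1])
    stop("disability_range must be an increasing integer range within 1..48")
  structure(as.list(environment()), class = "cohort_spec")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic two-group cohort
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `eeg_cohort`: `subjects` (each with `subject_id`,
#'   `group`, `disability`, `shift`, and an [eeg_recording()]) and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  restore <- set_local_seed(spec$seed)
  on.exit(restore())
  n_sub <- spec$n_patients + spec$n_controls
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)
  disability <- c(sample(spec$disability_range[1]:spec$disability_range[2],
                         spec$n_patients, replace = TRUE),
                  rep.int(0L, spec$n_controls))
  group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  shift <- ifelse(group == "patient",
                  clip01(spec$patient_shift +
                           spec$disability_slope * disability / 48),
                  clip01(spec$control_shift))
  n_samples <- spec$n_epochs * spec$epoch_length
  mixing <- if (spec$mixing_spread > 0)
    exponential_mixing(spec$n_channels, spec$mixing_spread) else NULL
  subjects <- lapply(seq_len(n_sub), function(i) {
    edges <- make_interpolated_tree(spec$n_channels, shift[i])
    cs <- coupling_spec(spec$n_channels, edges,
                        coupling_strength = spec$coupling_strength,
                        phase_lag = spec$phase_lag,
                        carrier_band = spec$carrier_band,
                        noise_sd = spec$noise_sd,
                        phase_noise_sd = spec$phase_noise_sd)
    rec <- generate_recording(cs, n_samples, spec$fs, seed = sub_seeds[i])
    if (!is.null(mixing)) rec <- apply_volume_conduction(rec, mixing)
    list(subject_id = sprintf("S%03d", i), group = group[i],
         disability = disability[i], shift = shift[i],
         tree_edges = edges, recording = rec)
  })
  structure(list(subjects = subjects, spec = spec), class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("<eeg_cohort> %d patients + %d controls, %d channels @ %g Hz\n",
              sum(g == "patient"), sum(g == "control"),
              x$spec$n_channels, x$spec$fs))
  invisible(x)
}

#' Write a cohort to disk as delimited text plus a manifest
#'
#' One recording file per subject (see [write_recording_txt()]) and a
#' tab-separated manifest with columns `subject_id`, `group`, `disability`,
#' `path`.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ".tsv"))
    write_recording_txt(s$recording, path)
    data.frame(subject_id = s$subject_id, group = s$group,
               disability = s$disability, path = path)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest and its recordings
#'
#' @param manifest_path path to a manifest written by [write_cohort()] (or
#'   hand-built to the same schema: `subject_id`, `group`, `disability`,
#'   `path`).
#' @param bad_channels,reference_exclusions applied to every recording.
#' @return An `eeg_cohort` (without a generator `spec`).
#' @export
read_cohort_manifest <- function(manifest_path, bad_channels = character(),
                                 reference_exclusions = character()) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "disability", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(man$path[i]))
    list(subject_id = man$subject_id[i], group = man$group[i],
         disability = man$disability[i],
         recording = read_recording_txt(p, bad_channels = bad_channels,
                                        reference_exclusions = reference_exclusions))
  })
  structure(list(subjects = subjects, spec = NULL), class = "eeg_cohort")
}

# Scoped seeding that restores the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
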