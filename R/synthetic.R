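#' Specification of one coupled narrowband oscillator pair
#'
#' The source model is a phase-coupled narrowband process: each signal is a
#' mixture of a shared band-limited component (rotated by a fixed phase lag
#' for the second signal) and an independent band-limited component, plus
#' white measurement noise. The shared-component variance fraction
#' (`coupling`) maps monotonically onto the downstream phase lag index.
#'
#' @param band Carrier band `c(low, high)` in Hz; must lie inside one of the
#'   six analysis bands (see [freq_bands()]).
#' @param lag Pairwise phase lag in radians.
#' @param coupling Shared phase-locked component fraction in `[0, 1]`.
#' @param noise_sd Standard deviation of additive white noise (>= 0).
#' @return A list of class `oscillator_spec`.
#' @export
oscillator_spec <- function(band = c(8, 10), lag = pi / 2, coupling = 0.5,
                            noise_sd = 1) {
  if (length(band) != 2 || band[1] >= band[2]) abort("`band` must be c(low, high)")
  bands <- freq_bands()
  inside <- any(band[1] >= bands$low & band[2] <= bands$high)
  if (!inside) {
    abort("carrier band must lie inside one of the six analysis bands")
  }
  if (coupling < 0 || coupling > 1) abort("`coupling` must be in [0, 1]")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(band = band, lag = lag, coupling = coupling,
                 noise_sd = noise_sd),
            class = "oscillator_spec")
}

# Band-limited complex analytic noise: i.i.d. complex Gaussian coefficients on
# the strictly positive frequency bins inside [low, high], zero elsewhere.
# The real part is the narrowband signal (normalized to unit variance); the
# one-sided spectrum makes exact phase rotation (z * exp(-i*lag)) available.
narrowband_component <- function(n, rate, low, high) {
  k <- seq_len(floor((n - 1) / 2))
  f <- k * rate / n
  sel <- which(f >= low & f <= high)
  if (length(sel) < 2) {
    abort("recording too short to resolve the carrier band")
  }
  Z <- complex(length.out = n)
  Z[sel + 1] <- complex(real = rnorm(length(sel)),
                        imaginary = rnorm(length(sel)))
  z <- fft(Z, inverse = TRUE)
  z / sd(Re(z))
}

#' Generate a pair of phase-coupled narrowband signals
#'
#' With `coupling = 1` and `noise_sd = 0` the instantaneous phase difference
#' equals `lag` at every sample (total phase locking); with `coupling = 0`
#' the two signals are independent and the downstream PLI tends to its
#' finite-sample null floor.
#'
#' @param spec An [oscillator_spec()].
#' @param n_samples Number of samples (> 0).
#' @param rate Sampling rate in Hz; must exceed twice the carrier's upper
#'   edge.
#' @param seed Integer seed; the pair is a deterministic function of
#'   `(spec, n_samples, rate, seed)`.
#' @return A [roi_ts()] with channels `"A"` and `"B"`.
#' @export
generate_coupled_pair <- function(spec, n_samples, rate, seed = 1) {
  stopifnot(inherits(spec, "oscillator_spec"))
  if (n_samples <= 0) abort("`n_samples` must be positive")
  if (rate <= 2 * spec$band[2]) {
    abort(sprintf("rate %g Hz too low for carrier band up to %g Hz (need > %g)",
                  rate, spec$band[2], 2 * spec$band[2]))
  }
  set.seed(seed)
  cpl <- spec$coupling
  zc <- narrowband_component(n_samples, rate, spec$band[1], spec$band[2])
  xa <- Re(narrowband_component(n_samples, rate, spec$band[1], spec$band[2]))
  xb <- Re(narrowband_component(n_samples, rate, spec$band[1], spec$band[2]))
  a <- sqrt(cpl) * Re(zc) + sqrt(1 - cpl) * xa +
    spec$noise_sd * rnorm(n_samples)
  b <- sqrt(cpl) * Re(zc * exp(-1i * spec$lag)) + sqrt(1 - cpl) * xb +
    spec$noise_sd * rnorm(n_samples)
  roi_ts(rbind(a, b), c("A", "B"), rate)
}

#' Apply an instantaneous (zero-lag) mixing matrix
#'
#' Volume-conduction surrogate: output sample `t` is `M %*% input sample t`,
#' with no temporal shift. The identity matrix reproduces the input
#' bit-identically. Because the mixing is strictly zero-lag, it adds no
#' nonzero-lag phase asymmetry and should not raise PLI between independent
#' sources.
#'
#' @param ts A [roi_ts()].
#' @param mixing_matrix Square numeric matrix matching the channel count.
#' @return A mixed `roi_ts` with unchanged labels and rate.
#' @export
apply_mixing <- function(ts, mixing_matrix) {
  stopifnot(inherits(ts, "roi_ts"))
  mixing_matrix <- as.matrix(mixing_matrix)
  if (nrow(mixing_matrix) != ncol(mixing_matrix) ||
      nrow(mixing_matrix) != nrow(ts$data)) {
    abort(sprintf("mixing matrix must be %d x %d to match the channel count",
                  nrow(ts$data), nrow(ts$data)))
  }
  out <- mixing_matrix %*% ts$data
  roi_ts(out, ts$labels, ts$rate, band = ts$band, roi = ts$roi)
}

#' Specification of a synthetic two-timepoint cohort
#'
#' Defaults mirror the study design the pipeline targets: ten subjects
#' measured before (T1) and after (T2) an intervention, five epochs of 4096
#' samples at 312.5 Hz, a connectivity increase injected at T2 into the
#' within-network pairs of selected resting-state networks in one analysis
#' band, and cognitive delta scores linearly linked to each subject's
#' injected connectivity change.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param effect_networks Names of networks receiving the T2 increase
#'   (default none: a null cohort).
#' @param effect_band Band carrying the injected effect (default
#'   `"lower_alpha"`).
#' @param effect_size Target mean within-network PLI increase at T2
#'   (default 0.05; must be >= 0).
#' @param baseline_pli Target mean within-network PLI at T1 (default 0.2,
#'   a typical alpha-band resting-state value).
#' @param baseline_sd Between-subject SD of the baseline network PLI target
#'   (default 0.02), shared by both timepoints.
#' @param heterogeneity Log-scale SD of the subject-specific effect
#'   multiplier (lognormal with mean 1; default 0.6), giving the
#'   between-subject spread of true connectivity change that the
#'   connectivity--cognition correlation rides on.
#' @param cognition_link Named vector mapping cognitive domains to slopes
#'   (z-score units per unit of true network PLI change); unnamed domains
#'   receive pure noise. Default links `verbal_memory` at 40.
#' @param cognitive_noise_sd SD of Gaussian noise on every cognitive delta
#'   (default 0.25 z units).
#' @param noise_sd White measurement noise SD on every channel (default 1).
#' @param rate,n_epochs,epoch_length Recording geometry (defaults 312.5 Hz,
#'   5 x 4096 samples).
#' @param voxels_per_roi When > 1, each ROI is expanded to this many jittered
#'   voxel copies with halving amplitude scales, so representative-voxel
#'   selection is exercised (default 1).
#' @param seed Integer seed; a fixed spec + seed yields a bit-identical
#'   cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10,
                        effect_networks = character(),
                        effect_band = "lower_alpha",
                        effect_size = 0.05,
                        baseline_pli = 0.2,
                        baseline_sd = 0.02,
                        heterogeneity = 0.6,
                        cognition_link = c(verbal_memory = 40),
                        cognitive_noise_sd = 0.25,
                        noise_sd = 1,
                        rate = 312.5,
                        n_epochs = 5,
                        epoch_length = 4096,
                        voxels_per_roi = 1,
                        seed = 1) {
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  if (n_subjects < 2) abort("need at least two subjects")
  get_band(effect_band)
  structure(
    list(n_subjects = n_subjects, effect_networks = effect_networks,
         effect_band = effect_band, effect_size = effect_size,
         baseline_pli = baseline_pli, baseline_sd = baseline_sd,
         heterogeneity = heterogeneity, cognition_link = cognition_link,
         cognitive_noise_sd = cognitive_noise_sd, noise_sd = noise_sd,
         rate = rate, n_epochs = n_epochs, epoch_length = epoch_length,
         voxels_per_roi = voxels_per_roi, seed = seed),
    class = "cohort_spec"
  )
}

#' Read a cohort specification from a YAML file
#'
#' Keys mirror the arguments of [cohort_spec()]; absent keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("spec file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown cohort spec key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$cognition_link)) cfg$cognition_link <- unlist(cfg$cognition_link)
  do.call(cohort_spec, cfg)
}

#' The six default cognitive domains
#' @return Character vector of domain names.
#' @export
cognitive_domains <- function() {
  c("executive_functioning", "verbal_memory", "working_memory",
    "information_processing", "attention", "psychomotor_speed")
}

#' Generate a synthetic source-space cohort
#'
#' Builds per-subject, per-timepoint multichannel recordings with known
#' phase-coupling structure: every resting-state network in `atlas` has a
#' shared narrowband component in the effect band, with member phase offsets
#' spread evenly over `(0, pi)` so all within-network pairs carry nonzero
#' lags; member coupling fractions are chosen by inverting the Monte-Carlo
#' calibrated coupling-to-PLI map so that the expected mean within-network
#' PLI hits the subject's baseline target at T1 and, for affected networks,
#' `baseline + effect` at T2. ROIs outside every network receive independent
#' narrowband activity. Cognitive delta scores equal
#' `cognition_link[domain] * (subject's true network PLI change)` plus
#' Gaussian noise.
#'
#' @param spec A [cohort_spec()].
#' @param atlas List with `registry` (labels) and `networks` (named member
#'   lists), e.g. from [load_rsn_config()].
#' @return A list of class `meg_cohort` with tibbles `recordings` (subject,
#'   timepoint, ts list-column), `cognition` (subject, domain, z_t1, z_t2,
#'   delta), `truth` (subject, network, band, target T1 PLI and true
#'   injected change), plus `spec` and `atlas`.
#' @export
generate_cohort <- function(spec, atlas = load_rsn_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  registry <- atlas$registry
  networks <- atlas$networks
  unknown <- setdiff(spec$effect_networks, names(networks))
  if (length(unknown) > 0) {
    abort(sprintf("unknown effect network(s): %s", paste(unknown, collapse = ", ")))
  }
  validate_rsns(networks, registry, hemisphere_check = FALSE)
  band <- get_band(spec$effect_band)
  n <- spec$n_epochs * spec$epoch_length
  set.seed(spec$seed)

  # subject-level latent structure
  base_pli <- pmax(0.02, spec$baseline_pli +
                     rnorm(spec$n_subjects, 0, spec$baseline_sd))
  mult <- if (spec$heterogeneity > 0) {
    exp(rnorm(spec$n_subjects, -spec$heterogeneity^2 / 2, spec$heterogeneity))
  } else rep(1, spec$n_subjects)
  delta_true <- spec$effect_size * mult

  # per-network member phase offsets: evenly spaced in (0, pi)
  offsets <- lapply(networks, function(members) {
    m <- length(members)
    setNames((seq_len(m) - 0.5) * pi / m, members)
  })

  scales <- 2^(-(seq_len(spec$voxels_per_roi) - 1))

  recs <- vector("list", spec$n_subjects * 2)
  truth <- list()
  i <- 0
  for (s in seq_len(spec$n_subjects)) {
    for (tp in c("T1", "T2")) {
      coupling <- lapply(names(networks), function(nm) {
        target <- base_pli[s]
        if (tp == "T2" && nm %in% spec$effect_networks) {
          target <- target + delta_true[s]
        }
        coupling_for_network_pli(target, length(networks[[nm]]))
      })
      names(coupling) <- names(networks)

      data <- matrix(0, length(registry), n)
      rownames(data) <- registry
      common <- lapply(names(networks), function(nm) {
        narrowband_component(n, spec$rate, band$low, band$high)
      })
      names(common) <- names(networks)
      for (r in registry) {
        in_nets <- names(networks)[vapply(networks, function(mm) r %in% mm,
                                          logical(1))]
        sig <- numeric(n)
        shared_var <- 0
        if (length(in_nets) > 0) {
          for (nm in in_nets) {
            w <- coupling[[nm]] / length(in_nets)
            sig <- sig + sqrt(w) *
              Re(common[[nm]] * exp(-1i * offsets[[nm]][r]))
            shared_var <- shared_var + w
          }
        }
        resid <- max(0, 1 - shared_var)
        sig <- sig + sqrt(resid) *
          Re(narrowband_component(n, spec$rate, band$low, band$high))
        sig <- sig + spec$noise_sd * rnorm(n)
        data[r, ] <- sig
      }

      if (spec$voxels_per_roi > 1) {
        vox <- do.call(rbind, lapply(registry, function(r) {
          t(vapply(scales, function(sc) {
            sc * data[r, ] + 0.2 * rnorm(n)
          }, numeric(n)))
        }))
        labels <- as.vector(t(outer(registry,
                                    paste0(".v", seq_along(scales)), paste0)))
        roi_map <- rep(registry, each = length(scales))
        ts <- roi_ts(vox, labels, spec$rate, roi = roi_map)
      } else {
        ts <- roi_ts(data, registry, spec$rate)
      }
      i <- i + 1
      recs[[i]] <- tibble::tibble(subject = s, timepoint = tp, ts = list(ts))
    }
    for (nm in names(networks)) {
      truth[[length(truth) + 1]] <- tibble::tibble(
        subject = s, network = nm, band = band$band,
        pli_t1_target = base_pli[s],
        delta_true = if (nm %in% spec$effect_networks) delta_true[s] else 0
      )
    }
  }

  domains <- cognitive_domains()
  link <- setNames(rep(0, length(domains)), domains)
  if (length(spec$cognition_link) > 0) {
    bad <- setdiff(names(spec$cognition_link), domains)
    if (length(bad) > 0) {
      abort(sprintf("unknown cognitive domain(s) in cognition_link: %s",
                    paste(bad, collapse = ", ")))
    }
    link[names(spec$cognition_link)] <- spec$cognition_link
  }
  effect_delta <- if (length(spec$effect_networks) > 0) delta_true else
    rep(0, spec$n_subjects)
  cog <- tidyr::expand_grid(subject = seq_len(spec$n_subjects),
                            domain = domains)
  cog$z_t1 <- rnorm(nrow(cog))
  cog$delta <- unname(link[cog$domain]) * effect_delta[cog$subject] +
    rnorm(nrow(cog), 0, spec$cognitive_noise_sd)
  cog$z_t2 <- cog$z_t1 + cog$delta
  cog <- cog[, c("subject", "domain", "z_t1", "z_t2", "delta")]

  structure(
    list(recordings = dplyr::bind_rows(recs),
         cognition = cog,
         truth = dplyr::bind_rows(truth),
         spec = spec, atlas = atlas),
    class = "meg_cohort"
  )
}

#' @export
print.meg_cohort <- function(x, ...) {
  cat(sprintf("<meg_cohort> %d subjects x 2 timepoints, %d ROIs @ %g Hz; effect: %s\n",
              x$spec$n_subjects, length(x$atlas$registry), x$spec$rate,
              if (length(x$spec$effect_networks))
                sprintf("%s +%g (%s)", paste(x$spec$effect_networks, collapse = ","),
                        x$spec$effect_size, x$spec$effect_band)
              else "none (null cohort)"))
  invisible(x)
}
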