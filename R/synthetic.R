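#' Configuration for the confined-diffusion trace simulator
#'
#' The inter-locus separation vector moves as a 2D Ornstein-Uhlenbeck
#' process (the simplest stationary confined-motion model): stationary
#' per-axis SD `confinement_radius / sqrt(2)` so the RMS 2D separation equals
#' `confinement_radius`, with relaxation time `relaxation_time`. After
#' `drug_time` (inducer addition), frames whose true separation is at most
#' `capture_radius` convert to the bound state with `bind_prob_per_frame`;
#' bound frames hold the separation at zero (plus localization noise in the
#' observation). Bound pairs unbind spontaneously with
#' `unbind_prob_per_frame`, and at a division frame are disrupted with
#' `division_disruption_prob`, in which case the separation is reset to
#' `division_displacement` (segregation by the spindle). Divisions recur
#' every `division_interval` minutes with a uniform random phase.
#'
#' Defaults state a realistic imaging experiment: 10-min frames, 40 frames,
#' 0.7 um confinement (giving unbound co-localization baselines in the
#' 10-40% range), 20-min relaxation, 0.4 um capture, and a division
#' disruption probability of 11/58 (disrupted:intact odds observed across
#' divisions).
#'
#' @param frame_interval Minutes between frames.
#' @param n_frames Number of frames.
#' @param confinement_radius RMS 2D separation of the unbound pair, um.
#' @param relaxation_time OU relaxation time, minutes.
#' @param capture_radius Separation below which binding can occur, um.
#' @param bind_prob_per_frame,unbind_prob_per_frame Per-frame probabilities.
#' @param drug_time Inducer addition time, minutes.
#' @param localization_noise_sd Per-axis localization error, um.
#' @param division_interval Minutes between divisions.
#' @param division_disruption_prob Probability a bound pair is disrupted at a
#'   division.
#' @param division_displacement Separation (um) imposed on a
#'   division-disrupted pair.
#' @param detection_dropout_prob Per-frame probability the distance is
#'   unobserved (NA), emulating lost dot signals.
#' @param seed Integer seed.
#' @return A `cici_diffusion_config` list.
#' @export
diffusion_config <- function(frame_interval = 10, n_frames = 40L,
                             confinement_radius = 0.7, relaxation_time = 20,
                             capture_radius = 0.4,
                             bind_prob_per_frame = 0.5,
                             unbind_prob_per_frame = 0.005,
                             drug_time = 0, localization_noise_sd = 0.05,
                             division_interval = 150,
                             division_disruption_prob = 11 / 58,
                             division_displacement = 1.2,
                             detection_dropout_prob = 0,
                             seed = 1L) {
  cfg <- list(frame_interval = frame_interval, n_frames = as.integer(n_frames),
              confinement_radius = confinement_radius,
              relaxation_time = relaxation_time,
              capture_radius = capture_radius,
              bind_prob_per_frame = bind_prob_per_frame,
              unbind_prob_per_frame = unbind_prob_per_frame,
              drug_time = drug_time,
              localization_noise_sd = localization_noise_sd,
              division_interval = division_interval,
              division_disruption_prob = division_disruption_prob,
              division_displacement = division_displacement,
              detection_dropout_prob = detection_dropout_prob,
              seed = as.integer(seed))
  for (f in c("frame_interval", "confinement_radius", "relaxation_time",
              "capture_radius", "division_interval", "division_displacement")) {
    stopifnot_positive(cfg[[f]], f)
  }
  if (cfg$n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  for (f in c("bind_prob_per_frame", "unbind_prob_per_frame",
              "division_disruption_prob", "detection_dropout_prob")) {
    stopifnot_prob(cfg[[f]], f)
  }
  if (!is.finite(cfg$drug_time) || cfg$drug_time < 0) {
    stop("`drug_time` must be non-negative and finite", call. = FALSE)
  }
  if (!is.finite(cfg$localization_noise_sd) || cfg$localization_noise_sd < 0) {
    stop("`localization_noise_sd` must be non-negative and finite", call. = FALSE)
  }
  class(cfg) <- "cici_diffusion_config"
  cfg
}

# first frame of the first run of >= min_run consecutive TRUEs; NA if none
first_run_start <- function(flag, min_run = 3L) {
  run <- 0L
  for (j in seq_along(flag)) {
    run <- if (isTRUE(flag[j])) run + 1L else 0L
    if (run == min_run) return(j - min_run + 1L)
  }
  NA_integer_
}

#' Simulate a single-cell inter-locus distance trace
#'
#' Runs the confined-diffusion + binding model of [diffusion_config] and
#' returns the observed trace alongside the ground truth. The observed
#' distance is the norm of the true separation vector plus 2D Gaussian
#' localization noise. `true_formation_frame` in the ground truth is the
#' first frame of the first run of >= 3 frames with true (noiseless)
#' distance <= 0.4 um — the observable contact rule applied to the noiseless
#' trace — while `bound_state` records molecular binding separately.
#'
#' @param config A [diffusion_config].
#' @return List with `trace` (a [distance_trace]) and `truth` (list:
#'   `bound_state`, `true_distance`, `true_formation_frame`,
#'   `true_disruption_frames`, `division_frames`).
#' @export
simulate_distance_trace <- function(config) {
  stopifnot(inherits(config, "cici_diffusion_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_frames
    dt <- cfg$frame_interval
    times <- seq(0, by = dt, length.out = n)
    s <- cfg$confinement_radius / sqrt(2)          # stationary per-axis SD
    rho <- exp(-dt / cfg$relaxation_time)
    innov_sd <- s * sqrt(1 - rho^2)

    phase <- stats::runif(1, 0, cfg$division_interval)
    div_times <- seq(phase, max(times) + dt, by = cfg$division_interval)
    # marker disappears during the interval ending at frame d:
    # times[d-1] < division time <= times[d]
    division_frames <- unique(as.integer(ceiling(div_times / dt)) + 1L)
    division_frames <- division_frames[division_frames >= 2L &
                                       division_frames <= n]

    # all randomness pre-drawn with state-independent consumption, so e.g.
    # disabling binding or moving drug_time never perturbs the diffusion path
    innov_x <- stats::rnorm(n, 0, innov_sd)
    innov_y <- stats::rnorm(n, 0, innov_sd)
    u_bind <- stats::runif(n)
    u_unbind <- stats::runif(n)
    u_div <- stats::runif(n)
    div_angle <- stats::runif(n, 0, 2 * pi)
    noise_x <- stats::rnorm(n, 0, cfg$localization_noise_sd)
    noise_y <- stats::rnorm(n, 0, cfg$localization_noise_sd)
    u_drop <- stats::runif(n)

    x <- stats::rnorm(1, 0, s)
    y <- stats::rnorm(1, 0, s)
    bound <- FALSE
    bound_state <- logical(n)
    true_dist <- numeric(n)
    disrupt <- integer(0)

    for (i in seq_len(n)) {
      if (i > 1L && !bound) {
        x <- rho * x + innov_x[i]
        y <- rho * y + innov_y[i]
      }
      r <- sqrt(x^2 + y^2)
      if (bound) {
        if (i %in% division_frames && u_div[i] < cfg$division_disruption_prob) {
          bound <- FALSE
          x <- cfg$division_displacement * cos(div_angle[i])
          y <- cfg$division_displacement * sin(div_angle[i])
          r <- cfg$division_displacement
          disrupt <- c(disrupt, i)
        } else if (u_unbind[i] < cfg$unbind_prob_per_frame) {
          bound <- FALSE
          disrupt <- c(disrupt, i)
          r <- sqrt(x^2 + y^2)
        } else {
          r <- 0
        }
      }
      if (!bound && times[i] >= cfg$drug_time && r <= cfg$capture_radius &&
          u_bind[i] < cfg$bind_prob_per_frame) {
        bound <- TRUE
        x <- 0; y <- 0
        r <- 0
      }
      bound_state[i] <- bound
      true_dist[i] <- r
    }
    # noise applied to the separation vector, so the observed distance stays
    # non-negative without truncation
    obs <- sqrt((true_dist + noise_x)^2 + noise_y^2)
    if (cfg$detection_dropout_prob > 0) {
      obs[u_drop < cfg$detection_dropout_prob] <- NA_real_
    }

    truth <- list(
      bound_state = bound_state,
      true_distance = true_dist,
      true_formation_frame = first_run_start(true_dist <= 0.4, 3L),
      true_disruption_frames = disrupt,
      division_frames = division_frames
    )
    list(
      trace = distance_trace(times, obs, cell_id = cfg$seed,
                             division_frames = division_frames),
      truth = truth
    )
  })
}

#' Simulate a cohort of distance traces
#'
#' @param n_cells Number of cells.
#' @param config Base [diffusion_config]; each cell gets a deterministic
#'   sub-seed derived from `config$seed` and its index.
#' @return List of `simulate_distance_trace` results.
#' @export
simulate_cohort <- function(n_cells, config) {
  lapply(seq_len(n_cells), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    simulate_distance_trace(cfg)
  })
}

#' Draw single-cell formation times from an exponential mixture
#'
#' Density `A1 * exp(-t/t1)/t1 + (1 - A1) * exp(-t/t2)/t2`.
#'
#' @param t1,t2 Time constants in minutes (> 0).
#' @param A1 Weight of the `t1` component, in `[0, 1]`.
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of `n` times in minutes.
#' @examples
#' mean(sample_formation_times(10, 10, 1, 1e4, seed = 1))  # ~ 10
#' @export
sample_formation_times <- function(t1, t2, A1, n, seed = NULL) {
  stopifnot_positive(t1, "t1")
  stopifnot_positive(t2, "t2")
  stopifnot_prob(A1, "A1")
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  with_seed(seed, {
    fast <- stats::runif(n) < A1
    ifelse(fast, stats::rexp(n, 1 / t1), stats::rexp(n, 1 / t2))
  })
}

#' Simulate a binomial population co-localization time course
#'
#' At each requested time the number of co-localized cells is drawn
#' `Binomial(n_cells_per_timepoint, P(t))` with `P(t)` from [coloc_model].
#'
#' @param a1,a2,k1,k2 Convolution-model parameters (see [coloc_model]).
#' @param times Times in minutes.
#' @param n_cells_per_timepoint Cells scored per timepoint.
#' @param seed Integer seed.
#' @return A [timecourse].
#' @export
simulate_population_timecourse <- function(a1, a2, k1, k2, times,
                                           n_cells_per_timepoint, seed = NULL) {
  p <- coloc_model(times, a1, a2, k1, k2)
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("model probability outside [0, 1] at a requested time", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  with_seed(seed, {
    k <- stats::rbinom(length(times), n_cells_per_timepoint, p)
    timecourse(times, k, rep(n_cells_per_timepoint, length(times)))
  })
}

#' Specification of a synthetic two-channel z-stack
#'
#' @param image_shape Integer `c(z, y, x)` in pixels.
#' @param pixel_size Lateral pixel size, um/pixel.
#' @param z_spacing Axial slice spacing, um.
#' @param psf_sigma Lateral PSF sigma, pixels.
#' @param axial_factor Axial sigma = `psf_sigma * axial_factor` in lateral
#'   pixel units (converted to slices internally); widefield PSFs are
#'   2-3x wider axially.
#' @param dot_photon_count Integrated photons per dot.
#' @param background_level Background photons per voxel.
#' @param cell_masks 2D integer label matrix (y, x); 0 = outside cells.
#' @param dot_positions Data frame with columns `cell_id`, `channel`
#'   (`"a"`/`"b"`), `x_um`, `y_um`, `z_um`.
#' @return A `cici_stack_spec` list.
#' @export
zstack_spec <- function(image_shape, pixel_size, z_spacing, psf_sigma,
                        dot_photon_count, background_level, cell_masks,
                        dot_positions, axial_factor = 2.5) {
  stopifnot(length(image_shape) == 3L, all(image_shape >= 1))
  stopifnot_positive(pixel_size, "pixel_size")
  stopifnot_positive(z_spacing, "z_spacing")
  stopifnot_positive(psf_sigma, "psf_sigma")
  if (dot_photon_count < 0 || background_level < 0) {
    stop("photon counts must be >= 0", call. = FALSE)
  }
  stopifnot(is.matrix(cell_masks),
            nrow(cell_masks) == image_shape[2],
            ncol(cell_masks) == image_shape[3])
  dp <- dot_positions
  if (nrow(dp)) {
    need <- c("cell_id", "channel", "x_um", "y_um", "z_um")
    if (!all(need %in% names(dp))) {
      stop("`dot_positions` needs columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    col <- floor(dp$x_um / pixel_size) + 1L
    row <- floor(dp$y_um / pixel_size) + 1L
    sl <- floor(dp$z_um / z_spacing) + 1L
    if (any(col < 1L | col > image_shape[3] | row < 1L | row > image_shape[2] |
            sl < 1L | sl > image_shape[1])) {
      stop("dot position outside image bounds", call. = FALSE)
    }
    inside <- cell_masks[cbind(row, col)] == dp$cell_id
    if (any(!inside)) stop("dot position outside its cell mask", call. = FALSE)
  }
  out <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              z_spacing = z_spacing, psf_sigma = psf_sigma,
              axial_factor = axial_factor,
              dot_photon_count = dot_photon_count,
              background_level = background_level,
              cell_masks = cell_masks, dot_positions = dp)
  class(out) <- "cici_stack_spec"
  out
}

#' Build a grid of rectangular cell masks
#'
#' Fixture helper: lays `n_cells` rectangular cells on a grid, each
#' `cell_px` x `cell_px` with a 2-pixel gap, labelled 1..n.
#'
#' @param n_cells Number of cells.
#' @param cell_px Cell side in pixels.
#' @param n_cols Cells per row (default: square-ish grid).
#' @return Integer label matrix.
#' @export
make_grid_masks <- function(n_cells, cell_px = 24L, n_cols = ceiling(sqrt(n_cells))) {
  gap <- 2L
  pitch <- cell_px + gap
  n_rows <- ceiling(n_cells / n_cols)
  m <- matrix(0L, n_rows * pitch + gap, n_cols * pitch + gap)
  for (i in seq_len(n_cells)) {
    r0 <- ((i - 1L) %/% n_cols) * pitch + gap + 1L
    c0 <- ((i - 1L) %% n_cols) * pitch + gap + 1L
    m[r0:(r0 + cell_px - 1L), c0:(c0 + cell_px - 1L)] <- i
  }
  m
}

# render one channel: Gaussian dots on a flat background, Poisson noise
render_channel <- function(spec, dots, noise = TRUE) {
  dims <- spec$image_shape  # (z, y, x)
  img <- array(spec$background_level, dim = dims)
  sxy <- spec$psf_sigma
  sz <- spec$psf_sigma * spec$axial_factor * spec$pixel_size / spec$z_spacing
  if (nrow(dots)) {
    for (i in seq_len(nrow(dots))) {
      # sub-pixel center in 1-based pixel coordinates (pixel k spans
      # [k-1, k) um/pixel_size; its center is at k - 0.5)
      cx <- dots$x_um[i] / spec$pixel_size + 0.5
      cy <- dots$y_um[i] / spec$pixel_size + 0.5
      cz <- dots$z_um[i] / spec$z_spacing + 0.5
      xr <- max(1L, floor(cx - 4 * sxy)):min(dims[3], ceiling(cx + 4 * sxy))
      yr <- max(1L, floor(cy - 4 * sxy)):min(dims[2], ceiling(cy + 4 * sxy))
      zr <- max(1L, floor(cz - 4 * sz)):min(dims[1], ceiling(cz + 4 * sz))
      gx <- exp(-(xr - cx)^2 / (2 * sxy^2))
      gy <- exp(-(yr - cy)^2 / (2 * sxy^2))
      gz <- exp(-(zr - cz)^2 / (2 * sz^2))
      g <- outer(gz, outer(gy, gx))           # (z, y, x) patch
      amp <- spec$dot_photon_count / ((2 * pi)^1.5 * sxy^2 * sz)
      img[zr, yr, xr] <- img[zr, yr, xr] + amp * g
    }
  }
  if (noise) {
    img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
  }
  img
}

#' Render a synthetic two-channel z-stack
#'
#' Each dot is a 3D Gaussian (lateral sigma `psf_sigma`, axially widened by
#' `axial_factor`) whose integral is `dot_photon_count`, added to a flat
#' background; Poisson shot noise is then applied voxel-wise.
#'
#' @param spec A [zstack_spec].
#' @param seed Integer seed for the shot noise.
#' @param noise Apply Poisson noise (`TRUE`) or return noiseless expectation.
#' @return List with 3D arrays `channel_a`, `channel_b` (dims `(z, y, x)`)
#'   and `truth` (the `dot_positions` table with sub-pixel centers).
#' @export
render_zstack <- function(spec, seed = NULL, noise = TRUE) {
  stopifnot(inherits(spec, "cici_stack_spec"))
  with_seed(seed, {
    da <- spec$dot_positions[spec$dot_positions$channel == "a", , drop = FALSE]
    db <- spec$dot_positions[spec$dot_positions$channel == "b", , drop = FALSE]
    list(channel_a = render_channel(spec, da, noise = noise),
         channel_b = render_channel(spec, db, noise = noise),
         truth = spec$dot_positions)
  })
}

#' Simulate a qPCR Ct table for replication timing
#'
#' Per locus, the copy number follows a sigmoidal 1-to-2 transition
#' `c(t) = 1 + 1 / (1 + exp(-slope * (t - midpoint)))`; Ct values assume
#' perfect doubling per cycle: `Ct = ct_baseline - log2(c(t)) + noise`. The
#' control locus is assigned the latest midpoint (it must replicate last).
#'
#' @param replication_midpoints Named numeric vector: locus -> midpoint
#'   (minutes after G1 release).
#' @param control_locus Name of the late-replicating control region; must
#'   carry the latest midpoint.
#' @param slope Sigmoid steepness, per minute.
#' @param times Sampling times in minutes.
#' @param ct_baseline Baseline Ct at copy number 1.
#' @param noise_sd Gaussian Ct noise SD, cycles.
#' @param strain Strain label for the output table.
#' @param n_replicates Biological replicates (independent noise).
#' @param drift Optional function `f(t)` returning a multiplicative
#'   copy-number drift applied to every non-control locus (emulates uneven
#'   G1 release); default none.
#' @param seed Integer seed.
#' @return Data frame with columns `strain`, `replicate`, `locus`,
#'   `time_min`, `ct`.
#' @export
simulate_qpcr <- function(replication_midpoints, control_locus,
                          slope = 0.25, times = seq(0, 70, by = 10),
                          ct_baseline = 20, noise_sd = 0.05,
                          strain = "background", n_replicates = 3L,
                          drift = NULL, seed = 1L) {
  mids <- replication_midpoints
  if (is.null(names(mids)) || any(!nzchar(names(mids)))) {
    stop("`replication_midpoints` must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(mids)) || any(mids < 0)) {
    stop("midpoints must be non-negative and finite", call. = FALSE)
  }
  if (!control_locus %in% names(mids)) {
    stop("`control_locus` must appear in `replication_midpoints`", call. = FALSE)
  }
  if (mids[control_locus] < max(mids)) {
    stop("the control locus must have the latest replication midpoint", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(n_replicates)) {
      for (locus in names(mids)) {
        cn <- 1 + 1 / (1 + exp(-slope * (times - mids[[locus]])))
        if (!is.null(drift) && locus != control_locus) cn <- cn * drift(times)
        ct <- ct_baseline - log2(cn) +
          stats::rnorm(length(times), 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = strain, replicate = rep_i, locus = locus,
          time_min = times, ct = ct
        )
      }
    }
    do.call(rbind, rows)
  })
}
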