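#' Construct an image stack
#'
#' A 3-D fluorescence stack with acquisition calibration. Voxels are stored as
#' a numeric array with axis order (z, y, x); coordinates used throughout the
#' package are 1-based array indices in the same order.
#'
#' @param voxels 3-D numeric array, dimensions (z, y, x), finite and
#'   non-negative.
#' @param pixel_size Lateral pixel size, nm/px.
#' @param z_spacing Axial spacing, nm.
#' @param stack_id Label.
#' @param autofluorescence Optional mean cellular intensity measured in
#'   fluorophore-free cells (a.u./voxel), used for intensity correction.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(voxels, pixel_size, z_spacing, stack_id = "stack",
                        autofluorescence = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            all(is.finite(voxels)), pixel_size > 0, z_spacing > 0)
  structure(
    list(voxels = voxels, pixel_size = pixel_size, z_spacing = z_spacing,
         stack_id = as.character(stack_id),
         autofluorescence = autofluorescence),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack '%s'> %d z-planes x %d x %d px, %.1f nm/px, %.0f nm z-spacing\n",
              x$stack_id, d[1], d[2], d[3], x$pixel_size, x$z_spacing))
  invisible(x)
}

#' Render a Gaussian focus into a stack
#'
#' Adds a diffraction-limited focus, modelled as a separable 3-D Gaussian
#' integrated per voxel, to an existing voxel array. The photon count is
#' distributed so that the full (untruncated) Gaussian integrates to
#' \code{photons}; rendering is restricted to a box of \eqn{\pm 4\sigma}
#' around the centre, which conserves better than 99.9% of the photons when
#' the box lies inside the stack. Centre coordinates are continuous, 1-based
#' voxel units (z, y, x); mass falling outside the stack (e.g. for a focus
#' near the first or last plane) is lost, as in a real acquisition.
#'
#' @param voxels 3-D array (z, y, x) to render into.
#' @param center Numeric length-3 centre, (z, y, x) in voxel units.
#' @param sigma Numeric length-3 Gaussian SD, (z, y, x) in voxel units.
#' @param photons Total photon count of the focus.
#' @return The voxel array with the focus added.
#' @export
render_focus <- function(voxels, center, sigma, photons) {
  stopifnot(length(center) == 3, length(sigma) == 3, all(sigma > 0),
            photons >= 0)
  d <- dim(voxels)
  ax <- vector("list", 3)
  idx <- vector("list", 3)
  for (k in 1:3) {
    lo <- max(1L, floor(center[k] - 4 * sigma[k]))
    hi <- min(d[k], ceiling(center[k] + 4 * sigma[k]))
    if (lo > hi) return(voxels)  # entirely outside
    i <- lo:hi
    # per-voxel integral of the axis Gaussian over [i - 0.5, i + 0.5]
    ax[[k]] <- pnorm(i + 0.5, center[k], sigma[k]) -
      pnorm(i - 0.5, center[k], sigma[k])
    idx[[k]] <- i
  }
  w <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dim(w) <- c(length(idx[[1]]), length(idx[[2]]), length(idx[[3]]))
  voxels[idx[[1]], idx[[2]], idx[[3]]] <-
    voxels[idx[[1]], idx[[2]], idx[[3]]] + photons * w
  voxels
}

# Rejection-sample n lateral positions with a minimum pairwise separation.
# Fails loudly if placement is impossible rather than silently dropping foci.
place_foci_xy <- function(n, frame_size, margin, min_sep, max_tries = 20000L) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  lo <- 1 + margin
  hi <- frame_size - margin
  if (hi <= lo) stop("frame too small for the requested edge margin")
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(
        "could not place %d foci with min separation %.1f px in a %d px field",
        n, min_sep, frame_size))
    x <- runif(1, lo, hi); y <- runif(1, lo, hi)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(y = ys, x = xs)
}

#' Simulate synthetic focus stacks with ground truth
#'
#' Generates a cohort of 3-D stacks in which each focus is a Gaussian spot of
#' integrated photon count \code{copies_per_focus * unit_intensity}, placed at
#' a random lateral position with a minimum pairwise separation and (by
#' default) a random axial offset spanning the stack depth — the axial offset
#' reproduces the variance of focus intensities measured at a single focal
#' plane. Poisson shot noise is applied to signal plus cytosolic background,
#' followed by additive Gaussian read noise.
#'
#' @param config A \code{\link{stack_sim_config}}.
#' @return A list with components \code{stacks} (list of
#'   \code{\link{image_stack}}) and \code{ground_truth} (data frame with one
#'   row per focus: \code{stack_id}, \code{focus_id}, \code{z}, \code{y},
#'   \code{x} (1-based voxel units), \code{copies}, \code{photons}).
#' @export
simulate_focus_stacks <- function(config) {
  stopifnot(inherits(config, "stack_sim_config"))
  set.seed(config$seed)
  n_foci <- config$cells_per_stack * config$foci_per_cell
  sig <- c(config$psf_sigma_axial / config$z_spacing,
           config$psf_sigma_lateral / config$pixel_size,
           config$psf_sigma_lateral / config$pixel_size)
  photons <- config$copies_per_focus * config$unit_intensity
  stacks <- vector("list", config$n_stacks)
  gt <- vector("list", config$n_stacks)
  for (s in seq_len(config$n_stacks)) {
    vox <- array(0, dim = c(config$z_planes, config$frame_size,
                            config$frame_size))
    if (n_foci > 0 && photons > 0) {
      yx <- place_foci_xy(n_foci, config$frame_size, config$edge_margin_px,
                          config$min_separation_px)
      zc <- if (config$z_placement == "uniform")
        runif(n_foci, 1, config$z_planes)
      else
        rep((config$z_planes + 1) / 2, n_foci)
      for (i in seq_len(n_foci))
        vox <- render_focus(vox, c(zc[i], yx[i, 1], yx[i, 2]), sig, photons)
      gt[[s]] <- data.frame(
        stack_id = sprintf("sim-%03d", s),
        focus_id = seq_len(n_foci),
        z = zc, y = yx[, 1], x = yx[, 2],
        copies = config$copies_per_focus,
        photons = photons
      )
    } else {
      gt[[s]] <- data.frame(stack_id = character(0), focus_id = integer(0),
                            z = numeric(0), y = numeric(0), x = numeric(0),
                            copies = integer(0), photons = numeric(0))
    }
    lambda <- vox + config$cytosolic_background
    noisy <- if (config$shot_noise)
      array(rpois(length(lambda), lambda), dim = dim(lambda))
    else lambda
    if (config$read_noise_sd > 0)
      noisy <- noisy + array(rnorm(length(noisy), 0, config$read_noise_sd),
                             dim = dim(noisy))
    noisy[noisy < 0] <- 0
    stacks[[s]] <- image_stack(noisy, config$pixel_size, config$z_spacing,
                               stack_id = sprintf("sim-%03d", s))
  }
  list(stacks = stacks, ground_truth = do.call(rbind, gt),
       config = config)
}

#' Simulate FRAP traces with ground truth
#'
#' Generates raw-intensity FRAP time series. Pre-bleach frames sit at ratio 1;
#' the bleach pulse (taken as instantaneous at time 0, immediately after the
#' last pre-bleach frame) removes \code{bleach_depth} of the spot signal, and
#' the spot ratio then recovers as
#' \code{R(t) = 1 - b*(1 - m*(1 - 2^(-t/t_half)))}. Gaussian noise of SD
#' \code{noise_sd} is added on the ratio scale and traces are re-expressed as
#' raw (spot, cell, background) intensities.
#'
#' @param config A \code{\link{frap_sim_config}}.
#' @return List with \code{traces} (list of \code{\link{frap_trace}}) and
#'   \code{ground_truth} (data frame: \code{trace_id}, \code{t_half},
#'   \code{mobile_fraction}, \code{bleach_depth}, \code{plateau} — the
#'   asymptotic unrecovered fraction of the bleached amplitude).
#' @export
simulate_frap_traces <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  set.seed(config$seed)
  n_pre <- config$pre_frames
  t_pre <- seq(-(n_pre - 1) * config$ref_interval, 0,
               by = config$ref_interval)
  t_ref_post <- seq_len(n_pre) * config$ref_interval
  t_sched <- numeric(0)
  t_cursor <- max(t_ref_post)
  for (seg in config$frame_schedule) {
    t_sched <- c(t_sched, t_cursor + cumsum(rep(seg[2], seg[1])))
    t_cursor <- max(t_sched)
  }
  t_post <- c(t_ref_post, t_sched)
  b <- config$bleach_depth
  m <- config$mobile_fraction
  traces <- vector("list", config$n_traces)
  for (i in seq_len(config$n_traces)) {
    r_true <- c(rep(1, n_pre),
                1 - b * (1 - m * (1 - 2^(-t_post / config$true_t_half))))
    r_obs <- r_true + rnorm(length(r_true), 0, config$noise_sd)
    id <- sprintf("%s-%03d", config$condition, i)
    traces[[i]] <- frap_trace(
      time_s = c(t_pre, t_post),
      I_spot = config$I_bg + r_obs * (config$I_cell - config$I_bg),
      I_cell = rep(config$I_cell, length(r_obs)),
      I_bg = rep(config$I_bg, length(r_obs)),
      bleach_index = n_pre,
      trace_id = id,
      condition = config$condition
    )
  }
  gt <- data.frame(
    trace_id = vapply(traces, function(tr) attr(tr, "trace_id"), ""),
    t_half = config$true_t_half,
    mobile_fraction = m,
    bleach_depth = b,
    plateau = 1 - m
  )
  list(traces = traces, ground_truth = gt, config = config)
}

#' Simulate single-molecule trajectories with ground truth
#'
#' Each molecule is assigned a diffusive population, a geometric track length
#' and a uniformly distributed activation frame; true positions follow 2-D
#' Brownian motion with per-axis step SD \code{sqrt(2*D*dt)} and reflective
#' boundaries at the cell box; independent Gaussian localization error is
#' added per frame.
#'
#' @param config A \code{\link{traj_sim_config}}.
#' @return List with \code{localizations} (data frame \code{frame},
#'   \code{x_um}, \code{y_um}, \code{molecule_id}, sorted by frame) and
#'   \code{ground_truth} (data frame \code{molecule_id}, \code{population},
#'   \code{D}, \code{start_frame}, \code{length}).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "traj_sim_config"))
  set.seed(config$seed)
  pop <- config$populations
  dt <- config$frame_interval
  labels <- sample.int(nrow(pop), config$n_molecules, replace = TRUE,
                       prob = pop$fraction)
  # geometric length with mean mean_track_length, minimum 1 frame
  p_geom <- 1 / config$mean_track_length
  lens <- 1L + rgeom(config$n_molecules, p_geom)
  starts <- sample.int(config$n_frames, config$n_molecules, replace = TRUE)
  bx <- config$cell_bounds[1]
  by <- config$cell_bounds[2]
  reflect <- function(v, upper) {
    # fold coordinates into [0, upper] (reflective boundary)
    v <- v %% (2 * upper)
    ifelse(v > upper, 2 * upper - v, v)
  }
  out <- vector("list", config$n_molecules)
  for (i in seq_len(config$n_molecules)) {
    n <- lens[i]
    D <- pop$D[labels[i]]
    step_sd <- sqrt(2 * D * dt)
    x <- cumsum(c(runif(1, 0, bx), rnorm(n - 1, 0, step_sd)))
    y <- cumsum(c(runif(1, 0, by), rnorm(n - 1, 0, step_sd)))
    x <- reflect(x, bx)
    y <- reflect(y, by)
    if (config$loc_error_sd > 0) {
      x <- x + rnorm(n, 0, config$loc_error_sd)
      y <- y + rnorm(n, 0, config$loc_error_sd)
    }
    out[[i]] <- data.frame(
      frame = starts[i] + seq_len(n) - 1L,
      x_um = x, y_um = y, molecule_id = i
    )
  }
  locs <- do.call(rbind, out)
  locs <- locs[order(locs$frame, locs$molecule_id), , drop = FALSE]
  rownames(locs) <- NULL
  gt <- data.frame(molecule_id = seq_len(config$n_molecules),
                   population = labels, D = pop$D[labels],
                   start_frame = starts, length = lens)
  list(localizations = locs, ground_truth = gt, config = config)
}
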