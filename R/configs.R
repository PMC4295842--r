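#' Simulation configuration for synthetic focus stacks
#'
#' Describes a cohort of 3-D fluorescence stacks containing diffraction-limited
#' membrane foci, each focus carrying an integer number of fluorophores, on top
#' of a cytosolic background with Poisson shot noise and Gaussian read noise.
#' Acquisition geometry follows optical-sectioning defaults: 150 nm z-spacing
#' and 7-15 z-planes, with the lateral pixel size chosen so that 3 px equal
#' 304 nm.
#'
#' @param n_stacks Number of image stacks to simulate.
#' @param cells_per_stack Number of cells per stack (foci are placed in
#'   distinct cells; only focus positions are modelled, not cell outlines).
#' @param foci_per_cell Foci per cell.
#' @param copies_per_focus Integer number of fluorophores per focus (e.g. 22
#'   for the C-ring protein, 24 for the reference ring).
#' @param unit_intensity Photons emitted per fluorophore per acquisition,
#'   before noise. The absolute photon budget of the original microscope is
#'   unknown, so this is a free parameter; the default gives foci that clear a
#'   5-SD detection threshold at every axial offset.
#' @param psf_sigma_lateral,psf_sigma_axial Gaussian PSF widths, nm.
#' @param pixel_size Lateral pixel size, nm/px.
#' @param z_spacing Axial plane spacing, nm.
#' @param z_planes Number of z planes (7-15 typical).
#' @param frame_size Lateral image size in pixels (square field).
#' @param cytosolic_background Mean background, photons/px.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param min_separation_px Minimum lateral distance between placed foci, px;
#'   must be at least 3 so that detected peaks are resolvable.
#' @param edge_margin_px Margin kept free of foci at the lateral image border
#'   so measurement ROIs stay inside the field.
#' @param z_placement \code{"uniform"} draws each focus centre uniformly over
#'   the axial extent of the stack (reproducing the intensity variance of
#'   foci above or below the imaging plane); \code{"center"} puts every focus
#'   on the middle plane (useful for photon-conservation checks).
#' @param shot_noise Apply Poisson shot noise (disable, together with
#'   \code{read_noise_sd = 0}, for noiseless photon-conservation checks).
#' @param seed Integer RNG seed.
#' @return An object of class \code{stack_sim_config}.
#' @export
stack_sim_config <- function(n_stacks = 11,
                             cells_per_stack = 30,
                             foci_per_cell = 4,
                             copies_per_focus = 22,
                             unit_intensity = 400,
                             psf_sigma_lateral = 100,
                             psf_sigma_axial = 300,
                             pixel_size = 304 / 3,
                             z_spacing = 150,
                             z_planes = 10,
                             frame_size = 256,
                             cytosolic_background = 100,
                             read_noise_sd = 3,
                             min_separation_px = 7,
                             edge_margin_px = 5,
                             z_placement = c("uniform", "center"),
                             shot_noise = TRUE,
                             seed = 1L) {
  z_placement <- match.arg(z_placement)
  stopifnot(
    n_stacks >= 1, cells_per_stack >= 1, foci_per_cell >= 0,
    copies_per_focus >= 0, unit_intensity >= 0,
    psf_sigma_lateral > 0, psf_sigma_axial > 0,
    pixel_size > 0, z_spacing > 0,
    z_planes >= 1, frame_size >= 16,
    cytosolic_background >= 0, read_noise_sd >= 0,
    min_separation_px >= 3, edge_margin_px >= 0
  )
  structure(
    list(
      n_stacks = as.integer(n_stacks),
      cells_per_stack = as.integer(cells_per_stack),
      foci_per_cell = as.integer(foci_per_cell),
      copies_per_focus = as.integer(copies_per_focus),
      unit_intensity = unit_intensity,
      psf_sigma_lateral = psf_sigma_lateral,
      psf_sigma_axial = psf_sigma_axial,
      pixel_size = pixel_size,
      z_spacing = z_spacing,
      z_planes = as.integer(z_planes),
      frame_size = as.integer(frame_size),
      cytosolic_background = cytosolic_background,
      read_noise_sd = read_noise_sd,
      min_separation_px = min_separation_px,
      edge_margin_px = edge_margin_px,
      z_placement = z_placement,
      shot_noise = isTRUE(shot_noise),
      seed = as.integer(seed)
    ),
    class = "stack_sim_config"
  )
}

#' Simulation configuration for FRAP traces
#'
#' Describes a cohort of raw-intensity FRAP time series. Each trace consists of
#' pre-bleach reference frames, a bleach event, rapid post-bleach reference
#' frames (both acquired at video rate, \code{ref_interval}), and a recovery
#' schedule of slower frames. The spot ratio recovers as
#' \deqn{R(t) = 1 - b (1 - m (1 - 2^{-t/t_{1/2}}))}
#' where \eqn{b} is the bleach depth and \eqn{m} the mobile fraction, so that
#' at \eqn{t = t_{1/2}} exactly half of the mobile amplitude has recovered.
#' Raw spot, cell and background intensity columns are emitted so downstream
#' ratio computation is exercised rather than bypassed.
#'
#' @param n_traces Number of traces.
#' @param true_t_half Ground-truth recovery half-time, s.
#' @param mobile_fraction Exchangeable fraction in \[0, 1\].
#' @param bleach_depth Fraction of the spot signal removed by the bleach
#'   pulse, in \[0, 1\].
#' @param pre_frames Number of pre-bleach reference frames (also the number of
#'   rapid post-bleach reference frames).
#' @param ref_interval Spacing of the reference frames, s (video rate; fast
#'   relative to recovery so the post-bleach ratio is measured before
#'   appreciable recovery).
#' @param frame_schedule Recovery acquisition schedule: a list of
#'   \code{c(n_frames, interval_s)} segments, e.g.
#'   \code{list(c(10, 2), c(10, 4), c(10, 6))}.
#' @param noise_sd Gaussian noise SD on the ratio scale.
#' @param I_bg,I_cell Baseline background and whole-cell ROI mean intensities
#'   (a.u.) used to re-express ratios as raw intensities.
#' @param condition Condition label attached to every trace.
#' @param seed Integer RNG seed.
#' @return An object of class \code{frap_sim_config}.
#' @export
frap_sim_config <- function(n_traces = 20,
                            true_t_half = 68.2,
                            mobile_fraction = 0.8,
                            bleach_depth = 0.9,
                            pre_frames = 10,
                            ref_interval = 0.04,
                            frame_schedule = list(c(100, 4)),
                            noise_sd = 0.05,
                            I_bg = 10,
                            I_cell = 110,
                            condition = "condition",
                            seed = 1L) {
  stopifnot(
    n_traces >= 1, true_t_half > 0,
    mobile_fraction >= 0, mobile_fraction <= 1,
    bleach_depth >= 0, bleach_depth <= 1,
    pre_frames >= 1, ref_interval > 0,
    length(frame_schedule) >= 1,
    noise_sd >= 0, I_cell > I_bg
  )
  for (seg in frame_schedule) {
    if (length(seg) != 2 || seg[1] < 1 || seg[2] <= 0)
      stop("each frame_schedule segment must be c(n_frames > 0, interval > 0)")
  }
  structure(
    list(
      n_traces = as.integer(n_traces),
      true_t_half = true_t_half,
      mobile_fraction = mobile_fraction,
      bleach_depth = bleach_depth,
      pre_frames = as.integer(pre_frames),
      ref_interval = ref_interval,
      frame_schedule = frame_schedule,
      noise_sd = noise_sd,
      I_bg = I_bg,
      I_cell = I_cell,
      condition = condition,
      seed = as.integer(seed)
    ),
    class = "frap_sim_config"
  )
}

#' Simulation configuration for single-molecule trajectories
#'
#' Describes two-dimensional Brownian trajectories of photoactivated
#' single molecules inside a rectangular cell, imaged at a fixed frame rate
#' with Gaussian localization error. Each molecule belongs to one of several
#' diffusive populations; per-axis step variance is \eqn{2 D \Delta t} and
#' boundaries are reflective. Track lengths are geometric (memoryless
#' photobleaching).
#'
#' @param populations Data frame with columns \code{fraction} and \code{D}
#'   (\eqn{\mu m^2/s}); fractions must sum to 1.
#' @param frame_interval Frame interval, s (default 15.26 ms).
#' @param loc_error_sd Localization error SD per axis, \eqn{\mu m}.
#' @param mean_track_length Mean track length in frames (geometric
#'   distribution, minimum 1 frame).
#' @param n_molecules Number of molecules.
#' @param cell_bounds Numeric length-2: cell box dimensions (x, y) in
#'   \eqn{\mu m}.
#' @param n_frames Total number of acquisition frames over which activation
#'   start times are spread (default 15000, a typical photoactivation
#'   acquisition; together with \code{n_molecules} it sets the molecule
#'   density per frame, which must stay sparse for reliable linking).
#' @param seed Integer RNG seed.
#' @return An object of class \code{traj_sim_config}.
#' @export
traj_sim_config <- function(populations = data.frame(fraction = c(0.5, 0.5),
                                                     D = c(0.5, 0.005)),
                            frame_interval = 0.01526,
                            loc_error_sd = 0.02,
                            mean_track_length = 12,
                            n_molecules = 200,
                            cell_bounds = c(2, 1),
                            n_frames = 15000,
                            seed = 1L) {
  stopifnot(
    is.data.frame(populations),
    all(c("fraction", "D") %in% names(populations)),
    nrow(populations) >= 1,
    all(populations$D >= 0),
    all(populations$fraction >= 0),
    abs(sum(populations$fraction) - 1) < 1e-8,
    frame_interval > 0, loc_error_sd >= 0,
    mean_track_length >= 1, n_molecules >= 1,
    length(cell_bounds) == 2, all(cell_bounds > 0),
    n_frames >= 1
  )
  structure(
    list(
      populations = populations,
      frame_interval = frame_interval,
      loc_error_sd = loc_error_sd,
      mean_track_length = mean_track_length,
      n_molecules = as.integer(n_molecules),
      cell_bounds = cell_bounds,
      n_frames = as.integer(n_frames),
      seed = as.integer(seed)
    ),
    class = "traj_sim_config"
  )
}
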