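#' Robust background statistics of a stack
#'
#' Mean and SD of the stack's voxel values after iterative 3-sigma clipping:
#' voxels more than 3 SD from the current mean are discarded and the
#' statistics recomputed until no voxel is removed or 10 iterations have run.
#' Clipping makes the estimate insensitive to the small fraction of bright
#' focus voxels without requiring a focus mask.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param n_sigma Clipping width in SDs.
#' @param max_iter Maximum clipping iterations.
#' @return Named numeric vector \code{c(mean, sd)}.
#' @export
estimate_background <- function(stack, n_sigma = 3, max_iter = 10) {
  stopifnot(inherits(stack, "image_stack"))
  v <- as.vector(stack$voxels)
  for (i in seq_len(max_iter)) {
    m <- mean(v)
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(c(mean = m, sd = 0))
    keep <- abs(v - m) <= n_sigma * s
    if (all(keep)) break
    v <- v[keep]
  }
  c(mean = mean(v), sd = sd(v))
}

# Logical array marking voxels that are >= all 26 neighbours (3x3x3
# neighbourhood); borders compare against -Inf outside the stack.
local_maxima_3d <- function(a) {
  d <- dim(a)
  is_max <- array(TRUE, dim = d)
  pad_shift <- function(a, dz, dy, dx) {
    out <- array(-Inf, dim = dim(a))
    d <- dim(a)
    zs <- seq_len(d[1]); ys <- seq_len(d[2]); xs <- seq_len(d[3])
    z_src <- zs - dz; y_src <- ys - dy; x_src <- xs - dx
    zk <- z_src >= 1 & z_src <= d[1]
    yk <- y_src >= 1 & y_src <= d[2]
    xk <- x_src >= 1 & x_src <= d[3]
    out[zs[zk], ys[yk], xs[xk]] <- a[z_src[zk], y_src[yk], x_src[xk]]
    out
  }
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    is_max <- is_max & (a >= pad_shift(a, dz, dy, dx))
    }
  is_max
}

#' Detect fluorescent foci in a 3-D stack
#'
#' Foci are local 3-D maxima whose intensity exceeds the robust stack
#' background mean by \code{threshold_sd} background SDs. Among candidate
#' peaks closer than \code{min_separation_px} in the lateral (y, x) plane,
#' only the brightest is kept; ties are broken by descending intensity, then
#' lexicographic (z, y, x) order, so the result is deterministic.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param threshold_sd Detection threshold in background SDs above the
#'   background mean (default 5).
#' @param min_separation_px Minimum lateral peak distance in pixels
#'   (default 3, i.e. 304 nm at the default calibration).
#' @param background Optional precomputed \code{c(mean, sd)}; computed with
#'   \code{\link{estimate_background}} when missing.
#' @return Data frame of foci: \code{z}, \code{y}, \code{x} (1-based voxel
#'   indices), \code{peak_intensity}, \code{stack_id}. Zero rows when nothing
#'   exceeds the threshold (e.g. a constant stack, whose background SD is 0
#'   and where no voxel is strictly above the threshold).
#' @export
detect_foci <- function(stack, threshold_sd = 5, min_separation_px = 3,
                        background = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$voxels
  if (is.null(background)) background <- estimate_background(stack)
  thr <- background[["mean"]] + threshold_sd * background[["sd"]]
  cand <- which(local_maxima_3d(a) & (a > thr), arr.ind = TRUE)
  empty <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      peak_intensity = numeric(0), stack_id = character(0))
  if (nrow(cand) == 0) return(empty)
  vals <- a[cand]
  ord <- order(-vals, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- which(keep)
    dy <- cand[kept, 2] - cand[i, 2]
    dx <- cand[kept, 3] - cand[i, 3]
    keep[i] <- all(dy * dy + dx * dx >= min_separation_px^2)
  }
  data.frame(z = unname(cand[keep, 1]), y = unname(cand[keep, 2]),
             x = unname(cand[keep, 3]), peak_intensity = vals[keep],
             stack_id = stack$stack_id)
}

#' Background-corrected integrated focus intensity
#'
#' Integrates the stack over a fixed cylindrical ROI (lateral radius
#' \code{radius_px}, all z planes) centred on the focus, then subtracts the
#' expected background contribution \code{(outside_background +
#' autofluorescence) * n_voxels}. The two correction terms mirror the
#' experimental procedure: camera/medium background measured outside cells,
#' and the mean cellular autofluorescence measured in fluorophore-free cells.
#' The corrected value may be negative for noise-dominated ROIs; it is
#' reported as-is. A focus whose ROI extends beyond the lateral stack bounds
#' is flagged \code{edge = TRUE} and should be excluded from stoichiometry.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param focus One-row data frame (or list) with \code{z}, \code{y},
#'   \code{x} voxel coordinates.
#' @param outside_background Mean background outside cells, a.u./voxel.
#' @param autofluorescence Mean cellular autofluorescence, a.u./voxel.
#' @param radius_px Lateral ROI radius in pixels.
#' @return List with \code{corrected_intensity}, \code{raw_intensity},
#'   \code{n_voxels}, \code{edge}.
#' @export
measure_focus_intensity <- function(stack, focus, outside_background,
                                    autofluorescence = 0, radius_px = 3) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  y0 <- round(focus$y); x0 <- round(focus$x)
  off <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  off <- off[off$dy^2 + off$dx^2 <= radius_px^2, ]
  ys <- y0 + off$dy
  xs <- x0 + off$dx
  edge <- any(ys < 1 | ys > d[2] | xs < 1 | xs > d[3])
  if (edge) {
    inside <- ys >= 1 & ys <= d[2] & xs >= 1 & xs <= d[3]
    ys <- ys[inside]; xs <- xs[inside]
  }
  n_vox <- length(ys) * d[1]
  raw <- 0
  for (k in seq_along(ys)) raw <- raw + sum(stack$voxels[, ys[k], xs[k]])
  corrected <- raw - (outside_background + autofluorescence) * n_vox
  list(corrected_intensity = corrected, raw_intensity = raw,
       n_voxels = n_vox, edge = edge)
}

#' Detect and measure all foci of a stack
#'
#' Convenience wrapper running \code{\link{detect_foci}} and
#' \code{\link{measure_focus_intensity}} on every detected focus, with the
#' robust stack background as the outside-of-cell correction and the stack's
#' \code{autofluorescence} field (0 when absent) as the cellular correction.
#' Edge-flagged foci are dropped.
#'
#' @inheritParams detect_foci
#' @param radius_px Lateral ROI radius in pixels.
#' @return Data frame: \code{stack_id}, \code{z}, \code{y}, \code{x},
#'   \code{peak_intensity}, \code{corrected_intensity}.
#' @export
quantify_stack <- function(stack, threshold_sd = 5, min_separation_px = 3,
                           radius_px = 3) {
  bg <- estimate_background(stack)
  foci <- detect_foci(stack, threshold_sd, min_separation_px, background = bg)
  if (nrow(foci) == 0) {
    foci$corrected_intensity <- numeric(0)
    return(foci)
  }
  auto <- if (is.null(stack$autofluorescence)) 0 else stack$autofluorescence
  meas <- lapply(seq_len(nrow(foci)), function(i)
    measure_focus_intensity(stack, foci[i, ], bg[["mean"]], auto, radius_px))
  foci$corrected_intensity <- vapply(meas, `[[`, 0, "corrected_intensity")
  foci$edge <- vapply(meas, `[[`, TRUE, "edge")
  out <- foci[!foci$edge, setdiff(names(foci), "edge"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative stoichiometry against a reference of known copy number
#'
#' Estimates the copy number of a tagged protein per focus from focus
#' intensities, relative to a reference protein of fixed known stoichiometry
#' imaged under identical conditions (e.g. the 24-subunit inner-membrane
#' ring). Each stack is treated as an independent observation: per-stack mean
#' intensities are computed first and the estimate is
#' \code{reference_copies * mean(target stack means) / mean(reference stack
#' means)}. The reported spread \code{sd_copies} is the per-focus intensity SD
#' of the target group scaled to copy units — the dominant source of
#' per-focus spread is the axial offset of individual foci relative to the
#' imaging plane, not stack-to-stack variation.
#'
#' @param target_foci Data frame with columns \code{stack_id} and
#'   \code{corrected_intensity} for the protein of unknown stoichiometry.
#' @param reference_foci Same, for the reference protein.
#' @param reference_copies Known copies per reference focus (default 24).
#' @param min_foci_per_stack Warn when any stack has fewer foci than this.
#' @return Object of class \code{stoich_estimate}: \code{mean_copies},
#'   \code{sd_copies}, \code{n_foci_target}, \code{n_foci_ref},
#'   \code{n_stacks_target}, \code{n_stacks_ref}, \code{reference_copies},
#'   \code{stack_means_target}, \code{stack_means_ref}.
#' @export
relative_stoichiometry <- function(target_foci, reference_foci,
                                   reference_copies = 24,
                                   min_foci_per_stack = 100) {
  stopifnot(reference_copies > 0)
  for (nm in c("target", "reference")) {
    df <- if (nm == "target") target_foci else reference_foci
    if (!all(c("stack_id", "corrected_intensity") %in% names(df)))
      stop(nm, " foci need columns stack_id and corrected_intensity")
    if (length(unique(df$stack_id)) < 2)
      stop(nm, " group needs at least 2 stacks")
    cnt <- table(df$stack_id)
    if (any(cnt < min_foci_per_stack))
      warning(sprintf("%s group has stacks with < %d foci", nm,
                      min_foci_per_stack))
  }
  tm <- tapply(target_foci$corrected_intensity, target_foci$stack_id, mean)
  rm_ <- tapply(reference_foci$corrected_intensity, reference_foci$stack_id,
                mean)
  ref_mean <- mean(rm_)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference mean intensity must be positive")
  mean_copies <- reference_copies * mean(tm) / ref_mean
  sd_copies <- reference_copies * sd(target_foci$corrected_intensity) /
    ref_mean
  structure(
    list(mean_copies = mean_copies, sd_copies = sd_copies,
         n_foci_target = nrow(target_foci), n_foci_ref = nrow(reference_foci),
         n_stacks_target = length(tm), n_stacks_ref = length(rm_),
         reference_copies = reference_copies,
         stack_means_target = tm, stack_means_ref = rm_),
    class = "stoich_estimate"
  )
}

#' @export
print.stoich_estimate <- function(x, ...) {
  cat(sprintf(
    "Relative stoichiometry: %.1f +/- %.1f copies per focus\n", x$mean_copies,
    x$sd_copies))
  cat(sprintf("  reference = %d copies; %d target foci in %d stacks, %d reference foci in %d stacks\n",
              x$reference_copies, x$n_foci_target, x$n_stacks_target,
              x$n_foci_ref, x$n_stacks_ref))
  invisible(x)
}

#' Normalized intensity histogram of a focus population
#'
#' @param intensities Numeric vector of focus intensities (at least one).
#' @param n_bins Number of histogram bins.
#' @return List with \code{breaks}, \code{density} (normalized to unit area),
#'   \code{counts}, \code{sd}, \code{iqr} — the width statistics allow
#'   comparing the spread of two populations (a wider distribution would
#'   indicate variable stoichiometry).
#' @export
intensity_distribution <- function(intensities, n_bins = 30) {
  stopifnot(length(intensities) >= 1, n_bins >= 1)
  h <- hist(intensities, breaks = n_bins, plot = FALSE)
  list(breaks = h$breaks, density = h$density, counts = h$counts,
       sd = if (length(intensities) > 1) sd(intensities) else 0,
       iqr = unname(diff(quantile(intensities, c(0.25, 0.75)))))
}

#' End-to-end stoichiometry estimate from two stack cohorts
#'
#' Runs detection and background-corrected intensity measurement on every
#' stack of a target and a reference cohort, then estimates the target copy
#' number with \code{\link{relative_stoichiometry}}.
#'
#' @param target_stacks,reference_stacks Lists of \code{\link{image_stack}}.
#' @param reference_copies Copies per reference focus.
#' @param threshold_sd,min_separation_px,radius_px Detection/measurement
#'   parameters, see \code{\link{detect_foci}} and
#'   \code{\link{measure_focus_intensity}}.
#' @return A \code{stoich_estimate} (see
#'   \code{\link{relative_stoichiometry}}).
#' @export
estimate_stoichiometry <- function(target_stacks, reference_stacks,
                                   reference_copies = 24, threshold_sd = 5,
                                   min_separation_px = 3, radius_px = 3) {
  q <- function(stacks) do.call(rbind, lapply(stacks, quantify_stack,
                                              threshold_sd = threshold_sd,
                                              min_separation_px = min_separation_px,
                                              radius_px = radius_px))
  relative_stoichiometry(q(target_stacks), q(reference_stacks),
                         reference_copies = reference_copies)
}
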