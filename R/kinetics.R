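#' Slope of the linear increasing region of a kinetic trace
#'
#' Scans all contiguous windows of \code{window} points, fits each by
#' ordinary least squares, and returns the maximal slope among windows whose
#' linearity (R^2) is at least \code{r2_min}. When no window passes the
#' linearity gate, the maximal-slope window is used and a warning is issued.
#' A window with zero response variance is treated as perfectly linear
#' (slope 0), so flat traces return 0 without warning.
#'
#' @param times Time points, s, strictly increasing.
#' @param fluorescence Response values, a.u.
#' @param window Window length in points (default 10).
#' @param r2_min Linearity gate on the window R^2 (default 0.95).
#' @return List with \code{slope} (a.u./s), \code{window_start} (index),
#'   \code{r_squared}, \code{linear} (whether the gate was met).
#' @export
linear_region_slope <- function(times, fluorescence, window = 10,
                                r2_min = 0.95) {
  n <- length(times)
  stopifnot(length(fluorescence) == n, all(diff(times) > 0), window >= 2)
  if (window > n) stop("window longer than the trace")
  n_win <- n - window + 1
  slopes <- numeric(n_win)
  r2 <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- i:(i + window - 1)
    tt <- times[idx]; yy <- fluorescence[idx]
    sxx <- sum((tt - mean(tt))^2)
    sxy <- sum((tt - mean(tt)) * (yy - mean(yy)))
    syy <- sum((yy - mean(yy))^2)
    slopes[i] <- sxy / sxx
    r2[i] <- if (syy == 0) 1 else (sxy^2 / (sxx * syy))
  }
  ok <- r2 >= r2_min
  if (any(ok)) {
    cand <- which(ok)
    best <- cand[which.max(slopes[cand])]
    linear <- TRUE
  } else {
    best <- which.max(slopes)
    linear <- FALSE
    warning("no window met the linearity gate; returning the maximal-slope window")
  }
  list(slope = slopes[best], window_start = best, r_squared = r2[best],
       linear = linear)
}

#' Normalize kinetic rates to a reference sample
#'
#' Expresses per-sample slopes as a percentage of a reference sample (e.g.
#' wild type set to 100%), with replicate means and SEM.
#'
#' @param slopes Data frame with columns \code{sample}, \code{replicate},
#'   \code{slope}.
#' @param reference_sample Label of the reference sample.
#' @return Data frame with one row per sample: \code{sample}, \code{n},
#'   \code{mean_percent}, \code{sem_percent}.
#' @export
normalize_rates <- function(slopes, reference_sample) {
  stopifnot(all(c("sample", "replicate", "slope") %in% names(slopes)))
  ref <- mean(slopes$slope[slopes$sample == reference_sample])
  if (!is.finite(ref) || ref <= 0)
    stop("reference sample slope must be positive")
  pct <- 100 * slopes$slope / ref
  agg <- tapply(pct, slopes$sample, function(v)
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_))
  out <- do.call(rbind, agg)
  data.frame(sample = rownames(out), n = out[, "n"],
             mean_percent = out[, "mean"], sem_percent = out[, "sem"],
             row.names = NULL)
}

#' Linear regression of focus counts on protein amount
#'
#' Ordinary least squares of the mean number of foci per cell on the
#' quantified amount of the titrated protein; a high R^2 across the titration
#' indicates that focus formation scales linearly with the available protein.
#'
#' @param amount Protein amount per titration point, a.u.
#' @param mean_foci_per_cell Mean focus count per cell at each point.
#' @param n_cells Optional cell counts per point; a warning is issued for
#'   points with fewer than \code{min_cells}.
#' @param min_cells Warning threshold on cells per point (default 170).
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n_points} and the underlying \code{lm} fit.
#' @export
titration_regression <- function(amount, mean_foci_per_cell, n_cells = NULL,
                                 min_cells = 170) {
  stopifnot(length(amount) == length(mean_foci_per_cell),
            length(amount) >= 2)
  if (length(unique(amount)) < 2)
    stop("all amounts are equal: regression undefined")
  if (!is.null(n_cells) && any(n_cells < min_cells))
    warning("some titration points have fewer than ", min_cells, " cells")
  fit <- lm(mean_foci_per_cell ~ amount)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n_points = length(amount),
       fit = fit)
}
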