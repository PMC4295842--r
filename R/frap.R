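#' Construct a FRAP trace
#'
#' A time series of raw fluorescence intensities around a photobleaching
#' event: per frame, the mean intensity of the bleached spot ROI
#' (\code{I_spot}), of the whole bacterium (\code{I_cell}) and of a
#' cell-free background ROI (\code{I_bg}). The bleach pulse is taken to occur
#' immediately after frame \code{bleach_index}, at the time stamp of that
#' frame.
#'
#' @param time_s Frame times, s, strictly increasing.
#' @param I_spot,I_cell,I_bg Per-frame ROI mean intensities, a.u.
#' @param bleach_index Index of the last pre-bleach frame.
#' @param trace_id Label.
#' @param condition Condition label (e.g. "secreting", "non-secreting").
#' @return A data frame of class \code{frap_trace} with attributes
#'   \code{bleach_index}, \code{trace_id}, \code{condition}.
#' @export
frap_trace <- function(time_s, I_spot, I_cell, I_bg, bleach_index,
                       trace_id = "trace", condition = NA_character_) {
  stopifnot(length(time_s) == length(I_spot),
            length(time_s) == length(I_cell),
            length(time_s) == length(I_bg),
            all(diff(time_s) > 0),
            bleach_index >= 1, bleach_index < length(time_s))
  structure(
    data.frame(time_s = time_s, I_spot = I_spot, I_cell = I_cell,
               I_bg = I_bg),
    bleach_index = as.integer(bleach_index),
    trace_id = as.character(trace_id),
    condition = as.character(condition),
    class = c("frap_trace", "data.frame")
  )
}

#' Spot intensity ratio
#'
#' The background-subtracted spot intensity normalized by the
#' background-subtracted cell intensity, \code{R = (I_S - I_0)/(I_B - I_0)}.
#' Dividing by the cell signal cancels acquisition photobleaching and
#' illumination fluctuations that affect spot and cell alike.
#'
#' @param I_S Spot ROI mean, a.u. (vectorized).
#' @param I_B Cell ROI mean, a.u.
#' @param I_0 Background ROI mean, a.u.
#' @return Numeric ratio(s).
#' @export
spot_ratio <- function(I_S, I_B, I_0) {
  den <- I_B - I_0
  bad <- which(den == 0)
  if (length(bad))
    stop("undefined spot ratio: I_cell equals I_bg at frame(s) ",
         paste(bad, collapse = ", "))
  (I_S - I_0) / den
}

#' Normalize a FRAP trace to the unrecovered fraction
#'
#' Computes the per-frame spot ratio, determines the pre- and post-bleach
#' reference ratios as the means of \code{n_ref_frames} frames immediately
#' before and after the bleach, and rescales post-bleach frames to
#' \deqn{N(t) = (R_{pre} - R(t)) / (R_{pre} - R_{post}),}
#' the fraction of the bleached amplitude that has not yet recovered: N is
#' about 1 immediately after the bleach and decays toward 1 minus the mobile
#' fraction. Times are measured from the bleach (the time stamp of the last
#' pre-bleach frame). This normalization is invariant to any affine rescaling
#' of the raw ratios.
#'
#' @param trace A \code{\link{frap_trace}}.
#' @param n_ref_frames Number of reference frames on each side of the bleach.
#' @return List with \code{times} (s since bleach, post-bleach frames only),
#'   \code{N}, \code{R_pre}, \code{R_post}, \code{ratios} (all frames) and
#'   the trace's id/condition.
#' @export
normalize_trace <- function(trace, n_ref_frames = 10) {
  stopifnot(inherits(trace, "frap_trace"), n_ref_frames >= 1)
  bi <- attr(trace, "bleach_index")
  n <- nrow(trace)
  if (bi < n_ref_frames)
    stop("need at least ", n_ref_frames, " frames before the bleach")
  if (n - bi < n_ref_frames)
    stop("need at least ", n_ref_frames, " frames after the bleach")
  r <- spot_ratio(trace$I_spot, trace$I_cell, trace$I_bg)
  r_pre <- mean(r[(bi - n_ref_frames + 1):bi])
  r_post <- mean(r[(bi + 1):(bi + n_ref_frames)])
  if (r_pre <= r_post)
    stop("pre-bleach ratio does not exceed post-bleach ratio: no bleach to fit")
  post <- (bi + 1):n
  list(times = trace$time_s[post] - trace$time_s[bi],
       N = (r_pre - r[post]) / (r_pre - r_post),
       R_pre = r_pre, R_post = r_post, ratios = r,
       trace_id = attr(trace, "trace_id"),
       condition = attr(trace, "condition"))
}

frap_curve <- function(t, start, end, tau) {
  start + (start - end) * (exp(-t / tau) - 1)
}

#' Fit the bounded exponential recovery model
#'
#' Fits the normalized unrecovered fraction with the single-exponential model
#' \deqn{N(t) = start + (start - end)(e^{-t/\tau} - 1)}
#' by box-constrained nonlinear least squares (Levenberg-Marquardt), with
#' \code{start} in \[0.9, 1.1\], \code{end} in \[-0.1, 0.4\] and \eqn{\tau > 0}.
#' Several deterministic \eqn{\tau} starting values guard against local
#' minima. The recovery half-time is \eqn{t_{1/2} = \tau \ln 2} and the
#' mobile fraction is \eqn{(start - end)/start}. Fits with \eqn{r^2 < }
#' \code{r2_min} (including degenerate data with zero variance) are flagged
#' \code{excluded}; the fit never errors on finite numeric input.
#'
#' @param times Post-bleach times, s.
#' @param N Normalized unrecovered fraction at those times.
#' @param start_bounds,end_bounds Box constraints for the plateaus.
#' @param tau_starts Deterministic multi-start values for \eqn{\tau}, s.
#' @param r2_min Exclusion threshold on \eqn{r^2} (default 0.4).
#' @param condition,trace_id Labels carried into the result.
#' @return An object of class \code{frap_fit} with elements \code{start},
#'   \code{end}, \code{tau}, \code{t_half}, \code{mobile_fraction},
#'   \code{r_squared}, \code{converged}, \code{excluded},
#'   \code{exclusion_reason}, plus the data and labels. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals} and \code{plot}.
#' @export
fit_recovery <- function(times, N, start_bounds = c(0.9, 1.1),
                         end_bounds = c(-0.1, 0.4),
                         tau_starts = c(20, 60, 180, 600), r2_min = 0.4,
                         condition = NA_character_, trace_id = NA_character_) {
  stopifnot(length(times) == length(N))
  ok <- is.finite(times) & is.finite(N)
  times <- times[ok]; N <- N[ok]
  if (length(times) < 5)
    stop("need at least 5 post-bleach points to fit")
  lower <- c(start_bounds[1], end_bounds[1], 1e-6)
  upper <- c(start_bounds[2], end_bounds[2], Inf)
  resid_fn <- function(p) N - frap_curve(times, p[1], p[2], p[3])
  best <- NULL
  for (tau0 in tau_starts) {
    p0 <- c(mean(start_bounds), mean(end_bounds), tau0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best_ssr) { best <- fit; best_ssr <- ssr }
  }
  converged <- !is.null(best) && best$info %in% 1:4
  if (is.null(best)) {
    par <- c(NA_real_, NA_real_, NA_real_)
    ssr <- NA_real_
  } else {
    par <- unname(best$par)
    ssr <- sum(best$fvec^2)
  }
  sst <- sum((N - mean(N))^2)
  r2 <- if (is.finite(ssr) && sst > 0) 1 - ssr / sst else NA_real_
  excluded <- FALSE
  reason <- NA_character_
  if (!converged) {
    excluded <- TRUE; reason <- "optimizer did not converge"
  } else if (sst == 0) {
    excluded <- TRUE; reason <- "zero variance in N (degenerate trace)"
  } else if (r2 < r2_min) {
    excluded <- TRUE
    reason <- sprintf("r_squared %.3f below %.2f", r2, r2_min)
  }
  structure(
    list(start = par[1], end = par[2], tau = par[3],
         t_half = par[3] * log(2),
         mobile_fraction = if (is.finite(par[1]) && par[1] != 0)
           (par[1] - par[2]) / par[1] else NA_real_,
         r_squared = r2, converged = converged, excluded = excluded,
         exclusion_reason = reason, times = times, N = N,
         condition = condition, trace_id = trace_id, r2_min = r2_min),
    class = "frap_fit"
  )
}

#' Construct a recovery model from known parameters
#'
#' Builds a \code{frap_fit} object directly from model parameters, without
#' data — useful for evaluating the fitted model analytically, e.g. the
#' predicted recovery at a given time for a published half-time and mobile
#' fraction.
#'
#' @param t_half Recovery half-time, s; \eqn{\tau = t_{1/2}/\ln 2}.
#' @param mobile_fraction Mobile fraction; sets \code{end = start * (1 -
#'   mobile_fraction)}.
#' @param start Post-bleach plateau (default 1).
#' @return A converged \code{frap_fit} with no data attached.
#' @export
frap_model <- function(t_half, mobile_fraction, start = 1) {
  stopifnot(t_half > 0, mobile_fraction >= 0, mobile_fraction <= 1,
            start > 0)
  tau <- t_half / log(2)
  end <- start * (1 - mobile_fraction)
  structure(
    list(start = start, end = end, tau = tau, t_half = t_half,
         mobile_fraction = mobile_fraction, r_squared = NA_real_,
         converged = TRUE, excluded = FALSE, exclusion_reason = NA_character_,
         times = numeric(0), N = numeric(0), condition = NA_character_,
         trace_id = "model", r2_min = NA_real_),
    class = "frap_fit"
  )
}

#' Fit a raw FRAP trace end to end
#'
#' Chains \code{\link{normalize_trace}} and \code{\link{fit_recovery}}.
#'
#' @param trace A \code{\link{frap_trace}}.
#' @param n_ref_frames Reference frames per side of the bleach.
#' @param ... Passed to \code{\link{fit_recovery}}.
#' @return A \code{frap_fit}.
#' @export
fit_frap_trace <- function(trace, n_ref_frames = 10, ...) {
  nt <- normalize_trace(trace, n_ref_frames = n_ref_frames)
  fit_recovery(nt$times, nt$N, condition = nt$condition,
               trace_id = nt$trace_id, ...)
}

#' Percent recovery predicted at a time
#'
#' Evaluates the fitted model and reports the recovered percentage of the
#' post-bleach amplitude, \code{100 * (start - N(t)) / start}: 0% at the
#' bleach, approaching \code{100 * mobile_fraction} at long times.
#'
#' @param fit A converged \code{frap_fit}.
#' @param t Time since bleach, s (vectorized).
#' @return Percent recovered.
#' @export
recovery_at <- function(fit, t) {
  stopifnot(inherits(fit, "frap_fit"), isTRUE(fit$converged))
  100 * (fit$start - frap_curve(t, fit$start, fit$end, fit$tau)) / fit$start
}

#' Summarize a group of recovery fits
#'
#' @param fits List of \code{frap_fit}.
#' @param condition Group label; taken from the first fit when missing.
#' @return Object of class \code{frap_group}: \code{condition}, \code{n}
#'   (non-excluded fits only), \code{mean_t_half}, \code{sem_t_half},
#'   \code{mean_mobile_fraction}, \code{t_half} (the retained values),
#'   \code{n_excluded}.
#' @export
aggregate_group <- function(fits, condition = NULL) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "frap_fit")))
  keep <- !vapply(fits, `[[`, TRUE, "excluded")
  if (sum(keep) < 2)
    stop("need at least 2 non-excluded fits to summarize a group")
  if (is.null(condition)) condition <- fits[[1]]$condition
  th <- vapply(fits[keep], `[[`, 0, "t_half")
  mf <- vapply(fits[keep], `[[`, 0, "mobile_fraction")
  structure(
    list(condition = condition, n = sum(keep),
         mean_t_half = mean(th), sem_t_half = sd(th) / sqrt(length(th)),
         mean_mobile_fraction = mean(mf), t_half = th,
         n_excluded = sum(!keep)),
    class = "frap_group"
  )
}

#' @export
print.frap_group <- function(x, ...) {
  cat(sprintf("FRAP group '%s': t1/2 = %.1f +/- %.1f s (mean +/- SEM, n = %d; %d excluded)\n",
              x$condition, x$mean_t_half, x$sem_t_half, x$n, x$n_excluded))
  cat(sprintf("  mean mobile fraction %.1f%%\n",
              100 * x$mean_mobile_fraction))
  invisible(x)
}

#' Compare recovery half-times between two conditions
#'
#' Welch's two-sided unequal-variance t-test on the half-times of the
#' non-excluded fits of each group.
#'
#' @param a,b Lists of \code{frap_fit}.
#' @return List with \code{difference} (mean a minus mean b, s),
#'   \code{p_value}, \code{n_a}, \code{n_b} and the underlying \code{htest}.
#' @export
compare_groups <- function(a, b) {
  ga <- aggregate_group(a)
  gb <- aggregate_group(b)
  ht <- t.test(ga$t_half, gb$t_half)
  list(difference = ga$mean_t_half - gb$mean_t_half,
       p_value = ht$p.value, n_a = ga$n, n_b = gb$n, test = ht)
}

# ---- frap_fit methods -------------------------------------------------------

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<frap_fit> not converged:", x$exclusion_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<frap_fit%s> t1/2 = %.1f s (tau = %.1f s), mobile fraction = %.1f%%\n",
              if (!is.na(x$trace_id)) paste0(" ", x$trace_id) else "",
              x$t_half, x$tau, 100 * x$mobile_fraction))
  if (is.finite(x$r_squared))
    cat(sprintf("  start = %.3f, end = %.3f, r^2 = %.3f%s\n", x$start, x$end,
                x$r_squared,
                if (x$excluded) paste0("  [EXCLUDED: ", x$exclusion_reason, "]")
                else ""))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(start = object$start, end = object$end, tau = object$tau,
    t_half = object$t_half, mobile_fraction = object$mobile_fraction)
}

#' @export
predict.frap_fit <- function(object, times = object$times, ...) {
  frap_curve(times, object$start, object$end, object$tau)
}

#' @export
fitted.frap_fit <- function(object, ...) predict(object)

#' @export
residuals.frap_fit <- function(object, ...) {
  object$N - predict(object)
}

#' @export
summary.frap_fit <- function(object, ...) {
  out <- list(coef = coef(object), r_squared = object$r_squared,
              n = length(object$times), converged = object$converged,
              excluded = object$excluded,
              exclusion_reason = object$exclusion_reason,
              trace_id = object$trace_id, condition = object$condition)
  class(out) <- "summary.frap_fit"
  out
}

#' @export
print.summary.frap_fit <- function(x, ...) {
  cat("Bounded single-exponential FRAP recovery fit\n")
  if (!is.na(x$trace_id)) cat("  trace:", x$trace_id,
                              if (!is.na(x$condition)) paste0(" (", x$condition, ")"), "\n")
  cat(sprintf("  n = %d post-bleach frames, converged = %s\n", x$n,
              x$converged))
  print(round(x$coef, 4))
  cat(sprintf("  r^2 = %.4f%s\n", x$r_squared,
              if (x$excluded) paste0("  [excluded: ", x$exclusion_reason, "]")
              else ""))
  invisible(x)
}

#' @export
plot.frap_fit <- function(x, ...) {
  if (length(x$times) == 0) {
    tt <- seq(0, 5 * x$t_half, length.out = 200)
    plot(tt, predict(x, tt), type = "l", xlab = "time since bleach (s)",
         ylab = "unrecovered fraction N(t)", ...)
    return(invisible(x))
  }
  plot(x$times, x$N, pch = 16, cex = 0.6, col = "grey40",
       xlab = "time since bleach (s)", ylab = "unrecovered fraction N(t)",
       ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  abline(h = x$end, lty = 3)
  invisible(x)
}
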