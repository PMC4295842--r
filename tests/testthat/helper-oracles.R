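# Independent brute-force oracles used to cross-check the implementation.

solve_assignment <- cringdyn:::solve_assignment

# Exhaustive 3-D focus detector: scans every voxel, applies the threshold and
# the 26-neighbourhood maximum condition by explicit loops, then resolves
# lateral min-distance conflicts greedily by descending intensity with
# (z, y, x) tie-break. Only feasible for small stacks.
oracle_detect_foci <- function(stack, threshold_sd = 5,
                               min_separation_px = 3, background = NULL) {
  a <- stack$voxels
  d <- dim(a)
  if (is.null(background)) background <- estimate_background(stack)
  thr <- background[["mean"]] + threshold_sd * background[["sd"]]
  cand <- NULL
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    v <- a[z, y, x]
    if (v <= thr) next
    is_max <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
        next
      if (a[zz, yy, xx] > v) { is_max <- FALSE; break }
    }
    if (is_max) cand <- rbind(cand, c(z, y, x, v))
  }
  if (is.null(cand))
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      peak_intensity = numeric(0)))
  cand <- cand[order(-cand[, 4], cand[, 1], cand[, 2], cand[, 3]), ,
               drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      if ((cand[j, 2] - cand[i, 2])^2 + (cand[j, 3] - cand[i, 3])^2 <
          min_separation_px^2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(z = cand[, 1], y = cand[, 2], x = cand[, 3],
             peak_intensity = cand[, 4])
}

# Minimal assignment cost by permutation enumeration (n <= 7).
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

# Enumerate all injective partial matchings from rows (open track ends) to
# columns (new localizations), returning the one minimizing
# sum(linked distances) + gate * (#unlinked rows + #unlinked cols),
# with links farther than the gate forbidden.
oracle_best_matching <- function(dmat, gate) {
  n_r <- nrow(dmat); n_c <- ncol(dmat)
  best <- list(cost = Inf, match = rep(0L, n_r))
  recurse <- function(r, match, used_c, cost) {
    if (r > n_r) {
      total <- cost + gate * (sum(match == 0L) + (n_c - sum(match > 0L)))
      if (total < best$cost) best <<- list(cost = total, match = match)
      return(invisible())
    }
    recurse(r + 1, { m <- match; m[r] <- 0L; m }, used_c, cost)
    for (j in seq_len(n_c)) {
      if (used_c[j] || dmat[r, j] > gate) next
      recurse(r + 1, { m <- match; m[r] <- j; m },
              { u <- used_c; u[j] <- TRUE; u }, cost + dmat[r, j])
    }
  }
  recurse(1L, rep(0L, n_r), rep(FALSE, n_c), 0)
  best$match
}

# Frame-by-frame linker using the exhaustive matching oracle; same
# objective and conventions as link_tracks, for <= 4 simultaneous molecules.
oracle_link_tracks <- function(localizations, max_displacement = 0.5,
                               min_track_length = 5) {
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  frames <- sort(unique(loc$frame))
  by_frame <- split(seq_len(nrow(loc)), loc$frame)
  track_of <- integer(nrow(loc))
  next_id <- 0L
  open_rows <- integer(0)
  for (fi in seq_along(frames)) {
    rows <- by_frame[[as.character(frames[fi])]]
    contiguous <- fi > 1 && frames[fi] - frames[fi - 1] == 1
    if (!contiguous || length(open_rows) == 0) {
      for (r in rows) { next_id <- next_id + 1L; track_of[r] <- next_id }
      open_rows <- rows
      next
    }
    dmat <- sqrt(outer(loc$x_um[open_rows], loc$x_um[rows], "-")^2 +
                 outer(loc$y_um[open_rows], loc$y_um[rows], "-")^2)
    match <- oracle_best_matching(dmat, max_displacement)
    new_open <- integer(0)
    linked <- logical(length(rows))
    for (k in seq_along(open_rows)) {
      j <- match[k]
      if (j > 0) {
        track_of[rows[j]] <- track_of[open_rows[k]]
        linked[j] <- TRUE
        new_open <- c(new_open, rows[j])
      }
    }
    for (j in which(!linked)) {
      next_id <- next_id + 1L
      track_of[rows[j]] <- next_id
      new_open <- c(new_open, rows[j])
    }
    open_rows <- new_open
  }
  loc$track_id <- track_of
  keep <- names(which(table(loc$track_id) >= min_track_length))
  out <- loc[loc$track_id %in% as.integer(keep),
             c("track_id", "frame", "x_um", "y_um")]
  out[order(out$track_id, out$frame), , drop = FALSE]
}

# Canonical representation of a track set for comparison: one string per
# track listing its (frame, x, y) sequence, sorted.
track_signature <- function(tracks, digits = 9) {
  if (nrow(tracks) == 0) return(character(0))
  sort(unname(vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    paste(sprintf(paste0("%d:%.", digits, "f:%.", digits, "f"),
                  tr$frame, tr$x_um, tr$y_um), collapse = "|")
  }, "")))
}

# Small noisy background stack with optionally rendered foci.
make_test_stack <- function(dims = c(7, 32, 32), bg_mean = 100, bg_sd = 5,
                            foci = NULL, photons = 2000,
                            sigma = c(2, 1, 1), seed = 1,
                            stack_id = "test") {
  set.seed(seed)
  vox <- array(rnorm(prod(dims), bg_mean, bg_sd), dim = dims)
  if (!is.null(foci))
    for (i in seq_len(nrow(foci)))
      vox <- render_focus(vox, unlist(foci[i, ]), sigma, photons)
  image_stack(vox, pixel_size = 304 / 3, z_spacing = 150,
              stack_id = stack_id)
}
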