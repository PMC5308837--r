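#' Subtract the temporal minimum projection from an image stack
#'
#' The per-pixel minimum over all frames captures non-moving background
#' structures; subtracting it (clipping at zero) leaves only moving cells.
#'
#' @param stack an `image_stack` with at least 2 frames.
#' @return background-subtracted `image_stack`.
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 2L)
    stop("background subtraction needs at least 2 frames")
  bg <- Reduce(pmin, stack$frames)
  stack$frames <- lapply(stack$frames, function(f) pmax(f - bg, 0))
  stack
}

#' Detect cells in one frame
#'
#' Applies a Gaussian blur (ImageJ convention: `blur_px` is the Gaussian
#' sigma in pixels, default 2 px) and finds local maxima of the blurred
#' image - pixels strictly greater than all 8 neighbours - above
#' `min_prominence`. The default prominence threshold is five times a
#' robust estimate (MAD) of the blurred image's background spread.
#'
#' @param frame numeric matrix (rows = y, columns = x), normally from a
#'   background-subtracted stack.
#' @param blur_px Gaussian blur sigma, px.
#' @param min_prominence minimum blurred-intensity at a maximum; `NULL`
#'   for the automatic threshold.
#' @return data.frame with columns `x_px`, `y_px` (1-based pixel indices).
#' @export
detect_cells <- function(frame, blur_px = 2, min_prominence = NULL) {
  stopifnot(is.matrix(frame))
  sm <- .gaussian_blur(frame, blur_px)
  # 5 x robust background spread, floored at a tiny fraction of the image
  # maximum so float-level blur ripples never register on noise-free images
  if (is.null(min_prominence))
    min_prominence <- max(5 * mad(sm), 1e-6 * max(sm), .Machine$double.eps)
  ny <- nrow(sm); nx <- ncol(sm)
  if (ny < 3L || nx < 3L) return(data.frame(x_px = numeric(), y_px = numeric()))
  core <- sm[2:(ny - 1L), 2:(nx - 1L)]
  is_max <- core > min_prominence
  # a plateau of tied maxima (e.g. two merged spots symmetric about a pixel
  # boundary) yields exactly one detection: ties are broken towards the
  # pixel earliest in scan order
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- sm[(2:(ny - 1L)) + dy, (2:(nx - 1L)) + dx]
    precedes <- dx < 0L || (dx == 0L && dy < 0L)
    is_max <- is_max & (if (precedes) core > nb else core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(x_px = as.numeric(idx[, 2L] + 1L),
             y_px = as.numeric(idx[, 1L] + 1L))
}

# separable Gaussian blur via EBImage
.gaussian_blur <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  # EBImage uses (x, y) indexing; transpose in and out
  m <- EBImage::gblur(t(frame), sigma = sigma)
  t(EBImage::imageData(m))
}

#' Detect cells in every frame of a stack
#'
#' @param stack an `image_stack` (background-subtracted).
#' @inheritParams detect_cells
#' @return data.frame with columns `frame`, `x_px`, `y_px`.
#' @export
detect_stack <- function(stack, blur_px = 2, min_prominence = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  out <- lapply(seq_along(stack$frames), function(f) {
    d <- detect_cells(stack$frames[[f]], blur_px, min_prominence)
    if (nrow(d)) cbind(frame = f, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(frame = integer(), x_px = numeric(),
                               y_px = numeric()) else out
}

#' Link per-frame detections into swimming tracks
#'
#' Motion-predicted nearest-neighbour linking: each live track predicts its
#' next position by linear extrapolation from its last two points (its last
#' point alone if it has only one) and claims the nearest detection to that
#' prediction within `max_link` pixels. Conflicts are resolved greedily in
#' ascending predicted-distance order (ties broken on coordinates, so the
#' result is independent of detection order within a frame); the losing
#' track treats the detection as absent. Unclaimed detections seed new
#' tracks; a track with no match is terminated permanently (no gap
#' closing).
#'
#' @param detections data.frame from [detect_stack()] (`frame`, `x_px`,
#'   `y_px`).
#' @param max_link maximum connection distance, px (default 15).
#' @param optics optional [optics_model()]; when given, tracks are returned
#'   in um and seconds, otherwise in px and frames.
#' @param n_frames total number of frames (defaults to `max(frame)`).
#' @return list of tracks; each a data.frame with `time`, `x`, `y` (um and
#'   s when `optics` given) plus `frame`, carrying attribute `frame_dt`.
#' @export
link_tracks <- function(detections, max_link = 15, optics = NULL,
                        n_frames = NULL) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  if (is.null(n_frames)) n_frames <- if (nrow(detections)) max(detections$frame) else 0L
  live <- list()    # each: list(xs, ys, frames)
  done <- list()
  for (f in seq_len(n_frames)) {
    det <- detections[detections$frame == f, , drop = FALSE]
    dx <- det$x_px; dy <- det$y_px
    nd <- length(dx)
    claimed_det <- rep(FALSE, nd)
    matched_track <- rep(FALSE, length(live))
    if (length(live) && nd) {
      pred <- vapply(live, function(tr) {
        np <- length(tr$xs)
        if (np >= 2L)
          c(2 * tr$xs[np] - tr$xs[np - 1L], 2 * tr$ys[np] - tr$ys[np - 1L])
        else c(tr$xs[np], tr$ys[np])
      }, numeric(2L))
      cand <- NULL
      for (ti in seq_along(live)) {
        d2 <- sqrt((dx - pred[1L, ti])^2 + (dy - pred[2L, ti])^2)
        ok <- which(d2 <= max_link)
        if (length(ok))
          cand <- rbind(cand, cbind(track = ti, det = ok, dist = d2[ok],
                                    x = dx[ok], y = dy[ok]))
      }
      if (!is.null(cand)) {
        ord <- order(cand[, "dist"], cand[, "x"], cand[, "y"], cand[, "track"])
        for (k in ord) {
          ti <- cand[k, "track"]; di <- cand[k, "det"]
          if (matched_track[ti] || claimed_det[di]) next
          matched_track[ti] <- TRUE
          claimed_det[di] <- TRUE
          live[[ti]]$xs <- c(live[[ti]]$xs, dx[di])
          live[[ti]]$ys <- c(live[[ti]]$ys, dy[di])
          live[[ti]]$frames <- c(live[[ti]]$frames, f)
        }
      }
    }
    # terminate unmatched tracks
    if (length(live)) {
      ended <- !matched_track
      done <- c(done, live[ended])
      live <- live[!ended]
    }
    # new tracks from unclaimed detections (stable order: by x then y)
    if (nd) {
      new_idx <- which(!claimed_det)
      new_idx <- new_idx[order(dx[new_idx], dy[new_idx])]
      for (di in new_idx)
        live <- c(live, list(list(xs = dx[di], ys = dy[di], frames = f)))
    }
  }
  done <- c(done, live)
  # stable ordering: by first frame, then first coordinates
  if (length(done)) {
    key <- vapply(done, function(tr) c(tr$frames[1L], tr$xs[1L], tr$ys[1L]),
                  numeric(3L))
    done <- done[order(key[1L, ], key[2L, ], key[3L, ])]
  }
  frame_dt <- if (!is.null(optics)) 1 / optics$frame_rate else 1
  scale <- if (!is.null(optics)) optics$pixel_size else 1
  lapply(done, function(tr) {
    out <- data.frame(time = (tr$frames - 1L) * frame_dt,
                      x = (tr$xs - 1L) * scale, y = (tr$ys - 1L) * scale,
                      frame = tr$frames)
    attr(out, "frame_dt") <- frame_dt
    class(out) <- c("cell_track", "data.frame")
    out
  })
}

#' Build a track directly from coordinates
#'
#' Convenience constructor for synthesized tracks (e.g. analytic circles)
#' without going through images.
#'
#' @param time,x,y equal-length numeric vectors; `time` uniformly spaced, s.
#' @return a `cell_track` data.frame.
#' @export
cell_track <- function(time, x, y) {
  stopifnot(length(time) == length(x), length(x) == length(y),
            length(time) >= 2L)
  out <- data.frame(time = time, x = x, y = y,
                    frame = seq_along(time))
  attr(out, "frame_dt") <- time[2L] - time[1L]
  class(out) <- c("cell_track", "data.frame")
  out
}

#' Speed and directional persistence of one track
#'
#' Velocities are sampled with an evaluation window `eval_dt` (default 2 s)
#' at every frame offset (overlapping windows):
#' \eqn{v_t = (x_{t+\delta t} - x_t)/\delta t}. Mean speed is the mean of
#' `|v_t|`; directional persistence is the mean cosine of the angle between
#' `v_t` and `v_{t+\delta t}` - 1 for straight swimming, 0 for
#' uncorrelated, -1 for oscillating movement. Zero-length velocity vectors
#' are skipped.
#'
#' @param track a `cell_track`.
#' @param eval_dt evaluation step, s (default 2).
#' @return list with `mean_speed` (um/s), `persistence`, `duration` (s).
#' @export
track_statistics <- function(track, eval_dt = 2) {
  stopifnot(inherits(track, "cell_track"))
  frame_dt <- attr(track, "frame_dt")
  k <- as.integer(round(eval_dt / frame_dt))
  if (k < 1L) stop("'eval_dt' shorter than the frame interval")
  np <- nrow(track)
  duration <- (np - 1L) * frame_dt
  if (np < 2L * k + 1L)
    stop("track too short for two velocity samples at this evaluation step")
  vx <- (track$x[(1L + k):np] - track$x[1:(np - k)]) / eval_dt
  vy <- (track$y[(1L + k):np] - track$y[1:(np - k)]) / eval_dt
  spd <- sqrt(vx^2 + vy^2)
  nv <- length(vx)
  i1 <- 1:(nv - k); i2 <- (1L + k):nv
  dot <- vx[i1] * vx[i2] + vy[i1] * vy[i2]
  den <- spd[i1] * spd[i2]
  ok <- den > 0
  list(mean_speed = mean(spd),
       persistence = if (any(ok)) mean(dot[ok] / den[ok]) else NA_real_,
       duration = duration)
}

#' Duration-weighted population statistics of a track set
#'
#' Tracks shorter than `min_duration` (default 5 s) are excluded. All
#' population statistics are weighted by track duration in seconds, to
#' eliminate bias towards behaviours that generate short tracks: the
#' weighted mean speed and persistence, the duration-weighted fraction of
#' tracks above each persistence threshold, and the weighted mean
#' persistence of tracks above each speed threshold.
#'
#' @param tracks list of `cell_track`.
#' @param eval_dt evaluation step, s.
#' @param min_duration minimum track duration, s.
#' @param persistence_thresholds,speed_thresholds thresholds for the
#'   fraction/conditional summaries.
#' @return list with `per_track` (data.frame), `n_tracks`, `mean_speed`,
#'   `mean_persistence`, `persistence_fraction` (named vector),
#'   `speed_conditional_persistence` (named vector). Empty input returns
#'   `n_tracks = 0` with NA statistics.
#' @export
population_summary <- function(tracks, eval_dt = 2, min_duration = 5,
                               persistence_thresholds = c(0.80, 0.90, 0.95),
                               speed_thresholds = c(5, 8, 10)) {
  rows <- list()
  for (tr in tracks) {
    frame_dt <- attr(tr, "frame_dt")
    dur <- (nrow(tr) - 1L) * frame_dt
    k <- as.integer(round(eval_dt / frame_dt))
    if (dur < min_duration || nrow(tr) < 2L * k + 1L) next
    st <- track_statistics(tr, eval_dt)
    rows[[length(rows) + 1L]] <- data.frame(
      mean_speed = st$mean_speed, persistence = st$persistence,
      duration = st$duration)
  }
  pf_names <- paste0("gt_", persistence_thresholds)
  sc_names <- paste0("gt_", speed_thresholds)
  if (!length(rows)) {
    return(list(per_track = data.frame(mean_speed = numeric(),
                                       persistence = numeric(),
                                       duration = numeric()),
                n_tracks = 0L, mean_speed = NA_real_,
                mean_persistence = NA_real_,
                persistence_fraction = setNames(rep(NA_real_,
                  length(persistence_thresholds)), pf_names),
                speed_conditional_persistence = setNames(rep(NA_real_,
                  length(speed_thresholds)), sc_names)))
  }
  per <- do.call(rbind, rows)
  w <- per$duration
  ok <- !is.na(per$persistence)
  pf <- vapply(persistence_thresholds, function(th)
    sum(w[ok & per$persistence > th]) / sum(w), numeric(1L))
  sc <- vapply(speed_thresholds, function(th) {
    sel <- ok & per$mean_speed > th
    if (!any(sel)) NA_real_
    else sum(w[sel] * per$persistence[sel]) / sum(w[sel])
  }, numeric(1L))
  list(per_track = per, n_tracks = nrow(per),
       mean_speed = sum(w * per$mean_speed) / sum(w),
       mean_persistence = sum(w[ok] * per$persistence[ok]) / sum(w[ok]),
       persistence_fraction = setNames(pf, pf_names),
       speed_conditional_persistence = setNames(sc, sc_names))
}

#' Directional persistence autocorrelation curve
#'
#' The population mean cosine of the angle between velocities `v_t` and
#' `v_(t+lag)` (velocities sampled with a short base window, default
#' 0.5 s), evaluated over a ladder of lags. The shape of this curve - a
#' sharp early decay from beat/rotation-scale reciprocating movement
#' followed by a slow decay - motivates evaluating persistence at a 2 s
#' step.
#'
#' @param tracks list of `cell_track`.
#' @param base_dt velocity sampling window, s (default 0.5).
#' @param lags evaluation lags, s (default 0 to 10 s).
#' @return data.frame with `lag` (s), `autocorrelation`, `n_pairs`.
#' @export
persistence_autocorrelation <- function(tracks, base_dt = 0.5,
                                        lags = seq(0, 10, by = 0.5)) {
  res <- data.frame(lag = lags, autocorrelation = NA_real_, n_pairs = 0L)
  for (li in seq_along(lags)) {
    tot <- 0; cnt <- 0L
    for (tr in tracks) {
      frame_dt <- attr(tr, "frame_dt")
      k <- as.integer(round(base_dt / frame_dt))
      kl <- as.integer(round(lags[li] / frame_dt))
      np <- nrow(tr)
      if (k < 1L || np < k + kl + 1L) next
      vx <- (tr$x[(1L + k):np] - tr$x[1:(np - k)]) / base_dt
      vy <- (tr$y[(1L + k):np] - tr$y[1:(np - k)]) / base_dt
      nv <- length(vx)
      if (nv < kl + 1L) next
      i1 <- 1:(nv - kl); i2 <- (1L + kl):nv
      dot <- vx[i1] * vx[i2] + vy[i1] * vy[i2]
      den <- sqrt(vx[i1]^2 + vy[i1]^2) * sqrt(vx[i2]^2 + vy[i2]^2)
      ok <- den > 0
      tot <- tot + sum(dot[ok] / den[ok])
      cnt <- cnt + sum(ok)
    }
    if (cnt > 0L) {
      res$autocorrelation[li] <- tot / cnt
      res$n_pairs[li] <- cnt
    }
  }
  res
}

#' Write tracks to CSV
#'
#' @param tracks list of `cell_track`.
#' @param path output CSV path (`track_id, frame, time_s, x_um, y_um`).
#' @return the path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(seq_along(tracks), function(i)
    data.frame(track_id = i, frame = tracks[[i]]$frame,
               time_s = tracks[[i]]$time, x_um = tracks[[i]]$x,
               y_um = tracks[[i]]$y))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), time_s = numeric(),
               x_um = numeric(), y_um = numeric())
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
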