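#' Optics model for synthetic dark-field videomicrographs
#'
#' Describes the low-magnification dark-field acquisition being emulated:
#' 5 Hz frame rate, 0.65 um/px, and point-like cells whose detectability
#' falls off with distance from the focal plane - constant within
#' `in_focus_halfwidth` um of the plane, then decaying exponentially with
#' length scale `detectability_decay_length`. Each cell is rendered as a
#' Gaussian spot whose width grows linearly with defocus
#' (`psf_sigma = psf_sigma0 + psf_defocus_coefficient * |z - focal|`).
#'
#' @param pixel_size um per pixel (default 0.65).
#' @param frame_rate Hz (default 5).
#' @param image_size `c(nx, ny)` pixels (x = columns, y = rows).
#' @param focal_plane_z focal plane position, um.
#' @param in_focus_halfwidth plateau half-width of detectability, um
#'   (default 10).
#' @param detectability_decay_length exponential decay length beyond the
#'   plateau, um (default 5).
#' @param psf_sigma0 in-focus Gaussian spot sigma, px (default 1.5).
#' @param psf_defocus_coefficient spot broadening with defocus, px/um.
#' @param peak_intensity in-focus spot amplitude, 16-bit counts.
#' @param background_level constant background, counts.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd gaussian noise sd, counts (used when
#'   `noise_model = "gaussian"`).
#' @return object of class `optics_model`.
#' @export
optics_model <- function(pixel_size = 0.65, frame_rate = 5,
                         image_size = c(256L, 256L), focal_plane_z = 50,
                         in_focus_halfwidth = 10,
                         detectability_decay_length = 5,
                         psf_sigma0 = 1.5, psf_defocus_coefficient = 0.05,
                         peak_intensity = 20000, background_level = 1000,
                         noise_model = c("none", "gaussian", "poisson"),
                         noise_sd = 50) {
  stopifnot(pixel_size > 0, frame_rate > 0, length(image_size) == 2L,
            all(image_size >= 2L), in_focus_halfwidth > 0,
            detectability_decay_length > 0, psf_sigma0 > 0,
            psf_defocus_coefficient >= 0, peak_intensity > 0,
            background_level >= 0)
  structure(list(pixel_size = pixel_size, frame_rate = frame_rate,
                 image_size = as.integer(image_size),
                 focal_plane_z = focal_plane_z,
                 in_focus_halfwidth = in_focus_halfwidth,
                 detectability_decay_length = detectability_decay_length,
                 psf_sigma0 = psf_sigma0,
                 psf_defocus_coefficient = psf_defocus_coefficient,
                 peak_intensity = peak_intensity,
                 background_level = background_level,
                 noise_model = match.arg(noise_model),
                 noise_sd = noise_sd),
            class = "optics_model")
}

# amplitude attenuation: plateau then exponential decay with defocus
.defocus_amplitude <- function(dz, optics) {
  excess <- pmax(0, abs(dz) - optics$in_focus_halfwidth)
  exp(-excess / optics$detectability_decay_length)
}

#' Render one dark-field frame from 3-D cell positions
#'
#' Each cell is drawn as a Gaussian spot at its (x, y) pixel position with
#' amplitude attenuated by defocus (see [optics_model()]). Cells outside
#' the field of view are simply not drawn. Intensities are clipped to the
#' 16-bit range.
#'
#' @param positions numeric matrix with columns x, y, z (um); zero rows
#'   give a uniform background frame.
#' @param optics an [optics_model()].
#' @return numeric matrix (`ny` rows x `nx` columns) of counts in
#'   \[0, 65535\]; rows index y, columns x.
#' @export
render_frame <- function(positions, optics) {
  stopifnot(inherits(optics, "optics_model"))
  positions <- matrix(as.numeric(positions), ncol = 3L)
  if (nrow(positions) > 0 && !all(is.finite(positions)))
    stop("non-finite positions")
  nx <- optics$image_size[1L]; ny <- optics$image_size[2L]
  img <- matrix(optics$background_level, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(positions))) {
    px <- positions[i, 1L] / optics$pixel_size + 1
    py <- positions[i, 2L] / optics$pixel_size + 1
    dz <- positions[i, 3L] - optics$focal_plane_z
    amp <- optics$peak_intensity * .defocus_amplitude(dz, optics)
    sigma <- optics$psf_sigma0 + optics$psf_defocus_coefficient * abs(dz)
    r <- ceiling(4 * sigma)
    cx <- round(px); cy <- round(py)
    if (cx < 1 - r || cx > nx + r || cy < 1 - r || cy > ny + r) next
    xs <- max(1L, cx - r):min(nx, cx + r)
    ys <- max(1L, cy - r):min(ny, cy + r)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-((xs - px)^2) / (2 * sigma^2))
    gy <- exp(-((ys - py)^2) / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx)
  }
  if (optics$noise_model == "gaussian") {
    img <- img + matrix(rnorm(length(img), 0, optics$noise_sd), ny, nx)
  } else if (optics$noise_model == "poisson") {
    img <- matrix(rpois(length(img), pmax(0, img)), ny, nx)
  }
  pmin(pmax(img, 0), 65535)
}

#' Render a trajectory set into a synthetic image stack
#'
#' Produces one frame per `1 / frame_rate` seconds, subsampling the
#' trajectories accordingly (the default simulation step of 0.2 s matches
#' the 5 Hz frame rate exactly; a 512-frame stack at 5 Hz spans 102.4 s).
#' The trajectory time base must divide the frame interval exactly.
#'
#' @param trajectories list of `swim_trajectory` (or data.frames with
#'   `time`, `x`, `y`, `z` columns), on a common uniform time base.
#' @param optics an [optics_model()].
#' @param n_frames number of frames; default: as many as the trajectories
#'   cover.
#' @return object of class `image_stack`: list with `frames` (list of
#'   matrices) and `optics`.
#' @export
render_stack <- function(trajectories, optics, n_frames = NULL) {
  stopifnot(inherits(optics, "optics_model"), length(trajectories) >= 1L)
  tvec <- trajectories[[1L]]$time
  traj_dt <- tvec[2L] - tvec[1L]
  frame_dt <- 1 / optics$frame_rate
  stride <- frame_dt / traj_dt
  if (abs(stride - round(stride)) > 1e-9)
    stop("trajectory time step must divide the frame interval")
  stride <- as.integer(round(stride))
  max_frames <- (length(tvec) - 1L) %/% stride + 1L
  # default: one frame per frame interval covered (a 102.4 s trajectory at
  # 5 Hz gives 512 frames, the final sample marking the end of the last one)
  if (is.null(n_frames)) n_frames <- max(1L, max_frames - 1L)
  if (n_frames > max_frames)
    stop("trajectories too short for the requested number of frames")
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    idx <- (f - 1L) * stride + 1L
    pos <- t(vapply(trajectories, function(tr)
      c(tr$x[idx], tr$y[idx], tr$z[idx]), numeric(3L)))
    frames[[f]] <- render_frame(pos, optics)
  }
  structure(list(frames = frames, optics = optics), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("image_stack: %d frames of %d x %d px, %.3g um/px, %g Hz\n",
              length(x$frames), d[2L], d[1L], x$optics$pixel_size,
              x$optics$frame_rate))
  invisible(x)
}

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' Pixel size (um) and frame rate (Hz) are recorded in the TIFF image
#' description tag.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  desc <- sprintf("chiroswim pixel_size_um=%g frame_rate_hz=%g",
                  stack$optics$pixel_size, stack$optics$frame_rate)
  imgs <- lapply(stack$frames, function(f) {
    attr(f, "description") <- desc
    f / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Accepts any multi-page grayscale TIFF. Pixel size and frame rate are
#' taken from the description tag written by [write_image_stack()] when
#' present, otherwise from the arguments.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_rate fallback metadata when the file carries
#'   none.
#' @return an `image_stack` (counts on the 16-bit scale).
#' @export
read_image_stack <- function(path, pixel_size = 0.65, frame_rate = 5) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  desc <- attr(pages[[1L]], "description")
  if (!is.null(desc) && grepl("pixel_size_um=", desc)) {
    pixel_size <- as.numeric(sub(".*pixel_size_um=([0-9.eE+-]+).*", "\\1", desc))
    frame_rate <- as.numeric(sub(".*frame_rate_hz=([0-9.eE+-]+).*", "\\1", desc))
  }
  frames <- lapply(pages, function(p) {
    m <- if (length(dim(p)) == 3L) p[, , 1L] else p
    m * 65535
  })
  d <- dim(frames[[1L]])
  optics <- optics_model(pixel_size = pixel_size, frame_rate = frame_rate,
                         image_size = c(d[2L], d[1L]))
  structure(list(frames = frames, optics = optics), class = "image_stack")
}
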