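#' Elliptical cell/nucleus geometry for synthetic microscopy frames
#'
#' @param width,height frame size in pixels.
#' @param cell_center,cell_axes center (x, y) and semi-axes of the cell
#'   ellipse, pixels.
#' @param nucleus_center,nucleus_axes same for the nucleus; the nucleus
#'   ellipse must lie strictly inside the cell ellipse.
#' @return object of class `frame_geometry` with the two logical masks.
#' @export
frame_geometry <- function(width = 96, height = 96,
                           cell_center = c(48, 48), cell_axes = c(40, 32),
                           nucleus_center = c(54, 46),
                           nucleus_axes = c(16, 13)) {
  inside <- function(cx, cy, ax, ay) {
    x <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
    y <- matrix(seq_len(height), nrow = height, ncol = width)
    ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
  }
  cell <- inside(cell_center[1], cell_center[2], cell_axes[1], cell_axes[2])
  nuc <- inside(nucleus_center[1], nucleus_center[2],
                nucleus_axes[1], nucleus_axes[2])
  if (any(nuc & !cell)) stop("nucleus ellipse must lie inside the cell ellipse")
  # strict containment: the nucleus boundary must not touch the cell boundary
  th <- seq(0, 2 * pi, length.out = 360)
  bx <- nucleus_center[1] + nucleus_axes[1] * cos(th)
  by <- nucleus_center[2] + nucleus_axes[2] * sin(th)
  if (any(((bx - cell_center[1]) / cell_axes[1])^2 +
          ((by - cell_center[2]) / cell_axes[2])^2 >= 1))
    stop("nucleus ellipse must lie strictly inside the cell ellipse")
  structure(list(width = width, height = height,
                 cell_mask = cell, nucleus_mask = nuc),
            class = "frame_geometry")
}

#' Render a synthetic time-lapse frame stack from a kinetic ground truth
#'
#' Partitions a fixed fluorophore budget between nucleus and cytoplasm
#' according to the noiseless concentration series of the kinetic model,
#' paints uniform compartment intensities on elliptical masks, adds an
#' affine background plane, and (optionally) Poisson shot noise per pixel.
#' Ground-truth masks and the noiseless per-frame nuclear signal fraction
#' are returned so that quantification can be validated roundtrip.
#'
#' @param spec a [cell_sim_spec()]; its kinetic truth drives the partition.
#' @param geometry a [frame_geometry()].
#' @param total_intensity photon budget per frame distributed over the cell.
#' @param background length-3 numeric `c(b0, bx, by)`: background plane
#'   `b0 + bx*x + by*y` added to every pixel (counts).
#' @param shot_noise if `TRUE` each pixel is replaced by a Poisson draw with
#'   its noiseless mean.
#' @return object of class `frame_stack`: list with `frames` (list of
#'   height-by-width matrices), `times` (absolute seconds), `phases`,
#'   `nucleus_mask`, `cell_mask`, and `truth` (data frame with the per-frame
#'   noiseless nuclear fraction `N_frac` and the concentration series).
#' @export
gen_frames <- function(spec, geometry = frame_geometry(),
                       total_intensity = 2e4,
                       background = c(10, 0, 0),
                       shot_noise = TRUE) {
  stopifnot(inherits(spec, "cell_sim_spec"), inherits(geometry, "frame_geometry"))
  conc <- .cell_conc(spec)
  nuc <- geometry$nucleus_mask
  cyt <- geometry$cell_mask & !nuc
  A_n <- sum(nuc); A_c <- sum(cyt)
  x <- matrix(seq_len(geometry$width), nrow = geometry$height,
              ncol = geometry$width, byrow = TRUE)
  y <- matrix(seq_len(geometry$height), nrow = geometry$height,
              ncol = geometry$width)
  bg <- background[1] + background[2] * x + background[3] * y

  # amount fractions from concentrations x compartment areas
  N_frac <- A_n * conc$N_conc / (A_n * conc$N_conc + A_c * conc$C_conc)

  frames <- withr::with_seed(spec$seed, lapply(seq_len(nrow(conc)), function(i) {
    f <- matrix(0, geometry$height, geometry$width)
    f[nuc] <- total_intensity * N_frac[i] / A_n
    f[cyt] <- total_intensity * (1 - N_frac[i]) / A_c
    f <- f + bg
    if (shot_noise) f[] <- stats::rpois(length(f), lambda = f)
    f
  }))
  structure(list(frames = frames, times = conc$t_abs, phases = conc$phase,
                 nucleus_mask = nuc, cell_mask = geometry$cell_mask,
                 truth = cbind(conc, N_frac = N_frac),
                 background = background),
            class = "frame_stack")
}

#' Write a frame stack to disk as multi-page TIFF plus sidecar files
#'
#' Frames go to `stack.tif` (32-bit float TIFF, one page per frame), the
#' masks to `nucleus_mask.png` / `cell_mask.png`, and the frame table
#' (index, absolute time, phase) to `frames.csv`.
#'
#' @param stack a `frame_stack`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(unlist(lapply(stack$frames, max)), 1)
  paths <- list(stack = file.path(dir, "stack.tif"),
                nucleus = file.path(dir, "nucleus_mask.png"),
                cell = file.path(dir, "cell_mask.png"),
                frames = file.path(dir, "frames.csv"))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / scale),
                  paths$stack, bits.per.sample = 32)
  png::writePNG(stack$nucleus_mask * 1, paths$nucleus)
  png::writePNG(stack$cell_mask * 1, paths$cell)
  utils::write.csv(data.frame(frame = seq_along(stack$times),
                              t_s = stack$times, phase = stack$phases,
                              intensity_scale = scale),
                   paths$frames, row.names = FALSE)
  invisible(paths)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param dir directory holding `stack.tif`, the mask PNGs and `frames.csv`.
#' @return a `frame_stack` (without ground truth).
#' @export
read_frame_stack <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "frames.csv"))
  frames <- tiff::readTIFF(file.path(dir, "stack.tif"), all = TRUE)
  scale <- if ("intensity_scale" %in% names(tab)) tab$intensity_scale[1] else 1
  frames <- lapply(frames, function(f) f * scale)
  structure(list(frames = frames, times = tab$t_s, phases = tab$phase,
                 nucleus_mask = png::readPNG(file.path(dir, "nucleus_mask.png")) > 0.5,
                 cell_mask = png::readPNG(file.path(dir, "cell_mask.png")) > 0.5),
            class = "frame_stack")
}
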