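#' Nucleus/cell mask pair
#'
#' Validated pair of binary masks used to integrate compartment signal:
#' the nucleus mask must be non-empty and contained in the (non-empty)
#' cell mask, and both must share the frame shape. The cytoplasm is
#' defined as cell minus nucleus.
#'
#' @param nucleus,cell logical (or 0/1) matrices of identical dimensions.
#' @return object of class `mask_pair`.
#' @export
mask_pair <- function(nucleus, cell) {
  nucleus <- nucleus > 0.5
  cell <- cell > 0.5
  if (!identical(dim(nucleus), dim(cell))) stop("mask shapes differ")
  if (!any(nucleus)) stop("nucleus mask is empty")
  if (!any(cell)) stop("cell mask is empty")
  if (any(nucleus & !cell)) stop("nucleus mask must be contained in cell mask")
  structure(list(nucleus = nucleus, cell = cell), class = "mask_pair")
}

#' Subtract the background level from one frame
#'
#' Background is estimated as the median pixel intensity of a region
#' outside the cell and subtracted from the whole frame; negative results
#' are clipped at zero.
#'
#' @param frame numeric intensity matrix.
#' @param background_region logical matrix (same shape) marking background
#'   pixels, disjoint from the cell.
#' @return corrected frame.
#' @export
background_correct <- function(frame, background_region) {
  background_region <- background_region > 0.5
  if (!identical(dim(frame), dim(background_region)))
    stop("background region shape differs from frame")
  if (!any(background_region)) stop("background region is empty")
  pmax(frame - stats::median(frame[background_region]), 0)
}

#' Normalized nuclear and cytoplasmic signal of one frame
#'
#' Integrates the (background-corrected) intensities over the nucleus and
#' whole-cell masks and normalizes both compartment signals by the total
#' cell signal, the proxy used for the compartment concentrations:
#' `N_norm = sum(nucleus)/sum(cell)`,
#' `C_norm = (sum(cell) - sum(nucleus))/sum(cell)`. The two always add to 1.
#'
#' @param frame background-corrected intensity matrix.
#' @param masks a [mask_pair()].
#' @return named numeric vector `c(N_norm = , C_norm = )`.
#' @export
quantify_frame <- function(frame, masks) {
  stopifnot(inherits(masks, "mask_pair"))
  if (!identical(dim(frame), dim(masks$cell)))
    stop("frame shape differs from masks")
  total <- sum(frame[masks$cell])
  if (!is.finite(total) || total <= 0) stop("zero total cell intensity")
  n <- sum(frame[masks$nucleus]) / total
  c(N_norm = n, C_norm = (total - sum(frame[masks$nucleus])) / total)
}

#' Assemble a quantified time course from a frame stack
#'
#' Runs optional background correction and per-frame quantification over a
#' stack, emits the nucleus-to-cytoplasm ratio, and re-zeroes the clock at
#' the first recovery frame (light off). Frames whose cytoplasmic signal is
#' zero get an infinite ratio and are flagged in `valid`.
#'
#' @param stack a `frame_stack` (from [gen_frames()] or [read_frame_stack()]).
#' @param masks a [mask_pair()]; defaults to the stack's own ground-truth
#'   masks when present.
#' @param background_region optional logical matrix of background pixels
#'   (disjoint from the cell mask) used to correct every frame.
#' @return a `timecourse` data frame: `phase`, `t_s` (per-phase clock),
#'   `t_abs`, `N_norm`, `C_norm`, `ratio`, `valid`.
#' @export
build_timecourse <- function(stack, masks = NULL, background_region = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(masks)) {
    if (is.null(stack$nucleus_mask)) stop("no nucleus mask available")
    if (is.null(stack$cell_mask)) stop("no cell mask available")
    masks <- mask_pair(stack$nucleus_mask, stack$cell_mask)
  }
  if (!is.null(background_region) && any(background_region > 0.5 & masks$cell))
    stop("background region overlaps the cell mask")
  q <- vapply(seq_along(stack$frames), function(i) {
    f <- stack$frames[[i]]
    if (!is.null(background_region)) f <- background_correct(f, background_region)
    tryCatch(quantify_frame(f, masks),
             error = function(e) stop(sprintf("frame %d: %s", i,
                                              conditionMessage(e)), call. = FALSE))
  }, numeric(2))
  phase <- as.character(stack$phases)
  t_abs <- stack$times
  if (any(diff(t_abs) <= 0)) stop("frame timestamps must be strictly increasing")
  t_s <- t_abs
  rec <- phase == "recovery"
  if (any(rec)) t_s[rec] <- t_abs[rec] - t_abs[which(rec)[1]]
  ratio <- q["N_norm", ] / q["C_norm", ]
  tc <- data.frame(phase = phase, t_s = t_s, t_abs = t_abs,
                   N_norm = q["N_norm", ], C_norm = q["C_norm", ],
                   ratio = ratio, valid = is.finite(ratio))
  class(tc) <- c("timecourse", "data.frame")
  tc
}

#' Write / read time courses as CSV
#'
#' @param tc a `timecourse` data frame.
#' @param path CSV file path.
#' @return `write_timecourse` returns `path` invisibly; `read_timecourse`
#'   returns a `timecourse`.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.csv(path)
  class(tc) <- c("timecourse", "data.frame")
  tc
}
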