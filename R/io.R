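# Frame-set I/O: multi-page grayscale TIFF stacks (one per channel) plus a
# per-bead ground-truth CSV. Intensities are stored as unsigned integers at
# the configured bit depth, so a write/read round trip quantizes values to
# the nearest integer a.u.

#' Write a frame set to TIFF stacks and a truth CSV
#'
#' @param frames A `frame_set` from [render_frames()].
#' @param localization_path,fluorescence_path Output TIFF paths (multi-page,
#'   grayscale, bit depth from the frame set's optics).
#' @param truth_path Optional CSV path for the ground-truth table.
#' @return Invisibly, the paths written.
#' @export
write_frameset <- function(frames, localization_path, fluorescence_path,
                           truth_path = NULL) {
  optics <- frames$optics
  maxval <- 2^optics$bit_depth - 1
  scale <- function(frs) lapply(frs, function(m) pmin(pmax(m / maxval, 0), 1))
  tiff::writeTIFF(scale(frames$localization_frames), localization_path,
                  bits.per.sample = optics$bit_depth, compression = "none")
  tiff::writeTIFF(scale(frames$fluorescence_frames), fluorescence_path,
                  bits.per.sample = optics$bit_depth, compression = "none")
  if (!is.null(truth_path))
    utils::write.csv(frames$truth_table, truth_path, row.names = FALSE)
  invisible(c(localization_path, fluorescence_path, truth_path))
}

#' Read a frame set from TIFF stacks
#'
#' @param localization_path,fluorescence_path Multi-page grayscale TIFF
#'   paths, co-registered 1:1.
#' @param bit_depth Bit depth used at write time (rescales the unit-range
#'   TIFF samples back to a.u.).
#' @return A list with `localization_frames` and `fluorescence_frames`
#'   (numeric matrices in a.u.), usable by [detect_frameset()].
#' @export
read_frameset <- function(localization_path, fluorescence_path,
                          bit_depth = 16L) {
  maxval <- 2^bit_depth - 1
  rd <- function(path) {
    frs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (is.matrix(frs)) frs <- list(frs)
    lapply(frs, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m * maxval
    })
  }
  loc <- rd(localization_path)
  flu <- rd(fluorescence_path)
  if (length(loc) != length(flu))
    db_stop("localization and fluorescence stacks have different page counts",
            "digibead_structural_error")
  list(localization_frames = loc, fluorescence_frames = flu)
}
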