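# Circular bead detection via a gradient (phase-coded style) circular Hough
# accumulator, plus per-bead maximum fluorescence extraction.

# Sobel gradients with replicate edge padding. Returns d/dcol (gx) and
# d/drow (gy) so that (gx, gy) points toward increasing intensity.
sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  gx <- (p[1:h, 3:(w + 2L)] - p[1:h, 1:w]) +
    2 * (p[2:(h + 1L), 3:(w + 2L)] - p[2:(h + 1L), 1:w]) +
    (p[3:(h + 2L), 3:(w + 2L)] - p[3:(h + 2L), 1:w])
  gy <- (p[3:(h + 2L), 1:w] - p[1:h, 1:w]) +
    2 * (p[3:(h + 2L), 2:(w + 1L)] - p[1:h, 2:(w + 1L)]) +
    (p[3:(h + 2L), 3:(w + 2L)] - p[1:h, 3:(w + 2L)])
  list(gx = gx, gy = gy)
}

# 3x3 box sum with zero padding (pools accumulator votes that rounding
# scatters across neighbouring bins).
box3_sum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  z <- matrix(0, h + 2L, w + 2L)
  z[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + z[(1L + dr):(h + dr), (1L + dc):(w + dc)]
  out
}

#' Detect circular beads in a localization frame
#'
#' Finds bead footprints as circles using a gradient circular Hough
#' accumulator: Sobel edge pixels vote along their gradient direction at each
#' candidate radius; accumulator peaks whose pooled votes exceed
#' `(1 - sensitivity)` of the circle perimeter are reported. Peaks closer
#' than `min_separation` are merged keeping the stronger peak, centers are
#' refined to sub-pixel precision by vote centroiding, radii by the median
#' center distance of center-pointing edge pixels, and circles extending past
#' the frame border are discarded.
#'
#' @param frame Numeric matrix (2-D localization image, finite values).
#' @param params A [detection_params()] object; `polarity` must match the
#'   modality ("dark" disks for brightfield, "bright" for darkfield).
#' @return A data.frame with one row per detection: `row`, `col` (0-based
#'   sub-pixel center), `radius` (px), `score` (normalized accumulator
#'   votes). Empty (zero-row) for blank or constant frames.
#' @export
detect_beads <- function(frame, params) {
  if (!inherits(params, "detection_params"))
    db_invalid("'params' must be a 'detection_params' object")
  if (!is.matrix(frame) || !is.numeric(frame))
    db_invalid("'frame' must be a numeric matrix")
  if (any(!is.finite(frame)))
    db_invalid("'frame' contains non-finite values")

  empty <- data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), score = numeric(0))
  h <- nrow(frame); w <- ncol(frame)
  if (diff(range(frame)) == 0) return(empty)

  img <- frame
  if (params$polarity == "dark") img <- -img

  g <- sobel_gradients(img)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # edge pixels: adaptive quantile, with a floor against strong isolated
  # gradients and a robust noise floor (most pixels are background, so the
  # median gradient magnitude estimates the noise scale; a pure-noise frame
  # then yields no edge pixels at all)
  thr <- max(stats::quantile(mag, 0.95), 0.2 * max(mag),
             6 * stats::median(mag))
  edge <- which(mag > thr)
  if (length(edge) == 0L) return(empty)

  er <- (edge - 1L) %% h          # 0-based row
  ec <- (edge - 1L) %/% h         # 0-based col
  ux <- g$gx[edge] / mag[edge]
  uy <- g$gy[edge] / mag[edge]

  radii <- seq(floor(params$radius_min), ceiling(params$radius_max), by = 1)
  nr <- length(radii)
  score <- vector("list", nr)
  raw <- vector("list", nr)
  best <- matrix(-Inf, h, w)
  bestk <- matrix(1L, h, w)
  for (k in seq_len(nr)) {
    r <- radii[k]
    # a bright disk's boundary gradient points inward, toward the center
    vr <- round(er + r * uy)
    vc <- round(ec + r * ux)
    ok <- vr >= 0 & vr < h & vc >= 0 & vc < w
    acc <- matrix(tabulate(vr[ok] + vc[ok] * h + 1L, nbins = h * w), h, w)
    pooled <- box3_sum(acc)
    raw[[k]] <- acc
    sc <- pooled / (2 * pi * r)
    score[[k]] <- sc
    upd <- sc > best
    best[upd] <- sc[upd]
    bestk[upd] <- k
  }

  min_score <- 1 - params$sensitivity
  cand <- which(best >= min_score)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(best[cand], decreasing = TRUE)]

  sel_r <- numeric(0); sel_c <- numeric(0); sel_k <- integer(0)
  sel_s <- numeric(0)
  for (ix in cand) {
    pr <- (ix - 1L) %% h
    pc <- (ix - 1L) %/% h
    if (length(sel_r) > 0L &&
        any((sel_r - pr)^2 + (sel_c - pc)^2 < params$min_separation^2))
      next
    sel_r <- c(sel_r, pr); sel_c <- c(sel_c, pc)
    sel_k <- c(sel_k, bestk[ix]); sel_s <- c(sel_s, best[ix])
  }

  out <- vector("list", length(sel_r))
  for (i in seq_along(sel_r)) {
    k <- sel_k[i]
    acc <- raw[[k]]
    r1 <- max(1L, sel_r[i]); r2 <- min(h, sel_r[i] + 2L)   # 3x3 around peak
    c1 <- max(1L, sel_c[i]); c2 <- min(w, sel_c[i] + 2L)
    win <- acc[r1:r2, c1:c2, drop = FALSE]
    tot <- sum(win)
    if (tot > 0) {
      rr <- (r1:r2) - 1L; cc <- (c1:c2) - 1L
      cr <- sum(rowSums(win) * rr) / tot
      cc0 <- sum(colSums(win) * cc) / tot
    } else {
      cr <- sel_r[i]; cc0 <- sel_c[i]
    }
    # radius: median distance of edge pixels whose gradient points at the
    # refined center
    dr <- cr - er; dc <- cc0 - ec
    dist <- sqrt(dr^2 + dc^2)
    near <- dist >= params$radius_min - 1.5 & dist <= params$radius_max + 1.5 &
      dist > 0
    if (any(near)) {
      cosang <- (dr[near] * uy[near] + dc[near] * ux[near]) / dist[near]
      pointing <- cosang > 0.8
      rad <- if (any(pointing)) stats::median(dist[near][pointing])
             else radii[k]
    } else rad <- radii[k]
    rad <- min(max(rad, params$radius_min), params$radius_max)
    out[[i]] <- data.frame(row = cr, col = cc0, radius = rad,
                           score = sel_s[i])
  }
  det <- do.call(rbind, out)
  # discard circles whose disk extends past the border; "past" is measured in
  # pixel-center terms with a half-pixel tolerance, since the intensity read
  # is over pixel centers and no center is lost until the disk reaches more
  # than 0.5 px beyond the outermost pixel center
  keep <- det$row >= det$radius - 0.5 & det$row <= (h - 1) - det$radius + 0.5 &
    det$col >= det$radius - 0.5 & det$col <= (w - 1) - det$radius + 0.5
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Extract per-bead maximum fluorescence intensity
#'
#' For each detected circle, takes the maximum fluorescence pixel over all
#' pixels whose center lies within the circle (boundary inclusive), in the
#' co-registered fluorescence frame. Detection order is preserved.
#'
#' @param detections A data.frame from [detect_beads()] (columns `row`,
#'   `col`, `radius`).
#' @param fluorescence_frame Numeric matrix co-registered with the
#'   localization frame the detections came from.
#' @return `detections` with a `max_intensity` column appended.
#' @export
extract_bead_intensity <- function(detections, fluorescence_frame) {
  if (!is.matrix(fluorescence_frame) || !is.numeric(fluorescence_frame))
    db_invalid("'fluorescence_frame' must be a numeric matrix")
  n <- nrow(detections)
  h <- nrow(fluorescence_frame); w <- ncol(fluorescence_frame)
  mx <- numeric(n)
  for (i in seq_len(n)) {
    r0 <- detections$row[i]; c0 <- detections$col[i]; rad <- detections$radius[i]
    r1 <- max(1L, floor(r0 - rad) + 1L); r2 <- min(h, ceiling(r0 + rad) + 1L)
    c1 <- max(1L, floor(c0 - rad) + 1L); c2 <- min(w, ceiling(c0 + rad) + 1L)
    if (r1 > r2 || c1 > c2)
      db_stop(sprintf("detected circle %d lies entirely outside the frame", i),
              "digibead_invalid_parameter")
    rr <- (r1:r2) - 1L; cc <- (c1:c2) - 1L
    mask <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= rad^2
    if (!any(mask))
      db_stop(sprintf("detected circle %d covers no pixel centers", i),
              "digibead_invalid_parameter")
    mx[i] <- max(fluorescence_frame[r1:r2, c1:c2][mask])
  }
  detections$max_intensity <- mx
  detections
}

#' Detect and measure beads across a whole frame set
#'
#' Runs [detect_beads()] on every localization frame and
#' [extract_bead_intensity()] on the paired fluorescence frame, returning the
#' concatenated per-bead table.
#'
#' @param frames A `frame_set` (see [render_frames()]) or any list with
#'   `localization_frames` and `fluorescence_frames` elements of equal
#'   length.
#' @param params A [detection_params()] object.
#' @return A data.frame with columns `frame_index` (1-based), `row`, `col`,
#'   `radius`, `score`, `max_intensity`; zero rows if no frames or no beads.
#' @export
detect_frameset <- function(frames, params) {
  loc <- frames$localization_frames
  flu <- frames$fluorescence_frames
  if (length(loc) != length(flu))
    db_stop("localization and fluorescence channels have different frame counts",
            "digibead_structural_error")
  out <- vector("list", length(loc))
  for (f in seq_along(loc)) {
    det <- detect_beads(loc[[f]], params)
    if (nrow(det) == 0L) next
    det <- extract_bead_intensity(det, flu[[f]])
    det$frame_index <- f
    out[[f]] <- det
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(frame_index = integer(0), row = numeric(0),
                      col = numeric(0), radius = numeric(0),
                      score = numeric(0), max_intensity = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[, c("frame_index", "row", "col", "radius", "score",
                 "max_intensity")]
  rownames(res) <- NULL
  res
}
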