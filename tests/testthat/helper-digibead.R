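# Shared fixtures: all synthetic inputs are generated in code at test time.

# Optics with every stochastic imaging term switched off, for tests that
# assert exact rendering identities.
noiseless_optics <- function(...) {
  optics_params(radius_jitter = 0, background_jitter_sd = 0,
                read_noise_sd = 0, ...)
}

# Greedy nearest-neighbour matching of detections against a truth table
# (both for a single frame or with matching frame columns). A truth bead is
# recalled when a detection center lies within `tol` pixels of it; each
# detection matches at most one truth bead.
match_detections <- function(det, truth, tol = 2) {
  det_frame <- if ("frame_index" %in% names(det)) det$frame_index
               else rep(1L, nrow(det))
  truth_frame <- if ("frame" %in% names(truth)) truth$frame
                 else rep(1L, nrow(truth))
  matched_truth <- logical(nrow(truth))
  matched_det <- logical(nrow(det))
  center_err <- radius_err <- rep(NA_real_, nrow(truth))
  for (f in unique(truth_frame)) {
    ti <- which(truth_frame == f)
    di <- which(det_frame == f & !matched_det)
    if (length(di) == 0L) next
    for (t in ti) {
      free <- di[!matched_det[di]]
      if (length(free) == 0L) break
      d <- sqrt((det$row[free] - truth$row[t])^2 +
                  (det$col[free] - truth$col[t])^2)
      j <- which.min(d)
      if (d[j] <= tol) {
        matched_truth[t] <- TRUE
        matched_det[free[j]] <- TRUE
        center_err[t] <- d[j]
        radius_err[t] <- abs(det$radius[free[j]] - truth$radius[t])
      }
    }
  }
  list(
    recall = mean(matched_truth),
    precision = if (nrow(det) > 0) sum(matched_det) / nrow(det) else NA_real_,
    center_err = center_err[matched_truth],
    radius_err = radius_err[matched_truth]
  )
}

# Minimal in-memory run list for analyze_runs-style processing.
runs_from_series <- function(sim) {
  lapply(seq_len(nrow(sim$manifest)), function(i) {
    list(condition = sim$manifest$condition[i],
         concentration = sim$manifest$concentration[i],
         replicate = sim$manifest$replicate[i],
         frames = sim$framesets[[i]])
  })
}
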