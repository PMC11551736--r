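#' Render traces into a TIRF-like image stack
#'
#' Each trace becomes a fixed 2-D Gaussian spot whose integrated intensity in
#' every frame equals the trace's intensity in that frame, on top of a
#' constant background with (optional) shot-like Poisson noise. Spots are
#' placed on a jittered grid unless `spot_positions` is supplied; every spot
#' must fit inside the field with a margin of `4 * psf_sd` pixels and no two
#' spots may be closer than `6 * psf_sd` pixels.
#'
#' @param traces list of `nisp_trace` objects (equal lengths).
#' @param field_size side of the square field (pixels).
#' @param psf_sd Gaussian point-spread sd (pixels).
#' @param spot_positions optional n x 2 matrix of (x, y) pixel centers.
#' @param background constant background level (counts/pixel).
#' @param shot_noise add Poisson noise to every pixel?
#' @param seed integer seed (noise and grid jitter).
#' @return list with `stack` (array `field_size x field_size x n_frames`),
#'   `positions` (true spot centers) and `background`.
#' @export
simulate_movie <- function(traces, field_size = 64, psf_sd = 1.2,
                           spot_positions = NULL, background = 100,
                           shot_noise = TRUE, seed = 1) {
  set.seed(seed)
  n_frames <- if (length(traces)) length(traces[[1]]$times) else 0L
  for (tr in traces)
    if (length(tr$times) != n_frames)
      stop("simulate_movie: traces must share one frame raster")
  margin <- 4 * psf_sd
  min_sep <- 6 * psf_sd
  n <- length(traces)
  if (is.null(spot_positions) && n > 0) {
    per_side <- ceiling(sqrt(n))
    usable <- field_size - 2 * margin
    if (usable <= 0 || (per_side > 1 && usable / (per_side - 1) < min_sep))
      stop("simulate_movie: layout error, field too crowded")
    jit <- min(1, min_sep / 8)
    g <- if (per_side == 1) margin + usable / 2
         else seq(margin + jit, field_size - margin - jit,
                  length.out = per_side)
    grid <- as.matrix(expand.grid(x = g, y = g))[seq_len(n), , drop = FALSE]
    spot_positions <- grid + matrix(stats::runif(2 * n, -jit, jit), ncol = 2)
  }
  if (n > 0) {
    if (any(spot_positions < margin) ||
        any(spot_positions > field_size - margin))
      stop("simulate_movie: layout error, spot too close to the border")
    if (n > 1 && min(stats::dist(spot_positions)) < min_sep)
      stop("simulate_movie: layout error, spots closer than 6*psf_sd")
  }
  if (n_frames == 0L) n_frames <- 1L
  stack <- array(background, dim = c(field_size, field_size, n_frames))
  if (n > 0) {
    r <- ceiling(4 * psf_sd)
    ax <- seq(-r, r)
    for (i in seq_len(n)) {
      cx <- spot_positions[i, 1]; cy <- spot_positions[i, 2]
      px <- round(cx) + ax; py <- round(cy) + ax
      vx <- px >= 1 & px <= field_size
      vy <- py >= 1 & py <= field_size
      px <- px[vx]; py <- py[vy]
      kx <- stats::dnorm(px, cx, psf_sd)
      ky <- stats::dnorm(py, cy, psf_sd)
      kern <- outer(kx, ky)
      kern <- kern / sum(kern)   # integrated spot intensity == trace value
      for (f in seq_len(dim(stack)[3])) {
        v <- traces[[i]]$intensities[f]
        stack[px, py, f] <- stack[px, py, f] + kern * v
      }
    }
  }
  if (shot_noise) {
    stack[] <- stats::rpois(length(stack), pmax(stack, 0))
  }
  list(stack = stack, positions = spot_positions, background = background)
}

#' Write / read an image stack as multi-frame 16-bit grayscale TIFF
#'
#' @param stack array `nx x ny x n_frames` of nonnegative counts.
#' @param path output file.
#' @param max_count full-scale count mapped to 16-bit white.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path, max_count = 65535) {
  frames <- lapply(seq_len(dim(stack)[3]), function(f)
    pmin(pmax(stack[, , f], 0), max_count) / max_count)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, max_count = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0, dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                            length(frames)))
  for (f in seq_along(frames)) stack[, , f] <- frames[[f]] * max_count
  stack
}

#' Extract single-molecule intensity traces from an image stack
#'
#' Spots are local maxima of the mean of the first 10 frames lying above
#' `background_mean + detect_threshold * background_sd` (robust field
#' statistics: median and MAD), non-maximum-suppressed within
#' `2 * window_radius` pixels. The per-frame trace value is the sum over the
#' `(2 * window_radius + 1)^2` pixel window minus the local median background
#' (estimated in a surrounding annulus) times the window area.
#'
#' @param stack array `nx x ny x n_frames` (counts), `n_frames >= 10`.
#' @param detect_threshold detection threshold in background-sd multiples.
#' @param window_radius half-size of the integration window (pixels).
#' @param frame_interval seconds per frame for the trace time axis.
#' @return list of `nisp_trace` objects; each `meta` carries the spot center.
#' @export
extract_traces_from_movie <- function(stack, detect_threshold = 5,
                                      window_radius = 3,
                                      frame_interval = 0.1) {
  stopifnot(length(dim(stack)) == 3)
  if (dim(stack)[3] < 10)
    stop("extract_traces_from_movie: need >= 10 frames for the detection average")
  sat <- apply(stack, 3, function(fr) any(fr >= 65535))
  use <- which(!sat)[seq_len(min(10, sum(!sat)))]
  if (!length(use)) stop("extract_traces_from_movie: all frames saturated")
  avg <- apply(stack[, , use, drop = FALSE], c(1, 2), mean)
  bg_mean <- stats::median(avg)
  bg_sd <- stats::mad(avg)
  if (bg_sd == 0) bg_sd <- stats::sd(avg)
  thr <- bg_mean + detect_threshold * bg_sd
  nx <- dim(avg)[1]; ny <- dim(avg)[2]
  wr <- window_radius
  cand <- which(avg > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > wr & cand[, 1] <= nx - wr &
               cand[, 2] > wr & cand[, 2] <= ny - wr, , drop = FALSE]
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, 1]; y <- cand[i, 2]
    nb <- avg[(x - 1):(x + 1), (y - 1):(y + 1)]
    is_max[i] <- avg[x, y] >= max(nb)
  }
  peaks <- cand[is_max, , drop = FALSE]
  if (nrow(peaks) > 1) {                      # non-maximum suppression
    ord <- order(avg[peaks], decreasing = TRUE)
    peaks <- peaks[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      if (!keep[i]) next
      d <- sqrt((peaks[, 1] - peaks[i, 1])^2 + (peaks[, 2] - peaks[i, 2])^2)
      keep[d < 2 * wr & d > 0 & seq_len(nrow(peaks)) > i] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  n_frames <- dim(stack)[3]
  times <- (seq_len(n_frames) - 0.5) * frame_interval
  area <- (2 * wr + 1)^2
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    x <- peaks[i, 1]; y <- peaks[i, 2]
    xw <- (x - wr):(x + wr); yw <- (y - wr):(y + wr)
    xo <- max(1, x - 3 * wr):min(nx, x + 3 * wr)
    yo <- max(1, y - 3 * wr):min(ny, y + 3 * wr)
    ann_mask <- !(outer(xo %in% xw, yo %in% yw, "&"))  # box minus window
    inten <- numeric(n_frames)
    for (f in seq_len(n_frames)) {
      med_bg <- stats::median(stack[xo, yo, f][ann_mask])
      inten[f] <- sum(stack[xw, yw, f]) - med_bg * area
    }
    out[[i]] <- new_trace(times, inten, truth = NULL,
                          meta = list(center = peaks[i, ],
                                      frame_interval = frame_interval))
  }
  out
}
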