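# bilinear sampling of img (rows = y, cols = x) at arbitrary coordinates;
# coordinates outside the image return `outside` (default 0)
.bilinearSample <- function(img, x, y, outside = 0) {
  h <- nrow(img)
  w <- ncol(img)
  valid <- x >= 1 & x <= w & y >= 1 & y <= h
  xc <- pmin(pmax(x, 1), w)
  yc <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(xc), w - 1L)
  y0 <- pmin(floor(yc), h - 1L)
  fx <- xc - x0
  fy <- yc - y0
  i00 <- (x0 - 1) * h + y0
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i00 + h] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy + img[i00 + h + 1] * fx * fy
  v[!valid] <- outside
  attr(v, "valid") <- valid
  v
}

# unit vector at `angle_deg` above horizontal pointing in -x (proximal),
# image y axis pointing down
.fascicleDir <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(-cos(a), -sin(a))
}

# endpoints (2x2, columns = insertion, distal tip) for a given length (mm)
# and pennation (deg) under an imaging configuration
.fascicleEndpoints <- function(length_mm, pennation_deg, cfg) {
  ins <- c(cfg$insertion_x_px, cfg$apo_y_px)
  tip <- ins + (length_mm / cfg$mm_per_px) * .fascicleDir(pennation_deg)
  cbind(ins, tip)
}

# additive Gaussian-profile bright segment between points p and q
.drawSegment <- function(img, p, q, amp, sigma) {
  h <- nrow(img)
  w <- ncol(img)
  x0 <- max(1L, floor(min(p[1], q[1]) - 4 * sigma))
  x1 <- min(w, ceiling(max(p[1], q[1]) + 4 * sigma))
  y0 <- max(1L, floor(min(p[2], q[2]) - 4 * sigma))
  y1 <- min(h, ceiling(max(p[2], q[2]) + 4 * sigma))
  xs <- x0:x1
  ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))
  d <- q - p
  len2 <- sum(d^2)
  tproj <- ((gx - p[1]) * d[1] + (gy - p[2]) * d[2]) / len2
  tproj <- pmin(pmax(tproj, 0), 1)
  dx <- gx - (p[1] + tproj * d[1])
  dy <- gy - (p[2] + tproj * d[2])
  img[ys, xs] <- img[ys, xs] + amp * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  img
}

#' Render a synthetic B-mode image sequence from a fascicle trace
#'
#' Produces speckle frames in which the commanded fascicle geometry is
#' exactly encoded: a static blurred-scatterer background is rendered once
#' and warped per frame by the affine transform that carries the frame-0
#' fascicle segment (fixed insertion, length scaling along the fascicle,
#' rotation to the commanded pennation) onto the frame-k segment, so affine
#' optical flow has a recoverable ground truth. A bright fascicle segment
#' and a horizontal aponeurosis band are then drawn at the commanded
#' coordinates, and an imaging trigger with one rising edge per frame is
#' generated on the signal clock.
#'
#' @param truth a \linkS4class{FascicleTrace} at the imaging frame rate.
#' @param cfg an \code{\link{imagingConfig}}.
#' @param fs signal sampling rate for the trigger, Hz (default 2048).
#' @param seed integer seed for the speckle background.
#' @return list with \code{frames} (list of height x width matrices in
#'   [0, 1]), \code{trigger} (binary trace at \code{fs}), \code{edges}
#'   (rising-edge sample of each frame), \code{endpoints} (list of 2x2
#'   ground-truth endpoint matrices, px) and \code{init}
#'   (\linkS4class{FascicleGeometry} of frame 1, the tracker's starting
#'   point).
#' @examples
#' tr <- fascicleTrace(rep(60.2, 8), rep(15.2, 8), frame_rate = 80)
#' r <- renderUltrasound(tr, imagingConfig(), seed = 1)
#' length(r$frames)
#' @export
renderUltrasound <- function(truth, cfg = imagingConfig(), fs = 2048,
                             seed = 1L) {
  stopifnot(is(truth, "FascicleTrace"))
  h <- cfg$height_px
  w <- cfg$width_px
  n_frames <- length(truth@length_mm)
  ep <- lapply(seq_len(n_frames), function(k)
    .fascicleEndpoints(truth@length_mm[k], truth@pennation_deg[k], cfg))
  for (k in seq_len(n_frames)) {
    e <- ep[[k]]
    if (any(e[1, ] < 1) || any(e[1, ] > w) || any(e[2, ] < 1) ||
        any(e[2, ] > h))
      stop(sprintf("frame %d: fascicle geometry falls outside the image", k))
  }
  force(seed)
  old <- .saveSeed()
  on.exit(.restoreSeed(old), add = TRUE)
  set.seed(as.integer(seed))
  speckle <- matrix(stats::rnorm(h * w), h, w)
  speckle <- EBImage::gblur(speckle, sigma = cfg$speckle_sigma_px)
  speckle <- 0.55 * (speckle - min(speckle)) / (max(speckle) - min(speckle))
  ins <- ep[[1L]][, 1L]
  u0 <- ep[[1L]][, 2L] - ins
  l0 <- sqrt(sum(u0^2))
  u0 <- u0 / l0
  b0 <- cbind(u0, c(-u0[2], u0[1]))
  gx <- matrix(rep(seq_len(w), each = h), h)
  gy <- matrix(rep(seq_len(h), times = w), h)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    uk <- ep[[k]][, 2L] - ins
    lk <- sqrt(sum(uk^2))
    uk <- uk / lk
    s <- lk / l0
    A <- cbind(s * uk, c(-uk[2], uk[1])) %*% solve(b0)
    Ainv <- solve(A)
    xr <- gx - ins[1]
    yr <- gy - ins[2]
    sx <- Ainv[1, 1] * xr + Ainv[1, 2] * yr + ins[1]
    sy <- Ainv[2, 1] * xr + Ainv[2, 2] * yr + ins[2]
    img <- matrix(.bilinearSample(speckle, as.numeric(sx), as.numeric(sy)),
                  h, w)
    img <- .drawSegment(img, ep[[k]][, 1L], ep[[k]][, 2L], amp = 0.35,
                        sigma = 1.0)
    img <- .drawSegment(img, c(1, cfg$apo_y_px), c(w, cfg$apo_y_px),
                        amp = 0.45, sigma = 1.2)
    frames[[k]] <- pmin(img, 1)
  }
  edges <- as.integer(round((seq_len(n_frames) - 1L) * fs /
                              truth@frame_rate) + 1L)
  pulse <- max(2L, round(fs / truth@frame_rate / 2))
  trigger <- numeric(edges[n_frames] + pulse)
  for (e in edges) trigger[e:(e + pulse - 1L)] <- 1
  init <- fascicleGeometry(ep[[1L]], apo_point = c(1, cfg$apo_y_px),
                           apo_dir = c(1, 0), mm_per_px = cfg$mm_per_px)
  list(frames = frames, trigger = trigger, edges = edges, endpoints = ep,
       init = init, cfg = cfg)
}
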