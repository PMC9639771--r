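# 2x downsampling by 2x2 block averaging (coarse pyramid level)
.pyrDown <- function(img) {
  h <- nrow(img) %/% 2L
  w <- ncol(img) %/% 2L
  i2 <- img[seq_len(2L * h), seq_len(2L * w)]
  0.25 * (i2[seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L)] +
          i2[seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L)] +
          i2[seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L)] +
          i2[seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L)])
}

# central-difference image gradients
.imageGradients <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' One Lucas-Kanade affine optical-flow step
#'
#' Estimates the affine warp carrying a region of interest of \code{prev}
#' onto \code{next}: iterative Gauss-Newton minimization of the sum of
#' squared intensity differences over the warped region, coarse-to-fine
#' over an image pyramid. The warp is parameterized about the region
#' centre for conditioning; convergence is declared when the
#' update-induced displacement falls below \code{tol} pixels.
#'
#' A textureless region (singular normal matrix) is flagged as a failure
#' and the identity transform is returned with \code{converged = FALSE}.
#'
#' @param prev,next_ equally sized image matrices (rows = y, cols = x).
#' @param roi integer (x0, x1, y0, y1) region of interest, inside both
#'   frames.
#' @param opts list: \code{pyramid_levels} (default 3), \code{max_iter}
#'   (default 50), \code{tol} (default 1e-3 px).
#' @return an \linkS4class{AffineParams} mapping \code{prev} image
#'   coordinates to \code{next_} image coordinates.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' p <- lkAffineStep(img, img, c(10, 50, 10, 50))
#' p@t  # ~ c(0, 0)
#' @export
lkAffineStep <- function(prev, next_, roi,
                         opts = list(pyramid_levels = 3, max_iter = 50,
                                     tol = 1e-3)) {
  if (!all(dim(prev) == dim(next_))) stop("frames must have equal size")
  levels <- if (is.null(opts$pyramid_levels)) 3L else opts$pyramid_levels
  max_iter <- if (is.null(opts$max_iter)) 50L else opts$max_iter
  tol <- if (is.null(opts$tol)) 1e-3 else opts$tol
  roi <- as.numeric(roi)
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > ncol(prev) || roi[4] > nrow(prev))
    stop("roi must lie inside the frames")
  # restrict pyramid depth so the coarsest roi still has content
  while (levels > 1L &&
         (min(roi[2] - roi[1], roi[4] - roi[3]) / 2^(levels - 1L)) < 12)
    levels <- levels - 1L
  pyr_p <- list(prev)
  pyr_n <- list(next_)
  for (l in seq_len(levels - 1L)) {
    pyr_p[[l + 1L]] <- .pyrDown(pyr_p[[l]])
    pyr_n[[l + 1L]] <- .pyrDown(pyr_n[[l]])
  }
  p <- numeric(6)  # (a11-1, a21, a12, a22-1, tx, ty) about the roi centre
  failed <- FALSE
  for (l in levels:1L) {
    sc <- 2^(l - 1L)
    P <- pyr_p[[l]]
    N <- pyr_n[[l]]
    g <- .imageGradients(N)
    x0 <- max(1, roi[1] / sc)
    x1 <- min(ncol(P), roi[2] / sc)
    y0 <- max(1, roi[3] / sc)
    y1 <- min(nrow(P), roi[4] / sc)
    xs <- seq(ceiling(x0), floor(x1))
    ys <- seq(ceiling(y0), floor(y1))
    if (length(xs) < 4L || length(ys) < 4L) next
    cx <- mean(range(xs))
    cy <- mean(range(ys))
    X <- rep(xs, each = length(ys)) - cx
    Y <- rep(ys, times = length(xs)) - cy
    Tv <- as.numeric(P[ys, xs])
    radius <- max(max(abs(X)), max(abs(Y)), 1)
    for (it in seq_len(max_iter)) {
      wx <- (1 + p[1]) * X + p[3] * Y + p[5] + cx
      wy <- p[2] * X + (1 + p[4]) * Y + p[6] + cy
      Iv <- .bilinearSample(N, wx, wy)
      valid <- attr(Iv, "valid")
      if (sum(valid) < 12L) { failed <- TRUE; break }
      Ix <- .bilinearSample(g$gx, wx, wy)
      Iy <- .bilinearSample(g$gy, wx, wy)
      r <- (Tv - Iv)[valid]
      J <- cbind(Ix * X, Iy * X, Ix * Y, Iy * Y, Ix, Iy)[valid, ,
                                                         drop = FALSE]
      H <- crossprod(J)
      dp <- tryCatch(solve(H, crossprod(J, r)),
                     error = function(e) NULL)
      if (is.null(dp)) { failed <- TRUE; break }
      p <- p + as.numeric(dp)
      disp <- sqrt(dp[5]^2 + dp[6]^2) +
        radius * sqrt(dp[1]^2 + dp[2]^2 + dp[3]^2 + dp[4]^2)
      if (disp < tol) break
    }
    if (failed) break
    if (l > 1L) {
      p[5] <- p[5] * 2
      p[6] <- p[6] * 2
    }
  }
  if (failed) return(affineParams(converged = FALSE))
  A <- matrix(c(1 + p[1], p[2], p[3], 1 + p[4]), 2, 2)
  centre <- c(cx, cy)  # centre used at the finest level
  t_abs <- centre + p[5:6] - A %*% centre
  affineParams(A = A, t = as.numeric(t_abs), converged = TRUE)
}

#' Track fascicle geometry through an image sequence
#'
#' Frame-to-frame pyramidal Lucas-Kanade affine optical flow over a region
#' of interest around the fascicle, with the per-step transforms composed
#' into an accumulated warp that carries the frame-0 fascicle endpoints and
#' aponeurosis line through the sequence (no key-frame re-anchoring; drift
#' is measured against synthetic ground truth rather than suppressed).
#' Fascicle length is the endpoint distance times the pixel scale, the rest
#' length is the frame-0 value, and pennation is the acute angle between
#' the propagated fascicle and aponeurosis directions. A failed flow step
#' carries the previous geometry forward and is flagged.
#'
#' @param frames list of image matrices.
#' @param init \linkS4class{FascicleGeometry} valid in the first frame.
#' @param opts flow options, see \code{\link{lkAffineStep}}; additionally
#'   \code{roi_margin_px} (default 20) dilates the fascicle bounding box
#'   and \code{exclude_apo_px} (default 4) clips the region to stay above
#'   the aponeurosis line, whose echo does not follow fascicle motion;
#'   \code{presmooth_px} (default 1) Gaussian-blurs the frames before
#'   differentiation, reducing the sub-pixel interpolation bias that
#'   otherwise accumulates as drift over long frame-to-frame compositions.
#' @return a \linkS4class{FascicleTrace} at an unspecified frame rate
#'   (set it from your trigger); attributes: \code{"endpoints"} (list of
#'   per-frame 2x2 matrices), \code{"failed"} (integer vector of flagged
#'   frames), \code{"frame_rate"} left at 1 until synchronized.
#' @examples
#' \donttest{
#' tr <- fascicleTrace(rep(60.2, 4), rep(15.2, 4), frame_rate = 80)
#' r <- renderUltrasound(tr, imagingConfig(), seed = 1)
#' out <- trackFascicle(r$frames, r$init)
#' }
#' @export
trackFascicle <- function(frames, init, opts = list()) {
  if (!length(frames)) stop("empty image sequence")
  margin <- if (is.null(opts$roi_margin_px)) 20 else opts$roi_margin_px
  apo_clip <- if (is.null(opts$exclude_apo_px)) 4 else opts$exclude_apo_px
  presmooth <- if (is.null(opts$presmooth_px)) 1 else opts$presmooth_px
  if (presmooth > 0)
    frames <- lapply(frames, EBImage::gblur, sigma = presmooth)
  n <- length(frames)
  h <- nrow(frames[[1L]])
  w <- ncol(frames[[1L]])
  cum <- affineParams()
  ep0 <- init@endpoints
  apo0 <- init@apo_point
  dir0 <- init@apo_dir
  eps <- vector("list", n)
  eps[[1L]] <- ep0
  lens <- numeric(n)
  pens <- numeric(n)
  geom <- init
  lens[1L] <- sqrt(sum((ep0[, 1] - ep0[, 2])^2)) * init@mm_per_px
  pens[1L] <- pennationAngle(init)
  failed <- integer(0)
  for (k in 2:n) {
    e <- eps[[k - 1L]]
    roi <- c(max(1, floor(min(e[1, ]) - margin)),
             min(w, ceiling(max(e[1, ]) + margin)),
             max(1, floor(min(e[2, ]) - margin)),
             min(h, ceiling(max(e[2, ]) + margin)))
    # keep the flow region off the aponeurosis echo (near-horizontal line)
    if (!is.null(apo_clip) && abs(geom@apo_dir[2]) < 0.3 * abs(geom@apo_dir[1])) {
      ymax <- floor(geom@apo_point[2] - apo_clip)
      if (ymax > roi[3] + 8) roi[4] <- min(roi[4], ymax)
    }
    step <- lkAffineStep(frames[[k - 1L]], frames[[k]], roi, opts = opts)
    if (!step@converged) {
      failed <- c(failed, k)
    } else {
      cum <- composeAffine(step, cum)
    }
    ek <- applyAffine(cum, ep0)
    eps[[k]] <- ek
    geom <- fascicleGeometry(ek,
                             apo_point = as.numeric(applyAffine(cum, apo0)),
                             apo_dir = as.numeric(cum@A %*% dir0),
                             mm_per_px = init@mm_per_px)
    lens[k] <- sqrt(sum((ek[, 1] - ek[, 2])^2)) * init@mm_per_px
    pens[k] <- pennationAngle(geom)
  }
  out <- fascicleTrace(lens, pens, frame_rate = 1,
                       rest_length_mm = lens[1L])
  attr(out, "endpoints") <- eps
  attr(out, "failed") <- failed
  out
}

#' Pennation angle of a fascicle geometry
#'
#' Unsigned acute angle between the fascicle direction and the aponeurosis
#' direction, in degrees within [0, 90].
#'
#' @param geometry a \linkS4class{FascicleGeometry}.
#' @return angle in degrees.
#' @examples
#' g <- fascicleGeometry(cbind(c(10, 10), c(0, 0)), c(0, 10), c(1, 0), 0.23)
#' pennationAngle(g)  # 45
#' @export
pennationAngle <- function(geometry) {
  d <- geometry@endpoints[, 2L] - geometry@endpoints[, 1L]
  a <- geometry@apo_dir
  nd <- sqrt(sum(d^2))
  na <- sqrt(sum(a^2))
  if (nd == 0 || na == 0) stop("zero-length direction")
  cosang <- abs(sum(d * a)) / (nd * na)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Resample a frame-rate trace onto the signal clock
#'
#' Places each per-frame value at its trigger-edge sample index and
#' interpolates with a cubic spline, the standard way fascicle traces are
#' brought onto the EMG/torque timeline. The output is defined between the
#' first and last edge; endpoints are exact and a linear-in-time trace is
#' reproduced exactly.
#'
#' @param x a \linkS4class{FascicleTrace} or a per-frame numeric vector.
#' @param edges trigger rising-edge sample indices (one per frame,
#'   increasing), or a \linkS4class{TriggerMap}.
#' @param fs signal sampling rate, Hz (default 2048; informational).
#' @return for a numeric input, a list with \code{samples} (interpolated
#'   values), \code{sample_index} (their positions on the signal clock) and
#'   \code{full} (length \code{max(edges)} vector, NA outside the covered
#'   span); for a \linkS4class{FascicleTrace}, the same plus parallel
#'   entries \code{length_mm}, \code{delta_mm} and \code{pennation_deg} as
#'   \code{full}-style vectors.
#' @examples
#' resampleToEmg(c(0, 1, 2), edges = c(1L, 26L, 51L))$samples[26]
#' @export
resampleToEmg <- function(x, edges, fs = 2048) {
  if (is(edges, "TriggerMap")) edges <- edges@edges
  edges <- as.numeric(edges)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  interp1 <- function(v) {
    if (length(v) != length(edges))
      stop("edge count must equal frame count")
    xo <- edges[1L]:edges[length(edges)]
    y <- stats::spline(edges, v, xout = xo, method = "fmm")$y
    full <- rep(NA_real_, edges[length(edges)])
    full[xo] <- y
    list(samples = y, sample_index = xo, full = full)
  }
  if (is(x, "FascicleTrace")) {
    L <- interp1(x@length_mm)
    P <- interp1(x@pennation_deg)
    return(list(samples = L$samples, sample_index = L$sample_index,
                length_mm = L$full,
                delta_mm = x@rest_length_mm - L$full,
                pennation_deg = P$full))
  }
  interp1(as.numeric(x))
}
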