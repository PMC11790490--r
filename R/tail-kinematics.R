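## Silhouette -> skeleton -> kinematics pipeline: median-filter smoothing,
## inversion, Otsu binarization, small-component removal, Zhang-Suen
## thinning, longest-geodesic-path extraction ordered head-first, then total
## tail angle, standard length, displacement kymograph and tail-beat spectrum.

## ---------------------------------------------------------------------------
## binary thinning (Zhang-Suen), vectorized over the image
## ---------------------------------------------------------------------------

## one-pixel-wide skeleton by iterative Zhang-Suen thinning (compiled);
## the scan is cropped to the foreground bounding box for speed
.zhangSuen <- function(mask) {
  m <- matrix(mask != 0, nrow(mask), ncol(mask))
  on <- which(m, arr.ind = TRUE)
  if (!nrow(on)) return(m)
  r0 <- max(1L, min(on[, 1]) - 1L); r1 <- min(nrow(m), max(on[, 1]) + 1L)
  c0 <- max(1L, min(on[, 2]) - 1L); c1 <- min(ncol(m), max(on[, 2]) + 1L)
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[r0:r1, c0:c1] <- .zsThin(m[r0:r1, c0:c1, drop = FALSE])
  out
}

## ---------------------------------------------------------------------------
## preprocessing
## ---------------------------------------------------------------------------

#' Preprocess a video frame into a binary silhouette mask
#'
#' Median-filters the grayscale frame (default 20 px window), inverts it,
#' binarizes with Otsu's threshold, removes connected components smaller
#' than `minArea` pixels, and returns the largest remaining component -- the
#' larva silhouette.
#'
#' @param image 2-D numeric matrix, grayscale frame (bright background,
#'   dark larva).
#' @param medianSize median filter window in px (default 20, applied as the
#'   centered odd window `2 * floor(size/2) + 1`; 0 skips filtering).
#' @param minArea minimum component area in px (default 600).
#' @return Logical matrix, TRUE inside the larva silhouette.
#' @export
preprocessFrame <- function(image, medianSize = 20, minArea = 600) {
  if (length(dim(image)) != 2) stop("'image' must be a 2-D grayscale frame")
  img <- image
  if (medianSize > 0) {
    img <- pmin(pmax(img, 0), 1)
    img <- EBImage::medianFilter(img, floor(medianSize / 2))
  }
  inv <- max(img) - img
  rng <- range(inv)
  if (diff(rng) < .Machine$double.eps^0.5)
    stop("empty silhouette: frame has no contrast")
  inv01 <- (inv - rng[1]) / diff(rng)
  mask <- inv01 > EBImage::otsu(EBImage::Image(inv01))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= minArea)
  if (!length(keep))
    stop("empty silhouette: no component of at least ", minArea, " px")
  matrix(lab == keep[which.max(sizes[keep])], nrow(image), ncol(image))
}

## ---------------------------------------------------------------------------
## skeleton extraction
## ---------------------------------------------------------------------------

#' Extract the ordered midline skeleton from a silhouette mask
#'
#' Thins the mask to a one-pixel-wide skeleton (Zhang-Suen), keeps the
#' longest geodesic path through the skeleton's 8-neighbor pixel graph
#' (Euclidean edge weights), and orients it head-first: the endpoint with
#' the larger distance-transform value lies in the wide head blob.
#'
#' @param mask logical or 0/1 matrix, single-component silhouette.
#' @param mmPerPx spatial scale carried into the result (default NA).
#' @return A [SkeletonPath] ordered from head anchor to tail tip.
#' @export
extractSkeleton <- function(mask, mmPerPx = NA_real_) {
  if (!any(mask != 0)) stop("empty mask")
  skel <- .zhangSuen(mask)
  pts <- which(skel, arr.ind = TRUE)
  if (nrow(pts) < 2)
    stop("degenerate skeleton: fewer than 2 pixels")
  # 8-neighbor graph over skeleton pixels
  key <- pts[, 1] + (pts[, 2] - 1L) * nrow(skel)
  edgeList <- list()
  wtList <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nbKey <- (pts[, 1] + d[1]) + (pts[, 2] + d[2] - 1L) * nrow(skel)
    inb <- pts[, 1] + d[1] >= 1 & pts[, 1] + d[1] <= nrow(skel) &
      pts[, 2] + d[2] >= 1 & pts[, 2] + d[2] <= ncol(skel)
    nbId <- match(nbKey, key)
    hit <- inb & !is.na(nbId)
    if (any(hit)) {
      edgeList[[length(edgeList) + 1L]] <- cbind(which(hit), nbId[hit])
      wtList[[length(wtList) + 1L]] <- rep(sqrt(sum(d^2)), sum(hit))
    }
  }
  if (!length(edgeList)) stop("degenerate skeleton: no connected path")
  edges <- do.call(rbind, edgeList)
  wts <- unlist(wtList)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (igraph::vcount(g) < nrow(pts))
    g <- igraph::add_vertices(g, nrow(pts) - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, main)
  path <- main[as.integer(igraph::get_diameter(sub))]
  if (length(path) < 2) stop("degenerate skeleton: no path of >= 2 px")
  coords <- pts[path, , drop = FALSE]
  # orient head-first: the head half of the path runs through the widest
  # mask region (largest distance-transform values)
  dm <- EBImage::distmap(matrix(as.numeric(mask != 0), nrow(mask)))
  along <- dm[coords]
  q <- max(2L, nrow(coords) %/% 4)
  if (max(head(along, q)) < max(tail(along, q)))
    coords <- coords[rev(seq_len(nrow(coords))), , drop = FALSE]
  dimnames(coords) <- list(NULL, c("row", "col"))
  new("SkeletonPath", coords = coords, mmPerPx = mmPerPx)
}

## ---------------------------------------------------------------------------
## kinematic measures
## ---------------------------------------------------------------------------

#' Total tail angle of a skeleton
#'
#' Sum of the signed turning angles between successive skeleton segments,
#' head to tail, in degrees. To suppress the 45-degree quantization of raw
#' pixel steps, the path is smoothed with a short moving average and
#' resampled at uniform arc-length steps before the turning angles are
#' summed; half of the first and last turning angle is added to compensate
#' the half-segment of curvature that chord headings miss at each end.
#' Sign convention: bending toward increasing row (image left when the head
#' points along +column) is positive.
#'
#' @param skeleton a [SkeletonPath], or an n x 2 coordinate matrix of an
#'   ordered midline (at least 3 points).
#' @param smoothWindow local-quadratic smoothing window in px (default 7).
#' @param resampleStep arc-length resampling step in px (default 2).
#' @param endFitLength arc length in px over which endpoint headings are
#'   extrapolated (default 24).
#' @return Total tail angle in degrees.
#' @export
totalTailAngle <- function(skeleton, smoothWindow = 7, resampleStep = 2,
                           endFitLength = 24) {
  xy <- if (is(skeleton, "SkeletonPath")) skeleton@coords else
    as.matrix(skeleton)
  if (nrow(xy) < 3) stop("need at least 3 skeleton points")
  r <- .smoothPath(xy[, 1], smoothWindow)
  c_ <- .smoothPath(xy[, 2], smoothWindow)
  al <- c(0, cumsum(sqrt(diff(r)^2 + diff(c_)^2)))
  L <- al[length(al)]
  # uniform arc-length grid that hits the path end exactly
  nSteps <- max(3L, ceiling(L / resampleStep))
  s <- seq(0, L, length.out = nSteps + 1L)
  rr <- approx(al, r, xout = s)$y
  cc <- approx(al, c_, xout = s)$y
  heading <- atan2(diff(rr), diff(cc))
  # unwrap so the running heading is continuous, then extrapolate the true
  # head and tail-tip tangent directions by short linear fits: exact for
  # constant curvature and robust to the pixel staircase at the path ends
  turn <- (diff(heading) + pi) %% (2 * pi) - pi
  hu <- cumsum(c(heading[1], turn))
  mids <- (s[-1] + s[-length(s)]) / 2
  K <- max(2L, min(length(hu) %/% 2, ceiling(endFitLength / (L / nSteps))))
  headFit <- stats::lm.fit(cbind(1, mids[seq_len(K)]),
                           hu[seq_len(K)])$coefficients
  tailIdx <- seq.int(length(hu) - K + 1L, length(hu))
  tailFit <- stats::lm.fit(cbind(1, mids[tailIdx]),
                           hu[tailIdx])$coefficients
  h0 <- headFit[1]
  hL <- tailFit[1] + tailFit[2] * L
  as.numeric(hL - h0) * 180 / pi
}

#' Standard length from a skeleton
#'
#' Polyline arc length of the (lightly smoothed) skeleton path scaled to mm.
#' Smoothing removes the staircase inflation of raw 8-connected pixel
#' chains, whose zig-zag steps overestimate the length of oblique midlines.
#'
#' @param skeleton a [SkeletonPath].
#' @param mmPerPx spatial scale; defaults to the skeleton's own.
#' @param smoothWindow path smoothing window in px (default 7; 1 disables).
#' @return Standard length in mm.
#' @export
standardLength <- function(skeleton, mmPerPx = NULL, smoothWindow = 7) {
  if (is.null(mmPerPx)) mmPerPx <- skeleton@mmPerPx
  if (is.na(mmPerPx) || mmPerPx <= 0) {
    warning("suspicious scale: mmPerPx is ", mmPerPx)
    mmPerPx <- max(0, mmPerPx, na.rm = TRUE)
    if (is.na(mmPerPx)) mmPerPx <- 0
  }
  xy <- cbind(.smoothPath(skeleton@coords[, 1], smoothWindow),
              .smoothPath(skeleton@coords[, 2], smoothWindow))
  .arcLengthPx(xy) * mmPerPx
}

## ---------------------------------------------------------------------------
## whole-stack analysis
## ---------------------------------------------------------------------------

#' Analyze a silhouette video stack
#'
#' Runs the full pipeline per frame (preprocess, skeletonize, total tail
#' angle, standard length) and builds a lateral displacement kymograph:
#' the rostrocaudal reference axis is fit to the first analyzable frame's
#' skeleton, each frame's skeleton is resampled by 1-D interpolation to the
#' minimum skeleton point count across frames, and the signed perpendicular
#' displacement to the axis is normalized by the stack-wide mean absolute
#' displacement. Frames whose preprocessing or skeletonization fails are
#' excluded with a warning.
#'
#' @param stack a [SilhouetteStack] (at least 2 frames).
#' @param medianSize median filter window in px (default 20).
#' @param minArea minimum silhouette area in px (default 600).
#' @param smoothWindow path smoothing window for the angle (default 7).
#' @return List with `trace` ([TailTrace]) and `kymograph`
#'   ([KymographMatrix], rows = positions head to tail).
#' @export
analyzeStack <- function(stack, medianSize = 20, minArea = 600,
                         smoothWindow = 7) {
  stopifnot(is(stack, "SilhouetteStack"))
  n <- nFrames(stack)
  if (n < 2) stop("need at least 2 frames")
  skels <- vector("list", n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    skels[[k]] <- tryCatch(
      extractSkeleton(
        preprocessFrame(stack@frames[, , k], medianSize, minArea),
        stack@mmPerPx),
      error = function(e) e)
    ok[k] <- is(skels[[k]], "SkeletonPath")
  }
  if (any(!ok))
    warning(sum(!ok), " frame(s) excluded: ",
            paste(unique(vapply(skels[!ok], conditionMessage, "")),
                  collapse = "; "))
  if (!any(ok)) stop("no analyzable frames in the stack")
  kept <- which(ok)
  angle <- vapply(skels[kept], totalTailAngle, numeric(1),
                  smoothWindow = smoothWindow)
  len <- vapply(skels[kept], standardLength, numeric(1))

  # rostrocaudal reference axis from the first analyzable frame (total
  # least squares through its skeleton)
  ref <- skels[[kept[1]]]@coords
  ctr <- colMeans(ref)
  v <- prcomp(ref)$rotation[, 1]
  minPts <- min(vapply(skels[kept], function(s) nrow(s@coords), integer(1)))
  disp <- vapply(skels[kept], function(s) {
    xy <- sweep(s@coords, 2, ctr)
    lateral <- xy[, 1] * v[2] - xy[, 2] * v[1]  # signed perpendicular dist
    along <- seq(0, 1, length.out = nrow(xy))
    approx(along, lateral, xout = seq(0, 1, length.out = minPts))$y
  }, numeric(minPts))
  norm <- mean(abs(disp))
  if (norm > 0) disp <- disp / norm

  list(trace = new("TailTrace", angle = angle, lengthMm = len,
                   frame = as.integer(kept), frameRate = stack@frameRate),
       kymograph = new("KymographMatrix", displacement = disp))
}

#' Dominant tail-beat frequency
#'
#' Frequency of the maximum non-DC bin of the Welch power spectrum of the
#' mean-detrended total-tail-angle trace (Hann window, 1 s segments, 50%
#' overlap).
#'
#' @param trace a [TailTrace], or a numeric angle trace if `frameRate` is
#'   given.
#' @param frameRate sampling rate in Hz (taken from the `TailTrace` when
#'   omitted).
#' @return Dominant frequency in Hz (nearest bin).
#' @export
dominantFrequency <- function(trace, frameRate = NULL) {
  if (is(trace, "TailTrace")) {
    x <- trace@angle
    frameRate <- trace@frameRate
  } else {
    x <- as.numeric(trace)
    if (is.null(frameRate)) stop("'frameRate' is required")
  }
  if (sd(x) == 0) stop("no peak: constant angle trace")
  nper <- min(length(x), round(frameRate))
  w <- welchPsd(x, frameRate, nperseg = nper)
  nonDC <- -1L
  if (max(w$power[nonDC]) <= 0) stop("no peak: zero spectrum")
  w$frequency[nonDC][which.max(w$power[nonDC])]
}
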