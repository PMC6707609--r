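#' Tolerances for loop-feature extraction
#'
#' @param pinchClusterRadius Radius (as a fraction of the normalised V-I
#'   axes) within which polyline self-intersections are merged into a
#'   single pinch point.
#' @param slopeEqualityRel Relative slope difference below which the two
#'   branches through a pinch are considered to touch with equal slopes
#'   (tangential) rather than cross (transversal).
#' @param symmetryTol Origin-symmetry score at or below which a loop is
#'   considered symmetric with respect to the origin.
#' @param asymmetryTol Score above which a loop is considered clearly
#'   asymmetric.
#' @param slopeWindow Half-width (in samples) of the local window used for
#'   the least-squares branch-slope estimate at a pinch.
#' @return An object of class `"LoopTolerances"`.
#' @export
loopTolerances <- function(pinchClusterRadius = 0.01,
                           slopeEqualityRel = 0.1,
                           symmetryTol = 0.02,
                           asymmetryTol = 0.05,
                           slopeWindow = 5L) {
  stopifnot(pinchClusterRadius > 0, pinchClusterRadius < 1,
            slopeEqualityRel > 0, slopeEqualityRel < 1,
            symmetryTol > 0, symmetryTol < 1, asymmetryTol >= symmetryTol,
            slopeWindow >= 2)
  structure(list(pinchClusterRadius = pinchClusterRadius,
                 slopeEqualityRel = slopeEqualityRel,
                 symmetryTol = symmetryTol,
                 asymmetryTol = asymmetryTol,
                 slopeWindow = as.integer(slopeWindow)),
            class = "LoopTolerances")
}

# --- polyline machinery ------------------------------------------------

# One period of the V-I curve as a polygon.  The period is sampled from its
# first to its last boundary sample; the polygon is treated as closed (a
# chord from the last back to the first vertex) when the endpoint gap is
# small on the normalised axes, i.e. when the trajectory is near-periodic.
.loopPolyline <- function(trace, periodIndex) {
  idx <- .periodIndices(trace, periodIndex)
  v <- trace$v[idx]
  i <- trace$i_total[idx]
  sv <- max(abs(v))
  si <- max(abs(i))
  if (sv == 0 || si == 0) {
    return(list(v = v, i = i, t = trace$t[idx], sv = max(sv, 1),
                si = max(si, 1), closed = FALSE, degenerate = TRUE))
  }
  gap <- sqrt(((v[1] - v[length(v)]) / sv)^2 + ((i[1] - i[length(i)]) / si)^2)
  list(v = v, i = i, t = trace$t[idx], sv = sv, si = si,
       closed = gap < 0.02, degenerate = FALSE)
}

# All transversal intersections between non-adjacent segments of a polygon
# given by normalised vertex coordinates.  Candidate pairs come from a
# uniform grid bucketing of segment bounding boxes; `closed` appends the
# closing chord as the final segment.
.segIntersections <- function(xn, yn, closed) {
  n <- length(xn)
  if (closed) {
    ax <- xn; ay <- yn
    bx <- c(xn[-1], xn[1]); by <- c(yn[-1], yn[1])
  } else {
    ax <- xn[-n]; ay <- yn[-n]
    bx <- xn[-1]; by <- yn[-1]
  }
  ns <- length(ax)
  # bucket segments on a grid wide enough that a segment spans few cells
  ng <- 64L
  rngx <- range(c(ax, bx)); rngy <- range(c(ay, by))
  wx <- max(rngx[2] - rngx[1], 1e-12) / ng
  wy <- max(rngy[2] - rngy[1], 1e-12) / ng
  # pad the boxes so segments that merely touch (e.g. exactly at the
  # origin) still share a cell
  padx <- 1e-9 * max(abs(rngx)); pady <- 1e-9 * max(abs(rngy))
  ix0 <- pmax(pmin(floor((pmin(ax, bx) - padx - rngx[1]) / wx), ng - 1L), 0L)
  ix1 <- pmax(pmin(floor((pmax(ax, bx) + padx - rngx[1]) / wx), ng - 1L), 0L)
  iy0 <- pmax(pmin(floor((pmin(ay, by) - pady - rngy[1]) / wy), ng - 1L), 0L)
  iy1 <- pmax(pmin(floor((pmax(ay, by) + pady - rngy[1]) / wy), ng - 1L), 0L)
  nx <- ix1 - ix0 + 1L
  ny <- iy1 - iy0 + 1L
  nc <- nx * ny
  segRep <- rep.int(seq_len(ns), nc)
  off <- sequence(nc) - 1L
  cellKey <- (ix0[segRep] + off %% nx[segRep]) * ng +
    (iy0[segRep] + off %/% nx[segRep])
  byCell <- split(segRep, cellKey)
  byCell <- byCell[lengths(byCell) > 1L]
  pairs <- do.call(rbind, lapply(byCell, function(s) {
    s <- sort.int(unique(s))
    if (length(s) < 2) return(NULL)
    cbind(rep(s, rev(seq_along(s)) - 1L),
          s[unlist(lapply(seq_along(s)[-1], function(k) k:length(s)))])
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(segA = integer(0), segB = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  pairs <- pairs[!duplicated(pairs[, 1] * (ns + 1) + pairs[, 2]), ,
                 drop = FALSE]
  a <- pairs[, 1]; b <- pairs[, 2]
  # drop segment pairs that share a vertex (adjacent along the polygon);
  # on a closed polygon the near-degenerate closing chord makes the first
  # and last few segments effectively adjacent as well
  sep <- b - a
  if (closed) sep <- pmin(sep, ns - sep)
  keep <- sep >= if (closed) 4L else 2L
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) {
    return(data.frame(segA = integer(0), segB = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  d1x <- bx[a] - ax[a]; d1y <- by[a] - ay[a]
  d2x <- bx[b] - ax[b]; d2y <- by[b] - ay[b]
  den <- d1x * d2y - d1y * d2x
  ex <- ax[b] - ax[a]; ey <- ay[b] - ay[a]
  ok <- abs(den) > 1e-300
  s <- ifelse(ok, (ex * d2y - ey * d2x) / den, NA_real_)
  u <- ifelse(ok, (ex * d1y - ey * d1x) / den, NA_real_)
  # slightly relaxed parameter bounds: crossings that fall exactly on a
  # vertex (common when samples land on the zero crossings of the drive)
  # must not be lost to rounding
  eps <- 1e-9
  hit <- ok & s >= -eps & s <= 1 + eps & u >= -eps & u <= 1 + eps
  data.frame(segA = a[hit], segB = b[hit],
             x = ax[a[hit]] + s[hit] * d1x[hit],
             y = ay[a[hit]] + s[hit] * d1y[hit])
}

# Contact points: pairs of vertices from well-separated parts of the curve
# that lie within `eps` of each other.  A tangential pinch is a touch, not
# a transversal crossing, so it can elude segment intersection; the two
# branches still pass through (numerically) the same point.
.vertexContacts <- function(xn, yn, closed, eps, minSep = 6L) {
  n <- length(xn)
  cx <- ceiling(xn / eps)
  cy <- ceiling(yn / eps)
  key <- paste(cx, cy, sep = ",")
  grp <- split(seq_len(n), key)
  grpNames <- names(grp)
  cand <- NULL
  # compare vertices within the same and neighbouring grid cells
  for (dx in -1:1) for (dy in -1:1) {
    key2 <- paste(cx + dx, cy + dy, sep = ",")
    m <- match(key2, grpNames)
    hit <- which(!is.na(m))
    if (length(hit) == 0) next
    pairs <- do.call(rbind, lapply(hit, function(j) {
      others <- grp[[m[j]]]
      others <- others[others > j]
      if (length(others) == 0) return(NULL)
      cbind(j, others)
    }))
    cand <- rbind(cand, pairs)
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(data.frame(segA = integer(0), segB = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  cand <- unique(cand)
  a <- cand[, 1]; b <- cand[, 2]
  sep <- b - a
  if (closed) sep <- pmin(sep, n - sep)
  d <- sqrt((xn[a] - xn[b])^2 + (yn[a] - yn[b])^2)
  keep <- sep >= minSep & d < eps
  a <- a[keep]; b <- b[keep]
  data.frame(segA = pmin(a, length(xn) - 1L),
             segB = pmin(b, length(xn) - 1L),
             x = (xn[a] + xn[b]) / 2, y = (yn[a] + yn[b]) / 2)
}

# local least-squares slope di/dv (A/V) around segment `seg` of a period
.branchSlope <- function(v, i, seg, window) {
  idx <- max(1L, seg - window):min(length(v), seg + 1L + window)
  vv <- v[idx]; ii <- i[idx]
  if (max(vv) - min(vv) <= 0) return(NA_real_)
  unname(stats::coef(stats::lm(ii ~ vv))[2])
}

#' Detect pinch points of a V-I hysteresis loop
#'
#' Finds the self-intersections of the closed voltage-current polyline of
#' one full signal period by segment-pair intersection (adjacent segments
#' excluded), normalises coordinates by the period's voltage and current
#' scales, merges intersections lying within `pinchClusterRadius` of each
#' other (single-linkage), and reports one pinch point per cluster together
#' with the local slopes of the two crossing branches.
#'
#' @param trace A `"SimulationTrace"` (or recording converted to one).
#' @param periodIndex Which full period to analyse (1-based).
#' @param tol A [loopTolerances()] object.
#' @return A list of `"PinchPoint"` objects, each with fields `v` (V), `i`
#'   (A), `slopeBranch1`, `slopeBranch2` (A/V) and `distance` (normalised
#'   distance from the origin).  A degenerate (zero-area) loop yields an
#'   empty list.
#' @export
detectPinchPoints <- function(trace, periodIndex = attr(trace, "nPeriods"),
                              tol = loopTolerances()) {
  loop <- .loopPolyline(trace, periodIndex)
  if (loop$degenerate) return(list())
  xn <- loop$v / loop$sv
  yn <- loop$i / loop$si
  # degenerate loop: all points collinear (e.g. pure resistor), measured by
  # the minor principal standard deviation of the normalised point cloud
  # (a figure-eight loop has zero *signed* area, so area is no criterion)
  ev <- eigen(stats::cov(cbind(xn, yn)), symmetric = TRUE, only.values = TRUE)
  if (sqrt(max(ev$values[2], 0)) < 1e-7) return(list())
  # contacts must connect well-separated passes of the curve (a genuine
  # touch), not the two flanks of a hairpin fold at a loop apex
  hits <- rbind(
    .segIntersections(xn, yn, loop$closed),
    .vertexContacts(xn, yn, loop$closed,
                    eps = tol$pinchClusterRadius / 10,
                    minSep = max(6L, (length(xn) - 1L) %/% 8L)))
  if (nrow(hits) == 0) return(list())
  cl <- if (nrow(hits) == 1) 1L else {
    stats::cutree(stats::hclust(stats::dist(hits[, c("x", "y")]),
                                method = "single"),
                  h = tol$pinchClusterRadius)
  }
  lapply(sort(unique(cl)), function(k) {
    sub <- hits[cl == k, , drop = FALSE]
    cx <- mean(sub$x); cy <- mean(sub$y)
    rep_ <- which.min((sub$x - cx)^2 + (sub$y - cy)^2)
    s1 <- .branchSlope(loop$v, loop$i, sub$segA[rep_], tol$slopeWindow)
    s2 <- .branchSlope(loop$v, loop$i, sub$segB[rep_], tol$slopeWindow)
    structure(list(v = cx * loop$sv, i = cy * loop$si,
                   slopeBranch1 = s1, slopeBranch2 = s2,
                   distance = sqrt(cx^2 + cy^2)),
              class = "PinchPoint")
  })
}

#' @export
print.PinchPoint <- function(x, ...) {
  cat(sprintf(
    "PinchPoint at (%.4g V, %.4g A), branch slopes %.4g / %.4g A/V (norm. dist %.4g)\n",
    x$v, x$i, x$slopeBranch1, x$slopeBranch2, x$distance))
  invisible(x)
}

#' Classify a pinch point as transversal or tangential
#'
#' The two loop branches either cross the pinch with different slopes
#' (transversal) or touch it with equal slopes (tangential); the decision
#' uses the relative slope difference against `slopeEqualityRel`.
#'
#' @param p A `"PinchPoint"`.
#' @param tol A [loopTolerances()] object.
#' @return `"tangential"` or `"transversal"`.
#' @export
classifyPinch <- function(p, tol = loopTolerances()) {
  s1 <- p$slopeBranch1; s2 <- p$slopeBranch2
  if (!is.finite(s1) || !is.finite(s2)) {
    stop("pinch point has non-finite branch slopes")
  }
  smax <- max(abs(s1), abs(s2))
  if (smax < 1e-12) {
    stop("branch slopes are both ~0; classification undefined")
  }
  if (abs(s1 - s2) / smax < tol$slopeEqualityRel) "tangential" else "transversal"
}

# --- quadrant geometry -------------------------------------------------

# insert interpolated vertices where the polygon crosses either axis, so
# that quadrant membership partitions the polygon exactly
.axisRefine <- function(x, y, closed) {
  n <- length(x)
  nx <- if (closed) c(x[-1], x[1]) else x[-1]
  ny <- if (closed) c(y[-1], y[1]) else y[-1]
  cx <- if (closed) x else x[-n]
  cy <- if (closed) y else y[-n]
  outX <- list(); outY <- list()
  for (j in seq_along(cx)) {
    ts <- numeric(0)
    dx <- nx[j] - cx[j]; dy <- ny[j] - cy[j]
    if (cx[j] * nx[j] < 0) ts <- c(ts, -cx[j] / dx)
    if (cy[j] * ny[j] < 0) ts <- c(ts, -cy[j] / dy)
    ts <- sort(ts[ts > 0 & ts < 1])
    outX[[j]] <- c(cx[j], cx[j] + ts * dx)
    outY[[j]] <- c(cy[j], cy[j] + ts * dy)
  }
  x2 <- unlist(outX, use.names = FALSE)
  y2 <- unlist(outY, use.names = FALSE)
  if (!closed) { x2 <- c(x2, x[n]); y2 <- c(y2, y[n]) }
  list(x = x2, y = y2)
}

.quadrantOf <- function(x, y) {
  q <- integer(length(x))
  q[x > 0 & y > 0] <- 1L
  q[x < 0 & y > 0] <- 2L
  q[x < 0 & y < 0] <- 3L
  q[x > 0 & y < 0] <- 4L
  q  # 0 on an axis
}

# signed shoelace areas of the polygon portions lying in each quadrant
.quadrantSignedAreas <- function(trace, periodIndex) {
  loop <- .loopPolyline(trace, periodIndex)
  ref <- .axisRefine(loop$v, loop$i, closed = TRUE)
  x <- ref$x; y <- ref$y
  n <- length(x)
  m <- .quadrantOf(x, y)
  vapply(1:4, function(q) {
    if (all(m == q)) {
      xs <- x; ys <- y
      return(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2)
    }
    if (!any(m == q)) return(0)
    # rotate so the polygon does not start inside the target quadrant
    off <- which(m != q)[1] - 1L
    rot <- c((off + 1L):n, seq_len(off))
    xr <- x[rot]; yr <- y[rot]; mr <- m[rot]
    inq <- mr == q
    r <- rle(inq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tot <- 0
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      # pull in the bounding on-axis vertices so lobes close at the axes
      if (a > 1 && mr[a - 1L] == 0L) a <- a - 1L
      if (b < n && mr[b + 1L] == 0L) b <- b + 1L
      xs <- xr[a:b]; ys <- yr[a:b]
      tot <- tot + sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2
    }
    tot
  }, numeric(1))
}

#' Orientation of the loop within one quadrant
#'
#' Signed (shoelace) area of the loop portion lying in the given quadrant:
#' counter-clockwise if positive, clockwise if negative, undefined if the
#' magnitude is below a machine-scale threshold.  Quadrant membership uses
#' the strict signs of voltage and current; samples on an axis belong to no
#' quadrant (lobes are closed at interpolated axis crossings).
#'
#' @inheritParams detectPinchPoints
#' @param quadrant Quadrant number, 1-4.
#' @return `"ccw"`, `"cw"` or `"undefined"`.
#' @export
quadrantOrientation <- function(trace, periodIndex = attr(trace, "nPeriods"),
                                quadrant) {
  stopifnot(quadrant %in% 1:4)
  loop <- .loopPolyline(trace, periodIndex)
  a <- .quadrantSignedAreas(trace, periodIndex)[quadrant]
  thresh <- 1e-10 * loop$sv * loop$si
  if (a > thresh) "ccw" else if (a < -thresh) "cw" else "undefined"
}

#' Per-quadrant lobe areas of the loop
#'
#' Absolute shoelace area of the loop portion in each quadrant, in
#' volt-ampere.
#'
#' @inheritParams detectPinchPoints
#' @return Named numeric vector `c(q1 =, q2 =, q3 =, q4 =)`, all >= 0.
#' @export
lobeAreas <- function(trace, periodIndex = attr(trace, "nPeriods")) {
  a <- abs(.quadrantSignedAreas(trace, periodIndex))
  names(a) <- paste0("q", 1:4)
  a
}

#' Origin-symmetry score of the loop
#'
#' For every sample `(v, i)` of the period the distance from the
#' point-reflected location `(-v, -i)` to the loop polyline is computed on
#' normalised axes; the score is the maximum such distance.  0 means the
#' loop is perfectly symmetric with respect to the origin.
#'
#' @inheritParams detectPinchPoints
#' @return A non-negative dimensionless score.
#' @export
originSymmetryScore <- function(trace,
                                periodIndex = attr(trace, "nPeriods")) {
  loop <- .loopPolyline(trace, periodIndex)
  if (loop$degenerate) return(0)
  x <- loop$v / loop$sv
  y <- loop$i / loop$si
  n <- length(x)
  if (loop$closed) {
    ax <- x; ay <- y
    bx <- c(x[-1], x[1]); by <- c(y[-1], y[1])
  } else {
    ax <- x[-n]; ay <- y[-n]
    bx <- x[-1]; by <- y[-1]
  }
  dxs <- bx - ax; dys <- by - ay
  len2 <- pmax(dxs^2 + dys^2, 1e-300)
  ns <- length(ax)
  qx <- -x; qy <- -y
  # coarse-to-fine nearest-segment search: locate the best few coarse
  # vertices globally, then measure exact point-to-segment distances in a
  # window around each (the window overlaps the coarse stride, so the true
  # nearest segment is always inspected)
  stride <- max(1L, ns %/% 256L)
  coarse <- seq(1L, ns, by = stride)
  d2c <- outer(qx, ax[coarse], "-")^2 + outer(qy, ay[coarse], "-")^2
  m1 <- max.col(-d2c, ties.method = "first")
  k1 <- coarse[m1]
  # blank out the neighbourhood of the first candidate so the second one
  # comes from a different pass of the curve
  nc <- length(coarse)
  for (dd in -2:2) {
    cc <- pmin(pmax(m1 + dd, 1L), nc)
    d2c[cbind(seq_len(n), cc)] <- Inf
  }
  m2 <- max.col(-d2c, ties.method = "first")
  k2 <- coarse[m2]
  for (dd in -2:2) {
    cc <- pmin(pmax(m2 + dd, 1L), nc)
    d2c[cbind(seq_len(n), cc)] <- Inf
  }
  k3 <- coarse[max.col(-d2c, ties.method = "first")]
  segDist2 <- function(q, segs) {
    px <- qx[q] - ax[segs]; py <- qy[q] - ay[segs]
    tt <- pmin(pmax((px * dxs[segs] + py * dys[segs]) / len2[segs], 0), 1)
    min((px - tt * dxs[segs])^2 + (py - tt * dys[segs])^2)
  }
  # the first window must cover everything blanked around k1
  w <- 3L * stride + 2L
  best2 <- vapply(seq_len(n), function(q) {
    s1 <- max(1L, k1[q] - w):min(ns, k1[q] + w)
    s2 <- max(1L, k2[q] - w):min(ns, k2[q] + w)
    s3 <- max(1L, k3[q] - w):min(ns, k3[q] + w)
    min(segDist2(q, s1), segDist2(q, s2), segDist2(q, s3))
  }, numeric(1))
  sqrt(max(best2))
}

#' Memductance extrema within one period
#'
#' Local maxima of the branch memductance over the period, with plateau
#' handling (a plateau higher than both neighbours is reported once, at its
#' start; a constant trace is reported as a single degenerate maximum at
#' the period start).
#'
#' @inheritParams detectPinchPoints
#' @param branch `"tangential"` or `"transversal"`.
#' @return A data frame with columns `time` (s) and `value` (S).
#' @export
memductanceExtrema <- function(trace,
                               periodIndex = attr(trace, "nPeriods"),
                               branch = c("tangential", "transversal")) {
  branch <- match.arg(branch)
  col <- if (branch == "tangential") "g_tang" else "g_tran"
  idx <- .periodIndices(trace, periodIndex)
  g <- trace[[col]][idx]
  tt <- trace$t[idx]
  if (all(is.na(g))) stop(sprintf("branch '%s' is not active in this trace", branch))
  if (max(g) - min(g) == 0) {
    return(data.frame(time = tt[1], value = g[1]))
  }
  s <- sign(diff(g))
  # merge plateaus: carry the previous non-zero direction forward
  for (j in seq_along(s)) if (s[j] == 0 && j > 1) s[j] <- s[j - 1]
  up <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  data.frame(time = tt[up], value = g[up])
}

#' Lag of the current extrema behind the voltage extrema
#'
#' Time of the total-current maximum minus the time of the voltage maximum
#' within the period (and the same for the minima), wrapped into
#' `(-t_period/2, t_period/2]`.  Positive lag means the current peak occurs
#' after the voltage peak.
#'
#' @inheritParams detectPinchPoints
#' @return A list with `lagMax` and `lagMin`, in seconds.
#' @export
currentPeakLag <- function(trace, periodIndex = attr(trace, "nPeriods")) {
  idx <- .periodIndices(trace, periodIndex)
  tt <- trace$t[idx]
  tp <- tt[length(tt)] - tt[1]
  wrap <- function(d) {
    d <- d %% tp
    if (d > tp / 2) d - tp else d
  }
  list(lagMax = wrap(tt[which.max(trace$i_total[idx])] -
                       tt[which.max(trace$v[idx])]),
       lagMin = wrap(tt[which.min(trace$i_total[idx])] -
                       tt[which.min(trace$v[idx])]))
}

#' Per-period drift of the internal states
#'
#' Differences of each active internal state between consecutive period
#' boundaries; a nonzero drift indicates a cumulative state change from
#' period to period (e.g. under a DC-offset drive).
#'
#' @param trace A `"SimulationTrace"` covering at least 2 periods.
#' @return A list with one numeric vector per active state (`temperature`
#'   in K, `x` dimensionless), each of length `nPeriods`; element `k` is
#'   the state change across period `k`.
#' @export
perPeriodDrift <- function(trace) {
  np <- attr(trace, "nPeriods")
  spp <- attr(trace, "samplesPerPeriod")
  if (np < 2) stop("per-period drift needs at least 2 simulated periods")
  bnd <- seq(1L, np * spp + 1L, by = spp)
  out <- list()
  if (!all(is.na(trace$temperature))) {
    out$temperature <- diff(trace$temperature[bnd])
  }
  if (!all(is.na(trace$x))) {
    out$x <- diff(trace$x[bnd])
  }
  out
}

#' Phase-angle range of a single-memristor circuit with parallel capacitance
#'
#' The parallel capacitance causes a state-dependent phase shift
#' \eqn{\alpha = \arctan(2\pi f C / G)} between voltage and current.  The
#' extreme phase angles over a period follow from the extreme branch
#' conductances reached during that period: the minimum angle at the
#' maximum conductance and vice versa.
#'
#' @inheritParams detectPinchPoints
#' @param capacitance Capacitance in farad; defaults to the trace's
#'   configured value.
#' @param frequency Signal frequency in Hz; defaults to the trace's
#'   stimulus frequency.
#' @return A list with `alphaMin` and `alphaMax`, in degrees
#'   (`alphaMin <= alphaMax`).
#' @export
phaseAngleRange <- function(trace, periodIndex = attr(trace, "nPeriods"),
                            capacitance = NULL, frequency = NULL) {
  cfg <- attr(trace, "config")
  if (is.null(capacitance)) capacitance <- cfg$capacitance
  if (is.null(frequency)) frequency <- attr(trace, "stimulus")$frequency
  stopifnot(capacitance >= 0)
  hasTang <- !all(is.na(trace$g_tang))
  hasTran <- !all(is.na(trace$g_tran))
  if (hasTang && hasTran) {
    stop("phase-angle range is defined for a single-memristor circuit only")
  }
  if (!hasTang && !hasTran) stop("no memristor branch active in trace")
  idx <- .periodIndices(trace, periodIndex)
  g <- if (hasTang) trace$g_tang[idx] else trace$g_tran[idx]
  b <- 2 * pi * frequency * capacitance
  list(alphaMin = atan(b / max(g)) * 180 / pi,
       alphaMax = atan(b / min(g)) * 180 / pi)
}

#' Full loop-feature summary for one period
#'
#' Runs the complete feature extractor: pinch-point detection and
#' classification, quadrant orientations, lobe areas, origin symmetry,
#' current peak lag, per-period state drift (when two or more periods are
#' present) and, for single-memristor circuits with known capacitance, the
#' phase-angle range.
#'
#' @inheritParams detectPinchPoints
#' @return An object of class `"LoopFeatures"`.
#' @export
loopFeatures <- function(trace, periodIndex = attr(trace, "nPeriods"),
                         tol = loopTolerances()) {
  pp <- detectPinchPoints(trace, periodIndex, tol)
  pinchClass <- if (length(pp) == 0) "none" else {
    nearest <- pp[[which.min(vapply(pp, `[[`, numeric(1), "distance"))]]
    tryCatch(classifyPinch(nearest, tol), error = function(e) "none")
  }
  phase <- tryCatch(phaseAngleRange(trace, periodIndex),
                    error = function(e) list(alphaMin = NA_real_,
                                             alphaMax = NA_real_))
  drift <- if (isTRUE(attr(trace, "nPeriods") >= 2)) perPeriodDrift(trace) else list()
  structure(list(
    pinchPoints = pp,
    pinchCount = length(pp),
    pinchClass = pinchClass,
    orientationQ1 = quadrantOrientation(trace, periodIndex, 1),
    orientationQ3 = quadrantOrientation(trace, periodIndex, 3),
    lobeAreas = lobeAreas(trace, periodIndex),
    originSymmetryScore = originSymmetryScore(trace, periodIndex),
    phaseMin = phase$alphaMin, phaseMax = phase$alphaMax,
    currentPeakLag = currentPeakLag(trace, periodIndex),
    perPeriodDrift = drift,
    periodIndex = periodIndex), class = "LoopFeatures")
}

#' @export
print.LoopFeatures <- function(x, ...) {
  cat(sprintf("LoopFeatures (period %d)\n", x$periodIndex))
  cat(sprintf("  pinch points: %d (%s)\n", x$pinchCount, x$pinchClass))
  for (p in x$pinchPoints) { cat("   "); print(p) }
  cat(sprintf("  orientation: Q1 %s, Q3 %s\n", x$orientationQ1, x$orientationQ3))
  cat(sprintf("  lobe areas (V*A): %s\n",
              paste(sprintf("%s=%.3g", names(x$lobeAreas), x$lobeAreas),
                    collapse = " ")))
  cat(sprintf("  origin symmetry score: %.4g\n", x$originSymmetryScore))
  if (is.finite(x$phaseMin)) {
    cat(sprintf("  phase range: %.3g to %.3g deg\n", x$phaseMin, x$phaseMax))
  }
  cat(sprintf("  current peak lag: max %+.3g s, min %+.3g s\n",
              x$currentPeakLag$lagMax, x$currentPeakLag$lagMin))
  invisible(x)
}

#' Write a loop-feature summary as JSON
#'
#' Mirrors the `"LoopFeatures"` object field-for-field; units are embedded
#' in the key names (V*A areas, degrees, seconds).
#'
#' @param features A `"LoopFeatures"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(features, path) {
  doc <- list(
    period_index = features$periodIndex,
    pinch_count = features$pinchCount,
    pinch_class = features$pinchClass,
    pinch_points = lapply(features$pinchPoints, function(p) {
      list(v_V = p$v, i_A = p$i, slope_branch_1_ApV = p$slopeBranch1,
           slope_branch_2_ApV = p$slopeBranch2,
           norm_distance_from_origin = p$distance)
    }),
    orientation_q1 = features$orientationQ1,
    orientation_q3 = features$orientationQ3,
    lobe_areas_VA = as.list(features$lobeAreas),
    origin_symmetry_score = features$originSymmetryScore,
    phase_min_deg = features$phaseMin,
    phase_max_deg = features$phaseMax,
    current_peak_lag_s = features$currentPeakLag,
    per_period_drift = features$perPeriodDrift)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
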