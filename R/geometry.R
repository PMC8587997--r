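# 3-D computational geometry for the subspace-overlap analysis: an
# incremental (Bowyer-Watson) Delaunay tetrahedralization, the alpha
# complex with the smallest alpha giving one connected region that
# encloses every point (the MATLAB `alphashape` default criterion), and
# seeded Monte-Carlo volume-overlap estimation.

tet_circumsphere <- function(v) {
  # v: 4 x 3 vertex matrix; returns center and squared radius
  a <- 2 * (v[2:4, , drop = FALSE] - matrix(v[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
  c <- solve(a, b)
  list(center = c, r2 = sum((c - v[1, ])^2))
}

tet_volume <- function(v) {
  abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
}

face_key <- function(i, j, k) {
  s <- sort(c(i, j, k))
  paste(s[1], s[2], s[3])
}

#' Delaunay tetrahedralization of 3-D points
#'
#' Incremental Bowyer-Watson construction. A deterministic sub-nanometric
#' jitter (relative to the cloud extent) breaks cospherical and coplanar
#' degeneracies, so results are reproducible for identical input.
#'
#' @param points numeric matrix n x 3 (n >= 4).
#' @return List with `points` (possibly jittered), `tets` (m x 4 vertex
#'   indices), `centers` (m x 3 circumcenters) and `r2` (squared
#'   circumradii).
#' @export
delaunay3d <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  scale <- max(apply(points, 2, function(x) diff(range(x))), 1e-12)
  if (qr(sweep(points, 2, colMeans(points)))$rank < 3) {
    warning("degenerate (coplanar) point set; jittering before triangulation")
    points <- points + with_seed(971, matrix(stats::rnorm(3 * n), n, 3)) *
      scale * 1e-4
  }
  pts <- points + with_seed(4099, matrix(stats::runif(3 * n, -1, 1), n, 3)) *
    scale * 1e-9

  ctr <- colMeans(pts)
  rad <- 2 * sqrt(max(rowSums(sweep(pts, 2, ctr)^2))) + scale
  super <- rbind(ctr + 20 * rad * c(1, 0, -1 / sqrt(2)),
                 ctr + 20 * rad * c(-1, 0, -1 / sqrt(2)),
                 ctr + 20 * rad * c(0, 1, 1 / sqrt(2)),
                 ctr + 20 * rad * c(0, -1, 1 / sqrt(2)))
  verts <- rbind(pts, super)
  sidx <- n + 1:4

  tets <- matrix(sidx, nrow = 1)
  cs <- tet_circumsphere(verts[sidx, ])
  centers <- matrix(cs$center, nrow = 1)
  r2 <- cs$r2

  for (i in seq_len(n)) {
    p <- verts[i, ]
    bad <- which(rowSums(sweep(centers, 2, p)^2) < r2)
    if (!length(bad)) bad <- which.min(rowSums(sweep(centers, 2, p)^2) - r2)
    faces <- list()
    counts <- new.env(hash = TRUE)
    for (t in bad) {
      tv <- tets[t, ]
      for (f in list(tv[-1], tv[-2], tv[-3], tv[-4])) {
        key <- face_key(f[1], f[2], f[3])
        counts[[key]] <- if (is.null(counts[[key]])) list(1L, f)
                         else list(counts[[key]][[1]] + 1L, f)
      }
    }
    boundary <- Filter(function(x) x[[1]] == 1L,
                       mget(ls(counts), envir = counts))
    new_tets <- do.call(rbind, lapply(boundary, function(x) c(x[[2]], i)))
    keep <- setdiff(seq_len(nrow(tets)), bad)
    tets <- rbind(tets[keep, , drop = FALSE], new_tets)
    centers <- centers[keep, , drop = FALSE]
    r2 <- r2[keep]
    for (t in seq_len(nrow(new_tets))) {
      cs <- tet_circumsphere(verts[new_tets[t, ], ])
      centers <- rbind(centers, cs$center)
      r2 <- c(r2, cs$r2)
    }
  }
  real <- apply(tets, 1, function(tv) all(tv <= n))
  list(points = pts, tets = tets[real, , drop = FALSE],
       centers = centers[real, , drop = FALSE], r2 = r2[real])
}

tets_connected <- function(tets) {
  m <- nrow(tets)
  if (m <= 1) return(TRUE)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  faces <- new.env(hash = TRUE)
  for (t in seq_len(m)) {
    tv <- tets[t, ]
    for (f in list(tv[-1], tv[-2], tv[-3], tv[-4])) {
      key <- face_key(f[1], f[2], f[3])
      other <- faces[[key]]
      if (is.null(other)) faces[[key]] <- t
      else {
        ri <- find(t); rj <- find(other)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(m), find, 1L))) == 1L
}

#' Alpha-shape bounding volume of a 3-D point cloud
#'
#' Builds the Delaunay tetrahedralization and keeps the tetrahedra with
#' circumradius below alpha. By default alpha is the smallest critical
#' value (a circumradius) at which the kept complex uses every input
#' point as a vertex and forms a single face-connected region — the
#' criterion MATLAB's `alphashape` applies when no radius is given. With
#' `alpha = Inf` the shape is the convex hull.
#'
#' @param points numeric matrix n x 3 of projected step cycles.
#' @param alpha fixed alpha radius, or NULL for the automatic criterion.
#' @return Object of class `alpha_shape3d`: `points`, `tets`, `alpha`,
#'   `volume`, per-tet volumes and the affine inverses used for fast
#'   membership tests.
#' @export
alpha_shape3d <- function(points, alpha = NULL) {
  dt <- delaunay3d(points)
  radii <- sqrt(dt$r2)
  if (is.null(alpha)) {
    cand <- sort(unique(radii))
    chosen <- NULL
    for (a in cand) {
      sub <- dt$tets[radii <= a, , drop = FALSE]
      if (length(unique(as.vector(sub))) < nrow(dt$points)) next
      if (tets_connected(sub)) { chosen <- a; break }
    }
    if (is.null(chosen)) chosen <- max(radii)
    alpha <- chosen
  }
  keep <- radii <= alpha
  tets <- dt$tets[keep, , drop = FALSE]
  m <- nrow(tets)
  vols <- numeric(m)
  v0 <- matrix(0, m, 3)
  minv <- vector("list", m)
  for (t in seq_len(m)) {
    v <- dt$points[tets[t, ], , drop = FALSE]
    vols[t] <- tet_volume(v)
    v0[t, ] <- v[1, ]
    e <- t(v[2:4, , drop = FALSE]) - v[1, ]   # 3 x 3 edge matrix
    minv[[t]] <- tryCatch(solve(e), error = function(err) NULL)
  }
  structure(list(points = dt$points, tets = tets, alpha = alpha,
                 volume = sum(vols), tet_volumes = vols, v0 = v0,
                 minv = minv),
            class = "alpha_shape3d")
}

#' @export
print.alpha_shape3d <- function(x, ...) {
  cat(sprintf("alpha shape: %d points, %d tetrahedra, alpha = %.4g, volume = %.4g\n",
              nrow(x$points), nrow(x$tets), x$alpha, x$volume))
  invisible(x)
}

#' Test points for membership in an alpha shape
#'
#' @param shape an [alpha_shape3d()].
#' @param pts numeric matrix n x 3.
#' @param tol barycentric tolerance.
#' @return Logical vector of length n.
#' @export
point_in_shape <- function(shape, pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  todo <- seq_len(nrow(pts))
  for (t in seq_len(nrow(shape$tets))) {
    if (!length(todo)) break
    mi <- shape$minv[[t]]
    if (is.null(mi)) next
    d <- t(pts[todo, , drop = FALSE]) - shape$v0[t, ]
    b <- mi %*% d
    ok <- b[1, ] >= -tol & b[2, ] >= -tol & b[3, ] >= -tol &
      colSums(b) <= 1 + tol
    inside[todo[ok]] <- TRUE
    todo <- todo[!ok]
  }
  inside
}

#' Sample points uniformly inside an alpha shape
#'
#' Tetrahedra are selected proportionally to their volume and points
#' drawn uniformly within each via symmetric-Dirichlet barycentric
#' weights, giving exactly uniform samples over the shape.
#'
#' @param shape an [alpha_shape3d()] with positive volume.
#' @param n number of samples (uses the current RNG state).
#' @return Numeric matrix n x 3.
#' @export
sample_in_shape <- function(shape, n) {
  if (shape$volume <= 0) stop("zero-volume shape", call. = FALSE)
  prob <- shape$tet_volumes / shape$volume
  pick <- sample.int(nrow(shape$tets), n, replace = TRUE, prob = prob)
  w <- matrix(stats::rexp(4 * n), n, 4)
  w <- w / rowSums(w)
  out <- matrix(0, n, 3)
  for (t in unique(pick)) {
    rows <- which(pick == t)
    v <- shape$points[shape$tets[t, ], , drop = FALSE]
    out[rows, ] <- w[rows, , drop = FALSE] %*% v
  }
  out
}

#' Monte-Carlo overlap of two bounding volumes
#'
#' Percentage of shape `a`'s volume shared with shape `b`: seeded uniform
#' samples inside `a`, fraction falling inside `b`, times 100. The
#' definition is deliberately asymmetric (the reference participant's
#' total volume is the denominator).
#'
#' @param a,b [alpha_shape3d()] objects; `a` is the reference.
#' @param mc_samples Monte-Carlo sample count.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return Overlap percentage in \[0, 100\].
#' @export
pairwise_overlap_percent <- function(a, b, mc_samples = 1e5, seed = NULL) {
  if (a$volume <= 0) stop("undefined overlap: reference volume is zero",
                          call. = FALSE)
  draw <- function() {
    s <- sample_in_shape(a, mc_samples)
    mean(point_in_shape(b, s)) * 100
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
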