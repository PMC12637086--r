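## Exact convex-hull volume in 1, 2 and 3 dimensions. The t-ratio statistic
## divides the fitted simplex volume by the hull volume of the data; the
## study fits simplices in at most 3 PC dimensions, so exact hulls are
## provided up to d = 3 (1D: range; 2D: shoelace on the hull polygon;
## 3D: quickhull).

#' Volume of the convex hull of a point cloud
#'
#' @param x n x d numeric matrix, d in 1..3.
#' @return hull volume (length for d=1, area for d=2).
#' @export
convex_hull_volume <- function(x) {
  x <- as.matrix(x)
  d <- ncol(x)
  .assert(nrow(x) > d, "need more than d points for a d-dimensional hull")
  if (d == 1) return(diff(range(x)))
  if (d == 2) {
    h <- grDevices::chull(x)
    p <- x[h, , drop = FALSE]  # counter-clockwise polygon
    n <- nrow(p)
    if (n < 3) return(0)
    i2 <- c(2:n, 1)
    return(abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2)
  }
  if (d == 3) return(.quickhull3_volume(x))
  .fail("convex hull volume only implemented for d <= 3 (got d = %d)", d)
}

## 3D quickhull, returning the hull volume.
.quickhull3_volume <- function(pts) {
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(c) diff(range(c))), .Machine$double.eps)
  eps <- 1e-10 * scale

  ## --- initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) .fail("degenerate point cloud (zero extent)")
  d12 <- pts[i2, ] - pts[i1, ]
  ## furthest from the line i1-i2
  w <- sweep(pts, 2, pts[i1, ])
  t <- as.vector(w %*% d12) / sum(d12^2)
  perp <- w - outer(t, d12)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) < eps) .fail("degenerate (collinear) points in 3D hull")
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- as.vector(w %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < eps) .fail("degenerate (coplanar) points in 3D hull")
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  faces <- list()
  new_face <- function(a, b, c, cand) {
    nv <- .cross3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    if (sum((pts[a, ] - interior) * nv) < 0) { tmp <- b; b <- c; c <- tmp; nv <- -nv }
    off <- sum(nv * pts[a, ])
    dst <- as.vector(pts[cand, , drop = FALSE] %*% nv) - off
    nrm2 <- sqrt(sum(nv^2))
    out <- cand[dst > eps * nrm2]
    list(v = c(a, b, c), normal = nv, offset = off, outside = out)
  }
  cand0 <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  faces[[1]] <- new_face(i1, i2, i3, cand0)
  faces[[2]] <- new_face(i1, i2, i4, cand0)
  faces[[3]] <- new_face(i1, i3, i4, cand0)
  faces[[4]] <- new_face(i2, i3, i4, cand0)

  ## --- iterate: expand past the furthest outside point of any face
  repeat {
    fi <- which(vapply(faces, function(f) length(f$outside) > 0, TRUE))
    if (!length(fi)) break
    f <- faces[[fi[1]]]
    dst <- as.vector(pts[f$outside, , drop = FALSE] %*% f$normal) - f$offset
    p <- f$outside[which.max(dst)]
    vis <- which(vapply(faces, function(g)
      sum(g$normal * pts[p, ]) - g$offset >
        eps * sqrt(sum(g$normal^2)), TRUE))
    ## horizon: edges of visible faces shared with no other visible face
    edges <- do.call(rbind, lapply(faces[vis], function(g)
      rbind(sort(g$v[c(1, 2)]), sort(g$v[c(2, 3)]), sort(g$v[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    cand <- unique(c(unlist(lapply(faces[vis], `[[`, "outside"))))
    cand <- setdiff(cand, p)
    faces[vis] <- NULL
    for (e in seq_len(nrow(horizon)))
      faces[[length(faces) + 1L]] <-
        new_face(horizon[e, 1], horizon[e, 2], p, cand)
  }

  ## --- volume: sum of tetrahedra (interior point, face)
  vol <- 0
  for (f in faces) {
    a <- pts[f$v[1], ] - interior
    b <- pts[f$v[2], ] - interior
    c <- pts[f$v[3], ] - interior
    vol <- vol + abs(sum(a * .cross3(b, c))) / 6
  }
  vol
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## volume of a d-simplex given (d+1) x d vertex matrix
.simplex_volume <- function(v) {
  d <- ncol(v)
  abs(det(sweep(v[-1, , drop = FALSE], 2, v[1, ]))) / factorial(d)
}
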