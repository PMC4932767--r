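cloud_tol <- function(points) 1e-9 * max(1, max(abs(points)))

#' Build a convex cloud from a point set
#'
#' Constructs the convex hull of an n x d point set (d <= 5) by
#' incremental insertion: facets a new point lies beyond are replaced by
#' the cone from the point to the horizon ridges, so the result equals
#' the hull of all points regardless of insertion order.  The cloud
#' stores the hull as half-spaces (outward unit normals and offsets), its
#' exact volume, and the indices of the boundary points (the convex
#' envelope).
#'
#' Affinely degenerate input (points spanning fewer than d dimensions)
#' yields a cloud with volume 0 and a `degenerate` flag; the hull is then
#' built recursively inside the spanned affine subspace so that
#' membership tests remain meaningful.
#'
#' @param points numeric matrix (rows = points, columns = dimensions,
#'   d <= 5).
#' @param tol numeric tolerance; defaults to `1e-9` times the coordinate
#'   scale.
#' @return an object of class `cloud`.
#' @export
build_hull <- function(points, tol = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points); d <- ncol(points)
  if (d > 5L) stop("clouds are supported up to 5 dimensions")
  if (n == 0L) {
    return(structure(list(points = points, dim = d, rank = 0L,
                          center = rep(NA_real_, d), tol = tol %||% 1e-9,
                          degenerate = TRUE, volume = 0,
                          normals = NULL, offsets = NULL, facet_verts = NULL,
                          boundary_idx = integer(0), basis = NULL,
                          subcloud = NULL),
                     class = "cloud"))
  }
  if (is.null(tol)) tol <- cloud_tol(points)
  center <- colMeans(points)
  ctr <- sweep(points, 2L, center)
  sv <- svd(ctr, nu = 0L)
  rank <- sum(sv$d > max(tol, 1e-12 * max(sv$d, 1)))
  out <- structure(list(points = points, dim = d, rank = rank,
                        center = center, tol = tol,
                        degenerate = rank < d, volume = 0,
                        normals = NULL, offsets = NULL, facet_verts = NULL,
                        boundary_idx = integer(0), basis = NULL,
                        subcloud = NULL),
                   class = "cloud")
  if (rank == d && n >= d + 1L) {
    res <- .hull_build_cpp(points, max(tol * 0.1, 1e-13))
    if (isTRUE(res$ok)) {
      out$degenerate <- FALSE
      out$volume <- res$volume
      out$normals <- res$normals
      out$offsets <- as.numeric(res$offsets)
      out$facet_verts <- res$facet_verts
      out$boundary_idx <- sort(as.integer(res$boundary_idx))
      return(out)
    }
    out$degenerate <- TRUE
    out$rank <- rank <- max(0L, min(rank, n - 1L))
  }
  # degenerate: recurse within the spanned affine subspace
  if (rank == 0L || n == 0L) {
    out$boundary_idx <- seq_len(min(n, 1L))
    return(out)
  }
  basis <- sv$v[, seq_len(rank), drop = FALSE]
  out$basis <- basis
  sub <- build_hull(ctr %*% basis)
  out$subcloud <- sub
  out$boundary_idx <- sub$boundary_idx
  out
}

#' @export
print.cloud <- function(x, ...) {
  cat(sprintf("Convex cloud: %d points in %d-D%s, volume %.6g, %d boundary point(s)\n",
              nrow(x$points), x$dim,
              if (x$degenerate) sprintf(" (degenerate, rank %d)", x$rank) else "",
              x$volume, length(x$boundary_idx)))
  invisible(x)
}

#' Point-in-cloud membership
#'
#' Boundary-inclusive: a point on a facet (within tolerance) counts as
#' inside.  For a degenerate cloud, membership is tested within its
#' affine subspace; points off the subspace are outside.
#'
#' @param cloud a [build_hull] result.
#' @param points numeric vector (one point) or matrix (rows = points).
#' @return logical vector.
#' @export
cloud_contains <- function(cloud, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != cloud$dim)
    stop("query dimensionality does not match the cloud")
  if (nrow(cloud$points) == 0L) return(rep(FALSE, nrow(points)))
  tol <- max(cloud$tol, cloud_tol(rbind(cloud$points, points)))
  if (!cloud$degenerate)
    return(as.logical(.hull_contains_cpp(cloud$normals, cloud$offsets,
                                         points, tol)))
  ctr <- sweep(points, 2L, cloud$center)
  if (cloud$rank == 0L)
    return(sqrt(rowSums(ctr^2)) <= tol)
  proj <- ctr %*% cloud$basis
  resid <- sqrt(rowSums((ctr - proj %*% t(cloud$basis))^2))
  ok <- resid <= tol
  ok[ok] <- cloud_contains(cloud$subcloud, proj[ok, , drop = FALSE])
  ok
}

#' Overlap of two clouds
#'
#' `Pov` counts the points of each cloud lying inside the other (exact,
#' via [cloud_contains]).  The overlap volume `Vov` is estimated either
#' by seeded Monte-Carlo rejection sampling (`method = "mc"`: uniform
#' draws in each hull's bounding box, kept if inside that hull, counted
#' if also inside the other; the two directional estimates are averaged
#' and a standard error is reported) or exactly for d <= 3
#' (`method = "exact"`: vertex enumeration of the intersection of the two
#' half-space systems, then the hull volume of those vertices).
#'
#' @param a,b clouds from [build_hull].
#' @param method `"mc"` or `"exact"`.
#' @param mc_samples Monte-Carlo draws per direction (default 1e5; fewer
#'   than 1000 records a warning).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return list with `Vov`, `Pov`, `method`, `mc_se` (NA for exact).
#' @export
cloud_overlap <- function(a, b, method = c("mc", "exact"),
                          mc_samples = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(a, "cloud"), inherits(b, "cloud"))
  Pov <- sum(cloud_contains(b, a$points)) + sum(cloud_contains(a, b$points))
  if (a$volume <= 0 || b$volume <= 0)
    return(list(Vov = 0, Pov = Pov, method = method, mc_se = 0))
  if (method == "exact") {
    if (a$dim > 3L)
      stop("exact overlap (half-space intersection) is supported for d <= 3")
    return(list(Vov = halfspace_intersection_volume(a, b), Pov = Pov,
                method = "exact", mc_se = NA_real_))
  }
  if (mc_samples < 1000)
    warning("fewer than 1000 Monte-Carlo samples: overlap estimate is noisy")
  set.seed(as.integer(seed))
  one_way <- function(from, other) {
    bb <- apply(from$points, 2L, range)
    m <- as.integer(mc_samples)
    X <- vapply(seq_len(from$dim),
                function(j) runif(m, bb[1L, j], bb[2L, j]),
                numeric(m))
    inside <- cloud_contains(from, X)
    k_in <- sum(inside)
    if (k_in == 0L) return(c(V = 0, se = NA_real_))
    p <- sum(cloud_contains(other, X[inside, , drop = FALSE])) / k_in
    c(V = from$volume * p,
      se = from$volume * sqrt(p * (1 - p) / k_in))
  }
  ea <- one_way(a, b)
  eb <- one_way(b, a)
  Vov <- min((ea[["V"]] + eb[["V"]]) / 2, a$volume, b$volume)
  se <- sqrt(sum(c(ea[["se"]], eb[["se"]])^2, na.rm = TRUE)) / 2
  list(Vov = Vov, Pov = Pov, method = "mc", mc_se = se)
}

#' Exact overlap volume by half-space intersection (d <= 3)
#'
#' Enumerates candidate vertices of the intersection polytope by solving
#' every d-subset of the combined facet hyperplanes, keeps the feasible
#' ones, and returns the hull volume of those vertices.  Serves as the
#' low-dimensional oracle for the Monte-Carlo estimator.
#'
#' @param a,b non-degenerate clouds of equal dimension d <= 3.
#' @return the intersection volume (0 when the clouds are disjoint).
#' @export
halfspace_intersection_volume <- function(a, b) {
  d <- a$dim
  stopifnot(d <= 3L, !a$degenerate, !b$degenerate)
  H <- unique(round(cbind(rbind(a$normals, b$normals),
                          c(a$offsets, b$offsets)), 9L))
  N <- H[, seq_len(d), drop = FALSE]
  off <- H[, d + 1L]
  m <- nrow(N)
  scale <- max(abs(rbind(a$points, b$points)), 1)
  tol <- max(a$tol, b$tol, 1e-9 * scale)
  combos <- combn(m, d)
  verts <- list()
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    A <- N[idx, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    v <- tryCatch(solve(A, off[idx]), error = function(e) NULL)
    if (is.null(v)) next
    if (all(N %*% v - off <= tol)) verts[[length(verts) + 1L]] <- v
  }
  if (length(verts) < d + 1L) return(0)
  V <- unique(round(do.call(rbind, verts), 9L))
  if (nrow(V) < d + 1L) return(0)
  # pyramid decomposition of the H-polytope: for every active constraint
  # plane, the (d-1)-measure of its face times its distance to an interior
  # point, summed and divided by d.  Robust to the coplanar vertex
  # configurations that intersection polytopes always have.
  ctr <- colMeans(V)
  face_tol <- 1e-7 * scale
  vol <- 0
  for (j in seq_len(m)) {
    on_face <- abs(V %*% N[j, ] - off[j]) <= face_tol
    if (sum(on_face) < d) next
    FV <- V[on_face, , drop = FALSE]
    h <- off[j] - sum(N[j, ] * ctr)
    if (h <= 0) next
    if (d == 2L) {
      dir <- c(-N[j, 2L], N[j, 1L])
      area <- diff(range(FV %*% dir))
    } else {
      # orthonormal basis of the face plane
      u <- if (abs(N[j, 1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- u - sum(u * N[j, ]) * N[j, ]
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(N[j, 2L] * e1[3L] - N[j, 3L] * e1[2L],
              N[j, 3L] * e1[1L] - N[j, 1L] * e1[3L],
              N[j, 1L] * e1[2L] - N[j, 2L] * e1[1L])
      P2 <- FV %*% cbind(e1, e2)
      if (nrow(unique(round(P2, 9L))) < 3L) next
      idx2 <- grDevices::chull(P2)
      H <- P2[idx2, , drop = FALSE]
      nn <- nrow(H)
      if (nn < 3L) next
      jj <- c(2:nn, 1L)
      area <- abs(sum(H[, 1L] * H[jj, 2L] - H[jj, 1L] * H[, 2L])) / 2
    }
    vol <- vol + area * h
  }
  vol / d
}

#' Remove the convex envelope of a cloud
#'
#' Deletes the boundary points (the peptides forming the convex envelope)
#' exactly once and rebuilds the hull from the remainder, suppressing
#' outlier-driven volume inflation.  If fewer than d + 1 points remain
#' the result is a degenerate cloud.  The fractions of points removed
#' and volume lost are attached as attributes `points_removed_frac` and
#' `volume_lost_frac`.
#'
#' @param cloud a [build_hull] result.
#' @return the stripped cloud.
#' @export
strip_envelope <- function(cloud) {
  stopifnot(inherits(cloud, "cloud"))
  n <- nrow(cloud$points)
  idx <- cloud$boundary_idx
  keep <- setdiff(seq_len(n), idx)
  out <- build_hull(cloud$points[keep, , drop = FALSE], tol = cloud$tol)
  attr(out, "points_removed_frac") <- length(idx) / max(n, 1L)
  attr(out, "volume_lost_frac") <-
    if (cloud$volume > 0) 1 - out$volume / cloud$volume else NA_real_
  out
}

# Are the affine supports of two degenerate clouds disjoint?  Tested
# point-wise: no point of either cloud lies in the other's affine
# subspace (within tolerance).
affine_supports_disjoint <- function(a, b) {
  # an empty cloud cannot demonstrate separation: not treated as disjoint
  if (nrow(a$points) == 0L || nrow(b$points) == 0L) return(FALSE)
  in_support <- function(cl, pts) {
    if (nrow(cl$points) == 0L) return(rep(FALSE, nrow(pts)))
    ctr <- sweep(pts, 2L, cl$center)
    if (cl$rank == 0L) return(sqrt(rowSums(ctr^2)) <= cl$tol)
    if (is.null(cl$basis)) return(rep(TRUE, nrow(pts)))  # full-rank support
    proj <- ctr %*% cl$basis
    sqrt(rowSums((ctr - proj %*% t(cl$basis))^2)) <= cl$tol
  }
  !any(in_support(b, a$points)) && !any(in_support(a, b$points))
}

#' Separation capacity score of two clouds
#'
#' The score combines a volume term and a peptide term:
#' `Sv = 1 - 2 * Vov / (V1 + V2)`, `Sp = 1 - Pov / (P1 + P2)`,
#' `S = Sv * Sp`.  S is 0 when the clouds overlap totally and 1 when the
#' clouds are disjoint and no peptide falls in the other cloud.  When
#' both volumes are zero (degenerate clouds) the volume term is defined
#' as 1 if the two affine supports are disjoint and 0 otherwise.
#'
#' @param a,b clouds (normally after [strip_envelope]).
#' @inheritParams cloud_overlap
#' @return an object of class `separation_result` with fields `V1`, `V2`,
#'   `Vov`, `P1`, `P2`, `Pov`, `Sv`, `Sp`, `S`, `method`, `mc_se`.
#' @export
separation_score <- function(a, b, method = c("mc", "exact"),
                             mc_samples = 1e5, seed = 1L) {
  method <- match.arg(method)
  ov <- cloud_overlap(a, b, method = method, mc_samples = mc_samples,
                      seed = seed)
  V1 <- a$volume; V2 <- b$volume
  P1 <- nrow(a$points); P2 <- nrow(b$points)
  Sv <- if (V1 + V2 > 0) 1 - 2 * ov$Vov / (V1 + V2)
        else if (affine_supports_disjoint(a, b)) 1 else 0
  Sv <- min(max(Sv, 0), 1)
  Sp <- if (P1 + P2 > 0) 1 - ov$Pov / (P1 + P2) else 1
  structure(list(V1 = V1, V2 = V2, Vov = ov$Vov,
                 P1 = P1, P2 = P2, Pov = ov$Pov,
                 Sv = Sv, Sp = Sp, S = Sv * Sp,
                 method = ov$method, mc_se = ov$mc_se),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(paste0("Separation capacity S = %.4f  (Sv = %.4f, Sp = %.4f)\n",
                     "  V1 = %.4g, V2 = %.4g, Vov = %.4g (%s%s)\n",
                     "  P1 = %d, P2 = %d, Pov = %d\n"),
              x$S, x$Sv, x$Sp, x$V1, x$V2, x$Vov, x$method,
              if (is.finite(x$mc_se)) sprintf(", se %.2g", x$mc_se) else "",
              x$P1, x$P2, x$Pov))
  invisible(x)
}
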