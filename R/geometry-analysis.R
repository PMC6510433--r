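# Analyses of the categorical geometry: lengths, areas, volumes and
# capacities in grains; local/global distortion between metrics; plane
# restrictions; 1-D and spherical isometric embeddings; harmonic surfaces.

#' Categorical length of a path
#'
#' Trapezoidal integration of \eqn{\sqrt{\dot v^T \Gamma \dot v}} along the
#' sampled path.
#'
#' @param field tensor field: a \code{"tensor_field"} grid, a function of an
#'   sRGB triple, or a constant 3 x 3 matrix (see [tensor_at()]).
#' @param path a [path_spec()].
#' @param density sample points per unit sRGB length (default 100).
#' @return list with \code{raw} (categorical metric units), \code{grains}
#'   (\code{raw / G1}) and \code{n_points}.
#' @export
path_length <- function(field, path, density = 100) {
  pts <- sample_path(path, density)
  n <- nrow(pts)
  if (n < 2) stop("degenerate path")
  speeds <- numeric(n - 1)
  T_prev <- tensor_at(field, pts[1, ])
  for (i in seq_len(n - 1)) {
    d <- pts[i + 1, ] - pts[i, ]
    T_next <- tensor_at(field, pts[i + 1, ])
    s1 <- sqrt(max(0, d %*% T_prev %*% d))
    s2 <- sqrt(max(0, d %*% T_next %*% d))
    speeds[i] <- (s1 + s2) / 2
    T_prev <- T_next
  }
  raw <- sum(speeds)
  list(raw = raw, grains = raw / grain_units()["G1"][[1]], n_points = n)
}

.plane_basis <- function(p1, p2, p3) {
  e1 <- p2 - p1; e2 <- p3 - p1
  x <- e1 / sqrt(sum(e1^2))
  y <- e2 - sum(e2 * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-12) return(NULL)
  list(x = x, y = y / ny)
}

#' Restrict a 3 x 3 tensor to a plane
#'
#' Forms \eqn{(x\,y)^T \Gamma (x\,y)} for an orthonormal in-plane frame.
#'
#' @param T 3 x 3 symmetric tensor.
#' @param x,y orthonormal plane-spanning vectors.
#' @return symmetric PSD 2 x 2 matrix.
#' @export
restrict_tensor <- function(T, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (abs(sum(x^2) - 1) > 1e-8 || abs(sum(y^2) - 1) > 1e-8 ||
      abs(sum(x * y)) > 1e-8)
    stop("x and y must be orthonormal")
  B <- cbind(x, y)
  M <- unname(t(B) %*% T %*% B)
  (M + t(M)) / 2
}

#' Categorical area of a triangulated surface
#'
#' Per triangle, the tensor at the centroid is restricted to the triangle's
#' plane; the categorical area is the Euclidean triangle area scaled by
#' \eqn{\sqrt{\det}} of the restricted tensor.
#'
#' @param field tensor field (see [tensor_at()]).
#' @param mesh a [mesh_spec()].
#' @return list with \code{raw} area, \code{grains} (\code{raw / G2}) and,
#'   when the mesh has a boundary loop, \code{boundary_raw} and
#'   \code{boundary_grains} (its categorical length).
#' @export
categorical_area <- function(field, mesh) {
  V <- mesh$vertices; Tr <- mesh$triangles
  raw <- 0
  for (t in seq_len(nrow(Tr))) {
    p1 <- V[Tr[t, 1], ]; p2 <- V[Tr[t, 2], ]; p3 <- V[Tr[t, 3], ]
    basis <- .plane_basis(p1, p2, p3)
    if (is.null(basis)) stop("degenerate triangle ", t)
    e1 <- p2 - p1; e2 <- p3 - p1
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    area_eu <- sqrt(sum(cr^2)) / 2
    centroid <- (p1 + p2 + p3) / 3
    T2 <- restrict_tensor(tensor_at(field, centroid), basis$x, basis$y)
    raw <- raw + sqrt(max(0, det(T2))) * area_eu
  }
  out <- list(raw = raw, grains = raw / grain_units()["G2"][[1]])
  if (length(mesh$boundary) >= 2) {
    bl <- path_length(field,
                      path_spec(V[mesh$boundary, , drop = FALSE],
                                closed = TRUE))
    out$boundary_raw <- bl$raw
    out$boundary_grains <- bl$grains
  }
  out
}

#' Categorical volume of the sRGB cube
#'
#' Midpoint-rule integration of \eqn{\sqrt{\det \Gamma}} over a regular
#' subgrid of the cube.
#'
#' @param field tensor field (see [tensor_at()]).
#' @param subdiv cells per axis (default 10).
#' @return list with \code{raw} volume and \code{grains}
#'   (\code{raw / G3}).
#' @export
categorical_volume <- function(field, subdiv = 10) {
  h <- 1 / subdiv
  centres <- seq(h / 2, 1 - h / 2, by = h)
  raw <- 0
  for (x in centres) for (y in centres) for (z in centres) {
    T <- tensor_at(field, c(x, y, z))
    raw <- raw + sqrt(max(0, det(T))) * h^3
  }
  list(raw = raw, grains = raw / grain_units()["G3"][[1]])
}

#' Categorical capacity with boundary correction
#'
#' \eqn{C(R) = |R|/G_n + \frac12 |\partial R| / G_{n-1}}: the number of
#' categorically distinct regions a manifold holds, with regions abutting
#' the boundary needing only half the usual extent. For a 1-D manifold the
#' boundary measure is its number of endpoints.
#'
#' @param measure manifold measure, already expressed in grains of its
#'   dimension.
#' @param boundary boundary measure in grains of one dimension lower (for
#'   dimension 1: the endpoint count); 0 for closed manifolds.
#' @param dim manifold dimension (1, 2 or 3); used for validation only.
#' @return the capacity.
#' @export
capacity <- function(measure, boundary = 0, dim = 1) {
  if (measure < 0 || boundary < 0) stop("measures must be nonnegative")
  if (!dim %in% 1:3) stop("dim must be 1, 2 or 3")
  measure + 0.5 * boundary
}

#' Capacity of the full sRGB cube
#'
#' Volume of the cube in volumetric grains plus half the total categorical
#' area of its six faces in areal grains.
#'
#' @param field tensor field (see [tensor_at()]).
#' @param subdiv volume subgrid cells per axis.
#' @param face_subdiv cells per axis for the face-area integration
#'   (defaults to \code{subdiv}).
#' @return list with \code{volume_grains}, \code{face_area_grains} (total
#'   over 6 faces), \code{capacity} and \code{capacity_uncorrected}.
#' @export
cube_capacity <- function(field, subdiv = 10, face_subdiv = subdiv) {
  vol <- categorical_volume(field, subdiv)
  h <- 1 / face_subdiv
  centres <- seq(h / 2, 1 - h / 2, by = h)
  axes <- diag(3)
  area_raw <- 0
  for (a in 1:3) for (side in c(0, 1)) {
    u <- axes[, (a %% 3) + 1]; v <- axes[, ((a + 1) %% 3) + 1]
    for (s in centres) for (t in centres) {
      p <- numeric(3); p[a] <- side
      p <- p + s * u + t * v
      T2 <- restrict_tensor(tensor_at(field, p), u, v)
      area_raw <- area_raw + sqrt(max(0, det(T2))) * h^2
    }
  }
  G <- grain_units()
  face_grains <- area_raw / G["G2"][[1]]
  list(volume_grains = vol$grains,
       face_area_grains = face_grains,
       capacity = capacity(vol$grains, face_grains, dim = 3),
       capacity_uncorrected = vol$grains)
}

# ---- distortion ------------------------------------------------------------

.mat_power <- function(A, p) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, 0)^p * t(e$vectors))
}

#' Geometric mean of two SPD matrices
#'
#' \eqn{A \# B = A^{1/2} (A^{-1/2} B A^{-1/2})^{1/2} A^{1/2}}; equals both
#' arguments when they coincide and is symmetric in them.
#'
#' @param A,B symmetric positive-definite matrices.
#' @return SPD matrix.
#' @export
spd_geometric_mean <- function(A, B) {
  Ah <- .mat_power(A, 0.5)
  Aih <- .mat_power(A, -0.5)
  M <- Ah %*% .mat_power(Aih %*% B %*% Aih, 0.5) %*% Ah
  (M + t(M)) / 2
}

#' Local distortion between two metrics
#'
#' \eqn{\frac12 \log_2 (v^T A v / v^T B v)}: the log ratio of the lengths
#' the two metrics assign to an infinitesimal displacement along \code{v}.
#'
#' @param A,B 3 x 3 metric tensors at the same location.
#' @param v direction vector.
#' @return scalar (log2 units; 0 means equal lengths).
#' @export
local_distortion <- function(A, B, v) {
  v <- as.numeric(v)
  0.5 * log2(as.numeric(v %*% A %*% v) / as.numeric(v %*% B %*% v))
}

#' Global distortion between two tensor fields
#'
#' Monte Carlo estimate of the standard deviation of local distortion over
#' the sRGB cube. Locations are sampled uniformly; at each location the SPD
#' geometric mean \eqn{C = A \# B} defines the sampling measure: directions
#' are drawn from \eqn{N(0, C^{-1})} and samples are weighted by
#' \eqn{|C|}. The weighted standard deviation of the local distortions is
#' returned; with a shared seed the statistic is exactly symmetric in the
#' two fields.
#'
#' @param field_a,field_b tensor fields (see [tensor_at()]).
#' @param n_samples Monte Carlo sample count (default 1e5).
#' @param seed RNG seed.
#' @return list with \code{global} (the weighted sd), \code{mean} (weighted
#'   mean local distortion), \code{quantiles} of the local distortions and
#'   \code{n_samples}.
#' @export
global_distortion <- function(field_a, field_b, n_samples = 1e5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- numeric(n_samples); w <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    z <- stats::runif(3)
    A <- tensor_at(field_a, z)
    B <- tensor_at(field_b, z)
    C <- spd_geometric_mean(A, B)
    eC <- eigen(C, symmetric = TRUE)
    if (any(eC$values <= 0))
      stop(sprintf("non-positive-definite tensor at (%.3f, %.3f, %.3f)",
                   z[1], z[2], z[3]))
    # v ~ N(0, C^{-1}): C^{-1} = U diag(1/lambda) U'
    v <- eC$vectors %*% (stats::rnorm(3) / sqrt(eC$values))
    d[i] <- local_distortion(A, B, v)
    w[i] <- prod(eC$values)
  }
  w <- w / sum(w)
  m <- sum(w * d)
  list(global = sqrt(sum(w * (d - m)^2)),
       mean = m,
       quantiles = stats::quantile(d, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       n_samples = n_samples)
}

#' 95% local-distortion range implied by a global distortion
#'
#' Under a normal model for local distortion, 95% of local distortions fall
#' in \eqn{2^{\pm 1.96 g}}; e.g. a global distortion of 0.50 implies a
#' 51-197% range.
#'
#' @param global the global distortion (sd of local, log2 units).
#' @return length-2 vector of ratio bounds (1 = 100%).
#' @export
distortion_range <- function(global) {
  2^(c(-1, 1) * 1.96 * global)
}

# ---- embeddings ------------------------------------------------------------

#' Isometric 1-D embedding of a path
#'
#' Open paths embed as their categorical arc-length map; closed paths embed
#' as a circle whose circumference is the categorical length (always
#' achievable with zero distortion for 1-D manifolds). The first path
#' sample sits at angle 0 and the path runs counter-clockwise.
#'
#' @param field tensor field (see [tensor_at()]).
#' @param path a [path_spec()].
#' @param density sample points per unit sRGB length.
#' @return list with \code{points} (the sampled sRGB points),
#'   \code{arc_length} (cumulative categorical length), \code{total},
#'   \code{grains}; for closed paths also \code{radius} and
#'   \code{positions} (2-D embedded coordinates).
#' @export
embed_1d <- function(field, path, density = 100) {
  pts <- sample_path(path, density)
  n <- nrow(pts)
  seg <- numeric(n - 1)
  T_prev <- tensor_at(field, pts[1, ])
  for (i in seq_len(n - 1)) {
    d <- pts[i + 1, ] - pts[i, ]
    T_next <- tensor_at(field, pts[i + 1, ])
    seg[i] <- (sqrt(max(0, d %*% T_prev %*% d)) +
               sqrt(max(0, d %*% T_next %*% d))) / 2
    T_prev <- T_next
  }
  s <- c(0, cumsum(seg))
  total <- s[n]
  if (total <= 0) stop("path has zero categorical length")
  out <- list(points = pts, arc_length = s, total = total,
              grains = total / grain_units()["G1"][[1]])
  if (path$closed) {
    r <- total / (2 * pi)
    ang <- 2 * pi * s / total
    out$radius <- r
    out$positions <- cbind(x = r * cos(ang), y = r * sin(ang))
  }
  out
}

#' Harmonic (Laplace) surface spanning a closed boundary
#'
#' Builds a quadrilateral grid whose perimeter is mapped onto the boundary
#' path by arc length, then solves the discrete Laplace equation for the
#' interior vertex coordinates (each interior vertex is the average of its
#' four grid neighbours). With the full colour locus as boundary this yields
#' the monkey-saddle full colour surface.
#'
#' @param boundary a closed [path_spec()].
#' @param resolution grid cells per side (default 16).
#' @return a [mesh_spec()] with triangles and the boundary loop.
#' @export
laplace_surface <- function(boundary, resolution = 16) {
  if (!boundary$closed) stop("boundary path must be closed")
  m <- as.integer(resolution) + 1L
  # perimeter of the grid, counter-clockwise from (1,1)
  per <- rbind(
    cbind(seq_len(m - 1), 1L),
    cbind(m, seq_len(m - 1)),
    cbind(m:2, m),
    cbind(1L, m:2))
  # map perimeter onto the boundary path by (sRGB) arc length
  v <- rbind(boundary$vertices, boundary$vertices[1, ])
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg)); Ltot <- cum[length(cum)]
  targets <- (seq_len(nrow(per)) - 1) / nrow(per) * Ltot
  bpts <- t(vapply(targets, function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(i, length(seg))
    t <- (s - cum[i]) / seg[i]
    v[i, ] + t * (v[i + 1, ] - v[i, ])
  }, numeric(3)))
  # grid coordinates: solve Laplace per colour channel
  idx <- matrix(seq_len(m * m), m, m)
  is_bnd <- matrix(FALSE, m, m)
  coords <- matrix(0, m * m, 3)
  for (p in seq_len(nrow(per))) {
    is_bnd[per[p, 1], per[p, 2]] <- TRUE
    coords[idx[per[p, 1], per[p, 2]], ] <- bpts[p, ]
  }
  interior <- which(!is_bnd)
  ni <- length(interior)
  if (ni > 0) {
    pos <- arrayInd(interior, c(m, m))
    L <- matrix(0, ni, ni)
    rhs <- matrix(0, ni, 3)
    imap <- rep(NA_integer_, m * m); imap[interior] <- seq_len(ni)
    for (q in seq_len(ni)) {
      i <- pos[q, 1]; j <- pos[q, 2]
      L[q, q] <- 4
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        lin <- idx[nb[1], nb[2]]
        if (is_bnd[nb[1], nb[2]]) rhs[q, ] <- rhs[q, ] + coords[lin, ]
        else L[q, imap[lin]] <- -1
      }
    }
    coords[interior, ] <- solve(L, rhs)
  }
  tris <- list()
  for (i in seq_len(m - 1)) for (j in seq_len(m - 1)) {
    tris[[length(tris) + 1]] <- c(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1])
    tris[[length(tris) + 1]] <- c(idx[i, j], idx[i + 1, j + 1], idx[i, j + 1])
  }
  bnd_loop <- idx[cbind(per[, 1], per[, 2])]
  mesh_spec(pmin(pmax(coords, 0), 1), do.call(rbind, tris), bnd_loop)
}

.mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)],
             triangles[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

#' Least-distortion spherical embedding of a 2-D sub-manifold
#'
#' Places the mesh vertices on a sphere so that spherical geodesic edge
#' lengths match the categorical edge lengths as closely as possible: the
#' placements minimize the edge-length-weighted variance of the log2 ratio
#' of embedded to categorical edge length, and the radius is then set so the
#' weighted mean log distortion is zero.
#'
#' @param field tensor field (see [tensor_at()]).
#' @param mesh a [mesh_spec()].
#' @param seed RNG seed (reserved for jittered initialization; the default
#'   initialization is deterministic).
#' @param edge_density sample points per unit sRGB length when measuring
#'   categorical edge lengths.
#' @param maxit optimizer iteration cap.
#' @return list with \code{radius}, \code{positions} (vertices on the
#'   sphere), \code{distortion_range} (95% range of per-edge distortion
#'   ratios), \code{global} (sd of log2 edge distortions) and
#'   \code{convergence}.
#' @export
embed_sphere <- function(field, mesh, seed = NULL, edge_density = 200,
                         maxit = 300) {
  if (!is.null(seed)) set.seed(seed)
  edges <- .mesh_edges(mesh$triangles)
  V <- mesh$vertices
  len <- apply(edges, 1, function(e) {
    path_length(field, path_spec(V[e, , drop = FALSE]),
                density = edge_density)$raw
  })
  keep <- len > 1e-10
  if (sum(keep) < 3) stop("mesh has too few edges with positive length")
  edges <- edges[keep, , drop = FALSE]; len <- len[keep]
  w <- len / sum(len)
  # init: project onto a sphere about a centre displaced from the mesh
  # centroid along the mesh normal (smallest principal axis), so that flat
  # or shallow meshes start as a spherical cap rather than an equator ring
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  pc <- stats::prcomp(V)
  nrml <- pc$rotation[, 3]
  dpth <- sqrt(mean(rowSums(Vc^2)))
  orig <- ctr - nrml * max(dpth, 1e-3)
  U0 <- sweep(V, 2, orig)
  nrm <- sqrt(rowSums(U0^2)); nrm[nrm < 1e-9] <- 1
  U0 <- U0 / nrm
  obj <- function(par) {
    U <- matrix(par, ncol = 3)
    nu <- sqrt(rowSums(U^2))
    if (any(nu < 1e-8)) return(1e10)
    U <- U / nu
    a <- acos(pmin(1, pmax(-1,
          rowSums(U[edges[, 1], , drop = FALSE] *
                  U[edges[, 2], , drop = FALSE]))))
    if (any(a < 1e-10)) return(1e10)
    r <- log2(a / len)
    mlog <- sum(w * r)
    sum(w * (r - mlog)^2)
  }
  fit <- stats::optim(as.numeric(U0), obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  U <- matrix(fit$par, ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  a <- acos(pmin(1, pmax(-1,
        rowSums(U[edges[, 1], , drop = FALSE] *
                U[edges[, 2], , drop = FALSE]))))
  a <- pmax(a, 1e-12)
  logr <- log2(a / len)
  mlog <- sum(w * logr)
  radius <- 2^(-mlog)               # distortion = radius * angle / length
  dist_edges <- 2^(logr - mlog)     # per-edge distortion ratios, mean-log 1
  qs <- stats::quantile(dist_edges, c(0.025, 0.975))
  list(radius = radius, positions = radius * U,
       distortion_range = unname(qs),
       global = sqrt(sum(w * (logr - mlog)^2)),
       convergence = fit$convergence)
}
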