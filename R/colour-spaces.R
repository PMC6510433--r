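# Colour coordinate conversions (sRGB <-> CIELAB, D65/2deg), CIE colour
# difference formulas, tensorization of distance formulas, and constructors
# for the standard sub-manifolds of the sRGB cube.

# D65 2-degree reference white (sRGB standard)
.white_d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

# sRGB (IEC 61966-2-1) linear RGB -> XYZ matrix
.rgb2xyz <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505), nrow = 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)

.as_rgb_matrix <- function(rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb[, c("r", "g", "b")])
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  storage.mode(rgb) <- "double"
  if (ncol(rgb) != 3) stop("rgb must have three columns")
  rgb
}

.as_lab_matrix <- function(lab) {
  if (is.data.frame(lab)) lab <- as.matrix(lab)
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
  storage.mode(lab) <- "double"
  if (ncol(lab) != 3) stop("lab must have three columns")
  lab
}

#' Convert sRGB coordinates to CIELAB
#'
#' Applies the standard chain: IEC sRGB transfer function, linear RGB to XYZ
#' (D65), then XYZ to CIELAB under the D65/2-degree white point.
#'
#' @param rgb numeric vector of length 3, or an n x 3 matrix/data frame of
#'   sRGB coordinates in \eqn{[0,1]}.
#' @return an n x 3 matrix with columns \code{L}, \code{a}, \code{b}
#'   (a length-3 named vector when a single triple is supplied).
#' @seealso [lab_to_srgb()] for the inverse.
#' @export
#' @examples
#' srgb_to_lab(c(0.5, 0.5, 0.5))
srgb_to_lab <- function(rgb) {
  single <- is.null(dim(rgb)) && !is.data.frame(rgb)
  rgb <- .as_rgb_matrix(rgb)
  if (anyNA(rgb) || any(rgb < -1e-12) || any(rgb > 1 + 1e-12))
    stop("sRGB components must lie in [0, 1]")
  rgb <- pmin(pmax(rgb, 0), 1)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.rgb2xyz)
  xyz <- sweep(xyz, 2, .white_d65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  if (single) lab[1, ] else lab
}

#' Convert CIELAB coordinates to sRGB
#'
#' Inverse of [srgb_to_lab()]; only meaningful for in-gamut colours.
#'
#' @param lab numeric vector of length 3, or an n x 3 matrix of CIELAB
#'   coordinates (D65/2-degree white).
#' @param clip clamp the result into \eqn{[0,1]} (default TRUE).
#' @return sRGB coordinates, same shape convention as [srgb_to_lab()].
#' @export
lab_to_srgb <- function(lab, clip = TRUE) {
  single <- is.null(dim(lab)) && !is.data.frame(lab)
  lab <- .as_lab_matrix(lab)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .white_d65, "*")
  lin <- xyz %*% t(.xyz2rgb)
  rgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  if (clip) rgb <- pmin(pmax(rgb, 0), 1)
  colnames(rgb) <- c("r", "g", "b")
  if (single) rgb[1, ] else rgb
}

#' Construct colour points carrying sRGB and CIELAB coordinates
#'
#' @param rgb n x 3 matrix (or length-3 vector) of sRGB coordinates.
#' @return data frame with columns \code{r,g,b,L,a,b_} (CIELAB b renamed to
#'   avoid the clash with sRGB b).
#' @export
colour_point <- function(rgb) {
  rgb <- .as_rgb_matrix(rgb)
  lab <- srgb_to_lab(rgb)
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
  data.frame(r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
             L = lab[, 1], a = lab[, 2], b_ = lab[, 3])
}

.deg_cos <- function(x) cos(x * pi / 180)
.deg_sin <- function(x) sin(x * pi / 180)

# CIEDE2000 (Sharma, Wu & Dalal 2005 formulation), vectorized over rows.
.de2000 <- function(lab1, lab2) {
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh, ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * .deg_sin(dhp / 2)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, hsum / 2 + 180, hsum / 2 - 180)))
  Tt <- 1 - 0.17 * .deg_cos(hbp - 30) + 0.24 * .deg_cos(2 * hbp) +
        0.32 * .deg_cos(3 * hbp + 6) - 0.20 * .deg_cos(4 * hbp - 63)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -.deg_sin(2 * dtheta) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

# CIE94 with the symmetric chroma reference sqrt(C1*C2) so that the distance
# is symmetric in its arguments (graphic-arts weighting constants).
.de94 <- function(lab1, lab2) {
  dL <- lab1[, 1] - lab2[, 1]
  C1 <- sqrt(lab1[, 2]^2 + lab1[, 3]^2)
  C2 <- sqrt(lab2[, 2]^2 + lab2[, 3]^2)
  dC <- C1 - C2
  da <- lab1[, 2] - lab2[, 2]; db <- lab1[, 3] - lab2[, 3]
  dH2 <- pmax(da^2 + db^2 - dC^2, 0)
  Cref <- sqrt(C1 * C2)
  SC <- 1 + 0.045 * Cref
  SH <- 1 + 0.015 * Cref
  sqrt(dL^2 + (dC / SC)^2 + dH2 / SH^2)
}

#' CIE colour differences
#'
#' Computes colour differences between pairs of colours under the CIE76
#' (Euclidean CIELAB), CIE94 or CIEDE2000 formulas.
#'
#' @param a,b colour coordinates: n x 3 matrices or length-3 vectors.
#' @param formula one of \code{"cie76"}, \code{"cie94"}, \code{"cie2000"}.
#' @param space \code{"lab"} (default) if the inputs are already CIELAB,
#'   \code{"rgb"} to convert from sRGB first.
#' @return numeric vector of distances.
#' @details CIE94 is evaluated with the symmetric chroma reference
#'   \eqn{\sqrt{C_1 C_2}}, so all three formulas are symmetric in their
#'   arguments. CIE94 and CIEDE2000 do not in general satisfy the triangle
#'   inequality.
#' @export
cie_distance <- function(a, b, formula = c("cie76", "cie94", "cie2000"),
                         space = c("lab", "rgb")) {
  formula <- match.arg(tolower(formula[1]),
                       c("cie76", "cie94", "cie2000"))
  space <- match.arg(space)
  a <- .as_lab_matrix(a); b <- .as_lab_matrix(b)
  if (space == "rgb") {
    a <- .as_lab_matrix(srgb_to_lab(a))
    b <- .as_lab_matrix(srgb_to_lab(b))
  }
  if (nrow(a) != nrow(b)) stop("a and b must have the same number of rows")
  switch(formula,
         cie76 = sqrt(rowSums((a - b)^2)),
         cie94 = .de94(a, b),
         cie2000 = .de2000(a, b))
}

# The 13 probe directions of the RGB frame: 3 axes, 6 face diagonals,
# 4 body diagonals (unit vectors).
.probe_directions <- local({
  d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  d / sqrt(rowSums(d^2))
})

# Symmetric PSD projection by eigenvalue clipping at zero.
.psd_clip <- function(T) {
  T <- (T + t(T)) / 2
  e <- eigen(T, symmetric = TRUE)
  if (all(e$values >= 0)) return(T)
  v <- pmax(e$values, 0)
  T2 <- e$vectors %*% (v * t(e$vectors))
  (T2 + t(T2)) / 2
}

.sym_from_comps <- function(t6) {
  matrix(c(t6[1], t6[2], t6[3],
           t6[2], t6[4], t6[5],
           t6[3], t6[5], t6[6]), 3, 3)
}

.comps_from_sym <- function(T) c(T[1, 1], T[1, 2], T[1, 3],
                                 T[2, 2], T[2, 3], T[3, 3])

#' Metric tensor compatible with a colour-difference formula
#'
#' Estimates, at a colour location, the 3 x 3 symmetric PSD tensor whose
#' quadratic form best reproduces (in least squares) the distances a
#' colour-difference formula assigns to 13 short probe pairs around the
#' location. The probe pairs straddle the location at \code{delta/2} on each
#' side (pair separation \code{delta}) along the 3 axes, 6 face diagonals and
#' 4 body diagonals of the RGB frame. Near cube faces the centre is shifted
#' inward so that every probe stays in gamut.
#'
#' @param formula a formula name accepted by [cie_distance()], \code{"srgb"}
#'   for Euclidean distance in sRGB itself, or a function
#'   \code{function(rgb_a, rgb_b)} returning distances for row-paired sRGB
#'   matrices.
#' @param z length-3 sRGB location.
#' @param delta probe pair separation in sRGB units (default 0.1).
#' @return 3 x 3 symmetric positive semi-definite matrix.
#' @export
tensor_from_distance <- function(formula, z, delta = 0.1) {
  z <- as.numeric(z)
  if (length(z) != 3) stop("z must be a length-3 sRGB triple")
  h <- delta / 2
  z <- pmin(pmax(z, h), 1 - h)
  a <- sweep(-.probe_directions * h, 2, z, "+")
  b <- sweep(.probe_directions * h, 2, z, "+")
  a <- pmin(pmax(a, 0), 1); b <- pmin(pmax(b, 0), 1)
  d <- if (is.function(formula)) {
    formula(a, b)
  } else if (identical(tolower(formula), "srgb")) {
    sqrt(rowSums((a - b)^2))
  } else {
    cie_distance(srgb_to_lab(a), srgb_to_lab(b), formula = formula)
  }
  v <- b - a
  X <- cbind(v[, 1]^2, 2 * v[, 1] * v[, 2], 2 * v[, 1] * v[, 3],
             v[, 2]^2, 2 * v[, 2] * v[, 3], v[, 3]^2)
  fit <- tryCatch(qr.solve(X, d^2), error = function(e)
    stop("degenerate probe set: normal equations are singular"))
  .psd_clip(.sym_from_comps(fit))
}

#' Tensor field induced by a colour-difference formula
#'
#' @param formula as in [tensor_from_distance()].
#' @param delta probe separation.
#' @return a function of an sRGB triple returning a 3 x 3 tensor, suitable
#'   for [path_length()], [global_distortion()] and friends.
#' @export
cie_tensor_field <- function(formula, delta = 0.1) {
  force(formula); force(delta)
  function(z) tensor_from_distance(formula, z, delta = delta)
}

#' Path specification in the sRGB cube
#'
#' @param vertices n x 3 matrix of sRGB vertices (visited in order).
#' @param closed should the last vertex connect back to the first?
#' @return object of class \code{"path_spec"}.
#' @export
path_spec <- function(vertices, closed = FALSE) {
  vertices <- .as_rgb_matrix(vertices)
  if (nrow(vertices) < 2) stop("a path needs at least two vertices")
  d <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                     vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive path vertices must be distinct")
  structure(list(vertices = vertices, closed = isTRUE(closed)),
            class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("<path_spec: %d vertices, %s>\n", nrow(x$vertices),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Sample a path at a given density
#'
#' @param path a [path_spec()].
#' @param density points per unit sRGB length.
#' @return matrix of sRGB points along the path (including both endpoints;
#'   for closed paths the first point is repeated at the end).
#' @export
sample_path <- function(path, density = 100) {
  v <- path$vertices
  if (path$closed) v <- rbind(v, v[1, ])
  out <- vector("list", nrow(v) - 1)
  for (i in seq_len(nrow(v) - 1)) {
    a <- v[i, ]; b <- v[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len * density))
    t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  rbind(do.call(rbind, out), v[nrow(v), ])
}

#' Standard sub-manifold paths of the sRGB cube
#'
#' The achromatic axis is the black-to-white diagonal; the full colour locus
#' is the closed non-planar hexagon of maximally saturated colours running
#' along six cube edges R -> Y -> G -> C -> B -> M -> R.
#'
#' @return list with elements \code{achromatic_axis} and
#'   \code{full_colour_locus}, both [path_spec()] objects.
#' @export
standard_paths <- function() {
  list(
    achromatic_axis = path_spec(rbind(c(0, 0, 0), c(1, 1, 1))),
    full_colour_locus = path_spec(rbind(
      c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
      c(0, 1, 1), c(0, 0, 1), c(1, 0, 1)), closed = TRUE))
}

.chromatic_vertices <- list(
  red = c(1, 0, 0), green = c(0, 1, 0), blue = c(0, 0, 1),
  cyan = c(0, 1, 1), magenta = c(1, 0, 1), yellow = c(1, 1, 0))

#' Triangulated mesh specification
#'
#' @param vertices n x 3 matrix of sRGB vertices.
#' @param triangles m x 3 integer matrix of vertex indices.
#' @param boundary integer vector: the boundary loop as vertex indices.
#' @return object of class \code{"mesh_spec"}.
#' @export
mesh_spec <- function(vertices, triangles, boundary = integer()) {
  vertices <- .as_rgb_matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (any(triangles < 1) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 boundary = as.integer(boundary)),
            class = "mesh_spec")
}

#' @export
print.mesh_spec <- function(x, ...) {
  cat(sprintf("<mesh_spec: %d vertices, %d triangles, boundary loop of %d>\n",
              nrow(x$vertices), nrow(x$triangles), length(x$boundary)))
  invisible(x)
}

#' Hue triangle mesh
#'
#' The planar triangle spanned by black, white and one chromatic vertex of
#' the sRGB cube, triangulated by uniform barycentric subdivision.
#'
#' @param corner a chromatic vertex name (\code{"red"}, \code{"green"},
#'   \code{"blue"}, \code{"cyan"}, \code{"magenta"}, \code{"yellow"}) or an
#'   sRGB triple that is a chromatic cube vertex.
#' @param subdivisions number of edge subdivisions (default 20).
#' @return a [mesh_spec()].
#' @export
hue_triangle <- function(corner = "red", subdivisions = 20) {
  if (is.character(corner)) {
    corner <- .chromatic_vertices[[match.arg(corner,
                                             names(.chromatic_vertices))]]
  } else {
    corner <- as.numeric(corner)
    ok <- length(corner) == 3 && all(corner %in% c(0, 1)) &&
      sum(corner) %in% c(1, 2)
    if (!ok) stop("corner must be a chromatic vertex of the sRGB cube")
  }
  A <- c(0, 0, 0); B <- c(1, 1, 1); C <- corner
  n <- as.integer(subdivisions)
  if (n < 1) stop("subdivisions must be >= 1")
  # barycentric lattice: rows i = 0..n, positions j = 0..i
  verts <- list(); idx <- matrix(NA_integer_, n + 1, n + 1)
  k <- 0L
  for (i in 0:n) for (j in 0:i) {
    k <- k + 1L
    idx[i + 1, j + 1] <- k
    w <- c(n - i, i - j, j) / n         # weights on A, B, C
    verts[[k]] <- w[1] * A + w[2] * B + w[3] * C
  }
  tris <- list()
  for (i in 0:(n - 1)) for (j in 0:i) {
    tris[[length(tris) + 1]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1],
                                  idx[i + 2, j + 2])
    if (j < i)
      tris[[length(tris) + 1]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 2],
                                    idx[i + 1, j + 2])
  }
  # boundary loop: A->B edge (j = 0), B->C edge (bottom row), C->A (j = i)
  left <- vapply(0:n, function(i) idx[i + 1, 1], integer(1))
  bottom <- vapply(1:n, function(j) idx[n + 1, j + 1], integer(1))
  diag_back <- vapply((n - 1):1, function(i) idx[i + 1, i + 1], integer(1))
  mesh_spec(do.call(rbind, verts), do.call(rbind, tris),
            boundary = c(left, bottom, diag_back))
}
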