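# Information-geometric machinery: divergences, Bhattacharyya angles, the
# square-root embedding, comb-filter blurring, finite-difference metric
# tensors, tensor grids with quadratic interpolation, and grid IO.

#' Kullback-Leibler divergence (bits)
#'
#' @param p,q probability vectors of equal length.
#' @return divergence in bits; \code{Inf} when \code{q} is zero somewhere
#'   \code{p} is positive.
#' @export
kld <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  i <- p > 0
  if (any(q[i] == 0)) return(Inf)
  sum(p[i] * log2(p[i] / q[i]))
}

#' Jensen-Shannon divergence (bits)
#'
#' \eqn{d_{JS}(P,Q) = \frac12 (D_{KL}(P,M) + D_{KL}(Q,M))} with mixture
#' \eqn{M = (P+Q)/2}; symmetric, bounded by 1 bit.
#'
#' @param p,q probability vectors of equal length.
#' @return divergence in bits.
#' @export
jsd <- function(p, q) {
  m <- (p + q) / 2
  0.5 * (kld(p, m) + kld(q, m))
}

#' @rdname jsd
#' @export
jsd_distance <- function(p, q) sqrt(jsd(p, q))

#' Bhattacharyya angle
#'
#' \eqn{\arccos \sum_i \sqrt{p_i q_i}}: the geodesic distance between the
#' square-rooted distributions on the unit sphere, in \eqn{[0, \pi/2]}.
#' Distributions without support in common are exactly \eqn{\pi/2} apart
#' (one grain).
#'
#' @param p,q probability vectors of equal length.
#' @return angle in radians.
#' @export
bhattacharyya_angle <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  acos(min(1, max(0, sum(sqrt(p * q)))))
}

#' Fisher information distance on the univariate normal family
#'
#' Infinitesimal information distance between normals
#' \eqn{\langle\mu,\sigma\rangle} and
#' \eqn{\langle\mu+\delta\mu, \sigma+\delta\sigma\rangle}:
#' \eqn{\sqrt{\frac14 \delta\mu^2 + \frac12 \delta\sigma^2}/\sigma}.
#' A closed-form oracle for the square-root-embedding pipeline.
#'
#' @param mu1,sigma1 first normal.
#' @param mu2,sigma2 second normal (displacements assumed small).
#' @return distance (radians on the sphere of square-rooted densities).
#' @export
normal_fisher_example <- function(mu1, sigma1, mu2, sigma2) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigma must be positive")
  sqrt(0.25 * (mu2 - mu1)^2 + 0.5 * (sigma2 - sigma1)^2) / sigma1
}

#' Natural categorical units (grains)
#'
#' One linear grain is the separation (\eqn{\pi/2}) of two naming
#' distributions with no responses in common; areal and volumetric grains
#' are the measures of a 1- and 2-sphere of radius \eqn{\pi/4}:
#' \eqn{G_1 = \pi/2}, \eqn{G_2 = \pi^3/16}, \eqn{G_3 = \pi^4/48}.
#'
#' @return named numeric vector \code{c(G1, G2, G3)}.
#' @export
grain_units <- function() {
  c(G1 = pi / 2, G2 = pi^3 / 16, G3 = pi^4 / 48)
}

# ---- distribution fields ---------------------------------------------------

#' Distribution field over the sRGB cube
#'
#' Wraps an evaluator mapping sRGB points to probability vectors over a
#' fixed vocabulary.
#'
#' @param fun function taking an n x 3 sRGB matrix, returning an n x V
#'   matrix of probabilities (rows sum to 1).
#' @param vocabulary character vector of names (columns of the output).
#' @return object of class \code{"distribution_field"}.
#' @export
distribution_field <- function(fun, vocabulary) {
  stopifnot(is.function(fun))
  structure(list(predict = fun, vocabulary = vocabulary),
            class = "distribution_field")
}

#' @export
print.distribution_field <- function(x, ...) {
  cat(sprintf("<distribution_field over %d names>\n", length(x$vocabulary)))
  invisible(x)
}

#' Distribution field of a naming model
#'
#' @param model a \code{"naming_model"}.
#' @return a [distribution_field()] evaluating the normalized naming
#'   distribution \eqn{P_n(z)}.
#' @export
model_field <- function(model) {
  force(model)
  distribution_field(function(rgb) predict(model, rgb, type = "prob"),
                     model$vocabulary)
}

.comb_offsets <- function(delta) {
  s <- (-2:2) * delta / 3
  g <- as.matrix(expand.grid(s, s, s))
  w1 <- c(1, 3, 4, 3, 1) / 12
  w <- as.matrix(expand.grid(w1, w1, w1))
  list(offsets = g, weights = w[, 1] * w[, 2] * w[, 3])
}

#' Standard deviation of the 1-D comb blurring filter
#'
#' The five-point dirac-comb averaging filter has spacing \code{delta/3} and
#' weights \eqn{\frac{1}{12}(1,3,4,3,1)}; its spatial spread is
#' \eqn{0.36\,\Delta}.
#'
#' @param delta smoothness length scale (default 0.1 sRGB units).
#' @return standard deviation in sRGB units.
#' @export
blur_filter_sd <- function(delta = 0.1) {
  s <- (-2:2) * delta / 3
  w <- c(1, 3, 4, 3, 1) / 12
  sqrt(sum(w * s^2))
}

#' Blur a distribution field with the comb filter
#'
#' Replaces the field by the 5^3-point weighted average over the 3-D outer
#' product of the comb filter (spacing \code{delta/3}, weights
#' \eqn{\frac{1}{12}(1,3,4,3,1)}), renormalized to unit sum. Probe points
#' falling outside the cube are clamped to it.
#'
#' @param field a [distribution_field()].
#' @param delta smoothness length scale (default 0.1).
#' @return a blurred [distribution_field()].
#' @export
blur_field <- function(field, delta = 0.1) {
  comb <- .comb_offsets(delta)
  inner <- field$predict
  fun <- function(rgb) {
    rgb <- .as_rgb_matrix(rgb)
    n <- nrow(rgb); m <- nrow(comb$offsets)
    pts <- rgb[rep(seq_len(n), each = m), , drop = FALSE] +
      comb$offsets[rep(seq_len(m), n), , drop = FALSE]
    pts <- pmin(pmax(pts, 0), 1)
    P <- inner(pts)
    W <- rep(comb$weights, n)
    out <- rowsum(P * W, rep(seq_len(n), each = m))
    out <- out / rowSums(out)
    dimnames(out) <- list(NULL, field$vocabulary)
    out
  }
  distribution_field(fun, field$vocabulary)
}

#' Categorical metric tensor at a colour
#'
#' Central differences of the square-rooted distributions along the R, G and
#' B axes with step \code{delta} give per-axis derivative vectors
#' \eqn{d_R, d_G, d_B}; the tensor is
#' \eqn{\Gamma = (d_R\,d_G\,d_B)^T (d_R\,d_G\,d_B)}. Near the cube faces the
#' probe points are clamped into the cube and the normalization uses the
#' actual probe separation.
#'
#' @param field a [distribution_field()] (blur it first with [blur_field()]
#'   for the standard pipeline).
#' @param z length-3 sRGB location.
#' @param delta finite-difference step (default 0.1).
#' @return 3 x 3 symmetric PSD matrix.
#' @export
metric_tensor <- function(field, z, delta = 0.1) {
  z <- as.numeric(z)
  probes <- matrix(rep(z, 6), ncol = 3, byrow = TRUE)
  for (a in 1:3) {
    probes[2 * a - 1, a] <- z[a] + delta / 2
    probes[2 * a, a] <- z[a] - delta / 2
  }
  probes <- pmin(pmax(probes, 0), 1)
  P <- sqrt(field$predict(probes))
  D <- matrix(0, 3, ncol(P))
  for (a in 1:3) {
    sep <- probes[2 * a - 1, a] - probes[2 * a, a]
    if (sep <= 0) next
    D[a, ] <- (P[2 * a - 1, ] - P[2 * a, ]) / sep
  }
  .psd_clip(D %*% t(D))
}

# ---- tensor grids ----------------------------------------------------------

#' Pre-computed tensor grid over the sRGB cube
#'
#' Computes [metric_tensor()] on a regular grid covering \eqn{[0,1]^3}
#' inclusive, for fast interpolated queries via [tensor_at()].
#'
#' @param field a [distribution_field()] (already blurred for the standard
#'   pipeline), or any function of an sRGB triple returning a 3 x 3 tensor.
#' @param spacing grid spacing; must divide 1 evenly (default 0.05).
#' @param delta finite-difference step passed to [metric_tensor()].
#' @return object of class \code{"tensor_field"}: grid coordinates and the
#'   6 upper-triangle components per node (R index fastest).
#' @export
tensor_grid <- function(field, spacing = 0.05, delta = 0.1) {
  m <- 1 / spacing
  if (abs(m - round(m)) > 1e-9) stop("spacing must divide 1 evenly")
  m <- as.integer(round(m)) + 1L
  coords <- seq(0, 1, length.out = m)
  nodes <- as.matrix(expand.grid(R = coords, G = coords, B = coords))
  tensor_fun <- if (inherits(field, "distribution_field"))
    function(z) metric_tensor(field, z, delta = delta)
  else if (is.function(field)) field
  else stop("field must be a distribution_field or a tensor function")
  comps <- matrix(NA_real_, nrow(nodes), 6)
  for (i in seq_len(nrow(nodes)))
    comps[i, ] <- .comps_from_sym(.psd_clip(tensor_fun(nodes[i, ])))
  structure(list(spacing = spacing, n = m, coords = coords,
                 comps = comps, delta = delta),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field: %d^3 nodes, spacing %g>\n", x$n, x$spacing))
  invisible(x)
}

.node_index <- function(i, j, k, m) (k - 1L) * m * m + (j - 1L) * m + i

# Separable piecewise-quadratic (3-node Lagrange) interpolation weights.
.quad_axis <- function(x, coords, m) {
  h <- coords[2] - coords[1]
  j <- round(x / h) + 1               # nearest node
  j <- min(max(j, 2L), m - 1L)        # centre must have both neighbours
  xs <- coords[(j - 1):(j + 1)]
  w <- c((x - xs[2]) * (x - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3])),
         (x - xs[1]) * (x - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3])),
         (x - xs[1]) * (x - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2])))
  list(idx = (j - 1L):(j + 1L), w = w)
}

#' Interpolate a tensor field at a colour
#'
#' Componentwise separable piecewise-quadratic interpolation on the 3^3
#' neighbourhood of the nearest grid node, with PSD clipping of the result.
#' Queries at grid nodes return the stored tensor exactly.
#'
#' @param tf a \code{"tensor_field"} from [tensor_grid()].
#' @param z length-3 sRGB location in \eqn{[0,1]^3}.
#' @return 3 x 3 symmetric PSD matrix.
#' @export
interpolate_tensor <- function(tf, z) {
  z <- as.numeric(z)
  if (any(z < -1e-12) || any(z > 1 + 1e-12))
    stop("query outside the sRGB cube")
  z <- pmin(pmax(z, 0), 1)
  ax <- lapply(z, .quad_axis, coords = tf$coords, m = tf$n)
  t6 <- numeric(6)
  for (a in 1:3) for (b in 1:3) for (c in 1:3) {
    w <- ax[[1]]$w[a] * ax[[2]]$w[b] * ax[[3]]$w[c]
    if (w == 0) next
    idx <- .node_index(ax[[1]]$idx[a], ax[[2]]$idx[b], ax[[3]]$idx[c], tf$n)
    t6 <- t6 + w * tf$comps[idx, ]
  }
  .psd_clip(.sym_from_comps(t6))
}

#' Evaluate any tensor-field representation at a colour
#'
#' Dispatches on the representation: a \code{"tensor_field"} grid is
#' interpolated, a function is called, a constant 3 x 3 matrix is returned
#' as-is.
#'
#' @param field a \code{"tensor_field"}, a function of an sRGB triple, or a
#'   3 x 3 matrix.
#' @param z length-3 sRGB location.
#' @return 3 x 3 matrix.
#' @export
tensor_at <- function(field, z) {
  if (inherits(field, "tensor_field")) return(interpolate_tensor(field, z))
  if (is.function(field)) return(field(z))
  if (is.matrix(field) && all(dim(field) == c(3, 3))) return(field)
  stop("unsupported tensor field representation")
}

#' Write a tensor grid to a plain-text file
#'
#' Tab-separated layout: header comment lines documenting the spacing,
#' finite-difference step and node ordering (R index fastest), then one row
#' per node with 0-based integer indices \code{i j k} followed by the 6
#' upper-triangle tensor components T11 T12 T13 T22 T23 T33.
#'
#' @param tf a \code{"tensor_field"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tensor_grid <- function(tf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spacing: %.17g", tf$spacing),
               sprintf("# delta: %.17g", tf$delta),
               "# order: R-fastest",
               "# components: T11 T12 T13 T22 T23 T33"), con)
  m <- tf$n
  ijk <- as.matrix(expand.grid(i = 0:(m - 1), j = 0:(m - 1),
                               k = 0:(m - 1)))
  df <- cbind(ijk, tf$comps)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tensor grid written by [write_tensor_grid()]
#'
#' @param path input path.
#' @return a \code{"tensor_field"}.
#' @export
read_tensor_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  spacing <- as.numeric(sub(".*spacing:\\s*", "",
                            grep("spacing:", hdr, value = TRUE)[1]))
  delta <- as.numeric(sub(".*delta:\\s*", "",
                          grep("delta:", hdr, value = TRUE)[1]))
  if (!is.finite(spacing)) stop("malformed grid: missing spacing header")
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  m <- as.integer(round(1 / spacing)) + 1L
  if (nrow(body) != m^3)
    stop(sprintf("malformed grid: %d rows, expected %d for spacing %g",
                 nrow(body), m^3, spacing))
  comps <- as.matrix(body[, 4:9])
  bad <- which(!is.finite(comps), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed grid: non-finite tensor at node row %d",
                 bad[1, 1]))
  ord <- order(body[, 3], body[, 2], body[, 1])   # ensure R-fastest
  comps <- comps[ord, , drop = FALSE]
  dimnames(comps) <- NULL
  structure(list(spacing = spacing, n = m,
                 coords = seq(0, 1, length.out = m),
                 comps = comps,
                 delta = if (is.finite(delta)) delta else NA_real_),
            class = "tensor_field")
}

#' Categorical metric pipeline from a fitted model
#'
#' Convenience wrapper over the standard pipeline: normalize, blur, take
#' square roots, finite-difference and grid. Returns the pre-computed tensor
#' grid of the categorical metric of a fitted naming model.
#'
#' @param model a \code{"naming_model"}.
#' @param spacing grid spacing (default 0.05).
#' @param delta smoothness length scale for the blur and finite differences
#'   (default 0.1).
#' @return a \code{"tensor_field"}.
#' @export
categorical_metric <- function(model, spacing = 0.05, delta = 0.1) {
  tensor_grid(blur_field(model_field(model), delta = delta),
              spacing = spacing, delta = delta)
}
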