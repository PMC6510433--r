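# Shared fixtures, built in code.

# two-name logistic handover along the R axis, constant in G and B
handover_field <- function(steepness = 12, profile = identity) {
  distribution_field(function(rgb) {
    p <- stats::plogis(steepness * (profile(rgb[, 1]) - 0.5))
    cbind(a = 1 - p, b = p)
  }, c("a", "b"))
}

# constant-distribution field
constant_field <- function(p = c(0.3, 0.7)) {
  distribution_field(function(rgb)
    matrix(p, nrow(rgb), length(p), byrow = TRUE),
    paste0("n", seq_along(p)))
}

# pullback metric of an azimuthal-equidistant map onto a sphere of radius r,
# on the plane B = 0.5 (degenerate in the B direction)
sphere_pullback_field <- function(r) {
  function(z) {
    x <- z[1] - 0.5; y <- z[2] - 0.5
    rho <- sqrt(x^2 + y^2)
    if (rho < 1e-9) return(diag(c(1, 1, 0)))
    er <- c(x, y, 0) / rho; ep <- c(-y, x, 0) / rho
    er %*% t(er) + (r^2 * sin(rho / r)^2 / rho^2) * ep %*% t(ep)
  }
}

# small square mesh in the plane B = 0.5
planar_square_mesh <- function(n = 5, lo = 0.3, hi = 0.7) {
  xs <- seq(lo, hi, length.out = n)
  V <- cbind(as.matrix(expand.grid(xs, xs)), 0.5)
  idx <- matrix(seq_len(n * n), n, n)
  tris <- list()
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    tris[[length(tris) + 1]] <- c(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1])
    tris[[length(tris) + 1]] <- c(idx[i, j], idx[i + 1, j + 1], idx[i, j + 1])
  }
  mesh_spec(V, do.call(rbind, tris),
            boundary = c(idx[, 1], idx[n, -1], idx[n:1, n][-1],
                         idx[1, (n - 1):2]))
}

# long-format naming records with controllable structure
make_records <- function(names_per_subject, chips = NULL) {
  n_sub <- length(names_per_subject)
  rows <- list()
  for (s in seq_len(n_sub)) {
    nm <- names_per_subject[[s]]
    ch <- if (is.null(chips)) matrix(stats::runif(3 * length(nm)), ncol = 3)
          else chips[seq_along(nm), , drop = FALSE]
    rows[[s]] <- data.frame(subject = s, r = ch[, 1], g = ch[, 2],
                            b = ch[, 3], name = nm)
  }
  do.call(rbind, rows)
}
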