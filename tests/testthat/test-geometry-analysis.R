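# Lengths, areas, volumes, capacities, distortion and embeddings.

test_that("path length, area and volume have their closed forms", {
  id <- diag(3)
  seg <- path_spec(rbind(c(0.1, 0.2, 0.3), c(0.6, 0.2, 0.3)))
  expect_equal(path_length(id, seg, density = 20)$raw, 0.5,
               tolerance = 1e-12)
  G <- grain_units()
  expect_equal(unname(G), c(pi / 2, pi^3 / 16, pi^4 / 48))
  expect_equal(unname(G["G1"]), 2 * (pi / 4))
  expect_equal(unname(G["G2"]), pi * (pi / 4)^2)
  expect_equal(unname(G["G3"]), 4 * pi * (pi / 4)^3 / 3)
  vol <- categorical_volume(id, subdiv = 3)
  expect_equal(vol$raw, 1, tolerance = 1e-12)
  expect_equal(vol$grains, 1 / unname(G["G3"]), tolerance = 1e-12)
  vold <- categorical_volume(matrix(diag(c(4, 9, 25)), 3), subdiv = 3)
  expect_equal(vold$raw, sqrt(4 * 9 * 25), tolerance = 1e-12)
})

test_that("measures scale as s, s^2, s^3 under a rescaled metric", {
  s2 <- 2.25
  base <- function(z) diag(c(1 + z[1], 2, 1 + z[3]))
  scaled <- function(z) s2 * base(z)
  seg <- path_spec(rbind(c(0.1, 0.1, 0.1), c(0.9, 0.8, 0.7)))
  expect_equal(path_length(scaled, seg, density = 30)$raw,
               sqrt(s2) * path_length(base, seg, density = 30)$raw,
               tolerance = 1e-10)
  msh <- planar_square_mesh(4)
  expect_equal(categorical_area(scaled, msh)$raw,
               s2 * categorical_area(base, msh)$raw, tolerance = 1e-10)
  expect_equal(categorical_volume(scaled, 3)$raw,
               s2^1.5 * categorical_volume(base, 3)$raw, tolerance = 1e-10)
})

test_that("capacity corrects for boundaries and is additive on merging", {
  expect_equal(capacity(1.7, 2, dim = 1), 2.7)
  expect_equal(capacity(5, 0, dim = 1), 5)      # closed loop
  expect_error(capacity(-1, 0), "nonnegative")
  # merging two abutting segments cancels the interior endpoint pair
  c1 <- capacity(1.2, 2, 1); c2 <- capacity(0.8, 2, 1)
  merged <- capacity(2.0, 2, 1)
  expect_equal(c1 + c2 - 2 * 0.5, merged + 0.5 * 2 - 0.5 * 2 + 0)
  expect_equal(merged, c1 + c2 - 1)
})

test_that("plane restriction keeps in-plane quadratic forms", {
  T <- diag(c(4, 9, 25))
  expect_equal(restrict_tensor(diag(3), c(1, 0, 0), c(0, 1, 0)), diag(2))
  expect_equal(restrict_tensor(T, c(1, 0, 0), c(0, 1, 0)), diag(c(4, 9)))
  set.seed(4)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  x <- c(1, 1, 0) / sqrt(2); y <- c(0, 0, 1)
  T2 <- restrict_tensor(A, x, y)
  for (i in 1:10) {
    ab <- rnorm(2)
    v <- ab[1] * x + ab[2] * y
    expect_equal(as.numeric(ab %*% T2 %*% ab),
                 as.numeric(v %*% A %*% v), tolerance = 1e-10)
  }
  expect_error(restrict_tensor(A, c(1, 0, 0), c(1, 0, 0)), "orthonormal")
})

test_that("local and global distortion behave under identity and scaling", {
  id <- diag(3)
  expect_equal(local_distortion(4 * id, id, c(1, 2, 3)), 1)
  g0 <- global_distortion(id, id, n_samples = 100, seed = 1)
  expect_equal(g0$global, 0, tolerance = 1e-12)
  gs <- global_distortion(function(z) 4 * diag(3), id,
                          n_samples = 100, seed = 1)
  expect_equal(gs$global, 0, tolerance = 1e-10)
  expect_equal(gs$mean, 1, tolerance = 1e-10)
  # the 95% range formula at global distortion 0.50 is 51-197%
  expect_equal(round(100 * distortion_range(0.50)), c(51, 197))
})

test_that("global distortion is symmetric and orders the CIE refinements", {
  Af <- function(z) diag(c(1 + z[1], 2, 0.5 + z[3]))
  Bf <- function(z) diag(c(2, 1 + z[2], 1))
  s1 <- global_distortion(Af, Bf, n_samples = 300, seed = 7)$global
  s2 <- global_distortion(Bf, Af, n_samples = 300, seed = 7)$global
  expect_equal(s1, s2, tolerance = 1e-12)
  # refinements of the CIE formulas are progressively more distorted
  # relative to Euclidean sRGB
  id <- diag(3)
  g76 <- global_distortion(id, cie_tensor_field("cie76"),
                           n_samples = 250, seed = 2)$global
  g94 <- global_distortion(id, cie_tensor_field("cie94"),
                           n_samples = 250, seed = 2)$global
  g00 <- global_distortion(id, cie_tensor_field("cie2000"),
                           n_samples = 250, seed = 2)$global
  expect_lt(g76, g94)
  expect_lt(g94, g00)
})

test_that("1-D embeddings are isometric and collapse constant regions", {
  id <- diag(3)
  seg <- path_spec(rbind(c(0, 0.5, 0.5), c(1, 0.5, 0.5)))
  e <- embed_1d(id, seg, density = 50)
  expect_equal(e$total, 1, tolerance = 1e-12)
  expect_equal(e$arc_length, sqrt(rowSums(sweep(e$points, 2,
               e$points[1, ])^2)), tolerance = 1e-9)
  # closed path: circle of circumference = categorical length
  loop <- standard_paths()$full_colour_locus
  ec <- embed_1d(id, loop, density = 40)
  expect_equal(ec$radius, 6 / (2 * pi), tolerance = 1e-9)
  gaps <- sqrt(rowSums(diff(ec$positions)^2))
  seg_chord <- 2 * ec$radius * sin(diff(ec$arc_length) / ec$total * pi)
  expect_equal(gaps, seg_chord, tolerance = 1e-9)
  # regions with constant response distribution shrink to points: the
  # clamped profile is exactly constant on the outer thirds of the path
  clamp <- function(t) pmin(pmax((t - 0.35) / 0.3, 0), 1)
  f <- function(z) metric_tensor(handover_field(40, clamp), z, delta = 0.02)
  eh <- embed_1d(f, seg, density = 200)
  ends <- eh$points[, 1] < 0.25
  expect_lt(diff(range(eh$arc_length[ends])), 1e-6 * eh$total)
  expect_gt(eh$total, 0.9 * pi / 2)
})

test_that("harmonic surfaces interpolate their boundary", {
  # planar boundary -> planar surface (harmonic extension of affine data)
  sq <- path_spec(rbind(c(0, 0, 0.5), c(1, 0, 0.5), c(1, 1, 0.5),
                        c(0, 1, 0.5)), closed = TRUE)
  ms <- laplace_surface(sq, resolution = 8)
  expect_lt(max(abs(ms$vertices[, 3] - 0.5)), 1e-10)
  # interior vertices average their neighbours (residual check via re-solve)
  # full colour locus -> monkey saddle through the cube centre
  ml <- laplace_surface(standard_paths()$full_colour_locus, resolution = 10)
  ctr <- ml$vertices[which.min(rowSums((ml$vertices - 0.5)^2)), ]
  expect_lt(max(abs(ctr - 0.5)), 0.05)
  # refinement changes interior positions by less than the mesh size
  m2 <- laplace_surface(standard_paths()$full_colour_locus, resolution = 20)
  c2 <- m2$vertices[which.min(rowSums((m2$vertices - 0.5)^2)), ]
  expect_lt(sqrt(sum((c2 - ctr)^2)), 0.1)
  expect_error(laplace_surface(path_spec(rbind(c(0, 0, 0), c(1, 1, 1)))),
               "closed")
})

test_that("sphere embedding recovers a known spherical geometry", {
  r <- 0.35
  msh <- planar_square_mesh(5)
  em <- embed_sphere(sphere_pullback_field(r), msh, edge_density = 100,
                     maxit = 400)
  expect_equal(em$radius, r, tolerance = 0.02 * r)
  expect_gt(em$distortion_range[1], 0.99)
  expect_lt(em$distortion_range[2], 1.01)
  # a flat metric on a planar mesh embeds on a much larger sphere
  emf <- embed_sphere(diag(3), msh, edge_density = 50, maxit = 300)
  expect_gt(emf$radius, 2 * r)
  expect_lt(emf$global, 0.05)
})
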