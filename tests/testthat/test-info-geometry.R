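# Divergences, Bhattacharyya angles, blurring, finite-difference tensors,
# grids and grid IO.

test_that("KL and JS divergences have their closed-form values", {
  expect_equal(kld(c(1, 0), c(1, 0)), 0)
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(kld(c(0.5, 0.5), c(1, 0)), Inf)
  expect_error(kld(c(1, 0), c(1, 0, 0)), "length")
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)          # disjoint: maximal 1 bit
  # brute-force evaluation of an asymmetric pair
  p <- c(3, 1) / 4; q <- c(1, 3) / 4; m <- (p + q) / 2
  direct <- 0.5 * (sum(p * log2(p / m)) + sum(q * log2(q / m)))
  expect_equal(jsd(p, q), direct)
  expect_equal(jsd(p, q), jsd(q, p))
  expect_equal(jsd_distance(p, q), sqrt(direct))
})

test_that("Bhattacharyya angle is spherical distance on sqrt-distributions", {
  expect_equal(bhattacharyya_angle(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bhattacharyya_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(bhattacharyya_angle(c(1, 0), c(0.5, 0.5)), pi / 4)
  # close distributions: angle ~ Euclidean norm of sqrt-vector difference
  set.seed(1)
  for (i in 1:20) {
    p <- runif(5); p <- p / sum(p)
    q <- p + rnorm(5, 0, 1e-3 * p); q <- abs(q) / sum(abs(q))
    ang <- bhattacharyya_angle(p, q)
    eu <- sqrt(sum((sqrt(p) - sqrt(q))^2))
    if (ang > 0 && ang < 0.05)
      expect_equal(ang, eu, tolerance = 0.01 * max(ang, 1e-12))
  }
})

test_that("the normal-family tensor gives the printed infinitesimal rule", {
  eps <- 1e-3
  expect_equal(normal_fisher_example(0, 1, eps, 1), eps / 2)
  expect_equal(normal_fisher_example(0, 2, 0, 2 + eps),
               eps / (2 * sqrt(2)), tolerance = 1e-9)
  # numerical Bhattacharyya angle on a fine discretization matches eps/2
  x <- seq(-10, 10, length.out = 100001)
  p1 <- dnorm(x, 0, 1); p2 <- dnorm(x, eps, 1)
  ang <- bhattacharyya_angle(p1 / sum(p1), p2 / sum(p2))
  expect_equal(ang, eps / 2, tolerance = eps / 2 * 0.01)
})

test_that("comb blurring preserves constants and has spread 0.36 delta", {
  expect_lt(abs(blur_filter_sd(0.1) - 0.36 * 0.1), 1e-4)
  cf <- constant_field(c(0.3, 0.7))
  bf <- blur_field(cf, delta = 0.1)
  z <- matrix(runif(15), ncol = 3)
  expect_equal(unname(bf$predict(z)),
               matrix(c(0.3, 0.7), 5, 2, byrow = TRUE), tolerance = 1e-12)
  # interior linear profiles are preserved by the symmetric comb
  lf <- distribution_field(function(rgb)
    cbind(0.2 + 0.3 * rgb[, 1], 0.8 - 0.3 * rgb[, 1]), c("a", "b"))
  bl <- blur_field(lf, delta = 0.1)
  zi <- matrix(c(0.5, 0.5, 0.5, 0.3, 0.7, 0.2), ncol = 3, byrow = TRUE)
  expect_equal(unname(bl$predict(zi)), unname(lf$predict(zi)),
               tolerance = 1e-10)
})

test_that("metric tensor vanishes on constant fields and matches the
           analytic logistic handover", {
  cf <- constant_field(c(0.4, 0.6))
  expect_equal(metric_tensor(cf, c(0.5, 0.5, 0.5)), matrix(0, 3, 3))
  s <- 12; x <- 0.4
  f <- handover_field(s)
  G <- metric_tensor(f, c(x, 0.5, 0.5), delta = 0.01)
  p <- plogis(s * (x - 0.5)); dp <- s * p * (1 - p)
  analytic <- dp^2 / (4 * p * (1 - p))   # |d/dx (sqrt p, sqrt 1-p)|^2
  expect_equal(G[1, 1], analytic, tolerance = 1e-3 * analytic)
  expect_equal(qr(G)$rank, 1)
  expect_equal(G, t(G))
})

test_that("a complete handover measures one grain however it is traversed", {
  path <- path_spec(rbind(c(0, 0.5, 0.5), c(1, 0.5, 0.5)))
  for (delta in c(0.02, 0.1, 0.2)) {
    g <- path_length(function(z)
      metric_tensor(handover_field(30), z, delta = delta),
      path, density = 300)$grains
    expect_equal(g, 1, tolerance = 0.05)
  }
  # a reparameterized (non-uniform speed) handover has the same length
  for (prof in list(function(t) t^2, function(t) sqrt(t))) {
    g <- path_length(function(z)
      metric_tensor(handover_field(30, prof), z, delta = 0.02),
      path, density = 600)$grains
    expect_equal(g, 1, tolerance = 0.02)
  }
})

test_that("path length is reparameterization-invariant across densities", {
  f <- function(z) metric_tensor(handover_field(20), z, delta = 0.05)
  path <- path_spec(rbind(c(0, 0.5, 0.5), c(1, 0.5, 0.5)))
  lens <- vapply(c(100, 200, 400), function(d)
    path_length(f, path, density = d)$raw, numeric(1))
  expect_lt(max(abs(lens - lens[3])) / lens[3], 0.005)
})

test_that("vocabulary permutation leaves the tensor unchanged", {
  m <- synthetic_naming_model(n_names = 3, seed = 4)
  f <- model_field(m)
  fperm <- distribution_field(function(rgb)
    f$predict(rgb)[, c(3, 1, 2, 4), drop = FALSE], f$vocabulary[c(3, 1, 2, 4)])
  z <- c(0.4, 0.6, 0.3)
  expect_equal(metric_tensor(f, z), metric_tensor(fperm, z),
               tolerance = 1e-12)
})

test_that("tensor grids are exact at nodes and interpolate accurately", {
  tfun <- function(z) {
    s <- 1 + 0.5 * sin(2 * pi * z[1]) * cos(pi * z[2])
    diag(c(s, 2 * s, 0.5 + z[3]))
  }
  tg <- tensor_grid(tfun, spacing = 0.25)
  for (z in list(c(0, 0, 0), c(0.5, 0.25, 0.75), c(1, 1, 1)))
    expect_equal(interpolate_tensor(tg, z), tfun(z), tolerance = 1e-12)
  # constant fields interpolate exactly everywhere
  tgc <- tensor_grid(function(z) diag(c(2, 3, 4)), spacing = 0.5)
  expect_equal(interpolate_tensor(tgc, c(0.123, 0.456, 0.789)),
               diag(c(2, 3, 4)), tolerance = 1e-12)
  # smooth fields: small relative error off-node
  set.seed(2)
  errs <- vapply(1:100, function(i) {
    z <- runif(3)
    A <- interpolate_tensor(tg, z); B <- tfun(z)
    norm(A - B, "F") / norm(B, "F")
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  expect_error(interpolate_tensor(tg, c(1.2, 0, 0)), "outside")
  expect_error(tensor_grid(tfun, spacing = 0.3), "divide")
})

test_that("grid interpolation tracks a smooth naming model closely", {
  # categories wide relative to the grid spacing, as the smoothness scale
  # delta presumes of fitted naming data
  ps <- list()
  mus <- rbind(c(30, 20, -30), c(60, -30, 20), c(75, 10, 40), c(45, 0, 0))
  set.seed(7)
  for (i in 1:4)
    ps[[i]] <- name_params(0.5, mus[i, ], runif(1, 30, 45)^2 * diag(3),
                           1.2, 0.2)
  names(ps) <- paste0("n", 1:4)
  bf <- blur_field(model_field(naming_model(ps)), delta = 0.1)
  tg <- tensor_grid(bf, spacing = 0.05, delta = 0.1)
  set.seed(3)
  errs <- vapply(1:40, function(i) {
    z <- runif(3, 0.05, 0.95)
    A <- interpolate_tensor(tg, z)
    B <- metric_tensor(bf, z, delta = 0.1)
    norm(A - B, "F") / max(norm(B, "F"), 1e-12)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("tensor grid files round-trip losslessly and reject bad grids", {
  tg <- tensor_grid(function(z) diag(1 + z), spacing = 0.5)
  tmp <- tempfile(fileext = ".tsv")
  write_tensor_grid(tg, tmp)
  tg2 <- read_tensor_grid(tmp)
  expect_equal(tg2$comps, tg$comps, tolerance = 1e-15)
  expect_equal(tg2$spacing, tg$spacing)
  # NaN tensors are rejected with a location
  lines <- readLines(tmp)
  body_at <- which(!grepl("^#", lines))[5]
  parts <- strsplit(lines[body_at], "\t")[[1]]
  parts[4] <- "NaN"
  lines[body_at] <- paste(parts, collapse = "\t")
  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(lines, tmp2)
  expect_error(read_tensor_grid(tmp2), "non-finite")
  # wrong row count for the declared spacing
  writeLines(lines[-body_at], tmp2)
  expect_error(read_tensor_grid(tmp2), "expected")
})
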