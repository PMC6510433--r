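# Synthetic data generators: toy 1-D category manifolds, the rank-power-law
# response sampler, ground-truth naming models and full synthetic naming
# datasets, so the entire pipeline can be exercised without survey data.

#' Toy 1-D category specification
#'
#' Unimodal per-name response-rate functions over a 1-D colour parameter
#' \eqn{t \in [0,1]}: Gaussian bumps with optional one-sided plateaus for
#' the edge categories (so the extremes of the manifold have constant
#' response distributions).
#'
#' @param centers peak locations in \eqn{[0,1]}.
#' @param widths Gaussian widths.
#' @param peaks peak response rates in (0, 1].
#' @param classes \code{"chromatic"} or \code{"tonal"} tags (informational).
#' @param one_sided per-category: \code{-1} holds the peak rate for all
#'   \code{t} left of the centre, \code{+1} right of it, \code{0} none.
#' @param names category names (default auto-generated).
#' @return object of class \code{"toy_category_spec"}.
#' @export
toy_category_spec <- function(centers, widths, peaks,
                              classes = rep("chromatic", length(centers)),
                              one_sided = rep(0L, length(centers)),
                              names = NULL) {
  n <- length(centers)
  stopifnot(length(widths) == n, length(peaks) == n,
            length(classes) == n, length(one_sided) == n,
            all(peaks > 0), all(peaks <= 1), all(widths > 0))
  if (is.null(names)) names <- paste0(substr(classes, 1, 1), seq_len(n))
  structure(list(centers = centers, widths = widths, peaks = peaks,
                 classes = classes, one_sided = as.integer(one_sided),
                 names = names), class = "toy_category_spec")
}

#' Default toy chromatic categories
#'
#' Three overlapping chromatic categories on the 1-D manifold: the two edge
#' categories reach rate 1 on plateaus at the extremes; the middle category
#' peaks lower and is never the sole response.
#'
#' @return a [toy_category_spec()].
#' @export
toy_chromatic_spec <- function() {
  toy_category_spec(centers = c(0.15, 0.5, 0.85),
                    widths = c(0.12, 0.10, 0.12),
                    peaks = c(1, 0.55, 1),
                    classes = rep("chromatic", 3),
                    one_sided = c(-1L, 0L, 1L),
                    names = c("blue", "turquoise", "green"))
}

#' Default toy tonal categories
#'
#' Five narrow, nearly disjoint tonal categories with low peak rates,
#' evenly spaced over the manifold.
#'
#' @param n number of tonal categories (default 5).
#' @return a [toy_category_spec()].
#' @export
toy_tonal_spec <- function(n = 5) {
  toy_category_spec(centers = seq(0.1, 0.9, length.out = n),
                    widths = rep(0.045, n),
                    peaks = rep(0.3, n),
                    classes = rep("tonal", n))
}

#' Combine toy category specifications
#'
#' @param ... \code{"toy_category_spec"} objects.
#' @return a merged [toy_category_spec()].
#' @export
combine_toy_specs <- function(...) {
  specs <- list(...)
  toy_category_spec(
    centers = unlist(lapply(specs, `[[`, "centers")),
    widths = unlist(lapply(specs, `[[`, "widths")),
    peaks = unlist(lapply(specs, `[[`, "peaks")),
    classes = unlist(lapply(specs, `[[`, "classes")),
    one_sided = unlist(lapply(specs, `[[`, "one_sided")),
    names = make.unique(unlist(lapply(specs, `[[`, "names"))))
}

.toy_rates <- function(spec, t) {
  n <- length(spec$centers)
  Q <- matrix(0, length(t), n)
  for (i in seq_len(n)) {
    d <- t - spec$centers[i]
    if (spec$one_sided[i] == -1L) d <- pmax(d, 0)
    if (spec$one_sided[i] == 1L) d <- pmin(d, 0)
    Q[, i] <- spec$peaks[i] * exp(-0.5 * (d / spec$widths[i])^2)
  }
  colnames(Q) <- spec$names
  Q
}

#' Full categorical pipeline on a toy 1-D manifold
#'
#' Normalizes the per-name rate functions to response distributions at each
#' point, embeds their square roots on the unit sphere, and measures the
#' manifold: the local metric (categorical speed), the cumulative isometric
#' warp, total length in grains, and capacity under the 1-D
#' boundary-corrected formula. Segment lengths are the exact Bhattacharyya
#' angles between consecutive distributions, so an instantaneous complete
#' handover contributes exactly one grain.
#'
#' @param spec a [toy_category_spec()].
#' @param n_points sampling resolution over \eqn{t \in [0,1]}.
#' @return list: \code{t}, \code{distributions} (rows sum to 1),
#'   \code{speed} (categorical length per unit t at segment midpoints),
#'   \code{warp} (cumulative categorical length: the isometric embedding of
#'   the open manifold), \code{length_raw}, \code{grains},
#'   \code{capacity}, and \code{sd_log2_metric} (sd of the log2 metric over
#'   segments with positive speed).
#' @export
toy_manifold <- function(spec, n_points = 1001) {
  t <- seq(0, 1, length.out = n_points)
  Q <- .toy_rates(spec, t)
  P <- Q / rowSums(Q)
  S <- sqrt(P)
  dots <- rowSums(S[-nrow(S), , drop = FALSE] * S[-1, , drop = FALSE])
  seg <- acos(pmin(1, pmax(0, dots)))
  warp <- c(0, cumsum(seg))
  total <- warp[length(warp)]
  dt <- diff(t)
  speed <- seg / dt
  G1 <- grain_units()["G1"][[1]]
  grains <- total / G1
  pos <- speed > 1e-9
  list(t = t, distributions = P, speed = speed, warp = warp,
       length_raw = total, grains = grains,
       capacity = capacity(grains, boundary = 2, dim = 1),
       sd_log2_metric = if (any(pos)) stats::sd(log2(speed[pos]))
                        else NA_real_)
}

#' Rank-power-law multinomial
#'
#' Probabilities decaying with rank \eqn{r} as \eqn{r^{-e}}, normalized over
#' the support; the model of a typical chip's naming-response distribution.
#'
#' @param exponent decay exponent (default 1.4).
#' @param support number of ranks (default 804).
#' @return probability vector of length \code{support}.
#' @export
rank_power_multinomial <- function(exponent = 1.4, support = 804) {
  if (support < 1) stop("support must be >= 1")
  p <- seq_len(support)^(-exponent)
  p / sum(p)
}

#' Sample counts from the rank-power-law multinomial
#'
#' @param n number of draws.
#' @param exponent,support as in [rank_power_multinomial()].
#' @param seed RNG seed.
#' @return integer vector of counts per rank (length \code{support}).
#' @export
rank_power_sample <- function(n, exponent = 1.4, support = 804,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rank_power_multinomial(exponent, support)
  tabulate(sample.int(support, n, replace = TRUE, prob = p), support)
}

#' Ground-truth synthetic naming model
#'
#' Builds a \code{"naming_model"} with known parameters: \code{n_names}
#' compact category "bumps" (peak rates 0.4-0.7, axis scales 12-22 CIELAB
#' units, sharpness in \eqn{[1, 1.8]}, random orientations) whose peak
#' locations are spread over the interior of the CIELAB image of the sRGB
#' cube by greedy maximin selection, plus one very broad low-informative
#' \code{"other"} category standing in for the long tail of rare names.
#' The background keeps the summed response rates close to 1 everywhere, so
#' the normalized naming distributions preserve the bump structure — the
#' regime in which per-name parameters are recoverable from sampled data.
#'
#' @param n_names number of compact categories (the \code{"other"}
#'   background is added on top).
#' @param seed RNG seed.
#' @param gamma lapse rate.
#' @return a \code{"naming_model"} usable with \code{predict}, the
#'   tensor-field pipeline and [synthetic_naming_dataset()].
#' @export
synthetic_naming_model <- function(n_names = 5, seed = 1, gamma = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  cand <- matrix(stats::runif(3 * 800, 0.1, 0.9), ncol = 3)
  lab_c <- .as_lab_matrix(srgb_to_lab(cand))
  sel <- sample(nrow(cand), 1)
  for (i in seq_len(n_names - 1)) {
    dmin <- apply(lab_c, 1, function(z)
      min(sqrt(colSums((t(lab_c[sel, , drop = FALSE]) - z)^2))))
    sel <- c(sel, which.max(dmin))
  }
  params <- list()
  for (i in seq_len(n_names)) {
    scales <- stats::runif(3, 12, 22)
    A <- matrix(stats::rnorm(9), 3)
    Qr <- qr.Q(qr(A))
    Sigma <- Qr %*% diag(scales^2) %*% t(Qr) + SIGMA_EIGEN_FLOOR * diag(3)
    params[[i]] <- name_params(
      k = stats::runif(1, 0.4, 0.7), mu = lab_c[sel[i], ], Sigma = Sigma,
      alpha = stats::runif(1, 1.0, 1.8), g = 0.5 / n_names)
  }
  names(params) <- sprintf("name%02d", seq_len(n_names))
  params$other <- name_params(
    k = 0.8, mu = srgb_to_lab(c(0.5, 0.5, 0.5)),
    Sigma = 300^2 * diag(3), alpha = 1, g = 0.5)
  naming_model(params, gamma = gamma)
}

.jittered_chip_grid <- function(n_per_axis = 8) {
  centres <- (seq_len(n_per_axis) - 0.5) / n_per_axis
  grid <- as.matrix(expand.grid(centres, centres, centres))
  jit <- matrix(stats::runif(length(grid), -0.4, 0.4) / n_per_axis,
                ncol = 3)
  pmin(pmax(grid + jit, 0), 1)
}

#' Generate a synthetic colour-naming dataset
#'
#' Draws naming responses per chip i.i.d. from the model's normalized
#' naming distribution, and arranges them into subject sessions of 20
#' sequential presentations in which the 18th presentation repeats the
#' subject's 3rd chip (a fresh response draw), mirroring the design of
#' crowd-sourced naming experiments so agreement statistics can be
#' exercised.
#'
#' @param model a \code{"naming_model"}.
#' @param chips n x 3 matrix of sRGB chips, or NULL for a jittered
#'   \code{round(n_chips^(1/3))}-per-axis grid.
#' @param n_chips chip count when \code{chips} is NULL (default 512,
#'   a cube-filling grid of several hundred chips).
#' @param responses_per_chip responses drawn per chip (default 30).
#' @param seed RNG seed.
#' @param subjects assign subject ids and repeat presentations?
#' @return list with \code{responses} (the long-format data frame),
#'   \code{table} (the cleaned \code{"naming_table"}) and \code{report}.
#' @export
synthetic_naming_dataset <- function(model, chips = NULL, n_chips = 512,
                                     responses_per_chip = 30, seed = NULL,
                                     subjects = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chips)) {
    n_axis <- max(2L, round(n_chips^(1 / 3)))
    chips <- .jittered_chip_grid(n_axis)
  }
  chips <- .as_rgb_matrix(chips)
  P <- predict(model, chips, type = "prob")
  vocab <- model$vocabulary
  nc <- nrow(chips)
  chip_stream <- sample(rep(seq_len(nc), responses_per_chip))
  name_stream <- vapply(chip_stream, function(ci)
    sample(vocab, 1, prob = P[ci, ]), character(1))
  if (!subjects) {
    # without subject structure the subject-based cleaning rules would be
    # vacuous or destructive, so the table is built uncleaned
    df <- data.frame(subject = 1L, r = chips[chip_stream, 1],
                     g = chips[chip_stream, 2], b = chips[chip_stream, 3],
                     name = name_stream)
    nt <- naming_table(df, clean = FALSE)
    return(list(responses = df, table = nt$table, report = nt$report))
  }
  # subjects see 19 distinct chips plus a repeat of their 3rd at slot 18
  per_subject <- 19L
  n_sub <- ceiling(length(chip_stream) / per_subject)
  rows <- list()
  pos <- 1L
  for (s in seq_len(n_sub)) {
    take <- min(per_subject, length(chip_stream) - pos + 1L)
    if (take <= 0) break
    ci <- chip_stream[pos:(pos + take - 1L)]
    nm <- name_stream[pos:(pos + take - 1L)]
    pres <- seq_len(take)
    pres[pres >= 18L] <- pres[pres >= 18L] + 1L   # leave slot 18 free
    if (take >= 3L) {
      rep_chip <- ci[3]
      rep_name <- sample(vocab, 1, prob = P[rep_chip, ])
      ci <- c(ci, rep_chip); nm <- c(nm, rep_name); pres <- c(pres, 18L)
    }
    rows[[s]] <- data.frame(subject = s, chip = ci, name = nm,
                            presentation_index = pres)
    pos <- pos + take
  }
  df <- do.call(rbind, rows)
  df <- data.frame(subject = df$subject,
                   r = chips[df$chip, 1], g = chips[df$chip, 2],
                   b = chips[df$chip, 3], name = df$name,
                   presentation_index = df$presentation_index)
  nt <- naming_table(df)
  list(responses = df, table = nt$table, report = nt$report)
}
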