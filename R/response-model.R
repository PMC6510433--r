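# The naming response model: per-name unimodal response-rate functions
#   Q_n(z) = gamma * g_n + (1 - gamma) * k_n * exp(-1/2 * m(z)^alpha_n)
# with m the squared Mahalanobis distance of z (CIELAB) from the peak mu_n
# under covariance Sigma_n. Each name is fitted independently by penalized
# maximum likelihood; the fitted rates are normalized across the vocabulary
# to give a distribution of names at any colour.

SIGMA_EIGEN_FLOOR <- 3.0^2   # CIELAB^2 floor on Sigma eigenvalues
ALPHA_RANGE <- c(1.0, 3.0)   # sharpness box

#' Per-name response parameters
#'
#' @param k peak response rate in (0, 1].
#' @param mu CIELAB triple: location of the peak.
#' @param Sigma 3 x 3 SPD covariance (CIELAB^2 units); eigenvalues must be
#'   at least \code{3^2}.
#' @param alpha sharpness in \eqn{[1, 3]}: 1 is a Gaussian falloff, larger
#'   values plateau near the peak then fall faster.
#' @param g global response rate of the name (feeds the lapse term).
#' @return list of class \code{"name_params"}.
#' @export
name_params <- function(k, mu, Sigma, alpha = 1, g = 0) {
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < SIGMA_EIGEN_FLOOR - 1e-6))
    stop("Sigma eigenvalues must be >= ", SIGMA_EIGEN_FLOOR)
  if (k <= 0 || k > 1) stop("k must be in (0, 1]")
  if (alpha < ALPHA_RANGE[1] - 1e-9 || alpha > ALPHA_RANGE[2] + 1e-9)
    stop("alpha must be in [", ALPHA_RANGE[1], ", ", ALPHA_RANGE[2], "]")
  structure(list(k = k, mu = as.numeric(mu), Sigma = Sigma,
                 alpha = alpha, g = g), class = "name_params")
}

#' Response rate of one name at colour locations
#'
#' Evaluates \eqn{Q(z) = \gamma g + (1-\gamma) k
#' \exp(-\frac12 m(z)^{\alpha})} with \eqn{m} the squared Mahalanobis
#' distance of the CIELAB coordinates of \code{z} from the peak.
#'
#' @param params a [name_params()].
#' @param gamma lapse rate in \eqn{[0, 1)}.
#' @param lab n x 3 matrix (or length-3 vector) of CIELAB coordinates.
#' @return vector of rates, strictly positive when \code{gamma * g > 0}.
#' @export
q_rate <- function(params, gamma, lab) {
  lab <- .as_lab_matrix(lab)
  d <- sweep(lab, 2, params$mu)
  Si <- tryCatch(solve(params$Sigma),
                 error = function(e) stop("singular Sigma"))
  m <- rowSums((d %*% Si) * d)
  m <- pmax(m, 0)
  params$g * gamma + (1 - gamma) * params$k * exp(-0.5 * m^params$alpha)
}

#' Binomial log-likelihood of one name's responses
#'
#' \eqn{L_n = \sum_c [\ln\binom{r+s}{r} + r \ln Q + s \ln(1-Q)]} over chips,
#' where \eqn{r} counts responses with the name and \eqn{s} the others.
#'
#' @param table a \code{"naming_table"}.
#' @param name a vocabulary entry.
#' @param params a [name_params()].
#' @param gamma lapse rate.
#' @return log-likelihood (natural log), including the combinatoric term.
#' @export
name_log_likelihood <- function(table, name, params, gamma = 0.01) {
  if (!name %in% table$vocabulary) stop("unknown name: ", name)
  r <- table$counts[, name]
  s <- rowSums(table$counts) - r
  Q <- q_rate(params, gamma, table$lab)
  if (any(Q <= 0) || any(Q >= 1))
    stop("response rate hit 0 or 1; log-likelihood undefined")
  sum(lchoose(r + s, r) + r * log(Q) + s * log1p(-Q))
}

# ---- optimizer parameterization -------------------------------------------
# theta = (logit k, mu (3), log-diag L (3), off-diag L (3), logit-box alpha)
# Sigma = L L' + floor * I guarantees the eigenvalue floor smoothly.

.theta_to_params <- function(theta, g) {
  k <- stats::plogis(theta[1])
  mu <- theta[2:4]
  L <- matrix(0, 3, 3)
  diag(L) <- exp(pmin(theta[5:7], 12))
  L[2, 1] <- theta[8]; L[3, 1] <- theta[9]; L[3, 2] <- theta[10]
  Sigma <- L %*% t(L) + SIGMA_EIGEN_FLOOR * diag(3)
  alpha <- ALPHA_RANGE[1] + diff(ALPHA_RANGE) * stats::plogis(theta[11])
  list(k = k, mu = mu, Sigma = Sigma, alpha = alpha, g = g)
}

.params_to_theta <- function(k, mu, Sigma, alpha) {
  k <- min(max(k, 1e-4), 1 - 1e-4)
  S0 <- Sigma - SIGMA_EIGEN_FLOOR * diag(3)
  e <- eigen((S0 + t(S0)) / 2, symmetric = TRUE)
  S0 <- e$vectors %*% (pmax(e$values, 1e-2) * t(e$vectors))
  L <- t(chol(S0))
  a <- (alpha - ALPHA_RANGE[1]) / diff(ALPHA_RANGE)
  a <- min(max(a, 1e-3), 1 - 1e-3)
  c(stats::qlogis(k), mu, log(diag(L)), L[2, 1], L[3, 1], L[3, 2],
    stats::qlogis(a))
}

.penalized_objective <- function(table, name, gamma, lambda) {
  r <- table$counts[, name]
  s <- rowSums(table$counts) - r
  lab <- table$lab
  bsum <- sum(lchoose(r + s, r))
  g <- sum(r) / sum(table$counts)
  function(theta) {
    p <- .theta_to_params(theta, g)
    d <- sweep(lab, 2, p$mu)
    Si <- tryCatch(solve(p$Sigma), error = function(e) NULL)
    if (is.null(Si)) return(-1e12)
    m <- pmax(rowSums((d %*% Si) * d), 0)
    Q <- p$g * gamma + (1 - gamma) * p$k * exp(-0.5 * m^p$alpha)
    Q <- pmin(pmax(Q, 1e-300), 1 - 1e-12)
    ll <- bsum + sum(r * log(Q) + s * log1p(-Q))
    pen <- lambda * (p$k * det(p$Sigma))^0.12
    val <- ll - pen
    if (!is.finite(val)) -1e12 else val
  }
}

.init_theta <- function(table, name, restart = 1L) {
  r <- table$counts[, name]
  lab <- table$lab
  w <- r / sum(r)
  mu0 <- colSums(lab * w)
  d <- sweep(lab, 2, mu0)
  S0 <- crossprod(d * sqrt(w)) + SIGMA_EIGEN_FLOOR * diag(3)
  if (sum(r > 0) < 4) S0 <- S0 + 25 * diag(3)
  R <- rowSums(table$counts)
  k0 <- min(max(max(r / pmax(R, 1)), 0.05), 0.9)
  theta <- .params_to_theta(k0, mu0, S0, 1.05)
  if (restart == 2L) {
    # second start: peak at the chip with the highest observed rate
    theta[2:4] <- lab[which.max(r / pmax(R, 1)), ]
  } else if (restart > 2L) {
    theta <- theta + stats::rnorm(length(theta), 0, 0.3)
    theta[2:4] <- theta[2:4] + stats::rnorm(3, 0, 12)
  }
  theta
}

#' Fit one name's response function by penalized maximum likelihood
#'
#' Maximizes \eqn{L_n - \lambda (k |\Sigma|)^{0.12}} by conjugate-gradient
#' ascent with multiple restarts. The penalty encodes the empirical rate law
#' of global naming rates and shrinks the support and peak of weakly
#' constrained names.
#'
#' @param table a \code{"naming_table"}.
#' @param name vocabulary entry to fit (needs at least 2 responses).
#' @param lambda penalty weight (default 100).
#' @param gamma lapse rate (default 0.01).
#' @param restarts number of jittered restarts (default 5).
#' @param seed RNG seed for the restart jitter (deterministic fit if set).
#' @param maxit conjugate-gradient iteration cap per restart.
#' @return a [name_params()] with attributes \code{objective} (the best
#'   penalized log-likelihood), \code{log_likelihood} and \code{convergence}.
#' @export
fit_name <- function(table, name, lambda = 100, gamma = 0.01,
                     restarts = 5, seed = NULL, maxit = 200) {
  if (!name %in% table$vocabulary) stop("unknown name: ", name)
  if (sum(table$counts[, name]) < 2)
    stop("name '", name, "' has fewer than 2 responses")
  if (!is.null(seed)) set.seed(seed)
  obj <- .penalized_objective(table, name, gamma, lambda)
  best <- NULL; best_val <- -Inf; conv <- 1L
  for (i in seq_len(max(1L, restarts))) {
    theta0 <- .init_theta(table, name, restart = i)
    fit <- tryCatch(
      stats::optim(theta0, obj, method = "CG",
                   control = list(fnscale = -1, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$value > best_val) {
      best_val <- fit$value; best <- fit$par; conv <- fit$convergence
    }
  }
  if (is.null(best)) stop("optimizer failed for name '", name, "'")
  if (conv > 1)
    warning("optimizer reported an error for '", name,
            "'; returning best parameters found")
  g <- sum(table$counts[, name]) / sum(table$counts)
  p <- .theta_to_params(best, g)
  out <- name_params(p$k, p$mu, p$Sigma, p$alpha, p$g)
  attr(out, "objective") <- best_val
  attr(out, "log_likelihood") <- name_log_likelihood(table, name, out, gamma)
  attr(out, "convergence") <- conv
  out
}

#' Fit the full colour-naming model
#'
#' Fits every name's response-rate function independently (see [fit_name()])
#' and assembles them into a queryable model of the distribution of naming
#' responses at any colour of the sRGB cube.
#'
#' @param table a \code{"naming_table"} (see [naming_table()]).
#' @param lambda penalty weight (default 100).
#' @param gamma lapse rate (default 0.01).
#' @param restarts restarts per name (default 5).
#' @param seed RNG seed; per-name fits derive their own sub-seeds so results
#'   do not depend on fitting order.
#' @param names subset of the vocabulary to fit (default: all).
#' @param maxit optimizer iteration cap per restart.
#' @param verbose print a line per fitted name.
#' @return object of class \code{"naming_model"}: per-name parameters, lapse
#'   rate, global rates and fit diagnostics. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{logLik},
#'   \code{simulate}, \code{plot}.
#' @export
#' @examples
#' gen <- synthetic_naming_model(n_names = 3, seed = 1)
#' tab <- synthetic_naming_dataset(gen, n_chips = 4^3,
#'                                 responses_per_chip = 20, seed = 2)
#' fit <- fit_naming_model(tab$table, restarts = 2, maxit = 80, seed = 3)
#' fit
fit_naming_model <- function(table, lambda = 100, gamma = 0.01,
                             restarts = 5, seed = 1, names = NULL,
                             maxit = 200, verbose = FALSE) {
  stopifnot(inherits(table, "naming_table"))
  vocab <- if (is.null(names)) table$vocabulary else {
    if (!all(names %in% table$vocabulary)) stop("unknown names requested")
    names
  }
  g_all <- colSums(table$counts) / sum(table$counts)
  params <- vector("list", length(vocab)); names(params) <- vocab
  diag_rows <- vector("list", length(vocab))
  for (i in seq_along(vocab)) {
    nm <- vocab[i]
    # independent, order-invariant sub-seed per name
    sub_seed <- if (is.null(seed)) NULL else
      (seed + sum(utf8ToInt(nm)) * 131L) %% .Machine$integer.max
    p <- fit_name(table, nm, lambda = lambda, gamma = gamma,
                  restarts = restarts, seed = sub_seed, maxit = maxit)
    params[[i]] <- p
    diag_rows[[i]] <- data.frame(
      name = nm, n_responses = sum(table$counts[, nm]),
      objective = attr(p, "objective"),
      log_likelihood = attr(p, "log_likelihood"),
      convergence = attr(p, "convergence"))
    if (verbose)
      message(sprintf("fitted '%s' (%d responses)", nm,
                      sum(table$counts[, nm])))
  }
  structure(list(
    params = params,
    gamma = gamma, lambda = lambda,
    vocabulary = vocab,
    g = g_all[vocab] / sum(g_all[vocab]),
    chips = table$chips,
    diagnostics = do.call(rbind, diag_rows),
    call = match.call()), class = "naming_model")
}

#' Assemble a naming model from known parameters
#'
#' Builds a \code{"naming_model"} directly from per-name parameters, without
#' fitting; used by the synthetic-data generators and anywhere a model with
#' known ground truth is needed.
#'
#' @param params named list of [name_params()].
#' @param gamma lapse rate.
#' @return a \code{"naming_model"}.
#' @export
naming_model <- function(params, gamma = 0.01) {
  stopifnot(length(params) >= 1, !is.null(names(params)))
  g <- vapply(params, function(p) p$g, numeric(1))
  if (any(g < 0)) stop("global rates must be nonnegative")
  if (sum(g) <= 0) g[] <- 1 / length(g)
  g <- g / sum(g)
  for (i in seq_along(params)) params[[i]]$g <- g[i]
  structure(list(params = params, gamma = gamma, lambda = NA_real_,
                 vocabulary = names(params), g = g,
                 chips = NULL, diagnostics = NULL, call = match.call()),
            class = "naming_model")
}

#' @export
print.naming_model <- function(x, ...) {
  cat(sprintf("<naming_model: %d names, gamma = %g%s>\n",
              length(x$vocabulary), x$gamma,
              if (is.na(x$lambda)) "" else sprintf(", lambda = %g", x$lambda)))
  invisible(x)
}

#' @export
summary.naming_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$vocabulary, function(nm) {
    p <- object$params[[nm]]
    data.frame(name = nm, k = p$k, mu_L = p$mu[1], mu_a = p$mu[2],
               mu_b = p$mu[3], alpha = p$alpha,
               spread = det(p$Sigma)^(1 / 6), g = p$g)
  }))
  structure(list(table = tab, gamma = object$gamma,
                 lambda = object$lambda,
                 diagnostics = object$diagnostics),
            class = "summary.naming_model")
}

#' @export
print.summary.naming_model <- function(x, ...) {
  cat(sprintf("Colour-naming response model (gamma = %g%s)\n", x$gamma,
              if (is.na(x$lambda)) "" else sprintf(", lambda = %g", x$lambda)))
  cat("Per-name parameters (spread = |Sigma|^(1/6), CIELAB units):\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.naming_model <- function(object, ...) {
  do.call(rbind, lapply(object$vocabulary, function(nm) {
    p <- object$params[[nm]]
    s <- .comps_from_sym(p$Sigma)
    out <- c(p$k, p$mu, p$alpha, s, p$g)
    names(out) <- c("k", "mu_L", "mu_a", "mu_b", "alpha",
                    "s_LL", "s_La", "s_Lb", "s_aa", "s_ab", "s_bb", "g")
    out
  })) -> m
  rownames(m) <- object$vocabulary
  m
}

#' Predict naming rates or distributions at colours
#'
#' @param object a \code{"naming_model"}.
#' @param newdata sRGB coordinates: n x 3 matrix, data frame with r,g,b, or
#'   a length-3 vector.
#' @param type \code{"prob"} for the normalized distribution of names
#'   (rows sum to 1), \code{"rate"} for the raw per-name rates Q.
#' @param space \code{"rgb"} (default) or \code{"lab"} if \code{newdata} is
#'   already CIELAB.
#' @param ... unused.
#' @return n x (number of names) matrix.
#' @export
predict.naming_model <- function(object, newdata,
                                 type = c("prob", "rate"),
                                 space = c("rgb", "lab"), ...) {
  type <- match.arg(type); space <- match.arg(space)
  lab <- if (space == "rgb") .as_lab_matrix(srgb_to_lab(newdata))
         else .as_lab_matrix(newdata)
  Q <- vapply(object$vocabulary,
              function(nm) q_rate(object$params[[nm]], object$gamma, lab),
              numeric(nrow(lab)))
  if (nrow(lab) == 1) Q <- matrix(Q, nrow = 1,
                                  dimnames = list(NULL, object$vocabulary))
  if (type == "rate") return(Q)
  Q / rowSums(Q)
}

#' Normalized naming distribution at a colour
#'
#' \eqn{P_n(z) = Q_n(z) / \sum_s Q_s(z)}; sums to 1 with every entry
#' positive thanks to the lapse floor.
#'
#' @param model a \code{"naming_model"}.
#' @param rgb sRGB coordinates (vector or matrix).
#' @return matrix of probabilities, one row per colour.
#' @export
normalize_model <- function(model, rgb) {
  predict(model, rgb, type = "prob")
}

#' @export
logLik.naming_model <- function(object, ...) {
  ll <- if (is.null(object$diagnostics)) NA_real_
        else sum(object$diagnostics$log_likelihood)
  structure(ll, df = 12 * length(object$vocabulary), class = "logLik")
}

#' @export
plot.naming_model <- function(x, path = standard_paths()$achromatic_axis,
                              density = 100, ...) {
  pts <- sample_path(path, density)
  P <- predict(x, pts, type = "prob")
  t <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  cum <- t(apply(P, 1, cumsum))
  graphics::plot(range(t), c(0, 1), type = "n",
                 xlab = "position along path (sRGB length)",
                 ylab = "cumulative naming proportion", ...)
  cols <- grDevices::hcl.colors(ncol(P), "Spectral")
  prev <- rep(0, length(t))
  for (j in seq_len(ncol(P))) {
    graphics::polygon(c(t, rev(t)), c(cum[, j], rev(prev)),
                      col = cols[j], border = NA)
    prev <- cum[, j]
  }
  invisible(x)
}

#' @export
simulate.naming_model <- function(object, nsim = 1, seed = NULL, ...,
                                  n_chips = 8^3, responses_per_chip = 30) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    synthetic_naming_dataset(object, n_chips = n_chips,
                             responses_per_chip = responses_per_chip))
  if (nsim == 1) out[[1]] else out
}

#' Compare baseline, fitted and saturated naming models
#'
#' Multinomial log-likelihoods of the response table under the baseline
#' model (global rates at every chip), the fitted model, and the saturated
#' model (empirical per-chip frequencies), with parameter counts
#' \eqn{N-1}, \eqn{12N} and \eqn{N_{chips}(N-1)}. Deviances (twice the
#' log-likelihood difference) are compared with the parameter-count
#' difference to give an AIC-style verdict.
#'
#' @param table a \code{"naming_table"}.
#' @param model a fitted \code{"naming_model"} over the same vocabulary.
#' @return object of class \code{"naming_model_comparison"}.
#' @export
model_comparison <- function(table, model) {
  if (!setequal(model$vocabulary, table$vocabulary))
    stop("model and table vocabularies differ")
  vocab <- table$vocabulary
  counts <- table$counts[, vocab, drop = FALSE]
  R <- rowSums(counts)
  lcoef <- sum(lgamma(R + 1)) - sum(lgamma(counts + 1))
  g <- colSums(counts) / sum(counts)
  ll_base <- lcoef + sum(sweep(counts, 2, log(g), "*"))
  P <- predict(model, as.matrix(table$chips[, c("r", "g", "b")]),
               type = "prob")[, vocab, drop = FALSE]
  ll_fit <- lcoef + sum(counts * log(P))
  F <- counts / R
  ll_sat <- lcoef + sum(counts[counts > 0] * log(F[counts > 0]))
  N <- length(vocab); Nc <- nrow(counts)
  pars <- c(baseline = N - 1, fitted = 12 * N, saturated = Nc * (N - 1))
  ll <- c(baseline = ll_base, fitted = ll_fit, saturated = ll_sat)
  dev_fb <- 2 * (ll["fitted"] - ll["baseline"])
  dev_sf <- 2 * (ll["saturated"] - ll["fitted"])
  verdicts <- c(
    fitted_vs_baseline = if (dev_fb > pars["fitted"] - pars["baseline"])
      "fitted preferred" else "baseline preferred",
    saturated_vs_fitted = if (dev_sf > pars["saturated"] - pars["fitted"])
      "saturated preferred" else "fitted preferred")
  structure(list(
    log_likelihood = ll, n_parameters = pars,
    deviance_fitted_baseline = unname(dev_fb),
    deviance_saturated_fitted = unname(dev_sf),
    verdicts = verdicts), class = "naming_model_comparison")
}

#' @export
print.naming_model_comparison <- function(x, ...) {
  df <- data.frame(model = names(x$log_likelihood),
                   log_likelihood = x$log_likelihood,
                   n_parameters = x$n_parameters)
  print(df, row.names = FALSE)
  cat(sprintf("fitted vs baseline:   deviance %.1f vs %d extra parameters -> %s\n",
              x$deviance_fitted_baseline,
              x$n_parameters["fitted"] - x$n_parameters["baseline"],
              x$verdicts["fitted_vs_baseline"]))
  cat(sprintf("saturated vs fitted:  deviance %.1f vs %d extra parameters -> %s\n",
              x$deviance_saturated_fitted,
              x$n_parameters["saturated"] - x$n_parameters["fitted"],
              x$verdicts["saturated_vs_fitted"]))
  invisible(x)
}

#' Sampling bias of the Bhattacharyya angle
#'
#' Demonstrates the severe sampling bias of the Bhattacharyya angle between
#' empirical distributions: pairs of small samples are drawn from one and
#' the same rank-power-law multinomial, so the population angle is exactly
#' zero, yet the empirical angles are far from it.
#'
#' @param n_samples responses per empirical distribution (default 31, a
#'   typical per-chip response count).
#' @param exponent rank decay exponent of the multinomial (default 1.4).
#' @param support number of ranks (default 804, a typical vocabulary size).
#' @param reps Monte Carlo replicate pairs (default 1e4).
#' @param seed RNG seed.
#' @return list: \code{mean_angle}, \code{sd_angle} (radians),
#'   \code{median_distinct} names per sample set, \code{mean_entropy} and
#'   \code{median_entropy} (bits) of the empirical sets, and the leading
#'   multinomial probabilities.
#' @export
bhattacharyya_bias_demo <- function(n_samples = 31, exponent = 1.4,
                                    support = 804, reps = 1e4,
                                    seed = NULL) {
  if (support < n_samples) stop("support must be >= n_samples")
  if (!is.null(seed)) set.seed(seed)
  p <- rank_power_multinomial(exponent = exponent, support = support)
  angles <- numeric(reps); distinct <- integer(reps); ent <- numeric(reps)
  for (i in seq_len(reps)) {
    a <- tabulate(sample.int(support, n_samples, TRUE, p), support)
    b <- tabulate(sample.int(support, n_samples, TRUE, p), support)
    angles[i] <- bhattacharyya_angle(a / n_samples, b / n_samples)
    distinct[i] <- sum(a > 0)
    ent[i] <- .entropy_bits(a / n_samples)
  }
  list(mean_angle = mean(angles), sd_angle = stats::sd(angles),
       median_distinct = stats::median(distinct),
       mean_entropy = mean(ent), median_entropy = stats::median(ent),
       leading_probabilities = utils::head(p, 4))
}
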