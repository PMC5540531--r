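#' Parameter distributions for probabilistic sensitivity analysis
#'
#' Constructors return lightweight `param_distribution` objects sampled
#' with [draw()]. Families: lognormal fitted to a point estimate and 95%
#' CI (effect sizes, relative risks), PERT (costs and effects quoted as
#' mode +/- spread), beta shifted to `[-1, 1]` (signed initiation/cessation
#' parameters), Dirichlet (prevalence triples) and a degenerate point mass.
#'
#' @name param_distribution
NULL

new_dist <- function(family, ...) {
  structure(list(family = family, ...),
            class = c(paste0("dist_", family), "param_distribution"))
}

#' @describeIn param_distribution Lognormal from a point estimate and 95% CI:
#'   `mu = log(point)`, `sigma = (log(hci) - log(lci)) / (2 * 1.96)`; the
#'   sampling median equals the point estimate. Degenerate when
#'   `lci == hci == point`.
#' @param point,lci,hci Positive point estimate and CI bounds with
#'   `lci <= point <= hci`.
#' @export
lognormal_from_ci <- function(point, lci, hci) {
  if (any(c(point, lci, hci) <= 0)) {
    stop("lognormal bounds must be positive", call. = FALSE)
  }
  if (lci > point || point > hci) {
    stop("require lci <= point <= hci", call. = FALSE)
  }
  new_dist("lognormal", mu = log(point),
           sigma = (log(hci) - log(lci)) / (2 * stats::qnorm(0.975)))
}

#' @describeIn param_distribution Standard PERT (beta with `lambda = 4`)
#'   on `[mode - |mode| * spread, mode + |mode| * spread]`; mean
#'   `(min + 4 mode + max) / 6`. `spread = 0` gives a point mass.
#' @param mode Most likely value.
#' @param spread_fraction Half-width as a fraction of `|mode|` (>= 0).
#' @export
pert_dist <- function(mode, spread_fraction) {
  stopifnot(spread_fraction >= 0)
  half <- abs(mode) * spread_fraction
  new_dist("pert", mode = mode, min = mode - half, max = mode + half)
}

#' @describeIn param_distribution Beta on `[0, 1]` affinely mapped to
#'   `[-1, 1]` with the first two moments matched to `(mean, sd)`; allows
#'   negative values (initiation) under a cessation-style beta. Errors if
#'   the moments are infeasible for a beta on that support.
#' @param mean Target mean in `(-1, 1)`.
#' @param sd Target standard deviation (> 0 for a proper distribution).
#' @export
shifted_beta <- function(mean, sd) {
  stopifnot(mean > -1, mean < 1, sd >= 0)
  if (sd == 0) return(new_dist("point", value = mean))
  mu <- (mean + 1) / 2
  v <- (sd / 2)^2
  if (v >= mu * (1 - mu)) {
    stop("infeasible (mean, sd): need sd^2/4 < mu*(1-mu) = ",
         signif(mu * (1 - mu), 4), call. = FALSE)
  }
  nu <- mu * (1 - mu) / v - 1
  new_dist("shifted_beta", alpha = mu * nu, beta = (1 - mu) * nu,
           mean = mean, sd = sd)
}

#' @describeIn param_distribution Dirichlet over a never/current/former
#'   prevalence triple with concentrations `proportions * effective_n`;
#'   zero categories are floored at 1e-6 (with a warning).
#' @param proportions Numeric simplex vector (e.g. never/current/former).
#' @param effective_n Effective sample size (> 0).
#' @export
dirichlet_from_prevalence <- function(proportions, effective_n) {
  stopifnot(effective_n > 0)
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (any(proportions < 1e-6)) {
    warning("zero prevalence category floored at 1e-6", call. = FALSE)
    proportions <- pmax(proportions, 1e-6)
    proportions <- proportions / sum(proportions)
  }
  new_dist("dirichlet", alpha = proportions * effective_n)
}

#' @describeIn param_distribution Degenerate point mass.
#' @param value The single support point.
#' @export
point_dist <- function(value) new_dist("point", value = value)

#' Sample from a parameter distribution
#'
#' @param dist A `param_distribution` object.
#' @param n Number of draws.
#' @param ... Unused.
#' @return For scalar families a numeric vector of length `n`; for the
#'   Dirichlet an `n x k` matrix of simplex rows.
#' @export
draw <- function(dist, n, ...) UseMethod("draw")

#' @export
draw.dist_lognormal <- function(dist, n, ...) {
  if (dist$sigma == 0) return(rep(exp(dist$mu), n))
  stats::rlnorm(n, dist$mu, dist$sigma)
}

#' @export
draw.dist_pert <- function(dist, n, ...) {
  rng <- dist$max - dist$min
  if (rng == 0) return(rep(dist$mode, n))
  a <- 1 + 4 * (dist$mode - dist$min) / rng
  b <- 1 + 4 * (dist$max - dist$mode) / rng
  dist$min + rng * stats::rbeta(n, a, b)
}

#' @export
draw.dist_shifted_beta <- function(dist, n, ...) {
  2 * stats::rbeta(n, dist$alpha, dist$beta) - 1
}

#' @export
draw.dist_dirichlet <- function(dist, n, ...) {
  k <- length(dist$alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(dist$alpha, each = n), rate = 1),
              nrow = n)
  g / rowSums(g)
}

#' @export
draw.dist_point <- function(dist, n, ...) rep(dist$value, n)

# internal: small stable hash so each parameter gets its own substream seed
param_seed <- function(root_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(root_seed) + 7919L * (h %% 100000L)) %% .Machine$integer.max
}

#' Pre-draw independent substreams for a named set of distributions
#'
#' Each parameter's draws come from its own deterministic substream
#' derived from the root seed and the parameter name, so adding or
#' removing a parameter does not perturb the draws of the others.
#'
#' @param dists Named list of `param_distribution` objects.
#' @param n_iter Number of iterations.
#' @param seed Root seed.
#' @return Named list of draw vectors/matrices, each of length/rows
#'   `n_iter`.
#' @export
draw_substreams <- function(dists, n_iter, seed) {
  out <- list()
  for (nm in names(dists)) {
    set.seed(param_seed(seed, nm))
    out[[nm]] <- draw(dists[[nm]], n_iter)
  }
  out
}
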