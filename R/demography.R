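#' Age-sex strata and grouping schemes
#'
#' Strata are closed-open intervals `[age_low, age_high)`; the open-ended
#' tail band has `age_high = Inf`. Two grouping schemes are used throughout:
#' the survey scheme (15-24, 25-34, ..., 65-74, 75+) on which smoking
#' prevalence is observed and initiation/cessation rates are calibrated, and
#' the Markov scheme (15-19, 20-24, ..., 80+; 14 bands) on which the CVD
#' cohort model runs.
#'
#' @param breaks Increasing vector of band lower bounds; the last band is
#'   open-ended unless `breaks` ends in `Inf`.
#' @param sexes Character vector of sexes to cross with the age bands.
#' @return A data frame with columns `sex`, `age_low`, `age_high`, one row
#'   per stratum, ordered by sex then age.
#' @export
age_scheme <- function(breaks, sexes = c("male", "female")) {
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  if (!is.infinite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  out <- expand.grid(age_low = lo, sex = sexes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$age_high <- rep(hi, times = length(sexes))
  out <- out[order(match(out$sex, sexes), out$age_low), c("sex", "age_low", "age_high")]
  rownames(out) <- NULL
  out
}

#' @rdname age_scheme
#' @export
survey_scheme <- function(sexes = c("male", "female")) {
  age_scheme(c(15, 25, 35, 45, 55, 65, 75), sexes)
}

#' @rdname age_scheme
#' @export
markov_scheme <- function(sexes = c("male", "female")) {
  age_scheme(seq(15, 80, by = 5), sexes)
}

# internal: stable key for joining stratified frames
stratum_key <- function(df) paste(df$sex, df$age_low, sep = ":")

# internal: index of the band containing each age, per sex-invariant scheme
band_index <- function(age, age_low, age_high) {
  idx <- findInterval(age, age_low)
  idx[age < age_low[1]] <- NA_integer_
  idx
}

#' Convert an annual rate to a one-cycle transition probability
#'
#' Uses the constant-hazard relation `P = 1 - exp(-rate)` for a one-year
#' cycle. The inverse is [prob_to_rate()].
#'
#' @param rate Nonnegative annual rate(s), per person-year.
#' @return Probability in `[0, 1)`.
#' @examples
#' rate_to_prob(0.01)       # 0.00995
#' rate_to_prob(log(2))     # 0.5
#' @export
rate_to_prob <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rate must be finite and nonnegative", call. = FALSE)
  }
  -expm1(-rate)
}

#' @rdname rate_to_prob
#' @param prob Probability in `[0, 1)`.
#' @export
prob_to_rate <- function(prob) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob >= 1)) {
    stop("prob must be in [0, 1)", call. = FALSE)
  }
  -log1p(-prob)
}

#' Linear interpolation/extrapolation of a sparse annual series
#'
#' Piecewise-linear between observations, linear extrapolation beyond the
#' observed range using the slope of the nearest segment, exact at
#' observation years. Values flagged as proportions are clamped to `[0, 1]`
#' (with a warning when clamping occurs).
#'
#' @param years Numeric vector of observation years (distinct, >= 2).
#' @param values Observed values, same length as `years`.
#' @param target_years Years at which to evaluate.
#' @param proportion If `TRUE`, clamp results into `[0, 1]`.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_series <- function(years, values, target_years, proportion = FALSE) {
  if (length(years) < 2 || anyDuplicated(years)) {
    stop("need at least two observations with distinct years", call. = FALSE)
  }
  ord <- order(years)
  years <- years[ord]; values <- values[ord]
  out <- stats::approx(years, values, xout = target_years, rule = 2)$y
  n <- length(years)
  lo <- target_years < years[1]
  hi <- target_years > years[n]
  if (any(lo)) {
    s <- (values[2] - values[1]) / (years[2] - years[1])
    out[lo] <- values[1] + s * (target_years[lo] - years[1])
  }
  if (any(hi)) {
    s <- (values[n] - values[n - 1]) / (years[n] - years[n - 1])
    out[hi] <- values[n] + s * (target_years[hi] - years[n])
  }
  if (proportion) {
    clamped <- out < 0 | out > 1
    if (any(clamped)) {
      warning(sum(clamped), " extrapolated proportion(s) clamped to [0, 1]",
              call. = FALSE)
      out <- pmin(pmax(out, 0), 1)
    }
  }
  out
}

#' Cohort-component population projection
#'
#' Advances a population pyramid in annual cycles: each stratum is depleted
#' by `rate_to_prob(mortality)`, a fraction `1 / band_width` of survivors
#' ages into the next band (stationary-within-band assumption), and new
#' entrants computed from age-specific fertility and the sex ratio at birth
#' enter the youngest band. For the open-ended tail band no one ages out.
#'
#' @param pyramid Data frame `sex, age_low, age_high, count`.
#' @param rates Demographic rates: list with `fertility` (data frame
#'   `sex, age_low, age_high, fertility` for female strata; births per
#'   woman-year) and `sex_ratio` (male births per female birth). Use
#'   `NULL` for a closed population.
#' @param lifetable Data frame `sex, age_low, age_high, mortality_rate`.
#' @param years Number of annual cycles (>= 0).
#' @return A pyramid data frame of the same shape.
#' @export
project_population <- function(pyramid, rates, lifetable, years) {
  stopifnot(years >= 0)
  if (years == 0) return(pyramid)
  key <- stratum_key(pyramid)
  m <- lifetable$mortality_rate[match(key, stratum_key(lifetable))]
  if (any(is.na(m))) stop("life table strata do not cover the pyramid", call. = FALSE)
  fert <- rep(0, nrow(pyramid))
  sex_ratio <- 1
  if (!is.null(rates)) {
    fk <- match(key, stratum_key(rates$fertility))
    fert <- ifelse(is.na(fk), 0, rates$fertility$fertility[fk])
    fert[pyramid$sex != "female"] <- 0
    sex_ratio <- rates$sex_ratio
  }
  width <- pyramid$age_high - pyramid$age_low
  out_frac <- ifelse(is.finite(width), 1 / width, 0)
  counts <- pyramid$count
  surv_p <- 1 - rate_to_prob(m)
  for (t in seq_len(years)) {
    births <- sum(fert * counts)  # fert is zero outside female strata
    survivors <- counts * surv_p
    moved <- survivors * out_frac
    new_counts <- survivors - moved
    for (s in unique(pyramid$sex)) {
      i <- which(pyramid$sex == s)
      i <- i[order(pyramid$age_low[i])]
      n <- length(i)
      new_counts[i[-1]] <- new_counts[i[-1]] + moved[i[-n]]
      entrants <- if (s == "male") births * sex_ratio / (1 + sex_ratio)
                  else births / (1 + sex_ratio)
      new_counts[i[1]] <- new_counts[i[1]] + entrants
    }
    counts <- new_counts
  }
  pyramid$count <- counts
  pyramid
}

#' Re-express stratified values on a different grouping scheme
#'
#' Values are refined to single-year ages (replication within a band), then
#' aggregated to the target bands as population-weighted means. Coarsening
#' preserves the population-weighted total mean; a refine-then-coarsen
#' round trip with the same weights is the identity.
#'
#' @param values Data frame `sex, age_low, age_high, value`.
#' @param to_scheme Target scheme data frame (`sex, age_low, age_high`).
#' @param weights Population pyramid (`sex, age_low, age_high, count`) used
#'   as aggregation weights; counts are spread uniformly over single-year
#'   ages within each of its bands (the open-ended band is truncated at 100).
#' @return Data frame on `to_scheme` with a `value` column.
#' @export
regroup <- function(values, to_scheme, weights) {
  out <- to_scheme
  out$value <- NA_real_
  for (s in unique(to_scheme$sex)) {
    vs <- values[values$sex == s, , drop = FALSE]
    ws <- weights[weights$sex == s, , drop = FALSE]
    if (nrow(ws) == 0) stop("missing weights for sex ", s, call. = FALSE)
    ages <- seq(min(vs$age_low), 99)
    vi <- band_index(ages, vs$age_low, vs$age_high)
    wi <- band_index(ages, ws$age_low, ws$age_high)
    if (any(is.na(vi)) || any(is.na(wi))) {
      stop("weights or values do not cover the target age range", call. = FALSE)
    }
    v1 <- vs$value[vi]
    w_width <- pmin(ws$age_high, 100) - ws$age_low
    w1 <- ws$count[wi] / w_width[wi]
    ts <- to_scheme[to_scheme$sex == s, , drop = FALSE]
    ti <- band_index(ages, ts$age_low, ts$age_high)
    agg_w <- tapply(w1, ti, sum)
    agg_vw <- tapply(v1 * w1, ti, sum)
    res <- as.numeric(agg_vw / agg_w)
    out$value[out$sex == s] <- res[match(seq_len(nrow(ts)), as.integer(names(agg_w)))]
  }
  out
}

#' Read/write a life table CSV
#'
#' Expected columns: `sex, age_low, age_high, mortality_rate, life_expectancy`.
#' @param path File path.
#' @return Life table data frame.
#' @export
read_lifetable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_low", "age_high", "mortality_rate", "life_expectancy")
  if (!all(need %in% names(df))) {
    stop("life table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$age_high <- as.numeric(df$age_high)
  if (any(df$mortality_rate < 0)) stop("negative mortality rate", call. = FALSE)
  df
}

#' @rdname read_lifetable
#' @param lifetable Life table data frame.
#' @export
write_lifetable <- function(lifetable, path) {
  utils::write.csv(lifetable, path, row.names = FALSE)
  invisible(path)
}

#' Read a population pyramid CSV (`sex, age_low, age_high, count`)
#' @param path File path.
#' @return Pyramid data frame.
#' @export
read_pyramid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_low", "age_high", "count")
  if (!all(need %in% names(df))) {
    stop("pyramid must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$age_high <- as.numeric(df$age_high)
  if (any(df$count < 0) || sum(df$count) <= 0) stop("invalid counts", call. = FALSE)
  df
}
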