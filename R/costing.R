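#' Equivalent annual cost of a capital item
#'
#' Annuitises a capital outlay over its useful life:
#' `amount * rate / (1 - (1 + rate)^-life)`; at `rate = 0` this is
#' straight-line depreciation `amount / life`. The default rate of 9.6%
#' reflects the average Tanzanian interest rate for 2012/13.
#'
#' @param amount Capital cost (currency units, >= 0).
#' @param useful_life Useful life in years (>= 1).
#' @param rate Annual discount rate (proportion, default 0.096).
#' @return Equivalent annual cost.
#' @examples
#' annuitize(1000, 5)        # 261.0
#' annuitize(1000, 5, 0)     # 200
#' @export
annuitize <- function(amount, useful_life, rate = 0.096) {
  stopifnot(all(amount >= 0), all(rate >= 0))
  if (any(useful_life < 1)) stop("useful_life must be >= 1", call. = FALSE)
  ifelse(rate == 0, amount / useful_life,
         amount * rate / (1 - (1 + rate)^(-useful_life)))
}

#' Classify a cost item as capital or recurrent
#'
#' Capital items costing less than the threshold (default US$62, the
#' TSh 100,000 cut-off) are treated as recurrent; items declared recurrent
#' stay recurrent regardless of amount. The boundary value itself stays
#' capital (strict less-than).
#'
#' @param kind Declared kind, `"capital"` or `"recurrent"`.
#' @param amount_usd Item cost in base-year USD.
#' @param threshold_usd Reclassification threshold (default 62).
#' @return `"capital"` or `"recurrent"` (vectorised).
#' @export
classify_capital <- function(kind, amount_usd, threshold_usd = 62) {
  stopifnot(all(kind %in% c("capital", "recurrent")))
  ifelse(kind == "capital" & amount_usd >= threshold_usd, "capital",
         "recurrent")
}

#' Convert local-currency costs to base-year USD
#'
#' Inflates/deflates to the base year with a GDP deflator series, then
#' divides by the base-year exchange rate (default Tshs 1605 per US$,
#' the 2013 mean).
#'
#' @param amount Amount in TZS.
#' @param price_year Year of the price.
#' @param deflator Data frame `year, deflator`.
#' @param base_year Target year (default 2013).
#' @param exchange_rate TZS per USD (default 1605).
#' @return Amount in base-year USD.
#' @export
convert_currency <- function(amount, price_year, deflator, base_year = 2013,
                             exchange_rate = 1605) {
  iy <- match(price_year, deflator$year)
  ib <- match(base_year, deflator$year)
  if (any(is.na(iy)) || is.na(ib)) {
    stop("deflator series missing required year(s)", call. = FALSE)
  }
  amount * (deflator$deflator[ib] / deflator$deflator[iy]) / exchange_rate
}

#' Step-down allocation of a cost ledger to interventions
#'
#' Converts items to base-year USD, reclassifies small capital items as
#' recurrent, annuitises capital items, assigns direct items fully to
#' their intervention and splits shared items across interventions by
#' their named allocation key. The grand total across interventions equals
#' the total annualised ledger cost (conservation).
#'
#' @param ledger List with `items` (data frame: `label, cost_center,
#'   amount, currency, price_year, kind, useful_life, shared,
#'   allocation_key, intervention`) and `allocation_keys` (named list of
#'   named nonnegative weight vectors over interventions, each summing
#'   to 1). `useful_life` may be `NA` for recurrent items.
#' @param interventions Character vector of intervention names.
#' @param annuitization_rate Rate for [annuitize()] (default 0.096).
#' @param threshold_usd Capital threshold for [classify_capital()].
#' @param deflator Optional deflator series for TZS items.
#' @param base_year,exchange_rate Currency conversion settings.
#' @return Data frame with one row per cost center, one column per
#'   intervention, plus a `Total` row; annual USD.
#' @export
step_down_allocate <- function(ledger, interventions,
                               annuitization_rate = 0.096,
                               threshold_usd = 62, deflator = NULL,
                               base_year = 2013, exchange_rate = 1605) {
  items <- ledger$items
  keys <- ledger$allocation_keys
  for (k in names(keys)) {
    w <- keys[[k]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("allocation key '", k, "' weights must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  centers <- c("program_development", "human_resources",
               "promotion_media_advocacy", "program_supplies",
               "rent_equipment_office", "operations")
  acc <- matrix(0, nrow = length(centers), ncol = length(interventions),
                dimnames = list(centers, interventions))
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    usd <- if (identical(it$currency, "TZS")) {
      if (is.null(deflator)) stop("TZS item but no deflator supplied", call. = FALSE)
      convert_currency(it$amount, it$price_year, deflator, base_year,
                       exchange_rate)
    } else it$amount
    kind <- classify_capital(it$kind, usd, threshold_usd)
    annual <- if (kind == "capital") {
      annuitize(usd, it$useful_life, annuitization_rate)
    } else usd
    if (!it$cost_center %in% centers) {
      stop("unknown cost center: ", it$cost_center, call. = FALSE)
    }
    if (isTRUE(it$shared)) {
      w <- keys[[it$allocation_key]]
      if (is.null(w)) stop("missing allocation key: ", it$allocation_key,
                           call. = FALSE)
      if (!all(names(w) %in% interventions)) {
        stop("allocation key '", it$allocation_key,
             "' names unknown interventions", call. = FALSE)
      }
      acc[it$cost_center, names(w)] <- acc[it$cost_center, names(w)] + annual * w
    } else {
      if (is.na(it$intervention) || !it$intervention %in% interventions) {
        stop("item '", it$label, "' is not assigned to an intervention",
             call. = FALSE)
      }
      acc[it$cost_center, it$intervention] <-
        acc[it$cost_center, it$intervention] + annual
    }
  }
  out <- as.data.frame(acc)
  out <- rbind(out, Total = colSums(acc))
  out <- cbind(cost_center = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Discounted cost of a multi-year program
#'
#' The costing exercise assumes a five-year program: investment plus
#' first-year promotion, retraining in year three, and ongoing management
#' throughout. Given the annualised program cost, this discounts the
#' per-year stream (payments at the start of each year) at the stated
#' rate. With `annualized = TRUE` (default) the mean discounted annual
#' cost is returned, which is on the same scale as the undiscounted
#' annual figure; with `annualized = FALSE` the present value of the
#' whole stream.
#'
#' @param annual_cost Annualised program cost (USD/year).
#' @param horizon Program span in years (default 5).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param annualized Return the mean discounted annual cost (default)
#'   rather than the stream's present value.
#' @return Discounted cost in USD.
#' @export
discounted_program_cost <- function(annual_cost, horizon = 5,
                                    discount_rate = 0.03,
                                    annualized = TRUE) {
  stopifnot(horizon >= 1, discount_rate >= 0)
  t <- 0:(horizon - 1)
  pv <- annual_cost * sum((1 + discount_rate)^(-t))
  if (annualized) pv / horizon else pv
}
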