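# Shared test fixtures, built in code.

# One synthetic truth bundle reused across tests (cheap to build).
truth_fixture <- function(seed = 1) make_truth(seed = seed)

# Starting smoker counts on the survey scheme from a truth bundle.
initial_counts <- function(truth) {
  key <- paste(truth$initial_prev$sex, truth$initial_prev$age_low)
  pkey <- paste(truth$pyramid_survey$sex, truth$pyramid_survey$age_low)
  cnt <- truth$pyramid_survey$count[match(key, pkey)]
  ini <- truth$initial_prev
  ini$never <- ini$never * cnt
  ini$current <- ini$current * cnt
  ini$former <- ini$former * cnt
  ini
}

# A small two-band, single-sex model for fast calibration experiments.
tiny_truth <- function(seed = 1) {
  set.seed(seed)
  sch <- age_scheme(c(40, 60), sexes = "male")
  lt <- make_lifetable(sch)
  rrs <- make_mortality_rrs(sch)
  flows <- data.frame(sch, signed_parameter = c(-0.02, 0.04))
  prev0 <- data.frame(sch, never = c(0.7, 0.6), current = c(0.2, 0.25),
                      former = c(0.1, 0.15))
  list(scheme = sch, lifetable = lt, rrs = rrs, flows = flows,
       initial_prev = prev0)
}

# Simulate a noisy survey panel for the tiny model.
tiny_panel <- function(tt, n = 800, seed = 1, noiseless = FALSE,
                       years = c(0, 10)) {
  ini <- tt$initial_prev
  ini[c("never", "current", "former")] <-
    1000 * ini[c("never", "current", "former")]
  sim <- simulate_prevalence(ini, tt$flows, tt$lifetable, tt$rrs, NULL,
                             years = max(years))
  set.seed(seed)
  panels <- lapply(years, function(y) {
    sl <- sim[sim$year == y, ]
    p <- as.matrix(sl[, c("never", "current", "former")])
    if (!noiseless) {
      for (i in seq_len(nrow(p))) p[i, ] <- rmultinom(1, n, p[i, ]) / n
    }
    data.frame(sex = sl$sex, age_low = sl$age_low, age_high = sl$age_high,
               year = 2000 + y, never = p[, 1], current = p[, 2],
               former = p[, 3], n_eff = n)
  })
  do.call(rbind, panels)
}

# Independent straight-loop reference simulator for the smoking model
# (explicit scalar loops; mirrors the documented update order).
reference_simulate <- function(initial, flows, lifetable, rrs, years,
                               entrants = 0) {
  ini <- initial[order(initial$age_low), ]
  nb <- nrow(ini)
  state <- as.matrix(ini[, c("never", "current", "former")])
  out <- list(state)
  for (t in seq_len(years)) {
    nxt <- matrix(0, nb, 3)
    for (b in seq_len(nb)) {
      tot <- sum(state[b, ])
      pc <- if (tot > 0) state[b, 2] / tot else 0
      pf <- if (tot > 0) state[b, 3] / tot else 0
      key <- paste(ini$sex[b], ini$age_low[b])
      m <- lifetable$mortality_rate[
        match(key, paste(lifetable$sex, lifetable$age_low))]
      rr_c <- rrs$rr_current[match(key, paste(rrs$sex, rrs$age_low))]
      rr_f <- rrs$rr_former[match(key, paste(rrs$sex, rrs$age_low))]
      mn <- m / (rr_c * pc + rr_f * pf + (1 - pc - pf))
      n <- state[b, 1] * exp(-mn)
      cc <- state[b, 2] * exp(-rr_c * mn)
      f <- state[b, 3] * exp(-rr_f * mn)
      sgn <- flows$signed_parameter[
        match(key, paste(flows$sex, flows$age_low))]
      init_r <- max(-sgn, 0); cess_r <- max(sgn, 0)
      st <- n * init_r; qt <- cc * cess_r
      nxt[b, ] <- c(n - st, cc + st - qt, f + qt)
    }
    aged <- matrix(0, nb, 3)
    for (b in seq_len(nb)) {
      w <- ini$age_high[b] - ini$age_low[b]
      frac <- if (is.finite(w)) 1 / w else 0
      mv <- nxt[b, ] * frac
      aged[b, ] <- aged[b, ] + nxt[b, ] - mv
      if (b < nb) aged[b + 1, ] <- aged[b + 1, ] + mv
      else aged[nb, ] <- aged[nb, ] + mv
    }
    aged[1, 1] <- aged[1, 1] + entrants
    state <- aged
    out[[t + 1]] <- state
  }
  out
}

# Brute-force dominance / frontier oracle for small (cost, effect) sets.
frontier_oracle <- function(df) {
  n <- nrow(df)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if ((df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
           (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])) ||
          (df$cost[j] == df$cost[i] && df$effect[j] == df$effect[i] &&
           df$intervention[j] < df$intervention[i])) {
        dominated[i] <- TRUE
      }
    }
  }
  dominated
}
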