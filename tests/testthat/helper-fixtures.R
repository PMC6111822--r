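# Shared fixture builders and independent oracles.

# Random signed-rank profile over G genes (signs random, magnitudes 1..G).
random_profile <- function(G, seed, genes = sprintf("g%03d", seq_len(G))) {
  set.seed(seed)
  stat <- rnorm(G)
  r <- as.integer(sign(stat) * rank(abs(stat)))
  names(r) <- genes
  r
}

# Direct product-limit oracle: evaluates S(t), Greenwood variance and RMST
# straight from the definition by looping over distinct event times.
km_oracle <- function(times, events, tau = max(times)) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  gw_sum <- 0
  surv <- numeric(length(ut))
  gw <- numeric(length(ut))
  n_risk <- integer(length(ut))
  n_event <- integer(length(ut))
  for (i in seq_along(ut)) {
    n_i <- sum(times >= ut[i])
    d_i <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    if (n_i > d_i) gw_sum <- gw_sum + d_i / (n_i * (n_i - d_i))
    surv[i] <- s
    gw[i] <- if (n_i == d_i) 0 else s^2 * gw_sum
    n_risk[i] <- n_i
    n_event[i] <- d_i
  }
  # rectangle-sum RMST
  tt <- c(0, pmin(ut, tau), tau)
  ss <- c(1, surv, surv[length(surv)])
  rmst <- sum(diff(tt) * ss[-length(ss)])
  list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv,
       greenwood_var = gw, rmst = rmst)
}

# Brute-force Pearson correlation from the covariance definition.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Tiny valid cohort for io round-trips.
toy_cohort <- function() {
  values <- matrix(c(1.5, 2, 3, 4,
                     5, 6, 7, 8,
                     2, 1, 4, 3), nrow = 3, byrow = TRUE,
                   dimnames = list(c("GENEA", "GENEB", "GENEC"),
                                   c("s1", "s2", "s3", "s4")))
  clinical <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                         time_months = c(12, 30, 8, 45),
                         event = c(1, 0, 1, 1),
                         stringsAsFactors = FALSE)
  expression_cohort(values, clinical)
}
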