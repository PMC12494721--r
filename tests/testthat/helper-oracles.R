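# Independent brute-force oracles used to pin down the numeric primitives.
# These are deliberately naive (loops, enumeration, quadrature) and share no
# code with the package implementations.

# step-up BH by the textbook definition, element by element
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)      # ascending rank of p[i]
    cand <- Inf
    for (j in seq(rank_i, n)) {
      cand <- min(cand, p[ord[j]] * n / j)
    }
    q[i] <- min(1, cand)
  }
  q
}

# linear-interpolation quantile, written out by hand (numpy/"type 7" rule)
oracle_quantile <- function(x, prob) {
  x <- sort(x)
  h <- (length(x) - 1) * prob
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
}

oracle_fence_mask <- function(x) {
  fin <- is.finite(x)
  q1 <- oracle_quantile(x[fin], 0.25)
  q3 <- oracle_quantile(x[fin], 0.75)
  iqr <- q3 - q1
  out <- rep(FALSE, length(x))
  out[fin] <- x[fin] < q1 - 1.5 * iqr | x[fin] > q3 + 1.5 * iqr
  out
}

# double-loop radius-neighbour mean
oracle_trend <- function(acq, v, radius, inc) {
  n <- length(v)
  out <- rep(NA_real_, n)
  usable <- inc & is.finite(v)
  for (i in seq_len(n)) {
    w <- usable & abs(acq - acq[i]) <= radius
    if (any(w)) out[i] <- mean(v[w])
  }
  # nearest-defined fallback; ties resolve to the earlier acquisition position
  for (i in which(is.na(out))) {
    cand <- acq[usable]
    x_near <- cand[order(abs(cand - acq[i]), cand)][1]
    w <- usable & abs(acq - x_near) <= radius
    out[i] <- mean(v[w])
  }
  out
}

# two-sided Fisher p by enumerating the hypergeometric distribution:
# sum of probabilities of all tables as or less probable than the observed
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # class size
  k <- a + c          # total hits
  n_tot <- a + b + c + d
  support <- max(0, k - (n_tot - m)):min(k, m)
  probs <- stats::dhyper(support, m, n_tot - m, k)
  p_obs <- stats::dhyper(a, m, n_tot - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# standard-normal survival function by adaptive quadrature
oracle_sf <- function(z) {
  stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-13,
                   abs.tol = 1e-14)$value
}

# small scenario used across module tests: quick but structurally complete
small_scenario <- function(...) {
  simulation_scenario(
    n_compounds = 120,
    species = c("E. coli", "R. gnavus"),
    metabolite_map = list("E. coli" = c("cadaverine", "putrescine"),
                          "R. gnavus" = "tryptamine"),
    ...
  )
}
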