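# Independent oracles used to freeze expected values: a stiff ODE integrator
# for chain activities, hand-computed Kaplan-Meier, a manual log-rank
# statistic with its permutation null, and an exhaustive permutation t-test.

# chain activities by numerical integration (deSolve, stiff solver)
ode_activities <- function(chain, a0, times, rtol = 1e-10, atol = 1e-10) {
  lam <- chain$lambda
  b <- chain$branching
  n <- chain$n
  rhs <- function(t, A, p) {
    dA <- numeric(n)
    dA[1] <- -lam[1] * A[1]
    if (n > 1) for (i in 2:n)
      dA[i] <- if (lam[i] > 0) lam[i] * (b[i - 1] * A[i - 1] - A[i]) else 0
    list(dA)
  }
  sol <- deSolve::lsoda(a0, times, rhs, NULL, rtol = rtol, atol = atol)
  unname(sol[, -1, drop = FALSE])
}

# product-limit estimator without censoring: empirical survivor function
km_hand_nocensor <- function(event_times) {
  t_sorted <- sort(unique(event_times))
  n <- length(event_times)
  vapply(t_sorted, function(tt) mean(event_times > tt), numeric(1))
}

# manual log-rank chi-square (hypergeometric variance form)
logrank_manual <- function(time, event, group) {
  g1 <- group == unique(group)[1L]
  dt <- sort(unique(time[event]))
  o <- e <- v <- 0
  for (tt in dt) {
    at <- time >= tt
    nj <- sum(at); n1 <- sum(at & g1); dj <- sum(time == tt & event)
    d1 <- sum(time == tt & event & g1)
    o <- o + d1
    e <- e + n1 * dj / nj
    if (nj > 1) v <- v + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  (o - e)^2 / v
}

# permutation p-value of the log-rank statistic under label shuffling
perm_logrank_p <- function(time, event, group, B = 10000, seed = 42) {
  set.seed(seed)
  obs <- logrank_manual(time, event, group)
  hits <- 0L
  for (b in seq_len(B)) {
    gp <- sample(group)
    if (logrank_manual(time, event, gp) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# pooled t statistic for exhaustive two-group permutation
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

exhaustive_perm_t_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(v), n1)
  obs <- abs(pooled_t(x, y))
  stats <- apply(idx, 2, function(i) abs(pooled_t(v[i], v[-i])))
  mean(stats >= obs - 1e-12)
}

# Kruskal-Wallis H by direct mid-rank computation with tie correction
kruskal_manual <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
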