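# Independent oracles used across the suite. Each re-derives the expected
# quantity by a different route than the implementation under test.

# brute-force circular mean of directions weighted by activity, built from
# first principles (unit vectors summed one by one)
oracle_circular_mean <- function(values, directions_deg) {
  vx <- 0; vy <- 0
  for (i in seq_along(values)) {
    vx <- vx + values[i] * cos(directions_deg[i] * pi / 180)
    vy <- vy + values[i] * sin(directions_deg[i] * pi / 180)
  }
  atan2(vy, vx) * 180 / pi
}

# dense-grid quadrature of the positive/negative parts of a continuous
# angular-velocity function, for the turn-ratio oracle
oracle_turn_ratio <- function(f, from, to, n = 2e5) {
  tt <- seq(from, to, length.out = n)
  w <- f(tt)
  dt <- tt[2] - tt[1]
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * dt
  pos <- trap(pmax(w, 0))
  neg <- trap(pmax(-w, 0))
  (pos - neg) / (pos + neg)
}

# literal enumeration of all 2^n sign assignments of the ranked absolute
# values (midranks for ties); feasible for n <= 14
oracle_signed_rank <- function(values, alternative) {
  v <- values[values != 0]
  n <- length(v)
  stopifnot(n <= 14)
  r <- rank(abs(v))
  w_obs <- sum(r[v > 0])
  stats <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  pg <- mean(stats >= w_obs - 1e-9)
  pl <- mean(stats <= w_obs + 1e-9)
  switch(alternative,
         greater = pg, less = pl, two_sided = min(1, 2 * min(pg, pl)))
}

# geometric-series closed form for the goal-field amplitude under constant
# input c and decay lambda after m updates
oracle_goal_amplitude <- function(c_in, lambda, m) {
  c_in * (1 - (1 - lambda)^m) / lambda
}

default_circuit <- function(...) circuit_config(...)
default_familiarity <- function(...) familiarity_config(...)
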