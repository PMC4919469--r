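# Independent brute-force oracles used to validate the solvers.  These
# are deliberately naive: plain bisection with no polishing, written
# against the chemistry directly, so they share no code path with the
# package implementation.

# bisection on the receptor mass balance in terms of free receptor r:
#   r + r*Lt/(KdL + r) + r*Ct/(KdC + r) = Rt
oracle_solve <- function(rt, lt, ct, kl, kc, iters = 200) {
  if (rt == 0) {
    r <- 0
  } else {
    f <- function(r) r + r * lt / (kl + r) + r * ct / (kc + r) - rt
    lo <- 0; hi <- rt
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    r <- (lo + hi) / 2
  }
  rl <- r * lt / (kl + r)
  rc <- if (ct > 0) r * ct / (kc + r) else 0
  list(free_receptor = r, free_ligand = lt - rl, free_competitor = ct - rc,
       complex_RL = rl, complex_RC = rc)
}

oracle_binary <- function(rt, lt, kd) oracle_solve(rt, lt, 0, kd, 1)

# relative difference with a guard for zero-magnitude quantities
rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)

# compare a solved state to the oracle on every concentration; returns
# the worst relative difference over fields whose oracle magnitude is
# non-negligible relative to the system scale
state_vs_oracle <- function(st, orc, scale) {
  fields <- c("free_receptor", "free_ligand", "free_competitor",
              "complex_RL", "complex_RC")
  worst <- 0
  for (f in fields) {
    a <- st[[f]]; b <- orc[[f]]
    if (abs(b) > 1e-12 * scale) worst <- max(worst, rel_diff(a, b))
    else worst <- max(worst, abs(a - b) / scale)
  }
  worst
}

# random valid binding systems: log-uniform Kd 1 nM - 100 uM, totals
# 1 nM - 1 mM (the spec of the property test)
random_system <- function(with_competitor = TRUE) {
  lu <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  list(rt = lu(1e-9, 1e-3), lt = lu(1e-9, 1e-3),
       ct = if (with_competitor) lu(1e-9, 1e-3) else 0,
       kl = lu(1e-9, 1e-4), kc = lu(1e-9, 1e-4))
}
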