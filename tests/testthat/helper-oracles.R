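# Independent oracles used to freeze expected values. These stay deliberately
# naive (enumeration, closed forms) and never call the code paths they check.

# Exact two-sided rank-sum p-value by full enumeration of rank assignments.
oracle_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- rank(c(a, b))
  W_obs <- sum(pooled[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  Ws <- apply(combs, 2, function(idx) sum(pooled[idx]) - n * (n + 1) / 2)
  # two-sided: double the smaller tail (with point mass), capped at 1
  EW <- n * m / 2
  p_lo <- mean(Ws <= W_obs)
  p_hi <- mean(Ws >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided signed-rank p-value by enumeration of sign patterns.
oracle_signedrank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  p_lo <- mean(Vs <= V_obs)
  p_hi <- mean(Vs >= V_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Closed-form solution of the two-conductance membrane equation at constant
# activation: V(t) = V_inf + (V0 - V_inf) exp(-t/tau).
oracle_voltage <- function(t, V0, a, g_leak, g_max, E_K, E_ops, C_m_pF) {
  g_tot <- g_leak + g_max * a
  V_inf <- (g_leak * E_K + g_max * a * E_ops) / g_tot
  tau <- C_m_pF / g_tot / 1000  # s
  V_inf + (V0 - V_inf) * exp(-t / tau)
}

# Sensor Hill curve and its delta-F/F relative to the reference pH.
oracle_hill_dff <- function(pH, pKa = 7.5, n = 1, pH_ref = 7.3) {
  f <- function(p) 1 / (1 + 10^(n * (pKa - p)))
  f(pH) / f(pH_ref) - 1
}

# Jaccard index between two logical masks.
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Small standard fixtures ----------------------------------------------------

short_protocol <- function() build_protocol(0.5, 1, 15, 15)

fast_opsin <- function(f_H = 0.5, g_max = 20, desens = 1) {
  opsin_params(g_max_nS = g_max, E_ops_mV = 4, f_H = f_H,
               EPD50_mW_cm2 = 22, tau_on_sat_ms = 4.5, tau_off_ms = 16,
               desensitization_ratio = desens,
               spectrum = c("488" = 1, "561" = 0))
}
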