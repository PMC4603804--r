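# Independent oracles used across tests.

# Efron-tie log partial likelihood for a single covariate, written directly
# from the likelihood definition (independent of survival's fitting code).
efron_loglik <- function(b, time, status, z) {
  r <- exp(b * z)
  ll <- 0
  for (tj in unique(time[status == 1])) {
    atrisk <- time >= tj
    dead <- time == tj & status == 1
    sr <- sum(r[atrisk])
    sd_ <- sum(r[dead])
    dj <- sum(dead)
    ll <- ll + b * sum(z[dead]) -
      sum(log(sr - (seq_len(dj) - 1) / dj * sd_))
  }
  ll
}

# D via explicit sorting + Blom scores + 1-d maximisation of the Efron
# partial likelihood; a from-scratch route to compare with estimate_d().
oracle_d <- function(time, status, pindex) {
  n <- length(pindex)
  sc <- numeric(n)
  sc[order(pindex)] <- qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  for (v in unique(pindex[duplicated(pindex)]))
    sc[pindex == v] <- mean(sc[pindex == v])
  z <- sc / sqrt(8 / base::pi)
  stats::optimize(efron_loglik, c(-15, 15), time = time, status = status,
                  z = z, maximum = TRUE, tol = 1e-9)$maximum
}

# Table of published (c, D, R^2_D) reference points used by the conversion
# tests (c from 0.50 to 0.92 in steps of 0.02).
reference_conversion_table <- function() {
  m <- matrix(c(
    0.50, 0.000, 0.000, 0.52, 0.110, 0.003, 0.54, 0.221, 0.011,
    0.56, 0.332, 0.026, 0.58, 0.445, 0.045, 0.60, 0.560, 0.070,
    0.62, 0.678, 0.099, 0.64, 0.798, 0.132, 0.66, 0.922, 0.169,
    0.68, 1.050, 0.208, 0.70, 1.182, 0.250, 0.72, 1.319, 0.294,
    0.74, 1.462, 0.338, 0.76, 1.610, 0.382, 0.78, 1.765, 0.427,
    0.80, 1.927, 0.470, 0.82, 2.096, 0.512, 0.84, 2.273, 0.552,
    0.86, 2.459, 0.591, 0.88, 2.652, 0.627, 0.90, 2.857, 0.661,
    0.92, 3.070, 0.692), ncol = 3, byrow = TRUE)
  data.frame(c = m[, 1], d = m[, 2], r2 = m[, 3])
}
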