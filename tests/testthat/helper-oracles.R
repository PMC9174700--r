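# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form and binned code paths.

# Damage along a linear depletion trajectory by adaptive quadrature of the
# response, split at the hypoxia-onset dose for accuracy.
quad_linear_damage <- function(o2_0, rate, dose,
                               params = default_response_params()) {
  f <- function(d) oxygen_response(pmax(o2_0 - rate * d, 0), params)
  d_hyp <- if (rate > 0) o2_0 / rate else Inf
  if (d_hyp < dose) {
    stats::integrate(f, 0, d_hyp, rel.tol = 1e-12, subdivisions = 1000L)$value +
      (dose - d_hyp) * oxygen_response(0, params)
  } else {
    stats::integrate(f, 0, dose, rel.tol = 1e-12, subdivisions = 1000L)$value
  }
}

quad_linear_sparing <- function(o2_0, rate, dose,
                                params = default_response_params()) {
  quad_linear_damage(o2_0, rate, dose, params) /
    (dose * oxygen_response(o2_0, params))
}

# All permutations of 1..n as rows (naive recursive construction).
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# Brute-force null distribution of sum(d^2) by full enumeration.
naive_d2_distribution <- function(n) {
  pm <- perms_all(n)
  d2 <- rowSums((pm - matrix(seq_len(n), nrow(pm), n, byrow = TRUE))^2)
  tab <- table(d2)
  data.frame(d2 = as.integer(names(tab)), count = as.integer(tab))
}
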