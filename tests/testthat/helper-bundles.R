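# Small builders used across the test files.

mk_bundle <- function(n_membrane = 2, alpha = 1.5, beta = 1, gamma = 10,
                      epsilon = 0, r_cell = 6, r_nuc = 2, d_cyt = 3,
                      d_mem = 0.03, p0 = 100, kind = "sphere3d",
                      signal = NULL, feedback = NULL) {
  validate_model(
    cascade_spec(3, n_membrane, alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, feedback = feedback),
    geometry_spec(kind, r_cell = r_cell, r_nuc = r_nuc),
    transport_spec(d_cyt = d_cyt, d_mem = d_mem),
    if (is.null(signal)) signal_spec("constant", amplitude = p0) else signal)
}

# dense Riemann-sum average/variance oracle on an analytic solution closure
riemann_average <- function(f, r_nuc, r_cell, a, n = 1e5) {
  r <- seq(r_nuc, r_cell, length.out = n)
  mid <- (r[-1] + r[-n]) / 2
  w <- mid^a * diff(r)
  sum(f(mid) * w) / sum(w)
}

# closed-form P3(t) of a three-stage linear chain with constant input u and
# distinct rates b (partial fractions of G u / (s (s+b1)(s+b2)(s+b3)))
chain_closed_form <- function(t, gains, b, u) {
  G <- prod(gains) * u
  vapply(t, function(tt) {
    G * (1 / prod(b) + sum(vapply(1:3, function(i)
      -exp(-b[i] * tt) / (b[i] * prod(b[setdiff(1:3, i)] - b[i])), numeric(1))))
  }, numeric(1))
}
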