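# shared fixtures, built in code

ref_pe2i <- function(A = 100, l1 = 0.05, l2 = 1.0) {
  make_reference_tac(pe2i_frame_schedule(), A, l1, l2)
}

ref_ded <- function(A = 80, l1 = 0.06, l2 = 0.8) {
  make_reference_tac(ded_frame_schedule(), A, l1, l2)
}

# closed-form running integral of A (e^{-l1 t} - e^{-l2 t})
biexp_integral <- function(t, A, l1, l2) {
  A * ((1 - exp(-l1 * t)) / l1 - (1 - exp(-l2 * t)) / l2)
}

# brute-force normal-equations OLS, the oracle for the QR path
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}
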