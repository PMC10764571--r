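# shared fixture builders (all fixtures are constructed in code)

schnak_layer <- function(a, b, s, d) {
  layer_model(make_preset("schnakenberg", list(a = a, b = b, s = s)), d)
}

# two identical Schnakenberg layers, bulk below threshold (d_vB = 15)
fig2_bilayer <- function(alpha = 1, beta = 1, L = 1000) {
  AB <- diag(c(alpha, beta))
  bilayer_model(schnak_layer(0.2305, 0.7695, 1, c(1, 20)),
                schnak_layer(0.2305, 0.7695, 1, c(1, 15)),
                A = AB, B = AB, geometry = geometry_1d1d(L))
}

# linear kinetics with a fixed Jacobian and equilibrium at the origin:
# exercises the dispersion machinery with arbitrary random systems
linear_kinetics <- function(J) {
  kinetics_model(nrow(J), list(),
                 rates = function(w) if (is.matrix(w)) J %*% w else drop(J %*% w),
                 jacobian = function(w) J,
                 label = "linear")
}

random_linear_bilayer <- function(n, m, eta = NULL, geometry = geometry_1d1d(100)) {
  J_S <- matrix(stats::rnorm(n * n), n, n)
  J_B <- matrix(stats::rnorm(m * m), m, m)
  bilayer_model(
    layer_model(linear_kinetics(J_S), stats::runif(n, 0.5, 3)),
    layer_model(linear_kinetics(J_B), stats::runif(m, 0.5, 3)),
    A = matrix(stats::rnorm(n * n), n, n),
    B = matrix(stats::rnorm(n * n), n, n),
    eta = if (is.null(eta)) stats::runif(1, 0, 2) else eta,
    geometry = geometry)
}

zero_equilibrium <- function(n, m, eta = 0) {
  list(u_S = rep(0, n), u_B = rep(0, m), eta = eta, residual = 0)
}

# bulk kinetics used in the chemotaxis studies (three species u, v, cells)
chemo_bulk_kinetics <- function() {
  make_preset("pseudo_linear_bulk",
              list(r0 = 0.2, a0 = 3, a1 = 8, b = 2, a2 = 7,
                   b0 = 0.75, c1 = 0.5, c2 = 1.5, d = 1, cstar = 0.25))
}

# polynomial evaluation, leading coefficient first (test-side oracle helper)
polyval_desc <- function(coefs, x) {
  out <- 0
  for (cf in coefs) out <- out * x + cf
  out
}
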