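#' Cofactor matrix
#'
#' Matrix of signed minors, `co(A)[i,j] = (-1)^(i+j) |A[-i,-j]|`. It enters
#' the analysis through Jacobi's formula for the differential of the
#' determinant, `d/dh |A + h B| = co(A) . B` at `h = 0`, where `.` is the
#' matrix dot product `sum(A * B)`. Works for singular matrices, which is
#' essential since the driving layer's dispersion matrix is exactly
#' singular at a marginal bifurcation point.
#'
#' @param A Square numeric matrix.
#' @return The cofactor matrix of `A`.
#' @examples
#' comatrix(diag(c(2, 3)))   # diag(3, 2)
#' @export
comatrix <- function(A) {
  n <- nrow(A)
  stopifnot(is.matrix(A), ncol(A) == n)
  if (n == 1L) return(matrix(1, 1, 1))
  C <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      C[i, j] <- (-1)^(i + j) * det(A[-i, -j, drop = FALSE])
  C
}

# matrix dot product Tr(t(A) B)
mat_dot <- function(A, B) sum(A * B)

#' Assemble the linearization of a bilayer model about an equilibrium
#'
#' Evaluates the Jacobians and (cross-)diffusion matrices of both layers at
#' the given equilibrium state, together with the exchange matrices, ready
#' for dispersion-relation work. For chemotaxis layers the bulk diffusion
#' matrix carries the cell-drift row \eqn{(-h(c^*)\nabla k(u^*)^T, d_c)}.
#'
#' @param bilayer A [bilayer_model()].
#' @param equilibrium An equilibrium as returned by [coupled_equilibrium()],
#'   or a list with elements `u_S` and `u_B`.
#' @return Object of class `bilayer_linearization` with elements `J_S`,
#'   `J_B`, `D_S`, `D_B`, `A`, `B`, `B_tilde`, `eta`, `geometry`, `n`, `m`.
#' @export
build_linearization <- function(bilayer, equilibrium) {
  n <- bilayer$n; m <- bilayer$m
  u_S <- equilibrium$u_S; u_B <- equilibrium$u_B
  stopifnot(length(u_S) == n, length(u_B) == m)
  J_S <- bilayer$surface$kinetics$jacobian(u_S)
  J_B <- bilayer$bulk$kinetics$jacobian(u_B)
  D_S <- diffusion_matrix(bilayer$surface, u_S)
  D_B <- diffusion_matrix(bilayer$bulk, u_B)
  for (D in list(D_S, D_B))
    if (any(Re(eigen(D, only.values = TRUE)$values) <= 0))
      stop("build_linearization: diffusion matrix is not positive (semi)definite",
           call. = FALSE)
  structure(list(J_S = J_S, J_B = J_B, D_S = D_S, D_B = D_B,
                 A = bilayer$A, B = bilayer$B,
                 B_tilde = pad_tilde(bilayer$B, m),
                 eta = bilayer$eta, geometry = bilayer$geometry,
                 n = n, m = m, equilibrium = equilibrium),
            class = "bilayer_linearization")
}

# (n+m) x (n+m) mode matrix C(xi) such that the dispersion matrix is
# lambda I + C; growth rates are the eigenvalues of -C
mode_matrix_1d1d <- function(lin, xi) {
  n <- lin$n; m <- lin$m
  P0 <- xi * lin$D_S - lin$J_S
  Q0 <- xi * lin$D_B - lin$J_B
  C <- matrix(0, n + m, n + m)
  C[seq_len(n), seq_len(n)] <- P0 + lin$eta * lin$A
  C[seq_len(n), n + seq_len(n)] <- -lin$eta * lin$A
  C[n + seq_len(n), seq_len(n)] <- -lin$eta * lin$B
  C[n + seq_len(m), n + seq_len(m)] <- Q0 + lin$eta * lin$B_tilde
  C
}

#' Characteristic dispersion polynomial in the 1D-1D geometry
#'
#' Coefficients of the degree-`(n+m)` polynomial in the growth rate
#' \eqn{\lambda} whose roots solve the dispersion relation
#' \eqn{\det M(\lambda, \xi) = 0} at squared wavenumber `xi`. The
#' coefficients are recovered by evaluating the determinant at
#' Chebyshev-spaced \eqn{\lambda} samples and interpolating, so no
#' eigen-decomposition is involved.
#'
#' @param lin A [build_linearization()] result with 1D-1D geometry.
#' @param xi Nonnegative squared wavenumber \eqn{\xi = k_q^2}.
#' @return Object of class `dispersion_polynomial`: numeric coefficients,
#'   leading (monic) coefficient first.
#' @export
char_poly_1d1d <- function(lin, xi) {
  if (lin$geometry$type != "1d1d")
    stop("char_poly_1d1d: geometry must be 1d1d", call. = FALSE)
  C <- mode_matrix_1d1d(lin, xi)
  N <- nrow(C)
  r <- max(1, max(abs(C)) * N)
  # N+1 Chebyshev nodes on [-r, r]
  lam <- r * cos(pi * (2 * seq_len(N + 1) - 1) / (2 * (N + 1)))
  dets <- vapply(lam, function(l) det(diag(l, N) + C), numeric(1))
  V <- outer(lam, N:0, `^`)
  coef <- solve(V, dets)
  coef <- coef / coef[1L]
  structure(coef, class = "dispersion_polynomial", xi = xi)
}

#' Routh-Hurwitz stability of a real polynomial
#'
#' Decides whether all roots of the polynomial have strictly negative real
#' part, using the Hurwitz leading principal minors. Marginal cases (any
#' minor or coefficient within tolerance of zero) are reported as unstable
#' so that instability regions are closed sets.
#'
#' @param poly Numeric coefficient vector, leading coefficient first (e.g.
#'   from [char_poly_1d1d()]).
#' @param tol Marginality tolerance applied after normalising the
#'   coefficients by their maximum magnitude.
#' @return `TRUE` if Hurwitz-stable, otherwise `FALSE`.
#' @examples
#' routh_hurwitz_stable(c(1, 1, 2))   # lambda^2 + lambda + 2 : stable
#' routh_hurwitz_stable(c(1, -1, 2))  # positive trace : unstable
#' @export
routh_hurwitz_stable <- function(poly, tol = 1e-10) {
  a <- as.numeric(poly)
  if (length(a) < 2L) return(TRUE)
  if (a[1L] == 0) stop("routh_hurwitz_stable: zero leading coefficient",
                       call. = FALSE)
  if (a[1L] < 0) a <- -a
  a <- a / max(abs(a))
  N <- length(a) - 1L
  # necessary: all coefficients strictly positive
  if (any(a <= tol)) return(FALSE)
  # Hurwitz matrix H[i, j] = a_{2j - i} (a_0 = leading)
  Hm <- matrix(0, N, N)
  for (i in seq_len(N))
    for (j in seq_len(N)) {
      k <- 2L * j - i
      if (k >= 0L && k <= N) Hm[i, j] <- a[k + 1L]
    }
  for (k in seq_len(N))
    if (det(Hm[seq_len(k), seq_len(k), drop = FALSE]) <= tol) return(FALSE)
  TRUE
}

#' Scan discrete modes for instability (1D-1D)
#'
#' Classifies every cosine mode \eqn{k_q = q\pi/L}, \eqn{q = 0, \dots,
#' q_{max}}, by the Routh-Hurwitz criterion applied to the dispersion
#' polynomial at \eqn{\xi = k_q^2}.
#'
#' @param lin A [build_linearization()] result (1D-1D geometry).
#' @param L Domain length.
#' @param q_max Largest mode index scanned.
#' @return Integer vector of unstable mode indices (possibly empty).
#' @export
mode_scan <- function(lin, L, q_max) {
  qs <- 0:q_max
  unstable <- vapply(qs, function(q) {
    xi <- (q * pi / L)^2
    !routh_hurwitz_stable(char_poly_1d1d(lin, xi))
  }, logical(1))
  qs[unstable]
}

#' Entire matrix functions of the transcendental bulk dispersion relation
#'
#' For a bulk of depth `H` with reduced dispersion matrix `R`, returns the
#' three entire functions
#' \deqn{F_1(H, R) = \sum_{k \ge 1} H^{2k-1} R^k / (2k-1)!,}
#' \deqn{F_2(H, R) = \sum_{k \ge 0} H^{2k} R^k / (2k)!,}
#' \deqn{\tilde F_2(H, R) = \sum_{k \ge 0} \frac{k+1}{2k+1} H^{2k} R^k / (2k)!.}
#' For scalar `z > 0` these are \eqn{\sqrt z \sinh(H\sqrt z)} and
#' \eqn{\cosh(H\sqrt z)}; being functions of \eqn{R} itself (not its square
#' root) they are evaluated without ever forming a matrix square root.
#' Small (or nilpotent) arguments are summed directly; large ones are
#' evaluated by scaling-and-squaring with the hyperbolic doubling
#' identities \eqn{F_2(2H) = 2F_2(H)^2 - I} and
#' \eqn{F_1(2H) = 2 F_1(H) F_2(H)}, which remain valid for defective
#' matrices. \eqn{\tilde F_2} has no doubling identity and falls back to an
#' eigen-decomposition at large arguments when `R` is diagonalizable.
#'
#' @param H Positive depth.
#' @param R Square matrix (may have negative or complex eigenvalues).
#' @param tol Relative truncation tolerance for the series path.
#' @return List with components `F1`, `F2`, `F2_tilde`.
#' @export
matrix_entire_functions <- function(H, R, tol = 1e-12) {
  stopifnot(H > 0)
  if (!is.matrix(R)) R <- matrix(R, 1, 1)
  m <- nrow(R)
  nrmR <- norm(R, "F")
  # nilpotent arguments terminate the series exactly after m terms
  Rm <- Reduce(`%*%`, rep(list(R), m))
  nilpotent <- norm(Rm, "F") <= 1e-12 * max(1, nrmR)^m

  series <- function(Hs) {
    I <- diag(1, m)
    term <- I                       # R^k accumulator
    F1 <- matrix(0, m, m); F2 <- I; F2t <- I
    for (k in seq_len(300L)) {
      term <- term %*% R
      c1 <- Hs^(2 * k - 1) / factorial(2 * k - 1)
      c2 <- Hs^(2 * k) / factorial(2 * k)
      F1 <- F1 + c1 * term
      F2 <- F2 + c2 * term
      F2t <- F2t + (k + 1) / (2 * k + 1) * c2 * term
      if (c2 * norm(term, "F") <= tol * max(norm(F2, "F"), 1) &&
          c1 * norm(term, "F") <= tol * max(norm(F1, "F"), 1))
        return(list(F1 = F1, F2 = F2, F2_tilde = F2t))
    }
    stop("matrix_entire_functions: series not converged within term budget",
         call. = FALSE)
  }

  if (H^2 * nrmR <= 25 || nilpotent) return(series(H))

  # scale H down until the series is safe, then apply the hyperbolic
  # doubling identities (valid for any, including defective, R)
  s <- ceiling(log2(H / sqrt(25 / nrmR)))
  Fs <- series(H / 2^s)
  F1 <- Fs$F1; F2 <- Fs$F2
  I <- diag(1, m)
  for (k in seq_len(s)) {
    F1n <- 2 * F1 %*% F2
    F2 <- 2 * F2 %*% F2 - I
    F1 <- F1n
  }
  # F2_tilde has no doubling identity; use the spectral form when possible
  F2t <- tryCatch({
    ev <- eigen(R)
    V <- ev$vectors
    condV <- tryCatch(kappa(V, exact = FALSE), error = function(e) Inf)
    if (!is.finite(condV) || condV > 1e8)
      stop("near-defective")
    t <- H * sqrt(as.complex(ev$values))   # even in sqrt: branch immaterial
    f2t <- ifelse(Mod(t) < 1e-8, 1 + 0i, (cosh(t) + sinh(t) / t) / 2)
    Mz <- V %*% diag(f2t, m) %*% solve(V)
    Re(Mz)
  }, error = function(e) {
    matrix(NA_real_, m, m)
  })
  list(F1 = F1, F2 = F2, F2_tilde = F2t)
}

# lambda = 0 dispersion matrix M0(xi) for either geometry, with all blocks
# assembled from the linearization
a0_matrix <- function(lin, xi) {
  n <- lin$n; m <- lin$m; eta <- lin$eta
  P0 <- xi * lin$D_S - lin$J_S
  if (lin$geometry$type == "1d1d") {
    Q0 <- xi * lin$D_B - lin$J_B
    M0 <- matrix(0, n + m, n + m)
    M0[seq_len(n), seq_len(n)] <- P0 + eta * lin$A
    M0[seq_len(n), n + seq_len(n)] <- -eta * lin$A
    M0[n + seq_len(n), seq_len(n)] <- -eta * lin$B
    M0[n + seq_len(m), n + seq_len(m)] <- (xi * lin$D_B - lin$J_B) +
      eta * lin$B_tilde
    return(M0)
  }
  H <- lin$geometry$H
  R0 <- xi * diag(1, m) - solve(lin$D_B, lin$J_B)
  Fs <- matrix_entire_functions(H, R0)
  W0 <- lin$D_B %*% Fs$F1
  M0 <- matrix(0, n + m, n + m)
  M0[seq_len(n), seq_len(n)] <- P0 + eta * lin$A
  M0[seq_len(n), n + seq_len(m)] <- -eta * lin$A %*%
    Fs$F2[seq_len(n), , drop = FALSE]
  M0[n + seq_len(n), seq_len(n)] <- -eta * lin$B
  M0[n + seq_len(m), n + seq_len(m)] <- W0 + eta * lin$B_tilde %*% Fs$F2
  M0
}

#' Marginal dispersion determinant and its wavenumber gradient
#'
#' Evaluates \eqn{a_0(\xi) = \det M(\lambda = 0, \xi)} for a bilayer,
#' optionally with one scalar model parameter (a diffusion coefficient or
#' the chemotaxis strength) overridden, together with
#' \eqn{\partial a_0/\partial\xi} by adaptive central differences. In the
#' 1D-2D geometry the bulk block is the transcendental factor
#' \eqn{W_0 = D_B F_1(H, R_0)} with the \eqn{F_2} interface factors.
#'
#' @param bilayer A [bilayer_model()].
#' @param equilibrium Equilibrium at the bilayer's coupling strength (see
#'   [coupled_equilibrium()]); computed on the fly when `NULL`.
#' @param xi Squared wavenumber.
#' @param delta_name Optional parameter name understood by [set_param()].
#' @param delta_value Override value for `delta_name`.
#' @return List with elements `a0` and `da0_dxi`.
#' @export
a0_and_grad <- function(bilayer, xi, equilibrium = NULL,
                        delta_name = NULL, delta_value = NULL) {
  if (!is.null(delta_name))
    bilayer <- set_param(bilayer, delta_name, delta_value)
  if (is.null(equilibrium))
    equilibrium <- coupled_equilibrium(bilayer, bilayer$eta)
  lin <- build_linearization(bilayer, equilibrium)
  h <- 1e-6 * (1 + xi)
  a0 <- det(a0_matrix(lin, xi))
  ap <- det(a0_matrix(lin, xi + h))
  am <- det(a0_matrix(lin, max(xi - h, 0)))
  da <- if (xi - h >= 0) (ap - am) / (2 * h) else (ap - a0) / h
  list(a0 = a0, da0_dxi = da)
}
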