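#' Homogeneous equilibrium of the coupled 1D-1D system
#'
#' Solves the coupled algebraic system
#' \deqn{f_S(u_S) + \eta A (\tilde u_B - u_S) = 0,\qquad
#'       f_B(u_B) + \eta \tilde B (\tilde u_S - u_B) = 0}
#' by Newton continuation in \eqn{\eta}, starting from the uncoupled
#' equilibria at \eqn{\eta = 0} (found with [find_equilibrium()] from the
#' supplied guesses or the presets' defaults). Only the branch continued
#' from the \eqn{\eta = 0} equilibrium is tracked. In the 1D-2D geometry
#' the interface forces a shared equilibrium, independent of \eqn{\eta}:
#' both reaction terms must vanish at the same point, otherwise an error is
#' raised.
#'
#' @param bilayer A [bilayer_model()].
#' @param eta Coupling strength at which the equilibrium is requested.
#' @param guess_S,guess_B Initial guesses for the uncoupled layer
#'   equilibria; defaults to a heuristic interior point.
#' @param tol Residual tolerance, relative to `1 + ||state||`.
#' @return Object of class `equilibrium_state`: list with `u_S`, `u_B`,
#'   `eta`, `residual`.
#' @export
coupled_equilibrium <- function(bilayer, eta = bilayer$eta,
                                guess_S = NULL, guess_B = NULL,
                                tol = 1e-12) {
  n <- bilayer$n; m <- bilayer$m
  kS <- bilayer$surface$kinetics; kB <- bilayer$bulk$kinetics
  if (is.null(guess_S)) guess_S <- .default_guess(kS)
  if (is.null(guess_B)) guess_B <- .default_guess(kB)
  uS0 <- find_equilibrium(kS, guess_S)
  uB0 <- find_equilibrium(kB, guess_B)

  if (bilayer$geometry$type == "1d2d") {
    # interface condition forces u_S* = first n components of u_B*
    mism <- max(abs(kS$rates(uB0[seq_len(n)]))) + max(abs(kB$rates(uB0)))
    if (max(abs(uS0 - uB0[seq_len(n)])) > 1e-8 * (1 + max(abs(uB0))) ||
        mism > 1e-10)
      stop("coupled_equilibrium: surface and bulk kinetics do not share a root; the 1D-2D geometry requires a common homogeneous equilibrium",
           call. = FALSE)
    res <- max(abs(c(kS$rates(uS0), kB$rates(uB0))))
    return(structure(list(u_S = uS0, u_B = uB0, eta = eta, residual = res),
                     class = "equilibrium_state"))
  }

  A <- bilayer$A; Bt <- pad_tilde(bilayer$B, m)
  resid <- function(w, et) {
    uS <- w[seq_len(n)]; uB <- w[n + seq_len(m)]
    c(kS$rates(uS) + et * A %*% (uB[seq_len(n)] - uS),
      kB$rates(uB) + et * Bt %*% (pad_vec(uS, m) - uB))
  }
  jac <- function(w, et) {
    uS <- w[seq_len(n)]; uB <- w[n + seq_len(m)]
    J <- matrix(0, n + m, n + m)
    J[seq_len(n), seq_len(n)] <- kS$jacobian(uS) - et * A
    J[seq_len(n), n + seq_len(n)] <- et * A
    J[n + seq_len(m), seq_len(n)] <- et * Bt[, seq_len(n)]
    J[n + seq_len(m), n + seq_len(m)] <- kB$jacobian(uB) - et * Bt
    J
  }
  newton <- function(w, et) {
    for (it in 1:50) {
      r <- resid(w, et)
      if (max(abs(r)) <= tol * (1 + sqrt(sum(w^2)))) return(w)
      J <- jac(w, et)
      dw <- tryCatch(solve(J, -r), error = function(e)
        stop("coupled_equilibrium: singular Jacobian along the continuation",
             call. = FALSE))
      w <- w + dw
    }
    r <- resid(w, et)
    if (max(abs(r)) <= tol * (1 + sqrt(sum(w^2)))) return(w)
    NULL
  }

  w <- c(uS0, uB0)
  et <- 0
  step <- min(1e-3, if (eta > 0) eta else 1e-3)
  while (et < eta) {
    step <- min(step, eta - et)
    wn <- newton(w, et + step)
    if (is.null(wn)) {
      step <- step / 2
      if (step < 1e-12)
        stop("coupled_equilibrium: Newton continuation failed (step underflow)",
             call. = FALSE)
      next
    }
    w <- wn; et <- et + step
    step <- min(step * 2, 1)
  }
  w <- if (eta == 0) w else newton(w, eta)
  res <- max(abs(resid(w, eta)))
  structure(list(u_S = w[seq_len(n)], u_B = w[n + seq_len(m)],
                 eta = eta, residual = res),
            class = "equilibrium_state")
}

# heuristic interior starting point per preset
.default_guess <- function(k) {
  switch(k$label,
    schnakenberg = {
      u <- k$params$a + k$params$b; c(u, k$params$b / u^2)
    },
    gierer_meinhardt = {
      u <- (k$params$a + 1) / k$params$b; c(u, u^2)
    },
    keller_segel_linear = {
      cs <- k$params$cstar; c(k$params$a * cs / k$params$b, cs)
    },
    pseudo_linear_bulk = {
      cs <- k$params$cstar
      v <- (k$params$b0 + (k$params$c1 + k$params$d) * cs) / k$params$c2
      u <- (k$params$a0 + k$params$a1 * cs - k$params$b * v) / k$params$a2
      c(u, v, cs)
    },
    jp_family = c(0, 0),
    rep(1, k$n_species))
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> eta = %g, residual = %.3g\n", x$eta,
              x$residual))
  cat("  u_S* =", signif(x$u_S, 8), "\n")
  cat("  u_B* =", signif(x$u_B, 8), "\n")
  invisible(x)
}

#' Sensitivity of the coupled equilibrium to weak coupling
#'
#' First derivative of the equilibrium curve \eqn{\eta \mapsto w^*(\eta)}
#' at \eqn{\eta = 0}:
#' \deqn{u_S^{*\prime}(0) = J_S^{-1} A (u_S^*(0) - \tilde u_B^*(0)),\qquad
#'       u_B^{*\prime}(0) = J_B^{-1} \tilde B (u_B^*(0) - \tilde u_S^*(0)),}
#' which vanishes when the uncoupled layers share their equilibrium and
#' otherwise contributes the asymmetric-equilibria term to the
#' weak-coupling bifurcation slope.
#'
#' @param bilayer A [bilayer_model()] (1D-1D geometry).
#' @param eq0 Optional equilibrium at `eta = 0`; computed when `NULL`.
#' @return List with `dU_S` (length n) and `dU_B` (length m).
#' @export
equilibrium_sensitivity <- function(bilayer, eq0 = NULL) {
  n <- bilayer$n; m <- bilayer$m
  if (is.null(eq0)) eq0 <- coupled_equilibrium(bilayer, 0)
  J_S <- bilayer$surface$kinetics$jacobian(eq0$u_S)
  J_B <- bilayer$bulk$kinetics$jacobian(eq0$u_B)
  for (J in list(J_S, J_B))
    if (abs(det(J)) < 1e-12 * max(1, max(abs(J)))^nrow(J))
      stop("equilibrium_sensitivity: singular Jacobian", call. = FALSE)
  Bt <- pad_tilde(bilayer$B, m)
  dU_S <- solve(J_S, bilayer$A %*% (eq0$u_S - eq0$u_B[seq_len(n)]))
  dU_B <- solve(J_B, Bt %*% (eq0$u_B - pad_vec(eq0$u_S, m)))
  list(dU_S = drop(dU_S), dU_B = drop(dU_B))
}
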