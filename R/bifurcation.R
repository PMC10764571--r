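#' Critical bifurcation parameter of a single uncoupled layer
#'
#' For a two-species pure reaction-diffusion layer with the second species'
#' diffusion as bifurcation parameter, uses the classical closed form
#' \deqn{\delta_c = d_u\left(\frac{\sqrt{f_u g_v - f_v g_u} +
#'   \sqrt{-f_v g_u}}{f_u}\right)^2}
#' together with the critical-wavenumber relation
#' \eqn{\xi_c = (\delta_c f_u + d_u g_v) / (2 d_u \delta_c)}. For three or
#' more species, or in the presence of chemotaxis, the onset is located
#' numerically: the determinant \eqn{\det(\xi D - J)} is a degree-`m`
#' polynomial in \eqn{\xi} whose minimum over \eqn{\xi > 0} is driven to
#' zero by bisection in \eqn{\delta} (relative tolerance `1e-6`).
#'
#' @param layer A [layer_model()].
#' @param delta_name Which scalar parameter is the bifurcation parameter:
#'   `"d_u"`, `"d_v"`, `"d_c"` (diagonal diffusion of species 1, 2, last)
#'   or `"chi"`.
#' @param equilibrium Layer equilibrium; computed with [find_equilibrium()]
#'   from the preset's default guess when `NULL`.
#' @param delta_window Numeric length-2 search window for the numeric
#'   branch.
#' @param xi_max Upper end of the wavenumber search interval.
#' @return List with `delta_c`, `xi_c`, and `method` (`"closed_form"` or
#'   `"bisection"`).
#' @examples
#' lay <- layer_model(make_preset("schnakenberg",
#'                                list(a = 0.2305, b = 0.7695, s = 1)),
#'                    diff_coef = c(1, 1))
#' layer_critical_diffusion(lay, "d_v")   # delta_c ~ 17.3
#' @export
layer_critical_diffusion <- function(layer, delta_name = "d_v",
                                     equilibrium = NULL,
                                     delta_window = c(1e-3, 1e4),
                                     xi_max = 1e3) {
  k <- layer$kinetics
  if (is.null(equilibrium)) equilibrium <- find_equilibrium(k, .default_guess(k))
  J <- k$jacobian(equilibrium)
  m <- k$n_species

  if (m == 2L && is.null(layer$chi) && delta_name == "d_v") {
    fu <- J[1, 1]; fv <- J[1, 2]; gu <- J[2, 1]; gv <- J[2, 2]
    du <- layer$diff_coef[1]
    if (fu * gv - fv * gu <= 0)
      stop("layer_critical_diffusion: det J <= 0, no diffusion-driven instability of a stable state",
           call. = FALSE)
    if (fu + gv >= 0)
      warning("layer_critical_diffusion: trace J >= 0, equilibrium unstable to homogeneous perturbations; the closed-form marginal value is still returned",
              call. = FALSE)
    if (fu <= 0)
      stop("layer_critical_diffusion: f_u <= 0, no classical two-species Turing instability",
           call. = FALSE)
    detJ <- fu * gv - fv * gu
    if (-fv * gu < 0)
      stop("layer_critical_diffusion: f_v * g_u > 0, cross terms do not form an activator-inhibitor pair",
           call. = FALSE)
    delta_c <- du * ((sqrt(detJ) + sqrt(-fv * gu)) / fu)^2
    xi_c <- (delta_c * fu + du * gv) / (2 * du * delta_c)
    return(list(delta_c = delta_c, xi_c = xi_c, method = "closed_form"))
  }

  # numeric branch: smallest delta in the window where min_xi det(xi D - J)
  # crosses zero
  min_det <- function(delta) {
    lay <- layer
    idx <- switch(delta_name, d_u = 1L, d_v = 2L, d_c = m, chi = NA_integer_,
                  stop(sprintf("layer_critical_diffusion: unknown parameter '%s'",
                               delta_name), call. = FALSE))
    if (delta_name == "chi") lay$chi <- delta else lay$diff_coef[idx] <- delta
    D <- diffusion_matrix(lay, equilibrium)
    detp <- function(xi) det(xi * D - J)
    # degree-m polynomial in xi via interpolation on Chebyshev nodes
    xs <- xi_max / 2 * (1 + cos(pi * (2 * seq_len(m + 1) - 1) / (2 * (m + 1))))
    V <- outer(xs, m:0, `^`)
    cf <- solve(V, vapply(xs, detp, numeric(1)))
    dcf <- cf[-(m + 1)] * (m:1)           # derivative coefficients
    rt <- polyroot(rev(dcf))
    cand <- Re(rt[abs(Im(rt)) < 1e-8 * (1 + abs(Re(rt)))])
    cand <- cand[cand > 0 & cand <= xi_max]
    vals <- vapply(cand, detp, numeric(1))
    best <- if (length(vals)) which.min(vals) else NA_integer_
    list(val = if (length(vals)) vals[best] else detp(xi_max),
         xi = if (length(vals)) cand[best] else xi_max)
  }
  grid <- exp(seq(log(delta_window[1]), log(delta_window[2]), length.out = 80))
  g <- vapply(grid, function(d) min_det(d)$val, numeric(1))
  sgn <- sign(g)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(cross))
    stop("layer_critical_diffusion: no sign change of the marginal determinant found in the search window",
         call. = FALSE)
  lo <- grid[cross[1]]; hi <- grid[cross[1] + 1]
  flo <- g[cross[1]]
  while ((hi - lo) > 1e-6 * lo) {
    mid <- sqrt(lo * hi)
    fm <- min_det(mid)$val
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  delta_c <- sqrt(lo * hi)
  list(delta_c = delta_c, xi_c = min_det(delta_c)$xi, method = "bisection")
}

# Newton solve of (a0, d a0/d xi) = 0 in (xi, delta) at fixed eta.
# Returns NULL on failure.
.critical_newton <- function(bilayer, eta, delta_name, xi, delta,
                             eq = NULL, tol = 1e-10, max_iter = 40L) {
  bil <- set_param(bilayer, "eta", eta)
  if (is.null(eq)) eq <- coupled_equilibrium(bil, eta)
  Fv <- function(x) {
    r <- a0_and_grad(bil, x[1], equilibrium = eq,
                     delta_name = delta_name, delta_value = x[2])
    c(r$a0, r$da0_dxi)
  }
  x <- c(xi, delta)
  scale <- max(abs(Fv(c(xi, delta * 1.25))), 1e-300)
  for (it in seq_len(max_iter)) {
    f0 <- Fv(x)
    if (max(abs(f0)) <= tol * scale &&
        it > 1) return(list(xi = x[1], delta = x[2], eq = eq))
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-6 * (1 + abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      Jm[, j] <- (Fv(xp) - Fv(xm)) / (2 * h)
    }
    dx <- tryCatch(solve(Jm, -f0), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) return(NULL)
    # keep xi (and a positive diffusion parameter) positive
    lam <- 1
    while (any(x + lam * dx <= 0 & x > 0) && lam > 1e-6) lam <- lam / 2
    x <- x + lam * dx
    if (max(abs(dx)) < 1e-12 * (1 + max(abs(x))))
      return(list(xi = x[1], delta = x[2], eq = eq))
  }
  f0 <- Fv(x)
  if (max(abs(f0)) <= 1e-6 * scale) list(xi = x[1], delta = x[2], eq = eq)
  else NULL
}

#' Critical point of the coupled dispersion relation
#'
#' Solves the marginal-bifurcation system \eqn{a_0(\xi_c, \delta_c) = 0},
#' \eqn{\partial_\xi a_0(\xi_c, \delta_c) = 0} for the coupled bilayer at
#' coupling strength `eta`, by Newton iteration in \eqn{(\xi, \delta)}
#' warm-started from the uncoupled classical value (or a supplied start).
#' When several local minima of \eqn{a_0} in \eqn{\xi} exist, each is
#' refined and the branch with the smallest \eqn{\delta_c} (the global
#' marginal onset) is returned, with all branches listed.
#'
#' @param bilayer A [bilayer_model()].
#' @param eta Coupling strength.
#' @param delta_name Bifurcation parameter name (see [set_param()]).
#' @param start Optional list with `xi` and `delta` warm-start values.
#' @param xi_grid Wavenumber grid used to enumerate candidate branches.
#' @return Object of class `critical_point`: list with `xi_c`, `delta_c`,
#'   `eta`, `branch_id`, `branches`.
#' @export
critical_point <- function(bilayer, eta, delta_name, start = NULL,
                           xi_grid = exp(seq(log(1e-4), log(1e2),
                                             length.out = 64))) {
  if (is.null(start)) {
    side <- if (grepl("S$", delta_name)) "surface" else "bulk"
    nm <- if (delta_name == "chi") "chi" else
      paste0("d_", sub("^d_([uvc]).*$", "\\1", delta_name))
    cp0 <- layer_critical_diffusion(bilayer[[side]], nm)
    start <- list(xi = cp0$xi_c, delta = cp0$delta_c)
  }
  bil <- set_param(bilayer, "eta", eta)
  eq <- coupled_equilibrium(bil, eta)

  # transversality at the uncoupled critical point: d2a0/dxi2 * da0/ddelta != 0
  sol <- .critical_newton(bilayer, eta, delta_name, start$xi, start$delta,
                          eq = eq)
  branches <- list()
  if (!is.null(sol)) branches[[1]] <- sol
  # enumerate additional xi-minima of a0 at the solved (or start) delta
  dref <- if (!is.null(sol)) sol$delta else start$delta
  da <- vapply(xi_grid, function(x)
    a0_and_grad(bil, x, equilibrium = eq, delta_name = delta_name,
                delta_value = dref)$da0_dxi, numeric(1))
  brks <- which(da[-length(da)] < 0 & da[-1] > 0)
  for (i in brks) {
    xi0 <- sqrt(xi_grid[i] * xi_grid[i + 1])
    if (!is.null(sol) && abs(log(xi0 / sol$xi)) < 0.5) next
    s2 <- .critical_newton(bilayer, eta, delta_name, xi0, dref, eq = eq)
    if (!is.null(s2) &&
        !any(vapply(branches, function(b)
          abs(b$xi - s2$xi) < 1e-6 * (1 + s2$xi), logical(1))))
      branches[[length(branches) + 1]] <- s2
  }
  if (!length(branches))
    stop("critical_point: Newton iteration did not converge from any branch",
         call. = FALSE)
  deltas <- vapply(branches, `[[`, numeric(1), "delta")
  best <- which.min(deltas)
  structure(list(xi_c = branches[[best]]$xi, delta_c = deltas[best],
                 eta = eta, branch_id = best,
                 branches = lapply(branches, function(b)
                   list(xi_c = b$xi, delta_c = b$delta))),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("<critical_point> eta = %g: delta_c = %.6g at xi_c = %.6g (branch %d of %d)\n",
              x$eta, x$delta_c, x$xi_c, x$branch_id, length(x$branches)))
  invisible(x)
}

#' Continue the marginal curve delta_c(eta)
#'
#' Natural continuation of [critical_point()] over a grid of coupling
#' strengths with warm starts from the previous point and adaptive step
#' refinement on Newton failure.
#'
#' @param bilayer A [bilayer_model()].
#' @param etas Increasing vector of coupling strengths.
#' @param delta_name Bifurcation parameter name.
#' @return Data frame with columns `eta`, `delta_c`, `xi_c`, `branch_id`.
#' @export
continue_critical_curve <- function(bilayer, etas, delta_name) {
  etas <- sort(unique(c(0, etas)))
  out <- vector("list", length(etas))
  start <- NULL
  prev_eta <- 0
  for (i in seq_along(etas)) {
    target <- etas[i]
    cp <- tryCatch(critical_point(bilayer, target, delta_name, start = start),
                   error = function(e) NULL)
    if (is.null(cp)) {
      # bridge with intermediate steps
      sub <- seq(prev_eta, target, length.out = 6)[-1]
      for (et in sub) {
        cp <- critical_point(bilayer, et, delta_name, start = start)
        start <- list(xi = cp$xi_c, delta = cp$delta_c)
      }
    }
    out[[i]] <- data.frame(eta = target, delta_c = cp$delta_c, xi_c = cp$xi_c,
                           branch_id = cp$branch_id)
    start <- list(xi = cp$xi_c, delta = cp$delta_c)
    prev_eta <- target
  }
  do.call(rbind, out)
}

#' First-order weak-coupling slope of the bifurcation curve
#'
#' Evaluates the first derivative \eqn{\delta_c'(0)} of the marginal curve
#' at zero coupling from the closed first-order formulas:
#' \deqn{\delta_c'(0) = -\frac{\mathrm{co}(P_0)\cdot A +
#'   u_S^{*\prime}(0)\cdot\nabla_{u^*}|P_0|}{\partial_\delta |P_0|}}
#' in the 1D-1D surface-driven case, with \eqn{(P_0, A, u_S^*)} replaced by
#' \eqn{(W_0, \tilde B, \tilde u_B^*)} in the bulk-driven case. In the
#' 1D-2D geometry the equilibrium term vanishes (shared equilibrium) and
#' the bulk-driven case carries the interface factor
#' \eqn{F_2(H, R_0)} in place of the hyperbolic cosine:
#' \eqn{\delta_c'(0) = -\mathrm{co}(W_0)\cdot(\tilde B F_2)/
#' \partial_\delta|W_0|} with \eqn{W_0 = D_B F_1(H, R_0)}.
#'
#' All quantities are evaluated at the uncoupled critical point
#' \eqn{(\xi_c(0), \delta_c(0))} of the driving layer; the equilibrium
#' gradient of the dispersion determinant is computed by central finite
#' differences through the analytic Jacobians.
#'
#' @param bilayer A [bilayer_model()].
#' @param case One of `"surface_1d1d"`, `"bulk_1d1d"`, `"surface_1d2d"`,
#'   `"bulk_1d2d"`.
#' @param delta_name Bifurcation parameter of the driving layer: `"d_u"`,
#'   `"d_v"`, `"d_c"` or `"chi"` (layer-local name).
#' @param crit Optional uncoupled critical point (list with `xi_c`,
#'   `delta_c`) to reuse.
#' @return The scalar slope \eqn{\delta_c'(0)}.
#' @export
weak_coupling_slope <- function(bilayer, case = c("surface_1d1d", "bulk_1d1d",
                                                  "surface_1d2d", "bulk_1d2d"),
                                delta_name = "d_v", crit = NULL) {
  case <- match.arg(case)
  surface_driven <- grepl("^surface", case)
  side <- if (surface_driven) "surface" else "bulk"
  lay <- bilayer[[side]]
  k <- lay$kinetics
  if (is.null(crit)) crit <- layer_critical_diffusion(lay, delta_name)
  xi_c <- crit$xi_c; delta_c <- crit$delta_c

  # layer with the bifurcation parameter pinned at its critical value
  lay_c <- lay
  if (delta_name == "chi") lay_c$chi <- delta_c else
    lay_c$diff_coef[switch(delta_name, d_u = 1L, d_v = 2L, d_c = k$n_species)] <-
      delta_c

  eq0 <- coupled_equilibrium(bilayer, 0)
  ustar <- if (surface_driven) eq0$u_S else eq0$u_B

  # det(xi D(u) - J(u)) as a function of the equilibrium state
  det_at <- function(u, dd = NULL) {
    lc <- lay_c
    if (!is.null(dd)) {
      if (delta_name == "chi") lc$chi <- dd else
        lc$diff_coef[switch(delta_name, d_u = 1L, d_v = 2L,
                            d_c = k$n_species)] <- dd
    }
    if (case == "bulk_1d2d") {
      D <- diffusion_matrix(lc, u)
      R0 <- xi_c * diag(1, k$n_species) - solve(D, k$jacobian(u))
      det(D %*% matrix_entire_functions(bilayer$geometry$H, R0)$F1)
    } else {
      det(xi_c * diffusion_matrix(lc, u) - k$jacobian(u))
    }
  }

  # marginal dispersion block of the driving layer
  D_c <- diffusion_matrix(lay_c, ustar)
  Jl <- k$jacobian(ustar)
  exch <- if (surface_driven) bilayer$A else pad_tilde(bilayer$B, bilayer$m)

  if (case == "bulk_1d2d") {
    H <- bilayer$geometry$H
    R0 <- xi_c * diag(1, k$n_species) - solve(D_c, Jl)
    Fs <- matrix_entire_functions(H, R0)
    W0 <- D_c %*% Fs$F1
    num <- mat_dot(comatrix(W0), exch %*% Fs$F2)
    h <- 1e-6 * (1 + abs(delta_c))
    den <- (det_at(ustar, delta_c + h) - det_at(ustar, delta_c - h)) / (2 * h)
    return(-num / den)
  }

  P0 <- xi_c * D_c - Jl
  coP <- comatrix(P0)
  num <- mat_dot(coP, exch)
  # asymmetric-equilibria contribution (1D-1D only)
  sens <- equilibrium_sensitivity(bilayer, eq0)
  dU <- if (surface_driven) sens$dU_S else sens$dU_B
  if (max(abs(dU)) > 0) {
    grad <- vapply(seq_along(ustar), function(j) {
      h <- 1e-6 * (1 + abs(ustar[j]))
      up <- ustar; up[j] <- up[j] + h
      um <- ustar; um[j] <- um[j] - h
      (det_at(up) - det_at(um)) / (2 * h)
    }, numeric(1))
    num <- num + sum(dU * grad)
  }
  # d/d delta of the layer determinant via Jacobi's formula
  dD <- matrix(0, k$n_species, k$n_species)
  if (delta_name == "chi") {
    dD[k$n_species, lay$k_index] <- -ustar[k$n_species]  # d/dchi of -chi*c*k_u
  } else {
    idx <- switch(delta_name, d_u = 1L, d_v = 2L, d_c = k$n_species)
    dD[idx, idx] <- 1
  }
  den <- mat_dot(coP, xi_c * dD)
  if (abs(den) < 1e-14 * max(1, abs(num)))
    stop("weak_coupling_slope: degenerate transversality (d|P0|/d delta = 0)",
         call. = FALSE)
  -num / den
}

#' Strong-coupling reduction and asymptotic critical parameter
#'
#' In the limit of large coupling the two layers equilibrate to their
#' common average and the bilayer reduces to the single cross-diffusion
#' system
#' \deqn{(A^{-1} + B^{-1})\,\partial_t u = A^{-1} f_S + B^{-1} f_B +
#'  \nabla\cdot\big((A^{-1} D_S + B^{-1} D_B)\nabla u\big).}
#' For two-species layers with equal activator diffusion
#' \eqn{d_{u_S} = d_{u_B}} and `A = B` the asymptotic critical inhibitor
#' diffusion in the surface is
#' \eqn{\delta_c(\infty) = 2\,\delta_c[(f_S + f_B)/2] - d_{v_B}}. When the
#' averaged kinetics fail the Turing preconditions (e.g. mass-conserving
#' layers with \eqn{f_S = -f_B}, for which the reduced reactions vanish),
#' `delta_c_infinity` is `NA` with an explanatory attribute.
#'
#' @param bilayer A [bilayer_model()] with equally many species per layer
#'   and invertible exchange matrices.
#' @return List with `kinetics` (the reduced [kinetics_model()]),
#'   `diffusion` (reduced diffusion matrix at the averaged equilibrium),
#'   `mass_matrix` (\eqn{A^{-1} + B^{-1}}), and `delta_c_infinity`.
#' @export
strong_coupling_limit <- function(bilayer) {
  n <- bilayer$n; m <- bilayer$m
  if (m != n)
    stop("strong_coupling_limit: requires equal species counts (m = n)",
         call. = FALSE)
  A <- bilayer$A; B <- bilayer$B
  for (M in list(A, B))
    if (abs(det(M)) < 1e-14)
      stop("strong_coupling_limit: singular exchange matrix", call. = FALSE)
  if (any(Re(eigen(A + B, only.values = TRUE)$values) < -1e-12))
    stop("strong_coupling_limit: A + B must have eigenvalues with nonnegative real part",
         call. = FALSE)
  Ai <- solve(A); Bi <- solve(B)
  kS <- bilayer$surface$kinetics; kB <- bilayer$bulk$kinetics
  red <- kinetics_model(
    n, list(),
    rates = function(w) drop(Ai %*% kS$rates(w) + Bi %*% kB$rates(w)),
    jacobian = function(w) Ai %*% kS$jacobian(w) + Bi %*% kB$jacobian(w),
    label = "strong_coupling_reduced")
  mass <- Ai + Bi

  delta_inf <- NA_real_
  msg <- NULL
  same_AB <- max(abs(A - B)) < 1e-12
  du_equal <- abs(bilayer$surface$diff_coef[1] - bilayer$bulk$diff_coef[1]) < 1e-12
  if (n == 2L && same_AB && du_equal && is.null(bilayer$bulk$chi)) {
    avg <- kinetics_average(kS, kB)
    eqavg <- tryCatch(
      find_equilibrium(avg, (.default_guess(kS) + .default_guess(kB)) / 2),
      error = function(e) NULL)
    if (is.null(eqavg) || max(abs(avg$rates(eqavg))) > 1e-8) {
      msg <- "no finite critical value: averaged kinetics have no equilibrium"
    } else {
      lav <- layer_model(avg, c(bilayer$surface$diff_coef[1], 1))
      cpav <- tryCatch(layer_critical_diffusion(lav, "d_v",
                                                equilibrium = eqavg),
                       error = function(e) e)
      if (inherits(cpav, "error")) {
        msg <- paste("no finite critical value:", conditionMessage(cpav))
      } else {
        delta_inf <- 2 * cpav$delta_c - bilayer$bulk$diff_coef[2]
      }
    }
  }
  diff_red <- tryCatch({
    eqr <- find_equilibrium(red, (.default_guess(kS) + .default_guess(kB)) / 2)
    Ai %*% diffusion_matrix(bilayer$surface, eqr) +
      Bi %*% diffusion_matrix(bilayer$bulk, pad_vec(eqr, m))
  }, error = function(e) Ai %*% diag(bilayer$surface$diff_coef, n) +
       Bi %*% diag(bilayer$bulk$diff_coef[seq_len(n)], n))
  structure(list(kinetics = red, diffusion = diff_red, mass_matrix = mass,
                 delta_c_infinity = delta_inf, note = msg),
            class = "strong_coupling_limit")
}

#' Midpoint-convexity verdict for strong coupling
#'
#' Compares the critical inhibitor diffusion of the averaged kinetics with
#' the average of the layer-wise critical diffusions. Strict midpoint
#' convexity of \eqn{\delta_c} (average below the midpoint) means two
#' independently non-patterning layers can pattern under strong coupling;
#' strict midpoint concavity means two independently patterning layers can
#' be stabilised; equality (within tolerance) allows neither.
#'
#' @param f_S,f_B Two-species [kinetics_model()] objects.
#' @param tol Absolute equality tolerance on the \eqn{\delta_c} scale.
#' @return One of `"strong_coupling_can_pattern"`,
#'   `"strong_coupling_can_stabilize"`, `"neither"`.
#' @export
midpoint_convexity_verdict <- function(f_S, f_B, tol = 1e-9) {
  dc <- function(k, guess) {
    eq <- find_equilibrium(k, guess)
    layer_critical_diffusion(layer_model(k, c(1, 1)), "d_v",
                             equilibrium = eq)$delta_c
  }
  dS <- dc(f_S, .default_guess(f_S))
  dB <- dc(f_B, .default_guess(f_B))
  avg <- kinetics_average(f_S, f_B)
  dA <- dc(avg, (.default_guess(f_S) + .default_guess(f_B)) / 2)
  diffm <- dA - (dS + dB) / 2
  if (diffm > tol) "strong_coupling_can_stabilize"
  else if (diffm < -tol) "strong_coupling_can_pattern"
  else "neither"
}

#' Instability band of the homogeneous mode under coupling
#'
#' Two identical two-species layers with shared Jacobian `J`, coupled by
#' `A = B = diag(alpha, beta)`, can lose stability of the spatially
#' homogeneous mode \eqn{\xi = 0} for intermediate coupling: the mode is
#' unstable exactly for \eqn{\eta} between the real roots of
#' \deqn{4\alpha\beta\,\eta^2 - 2(\alpha g_v + \beta f_u)\,\eta + |J|.}
#' (The coupled \eqn{\xi = 0} eigenvalues are those of `J` and of
#' `J - 2 eta A`.)
#'
#' @param J 2x2 Jacobian of the shared kinetics at equilibrium.
#' @param alpha,beta Nonnegative exchange rates of the two species.
#' @return List with `coefficients` (quadratic, leading first) and `roots`
#'   (increasing real roots, or `numeric(0)` when the discriminant is
#'   negative).
#' @export
homogeneous_mode_band <- function(J, alpha, beta) {
  stopifnot(all(dim(J) == c(2, 2)))
  fu <- J[1, 1]; gv <- J[2, 2]
  coefs <- c(4 * alpha * beta, -2 * (alpha * gv + beta * fu), det(J))
  if (alpha * beta == 0) {
    warning("homogeneous_mode_band: alpha * beta = 0, quadratic degenerates")
    if (coefs[2] != 0) {
      r <- -coefs[3] / coefs[2]
      return(list(coefficients = coefs,
                  roots = if (r > 0) r else numeric(0)))
    }
    return(list(coefficients = coefs, roots = numeric(0)))
  }
  disc <- coefs[2]^2 - 4 * coefs[1] * coefs[3]
  roots <- if (disc > 0)
    sort((-coefs[2] + c(-1, 1) * sqrt(disc)) / (2 * coefs[1]))
  else numeric(0)
  list(coefficients = coefs, roots = roots)
}

#' Instability region raster in the (eta, delta) plane
#'
#' For every grid cell the coupled equilibrium is recomputed, the
#' bifurcation parameter overridden, and the discrete modes scanned with
#' the Routh-Hurwitz criterion; a cell is unstable when any mode
#' \eqn{q \in \{0, \dots, q_{max}\}} is.
#'
#' @param bilayer A [bilayer_model()] (1D-1D geometry).
#' @param eta_grid,delta_grid Grid vectors.
#' @param delta_name Bifurcation parameter name (see [set_param()]).
#' @param L Domain length for the discrete modes \eqn{k_q = q\pi/L}.
#' @param q_max Largest mode index.
#' @return Object of class `instability_region`: list with the grids, a
#'   logical `unstable` matrix (rows: eta, columns: delta), a logical
#'   `valid` matrix, and the scan settings.
#' @export
instability_region <- function(bilayer, eta_grid, delta_grid, delta_name,
                               L, q_max) {
  if (bilayer$geometry$type != "1d1d")
    stop("instability_region: polynomial dispersion requires the 1d1d geometry",
         call. = FALSE)
  ne <- length(eta_grid); nd <- length(delta_grid)
  unstable <- matrix(FALSE, ne, nd)
  valid <- matrix(TRUE, ne, nd)
  for (i in seq_len(ne)) {
    eta <- eta_grid[i]
    bil_eta <- set_param(bilayer, "eta", eta)
    eq <- tryCatch(coupled_equilibrium(bil_eta, eta), error = function(e) NULL)
    if (is.null(eq)) { valid[i, ] <- FALSE; next }
    for (j in seq_len(nd)) {
      bil <- set_param(bil_eta, delta_name, delta_grid[j])
      lin <- build_linearization(bil, eq)
      unstable[i, j] <- length(mode_scan(lin, L, q_max)) > 0
    }
  }
  structure(list(eta_grid = eta_grid, delta_grid = delta_grid,
                 unstable = unstable, valid = valid,
                 mode_L = L, q_max = q_max),
            class = "instability_region")
}
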