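#' Piecewise-linear clip function
#'
#' Returns the continuous piecewise-linear function
#' \eqn{\phi(\zeta) = \max(0, \min(\zeta, M))}, used by the pseudo-linear
#' kinetics presets to keep reaction rates bounded: the clip guarantees
#' positivity of solutions and prevents blow-up while acting as the identity
#' on the linear branch \eqn{(0, M)} where the equilibrium lives.
#'
#' @param M Positive real cap.
#' @return A vectorised function of one argument with attribute `M`.
#' @examples
#' phi <- clip_function(10)
#' phi(c(-1, 0.5, 42))
#' @export
clip_function <- function(M) {
  stopifnot(is.numeric(M), length(M) == 1L, M > 0)
  f <- function(zeta) pmax(0, pmin(zeta, M))
  attr(f, "M") <- M
  f
}

#' Construct a reaction-kinetics model
#'
#' Low-level constructor bundling a rate function, its analytic Jacobian and
#' a parameter record. Most users should call [make_preset()] instead.
#'
#' @param n_species Number of interacting species.
#' @param params Named list of real parameters.
#' @param rates Function mapping a state vector (or a species-by-cell state
#'   matrix, applied columnwise) to the reaction rate vector.
#' @param jacobian Function mapping a state vector to the
#'   `n_species x n_species` Jacobian matrix of `rates`.
#' @param label Preset identifier string.
#' @return An object of class `kinetics_model`.
#' @export
kinetics_model <- function(n_species, params, rates, jacobian, label = "custom") {
  stopifnot(n_species >= 1, is.function(rates), is.function(jacobian))
  structure(
    list(n_species = as.integer(n_species), params = params,
         rates = rates, jacobian = jacobian, label = label),
    class = "kinetics_model")
}

#' @export
print.kinetics_model <- function(x, ...) {
  cat("<kinetics_model>", x$label, "with", x$n_species, "species\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

.require_params <- function(params, keys, preset) {
  missing <- setdiff(keys, names(params))
  if (length(missing))
    stop(sprintf("preset '%s': missing parameter(s) %s", preset,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Named reaction-kinetics presets
#'
#' Builds one of the reaction systems used throughout the package:
#'
#' * `"schnakenberg"`: the two-species activator-depletion system
#'   \eqn{f = s(a - u + u^2 v)}, \eqn{g = s(b - u^2 v)} with
#'   \eqn{0 < a < b}, \eqn{s > 0}. Equilibrium \eqn{u^* = a + b},
#'   \eqn{v^* = b/(a+b)^2}.
#' * `"pseudo_linear_surface"`: two signalling species produced
#'   autocatalytically by a fixed density of surface cells,
#'   \eqn{f = \phi(a_0 + a_1 u - b v) - a_2 u},
#'   \eqn{g = \phi(b_0 + c_1 v + d u) - c_2 v}, where \eqn{\phi} is the
#'   clip function with cap `M`.
#' * `"pseudo_linear_bulk"`: the three-species bulk analogue in which the
#'   chemicals are produced by chemotactic cells `c` without feedback,
#'   \eqn{f = \phi(a_0 + a_1 c - b v) - a_2 u},
#'   \eqn{g = \phi(b_0 + (c_1 + d) c) - c_2 v},
#'   \eqn{r = r_0 c (c^* - c)}. State ordering is `(u, v, c)`.
#' * `"keller_segel_linear"`: chemoattractant `u` plus cells `c` with
#'   \eqn{f = a c - b u}, \eqn{r = c(c^* - c)}. State ordering `(u, c)`.
#' * `"jp_family"`: the one-parameter linearised family whose Jacobian at
#'   the origin is \eqn{[[1, -1], [p, 1 - p]]}; its critical inhibitor
#'   diffusion has the closed form \eqn{1 + p + 2\sqrt{p}}.
#' * `"gierer_meinhardt"`: classical activator-inhibitor kinetics
#'   \eqn{f = a - b u + u^2/v}, \eqn{g = u^2 - v}, provided for
#'   convexity-criterion experiments.
#'
#' Pseudo-linear presets accept an optional cap `M`; the default is ten
#' times the largest image of the linear branch at equilibrium, large
#' enough that the kinetics act linearly around the equilibrium.
#'
#' @param name Preset identifier (see above).
#' @param params Named list of preset parameters.
#' @return A [kinetics_model()].
#' @examples
#' k <- make_preset("schnakenberg", list(a = 0.2305, b = 0.7695, s = 1))
#' k$rates(c(1, 0.7695))   # equilibrium: both rates vanish
#' @export
make_preset <- function(name, params = list()) {
  params <- as.list(params)
  switch(name,
    schnakenberg = .preset_schnakenberg(params),
    pseudo_linear_surface = .preset_pl_surface(params),
    pseudo_linear_bulk = .preset_pl_bulk(params),
    keller_segel_linear = .preset_keller_segel(params),
    jp_family = .preset_jp(params),
    gierer_meinhardt = .preset_gm(params),
    stop(sprintf("unknown preset '%s'", name), call. = FALSE))
}

.preset_schnakenberg <- function(p) {
  .require_params(p, c("a", "b", "s"), "schnakenberg")
  a <- p$a; b <- p$b; s <- p$s
  if (!(a > 0 && a < b)) stop("schnakenberg: need 0 < a < b", call. = FALSE)
  if (!(s > 0)) stop("schnakenberg: need s > 0", call. = FALSE)
  rates <- function(w) {
    mat <- is.matrix(w)
    u <- if (mat) w[1L, ] else w[1L]; v <- if (mat) w[2L, ] else w[2L]
    if (mat) rbind(s * (a - u + u^2 * v), s * (b - u^2 * v))
    else c(s * (a - u + u^2 * v), s * (b - u^2 * v))
  }
  jacobian <- function(w) {
    u <- w[1L]; v <- w[2L]
    matrix(c(s * (-1 + 2 * u * v), s * u^2,
             -2 * s * u * v,       -s * u^2), 2L, 2L, byrow = TRUE)
  }
  kinetics_model(2L, list(a = a, b = b, s = s), rates, jacobian, "schnakenberg")
}

.preset_gm <- function(p) {
  .require_params(p, c("a", "b"), "gierer_meinhardt")
  a <- p$a; b <- p$b
  if (!(b > 0)) stop("gierer_meinhardt: need b > 0", call. = FALSE)
  rates <- function(w) {
    mat <- is.matrix(w)
    u <- if (mat) w[1L, ] else w[1L]; v <- if (mat) w[2L, ] else w[2L]
    if (mat) rbind(a - b * u + u^2 / v, u^2 - v)
    else c(a - b * u + u^2 / v, u^2 - v)
  }
  jacobian <- function(w) {
    u <- w[1L]; v <- w[2L]
    matrix(c(-b + 2 * u / v, -u^2 / v^2,
             2 * u,          -1), 2L, 2L, byrow = TRUE)
  }
  kinetics_model(2L, list(a = a, b = b), rates, jacobian, "gierer_meinhardt")
}

# equilibrium image of the linear production branches, used to size the cap M
.pl_default_cap <- function(images) 10 * max(images, 1)

.clip_warn_jacobian <- function(z, M, label) {
  if (any(z <= 0 | z >= M))
    warning(sprintf("%s: Jacobian evaluated on a clipped branch (phi' = 0); ",
                    label),
            "linearisation is only meaningful on the linear branch",
            call. = FALSE)
}

.preset_pl_surface <- function(p) {
  keys <- c("a0", "a1", "b", "a2", "b0", "c1", "d", "c2")
  .require_params(p, keys, "pseudo_linear_surface")
  for (k in keys) if (p[[k]] < 0)
    stop(sprintf("pseudo_linear_surface: parameter %s must be >= 0", k),
         call. = FALSE)
  a0 <- p$a0; a1 <- p$a1; b <- p$b; a2 <- p$a2
  b0 <- p$b0; c1 <- p$c1; d <- p$d; c2 <- p$c2
  # equilibrium of the linear branch: (a1-a2) u - b v = -a0 ; d u + (c1-c2) v = -b0
  Alin <- matrix(c(a1 - a2, -b, d, c1 - c2), 2L, 2L, byrow = TRUE)
  eq <- tryCatch(solve(Alin, c(-a0, -b0)), error = function(e) c(1, 1))
  M <- if (!is.null(p$M)) p$M else
    .pl_default_cap(c(a0 + a1 * eq[1] - b * eq[2], b0 + c1 * eq[2] + d * eq[1]))
  phi <- clip_function(M)
  rates <- function(w) {
    mat <- is.matrix(w)
    u <- if (mat) w[1L, ] else w[1L]; v <- if (mat) w[2L, ] else w[2L]
    r1 <- phi(a0 + a1 * u - b * v) - a2 * u
    r2 <- phi(b0 + c1 * v + d * u) - c2 * v
    if (mat) rbind(r1, r2) else c(r1, r2)
  }
  jacobian <- function(w) {
    u <- w[1L]; v <- w[2L]
    .clip_warn_jacobian(c(a0 + a1 * u - b * v, b0 + c1 * v + d * u), M,
                        "pseudo_linear_surface")
    matrix(c(a1 - a2, -b, d, c1 - c2), 2L, 2L, byrow = TRUE)
  }
  kinetics_model(2L, c(p[keys], list(M = M)), rates, jacobian,
                 "pseudo_linear_surface")
}

.preset_pl_bulk <- function(p) {
  keys <- c("a0", "a1", "b", "a2", "b0", "c1", "d", "c2", "r0", "cstar")
  .require_params(p, keys, "pseudo_linear_bulk")
  a0 <- p$a0; a1 <- p$a1; b <- p$b; a2 <- p$a2
  b0 <- p$b0; c1 <- p$c1; d <- p$d; c2 <- p$c2
  r0 <- p$r0; cstar <- p$cstar
  if (r0 <= 0 || cstar <= 0)
    stop("pseudo_linear_bulk: need r0 > 0 and cstar > 0", call. = FALSE)
  # both production terms read the cell density c; equilibrium at c = cstar
  veq <- (b0 + (c1 + d) * cstar) / c2
  ueq <- (a0 + a1 * cstar - b * veq) / a2
  M <- if (!is.null(p$M)) p$M else
    .pl_default_cap(c(a0 + a1 * cstar - b * veq, b0 + (c1 + d) * cstar))
  phi <- clip_function(M)
  rates <- function(w) {
    mat <- is.matrix(w)
    u <- if (mat) w[1L, ] else w[1L]
    v <- if (mat) w[2L, ] else w[2L]
    cc <- if (mat) w[3L, ] else w[3L]
    r1 <- phi(a0 + a1 * cc - b * v) - a2 * u
    r2 <- phi(b0 + (c1 + d) * cc) - c2 * v
    r3 <- r0 * cc * (cstar - cc)
    if (mat) rbind(r1, r2, r3) else c(r1, r2, r3)
  }
  jacobian <- function(w) {
    v <- w[2L]; cc <- w[3L]
    .clip_warn_jacobian(c(a0 + a1 * cc - b * v, b0 + (c1 + d) * cc), M,
                        "pseudo_linear_bulk")
    matrix(c(-a2, -b, a1,
             0, -c2, c1 + d,
             0, 0, r0 * (cstar - 2 * cc)), 3L, 3L, byrow = TRUE)
  }
  kinetics_model(3L, c(p[keys], list(M = M)), rates, jacobian,
                 "pseudo_linear_bulk")
}

.preset_keller_segel <- function(p) {
  .require_params(p, c("a", "b", "cstar"), "keller_segel_linear")
  a <- p$a; b <- p$b; cstar <- p$cstar
  if (a <= 0 || b <= 0 || cstar <= 0)
    stop("keller_segel_linear: need a, b, cstar > 0", call. = FALSE)
  rates <- function(w) {
    mat <- is.matrix(w)
    u <- if (mat) w[1L, ] else w[1L]; cc <- if (mat) w[2L, ] else w[2L]
    if (mat) rbind(a * cc - b * u, cc * (cstar - cc))
    else c(a * cc - b * u, cc * (cstar - cc))
  }
  jacobian <- function(w) {
    cc <- w[2L]
    matrix(c(-b, a, 0, cstar - 2 * cc), 2L, 2L, byrow = TRUE)
  }
  kinetics_model(2L, list(a = a, b = b, cstar = cstar), rates, jacobian,
                 "keller_segel_linear")
}

.preset_jp <- function(p) {
  .require_params(p, "p", "jp_family")
  pp <- p$p
  if (pp <= 1) stop("jp_family: need p > 1", call. = FALSE)
  J <- matrix(c(1, -1, pp, 1 - pp), 2L, 2L, byrow = TRUE)
  rates <- function(w) {
    if (is.matrix(w)) J %*% w else drop(J %*% w)
  }
  jacobian <- function(w) J
  kinetics_model(2L, list(p = pp), rates, jacobian, "jp_family")
}

#' Finite-difference Jacobian of a rate function
#'
#' Central-difference Jacobian, used in the test-suite as an independent
#' oracle for the analytic Jacobians of the presets.
#'
#' @param rates Rate function (vector to vector).
#' @param w State vector.
#' @param h Relative step.
#' @return Square Jacobian matrix.
#' @export
fd_jacobian <- function(rates, w, h = 1e-6) {
  n <- length(w)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dw <- h * (1 + abs(w[j]))
    wp <- w; wp[j] <- wp[j] + dw
    wm <- w; wm[j] <- wm[j] - dw
    J[, j] <- (rates(wp) - rates(wm)) / (2 * dw)
  }
  J
}

#' Newton solver for a homogeneous single-layer equilibrium
#'
#' Solves \eqn{f(w) = 0} by Newton iteration with the analytic Jacobian.
#'
#' @param model A [kinetics_model()].
#' @param guess Initial state, in the interior of the admissible region
#'   (for clipped kinetics, strictly on the linear branch).
#' @param tol Residual tolerance, relative to `1 + ||w||`.
#' @param max_iter Iteration budget.
#' @return Equilibrium state vector.
#' @examples
#' k <- make_preset("schnakenberg", list(a = 0.15, b = 0.2, s = 0.5))
#' find_equilibrium(k, c(0.3, 1.5))  # (0.35, 0.2/0.35^2)
#' @export
find_equilibrium <- function(model, guess, tol = 1e-12, max_iter = 100L) {
  w <- as.numeric(guess)
  stopifnot(length(w) == model$n_species)
  for (it in seq_len(max_iter)) {
    r <- model$rates(w)
    if (max(abs(r)) <= tol * (1 + sqrt(sum(w^2)))) return(w)
    J <- model$jacobian(w)
    if (!all(is.finite(J)) || abs(det(J)) < 1e-14 * max(1, max(abs(J)))^length(w))
      stop("find_equilibrium: singular Jacobian at iterate", call. = FALSE)
    step <- solve(J, -r)
    # damped update so clipped kinetics stay on the linear branch
    lam <- 1
    repeat {
      wn <- w + lam * step
      rn <- tryCatch(model$rates(wn), warning = function(w_) model$rates(wn))
      if (max(abs(rn)) < max(abs(r)) || lam < 1e-4) break
      lam <- lam / 2
    }
    w <- wn
  }
  r <- model$rates(w)
  if (max(abs(r)) <= tol * (1 + sqrt(sum(w^2)))) return(w)
  stop("find_equilibrium: no convergence within iteration budget",
       call. = FALSE)
}

#' Pointwise average of two kinetics models
#'
#' Returns the kinetics \eqn{(f_1 + f_2)/2}, the reaction term of the
#' reduced one-layer system that governs the strong-coupling limit of two
#' layers exchanging species at equal rates.
#'
#' @param k1,k2 Two [kinetics_model()] objects with equal species count.
#' @return A [kinetics_model()] labelled `"average"`.
#' @export
kinetics_average <- function(k1, k2) {
  stopifnot(k1$n_species == k2$n_species)
  kinetics_model(
    k1$n_species, list(),
    rates = function(w) (k1$rates(w) + k2$rates(w)) / 2,
    jacobian = function(w) (k1$jacobian(w) + k2$jacobian(w)) / 2,
    label = sprintf("average(%s,%s)", k1$label, k2$label))
}
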