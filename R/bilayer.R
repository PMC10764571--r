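#' Single-layer model: kinetics plus (cross-)diffusion
#'
#' Couples a [kinetics_model()] with its diffusion coefficients. Chemotaxis
#' is encoded as a state-dependent lower-triangular block of the diffusion
#' matrix: the cell species (by convention the last one) drifts up gradients
#' of the chemoattractant with flux \eqn{-\nabla\cdot(h(c)\nabla k(u))},
#' where \eqn{h(c) = \chi c} and \eqn{k(u) = u_{k}} selects one chemical
#' species. The resulting diffusion matrix carries the row
#' \eqn{(-h(c^*) \nabla k^T, d_c)} for the cell equation.
#'
#' @param kinetics A [kinetics_model()].
#' @param diff_coef Named or plain numeric vector of diagonal diffusion
#'   coefficients, one per species.
#' @param chi Chemotaxis strength \eqn{\chi} (default `NULL`: pure
#'   reaction-diffusion).
#' @param k_index Index of the chemoattractant species in \eqn{k(u)}
#'   (default 1).
#' @return Object of class `layer_model`.
#' @export
layer_model <- function(kinetics, diff_coef, chi = NULL, k_index = 1L) {
  n <- kinetics$n_species
  stopifnot(length(diff_coef) == n, all(diff_coef > 0))
  if (!is.null(chi)) stopifnot(n >= 2, k_index < n)
  structure(list(kinetics = kinetics, diff_coef = as.numeric(diff_coef),
                 chi = chi, k_index = as.integer(k_index)),
            class = "layer_model")
}

#' Diffusion matrix of a layer evaluated at a state
#'
#' @param layer A [layer_model()].
#' @param state State vector at which the (possibly state-dependent)
#'   cross-diffusion matrix is evaluated; only needed for chemotaxis.
#' @return `n x n` diffusion matrix.
#' @export
diffusion_matrix <- function(layer, state = NULL) {
  n <- layer$kinetics$n_species
  D <- diag(layer$diff_coef, n, n)
  if (!is.null(layer$chi)) {
    cc <- state[n]
    D[n, layer$k_index] <- -layer$chi * cc   # -h(c) k_u with h(c) = chi*c, k_u = 1
  }
  D
}

#' Coupled bilayer model
#'
#' A surface layer with `n` species and a bulk layer with `m >= n` species,
#' exchanging their first `n` species linearly across the interface with
#' strength `eta`: the surface receives \eqn{\eta A(\tilde u_B - u_S)} and
#' the bulk \eqn{\eta \tilde B(\tilde u_S - u_B)}, where \eqn{\tilde B} is
#' `B` zero-padded to `m x m`.
#'
#' @param surface,bulk [layer_model()] objects; the bulk must have at least
#'   as many species as the surface.
#' @param A,B `n x n` exchange-rate matrices (into the surface and into the
#'   bulk respectively). Scalars and vectors are promoted to diagonal
#'   matrices.
#' @param eta Nonnegative coupling strength.
#' @param geometry Either `geometry_1d1d(L)` or `geometry_1d2d(L, H)`.
#' @return Object of class `bilayer_model`.
#' @export
bilayer_model <- function(surface, bulk, A, B = A, eta = 0,
                          geometry = geometry_1d1d(100)) {
  n <- surface$kinetics$n_species
  m <- bulk$kinetics$n_species
  if (m < n) stop("bilayer_model: bulk must have at least as many species as the surface (m >= n)",
                  call. = FALSE)
  A <- .as_square(A, n); B <- .as_square(B, n)
  stopifnot(eta >= 0)
  structure(list(surface = surface, bulk = bulk, A = A, B = B,
                 eta = eta, geometry = geometry, n = n, m = m),
            class = "bilayer_model")
}

.as_square <- function(M, n) {
  if (is.matrix(M)) {
    stopifnot(nrow(M) == n, ncol(M) == n)
    return(M)
  }
  if (length(M) == 1L) return(diag(as.numeric(M), n, n))
  stopifnot(length(M) == n)
  diag(as.numeric(M), n, n)
}

#' @rdname bilayer_model
#' @param L Domain length along the interface.
#' @export
geometry_1d1d <- function(L) {
  stopifnot(L > 0)
  structure(list(type = "1d1d", L = L), class = "bilayer_geometry")
}

#' @rdname bilayer_model
#' @param H Bulk depth (1D-2D geometry only).
#' @export
geometry_1d2d <- function(L, H) {
  stopifnot(L > 0, H > 0)
  structure(list(type = "1d2d", L = L, H = H), class = "bilayer_geometry")
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat(sprintf("<bilayer_model> %s surface (%d sp.) / %s bulk (%d sp.), eta = %g, %s\n",
              x$surface$kinetics$label, x$n, x$bulk$kinetics$label, x$m,
              x$eta, x$geometry$type))
  invisible(x)
}

# zero-pad B (n x n) into an m x m matrix acting on the first n bulk species
pad_tilde <- function(B, m) {
  n <- nrow(B)
  Bt <- matrix(0, m, m)
  Bt[seq_len(n), seq_len(n)] <- B
  Bt
}

# pad an n-vector with zeros to length m
pad_vec <- function(v, m) c(v, rep(0, m - length(v)))

#' Override one scalar model parameter of a bilayer
#'
#' Parameter-override hook used to treat any diffusion coefficient or the
#' chemotaxis strength as the bifurcation parameter. Recognised names follow
#' the pattern `d_<species><layer>` for diagonal diffusion coefficients,
#' e.g. `"d_vS"` (surface species 2), `"d_uB"` (bulk species 1), `"d_cB"` or
#' `"d_c"` (bulk cell species), plus `"chi"` (bulk chemotaxis strength) and
#' `"eta"`. Species letters map to indices as `u = 1`, `v = 2`, `c` = last
#' bulk species.
#'
#' @param bilayer A [bilayer_model()].
#' @param name Parameter name.
#' @param value New value.
#' @return The modified bilayer model.
#' @export
set_param <- function(bilayer, name, value) {
  if (name == "eta") {
    bilayer$eta <- value
    return(bilayer)
  }
  if (name == "chi") {
    if (is.null(bilayer$bulk$chi))
      stop("set_param: bulk layer has no chemotaxis term", call. = FALSE)
    bilayer$bulk$chi <- value
    return(bilayer)
  }
  mm <- regmatches(name, regexec("^d_([uvc])([SB]?)$", name))[[1]]
  if (length(mm) == 0L)
    stop(sprintf("set_param: unknown parameter name '%s'", name), call. = FALSE)
  sp <- mm[2]; side <- mm[3]
  if (sp == "c" || side == "B" || side == "") {
    layer <- "bulk"
  }
  if (side == "S") layer <- "surface"
  if (sp == "c" && side == "S")
    stop("set_param: the cell species lives in the bulk", call. = FALSE)
  idx <- switch(sp, u = 1L, v = 2L,
                c = bilayer$bulk$kinetics$n_species)
  if (idx > bilayer[[layer]]$kinetics$n_species)
    stop(sprintf("set_param: layer has no species for '%s'", name),
         call. = FALSE)
  bilayer[[layer]]$diff_coef[idx] <- value
  bilayer
}
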