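#' Simulation configuration
#'
#' Settings for the method-of-lines integrator: grid sizes, time step,
#' final time, seeded initial noise and output cadence. Time integration is
#' first-order IMEX: diffusion implicit (tridiagonal solves, dimensional
#' splitting in 2D), reactions, inter-layer exchange and chemotaxis
#' explicit. The initial condition is the homogeneous equilibrium perturbed
#' multiplicatively by uniform noise in `[-1, 1] * init_noise`.
#'
#' @param N_x Number of grid cells along the interface.
#' @param N_y Number of cells through the bulk depth (1D-2D geometry).
#' @param dt Time step; halved automatically (up to 4 times) when blow-up
#'   is detected.
#' @param t_final Final integration time.
#' @param seed Integer seed for the initial noise.
#' @param init_noise Relative amplitude of the initial perturbation.
#' @param output_every Time interval between stored snapshots.
#' @param steady_tol Quasi-steady-state criterion: maximum relative field
#'   change per unit time below which integration stops early.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(N_x = 128L, N_y = NULL, dt = 1e-2, t_final = 100,
                       seed = 1L, init_noise = 1e-2, output_every = NULL,
                       steady_tol = 1e-6) {
  if (is.null(output_every)) output_every <- t_final / 10
  structure(list(N_x = as.integer(N_x),
                 N_y = if (is.null(N_y)) NULL else as.integer(N_y),
                 dt = dt, t_final = t_final, seed = as.integer(seed),
                 init_noise = init_noise, output_every = output_every,
                 steady_tol = steady_tol),
            class = "sim_config")
}

# Thomas solve of (I - a * Lap_1d) x = b for constant coefficient a >= 0,
# zero-flux (reflecting) ends; b may be a matrix (one system per column).
.implicit_1d_factor <- function(N, a) {
  dl <- rep(-a, N - 1)
  d <- c(1 + a, rep(1 + 2 * a, max(N - 2, 0)), 1 + a)
  if (N == 1L) d <- 1
  cp <- numeric(N - 1)      # modified upper coefficients
  dp <- numeric(N)          # modified diagonal (for reuse across solves)
  dp[1] <- d[1]
  for (i in seq_len(N - 1)) {
    cp[i] <- dl[i] / dp[i]
    dp[i + 1] <- d[i + 1] - cp[i] * dl[i]
  }
  list(dl = dl, dp = dp, cp = cp, N = N)
}

.implicit_1d_solve <- function(fac, b) {
  N <- fac$N
  if (N == 1L) return(b / fac$dp[1])
  b <- as.matrix(b)
  for (i in 2:N) b[i, ] <- b[i, ] - fac$cp[i - 1] * b[i - 1, ]
  x <- b
  x[N, ] <- b[N, ] / fac$dp[N]
  for (i in (N - 1):1) x[i, ] <- (b[i, ] - fac$dl[i] * x[i + 1, ]) / fac$dp[i]
  x
}

# divergence of the chemotaxis drift flux h(c) d/dx k(u) on a 1D
# cell-centred grid with zero-flux ends; returns the term entering
# dc/dt = -div(flux) + ...  Donor-cell upwinding in c: the advective flux
# takes the cell density from the side the drift comes from, which keeps
# the density nonnegative where a centred average does not once spikes
# sharpen.
.chemo_div_1d <- function(u_k, cc, chi, dx) {
  N <- length(cc)
  v <- chi * (u_k[-1] - u_k[-N]) / dx        # drift velocity on faces
  cdon <- ifelse(v > 0, cc[-N], cc[-1])      # donor cell
  flux <- v * cdon                           # length N-1, interior faces
  div <- (c(flux, 0) - c(0, flux)) / dx
  -div
}

.noise_init <- function(eq_field, init_noise) {
  eq_field * (1 + init_noise * stats::runif(length(eq_field), -1, 1))
}

#' Simulate the coupled 1D-1D bilayer system
#'
#' Integrates
#' \deqn{\partial_t u_S = f_S(u_S) + \eta A(\tilde u_B - u_S) +
#'       \nabla\cdot(D_S \nabla u_S)}
#' and the bulk analogue on `[0, L]` with zero-flux ends, starting from the
#' coupled homogeneous equilibrium perturbed by seeded noise. Diagonal
#' diffusion is implicit (per-species tridiagonal solves); reactions,
#' exchange and chemotaxis are explicit.
#'
#' @param bilayer A [bilayer_model()] with 1D-1D geometry.
#' @param config A [sim_config()].
#' @param equilibrium Optional precomputed [coupled_equilibrium()].
#' @param init Optional list with `u_S` (n x N_x) and `u_B` (m x N_x)
#'   initial fields, overriding the noisy-equilibrium default.
#' @return Object of class `sim_result`: snapshot times, fields per layer,
#'   the final state, and flags `converged` (quasi-steady reached) and
#'   `blown_up`.
#' @export
simulate_1d1d <- function(bilayer, config, equilibrium = NULL, init = NULL) {
  if (bilayer$geometry$type != "1d1d")
    stop("simulate_1d1d: bilayer must have 1d1d geometry", call. = FALSE)
  n <- bilayer$n; m <- bilayer$m
  L <- bilayer$geometry$L
  Nx <- config$N_x
  dx <- L / Nx
  eta <- bilayer$eta
  if (is.null(equilibrium)) equilibrium <- coupled_equilibrium(bilayer, eta)
  kS <- bilayer$surface$kinetics; kB <- bilayer$bulk$kinetics
  A <- bilayer$A; Bt <- pad_tilde(bilayer$B, m)
  chiB <- bilayer$bulk$chi; kidx <- bilayer$bulk$k_index
  scale_ref <- max(abs(c(equilibrium$u_S, equilibrium$u_B)), 1)

  dt <- config$dt
  for (attempt in 0:4) {
    set.seed(config$seed)
    if (is.null(init)) {
      U_S <- matrix(.noise_init(matrix(equilibrium$u_S, n, Nx), config$init_noise), n, Nx)
      U_B <- matrix(.noise_init(matrix(equilibrium$u_B, m, Nx), config$init_noise), m, Nx)
    } else {
      U_S <- init$u_S; U_B <- init$u_B
    }
    facS <- lapply(bilayer$surface$diff_coef, function(d)
      .implicit_1d_factor(Nx, dt * d / dx^2))
    facB <- lapply(bilayer$bulk$diff_coef, function(d)
      .implicit_1d_factor(Nx, dt * d / dx^2))

    nsteps <- ceiling(config$t_final / dt)
    out_stride <- max(1L, round(config$output_every / dt))
    times <- numeric(0); snaps_S <- list(); snaps_B <- list()
    blown <- FALSE; converged <- FALSE
    prev_S <- U_S; prev_B <- U_B; check_stride <- out_stride

    for (step in seq_len(nsteps)) {
      R_S <- kS$rates(U_S) + eta * (A %*% (U_B[seq_len(n), , drop = FALSE] - U_S))
      R_B <- kB$rates(U_B) + eta * (Bt %*% (rbind(U_S, matrix(0, m - n, Nx)) - U_B))
      if (!is.null(chiB))
        R_B[m, ] <- R_B[m, ] + .chemo_div_1d(U_B[kidx, ], U_B[m, ], chiB, dx)
      U_S <- U_S + dt * R_S
      U_B <- U_B + dt * R_B
      for (i in seq_len(n)) U_S[i, ] <- .implicit_1d_solve(facS[[i]], U_S[i, ])
      for (i in seq_len(m)) U_B[i, ] <- .implicit_1d_solve(facB[[i]], U_B[i, ])

      if (!all(is.finite(U_S)) || !all(is.finite(U_B)) ||
          max(abs(U_S), abs(U_B)) > 1e8 * scale_ref) {
        blown <- TRUE; break
      }
      if (step %% out_stride == 0L || step == nsteps) {
        times <- c(times, step * dt)
        snaps_S[[length(snaps_S) + 1]] <- U_S
        snaps_B[[length(snaps_B) + 1]] <- U_B
      }
      if (step %% check_stride == 0L) {
        chg <- max(abs(U_S - prev_S), abs(U_B - prev_B)) /
          (scale_ref * check_stride * dt)
        prev_S <- U_S; prev_B <- U_B
        if (chg < config$steady_tol) { converged <- TRUE; break }
      }
    }
    if (!blown) {
      if (length(times) == 0L || times[length(times)] < step * dt) {
        times <- c(times, step * dt)
        snaps_S[[length(snaps_S) + 1]] <- U_S
        snaps_B[[length(snaps_B) + 1]] <- U_B
      }
      return(structure(list(times = times, u_S = snaps_S, u_B = snaps_B,
                            final_S = U_S, final_B = U_B, dt = dt, dx = dx,
                            geometry = bilayer$geometry,
                            equilibrium = equilibrium,
                            converged = converged, blown_up = FALSE),
                       class = "sim_result"))
    }
    dt <- dt / 2
  }
  stop(sprintf("simulate_1d1d: blow-up persists after time-step refinement (last dt = %g); fields exceeded 1e8 x equilibrium scale", dt),
       call. = FALSE)
}

#' Simulate the coupled 1D-2D bilayer system
#'
#' The bulk occupies `[0, L] x [0, H]` with zero-flux lateral and bottom
#' boundaries; the surface is the 1D line at `y = H`. The interfacial
#' transport law \eqn{D_B \partial_y u_B = \eta\tilde B(\tilde u_S - u_B)}
#' enters the top bulk cell through its ghost-point flux (treated
#' explicitly), and the surface receives \eqn{\eta A(\tilde u_B|_{y=H} -
#' u_S)} pointwise. Chemotaxis uses centred fluxes on faces with
#' face-averaged \eqn{h(c)}. Diffusion is implicit by dimensional
#' splitting; no positivity clamp is applied, so positivity must emerge
#' from the clipped kinetics.
#'
#' @inheritParams simulate_1d1d
#' @return A `sim_result`; bulk snapshots are `m x N_x x N_y` arrays with
#'   the interface at the last `y` index.
#' @export
simulate_1d2d <- function(bilayer, config, equilibrium = NULL, init = NULL) {
  if (bilayer$geometry$type != "1d2d")
    stop("simulate_1d2d: bilayer must have 1d2d geometry", call. = FALSE)
  n <- bilayer$n; m <- bilayer$m
  L <- bilayer$geometry$L; H <- bilayer$geometry$H
  Nx <- config$N_x
  Ny <- if (is.null(config$N_y)) config$N_x else config$N_y
  dx <- L / Nx; dy <- H / Ny
  eta <- bilayer$eta
  if (is.null(equilibrium)) equilibrium <- coupled_equilibrium(bilayer, eta)
  kS <- bilayer$surface$kinetics; kB <- bilayer$bulk$kinetics
  A <- bilayer$A; Bt <- pad_tilde(bilayer$B, m)
  chiB <- bilayer$bulk$chi; kidx <- bilayer$bulk$k_index
  scale_ref <- max(abs(c(equilibrium$u_S, equilibrium$u_B)), 1)

  dt <- config$dt
  for (attempt in 0:4) {
    set.seed(config$seed)
    if (is.null(init)) {
      U_S <- matrix(.noise_init(matrix(equilibrium$u_S, n, Nx), config$init_noise), n, Nx)
      U_B <- array(0, c(m, Nx, Ny))
      for (i in seq_len(m))
        U_B[i, , ] <- .noise_init(matrix(equilibrium$u_B[i], Nx, Ny),
                                  config$init_noise)
    } else {
      U_S <- init$u_S; U_B <- init$u_B
    }
    facS <- lapply(bilayer$surface$diff_coef, function(d)
      .implicit_1d_factor(Nx, dt * d / dx^2))
    facBx <- lapply(bilayer$bulk$diff_coef, function(d)
      .implicit_1d_factor(Nx, dt * d / dx^2))
    facBy <- lapply(bilayer$bulk$diff_coef, function(d)
      .implicit_1d_factor(Ny, dt * d / dy^2))

    nsteps <- ceiling(config$t_final / dt)
    out_stride <- max(1L, round(config$output_every / dt))
    times <- numeric(0); snaps_S <- list(); snaps_B <- list()
    blown <- FALSE; converged <- FALSE
    prev_S <- U_S; prev_B <- U_B

    for (step in seq_len(nsteps)) {
      top <- U_B[, , Ny, drop = FALSE]; dim(top) <- c(m, Nx)
      # surface: reaction + exchange, then implicit x-diffusion
      R_S <- kS$rates(U_S) + eta * (A %*% (top[seq_len(n), , drop = FALSE] - U_S))
      U_S_new <- U_S + dt * R_S
      for (i in seq_len(n))
        U_S_new[i, ] <- .implicit_1d_solve(facS[[i]], U_S_new[i, ])

      # bulk: reaction everywhere + interfacial flux in the top cell
      Wflat <- matrix(U_B, m, Nx * Ny)
      R_B <- kB$rates(Wflat)
      R_B <- array(R_B, c(m, Nx, Ny))
      exch <- Bt %*% (rbind(U_S, matrix(0, m - n, Nx)) - top)
      R_B[, , Ny] <- R_B[, , Ny] + eta * exch / dy
      if (!is.null(chiB)) {
        uk <- matrix(U_B[kidx, , ], Nx, Ny)
        cc <- matrix(U_B[m, , ], Nx, Ny)
        # donor-cell upwind advective fluxes (see .chemo_div_1d)
        vx <- chiB * (uk[-1, ] - uk[-Nx, ]) / dx
        fx <- vx * ifelse(vx > 0, cc[-Nx, ], cc[-1, ])
        divx <- (rbind(fx, 0) - rbind(0, fx)) / dx
        vy <- chiB * (uk[, -1] - uk[, -Ny]) / dy
        fy <- vy * ifelse(vy > 0, cc[, -Ny], cc[, -1])
        divy <- (cbind(fy, 0) - cbind(0, fy)) / dy
        R_B[m, , ] <- R_B[m, , ] - (divx + divy)
      }
      U_B <- U_B + dt * R_B
      # implicit diffusion, dimensional splitting
      for (i in seq_len(m)) {
        Fi <- matrix(U_B[i, , ], Nx, Ny)
        Fi <- .implicit_1d_solve(facBx[[i]], Fi)          # along x
        Fi <- t(.implicit_1d_solve(facBy[[i]], t(Fi)))    # along y
        U_B[i, , ] <- Fi
      }
      U_S <- U_S_new

      if (!all(is.finite(U_S)) || !all(is.finite(U_B)) ||
          max(abs(U_S), abs(U_B)) > 1e8 * scale_ref) {
        blown <- TRUE; break
      }
      if (step %% out_stride == 0L || step == nsteps) {
        times <- c(times, step * dt)
        snaps_S[[length(snaps_S) + 1]] <- U_S
        snaps_B[[length(snaps_B) + 1]] <- U_B
      }
      if (step %% out_stride == 0L) {
        chg <- max(abs(U_S - prev_S), abs(U_B - prev_B)) /
          (scale_ref * out_stride * dt)
        prev_S <- U_S; prev_B <- U_B
        if (chg < config$steady_tol) { converged <- TRUE; break }
      }
    }
    if (!blown) {
      if (length(times) == 0L || times[length(times)] < step * dt) {
        times <- c(times, step * dt)
        snaps_S[[length(snaps_S) + 1]] <- U_S
        snaps_B[[length(snaps_B) + 1]] <- U_B
      }
      return(structure(list(times = times, u_S = snaps_S, u_B = snaps_B,
                            final_S = U_S, final_B = U_B, dt = dt,
                            dx = dx, dy = dy,
                            geometry = bilayer$geometry,
                            equilibrium = equilibrium,
                            converged = converged, blown_up = FALSE),
                       class = "sim_result"))
    }
    dt <- dt / 2
  }
  stop(sprintf("simulate_1d2d: blow-up persists after time-step refinement (last dt = %g)", dt),
       call. = FALSE)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s, t in [0, %g], %d snapshots, converged: %s\n",
              x$geometry$type, max(x$times), length(x$times), x$converged))
  invisible(x)
}

# dominant cosine-mode index of a 1D profile via the even (mirrored)
# extension, so bin q corresponds exactly to cos(q pi x / L)
.dominant_mode <- function(u) {
  N <- length(u)
  y <- c(u, rev(u)) - mean(u)
  p <- Mod(stats::fft(y))[seq_len(N)]
  if (max(p[-1]) <= 1e-12 * max(p[1], 1e-300)) return(NA_integer_)
  which.max(p[-1])
}

#' Amplitude and dominant wavenumber of a simulated pattern
#'
#' Amplitude is the max-minus-min range of each species' final field per
#' layer; the dominant wavenumber is the peak of the discrete cosine
#' spectrum along `x` (for the 2D bulk, taken on the interface row). When
#' the run did not reach a quasi-steady state the metrics are still
#' returned with `converged = FALSE`.
#'
#' @param result A `sim_result` from [simulate_1d1d()] or
#'   [simulate_1d2d()].
#' @return List with per-layer amplitude vectors (one entry per species),
#'   dominant mode indices `q_S`, `q_B`, and the `converged` flag.
#' @export
pattern_metrics <- function(result) {
  if (!isTRUE(result$converged))
    warning("pattern_metrics: run did not reach a quasi-steady state; metrics refer to the final time",
            call. = FALSE)
  US <- result$final_S
  amp_S <- apply(US, 1, function(r) max(r) - min(r))
  if (result$geometry$type == "1d1d") {
    UB <- result$final_B
    amp_B <- apply(UB, 1, function(r) max(r) - min(r))
    prof_B <- UB[1, ]
  } else {
    UB <- result$final_B
    amp_B <- apply(UB, 1, function(sl) max(sl) - min(sl))
    prof_B <- UB[1, , dim(UB)[3]]
  }
  tol_flat <- 1e-9 * max(abs(result$equilibrium$u_S), 1)
  q_S <- if (max(amp_S) < tol_flat) NA_integer_ else .dominant_mode(US[1, ])
  q_B <- if (max(amp_B) < tol_flat) NA_integer_ else .dominant_mode(prof_B)
  list(amplitude_S = amp_S, amplitude_B = amp_B,
       q_S = q_S, q_B = q_B, converged = isTRUE(result$converged))
}
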