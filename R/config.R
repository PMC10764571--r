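#' Figure-caption presets
#'
#' Fully parameterised bilayer models matching the reference parameter
#' sets used throughout the package's validation studies. Each preset
#' returns the bilayer model together with the matching bifurcation
#' parameter name and mode-scan settings.
#'
#' Available presets:
#' * `fig2a` / `fig2b`: two identical Schnakenberg layers
#'   (a = 0.2305, b = 0.7695, s = 1), bulk diffusion (1, 15), `A = B`
#'   diagonal with (1, 1) resp. (1, 30); L = 1000, modes 0..1500.
#' * `fig3`: asymmetric-equilibria pair, surface Schnakenberg s = 2,
#'   bulk Schnakenberg (a = 0.15, b = 0.2, s = 0.5) with diffusion (1, 15),
#'   `A = B = I`.
#' * `fig6a`: alias of `fig2a` (strong-coupling study).
#' * `fig6b`: pseudo-linear `jp_family` pair, p = 200 surface, p = 2 bulk
#'   with bulk diffusion (1, 10).
#' * `fig7`: two identical Schnakenberg layers with s = 2, bulk diffusion
#'   (1, 1), `A = B = diag(1, 40)` (homogeneous-mode band).
#' * `fig4a`, `fig4b`, `fig5`: 1D-2D pseudo-linear surface plus
#'   three-species chemotaxis bulk (cells chemo-attracted by the first
#'   chemical), with the caption diffusion coefficients and chemotaxis
#'   strengths.
#'
#' The surface inhibitor diffusion (the usual bifurcation parameter) is
#' initialised at the caption value where one is printed and at a
#' patterning-side default otherwise; override it with [set_param()].
#'
#' Note that the printed `fig4*`/`fig5` parameter sets give different
#' surface and bulk equilibria, which the 1D-2D interface condition does
#' not admit; `adjust_shared = TRUE` replaces the surface production
#' offsets by the synthetic values (a0 = 1.5, b0 = 0.25) so that both
#' layers share the bulk equilibrium (0.5, 0.75), enabling simulation.
#'
#' @param name Preset identifier.
#' @param adjust_shared Logical; for the 1D-2D presets, adjust the surface
#'   kinetics to share the bulk equilibrium (see Details).
#' @return List with elements `bilayer`, `delta_name`, `L`, `q_max`,
#'   `eta`, `name`.
#' @export
figure_preset <- function(name, adjust_shared = FALSE) {
  schnak <- function(a, b, s) make_preset("schnakenberg",
                                          list(a = a, b = b, s = s))
  pick <- function(bil, delta_name, L, q_max, eta = 0)
    list(bilayer = bil, delta_name = delta_name, L = L, q_max = q_max,
         eta = eta, name = name)

  if (name %in% c("fig2a", "fig2b", "fig6a")) {
    AB <- if (name == "fig2b") diag(c(1, 30)) else diag(2)
    bil <- bilayer_model(
      layer_model(schnak(0.2305, 0.7695, 1), c(1, 20)),
      layer_model(schnak(0.2305, 0.7695, 1), c(1, 15)),
      A = AB, B = AB, geometry = geometry_1d1d(1000))
    return(pick(bil, "d_vS", 1000, 1500))
  }
  if (name == "fig3") {
    bil <- bilayer_model(
      layer_model(schnak(0.2305, 0.7695, 2), c(1, 20)),
      layer_model(schnak(0.15, 0.2, 0.5), c(1, 15)),
      A = diag(2), B = diag(2), geometry = geometry_1d1d(1000))
    return(pick(bil, "d_vS", 1000, 1500))
  }
  if (name == "fig6b") {
    bil <- bilayer_model(
      layer_model(make_preset("jp_family", list(p = 200)), c(1, 240)),
      layer_model(make_preset("jp_family", list(p = 2)), c(1, 10)),
      A = diag(2), B = diag(2), geometry = geometry_1d1d(1000))
    return(pick(bil, "d_vS", 1000, 1500))
  }
  if (name == "fig7") {
    AB <- diag(c(1, 40))
    bil <- bilayer_model(
      layer_model(schnak(0.2305, 0.7695, 2), c(1, 20)),
      layer_model(schnak(0.2305, 0.7695, 2), c(1, 1)),
      A = AB, B = AB, geometry = geometry_1d1d(1000))
    return(pick(bil, "d_vS", 1000, 1500))
  }
  if (name %in% c("fig4a", "fig4b", "fig5")) {
    surf_par <- list(a0 = 1, a1 = 2, b = 2, a2 = 2,
                     b0 = 0.25, c1 = 1, d = 1, c2 = 2)
    if (adjust_shared) { surf_par$a0 <- 1.5; surf_par$b0 <- 0.25 }
    bulk_par <- list(r0 = 0.2, a0 = 3, a1 = 8, b = 2, a2 = 7,
                     b0 = 0.75, c1 = 0.5, c2 = 1.5, d = 1, cstar = 0.25)
    dvS <- switch(name, fig4a = 6.41, fig4b = 2.91, fig5 = 2.91)
    chi <- switch(name, fig4a = 50, fig4b = 50, fig5 = 120)
    dB <- switch(name,
                 fig4a = c(10, 6, 10), fig4b = c(10, 60, 10),
                 fig5 = c(25, 35, 25))
    Bm <- if (name == "fig5") diag(c(1, 180)) else diag(2)
    bil <- bilayer_model(
      layer_model(make_preset("pseudo_linear_surface", surf_par), c(1, dvS)),
      layer_model(make_preset("pseudo_linear_bulk", bulk_par), dB,
                  chi = chi, k_index = 1L),
      A = diag(2), B = Bm, eta = 0.01, geometry = geometry_1d2d(100, 50))
    return(pick(bil, "d_vB", 100, 200, eta = 0.01))
  }
  stop(sprintf("figure_preset: unknown preset '%s'", name), call. = FALSE)
}

#' Load a declarative run configuration
#'
#' Reads a YAML configuration describing a bilayer model (either a figure
#' preset plus overrides, or explicit kinetics/diffusion/coupling
#' sections), the geometry, the requested analysis and the simulation
#' settings. Matrices are given row-major; parameter names follow the
#' conventional symbols (`d_uS`, `d_vS`, `d_uB`, `d_vB`, `d_c`, `chi`,
#' `alpha`, `beta`, `eta`, `a`, `b`, `s`, `L`, `H`).
#'
#' @param path Path to a YAML file.
#' @return List of class `run_config` with elements `bilayer`,
#'   `delta_name`, `analysis`, `simulation`, `seed`, `raw` (the resolved
#'   configuration list).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("load_config: file '%s' not found", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg))
    stop("load_config: configuration must be a YAML mapping", call. = FALSE)

  if (!is.null(cfg$preset)) {
    pr <- figure_preset(cfg$preset,
                        adjust_shared = isTRUE(cfg$adjust_shared))
    bil <- pr$bilayer
    delta_name <- cfg$delta_name %||% pr$delta_name
    L <- pr$L; q_max <- pr$q_max
  } else {
    mdl <- cfg$model
    if (is.null(mdl))
      stop("load_config: need either 'preset' or a 'model' section",
           call. = FALSE)
    mk_layer <- function(sec, what) {
      if (is.null(sec))
        stop(sprintf("load_config: model$%s section missing", what),
             call. = FALSE)
      kin <- make_preset(sec$kinetics, sec$params)
      layer_model(kin, as.numeric(sec$diff_coef),
                  chi = sec$chi, k_index = sec$k_index %||% 1L)
    }
    sl <- mk_layer(mdl$surface, "surface")
    bl <- mk_layer(mdl$bulk, "bulk")
    n <- sl$kinetics$n_species
    geo <- cfg$geometry %||% list(type = "1d1d", L = 100)
    geom <- if ((geo$type %||% "1d1d") == "1d2d")
      geometry_1d2d(geo$L %||% 100, geo$H %||% 50)
    else geometry_1d1d(geo$L %||% 100)
    Amat <- if (is.null(mdl$A)) diag(n) else
      matrix(as.numeric(unlist(mdl$A)), n, n, byrow = TRUE)
    Bmat <- if (is.null(mdl$B)) Amat else
      matrix(as.numeric(unlist(mdl$B)), n, n, byrow = TRUE)
    bil <- bilayer_model(sl, bl, A = Amat, B = Bmat,
                         eta = mdl$eta %||% 0, geometry = geom)
    delta_name <- cfg$delta_name %||% "d_vS"
    L <- bil$geometry$L
    q_max <- cfg$analysis$q_max %||% 200L
  }

  # scalar overrides applied after preset expansion
  for (nmv in names(cfg$overrides %||% list()))
    bil <- set_param(bil, nmv, cfg$overrides[[nmv]])
  if (!is.null(cfg$eta)) bil <- set_param(bil, "eta", cfg$eta)

  structure(list(bilayer = bil, delta_name = delta_name,
                 analysis = utils::modifyList(list(L = L, q_max = q_max),
                                              cfg$analysis %||% list()),
                 simulation = cfg$simulation %||% list(),
                 seed = cfg$seed %||% 1L, raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a curve or table as annotated CSV
#'
#' Columnar text output with `#`-prefixed header lines recording a content
#' hash of the resolved configuration and the seed, so that reruns can be
#' matched to their provenance.
#'
#' @param df Data frame.
#' @param path Output file.
#' @param meta Named list written into the header.
#' @export
write_curve <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# stable short hash of an R object (provenance annotation)
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, vec.len = 1e6)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Export an instability region as columnar text
#'
#' One row per grid cell with the verdict, suitable for replotting.
#'
#' @param region An [instability_region()] result.
#' @param path Output file.
#' @param meta Named list for the provenance header.
#' @export
write_region <- function(region, path, meta = list()) {
  df <- expand.grid(eta = region$eta_grid, delta = region$delta_grid)
  df$unstable <- as.vector(region$unstable)
  df$valid <- as.vector(region$valid)
  write_curve(df, path, meta)
}
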