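#' Convective boundary model
#'
#' Robin boundary conditions for heat and moisture exchange with the cavity
#' air, parameterised by fixed Biot numbers. The instantaneous transfer
#' coefficients are recovered as \eqn{h = Bi_{heat}\, k / L} and
#' \eqn{h_m = Bi_{mass}\, D / L} from the local (per-edge) conductivity and
#' diffusivity, so they track the evolving seed state while the Biot numbers
#' stay constant through the process. Setting a Biot number to zero insulates
#' the corresponding boundary.
#'
#' @param bi_heat Heat-transfer Biot number (dimensionless, >= 0).
#' @param bi_mass Mass-transfer Biot number (dimensionless, >= 0).
#' @param Ta_K Ambient air temperature (K), default 296.15.
#' @param Me Equilibrium moisture content (d.b. decimal), default 0.
#' @param L Characteristic length (m); taken from the mesh geometry when `NULL`.
#' @param freeze_transfer_coefficients If `TRUE`, `h` and `h_m` are evaluated
#'   once from the initial field and held constant afterwards.
#' @return An object of class `boundary_model`.
#' @export
boundary_model <- function(bi_heat, bi_mass, Ta_K = 296.15, Me = 0, L = NULL,
                           freeze_transfer_coefficients = FALSE) {
  if (bi_heat < 0 || bi_mass < 0) stop("Biot numbers must be >= 0")
  if (Me < 0) stop("`Me` must be >= 0")
  structure(list(bi_heat = bi_heat, bi_mass = bi_mass, Ta_K = Ta_K, Me = Me,
                 L = L, freeze = freeze_transfer_coefficients),
            class = "boundary_model")
}

#' Simulation configuration
#'
#' @param T0_C Initial uniform seed temperature (degrees Celsius).
#' @param M0 Initial uniform dry-basis moisture content (decimal).
#' @param t_end Process duration (s).
#' @param dt Time-step size (s), default 0.5.
#' @param output_times Instants (s) at which full nodal fields are stored;
#'   summary series are always stored at every step.
#' @param include_evaporation Include the evaporative heat sink (default
#'   `TRUE`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(T0_C, M0, t_end, dt = 0.5, output_times = NULL,
                              include_evaporation = TRUE) {
  if (dt <= 0 || t_end < dt) stop("need dt > 0 and t_end >= dt")
  T0_K <- T0_C + 273.15
  if (T0_K < 273 || T0_K > 373) stop("`T0_C` outside the 0-100 degC sanity band")
  if (M0 < 0) stop("`M0` must be >= 0")
  structure(list(T0_K = T0_K, M0 = M0, t_end = t_end, dt = dt,
                 output_times = output_times,
                 include_evaporation = include_evaporation),
            class = "simulation_config")
}

#' Assemble axisymmetric finite-element operators
#'
#' Precomputes, for linear (P1) triangles on the (r, z) cross-section with
#' full-revolution r-weighting: the lumped r-weighted mass vector (row sums of
#' the consistent mass matrix, exact for linear r), the geometric stiffness
#' factors per element (one-point radial quadrature, exact for P1 gradients),
#' and the lumped convective-boundary weights per edge. Property-dependent
#' operators are rebuilt from these factors at every time step.
#'
#' @param mesh A [generate_mesh()] result.
#' @return An object of class `fem_operators`.
#' @export
fem_assemble <- function(mesh) {
  stopifnot(inherits(mesh, "lens_mesh"))
  p <- mesh$nodes
  tri <- mesh$triangles
  n <- nrow(p); m <- nrow(tri)
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  if (any(area <= 0)) stop("singular element (non-positive area): broken mesh")
  # P1 gradient coefficients: grad N_k = (b_k, c_k) / (2 A)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  rbar <- (x1 + x2 + x3) / 3

  # lumped r-weighted mass: node share A (2 r_i + r_j + r_k) / 12, times 2 pi
  rmat <- cbind(x1, x2, x3)
  lump <- 2 * pi * area / 12 * (rmat + rowSums(rmat))
  agg <- rowsum(as.numeric(lump), group = as.numeric(tri))
  vol_w <- numeric(n)
  vol_w[as.integer(rownames(agg))] <- agg[, 1]

  # stiffness triplets: K_e[i,j] = cbar_e * 2 pi rbar_e (b_i b_j + c_i c_c) / (4 A)
  ii <- jj <- integer(9 * m); gv <- numeric(9 * m)
  pos <- 1L
  for (i in 1:3) for (j in 1:3) {
    sl <- pos:(pos + m - 1L)
    ii[sl] <- tri[, i]; jj[sl] <- tri[, j]
    gv[sl] <- 2 * pi * rbar * (b[, i] * b[, j] + cc[, i] * cc[, j]) / (4 * area)
    pos <- pos + m
  }
  # reorder element-major so coefficients can be replicated per element
  ord <- order(rep(seq_len(m), 9))
  ii <- ii[ord]; jj <- jj[ord]; gv <- gv[ord]

  be <- mesh$boundary_edges
  e1 <- be[, 1]; e2 <- be[, 2]
  elen <- sqrt((p[e1, 1] - p[e2, 1])^2 + (p[e1, 2] - p[e2, 2])^2)
  # lumped r-weighted edge weights (row sums of the consistent edge mass)
  w1 <- 2 * pi * elen * (2 * p[e1, 1] + p[e2, 1]) / 6
  w2 <- 2 * pi * elen * (2 * p[e2, 1] + p[e1, 1]) / 6

  rob_idx <- c(e1, e2)
  rob_perm <- order(rob_idx)
  rob_sorted <- rob_idx[rob_perm]
  rob_ends <- which(c(rob_sorted[-1] != rob_sorted[-length(rob_sorted)], TRUE))
  rob_nodes <- rob_sorted[rob_ends]
  rob_w <- c(w1, w2)

  surf_w <- numeric(n)
  cs <- cumsum(rob_w[rob_perm])
  surf_w[rob_nodes] <- cs[rob_ends] - c(0, cs[rob_ends[-length(rob_ends)]])

  center_node <- which.min(p[, 1]^2 + p[, 2]^2)

  # Small systems go through dense LAPACK solves: profiling shows sparse
  # construction overhead dominating below a few hundred unknowns, and the
  # inverse estimation calls the solver thousands of times.
  dense <- n <= 400L
  flat <- ii + (jj - 1L) * n
  # fixed-pattern aggregation: triplets sorted by destination entry, summed
  # per step with a cumsum-difference (cheaper than rowsum in the hot loop)
  agg_perm <- order(flat)
  flat_sorted <- flat[agg_perm]
  agg_ends <- which(c(flat_sorted[-1] != flat_sorted[-length(flat_sorted)], TRUE))
  dense_pos <- flat_sorted[agg_ends]
  diag_pos <- seq_len(n) + (seq_len(n) - 1L) * n

  structure(list(mesh = mesh, n = n, m = m, tri = tri, area = area,
                 rbar = rbar, vol_w = vol_w, ii = ii, jj = jj, gv = gv,
                 dense = dense, agg_perm = agg_perm, agg_ends = agg_ends,
                 dense_pos = dense_pos, diag_pos = diag_pos,
                 edge_nodes = cbind(e1, e2), edge_w = cbind(w1, w2),
                 rob_perm = rob_perm, rob_ends = rob_ends,
                 rob_nodes = rob_nodes, rob_w = rob_w,
                 surf_w = surf_w, center_node = center_node,
                 volume = sum(vol_w), surface_area = sum(surf_w)),
            class = "fem_operators")
}

#' @export
print.fem_operators <- function(x, ...) {
  cat(sprintf("<fem_operators>  %d nodes, %d elements, revolved V = %.4g m3\n",
              x$n, x$m, x$volume))
  invisible(x)
}

# Stiffness matrix for a nodal coefficient field (element-mean coefficient).
fem_stiffness <- function(fem, coef_nodal) {
  cbar <- (coef_nodal[fem$tri[, 1]] + coef_nodal[fem$tri[, 2]] +
             coef_nodal[fem$tri[, 3]]) / 3
  x <- rep(cbar, each = 9L) * fem$gv
  if (fem$dense) {
    K <- matrix(0, fem$n, fem$n)
    cs <- cumsum(x[fem$agg_perm])
    K[fem$dense_pos] <- cs[fem$agg_ends] -
      c(0, cs[fem$agg_ends[-length(fem$agg_ends)]])
    K
  } else {
    Matrix::sparseMatrix(i = fem$ii, j = fem$jj, x = x, dims = c(fem$n, fem$n))
  }
}

# Solve (K + diag(dvec)) u = rhs on either storage backend.
fem_system_solve <- function(fem, K, dvec, rhs) {
  if (fem$dense) {
    K[fem$diag_pos] <- K[fem$diag_pos] + dvec
    as.numeric(solve(K, rhs))
  } else {
    as.numeric(Matrix::solve(K + Matrix::Diagonal(fem$n, dvec), rhs))
  }
}

# Lumped Robin diagonal for a per-edge transfer coefficient.
fem_robin_diag <- function(fem, h_edge) {
  rob <- numeric(fem$n)
  cs <- cumsum((c(h_edge, h_edge) * fem$rob_w)[fem$rob_perm])
  rob[fem$rob_nodes] <- cs[fem$rob_ends] -
    c(0, cs[fem$rob_ends[-length(fem$rob_ends)]])
  rob
}

edge_mean <- function(fem, nodal) {
  (nodal[fem$edge_nodes[, 1]] + nodal[fem$edge_nodes[, 2]]) / 2
}

#' Implicit moisture step
#'
#' One backward-Euler step of Fick's second law
#' \eqn{\partial M/\partial t = \nabla\cdot(D \nabla M)} with the Robin flux
#' \eqn{h_m (M - M_e)} on the convective boundary; `D` and `h_m` frozen at the
#' start-of-step state.
#'
#' @param fem A [fem_assemble()] result.
#' @param T_K,M Nodal temperature (K) and moisture (d.b.) at the start of the
#'   step.
#' @param dt Step size (s).
#' @param diff A [diffusivity_model()].
#' @param bc A [boundary_model()] (with `L` resolved).
#' @param hm_edge Optional frozen per-edge mass-transfer coefficients.
#' @return Nodal moisture at the end of the step.
#' @export
fem_step_moisture <- function(fem, T_K, M, dt, diff, bc, hm_edge = NULL) {
  D <- diffusivity(T_K, M, diff)
  if (is.null(hm_edge)) hm_edge <- bc$bi_mass * edge_mean(fem, D) / bc$L
  K <- fem_stiffness(fem, D)
  rob <- fem_robin_diag(fem, hm_edge)
  rhs <- fem$vol_w / dt * M + rob * bc$Me
  fem_system_solve(fem, K, fem$vol_w / dt + rob, rhs)
}

#' Implicit heat step
#'
#' One backward-Euler step of the energy equation
#' \eqn{\rho C_p \partial T/\partial t = \nabla\cdot(k \nabla T) + q_{MW}
#' - H_{evap} M_v}, with the volumetric evaporation sink
#' \eqn{M_v = -\rho\, \partial M/\partial t} evaluated nodewise from the
#' moisture step just taken, the microwave source from the start-of-step loss
#' factor, and the Robin flux \eqn{h (T_a - T)}.
#'
#' @inheritParams fem_step_moisture
#' @param M_new Nodal moisture after the moisture step for this interval.
#' @param loss A [loss_factor_model()].
#' @param source A [microwave_source()].
#' @param include_evaporation Include the evaporative sink.
#' @param h_edge Optional frozen per-edge heat-transfer coefficients.
#' @return Nodal temperature at the end of the step.
#' @export
fem_step_heat <- function(fem, T_K, M, M_new, dt, loss, source, bc,
                          include_evaporation = TRUE, h_edge = NULL) {
  rho <- lentil_density(M)
  Cp <- lentil_specific_heat(T_K, M)
  k <- lentil_thermal_conductivity(T_K, M)
  eps_pp <- loss_factor(T_K, M, loss)
  q <- volumetric_heating(source$E, eps_pp, source)
  if (is.null(h_edge)) h_edge <- bc$bi_heat * edge_mean(fem, k) / bc$L
  K <- fem_stiffness(fem, k)
  rob <- fem_robin_diag(fem, h_edge)
  cap <- fem$vol_w * rho * Cp / dt
  rhs <- cap * T_K + fem$vol_w * q + rob * bc$Ta_K
  if (include_evaporation) {
    Mv <- -rho * (M_new - M) / dt
    rhs <- rhs - fem$vol_w * latent_heat(T_K) * Mv
  }
  fem_system_solve(fem, K, cap + rob, rhs)
}

#' Run the coupled forward drying simulation
#'
#' Segregated time marching: per step one implicit moisture step then one
#' implicit heat step, with property coefficients lagged to the start of the
#' step. Summary series (volume-averaged mean, convective-boundary-averaged
#' surface, and center-node values) are recorded at every step; full nodal
#' fields at the configured `output_times`.
#'
#' @param fem A [fem_assemble()] result (or a mesh, assembled on the fly).
#' @param config A [simulation_config()].
#' @param loss A [loss_factor_model()].
#' @param diff A [diffusivity_model()].
#' @param source A [microwave_source()].
#' @param bc A [boundary_model()].
#' @param stop_below_M Optional mean-moisture threshold (d.b.); marching stops
#'   at the first step where the volume-averaged moisture falls below it,
#'   mirroring a drying process run until a target moisture is reached.
#' @return An object of class `field_solution`; its `$summary` element is a
#'   tibble with columns `time_s`, `mean_T_C`, `surface_T_C`, `center_T_C`,
#'   `mean_M_db`, `surface_M_db`, `center_M_db`.
#' @export
run_forward <- function(fem, config, loss, diff, source, bc,
                        stop_below_M = NULL) {
  if (inherits(fem, "lens_mesh")) fem <- fem_assemble(fem)
  stopifnot(inherits(fem, "fem_operators"), inherits(config, "simulation_config"))
  if (is.null(bc$L)) bc$L <- characteristic_length(fem$mesh$geom)

  n <- fem$n
  dt <- config$dt
  times <- seq(0, config$t_end, by = dt)
  if (utils::tail(times, 1) < config$t_end) times <- c(times, config$t_end)
  nt <- length(times)

  T_K <- rep(config$T0_K, n)
  M <- rep(config$M0, n)

  h_edge <- hm_edge <- NULL
  if (isTRUE(bc$freeze)) {
    k0 <- lentil_thermal_conductivity(T_K, M)
    D0 <- diffusivity(T_K, M, diff)
    h_edge <- bc$bi_heat * edge_mean(fem, k0) / bc$L
    hm_edge <- bc$bi_mass * edge_mean(fem, D0) / bc$L
  }

  vw <- fem$vol_w / sum(fem$vol_w)
  sw <- fem$surf_w / sum(fem$surf_w)
  cn <- fem$center_node
  mean_T <- surface_T <- center_T <- mean_M <- surface_M <- center_M <- numeric(nt)
  record <- function(i) {
    mean_T[i] <<- sum(vw * T_K); surface_T[i] <<- sum(sw * T_K); center_T[i] <<- T_K[cn]
    mean_M[i] <<- sum(vw * M); surface_M[i] <<- sum(sw * M); center_M[i] <<- M[cn]
  }
  record(1L)

  snap_times <- config$output_times
  snapshots <- list()
  if (!is.null(snap_times))
    snap_idx <- vapply(snap_times, function(s) which.min(abs(times - s)), 1L)

  for (i in 2:nt) {
    dt_i <- times[i] - times[i - 1]
    M_new <- fem_step_moisture(fem, T_K, M, dt_i, diff, bc, hm_edge = hm_edge)
    T_new <- fem_step_heat(fem, T_K, M, M_new, dt_i, loss, source, bc,
                           include_evaporation = config$include_evaporation,
                           h_edge = h_edge)
    if (any(!is.finite(T_new)) || any(!is.finite(M_new)) ||
        max(abs(T_new)) > 600 || min(M_new) < -1e-6)
      stop(sprintf(paste0("forward solve blew up at step %d (t = %.1f s): ",
                          "T range [%.1f, %.1f] K, M range [%.4g, %.4g]"),
                   i - 1L, times[i], min(T_new), max(T_new), min(M_new), max(M_new)))
    T_K <- T_new; M <- M_new
    record(i)
    if (!is.null(snap_times) && i %in% snap_idx)
      snapshots[[as.character(times[i])]] <- list(T_K = T_K, M = M)
    if (!is.null(stop_below_M) && mean_M[i] <= stop_below_M) {
      keep <- seq_len(i)
      times <- times[keep]
      mean_T <- mean_T[keep]; surface_T <- surface_T[keep]; center_T <- center_T[keep]
      mean_M <- mean_M[keep]; surface_M <- surface_M[keep]; center_M <- center_M[keep]
      nt <- i
      break
    }
  }

  summary <- tibble::tibble(
    time_s = times,
    mean_T_C = mean_T - 273.15, surface_T_C = surface_T - 273.15,
    center_T_C = center_T - 273.15,
    mean_M_db = mean_M, surface_M_db = surface_M, center_M_db = center_M
  )
  structure(list(summary = summary, snapshots = snapshots, fem = fem,
                 config = config, final_T_K = T_K, final_M = M),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<field_solution>  %d steps over %.0f s\n",
                     "  mean T: %.1f -> %.1f degC, mean M: %.3f -> %.3f d.b.\n"),
              nrow(s) - 1L, max(s$time_s),
              s$mean_T_C[1], utils::tail(s$mean_T_C, 1),
              s$mean_M_db[1], utils::tail(s$mean_M_db, 1)))
  invisible(x)
}

#' Interpolate simulation summaries at arbitrary instants
#'
#' Linear interpolation in time of the recorded summary series; requests
#' outside the simulated interval are rejected rather than extrapolated.
#'
#' @param solution A [run_forward()] result.
#' @param times Instants (s) within the simulated range.
#' @param quantities Which summary columns to interpolate (default all).
#' @return A tibble with `time_s` plus the requested columns.
#' @export
summaries <- function(solution, times,
                      quantities = c("mean_T_C", "surface_T_C", "center_T_C",
                                     "mean_M_db", "surface_M_db", "center_M_db")) {
  stopifnot(inherits(solution, "field_solution"))
  s <- solution$summary
  if (any(times < min(s$time_s) - 1e-9) || any(times > max(s$time_s) + 1e-9))
    stop("requested times outside the simulated interval [",
         min(s$time_s), ", ", max(s$time_s), "] s")
  quantities <- match.arg(quantities, several.ok = TRUE)
  out <- tibble::tibble(time_s = times)
  for (q in quantities)
    out[[q]] <- stats::approx(s$time_s, s[[q]], xout = times, rule = 1)$y
  out
}

#' Simulate a drying treatment
#'
#' High-level tidy wrapper: builds mesh and operators for the default seed
#' geometry, runs the coupled forward model, and returns the summary tibble
#' (the full `field_solution` is attached as attribute `"solution"`).
#'
#' @param treatment Treatment id (see [lentil_treatments()]) or `"average"`.
#' @param t_end Process duration (s).
#' @param dt Time step (s).
#' @param target_h Mesh edge length (m).
#' @param ash_db Ash content (percent d.b.).
#' @param ... Further arguments passed to [simulation_config()].
#' @return A tibble of summary series in seconds, degrees Celsius and
#'   dry-basis decimals.
#' @examples
#' \donttest{
#' sim <- simulate_drying("0.70kW-50", t_end = 120, dt = 1, target_h = 4e-4)
#' tail(sim)
#' }
#' @export
simulate_drying <- function(treatment, t_end, dt = 0.5, target_h = 1e-4,
                            ash_db = 2.6, ...) {
  tm <- treatment_models(treatment, ash_db = ash_db)
  mesh <- generate_mesh(lens_geometry(), target_h = target_h)
  fem <- fem_assemble(mesh)
  config <- simulation_config(T0_C = tm$T0_C, M0 = tm$imc_db,
                              t_end = t_end, dt = dt, ...)
  bc <- boundary_model(bi_heat = tm$bi_heat, bi_mass = tm$bi_mass)
  sol <- run_forward(fem, config, tm$loss, tm$diff, tm$source, bc)
  out <- sol$summary
  attr(out, "solution") <- sol
  class(out) <- c("drying_simulation", class(out))
  out
}
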