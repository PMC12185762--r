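#' Mechanical parameters of the vertex model
#'
#' The constitutive law is logarithmic in both strains: a cell of area
#' \eqn{A} and perimeter \eqn{L} has internal pressure
#' \eqn{p = -\sigma \ln(A/A_0)} and cortical tension
#' \eqn{t = \sigma \Gamma \ln(L/L_0)}, where \eqn{\sigma} is the cell's
#' stiffness prefactor (10 for stiff multiciliated cells in the default
#' protocol, 1 for bulk cells).  These are the derivatives of the potential
#' assembled by [total_energy()].  Defaults place the tissue in the jammed
#' regime: preferred perimeter `L0 = 0.75` (in units where the bulk preferred
#' area is 1), relative cortical stiffness `gamma = 0.2`, uniform external
#' pressure `p_ext = 0.5`.
#'
#' @param gamma relative cortical stiffness (dimensionless, > 0).
#' @param L0 preferred perimeter, model length units.
#' @param p_ext uniform external pressure loading the monolayer boundary.
#' @param eta drag coefficient of the overdamped vertex dynamics.
#' @param dt initial integration step of the adaptive Euler integrator.
#' @param force_tol equilibrium threshold on the maximum vertex-force
#'   magnitude (used for the final relaxation).
#' @param growth_tol looser force threshold used for the relaxations between
#'   divisions while the tissue grows.
#' @param t1_threshold edge length below which a T1 neighbour exchange is
#'   triggered; the reopened edge has length `1.5 * t1_threshold`.
#' @param cycle_time mean cell-cycle duration (model time units).
#' @param cycle_jitter relative half-width of the per-cell cycle-time draw
#'   (uniform on `cycle_time * [1 - j, 1 + j]`).
#' @return a list of class `mech_params`.
#' @export
mech_params <- function(gamma = 0.2, L0 = 0.75, p_ext = 0.5, eta = 1,
                        dt = 0.02, force_tol = 1e-6, growth_tol = 1e-3,
                        t1_threshold = 0.05, cycle_time = 1,
                        cycle_jitter = 0.2) {
  stopifnot(gamma > 0, L0 > 0, p_ext >= 0, eta > 0, dt > 0, force_tol > 0,
            growth_tol > 0, t1_threshold >= 0,
            cycle_time > 0, cycle_jitter >= 0, cycle_jitter < 1)
  structure(list(gamma = gamma, L0 = L0, p_ext = p_ext, eta = eta, dt = dt,
                 force_tol = force_tol, growth_tol = growth_tol,
                 t1_threshold = t1_threshold, cycle_time = cycle_time,
                 cycle_jitter = cycle_jitter),
            class = "mech_params")
}

#' Per-cell internal pressure
#'
#' \eqn{p_i = -\sigma_i \ln(A_i / A_{0,i})}: zero at the preferred area,
#' positive when the cell is squeezed below it, and scaled by the stiffness
#' prefactor so a given areal strain produces a force \eqn{\sigma}-fold
#' larger in stiff cells.
#'
#' @param mesh an `epi_mesh`.
#' @param params a [mech_params()] list.
#' @return numeric vector of per-cell pressures.
#' @export
cell_pressure <- function(mesh, params = mech_params()) {
  g <- geometry_vectors(mesh)
  if (any(g$area <= 0))
    stop("non-positive cell area; cannot evaluate pressure")
  -mesh$cells$sigma * log(g$area / mesh$cells$A0)
}

#' Per-cell cortical tension
#'
#' \eqn{t_i = \sigma_i \Gamma \ln(L_i / L_0)}: zero at the preferred
#' perimeter and \eqn{\sigma}-fold larger in stiff cells at equal strain.
#'
#' @inheritParams cell_pressure
#' @return numeric vector of per-cell tensions.
#' @export
cell_tension <- function(mesh, params = mech_params()) {
  g <- geometry_vectors(mesh)
  if (any(g$perimeter <= 0))
    stop("non-positive cell perimeter; cannot evaluate tension")
  mesh$cells$sigma * params$gamma * log(g$perimeter / params$L0)
}

#' Total mechanical energy of the monolayer
#'
#' \deqn{E = \sum_i \sigma_i [A_i \ln(A_i/A_{0,i}) - A_i + A_{0,i}]
#'         + \sum_i \sigma_i \Gamma [L_i \ln(L_i/L_0) - L_i + L_0]
#'         + P_{ext} \sum_i A_i.}
#' Each bracketed term is non-negative with its minimum 0 at the preferred
#' value, and \eqn{\partial E/\partial A_i = -p_i},
#' \eqn{\partial E/\partial L_i = t_i}, so the vertex forces of
#' [vertex_forces()] are exactly \eqn{-\nabla E}.
#'
#' @inheritParams cell_pressure
#' @return scalar energy.
#' @export
total_energy <- function(mesh, params = mech_params()) {
  csr <- mesh_csr(mesh)
  mesh_energy_cpp(mesh$vertices, csr$tail, csr$head, csr$cptr, csr$cedge,
                  csr$csign, mesh$cells$sigma, mesh$cells$A0,
                  params$gamma, params$L0, params$p_ext)
}

#' Vertex forces
#'
#' Assembles \eqn{F = -\nabla E} edge-wise through the incidence structure:
#' each cell contributes its pressure along the shoelace area gradient and
#' its cortical tension along unit edge tangents; the external pressure
#' enters through the total-area term and therefore loads boundary edges
#' inward (interior contributions cancel pairwise).
#'
#' @inheritParams cell_pressure
#' @return numeric matrix (n_vertices x 2) of forces.
#' @export
vertex_forces <- function(mesh, params = mech_params()) {
  csr <- mesh_csr(mesh)
  res <- mesh_forces_cpp(mesh$vertices, csr$tail, csr$head, csr$cptr,
                         csr$cedge, csr$csign, mesh$cells$sigma,
                         mesh$cells$A0, params$gamma, params$L0, params$p_ext)
  res$force
}

#' Relax a mesh to mechanical equilibrium
#'
#' Overdamped explicit Euler (`x <- x + dt/eta * F`) with an adaptive step:
#' the step is halved whenever a trial move would raise the energy and grown
#' by 1.1x after ten consecutive accepted moves, so the energy is
#' non-increasing across accepted steps.  Whenever an interior edge with two
#' degree-3 endpoints drops below `params$t1_threshold` a T1 neighbour
#' exchange is applied and integration resumes.  Termination: maximum vertex
#' force below `tol` (converged), or `max_steps` exhausted (the result is
#' flagged, not an error).
#'
#' @inheritParams cell_pressure
#' @param max_steps total iteration budget (shared across T1 restarts).
#' @param tol force tolerance; defaults to `params$force_tol`.
#' @param t1 logical; apply T1 transitions when edges collapse (default TRUE).
#' @return the relaxed `epi_mesh`, with a `relax_info` attribute: list with
#'   `converged`, `steps`, `n_t1`, `energy`, `max_force`,
#'   `max_energy_increase`.
#' @export
relax <- function(mesh, params = mech_params(), max_steps = 50000L,
                  tol = params$force_tol, t1 = TRUE) {
  steps_left <- as.integer(max_steps)
  total_steps <- 0L
  n_t1 <- 0L
  info <- NULL
  blocked <- integer()   # edges whose T1 was skipped during this call
  elig <- NULL
  repeat {
    csr <- mesh_csr(mesh)
    if (is.null(elig)) {
      elig <- if (t1) t1_eligible(mesh) else integer(nrow(mesh$edges))
      elig[blocked] <- 0L
    }
    res <- relax_cpp(mesh$vertices, csr$tail, csr$head, csr$cptr, csr$cedge,
                     csr$csign, mesh$cells$sigma, mesh$cells$A0,
                     params$gamma, params$L0, params$p_ext, params$eta,
                     params$dt, tol, steps_left,
                     if (t1) params$t1_threshold else 0, elig)
    mesh$vertices <- res$vertices
    total_steps <- total_steps + res$steps
    steps_left <- steps_left - res$steps
    info <- res
    if (res$status == "t1" && steps_left > 0L) {
      mesh2 <- suppressMessages(t1_transition(mesh, res$t1_edge, params))
      if (is.null(attr(mesh2, "t1_skipped"))) {
        n_t1 <- n_t1 + 1L
        mesh <- mesh2
        elig <- NULL     # topology changed; recompute eligibility
      } else {
        blocked <- c(blocked, res$t1_edge)
        elig[res$t1_edge] <- 0L
      }
      next
    }
    break
  }
  attr(mesh, "relax_info") <- list(
    converged = info$status == "converged",
    status = info$status, steps = total_steps, n_t1 = n_t1,
    energy = info$energy, max_force = info$max_force,
    max_energy_increase = info$max_energy_increase)
  mesh
}
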