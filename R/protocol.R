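#' Configuration of the growth-and-MCC simulation protocol
#'
#' The default protocol grows a 61-cell hexagonal founder patch (4 rings) to
#' 400 cells, introduces evenly spaced multiciliated cells (MCCs) with the
#' exclusion-radius placement of [select_mccs()], multiplies their stiffness
#' prefactor by `sigma_mcc` and blocks their division, grows on to 800
#' cells, stops all division, and relaxes to equilibrium.  Thresholds are
#' checked after every single division, so the 400- and 800-cell counts are
#' hit exactly.
#'
#' @param rings rings of the hexagonal founder patch (4 gives 61 cells).
#' @param n_at_mcc_intro cell count at which MCCs are introduced.
#' @param n_final cell count at which all division stops.
#' @param sigma_mcc stiffness prefactor assigned to MCCs (1 or 10 in the
#'   study conditions).
#' @param mcc_divide logical; control condition in which MCCs keep dividing
#'   (with `sigma_mcc = 1` MCCs are then indistinguishable from bulk cells).
#' @param n_replicates ensemble size (default 10).
#' @param base_seed seed of replicate 1; replicate k uses `base_seed + k - 1`.
#' @param params a [mech_params()] list.
#' @param final_max_steps iteration budget of the final relaxation.
#' @return list of class `protocol_config`.
#' @export
protocol_config <- function(rings = 4, n_at_mcc_intro = 400, n_final = 800,
                            sigma_mcc = 10, mcc_divide = FALSE,
                            n_replicates = 10, base_seed = 1,
                            params = mech_params(),
                            final_max_steps = 200000L) {
  n0 <- 3 * rings * (rings + 1) + 1
  if (!(n0 <= n_at_mcc_intro && n_at_mcc_intro <= n_final))
    stop("cell-count thresholds must satisfy initial <= mcc_intro <= final")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(rings = rings, n_at_mcc_intro = n_at_mcc_intro,
                 n_final = n_final, sigma_mcc = sigma_mcc,
                 mcc_divide = mcc_divide, n_replicates = n_replicates,
                 base_seed = base_seed, params = params,
                 final_max_steps = as.integer(final_max_steps)),
            class = "protocol_config")
}

#' Scaled-down protocol profile
#'
#' A 3-ring (37-cell) founder grown to 100 cells for MCC introduction and
#' 200 cells at arrest; used for fast test runs.
#' @param ... overrides passed to [protocol_config()].
#' @export
protocol_config_ci <- function(...) {
  protocol_config(rings = 3, n_at_mcc_intro = 100, n_final = 200,
                  final_max_steps = 100000L, ...)
}

#' Select evenly spaced MCCs by exclusion radius
#'
#' Iteratively picks a cell uniformly at random from the eligible pool
#' (non-peripheral cells not within graph distance 3 of any chosen MCC) and
#' removes the chosen cell's first, second and third topological neighbour
#' shells from the pool, until the pool is empty.  The result is maximal:
#' every remaining bulk cell is excluded, and no path of fewer than 3
#' adjacent cells connects any two MCCs (pairwise graph distance >= 4).
#'
#' @param mesh an `epi_mesh`.
#' @param graph optional precomputed [adjacency_graph()].
#' @return integer vector of MCC cell indices (empty, with a warning, if no
#'   cell is eligible).
#' @export
select_mccs <- function(mesh, graph = NULL) {
  g <- if (is.null(graph)) adjacency_graph(mesh) else graph
  pool <- setdiff(seq_len(n_cells(mesh)), peripheral_cells(mesh))
  if (!length(pool)) {
    warning("no non-peripheral cells; returning empty MCC set")
    return(integer())
  }
  chosen <- integer()
  while (length(pool)) {
    pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
    chosen <- c(chosen, pick)
    shells <- igraph::ego(g, order = 3, nodes = pick)[[1]]
    pool <- setdiff(pool, as.integer(shells))
  }
  sort(chosen)
}

#' Run one simulation of the growth-and-MCC protocol
#'
#' @param config a [protocol_config()].
#' @param seed integer seed controlling every random draw of the run.
#' @return a `sim_result` list: `final` (equilibrated mesh), `snapshots`
#'   (`founder`, `mcc_intro`, `arrest` meshes), `mcc_ids`, `config`, `seed`,
#'   `converged`.
#' @export
run_protocol <- function(config = protocol_config(), seed = 1L) {
  params <- config$params
  with_seed(seed, {
    mesh <- build_hex_monolayer(config$rings, params)
    mesh <- relax(mesh, params, tol = params$growth_tol)
    founder <- mesh
    mesh <- grow_to_count(mesh, params, config$n_at_mcc_intro)
    mccs <- select_mccs(mesh)
    mesh$cells$sigma[mccs] <- config$sigma_mcc
    mesh$cells$is_mcc[mccs] <- TRUE
    mesh$cells$can_divide[mccs] <- config$mcc_divide
    snap_intro <- mesh
    mesh <- grow_to_count(mesh, params, config$n_final)
    mesh$cells$can_divide <- FALSE
    snap_arrest <- mesh
    mesh <- relax(mesh, params, max_steps = config$final_max_steps,
                  tol = params$force_tol)
    info <- attr(mesh, "relax_info")
    structure(list(final = mesh,
                   snapshots = list(founder = founder,
                                    mcc_intro = snap_intro,
                                    arrest = snap_arrest),
                   mcc_ids = which(mesh$cells$is_mcc),
                   config = config, seed = seed,
                   converged = isTRUE(info$converged)),
              class = "sim_result")
  })
}

#' @exportS3Method base::print
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> seed %d: %d cells (%d MCCs, sigma=%g), converged: %s\n",
    x$seed, n_cells(x$final), length(x$mcc_ids), x$config$sigma_mcc,
    x$converged))
  invisible(x)
}

#' Run an ensemble of independent protocol simulations
#'
#' Replicate k runs with seed `base_seed + k - 1`; per-run failures are
#' collected as condition objects rather than aborting the ensemble.
#'
#' @param config a [protocol_config()].
#' @return list of `sim_result` (or error conditions), length
#'   `config$n_replicates`.
#' @export
run_ensemble <- function(config = protocol_config()) {
  lapply(seq_len(config$n_replicates), function(k) {
    tryCatch(run_protocol(config, seed = as.integer(config$base_seed) + k - 1L),
             error = function(e) e)
  })
}
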