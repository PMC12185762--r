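# Per-cell stress measures and MCC-neighbourhood decile enrichment.

#' Per-cell stress tensors
#'
#' For each cell the symmetric 2x2 tensor
#' \deqn{\sigma_i = -(p_i - P_{ext}) I
#'   + \frac{t_i}{A_i} \sum_{e \in i} \frac{\ell_e \otimes \ell_e}{|\ell_e|}}
#' with \eqn{p_i} the internal pressure, \eqn{t_i} the cortical tension and
#' \eqn{\ell_e} the edge vectors of the cell.  The isotropic (pressure) part
#' \eqn{-(p_i - P_{ext})} is reported as the cell's *effective pressure*:
#' it is negative for compressed cells (squeezed below their preferred
#' area), which fixes the sign convention used by the decile statistics.
#' The full trace/2 additionally contains the isotropic part of the tension
#' term.
#'
#' @param mesh an equilibrated `epi_mesh` (a warning is emitted when the
#'   maximum vertex force exceeds 100x `params$force_tol`).
#' @param params a [mech_params()] list.
#' @param check_equilibrium logical; warn on unequilibrated input.
#' @return data frame with columns `cell`, `sxx`, `sxy`, `syy`,
#'   `eff_pressure`, `tension`, `shear`.
#' @export
cell_stress_tensors <- function(mesh, params = mech_params(),
                                check_equilibrium = TRUE) {
  if (check_equilibrium) {
    f <- vertex_forces(mesh, params)
    if (max(sqrt(rowSums(f^2))) > 100 * params$force_tol)
      warning("mesh does not look equilibrated; stress measures refer to ",
              "a non-stationary configuration")
  }
  g <- geometry_vectors(mesh)
  p <- cell_pressure(mesh, params)
  tn <- cell_tension(mesh, params)
  V <- mesh$vertices
  ex <- V[mesh$edges[, 2], 1] - V[mesh$edges[, 1], 1]
  ey <- V[mesh$edges[, 2], 2] - V[mesh$edges[, 1], 2]
  el <- sqrt(ex^2 + ey^2)
  dxx <- ex * ex / el
  dxy <- ex * ey / el
  dyy <- ey * ey / el
  n <- n_cells(mesh)
  sxx <- sxy <- syy <- numeric(n)
  for (ci in seq_len(n)) {
    ids <- abs(mesh$cell_edges[[ci]])
    iso <- -(p[ci] - params$p_ext)
    sxx[ci] <- iso + tn[ci] / g$area[ci] * sum(dxx[ids])
    sxy[ci] <- tn[ci] / g$area[ci] * sum(dxy[ids])
    syy[ci] <- iso + tn[ci] / g$area[ci] * sum(dyy[ids])
  }
  data.frame(cell = seq_len(n), sxx = sxx, sxy = sxy, syy = syy,
             eff_pressure = -(p - params$p_ext), tension = tn,
             shear = sqrt(((sxx - syy) / 2)^2 + sxy^2))
}

#' Shear stress of a symmetric 2x2 tensor
#'
#' Half the difference of the principal stresses,
#' \eqn{(\lambda_{max} - \lambda_{min})/2 \ge 0}; rotation invariant.
#'
#' @param tensor a symmetric 2x2 matrix, or a data frame with columns
#'   `sxx`, `sxy`, `syy` (e.g. from [cell_stress_tensors()]).
#' @return non-negative scalar (or vector for data-frame input).
#' @export
shear_stress <- function(tensor) {
  if (is.data.frame(tensor))
    return(sqrt(((tensor$sxx - tensor$syy) / 2)^2 + tensor$sxy^2))
  stopifnot(is.matrix(tensor), all(dim(tensor) == 2))
  if (abs(tensor[1, 2] - tensor[2, 1]) > 1e-8 * (1 + max(abs(tensor))))
    stop("tensor is not symmetric")
  sqrt(((tensor[1, 1] - tensor[2, 2]) / 2)^2 + tensor[1, 2]^2)
}

#' Classify cells by MCC adjacency
#'
#' Peripheral cells are labelled `peripheral` regardless of adjacency (the
#' analyses exclude the monolayer boundary); remaining cells are `mcc`,
#' `mcc_adjacent` (share an edge with at least one MCC) or `non_adjacent`.
#'
#' @param mesh an `epi_mesh` with MCC flags assigned.
#' @param graph optional precomputed [adjacency_graph()].
#' @return factor of length `n_cells(mesh)` with levels `mcc`,
#'   `mcc_adjacent`, `non_adjacent`, `peripheral`.
#' @export
classify_cells <- function(mesh, graph = NULL) {
  n <- n_cells(mesh)
  mccs <- which(mesh$cells$is_mcc)
  lab <- rep("non_adjacent", n)
  if (!length(mccs)) {
    warning("mesh has no MCCs; all bulk cells labelled non_adjacent")
  } else {
    g <- if (is.null(graph)) adjacency_graph(mesh) else graph
    nb <- unique(unlist(igraph::adjacent_vertices(g, mccs)))
    lab[nb] <- "mcc_adjacent"
    lab[mccs] <- "mcc"
  }
  lab[peripheral_cells(mesh)] <- "peripheral"
  factor(lab, levels = c("mcc", "mcc_adjacent", "non_adjacent", "peripheral"))
}

#' Fraction of each adjacency group beyond a pooled decile cut
#'
#' Values of `mcc_adjacent` and `non_adjacent` cells are pooled; the cut is
#' the empirical 90th (`tail = "highest"`) or 10th (`tail = "lowest"`)
#' percentile (linear interpolation between order statistics), and for each
#' group the percentage of members strictly beyond the cut is returned.
#' MCCs and peripheral cells never enter the pool.  Compression is queried
#' as `tail = "lowest"` on effective pressure (most negative = most
#' compressed).
#'
#' @param values numeric vector over all cells.
#' @param labels factor from [classify_cells()].
#' @param tail `"highest"` or `"lowest"`.
#' @return named numeric vector: percentages for `mcc_adjacent`,
#'   `non_adjacent`, and the pooled percentage.
#' @export
decile_fraction <- function(values, labels, tail = c("highest", "lowest")) {
  tail <- match.arg(tail)
  stopifnot(length(values) == length(labels))
  keep <- labels %in% c("mcc_adjacent", "non_adjacent")
  v <- values[keep]
  l <- droplevels(factor(labels[keep],
                         levels = c("mcc_adjacent", "non_adjacent")))
  if (length(v) < 10)
    stop("fewer than 10 included cells; decile is not defined")
  if (tail == "highest") {
    cut <- quantile(v, 0.9, type = 7, names = FALSE)
    beyond <- v > cut
  } else {
    cut <- quantile(v, 0.1, type = 7, names = FALSE)
    beyond <- v < cut
  }
  out <- vapply(c("mcc_adjacent", "non_adjacent"), function(gr) {
    idx <- l == gr
    if (!any(idx)) return(NA_real_)
    100 * mean(beyond[idx])
  }, 0)
  c(out, pooled = 100 * mean(beyond))
}

#' Paired two-sided t-test across replicates
#'
#' Classical paired t on the differences `x - y` via [stats::t.test()], with
#' the degenerate cases fixed: all-identical pairs give `t = 0, p = 1`;
#' zero-variance differences with nonzero mean give `p = 0` (reported as a
#' limit) with `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors (e.g. per-replicate group fractions).
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Decile-enrichment report over a simulation ensemble
#'
#' For each replicate, computes per-group fractions in the lowest decile of
#' effective pressure (compression), the lowest decile of cortical tension,
#' and the highest decile of shear stress, pooling within the replicate;
#' then compares `mcc_adjacent` against `non_adjacent` fractions across
#' replicates with a paired two-sided t-test per metric.
#'
#' @param ensemble list of `sim_result` (from [run_ensemble()]).
#' @param params a [mech_params()] list (defaults to the ensemble's own).
#' @return list with `fractions` (data frame: replicate, metric, group,
#'   fraction) and `tests` (data frame: metric, mean fractions, t, p).
#' @export
enrichment_report <- function(ensemble, params = NULL) {
  ok <- vapply(ensemble, inherits, TRUE, what = "sim_result")
  if (!all(ok)) warning(sum(!ok), " failed replicate(s) dropped")
  ensemble <- ensemble[ok]
  if (!length(ensemble)) stop("no successful replicates")
  if (is.null(params)) params <- ensemble[[1]]$config$params
  metrics <- c(eff_pressure = "lowest", tension = "lowest", shear = "highest")
  rows <- list()
  for (r in seq_along(ensemble)) {
    mesh <- ensemble[[r]]$final
    st <- cell_stress_tensors(mesh, params, check_equilibrium = FALSE)
    lab <- classify_cells(mesh)
    for (m in names(metrics)) {
      fr <- decile_fraction(st[[m]], lab, tail = metrics[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, metric = m,
        group = c("mcc_adjacent", "non_adjacent"),
        fraction = unname(fr[c("mcc_adjacent", "non_adjacent")]))
    }
  }
  fractions <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(names(metrics), function(m) {
    adj <- fractions$fraction[fractions$metric == m &
                                fractions$group == "mcc_adjacent"]
    non <- fractions$fraction[fractions$metric == m &
                                fractions$group == "non_adjacent"]
    tt <- paired_ttest(adj, non)
    data.frame(metric = m, tail = metrics[[m]],
               mean_adjacent = mean(adj), mean_non_adjacent = mean(non),
               t = tt$t, p = tt$p)
  }))
  list(fractions = fractions, tests = tests)
}

#' Geometry of the neighbour ring around an MCC
#'
#' Neighbours are ordered by angle about the MCC centroid.  Each neighbour's
#' tangential-elongation index is
#' \eqn{\frac{\lambda_1 - \lambda_2}{\lambda_1 + \lambda_2} \cos 2\theta},
#' where \eqn{\lambda_{1,2}} are the principal second area moments of the
#' neighbour polygon and \eqn{\theta} the angle between its long axis and
#' the local tangent direction: +1 means a strongly tangentially stretched
#' (rosette-like) neighbour, 0 an isotropic one.
#'
#' @param mesh an `epi_mesh`.
#' @param mcc_id index of an MCC cell.
#' @param graph optional precomputed [adjacency_graph()].
#' @return data frame: `neighbor`, `angle`, `elongation_index`, ordered by
#'   angle.
#' @export
neighbor_ring_geometry <- function(mesh, mcc_id, graph = NULL) {
  if (!mesh$cells$is_mcc[mcc_id]) stop("cell ", mcc_id, " is not an MCC")
  g <- if (is.null(graph)) adjacency_graph(mesh) else graph
  nb <- as.integer(igraph::neighbors(g, mcc_id))
  ctr <- polygon_centroid(mesh$vertices[cell_vertices(mesh, mcc_id), ,
                                        drop = FALSE])
  out <- do.call(rbind, lapply(nb, function(ci) {
    vs <- mesh$vertices[cell_vertices(mesh, ci), , drop = FALSE]
    nctr <- polygon_centroid(vs)
    radial <- atan2(nctr[2] - ctr[2], nctr[1] - ctr[1])
    cov <- polygon_covariance(vs)
    eg <- eigen(cov, symmetric = TRUE)
    aniso <- (eg$values[1] - eg$values[2]) / sum(eg$values)
    long_angle <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    tang <- radial + pi / 2
    data.frame(neighbor = ci, angle = radial,
               elongation_index = aniso * cos(2 * (long_angle - tang)))
  }))
  out[order(out$angle), ]
}
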