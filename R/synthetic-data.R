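# Generators for synthetic tissues, known-tension networks, and
# macropinocytosis event/track tables with the measured statistical
# structure of the real epithelium.

#' Parameters of the macropinocytosis event generator
#'
#' Defaults reproduce the measured event statistics: ruffle duration
#' 9.3 +/- 2.3 min, peak ruffle area 94 +/- 36 um^2 (which on ~412 um^2
#' host cells is the observed 22.8 +/- 6.6 % of apical area), mean apical
#' area loss of 10% per event scaling with event size, 10% shortening of
#' the event junction, and a preference for junctional localisation.
#' `loss_noise_sd` was calibrated once by bisection so that the sampling
#' distribution of the loss-size r-squared at n = 43 events centres near
#' 0.4, and is fixed here.
#'
#' @param rate baseline event rate (events per cell per hour).
#' @param duration_mean,duration_sd ruffle duration (min); draws are normal
#'   truncated above 1 min.
#' @param peak_mean,peak_sd peak ruffle area (um^2); draws are normal
#'   truncated to (0, host apical area).
#' @param apical_frac_mean,apical_frac_sd reference peak area as percent of
#'   host apical area (emerges from peak area and host size; kept for
#'   schema validation).
#' @param loss_frac mean apical-area loss fraction per event.
#' @param loss_noise_sd SD of the additive noise on the loss fraction.
#' @param junction_shorten fractional shortening of the event junction.
#' @param p_junctional probability an event is junctional (vs medial).
#' @param adjacency_multiplier event-rate multiplier for MCC-adjacent cells.
#' @param frame_interval track frame interval (min).
#' @param frame_noise_sd multiplicative per-frame measurement noise SD.
#' @return list of class `event_gen_params`.
#' @export
event_gen_params <- function(rate = 0.3, duration_mean = 9.3,
                             duration_sd = 2.3, peak_mean = 94,
                             peak_sd = 36, apical_frac_mean = 22.8,
                             apical_frac_sd = 6.6, loss_frac = 0.10,
                             loss_noise_sd = 0.036,
                             junction_shorten = 0.10, p_junctional = 0.7,
                             adjacency_multiplier = 2,
                             frame_interval = 0.5, frame_noise_sd = 0.01) {
  stopifnot(rate >= 0, duration_sd >= 0, peak_sd >= 0, loss_noise_sd >= 0,
            p_junctional >= 0, p_junctional <= 1, adjacency_multiplier >= 0,
            frame_interval > 0, frame_noise_sd >= 0)
  structure(list(rate = rate, duration_mean = duration_mean,
                 duration_sd = duration_sd, peak_mean = peak_mean,
                 peak_sd = peak_sd, apical_frac_mean = apical_frac_mean,
                 apical_frac_sd = apical_frac_sd, loss_frac = loss_frac,
                 loss_noise_sd = loss_noise_sd,
                 junction_shorten = junction_shorten,
                 p_junctional = p_junctional,
                 adjacency_multiplier = adjacency_multiplier,
                 frame_interval = frame_interval,
                 frame_noise_sd = frame_noise_sd),
            class = "event_gen_params")
}

# ---- Voronoi tessellation by half-plane clipping -------------------------

# Sutherland-Hodgman clip of a convex CCW polygon by n.x <= c
clip_halfplane <- function(poly, nrm, cc) {
  s <- poly %*% nrm - cc
  n <- nrow(poly)
  if (all(s <= 0)) return(poly)
  if (all(s >= 0)) return(poly[0, , drop = FALSE])
  out <- matrix(0, 0, 2)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (s[k] <= 0) out <- rbind(out, poly[k, ])
    if (s[k] * s[k2] < 0) {
      tt <- s[k] / (s[k] - s[k2])
      out <- rbind(out, poly[k, ] + tt * (poly[k2, ] - poly[k, ]))
    }
  }
  out
}

voronoi_polygons <- function(pts, boundary) {
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    poly <- boundary
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      # bisector can no longer cut once the neighbour is twice as far as
      # the farthest current polygon corner
      rmax2 <- max((poly[, 1] - pts[i, 1])^2 + (poly[, 2] - pts[i, 2])^2)
      if (d2[j] > 4 * rmax2) break
      nrm <- pts[j, ] - pts[i, ]
      cc <- (sum(pts[j, ]^2) - sum(pts[i, ]^2)) / 2
      poly <- clip_halfplane(poly, nrm, cc)
      if (nrow(poly) < 3) stop("degenerate Voronoi cell for seed ", i)
    }
    poly
  })
}

# merge points within `tol` (union-find over neighbouring grid bins)
merge_points <- function(P, tol = 1e-6) {
  n <- nrow(P)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  bins <- new.env(hash = TRUE, parent = emptyenv())
  bx <- floor(P[, 1] / tol)
  by <- floor(P[, 2] / tol)
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(bx[i] + dx, by[i] + dy)
      js <- bins[[key]]
      if (!is.null(js)) {
        for (j in js) {
          if (sum((P[i, ] - P[j, ])^2) <= tol^2) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    key <- paste(bx[i], by[i])
    bins[[key]] <- c(bins[[key]], i)
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- match(comp, unique(comp))
  coords <- matrix(0, max(ids), 2)
  for (k in seq_len(max(ids))) {
    idx <- which(ids == k)
    coords[k, ] <- colMeans(P[idx, , drop = FALSE])
  }
  list(ids = ids, coords = coords)
}

polygons_to_mesh <- function(polys, tol = 1e-6) {
  all_pts <- do.call(rbind, polys)
  mp <- merge_points(all_pts, tol)
  offsets <- c(0L, cumsum(vapply(polys, nrow, 0L)))
  ekey <- new.env(hash = TRUE, parent = emptyenv())
  edges <- matrix(0L, 0, 2)
  cell_edges <- vector("list", length(polys))
  for (ci in seq_along(polys)) {
    ids <- mp$ids[(offsets[ci] + 1L):offsets[ci + 1L]]
    ids <- ids[c(TRUE, ids[-1] != ids[-length(ids)])]
    if (ids[length(ids)] == ids[1]) ids <- ids[-length(ids)]
    if (length(ids) < 3) stop("degenerate polygon after vertex merging")
    loop <- integer(length(ids))
    for (k in seq_along(ids)) {
      v1 <- ids[k]
      v2 <- ids[if (k == length(ids)) 1L else k + 1L]
      key <- paste(min(v1, v2), max(v1, v2))
      e <- ekey[[key]]
      if (is.null(e)) {
        edges <- rbind(edges, c(v1, v2))
        e <- nrow(edges)
        ekey[[key]] <- e
        loop[k] <- e
      } else {
        loop[k] <- if (edges[e, 1] == v1) e else -e
      }
    }
    cell_edges[[ci]] <- loop
  }
  cells <- default_cell_state(length(polys))
  mesh <- new_mesh(mp$coords, edges, cell_edges, cells)
  mesh$cells$A0 <- geometry_vectors(mesh)$area
  mesh
}

#' Generate a synthetic epithelial tissue
#'
#' Poisson-disc seed points in a disc, Voronoi tessellation (computed by
#' half-plane clipping) and 3 Lloyd relaxation iterations produce a
#' realistic polygonal epithelium with mean apical area `mean_area`
#' (defaults to 412 um^2, the host-cell size implied by peak ruffle areas
#' of 94 um^2 covering 22.8% of the apical surface).  Optionally labels
#' MCCs using the exclusion-radius placement of [select_mccs()].
#'
#' @param n_cells number of cells (>= 3).
#' @param seed integer seed; the generator is a deterministic function of
#'   `(n_cells, seed, ...)`.
#' @param mean_area target mean apical area (um^2).
#' @param mcc logical; label MCCs.
#' @param lloyd number of Lloyd iterations.
#' @return a `synthetic_tissue`: list with `mesh` (an `epi_mesh` in um
#'   units), `cells` (data frame: `cell`, `x`, `y`, `area`, `is_mcc`,
#'   `group`), `seed`.
#' @export
gen_tissue <- function(n_cells, seed = 1L, mean_area = 412, mcc = FALSE,
                       lloyd = 3) {
  if (n_cells < 3) stop("n_cells must be >= 3")
  with_seed(seed, {
    R <- sqrt(mean_area * n_cells / pi)
    dmin <- 0.7 * sqrt(mean_area)
    th <- 2 * pi * (seq_len(64) - 1) / 64
    boundary <- cbind(R * cos(th), R * sin(th))
    pts <- matrix(0, 0, 2)
    tries <- 0
    while (nrow(pts) < n_cells) {
      cand <- c(runif(1, -R, R), runif(1, -R, R))
      tries <- tries + 1
      if (tries > 20000 * n_cells) stop("Poisson-disc sampling stalled")
      if (sum(cand^2) > (R - dmin / 2)^2) next
      if (nrow(pts) &&
          min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) < dmin^2)
        next
      pts <- rbind(pts, cand)
    }
    for (it in seq_len(lloyd)) {
      polys <- voronoi_polygons(pts, boundary)
      pts <- t(vapply(polys, polygon_centroid, c(0, 0)))
    }
    polys <- voronoi_polygons(pts, boundary)
    mesh <- polygons_to_mesh(polys)

    if (mcc) {
      mccs <- select_mccs(mesh)
      mesh$cells$is_mcc[mccs] <- TRUE
      mesh$cells$can_divide[mccs] <- FALSE
    }
    ctr <- cell_centroids(mesh)
    area <- geometry_vectors(mesh)$area
    group <- if (mcc) classify_cells(mesh) else {
      lab <- rep("non_adjacent", n_cells(mesh))
      lab[peripheral_cells(mesh)] <- "peripheral"
      factor(lab, levels = c("mcc", "mcc_adjacent", "non_adjacent",
                             "peripheral"))
    }
    structure(list(mesh = mesh,
                   cells = data.frame(cell = seq_len(n_cells(mesh)),
                                      x = ctr[, 1], y = ctr[, 2],
                                      area = area,
                                      is_mcc = mesh$cells$is_mcc,
                                      group = group),
                   seed = seed),
              class = "synthetic_tissue")
  })
}

#' Generate a tissue geometry equilibrated under known junction tensions
#'
#' Draws target lognormal tensions (mean 1, coefficient of variation
#' `tension_cv`) for the junctions of a synthetic tessellation and produces
#' a straight-edge geometry in exact force balance
#' (\eqn{\sum_j t_j \hat u_j = 0} at every internal node) together with its
#' tension truth table.  Because not every tension assignment is realisable
#' by a straight-edge network with pinned boundary (overloaded junctions
#' collapse), the draw is projected onto the realisable set: for positive
#' junction weights \eqn{w_j} the tension-weighted Laplacian (Tutte)
#' embedding is an exact equilibrium of the tensions
#' \eqn{t_j = w_j \ell_j}, and the weights are adjusted by a damped
#' self-consistency iteration towards the target draw.  The recorded truth
#' is the realised tensions; their coefficient of variation stays close to
#' `tension_cv`.
#'
#' @param n_cells tessellation size (>= 7).
#' @param tension_cv coefficient of variation of the target tension draw.
#' @param seed integer seed.
#' @param tol maximum node force-balance residual accepted at output.
#' @param n_project damped self-consistency iterations.
#' @return a `known_tension_mesh`: list with `network` (straight-segment
#'   junction geometry), `tensions` (realised true tensions, mean 1),
#'   `target_tensions` (the raw draw), `residual`, `converged`, `seed`.
#' @export
gen_known_tension_mesh <- function(n_cells = 50, tension_cv = 0.3,
                                   seed = 1L, tol = 1e-8, n_project = 60) {
  if (n_cells < 7) stop("n_cells must be >= 7")
  tissue <- gen_tissue(n_cells, seed = seed)
  network <- build_junction_network(tissue$mesh)
  jn <- network$junctions
  nd <- network$nodes
  target <- with_seed(seed + 1L, {
    if (tension_cv > 0) {
      sdlog <- sqrt(log(1 + tension_cv^2))
      rlnorm(nrow(jn), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(jn))
  })

  coords <- cbind(nd$x, nd$y)
  int_idx <- which(nd$internal)
  i1 <- match(jn$node1, nd$vertex)
  i2 <- match(jn$node2, nd$vertex)
  ip <- match(seq_len(nrow(nd)), int_idx)

  solve_tutte <- function(w, coords) {
    ni <- length(int_idx)
    Lmat <- matrix(0, ni, ni)
    b <- matrix(0, ni, 2)
    for (j in seq_along(i1)) {
      a1 <- ip[i1[j]]; a2 <- ip[i2[j]]
      if (!is.na(a1)) Lmat[a1, a1] <- Lmat[a1, a1] + w[j]
      if (!is.na(a2)) Lmat[a2, a2] <- Lmat[a2, a2] + w[j]
      if (!is.na(a1) && !is.na(a2)) {
        Lmat[a1, a2] <- Lmat[a1, a2] - w[j]
        Lmat[a2, a1] <- Lmat[a2, a1] - w[j]
      } else if (!is.na(a1)) {
        b[a1, ] <- b[a1, ] + w[j] * coords[i2[j], ]
      } else if (!is.na(a2)) {
        b[a2, ] <- b[a2, ] + w[j] * coords[i1[j], ]
      }
    }
    coords[int_idx, ] <- solve(Lmat, b)
    coords
  }
  lens <- function(coords)
    sqrt((coords[i2, 1] - coords[i1, 1])^2 +
           (coords[i2, 2] - coords[i1, 2])^2)

  med0 <- stats::median(jn$length)
  w <- target / jn$length
  for (k in seq_len(n_project)) {
    coords <- solve_tutte(w, coords)
    ln <- lens(coords)
    adj <- (target / (w * ln))^0.5
    adj[ln < 0.1 * med0 & adj > 1] <- 1  # stop inflating collapsing junctions
    w <- w * adj
  }
  coords <- solve_tutte(w, coords)
  ln <- lens(coords)
  tensions <- w * ln
  tensions <- tensions / mean(tensions)

  dxy <- cbind(coords[i2, 1] - coords[i1, 1], coords[i2, 2] - coords[i1, 2])
  fx <- tensions * dxy[, 1] / ln
  fy <- tensions * dxy[, 2] / ln
  rx <- ry <- numeric(nrow(coords))
  for (j in seq_along(i1)) {
    rx[i1[j]] <- rx[i1[j]] + fx[j]; ry[i1[j]] <- ry[i1[j]] + fy[j]
    rx[i2[j]] <- rx[i2[j]] - fx[j]; ry[i2[j]] <- ry[i2[j]] - fy[j]
  }
  res <- max(sqrt(rx[int_idx]^2 + ry[int_idx]^2))
  converged <- res < tol
  if (!converged)
    warning("known-tension equilibration residual ", signif(res, 3),
            " exceeds tol")

  nd$x <- coords[, 1]
  nd$y <- coords[, 2]
  jn$length <- ln
  jn$t1x <- dxy[, 1] / ln; jn$t1y <- dxy[, 2] / ln
  jn$t2x <- -jn$t1x; jn$t2y <- -jn$t1y
  network$nodes <- nd
  network$junctions <- jn
  structure(list(network = network, tensions = tensions,
                 target_tensions = target, residual = res,
                 converged = converged, seed = seed),
            class = "known_tension_mesh")
}

# truncated-normal draw by rejection
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

# shared track builder: multiplicative event ramps + frame noise
build_tracks <- function(tissue, events, params, duration, network) {
  times <- seq(0, duration, by = params$frame_interval)
  nc <- nrow(tissue$cells)
  areas <- matrix(rep(tissue$cells$area, each = length(times)),
                  nrow = length(times))
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      ramp <- rep(1, length(times))
      ramp[times >= ev$end] <- 1 - ev$loss_frac
      mid <- times > ev$onset & times < ev$end
      ramp[mid] <- 1 - ev$loss_frac * (times[mid] - ev$onset) /
        (ev$end - ev$onset)
      areas[, ev$cell] <- areas[, ev$cell] * ramp
    }
  }
  areas <- areas * matrix(1 + rnorm(length(areas), 0, params$frame_noise_sd),
                          nrow = nrow(areas))
  cells_long <- data.frame(
    cell = rep(seq_len(nc), each = length(times)),
    time = rep(times, nc),
    area = as.vector(areas))

  jn <- network$junctions
  interior <- which(!is.na(jn$cell2))
  lens <- matrix(rep(jn$length[interior], each = length(times)),
                 nrow = length(times))
  colnames(lens) <- jn$junction[interior]
  if (nrow(events)) {
    jev <- events[!is.na(events$junction), , drop = FALSE]
    for (k in seq_len(nrow(jev))) {
      ev <- jev[k, ]
      col <- match(ev$junction, jn$junction[interior])
      if (is.na(col)) next
      ramp <- rep(1, length(times))
      ramp[times >= ev$end] <- 1 - params$junction_shorten
      mid <- times > ev$onset & times < ev$end
      ramp[mid] <- 1 - params$junction_shorten * (times[mid] - ev$onset) /
        (ev$end - ev$onset)
      lens[, col] <- lens[, col] * ramp
    }
  }
  lens <- lens * matrix(1 + rnorm(length(lens), 0, params$frame_noise_sd),
                        nrow = nrow(lens))
  junctions_long <- data.frame(
    junction = rep(jn$junction[interior], each = length(times)),
    time = rep(times, length(interior)),
    length = as.vector(lens))

  structure(list(cells = cells_long, junctions = junctions_long,
                 frame_interval = params$frame_interval, times = times,
                 extrusions = data.frame(cell = integer(), time = numeric(),
                                         x = numeric(), y = numeric())),
            class = "cell_tracks")
}

round_to_frame <- function(t, dt) round(t / dt) * dt

#' Generate macropinocytosis events and cell/junction tracks
#'
#' Events arrive per cell as a Poisson process at the configured rate
#' (multiplied by `adjacency_multiplier` for MCC-adjacent cells; MCCs never
#' host events).  Per event: duration ~ Normal(9.3, 2.3) truncated above
#' 1 min; peak ruffle area ~ Normal(94, 36) truncated to (0, host area);
#' the host apical-area trace loses the fraction
#' `loss_frac * peak / peak_mean + Normal(0, loss_noise_sd)` (clipped at 0)
#' ramped linearly over the event, and junctional events shorten their
#' junction by `junction_shorten`.  Multiplicative frame noise is applied
#' to all traces.
#'
#' @param tissue a [gen_tissue()] result.
#' @param params an [event_gen_params()] list.
#' @param duration recording length (min); must exceed the longest event
#'   plus margins.
#' @param seed integer seed.
#' @return list with `events` (data frame: `event`, `cell`, `onset`,
#'   `duration`, `end`, `peak_area`, `loss_frac`, `location`, `junction`,
#'   `adjacency`), `tracks` (a `cell_tracks`), `params`, `seed`.
#' @export
gen_events <- function(tissue, params = event_gen_params(), duration = 60,
                       seed = 1L) {
  network <- build_junction_network(tissue$mesh)
  with_seed(seed, {
    nc <- nrow(tissue$cells)
    adj <- tissue$cells$group == "mcc_adjacent"
    lambda <- params$rate * ifelse(adj, params$adjacency_multiplier, 1) *
      (duration / 60)
    lambda[tissue$cells$is_mcc] <- 0
    n_ev <- rpois(nc, lambda)
    host <- rep(seq_len(nc), n_ev)
    n <- length(host)
    if (n == 0) {
      events <- data.frame(event = integer(), cell = integer(),
                           onset = numeric(), duration = numeric(),
                           end = numeric(), peak_area = numeric(),
                           loss_frac = numeric(), location = character(),
                           junction = integer(), adjacency = character())
      return(list(events = events,
                  tracks = build_tracks(tissue, events, params, duration,
                                        network),
                  params = params, seed = seed))
    }
    dur <- rtrunc_norm(n, params$duration_mean, params$duration_sd, lower = 1)
    if (any(dur + 2 > duration))
      stop("recording too short for the drawn event durations")
    onset <- round_to_frame(runif(n, 1, duration - dur - 1),
                            params$frame_interval)
    end <- round_to_frame(onset + dur, params$frame_interval)
    peak <- vapply(seq_len(n), function(k)
      rtrunc_norm(1, params$peak_mean, params$peak_sd, lower = 0,
                  upper = tissue$cells$area[host[k]]), 0)
    loss <- pmax(params$loss_frac * peak / params$peak_mean +
                   rnorm(n, 0, params$loss_noise_sd), 0)
    junctional <- runif(n) < params$p_junctional
    jn <- network$junctions
    junction <- rep(NA_integer_, n)
    for (k in which(junctional)) {
      cand <- jn$junction[!is.na(jn$cell2) &
                            (jn$cell1 == host[k] | jn$cell2 == host[k])]
      if (length(cand))
        junction[k] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    events <- data.frame(
      event = seq_len(n), cell = host, onset = onset, duration = dur,
      end = end, peak_area = peak, loss_frac = loss,
      location = ifelse(!is.na(junction), "junctional", "medial"),
      junction = junction,
      adjacency = as.character(tissue$cells$group[host]))
    list(events = events,
         tracks = build_tracks(tissue, events, params, duration, network),
         params = params, seed = seed)
  })
}

#' Generate a compression-induced wave of macropinocytosis
#'
#' Event onsets follow a Gaussian pulse in time (centre `pulse_time`, width
#' `pulse_sd`) with per-cell expected event count `pulse_events`, reaching
#' nearly every cell at the defaults; optional extrusions locally suppress
#' the event rate of the extruded cell's direct neighbours (factor
#' `neighbor_suppression` within 10 min after extrusion).  Inhibitor mode
#' scales the event rate by 0.1 and multiplies the number of extrusions by
#' `extrusion_multiplier`.
#'
#' @param tissue a [gen_tissue()] result.
#' @param seed integer seed.
#' @param params an [event_gen_params()] list.
#' @param duration recording length (min).
#' @param pulse_time,pulse_sd centre and SD of the event-onset pulse (min).
#' @param pulse_events expected events per cell over the pulse.
#' @param n_extrusions number of extrusion events.
#' @param neighbor_suppression event-rate multiplier for direct neighbours
#'   of an extruded cell within 10 min after the extrusion.
#' @param inhibitor logical; macropinocytosis-inhibited condition.
#' @param extrusion_multiplier extrusion-count multiplier under inhibition.
#' @return list with `events`, `tracks` (extrusions attached), `extrusions`,
#'   `params`, `seed`.
#' @export
gen_compression_wave <- function(tissue, seed = 1L,
                                 params = event_gen_params(),
                                 duration = 40, pulse_time = 12,
                                 pulse_sd = 3, pulse_events = 3,
                                 n_extrusions = 2,
                                 neighbor_suppression = 0.3,
                                 inhibitor = FALSE,
                                 extrusion_multiplier = 3) {
  network <- build_junction_network(tissue$mesh)
  g <- adjacency_graph(tissue$mesh)
  with_seed(seed, {
    nc <- nrow(tissue$cells)
    lam <- rep(pulse_events, nc)
    if (inhibitor) lam <- lam * 0.1
    lam[tissue$cells$is_mcc] <- 0
    nx <- n_extrusions * if (inhibitor) extrusion_multiplier else 1
    eligible <- which(!tissue$cells$is_mcc &
                        tissue$cells$group != "peripheral")
    ext_cells <- sample(eligible, min(nx, length(eligible)))
    ext_times <- round_to_frame(
      pmin(pmax(rnorm(length(ext_cells), pulse_time, pulse_sd / 2), 2),
           duration - 2), params$frame_interval)
    extrusions <- data.frame(cell = ext_cells, time = ext_times,
                             x = tissue$cells$x[ext_cells],
                             y = tissue$cells$y[ext_cells])

    n_ev <- rpois(nc, lam)
    host <- rep(seq_len(nc), n_ev)
    n <- length(host)
    dur <- rtrunc_norm(n, params$duration_mean, params$duration_sd, lower = 1)
    onset <- rnorm(n, pulse_time, pulse_sd)
    onset <- round_to_frame(pmin(pmax(onset, 1), duration - dur - 1),
                            params$frame_interval)
    # thin neighbour events after extrusions
    keep <- rep(TRUE, n)
    for (x in seq_len(nrow(extrusions))) {
      nb <- as.integer(igraph::neighbors(g, extrusions$cell[x]))
      hit <- host %in% nb & onset > extrusions$time[x] &
        onset <= extrusions$time[x] + 10
      keep[hit] <- keep[hit] & (runif(sum(hit)) < neighbor_suppression)
    }
    host <- host[keep]; dur <- dur[keep]; onset <- onset[keep]
    n <- length(host)
    end <- round_to_frame(onset + dur, params$frame_interval)
    peak <- vapply(seq_len(n), function(k)
      rtrunc_norm(1, params$peak_mean, params$peak_sd, lower = 0,
                  upper = tissue$cells$area[host[k]]), 0)
    loss <- pmax(params$loss_frac * peak / params$peak_mean +
                   rnorm(n, 0, params$loss_noise_sd), 0)
    junctional <- runif(n) < params$p_junctional
    jnj <- network$junctions
    junction <- rep(NA_integer_, n)
    for (k in which(junctional)) {
      cand <- jnj$junction[!is.na(jnj$cell2) &
                             (jnj$cell1 == host[k] | jnj$cell2 == host[k])]
      if (length(cand))
        junction[k] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    events <- data.frame(
      event = seq_len(n), cell = host, onset = onset, duration = dur,
      end = end, peak_area = peak, loss_frac = loss,
      location = ifelse(!is.na(junction), "junctional", "medial"),
      junction = junction,
      adjacency = as.character(tissue$cells$group[host]))
    tracks <- build_tracks(tissue, events, params, duration, network)
    tracks$extrusions <- extrusions
    list(events = events, tracks = tracks, extrusions = extrusions,
         params = params, seed = seed)
  })
}
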