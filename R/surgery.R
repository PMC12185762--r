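# Topological surgeries: cell division and T1 neighbour exchange.
# Both rebuild the affected cell loops by chaining their edge sets and
# re-orienting counter-clockwise, which keeps B %*% A = 0 by construction.

# chain an unsigned edge set into a signed CCW loop
chain_loop <- function(edges, vertices, edge_ids) {
  remaining <- edge_ids
  e0 <- remaining[1]
  loop <- e0
  startv <- edges[e0, 1]
  cur <- edges[e0, 2]
  remaining <- remaining[-1]
  while (length(remaining)) {
    hit <- which(edges[remaining, 1] == cur | edges[remaining, 2] == cur)
    if (!length(hit)) stop("edge set does not chain into a loop")
    e <- remaining[hit[1]]
    if (edges[e, 1] == cur) {
      loop <- c(loop, e)
      cur <- edges[e, 2]
    } else {
      loop <- c(loop, -e)
      cur <- edges[e, 1]
    }
    remaining <- remaining[-hit[1]]
  }
  if (cur != startv) stop("edge set does not close into a loop")
  vs <- ifelse(loop > 0, edges[abs(loop), 1], edges[abs(loop), 2])
  p <- vertices[vs, , drop = FALSE]
  j <- c(2:nrow(p), 1)
  if (sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) < 0) loop <- rev(-loop)
  loop
}

# insert a vertex at `pt` on edge e; returns list(mesh, vertex, new_edge)
split_edge <- function(mesh, e, pt) {
  h <- mesh$edges[e, 2]
  mesh$vertices <- rbind(mesh$vertices, matrix(pt, 1, 2))
  m <- nrow(mesh$vertices)
  mesh$edges[e, 2] <- m
  mesh$edges <- rbind(mesh$edges, c(m, h))
  e2 <- nrow(mesh$edges)
  for (ci in seq_along(mesh$cell_edges)) {
    lp <- mesh$cell_edges[[ci]]
    k <- which(abs(lp) == e)
    if (!length(k)) next
    piece <- if (lp[k] > 0) c(e, e2) else c(-e2, -e)
    mesh$cell_edges[[ci]] <- append(lp[-k], piece, after = k - 1L)
  }
  list(mesh = mesh, vertex = m, new_edge = e2)
}

#' Divide a cell along its short axis
#'
#' The cell is split by a chord through its centroid perpendicular to its
#' long axis (the principal axis of the polygon's second area moment).  Two
#' vertices are inserted on the crossed edges and joined by a new edge;
#' daughters restart at age 0 with preferred area 1, inherit the parent's
#' stiffness prefactor and flags, and redraw their cycle times.  If the chord
#' fails to cross exactly two edges the axis is jittered (up to 10 tries).
#'
#' @param mesh an `epi_mesh`.
#' @param cell index of the dividing cell; must have `can_divide = TRUE`.
#' @param params a [mech_params()] list (cycle-time redraw).
#' @return the mesh with one extra cell, two extra vertices, three extra
#'   edges.
#' @export
divide_cell <- function(mesh, cell, params = mech_params()) {
  if (!mesh$cells$can_divide[cell])
    stop("cell ", cell, " is not allowed to divide")
  vs <- cell_vertices(mesh, cell)
  P <- mesh$vertices[vs, , drop = FALSE]
  ctr <- polygon_centroid(P)
  eg <- eigen(polygon_covariance(P), symmetric = TRUE)
  axis_normal <- eg$vectors[, 1]   # long axis: chord runs perpendicular to it
  nv <- length(vs)
  j <- c(2:nv, 1)

  for (try in 1:10) {
    nrm <- axis_normal
    if (try > 1) {
      th <- runif(1, -0.4, 0.4)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      nrm <- as.vector(R %*% axis_normal)
    }
    s <- (P[, 1] - ctr[1]) * nrm[1] + (P[, 2] - ctr[2]) * nrm[2]
    if (any(abs(s) < 1e-10)) next
    crossing <- which(s * s[j] < 0)
    if (length(crossing) != 2) next

    lp <- mesh$cell_edges[[cell]]
    pts <- lapply(crossing, function(k) {
      tpar <- s[k] / (s[k] - s[j[k]])
      P[k, ] + tpar * (P[j[k], ] - P[k, ])
    })
    ge <- abs(lp[crossing])   # global edges crossed

    sp1 <- split_edge(mesh, ge[1], pts[[1]])
    m1 <- sp1$vertex
    sp2 <- split_edge(sp1$mesh, ge[2], pts[[2]])
    m2 <- sp2$vertex
    mesh2 <- sp2$mesh

    mesh2$edges <- rbind(mesh2$edges, c(m1, m2))
    d <- nrow(mesh2$edges)

    lp2 <- mesh2$cell_edges[[cell]]
    w <- ifelse(lp2 > 0, mesh2$edges[abs(lp2), 1], mesh2$edges[abs(lp2), 2])
    i1 <- which(w == m1)
    i2 <- which(w == m2)
    lo <- min(i1, i2); hi <- max(i1, i2)
    seg1 <- abs(lp2[lo:(hi - 1L)])
    seg2 <- abs(lp2[setdiff(seq_along(lp2), lo:(hi - 1L))])

    mesh2$cell_edges[[cell]] <- chain_loop(mesh2$edges, mesh2$vertices,
                                           c(seg1, d))
    mesh2$cell_edges[[length(mesh2$cell_edges) + 1L]] <-
      chain_loop(mesh2$edges, mesh2$vertices, c(seg2, d))

    parent <- mesh2$cells[cell, ]
    daughter <- parent
    daughter$age <- 0
    daughter$A0 <- 1
    daughter$cycle_time <- draw_cycle_time(1, params$cycle_time,
                                           params$cycle_jitter)
    mesh2$cells[cell, ] <- daughter
    mesh2$cells <- rbind(mesh2$cells, {
      d2 <- daughter
      d2$cycle_time <- draw_cycle_time(1, params$cycle_time,
                                       params$cycle_jitter)
      d2
    })
    rownames(mesh2$cells) <- NULL
    return(mesh2)
  }
  stop("division chord failed to cross exactly 2 edges after 10 jittered tries")
}

#' T1 neighbour exchange on a short edge
#'
#' The edge is collapsed to its midpoint and reopened perpendicular with
#' length `1.5 * params$t1_threshold`; the two cells formerly sharing it
#' lose adjacency and the two flanking cells gain it.  Vertex, edge and cell
#' counts are unchanged.  Ineligible calls (boundary edge, endpoint degree
#' not 3, missing or identical flanking cells) skip with a message and
#' return the mesh unchanged, carrying attribute `t1_skipped`.
#'
#' @param mesh an `epi_mesh`.
#' @param e edge index.
#' @param params a [mech_params()] list.
#' @return the modified mesh (or unchanged mesh with attribute `t1_skipped`).
#' @export
t1_transition <- function(mesh, e, params = mech_params()) {
  skip <- function(reason) {
    message("T1 skipped on edge ", e, ": ", reason)
    attr(mesh, "t1_skipped") <- reason
    mesh
  }
  ec <- edge_cells(mesh)
  cs <- ec[[e]]
  if (length(cs) != 2) return(skip("boundary edge"))
  c1 <- cs[1]; c2 <- cs[2]
  u <- mesh$edges[e, 1]; w <- mesh$edges[e, 2]
  deg <- tabulate(c(mesh$edges[, 1], mesh$edges[, 2]),
                  nbins = nrow(mesh$vertices))
  if (deg[u] != 3 || deg[w] != 3) return(skip("endpoint degree != 3"))

  eu <- setdiff(which(mesh$edges[, 1] == u | mesh$edges[, 2] == u), e)
  ew <- setdiff(which(mesh$edges[, 1] == w | mesh$edges[, 2] == w), e)
  a <- setdiff(unique(unlist(ec[eu])), c(c1, c2))
  b <- setdiff(unique(unlist(ec[ew])), c(c1, c2))
  if (length(a) != 1 || length(b) != 1) return(skip("no flanking cell"))
  if (a == b) return(skip("flanking cells coincide"))

  beta  <- eu[vapply(ec[eu], function(z) c2 %in% z, FALSE)]  # u-edge of c2
  gamma <- ew[vapply(ec[ew], function(z) c1 %in% z, FALSE)]  # w-edge of c1
  if (length(beta) != 1 || length(gamma) != 1)
    return(skip("ambiguous local configuration"))

  vu <- mesh$vertices[u, ]; vw <- mesh$vertices[w, ]
  mid <- (vu + vw) / 2
  tangent <- vw - vu
  nrm <- c(-tangent[2], tangent[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  ctr1 <- polygon_centroid(mesh$vertices[cell_vertices(mesh, c1), ,
                                         drop = FALSE])
  if (sum(nrm * (ctr1 - mid)) < 0) nrm <- -nrm
  newlen <- 1.5 * params$t1_threshold
  if (newlen <= 0) newlen <- 1.5 * 0.05
  mesh$vertices[u, ] <- mid + nrm * newlen / 2   # u stays on the c1 side
  mesh$vertices[w, ] <- mid - nrm * newlen / 2

  # rewire: gamma releases w and grabs u; beta releases u and grabs w
  mesh$edges[gamma, ][mesh$edges[gamma, ] == w] <- u
  mesh$edges[beta, ][mesh$edges[beta, ] == u] <- w

  sets <- list()
  sets[[1]] <- setdiff(abs(mesh$cell_edges[[c1]]), e)
  sets[[2]] <- setdiff(abs(mesh$cell_edges[[c2]]), e)
  sets[[3]] <- c(abs(mesh$cell_edges[[a]]), e)
  sets[[4]] <- c(abs(mesh$cell_edges[[b]]), e)
  ids <- c(c1, c2, a, b)
  for (k in 1:4)
    mesh$cell_edges[[ids[k]]] <- chain_loop(mesh$edges, mesh$vertices,
                                            sets[[k]])
  mesh
}

#' Advance the tissue in time with growth
#'
#' Interleaves quasi-static relaxation with age increments.  When a cell's
#' age exceeds its drawn cycle time it divides; divisions are processed one
#' at a time in order of imminence, so any cell-count threshold is reached
#' exactly.  With `divide = FALSE` this reduces to a relaxation (ages still
#' advance).
#'
#' @param mesh an `epi_mesh`.
#' @param params a [mech_params()] list.
#' @param duration model time to advance.
#' @param divide logical; allow divisions.
#' @param tol force tolerance for the interleaved relaxations.
#' @param max_steps_each relaxation budget after each division.
#' @return the advanced mesh.
#' @export
advance <- function(mesh, params = mech_params(), duration = 1,
                    divide = TRUE, tol = params$growth_tol,
                    max_steps_each = 5000L) {
  if (duration <= 0) return(mesh)
  t <- 0
  repeat {
    dividable <- if (divide) which(mesh$cells$can_divide) else integer(0)
    if (length(dividable)) {
      wait <- pmax(mesh$cells$cycle_time[dividable] -
                     mesh$cells$age[dividable], 0)
      k <- dividable[which.min(wait)]
      wmin <- min(wait)
    } else {
      wmin <- Inf
    }
    if (t + wmin > duration) {
      mesh$cells$age <- mesh$cells$age + (duration - t)
      mesh <- relax(mesh, params, max_steps = max_steps_each, tol = tol)
      return(mesh)
    }
    mesh$cells$age <- mesh$cells$age + wmin
    t <- t + wmin
    mesh <- divide_cell(mesh, k, params)
    mesh <- relax(mesh, params, max_steps = max_steps_each, tol = tol)
  }
}

# grow by sequential divisions until the cell count reaches `target` exactly
grow_to_count <- function(mesh, params, target, tol = params$growth_tol,
                          max_steps_each = 5000L) {
  while (n_cells(mesh) < target) {
    dividable <- which(mesh$cells$can_divide)
    if (!length(dividable))
      stop("no dividable cells left before reaching ", target, " cells")
    wait <- pmax(mesh$cells$cycle_time[dividable] -
                   mesh$cells$age[dividable], 0)
    k <- dividable[which.min(wait)]
    mesh$cells$age <- mesh$cells$age + min(wait)
    mesh <- divide_cell(mesh, k, params)
    mesh <- relax(mesh, params, max_steps = max_steps_each, tol = tol)
  }
  mesh
}
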