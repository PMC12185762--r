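# Geometry-based relative junction-tension inference (force balance at
# triple junctions) with N1-N4 ring classification around an event.

#' Build a junction network from a polygonal tessellation
#'
#' Nodes are mesh vertices of degree >= 3; chains of degree-2 vertices are
#' merged into single junction curves between nodes (so 4-fold vertices are
#' retained as one node with 4 junctions).  Endpoint unit tangents are
#' estimated from the first curve segment at each node, directed away from
#' the node.  A node is internal when none of its incident mesh edges is a
#' boundary edge; only internal nodes contribute force-balance equations.
#'
#' @param mesh an `epi_mesh` (simulated monolayer or synthetic tessellation).
#' @return a `junction_network`: list with data frames `nodes` (`vertex`,
#'   `x`, `y`, `degree`, `internal`) and `junctions` (`junction`, `node1`,
#'   `node2`, `cell1`, `cell2`, `length`, tangent components `t1x`, `t1y`,
#'   `t2x`, `t2y`).
#' @export
build_junction_network <- function(mesh) {
  deg <- tabulate(c(mesh$edges[, 1], mesh$edges[, 2]),
                  nbins = nrow(mesh$vertices))
  if (any(deg == 1))
    stop("dangling edges at vertices: ",
         paste(utils::head(which(deg == 1), 10), collapse = ", "))
  cnt <- edge_cell_count(mesh)
  ec <- edge_cells(mesh)
  is_node <- deg >= 3
  node_ids <- which(is_node)
  if (!length(node_ids)) stop("tessellation has no junction nodes")

  # vertex -> incident edges
  inc <- split(rep(seq_len(nrow(mesh$edges)), 2),
               c(mesh$edges[, 1], mesh$edges[, 2]))
  other_end <- function(e, v)
    if (mesh$edges[e, 1] == v) mesh$edges[e, 2] else mesh$edges[e, 1]

  visited <- logical(nrow(mesh$edges))
  jlist <- list()
  for (v0 in node_ids) {
    for (e0 in inc[[as.character(v0)]]) {
      if (visited[e0]) next
      chain <- e0
      prev <- v0
      cur <- other_end(e0, v0)
      while (!is_node[cur]) {
        es <- inc[[as.character(cur)]]
        nxt <- es[es != chain[length(chain)]]
        chain <- c(chain, nxt)
        prev <- cur
        cur <- other_end(nxt, cur)
      }
      visited[chain] <- TRUE
      # tangents from the first segment at each endpoint, away from the node
      first_other <- other_end(chain[1], v0)
      last_e <- chain[length(chain)]
      last_other <- other_end(last_e, cur)
      t1 <- mesh$vertices[first_other, ] - mesh$vertices[v0, ]
      t2 <- mesh$vertices[last_other, ] - mesh$vertices[cur, ]
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- t2 / sqrt(sum(t2^2))
      cells <- sort(unique(unlist(ec[chain])))
      seg <- mesh$vertices[mesh$edges[chain, 2], , drop = FALSE] -
        mesh$vertices[mesh$edges[chain, 1], , drop = FALSE]
      jlist[[length(jlist) + 1L]] <- data.frame(
        node1 = v0, node2 = cur,
        cell1 = cells[1], cell2 = if (length(cells) > 1) cells[2] else NA,
        length = sum(sqrt(rowSums(seg^2))),
        t1x = t1[1], t1y = t1[2], t2x = t2[1], t2y = t2[2])
    }
  }
  junctions <- do.call(rbind, jlist)
  junctions$junction <- seq_len(nrow(junctions))
  junctions <- junctions[, c("junction", "node1", "node2", "cell1", "cell2",
                             "length", "t1x", "t1y", "t2x", "t2y")]
  boundary_v <- unique(as.vector(mesh$edges[cnt == 1L, ]))
  nodes <- data.frame(vertex = node_ids,
                      x = mesh$vertices[node_ids, 1],
                      y = mesh$vertices[node_ids, 2],
                      degree = deg[node_ids],
                      internal = !(node_ids %in% boundary_v))
  structure(list(nodes = nodes, junctions = junctions),
            class = "junction_network")
}

#' @exportS3Method base::print
print.junction_network <- function(x, ...) {
  cat(sprintf("<junction_network> %d nodes (%d internal), %d junctions\n",
              nrow(x$nodes), sum(x$nodes$internal), nrow(x$junctions)))
  invisible(x)
}

#' Infer relative junction tensions from geometry
#'
#' Stacks two force-balance rows per internal node,
#' \eqn{\sum_{j \ni n} t_j \hat u_j = 0} with \eqn{\hat u_j} the unit
#' tangent of junction j directed away from node n, and solves the
#' homogeneous least-squares problem subject to the mean of the solved
#' tensions being 1 (tensions are only identifiable up to a global scale).
#' Junctions touching no internal node are unconstrained and reported as
#' `NA`.
#'
#' @param network a [build_junction_network()] result.
#' @param normalization `"mean"` (mean of solved tensions = 1, the
#'   convention used throughout) or `"unit"` (unit Euclidean norm scaled to
#'   mean 1 afterwards is identical here, kept for interface compatibility).
#' @return a `tension_solution`: list with `tensions` (full-length vector,
#'   `NA` where unsolved), `solved` (junction ids), `residual`,
#'   `rank_deficient`, `underdetermined`, `n_equations`.
#' @export
infer_tensions <- function(network, normalization = c("mean", "unit")) {
  normalization <- match.arg(normalization)
  jn <- network$junctions
  internal <- network$nodes$vertex[network$nodes$internal &
                                     network$nodes$degree >= 3]
  if (!length(internal))
    stop("network has no internal node; tensions are not identifiable")
  solved <- jn$junction[jn$node1 %in% internal | jn$node2 %in% internal]
  ns <- length(solved)
  col_of <- match(jn$junction, solved)
  M <- matrix(0, 2 * length(internal), ns)
  for (k in seq_along(internal)) {
    nd <- internal[k]
    at1 <- which(jn$node1 == nd)
    at2 <- which(jn$node2 == nd)
    for (j in at1) {
      M[2 * k - 1, col_of[j]] <- M[2 * k - 1, col_of[j]] + jn$t1x[j]
      M[2 * k,     col_of[j]] <- M[2 * k,     col_of[j]] + jn$t1y[j]
    }
    for (j in at2) {
      M[2 * k - 1, col_of[j]] <- M[2 * k - 1, col_of[j]] + jn$t2x[j]
      M[2 * k,     col_of[j]] <- M[2 * k,     col_of[j]] + jn$t2y[j]
    }
  }
  underdetermined <- nrow(M) + 1L < ns
  K <- rbind(cbind(2 * crossprod(M), rep(1, ns)), c(rep(1, ns), 0))
  rhs <- c(rep(0, ns), ns)
  sol <- tryCatch(solve(K, rhs), error = function(e) MASS::ginv(K) %*% rhs)
  t_solved <- as.vector(sol)[seq_len(ns)]
  t_solved <- t_solved / mean(t_solved)
  rank_m <- qr(M)$rank
  tensions <- rep(NA_real_, nrow(jn))
  tensions[match(solved, jn$junction)] <- t_solved
  structure(list(tensions = tensions, solved = solved,
                 residual = sqrt(sum((M %*% t_solved)^2)),
                 rank_deficient = rank_m < ns - 1L,
                 underdetermined = underdetermined,
                 n_equations = nrow(M)),
            class = "tension_solution")
}

#' @exportS3Method base::print
print.tension_solution <- function(x, ...) {
  cat(sprintf(
    "<tension_solution> %d solved junctions, residual %.3g%s\n",
    length(x$solved), x$residual,
    if (x$rank_deficient) " (rank deficient)" else ""))
  invisible(x)
}

#' Label junctions by contiguity distance from an event (N1-N4)
#'
#' N1 are the junction(s) of the macropinocytotic event: the given junction
#' when the event sits on a specific junction, otherwise every junction of
#' the host cell.  N2 are junctions sharing a node with any N1 junction,
#' N3 and N4 follow by iterated contiguity; the first assigned label wins,
#' and junctions further than 4 steps are labelled `beyond`.
#'
#' @param network a [build_junction_network()] result.
#' @param event_cell host-cell index (used when `event_junction` is NULL).
#' @param event_junction optional junction id of the event.
#' @return factor over junctions with levels `N1`..`N4`, `beyond`.
#' @export
ring_labels <- function(network, event_cell = NULL, event_junction = NULL) {
  jn <- network$junctions
  if (!is.null(event_junction)) {
    if (!all(event_junction %in% jn$junction))
      stop("event junction not present in the network: ",
           paste(setdiff(event_junction, jn$junction), collapse = ", "))
    n1 <- event_junction
  } else {
    if (is.null(event_cell))
      stop("either event_cell or event_junction must be given")
    n1 <- jn$junction[which(jn$cell1 %in% event_cell |
                              jn$cell2 %in% event_cell)]
    if (!length(n1)) stop("event cell borders no junction in the network")
  }
  lab <- rep(NA_character_, nrow(jn))
  lab[match(n1, jn$junction)] <- "N1"
  frontier_nodes <- unique(c(jn$node1[!is.na(lab)], jn$node2[!is.na(lab)]))
  for (ring in c("N2", "N3", "N4")) {
    nxt <- which(is.na(lab) & (jn$node1 %in% frontier_nodes |
                                 jn$node2 %in% frontier_nodes))
    if (!length(nxt)) break
    lab[nxt] <- ring
    frontier_nodes <- unique(c(frontier_nodes, jn$node1[nxt], jn$node2[nxt]))
  }
  lab[is.na(lab)] <- "beyond"
  factor(lab, levels = c("N1", "N2", "N3", "N4", "beyond"))
}

#' Per-ring tension ratio after versus before an event
#'
#' For each ring label, the mean over the after frames of the ring's mean
#' inferred tension, divided by the same quantity over the before frames.
#' Tensions are relative (mean-normalised per frame), so a global rescaling
#' of any frame leaves the ratios unchanged.  Empty rings give `NA`.
#'
#' @param solutions_before,solutions_after lists (1-4 frames each) of
#'   [infer_tensions()] solutions or plain tension vectors with consistent
#'   junction indexing.
#' @param labels ring factor from [ring_labels()].
#' @return named numeric vector of ratios for `N1`..`N4` and `beyond`.
#' @export
before_after_ratio <- function(solutions_before, solutions_after, labels) {
  get_t <- function(s) if (inherits(s, "tension_solution")) s$tensions else s
  pull <- function(sols) {
    stopifnot(length(sols) >= 1)
    if (length(sols) > 4)
      warning("more than 4 frames supplied; all are averaged")
    do.call(rbind, lapply(sols, get_t))
  }
  tb <- pull(solutions_before)
  ta <- pull(solutions_after)
  stopifnot(ncol(tb) == length(labels), ncol(ta) == length(labels))
  vapply(levels(labels), function(rg) {
    idx <- which(labels == rg)
    if (!length(idx)) return(NA_real_)
    mb <- mean(rowMeans(tb[, idx, drop = FALSE], na.rm = TRUE))
    ma <- mean(rowMeans(ta[, idx, drop = FALSE], na.rm = TRUE))
    ma / mb
  }, 0)
}
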