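#' @useDynLib epivertex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif quantile sd rnorm rpois rlnorm setNames
#' @importFrom utils head tail
NULL

#' Construct a polygonal monolayer mesh
#'
#' A mesh is a planar polygonal tiling stored as vertex coordinates, directed
#' edges, and per-cell ordered signed edge loops.  The signed edge-vertex
#' incidence matrix \eqn{A} (+1 at the head, -1 at the tail of each edge) and
#' the signed cell-edge incidence matrix \eqn{B} (+1 when the stored edge
#' direction agrees with the cell's counter-clockwise traversal) are derived
#' from this representation; closure of every cell boundary is equivalent to
#' \eqn{B A = 0}.
#'
#' @param vertices numeric matrix (n_v x 2) of vertex coordinates.
#' @param edges integer matrix (n_e x 2) with columns tail, head.
#' @param cell_edges list of signed integer vectors; entry `k` of cell `c` is
#'   `+e` if edge `e` is traversed tail-to-head at position `k` of the cell's
#'   counter-clockwise boundary loop, `-e` otherwise.
#' @param cells data frame of per-cell state with columns `age`, `A0`,
#'   `sigma`, `is_mcc`, `can_divide`, `cycle_time`.
#' @return an object of class `epi_mesh`.
#' @export
new_mesh <- function(vertices, edges, cell_edges, cells) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2,
            is.matrix(edges), ncol(edges) == 2,
            is.list(cell_edges), is.data.frame(cells),
            nrow(cells) == length(cell_edges))
  needed <- c("age", "A0", "sigma", "is_mcc", "can_divide", "cycle_time")
  missing <- setdiff(needed, names(cells))
  if (length(missing))
    stop("cells data frame lacks columns: ", paste(missing, collapse = ", "))
  storage.mode(edges) <- "integer"
  structure(list(vertices = vertices, edges = edges,
                 cell_edges = cell_edges, cells = cells),
            class = "epi_mesh")
}

#' @exportS3Method base::print
print.epi_mesh <- function(x, ...) {
  cat(sprintf("<epi_mesh> %d cells, %d edges, %d vertices (%d MCCs)\n",
              n_cells(x), nrow(x$edges), nrow(x$vertices),
              sum(x$cells$is_mcc)))
  invisible(x)
}

#' Number of cells in a mesh
#' @param mesh an `epi_mesh`.
#' @export
n_cells <- function(mesh) length(mesh$cell_edges)

default_cell_state <- function(n, age = 0, cycle_time = 1, cycle_jitter = 0.2) {
  data.frame(age = rep_len(age, n), A0 = 1, sigma = 1,
             is_mcc = FALSE, can_divide = TRUE,
             cycle_time = draw_cycle_time(n, cycle_time, cycle_jitter))
}

draw_cycle_time <- function(n, cycle_time, cycle_jitter) {
  runif(n, cycle_time * (1 - cycle_jitter), cycle_time * (1 + cycle_jitter))
}

#' Build a centered hexagonal monolayer of regular unit-area cells
#'
#' The founder tissue is a centered hexagonal patch of
#' \eqn{3 r (r+1) + 1} regular hexagonal cells (`rings = 4` gives the 61-cell
#' founder used by the growth protocol).  Edge lengths are chosen so every
#' cell has area exactly 1, the unit of area throughout the package.  Founder
#' ages are drawn uniformly on `[0, cycle_time)` so the population divides
#' asynchronously.
#'
#' @param rings non-negative integer; number of hexagon rings around the
#'   central cell.
#' @param params a [mech_params()] list (supplies `cycle_time`,
#'   `cycle_jitter`).
#' @return an `epi_mesh` with all cells `A0 = 1`, `sigma = 1`.
#' @export
build_hex_monolayer <- function(rings, params = mech_params()) {
  if (length(rings) != 1 || is.na(rings) || rings < 0 || rings != floor(rings))
    stop("`rings` must be a single non-negative integer")
  a <- sqrt(2 / (3 * sqrt(3)))   # hexagon circumradius for unit area
  d <- sqrt(3) * a               # center-to-center spacing (pointy-top)

  centers <- list()
  for (q in -rings:rings) for (r in -rings:rings) {
    if (abs(q + r) <= rings)
      centers[[length(centers) + 1L]] <- c(q, r)
  }
  centers <- do.call(rbind, centers)
  cx <- d * (centers[, 1] + centers[, 2] / 2)
  cy <- d * centers[, 2] * sqrt(3) / 2
  nc <- nrow(centers)

  ang <- pi / 6 + (0:5) * pi / 3  # counter-clockwise corner angles
  vkey <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- new.env(hash = TRUE, parent = emptyenv())
  verts <- matrix(0, 0, 2)
  edges <- matrix(0L, 0, 2)
  cell_edges <- vector("list", nc)

  vid <- function(x, y) {
    k <- paste(round(x / 1e-9), round(y / 1e-9))
    id <- vkey[[k]]
    if (is.null(id)) {
      verts <<- rbind(verts, c(x, y))
      id <- nrow(verts)
      vkey[[k]] <- id
    }
    id
  }
  for (c_i in seq_len(nc)) {
    corner_ids <- integer(6)
    for (k in 1:6)
      corner_ids[k] <- vid(cx[c_i] + a * cos(ang[k]), cy[c_i] + a * sin(ang[k]))
    loop <- integer(6)
    for (k in 1:6) {
      v1 <- corner_ids[k]
      v2 <- corner_ids[if (k == 6) 1 else k + 1]
      key <- paste(min(v1, v2), max(v1, v2))
      e <- ekey[[key]]
      if (is.null(e)) {
        edges <- rbind(edges, c(v1, v2))
        e <- nrow(edges)
        ekey[[key]] <- e
        loop[k] <- e           # stored direction matches traversal
      } else {
        loop[k] <- if (edges[e, 1] == v1) e else -e
      }
    }
    cell_edges[[c_i]] <- loop
  }

  cells <- default_cell_state(nc, cycle_time = params$cycle_time,
                              cycle_jitter = params$cycle_jitter)
  cells$age <- runif(nc, 0, params$cycle_time)
  new_mesh(verts, edges, cell_edges, cells)
}

#' Ordered vertex loop of one cell (counter-clockwise)
#' @param mesh an `epi_mesh`.
#' @param cell cell index.
#' @return integer vector of vertex ids in traversal order.
#' @export
cell_vertices <- function(mesh, cell) {
  loop <- mesh$cell_edges[[cell]]
  ifelse(loop > 0, mesh$edges[abs(loop), 1], mesh$edges[abs(loop), 2])
}

#' Per-cell area and perimeter
#'
#' Areas are signed shoelace areas of the counter-clockwise vertex loops
#' (positive for a valid mesh); perimeters are summed edge lengths.
#'
#' @param mesh an `epi_mesh`.
#' @return data frame with columns `cell`, `area`, `perimeter`.
#' @export
cell_geometry <- function(mesh) {
  g <- geometry_vectors(mesh)
  if (any(g$area <= 0))
    stop("non-positive cell area; mesh geometry is invalid (cells: ",
         paste(which(g$area <= 0), collapse = ", "), ")")
  data.frame(cell = seq_len(n_cells(mesh)), area = g$area,
             perimeter = g$perimeter)
}

# vectorized internal version; no validity check
geometry_vectors <- function(mesh) {
  V <- mesh$vertices
  t_i <- mesh$edges[, 1]; h_i <- mesh$edges[, 2]
  crs <- V[t_i, 1] * V[h_i, 2] - V[t_i, 2] * V[h_i, 1]
  len <- sqrt((V[h_i, 1] - V[t_i, 1])^2 + (V[h_i, 2] - V[t_i, 2])^2)
  area <- vapply(mesh$cell_edges,
                 function(lp) 0.5 * sum(sign(lp) * crs[abs(lp)]), 0)
  perim <- vapply(mesh$cell_edges, function(lp) sum(len[abs(lp)]), 0)
  list(area = area, perimeter = perim, edge_length = len)
}

#' Signed incidence matrices of a mesh
#'
#' @param mesh an `epi_mesh`.
#' @return list with sparse `A` (edges x vertices, +1 head / -1 tail) and
#'   `B` (cells x edges, traversal orientation signs).
#' @export
incidence_matrices <- function(mesh) {
  ne <- nrow(mesh$edges)
  nv <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(ne), 2L),
    j = c(mesh$edges[, 1], mesh$edges[, 2]),
    x = c(rep(-1, ne), rep(1, ne)), dims = c(ne, nv))
  lens <- lengths(mesh$cell_edges)
  ce <- unlist(mesh$cell_edges, use.names = FALSE)
  B <- Matrix::sparseMatrix(
    i = rep(seq_along(lens), lens),
    j = abs(ce), x = sign(ce), dims = c(length(lens), ne))
  list(A = A, B = B)
}

# integer vector: number of cells bordering each edge
edge_cell_count <- function(mesh) {
  tabulate(abs(unlist(mesh$cell_edges, use.names = FALSE)),
           nbins = nrow(mesh$edges))
}

# list: for each edge, the cells that contain it
edge_cells <- function(mesh) {
  ce <- unlist(mesh$cell_edges, use.names = FALSE)
  cid <- rep(seq_along(mesh$cell_edges), lengths(mesh$cell_edges))
  split(cid, factor(abs(ce), levels = seq_len(nrow(mesh$edges))))
}

#' Cell-adjacency graph
#'
#' Cells are adjacent when they share at least one edge.  The graph is
#' simple (no self loops, no multi-edges) with one vertex per cell.
#'
#' @param mesh an `epi_mesh`.
#' @return an [igraph::graph] object.
#' @export
adjacency_graph <- function(mesh) {
  ec <- edge_cells(mesh)
  pairs <- do.call(rbind, lapply(ec, function(cs)
    if (length(cs) == 2) cs else NULL))
  g <- igraph::make_empty_graph(n = n_cells(mesh), directed = FALSE)
  if (!is.null(pairs) && nrow(pairs))
    g <- igraph::add_edges(g, t(unique(t(apply(pairs, 1, sort)))))
  igraph::simplify(g)
}

#' Cells on the monolayer periphery
#'
#' A cell is peripheral when it owns at least one boundary edge (an edge
#' bordered by a single cell).
#'
#' @param mesh an `epi_mesh`.
#' @return integer vector of peripheral cell indices.
#' @export
peripheral_cells <- function(mesh) {
  cnt <- edge_cell_count(mesh)
  boundary <- which(cnt == 1L)
  which(vapply(mesh$cell_edges,
               function(lp) any(abs(lp) %in% boundary), FALSE))
}

#' Validate mesh topology
#'
#' Checks the incidence-matrix contract: every cell loop closed
#' (\eqn{B A = 0}), every edge with exactly two distinct endpoints, every
#' edge bordered by one (boundary) or two (interior) cells, the disc Euler
#' relation \eqn{V - E + F = 1}, positive signed cell areas, and no repeated
#' vertex within a cell loop.  Failures are reported, never raised.
#'
#' @param mesh an `epi_mesh`.
#' @return list with logical `ok` and character vector `failures`.
#' @export
validate_topology <- function(mesh) {
  failures <- character()
  inc <- incidence_matrices(mesh)
  ba <- inc$B %*% inc$A
  if (max(abs(ba)) > 0)
    failures <- c(failures, "B %*% A is not identically zero (open cell loop)")
  if (any(mesh$edges[, 1] == mesh$edges[, 2]))
    failures <- c(failures, "edge with identical endpoints")
  cnt <- edge_cell_count(mesh)
  if (any(cnt < 1 | cnt > 2))
    failures <- c(failures, sprintf(
      "edges bordered by %s cells: %s",
      paste(sort(unique(cnt[cnt < 1 | cnt > 2])), collapse = "/"),
      paste(utils::head(which(cnt < 1 | cnt > 2), 5), collapse = ", ")))
  v <- nrow(mesh$vertices); e <- nrow(mesh$edges); f <- n_cells(mesh)
  if (v - e + f != 1L)
    failures <- c(failures, sprintf("Euler relation V-E+F = %d != 1",
                                    v - e + f))
  g <- geometry_vectors(mesh)
  if (any(g$area <= 0))
    failures <- c(failures, sprintf(
      "non-positive signed area for cells: %s",
      paste(utils::head(which(g$area <= 0), 5), collapse = ", ")))
  dup <- vapply(seq_len(f), function(ci) {
    vs <- cell_vertices(mesh, ci)
    anyDuplicated(vs) > 0
  }, FALSE)
  if (any(dup))
    failures <- c(failures, sprintf(
      "repeated vertex within cell loop: %s",
      paste(utils::head(which(dup), 5), collapse = ", ")))
  list(ok = length(failures) == 0L, failures = failures)
}

# CSR arrays handed to the C++ kernels (0-based)
mesh_csr <- function(mesh) {
  lens <- lengths(mesh$cell_edges)
  ce <- unlist(mesh$cell_edges, use.names = FALSE)
  list(tail = mesh$edges[, 1] - 1L,
       head = mesh$edges[, 2] - 1L,
       cptr = c(0L, cumsum(lens)),
       cedge = abs(ce) - 1L,
       csign = as.integer(sign(ce)))
}

# edges eligible for a T1: interior, both endpoints interior and of degree 3
t1_eligible <- function(mesh) {
  cnt <- edge_cell_count(mesh)
  deg <- tabulate(c(mesh$edges[, 1], mesh$edges[, 2]),
                  nbins = nrow(mesh$vertices))
  on_boundary <- logical(nrow(mesh$vertices))
  on_boundary[as.vector(mesh$edges[cnt == 1L, ])] <- TRUE
  as.integer(cnt == 2L & deg[mesh$edges[, 1]] == 3L &
               deg[mesh$edges[, 2]] == 3L &
               !on_boundary[mesh$edges[, 1]] & !on_boundary[mesh$edges[, 2]])
}

#' Centroids of cell polygons
#' @param mesh an `epi_mesh`.
#' @return numeric matrix (n_cells x 2) of polygon centroids.
#' @export
cell_centroids <- function(mesh) {
  t(vapply(seq_len(n_cells(mesh)), function(ci) {
    vs <- mesh$vertices[cell_vertices(mesh, ci), , drop = FALSE]
    polygon_centroid(vs)
  }, c(0, 0)))
}

polygon_centroid <- function(vs) {
  n <- nrow(vs)
  j <- c(2:n, 1)
  cr <- vs[, 1] * vs[j, 2] - vs[j, 1] * vs[, 2]
  a <- sum(cr) / 2
  c(sum((vs[, 1] + vs[j, 1]) * cr), sum((vs[, 2] + vs[j, 2]) * cr)) / (6 * a)
}

# area-moment (covariance) tensor of a polygon about its centroid
polygon_covariance <- function(vs) {
  ctr <- polygon_centroid(vs)
  p <- sweep(vs, 2, ctr)
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  ixx <- sum(cr * (p[, 1]^2 + p[, 1] * p[j, 1] + p[j, 1]^2)) / 12
  iyy <- sum(cr * (p[, 2]^2 + p[, 2] * p[j, 2] + p[j, 2]^2)) / 12
  ixy <- sum(cr * (2 * p[, 1] * p[, 2] + p[, 1] * p[j, 2] +
                     p[j, 1] * p[, 2] + 2 * p[j, 1] * p[j, 2])) / 24
  matrix(c(ixx, ixy, ixy, iyy), 2, 2) / a
}
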