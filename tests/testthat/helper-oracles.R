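# Independent loop-based oracles, deliberately written without reusing the
# package's vectorised/compiled code paths.

# polygon area by fan triangulation from the first vertex
oracle_polygon_area <- function(vs) {
  a <- 0
  for (k in 2:(nrow(vs) - 1)) {
    v1 <- vs[k, ] - vs[1, ]
    v2 <- vs[k + 1, ] - vs[1, ]
    a <- a + 0.5 * (v1[1] * v2[2] - v1[2] * v2[1])
  }
  a
}

# total energy by explicit per-cell loops (shoelace + summed edge lengths)
oracle_energy <- function(mesh, params) {
  E <- 0
  for (ci in seq_len(n_cells(mesh))) {
    vs <- mesh$vertices[cell_vertices(mesh, ci), , drop = FALSE]
    n <- nrow(vs)
    j <- c(2:n, 1)
    A <- 0.5 * sum(vs[, 1] * vs[j, 2] - vs[j, 1] * vs[, 2])
    L <- sum(sqrt(rowSums((vs[j, ] - vs)^2)))
    sg <- mesh$cells$sigma[ci]
    A0 <- mesh$cells$A0[ci]
    E <- E + sg * (A * log(A / A0) - A + A0) +
      sg * params$gamma * (L * log(L / params$L0) - L + params$L0) +
      params$p_ext * A
  }
  E
}

# central finite differences of the oracle energy at selected vertices
oracle_fd_forces <- function(mesh, params, vids, h = 1e-6) {
  out <- matrix(0, length(vids), 2)
  for (i in seq_along(vids)) {
    for (d in 1:2) {
      m1 <- mesh
      m1$vertices[vids[i], d] <- m1$vertices[vids[i], d] + h
      m2 <- mesh
      m2$vertices[vids[i], d] <- m2$vertices[vids[i], d] - h
      out[i, d] <- -(oracle_energy(m1, params) -
                       oracle_energy(m2, params)) / (2 * h)
    }
  }
  out
}

# per-cell stress tensor by brute-force per-edge dyadic summation
oracle_stress_tensor <- function(mesh, params, ci) {
  vs_idx <- cell_vertices(mesh, ci)
  vs <- mesh$vertices[vs_idx, , drop = FALSE]
  n <- nrow(vs)
  j <- c(2:n, 1)
  A <- 0.5 * sum(vs[, 1] * vs[j, 2] - vs[j, 1] * vs[, 2])
  L <- sum(sqrt(rowSums((vs[j, ] - vs)^2)))
  p <- -mesh$cells$sigma[ci] * log(A / mesh$cells$A0[ci])
  tn <- mesh$cells$sigma[ci] * params$gamma * log(L / params$L0)
  S <- -(p - params$p_ext) * diag(2)
  for (k in seq_len(n)) {
    ell <- vs[j[k], ] - vs[k, ]
    S <- S + tn / A * (ell %o% ell) / sqrt(sum(ell^2))
  }
  S
}

# textbook paired t
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), n - 1))
}

# maximum vertex-force magnitude
max_force <- function(mesh, params) {
  f <- vertex_forces(mesh, params)
  max(sqrt(rowSums(f^2)))
}
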