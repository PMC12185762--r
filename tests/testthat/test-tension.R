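test_that("honeycomb junction networks have 120-degree triple junctions", {
  m <- build_hex_monolayer(2)
  net <- build_junction_network(m)
  expect_true(all(net$nodes$degree == 3))
  # junction count: every degree-2 vertex merges two mesh edges into one curve
  deg <- tabulate(c(m$edges[, 1], m$edges[, 2]), nbins = nrow(m$vertices))
  expect_equal(nrow(net$junctions), nrow(m$edges) - sum(deg == 2))
  expect_equal(sum(deg >= 3), nrow(net$nodes))
  # unit tangents at internal nodes pairwise at 120 degrees
  jn <- net$junctions
  for (nd in net$nodes$vertex[net$nodes$internal]) {
    tg <- rbind(as.matrix(jn[jn$node1 == nd, c("t1x", "t1y")]),
                as.matrix(jn[jn$node2 == nd, c("t2x", "t2y")]))
    expect_equal(nrow(tg), 3)
    expect_equal(unname(sqrt(rowSums(tg^2))), rep(1, 3), tolerance = 1e-12)
    dots <- tcrossprod(tg)[upper.tri(diag(3))]
    expect_equal(dots, rep(-0.5, 3), tolerance = 1e-9)
  }
})

test_that("a 4-fold vertex is retained as one node with four junctions", {
  polys <- list(cbind(c(-1, 0, 0, -1), c(-1, -1, 0, 0)),
                cbind(c(0, 1, 1, 0), c(-1, -1, 0, 0)),
                cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                cbind(c(-1, 0, 0, -1), c(0, 0, 1, 1)))
  m <- epivertex:::polygons_to_mesh(polys)
  net <- build_junction_network(m)
  four <- net$nodes[net$nodes$degree == 4, ]
  expect_equal(nrow(four), 1)
  jn <- net$junctions
  expect_equal(sum(jn$node1 == four$vertex) + sum(jn$node2 == four$vertex), 4)
})

test_that("inference returns unit tensions on the honeycomb", {
  net <- build_junction_network(build_hex_monolayer(3))
  sol <- infer_tensions(net)
  solved <- sol$tensions[!is.na(sol$tensions)]
  expect_true(all(abs(solved - 1) < 1e-6))
  expect_lt(sol$residual, 1e-9)
  expect_equal(mean(solved), 1, tolerance = 1e-9)
})

test_that("inference recovers known heterogeneous tensions", {
  kt <- gen_known_tension_mesh(50, tension_cv = 0.3, seed = 101L)
  expect_true(kt$converged)
  sol <- infer_tensions(kt$network)
  ok <- !is.na(sol$tensions)
  truth <- kt$tensions[ok] / mean(kt$tensions[ok])
  expect_gt(cor(truth, sol$tensions[ok]), 0.95)
})

test_that("the inferred solution is invariant under rigid motion of the geometry", {
  kt <- gen_known_tension_mesh(30, tension_cv = 0.2, seed = 55L)
  sol <- infer_tensions(kt$network)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  net2 <- kt$network
  xy <- as.matrix(net2$nodes[, c("x", "y")]) %*% t(R)
  net2$nodes$x <- xy[, 1] + 4
  net2$nodes$y <- xy[, 2] - 2
  t1 <- as.matrix(net2$junctions[, c("t1x", "t1y")]) %*% t(R)
  t2 <- as.matrix(net2$junctions[, c("t2x", "t2y")]) %*% t(R)
  net2$junctions[, c("t1x", "t1y")] <- t1
  net2$junctions[, c("t2x", "t2y")] <- t2
  sol2 <- infer_tensions(net2)
  expect_equal(sol2$tensions, sol$tensions, tolerance = 1e-8)
})

test_that("ring labels spread by contiguity from the event junction", {
  net <- build_junction_network(build_hex_monolayer(4))
  jn <- net$junctions
  # event on a junction of the central cell
  ctrd <- cell_centroids(build_hex_monolayer(4))
  central <- which.min(rowSums(ctrd^2))
  ej <- jn$junction[which(jn$cell1 == central | jn$cell2 == central)][1]
  lab <- ring_labels(net, event_junction = ej)
  expect_equal(as.character(lab[match(ej, jn$junction)]), "N1")
  # junctions sharing a node with the event junction are N2
  nd <- unlist(jn[jn$junction == ej, c("node1", "node2")])
  touching <- setdiff(jn$junction[jn$node1 %in% nd | jn$node2 %in% nd], ej)
  expect_true(all(lab[match(touching, jn$junction)] == "N2"))
  expect_true("beyond" %in% lab)  # a rings-4 patch extends past N4

  # event given as a host cell: all of its junctions are N1
  lab2 <- ring_labels(net, event_cell = central)
  cellj <- jn$junction[jn$cell1 %in% central | jn$cell2 %in% central]
  expect_true(all(lab2[match(cellj, jn$junction)] == "N1"))
  expect_error(ring_labels(net, event_junction = 10000), "not present")
})

test_that("before/after ratios respond only to relative ring changes", {
  net <- build_junction_network(build_hex_monolayer(3))
  jn <- net$junctions
  ej <- jn$junction[1]
  lab <- ring_labels(net, event_junction = ej)
  base <- rep(1, nrow(jn))
  expect_equal(unname(before_after_ratio(list(base, base), list(base), lab)),
               rep(1, 5))
  after <- base
  after[lab == "N1"] <- 1.1
  r <- before_after_ratio(list(base), list(after), lab)
  expect_equal(unname(r["N1"]), 1.1)
  expect_equal(unname(r[c("N2", "N3", "N4")]), rep(1, 3))
})

test_that("solved tensions are mean-normalised with a reported residual", {
  kt <- gen_known_tension_mesh(40, tension_cv = 0.25, seed = 7L)
  sol <- infer_tensions(kt$network)
  expect_equal(mean(sol$tensions[!is.na(sol$tensions)]), 1,
               tolerance = 1e-9)
  expect_lt(sol$residual, 1e-8)
  expect_false(sol$rank_deficient)
})
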