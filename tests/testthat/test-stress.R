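test_that("stress tensors are symmetric and match the dyadic-sum oracle", {
  m <- relaxed_patch()
  m$cells$sigma[7] <- 10
  p <- mech_params()
  st <- cell_stress_tensors(m, p, check_equilibrium = FALSE)
  for (ci in c(1, 7, 12)) {
    S <- oracle_stress_tensor(m, p, ci)
    scale <- 1 + max(abs(S))
    expect_lt(abs(st$sxx[ci] - S[1, 1]), 1e-12 * scale)
    expect_lt(abs(st$sxy[ci] - S[1, 2]), 1e-12 * scale)
    expect_lt(abs(st$syy[ci] - S[2, 2]), 1e-12 * scale)
    expect_equal(S[1, 2], S[2, 1])
  }
})

test_that("a regular polygon cell carries zero shear", {
  m <- make_polygon_mesh(regular_polygon(6, r = 0.62))
  st <- cell_stress_tensors(m, mech_params(), check_equilibrium = FALSE)
  expect_equal(st$sxy, 0, tolerance = 1e-12)
  expect_equal(st$sxx, st$syy, tolerance = 1e-12)
  expect_equal(st$shear, 0, tolerance = 1e-12)
})

test_that("shear stress has its closed forms and rotation invariance", {
  expect_equal(shear_stress(diag(c(3, 3))), 0)
  expect_equal(shear_stress(diag(c(1, -1))), 1)
  expect_error(shear_stress(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  set.seed(40)
  for (k in 1:20) {
    a <- rnorm(3)
    S <- matrix(c(a[1], a[3], a[3], a[2]), 2, 2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(shear_stress(R %*% S %*% t(R)), shear_stress(S),
                 tolerance = 1e-12)
  }
})

test_that("cell classification partitions the monolayer", {
  run <- ci_run()
  mesh <- run$final
  lab <- classify_cells(mesh)
  expect_equal(length(lab), n_cells(mesh))
  expect_false(any(is.na(lab)))
  expect_setequal(which(lab == "mcc"), run$mcc_ids)
  # interior neighbours of an MCC are mcc_adjacent, peripheral ones excluded
  g <- adjacency_graph(mesh)
  per <- peripheral_cells(mesh)
  for (mc in run$mcc_ids) {
    nb <- as.integer(igraph::neighbors(g, mc))
    expect_true(all(lab[setdiff(nb, per)] %in% c("mcc_adjacent", "mcc")))
    expect_true(all(lab[intersect(nb, per)] == "peripheral"))
  }
  nolab <- mesh
  nolab$cells$is_mcc <- FALSE
  expect_warning(l2 <- classify_cells(nolab), "no MCCs")
  expect_true(all(l2 %in% c("non_adjacent", "peripheral")))
})

test_that("decile fractions behave at random, constructed and mirrored inputs", {
  set.seed(41)
  n <- 1000
  v <- rnorm(n)
  lab <- factor(sample(c("mcc_adjacent", "non_adjacent"), n, replace = TRUE),
                levels = c("mcc", "mcc_adjacent", "non_adjacent",
                           "peripheral"))
  fr <- decile_fraction(v, lab, "highest")
  expect_equal(unname(fr["pooled"]), 10, tolerance = 1)
  expect_lt(abs(fr[["mcc_adjacent"]] - 10), 4)
  expect_lt(abs(fr[["non_adjacent"]] - 10), 4)

  # constructed: the top decile is exactly the adjacent group
  v2 <- c(100 + 1:10, seq_len(90))
  lab2 <- factor(rep(c("mcc_adjacent", "non_adjacent"), c(10, 90)),
                 levels = levels(lab))
  cut_oracle <- sort(v2)[90] + 0.1 * (sort(v2)[91] - sort(v2)[90])
  fr2 <- decile_fraction(v2, lab2, "highest")
  expect_equal(unname(fr2["mcc_adjacent"]),
               100 * sum(v2[1:10] > cut_oracle) / 10)
  expect_equal(unname(fr2["non_adjacent"]), 0)

  fr_hi <- decile_fraction(v, lab, "highest")
  fr_lo <- decile_fraction(-v, lab, "lowest")
  expect_equal(fr_hi, fr_lo)

  expect_error(decile_fraction(v[1:5], lab[1:5]), "fewer than 10")
})

test_that("paired t-test matches the closed form and its degenerate limits", {
  tt <- paired_ttest(c(2, 3, 4, 5), c(1, 1, 1, 1))
  o <- oracle_paired_t(c(2, 3, 4, 5), c(1, 1, 1, 1))
  expect_equal(tt$t, o$t, tolerance = 1e-12)
  expect_equal(tt$p, o$p, tolerance = 1e-12)

  sw <- paired_ttest(c(1, 1, 1, 1), c(2, 3, 4, 5))
  expect_equal(sw$t, -tt$t, tolerance = 1e-12)
  expect_equal(sw$p, tt$p, tolerance = 1e-12)

  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_equal(degen$t, Inf)
})

test_that("shuffling group labels flattens decile enrichment", {
  run <- ci_run()
  st <- cell_stress_tensors(run$final, check_equilibrium = FALSE)
  lab <- classify_cells(run$final)
  real <- decile_fraction(st$eff_pressure, lab, "lowest")
  set.seed(42)
  diffs <- replicate(20, {
    keep <- lab %in% c("mcc_adjacent", "non_adjacent")
    shuf <- lab
    shuf[keep] <- sample(lab[keep])
    fr <- decile_fraction(st$eff_pressure, shuf, "lowest")
    fr[["mcc_adjacent"]] - fr[["non_adjacent"]]
  })
  expect_lt(abs(mean(diffs)), abs(real[["mcc_adjacent"]] -
                                    real[["non_adjacent"]]))
  expect_lt(abs(mean(diffs)), 3)
})

test_that("rosette neighbours read out tangential elongation", {
  # isotropic neighbourhood: regular hexagons around a central MCC
  m <- build_hex_monolayer(2)
  ctr <- cell_centroids(m)
  central <- which.min(rowSums(ctr^2))
  m$cells$is_mcc[central] <- TRUE
  rg <- neighbor_ring_geometry(m, central)
  expect_equal(nrow(rg), 6)
  expect_equal(rg$elongation_index, rep(0, 6), tolerance = 1e-8)
  expect_false(is.unsorted(rg$angle))

  # constructed rosette: thin annulus cells stretched along the tangent
  r1 <- 1; r2 <- 1.35
  th <- 2 * pi * (0:5) / 6
  inner <- cbind(r1 * cos(th), r1 * sin(th))
  outer <- cbind(r2 * cos(th), r2 * sin(th))
  polys <- c(list(inner),
             lapply(1:6, function(k) {
               k2 <- if (k == 6) 1 else k + 1
               rbind(inner[k, ], outer[k, ], outer[k2, ], inner[k2, ])
             }))
  rosette <- epivertex:::polygons_to_mesh(polys)
  rosette$cells$is_mcc[1] <- TRUE
  rr <- neighbor_ring_geometry(rosette, 1)
  expect_gt(mean(rr$elongation_index), 0.5)
  rot <- rotate_mesh(rosette, 0.9)
  rr2 <- neighbor_ring_geometry(rot, 1)
  expect_equal(sort(rr2$elongation_index), sort(rr$elongation_index),
               tolerance = 1e-8)
})
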