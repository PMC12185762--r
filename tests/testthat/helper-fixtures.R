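# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# scaled-down protocol run (37 -> 100 -> 200 cells)
ci_run <- function() cached_fixture("ci_run", suppressMessages(
  run_protocol(protocol_config_ci(), seed = 11L)))

# full protocol run (61 -> 400 -> 800 cells); shared across test files
# so the expensive growth happens once
full_run <- function() cached_fixture("full_run", suppressMessages(
  run_protocol(protocol_config(), seed = 1L)))

# small relaxed patch for mechanics/stress tests
relaxed_patch <- function() cached_fixture("relaxed_patch", suppressMessages(
  with_seed(3L, relax(build_hex_monolayer(2), mech_params()))))

# a reference synthetic event dataset sized like the measured data
event_dataset <- function() cached_fixture("event_dataset", {
  tissue <- gen_tissue(60, seed = 21L, mcc = TRUE)
  ev <- gen_events(tissue, event_gen_params(rate = 0.45), duration = 100,
                   seed = 22L)
  list(tissue = tissue, events = ev$events, tracks = ev$tracks)
})

# single-cell mesh from a CCW polygon
make_polygon_mesh <- function(vs, A0 = 1, sigma = 1) {
  n <- nrow(vs)
  edges <- cbind(seq_len(n), c(2:n, 1L))
  cells <- data.frame(age = 0, A0 = A0, sigma = sigma, is_mcc = FALSE,
                      can_divide = TRUE, cycle_time = 1)
  new_mesh(vs, edges, list(seq_len(n)), cells)
}

regular_polygon <- function(n, r = 1, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th))
}

random_convex_polygon <- function(n) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(1, 0.5, 3)
  cbind(r * cos(th), r * sin(th)) + matrix(rnorm(2, sd = 2), n, 2,
                                           byrow = TRUE)
}

rotate_mesh <- function(mesh, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, -shift)
  mesh
}
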