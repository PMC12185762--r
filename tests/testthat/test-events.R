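# hand-built tracks: constant areas except prescribed event ramps
flat_tracks <- function(n_cells = 4, duration = 30, dt = 0.5, area = 400) {
  times <- seq(0, duration, by = dt)
  structure(list(
    cells = data.frame(cell = rep(seq_len(n_cells), each = length(times)),
                       time = rep(times, n_cells), area = area),
    junctions = data.frame(junction = integer(), time = numeric(),
                           length = numeric()),
    frame_interval = dt, times = times,
    extrusions = data.frame(cell = integer(), time = numeric(),
                            x = numeric(), y = numeric())),
    class = "cell_tracks")
}

one_event <- function(cell = 1, onset = 10, duration = 8, peak = 94) {
  data.frame(event = 1L, cell = cell, onset = onset, duration = duration,
             end = onset + duration, peak_area = peak, loss_frac = 0,
             location = "medial", junction = NA_integer_,
             adjacency = "non_adjacent")
}

test_that("synchronised traces are flat for constant-area tissue", {
  tr <- flat_tracks()
  ev <- rbind(one_event(cell = 1), one_event(cell = 2, onset = 12))
  ev$event <- 1:2
  sy <- synchronize_area_traces(tr, ev, window = c(-4, 10))
  expect_true(all(abs(sy$mean - 1) < 1e-12))
  expect_true(all(sy$sd == 0))
  expect_setequal(unique(sy$group), c("event", "control"))
})

test_that("the generator's 10% apical loss is recovered at n = 43 cells", {
  losses <- plateaus <- c()
  for (s in 1:4) {
    ts <- gen_tissue(120, seed = 700 + s, mcc = TRUE)
    ev <- gen_events(ts, event_gen_params(rate = 0.3), duration = 90,
                     seed = 750 + s)
    e43 <- ev$events[seq_len(min(43, nrow(ev$events))), ]
    ar <- area_reduction_and_correlation(ev$tracks, e43)
    losses <- c(losses, mean(ar$per_event$delta_area))
    sy <- synchronize_area_traces(ev$tracks, e43, window = c(-3, 16))
    plateaus <- c(plateaus,
                  mean(sy$mean[sy$group == "event" & sy$offset >= 13]))
    ctrl <- sy$mean[sy$group == "control"]
    expect_lt(max(abs(ctrl - 1)), 0.05)   # controls stay flat within noise
  }
  expect_lt(abs(mean(losses) - 0.10), 0.02)
  expect_lt(abs(mean(plateaus) - 0.90), 0.02)
})

test_that("loss-size correlation is exact without noise and dies on shuffling", {
  # noiseless linear relation -> r^2 = 1
  ts <- gen_tissue(100, seed = 801, mcc = TRUE)
  p0 <- event_gen_params(rate = 0.25, loss_noise_sd = 0,
                         frame_noise_sd = 0)
  ev <- gen_events(ts, p0, duration = 90, seed = 802)
  single <- ev$events[ev$events$cell %in%
                        names(which(table(ev$events$cell) == 1)), ]
  ar <- suppressWarnings(area_reduction_and_correlation(ev$tracks, single))
  expect_gt(ar$r_squared, 0.999)

  # shuffling the event-cell pairing destroys the correlation
  shuffled <- single
  set.seed(803)
  shuffled$peak_area <- sample(shuffled$peak_area)
  ar2 <- area_reduction_and_correlation(ev$tracks, shuffled)
  expect_lt(ar2$r_squared, 0.15)

  expect_error(area_reduction_and_correlation(ev$tracks, ev$events[1:2, ]),
               "at least 3")
  same <- ev$events[1:5, ]
  same$peak_area <- 94
  expect_error(area_reduction_and_correlation(ev$tracks, same),
               "zero variance")
})

test_that("junction shortening of 10% is recovered within 1% at n = 40", {
  chg <- c()
  for (s in 1:4) {
    ts <- gen_tissue(120, seed = 820 + s, mcc = TRUE)
    ev <- gen_events(ts, event_gen_params(rate = 0.35), duration = 100,
                     seed = 840 + s)
    jc <- junction_length_change(ev$tracks, ev$events)
    expect_gte(length(jc$event_changes), 40)
    chg <- c(chg, mean(jc$event_changes[1:40]))
    expect_lt(jc$p, 1e-6)
    expect_lt(abs(jc$mean_control), 1)
  }
  expect_lt(abs(mean(chg) - (-10)), 1)
})

test_that("junction comparison reproduces a hand-computed unpaired t", {
  dt <- 0.5
  times <- seq(0, 20, by = dt)
  mk <- function(j, l0, l1) data.frame(junction = j, time = times,
                                       length = seq(l0, l1,
                                                    length.out = length(times)))
  jtr <- do.call(rbind, c(lapply(1:4, function(j) mk(j, 10, 10 * (1 - 0.01 * j))),
                          lapply(5:8, function(j) mk(j, 10, 10))))
  tracks <- flat_tracks(8, 20)
  tracks$junctions <- jtr
  events <- do.call(rbind, lapply(1:4, function(j) {
    e <- one_event(cell = j, onset = 0, duration = 20)
    e$event <- j; e$junction <- j; e$location <- "junctional"
    e
  }))
  jc <- junction_length_change(tracks, events)
  ev_pct <- -c(1, 2, 3, 4)
  ct_pct <- c(0, 0, 0, 0)
  se <- sqrt(var(ev_pct) / 4 + var(ct_pct) / 4)
  t_hand <- (mean(ev_pct) - mean(ct_pct)) / se
  expect_equal(jc$mean_event, mean(ev_pct), tolerance = 1e-9)
  expect_equal(jc$t, t_hand, tolerance = 1e-9)
})

test_that("event rates normalise by class size and duration", {
  ev <- do.call(rbind, lapply(1:10, function(k) one_event(cell = k)))
  r <- event_rate_by_adjacency(ev, c(non_adjacent = 20), duration = 60)
  expect_equal(r$rate, 0.5)
  r2 <- event_rate_by_adjacency(ev, c(non_adjacent = 20), duration = 120)
  expect_equal(r2$rate, 0.25)
  r3 <- event_rate_by_adjacency(ev, c(non_adjacent = 20, mcc_adjacent = 0),
                                duration = 60)
  expect_true(is.na(r3$rate[r3$class == "mcc_adjacent"]))
  expect_error(event_rate_by_adjacency(ev, c(non_adjacent = 20), 0),
               "positive")
})

test_that("the 2x MCC-adjacency rate bias is recovered at n >= 191 events", {
  events_all <- census <- NULL
  n_ev <- 0
  for (s in 1:3) {
    ts <- gen_tissue(150, seed = 860 + s, mcc = TRUE)
    ev <- gen_events(ts, event_gen_params(rate = 0.5), duration = 120,
                     seed = 880 + s)
    rt <- event_rate_by_adjacency(
      ev$events,
      c(mcc_adjacent = sum(ts$cells$group == "mcc_adjacent"),
        non_adjacent = sum(ts$cells$group == "non_adjacent")),
      duration = 120)
    n_ev <- n_ev + nrow(ev$events)
    events_all <- rbind(events_all, rt)
  }
  expect_gte(n_ev, 191)
  ratio <- sum(events_all$n_events[events_all$class == "mcc_adjacent"]) /
    sum(events_all$n_cells[events_all$class == "mcc_adjacent"]) /
    (sum(events_all$n_events[events_all$class == "non_adjacent"]) /
       sum(events_all$n_cells[events_all$class == "non_adjacent"]))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("log2 fold changes are exact, guarded, and unbiased on Poisson counts", {
  expect_equal(fold_change_log2(12, 12), 0)
  expect_equal(fold_change_log2(5, 20), 2)
  expect_error(fold_change_log2(0, 10), "zero basal")
  set.seed(870)
  lfc <- replicate(20, fold_change_log2(rpois(1, 100), rpois(1, 300)))
  expect_lt(abs(mean(lfc) - log2(3)), 0.1)
})

test_that("remodeling index is zero for static tissue and tracks the wave", {
  tr <- flat_tracks(6, 30)
  ri <- remodeling_index(tr, bin_width = 2)
  expect_true(all(ri$remodeling_pct == 0))

  ts <- gen_tissue(90, seed = 901, mcc = TRUE)
  wv <- gen_compression_wave(ts, seed = 902)
  ri2 <- remodeling_index(wv$tracks, bin_width = 2, events = wv$events)
  peak_rem <- ri2$bin_mid[which.max(ri2$remodeling_pct)]
  peak_ev <- ri2$bin_mid[which.max(ri2$n_events)]
  expect_lte(abs(peak_rem - peak_ev), 2)  # within one 2-min bin
})

test_that("extrusion neighbourhood rates detect suppression and respect the window", {
  ts <- gen_tissue(90, seed = 910, mcc = TRUE)
  wv <- gen_compression_wave(ts, seed = 911, n_extrusions = 4)
  ex <- extrusion_neighbor_rate(wv$events, ts, wv$extrusions)
  expect_lt(ex$ratio, 1)

  # uniform field without suppression: ratio near 1
  ev <- gen_events(ts, event_gen_params(rate = 2), duration = 60, seed = 912)
  fake_ext <- data.frame(cell = c(11, 25), time = c(10, 20),
                         x = ts$cells$x[c(11, 25)],
                         y = ts$cells$y[c(11, 25)])
  exu <- extrusion_neighbor_rate(ev$events, ts, fake_ext)
  expect_gt(exu$ratio, 0.5)
  expect_lt(exu$ratio, 2)

  # an event after the window is never counted
  late <- one_event(cell = 11, onset = 35)
  ex0 <- extrusion_neighbor_rate(late, ts,
                                 data.frame(cell = 25, time = 10,
                                            x = ts$cells$x[25],
                                            y = ts$cells$y[25]))
  expect_equal(sum(ex0$per_extrusion$ev_neighbors) +
                 sum(ex0$per_extrusion$ev_annulus), 0)
  expect_equal(extrusion_neighbor_rate(late, ts, NULL)$ratio, NA_real_)
})

test_that("ruffle summaries reproduce the measured distributions", {
  dat <- event_dataset()
  s <- ruffle_summary(dat$events, dat$tissue$cells$area)
  expect_lt(abs(s$duration[["mean"]] - 9.3), 0.5 + 3 * 2.3 / sqrt(s$n))
  expect_gt(s$fraction_junctional, 0.5)

  row <- one_event(peak = 94)
  s1 <- ruffle_summary(row, c(412))
  expect_equal(s1$pct_apical[["mean"]], 100 * 94 / 412, tolerance = 1e-9)
  expect_equal(s1$pct_apical[["mean"]], 22.8, tolerance = 0.02)
  expect_equal(s1$duration[["sd"]], 0)
  expect_error(ruffle_summary(row[0, ], c(412)), "empty")

  # duration mean at the measured n = 90 ruffles
  set.seed(920)
  ts <- gen_tissue(150, seed = 921, mcc = TRUE)
  ev <- gen_events(ts, event_gen_params(rate = 0.45), duration = 100,
                   seed = 922)
  e90 <- ev$events[seq_len(min(90, nrow(ev$events))), ]
  s90 <- ruffle_summary(e90, ts$cells$area)
  expect_lt(abs(s90$duration[["mean"]] - 9.3), 0.5 + 3 * 2.3 / sqrt(90))
})
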