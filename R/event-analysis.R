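# Quantification procedures for macropinocytosis event tables and
# apical-area / junction-length tracks.

track_matrix <- function(df, id_col, value_col) {
  times <- sort(unique(df$time))
  ids <- sort(unique(df[[id_col]]))
  m <- matrix(NA_real_, length(times), length(ids),
              dimnames = list(NULL, ids))
  m[cbind(match(df$time, times), match(df[[id_col]], ids))] <- df[[value_col]]
  list(times = times, values = m, ids = ids)
}

nearest_frame <- function(t, times) vapply(t, function(z)
  which.min(abs(times - z)), 0L)

#' Event-synchronised normalised apical-area traces
#'
#' Each event cell's area trace is divided by its area at event onset and
#' aligned at the onset; control cells (cells hosting no event) are aligned
#' at times sampled from the empirical event-onset distribution.  Cells
#' whose track does not cover the window are dropped.
#'
#' @param tracks a `cell_tracks` (from [gen_events()]).
#' @param events event data frame.
#' @param window numeric length-2: time window around onset (min).
#' @param control_seed seed for the control alignment-time draw.
#' @return data frame: `offset`, `group` (`event`/`control`), `mean`, `sd`,
#'   `n`.
#' @export
synchronize_area_traces <- function(tracks, events, window = c(-5, 20),
                                    control_seed = 1L) {
  tm <- track_matrix(tracks$cells, "cell", "area")
  dt <- tracks$frame_interval
  offs <- seq(round_to_frame(window[1], dt), round_to_frame(window[2], dt),
              by = dt)
  k_off <- round(offs / dt)

  collect <- function(cells, align_times) {
    rows <- list()
    for (i in seq_along(cells)) {
      col <- match(as.character(cells[i]), colnames(tm$values))
      k0 <- nearest_frame(align_times[i], tm$times)
      kk <- k0 + k_off
      if (any(kk < 1 | kk > length(tm$times))) next   # window not covered
      tr <- tm$values[kk, col] / tm$values[k0, col]
      rows[[length(rows) + 1L]] <- tr
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }

  ev_m <- collect(events$cell, events$onset)
  ctrl_cells <- setdiff(as.integer(colnames(tm$values)), events$cell)
  ctrl_m <- with_seed(control_seed, {
    at <- sample(events$onset, length(ctrl_cells), replace = TRUE)
    collect(ctrl_cells, at)
  })
  build <- function(m, gr) {
    if (is.null(m)) return(NULL)
    data.frame(offset = offs, group = gr, mean = colMeans(m),
               sd = apply(m, 2, sd), n = nrow(m))
  }
  out <- rbind(build(ev_m, "event"), build(ctrl_m, "control"))
  rownames(out) <- NULL
  out
}

#' Per-event apical-area reduction and its correlation with event size
#'
#' The per-event reduction is `(area at onset - area at event end) / area
#' at onset`; ordinary least squares of the reduction on peak ruffle area
#' gives the fitted line, and r-squared is the squared Pearson correlation.
#'
#' @param tracks a `cell_tracks`.
#' @param events event data frame (>= 3 events).
#' @return list with `per_event` (data frame: `event`, `peak_area`,
#'   `delta_area`), `slope`, `intercept`, `r_squared`, `n`.
#' @export
area_reduction_and_correlation <- function(tracks, events) {
  if (nrow(events) < 3) stop("need at least 3 events")
  if (sd(events$peak_area) == 0)
    stop("zero variance in peak ruffle area; correlation undefined")
  tm <- track_matrix(tracks$cells, "cell", "area")
  delta <- vapply(seq_len(nrow(events)), function(k) {
    col <- match(as.character(events$cell[k]), colnames(tm$values))
    a_on <- tm$values[nearest_frame(events$onset[k], tm$times), col]
    a_end <- tm$values[nearest_frame(events$end[k], tm$times), col]
    (a_on - a_end) / a_on
  }, 0)
  fit <- stats::lm(delta ~ peak_area,
                   data = data.frame(delta = delta,
                                     peak_area = events$peak_area))
  list(per_event = data.frame(event = events$event,
                              peak_area = events$peak_area,
                              delta_area = delta),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(delta))
}

#' Junction-length change: event versus non-event junctions
#'
#' For each junctional event, the percent change of the event junction's
#' length from onset to event end; control junctions (never associated with
#' an event) are measured over windows recycled from the event windows, and
#' the two groups are compared with a two-sided unpaired t-test.
#'
#' @param tracks a `cell_tracks` with junction traces.
#' @param events event data frame.
#' @return list with `event_changes`, `control_changes` (percent),
#'   `mean_event`, `mean_control`, `t`, `p`.
#' @export
junction_length_change <- function(tracks, events) {
  jev <- events[!is.na(events$junction), , drop = FALSE]
  if (!nrow(jev)) stop("no junctional events")
  tm <- track_matrix(tracks$junctions, "junction", "length")
  pct <- function(j, t0, t1) {
    col <- match(as.character(j), colnames(tm$values))
    if (is.na(col)) return(NA_real_)
    l0 <- tm$values[nearest_frame(t0, tm$times), col]
    l1 <- tm$values[nearest_frame(t1, tm$times), col]
    100 * (l1 - l0) / l0
  }
  ev_chg <- vapply(seq_len(nrow(jev)), function(k)
    pct(jev$junction[k], jev$onset[k], jev$end[k]), 0)
  ctrl_j <- setdiff(as.integer(colnames(tm$values)), jev$junction)
  if (!length(ctrl_j)) stop("no control junctions available")
  win <- seq_len(nrow(jev))[((seq_along(ctrl_j) - 1L) %% nrow(jev)) + 1L]
  ctrl_chg <- vapply(seq_along(ctrl_j), function(k)
    pct(ctrl_j[k], jev$onset[win[k]], jev$end[win[k]]), 0)
  ev_chg <- ev_chg[!is.na(ev_chg)]
  ctrl_chg <- ctrl_chg[!is.na(ctrl_chg)]
  if (sd(ev_chg) == 0 && sd(ctrl_chg) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
    if (mean(ev_chg) != mean(ctrl_chg))
      tt <- list(statistic = c(t = Inf * sign(mean(ev_chg) -
                                                mean(ctrl_chg))),
                 p.value = 0)
  } else {
    tt <- stats::t.test(ev_chg, ctrl_chg)
  }
  list(event_changes = ev_chg, control_changes = ctrl_chg,
       mean_event = mean(ev_chg), mean_control = mean(ctrl_chg),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Event rate per cell per hour by MCC adjacency
#'
#' `rate = events in class / (cells in class x hours)`.
#'
#' @param events event data frame with an `adjacency` column.
#' @param census named vector or data frame giving the number of cells per
#'   adjacency class.
#' @param duration recording duration in minutes.
#' @return data frame: `class`, `n_cells`, `n_events`, `rate`.
#' @export
event_rate_by_adjacency <- function(events, census, duration) {
  if (duration <= 0) stop("duration must be positive")
  if (is.data.frame(census))
    census <- setNames(census$n, as.character(census$class))
  hours <- duration / 60
  cls <- names(census)
  data.frame(
    class = cls,
    n_cells = as.vector(census),
    n_events = vapply(cls, function(cl) sum(events$adjacency == cl), 0L),
    rate = vapply(cls, function(cl) {
      if (census[[cl]] == 0) return(NA_real_)
      sum(events$adjacency == cl) / (census[[cl]] * hours)
    }, 0))
}

#' Log2 fold change of event counts
#'
#' `log2(after / before)`.  A zero basal count is an error (no pseudocount;
#' the basal window is required to be informative).
#'
#' @param count_before,count_after non-negative event counts.
#' @return log2 ratio.
#' @export
fold_change_log2 <- function(count_before, count_after) {
  if (count_before <= 0)
    stop("zero basal count; fold change undefined (no pseudocount is used)")
  log2(count_after / count_before)
}

#' Tissue remodeling index over time
#'
#' Per time bin, the mean over cells of `|area change across the bin| /
#' area at bin start`, in percent, together with the number of events
#' active during the bin (an event spreads its area loss over its whole
#' duration, so activity — not onset — is the quantity remodeling tracks).
#' Area-based, hence insensitive to rigid tissue motion.
#'
#' @param tracks a `cell_tracks`.
#' @param bin_width bin width in minutes (default 2).
#' @param events optional event data frame for the per-bin event counts.
#' @return data frame: `bin_start`, `bin_mid`, `remodeling_pct`, `n_events`.
#' @export
remodeling_index <- function(tracks, bin_width = 2, events = NULL) {
  tm <- track_matrix(tracks$cells, "cell", "area")
  t0 <- min(tm$times)
  t1 <- max(tm$times)
  starts <- seq(t0, t1 - bin_width, by = bin_width)
  out <- do.call(rbind, lapply(starts, function(s) {
    k0 <- nearest_frame(s, tm$times)
    k1 <- nearest_frame(s + bin_width, tm$times)
    if (k1 <= k0) return(NULL)
    chg <- 100 * abs(tm$values[k1, ] - tm$values[k0, ]) / tm$values[k0, ]
    data.frame(bin_start = s, bin_mid = s + bin_width / 2,
               remodeling_pct = mean(chg, na.rm = TRUE),
               n_events = if (is.null(events)) NA_integer_ else
                 sum(events$onset < s + bin_width & events$end > s))
  }))
  rownames(out) <- NULL
  out
}

#' Macropinocytosis rate around extrusions: neighbours versus annulus
#'
#' For each extrusion, events within 10 min after the extrusion are counted
#' among the extruded cell's direct former neighbours and among control
#' cells whose centroids lie within twice the mean neighbour-centroid
#' radius (excluding the direct neighbours and the extruded cell); rates
#' are pooled across extrusions as events per cell per hour.
#'
#' @param events event data frame.
#' @param tissue a [gen_tissue()] result (supplies geometry and adjacency).
#' @param extrusions data frame with `cell`, `time`, `x`, `y`.
#' @param window post-extrusion window (min, default 10).
#' @return list with `neighbor_rate`, `annulus_rate`, `ratio`,
#'   `per_extrusion` data frame; empty result when there are no extrusions.
#' @export
extrusion_neighbor_rate <- function(events, tissue, extrusions,
                                    window = 10) {
  if (is.null(extrusions) || !nrow(extrusions))
    return(list(neighbor_rate = NA_real_, annulus_rate = NA_real_,
                ratio = NA_real_,
                per_extrusion = data.frame()))
  g <- adjacency_graph(tissue$mesh)
  rows <- list()
  for (k in seq_len(nrow(extrusions))) {
    xc <- extrusions$cell[k]
    t0 <- extrusions$time[k]
    nb <- as.integer(igraph::neighbors(g, xc))
    ctr <- c(tissue$cells$x[xc], tissue$cells$y[xc])
    rad <- mean(sqrt((tissue$cells$x[nb] - ctr[1])^2 +
                       (tissue$cells$y[nb] - ctr[2])^2))
    d <- sqrt((tissue$cells$x - ctr[1])^2 + (tissue$cells$y - ctr[2])^2)
    annulus <- setdiff(which(d <= 2 * rad), c(nb, xc))
    in_win <- events$onset > t0 & events$onset <= t0 + window
    rows[[k]] <- data.frame(
      extrusion = k,
      n_neighbors = length(nb),
      n_annulus = length(annulus),
      ev_neighbors = sum(in_win & events$cell %in% nb),
      ev_annulus = sum(in_win & events$cell %in% annulus))
  }
  per <- do.call(rbind, rows)
  hours <- window / 60
  nr <- sum(per$ev_neighbors) / (sum(per$n_neighbors) * hours)
  ar <- sum(per$ev_annulus) / (sum(per$n_annulus) * hours)
  list(neighbor_rate = nr, annulus_rate = ar, ratio = nr / ar,
       per_extrusion = per)
}

#' Summary statistics of ruffle events
#'
#' Mean +/- SD of duration, peak area and peak area as percent of host
#' apical area, and the junctional fraction.
#'
#' @param events nonempty event data frame.
#' @param cell_areas numeric vector of host apical areas indexed by cell id.
#' @return list with `duration`, `peak_area`, `pct_apical` (each
#'   `c(mean, sd)`), `fraction_junctional`, `n`.
#' @export
ruffle_summary <- function(events, cell_areas) {
  if (!nrow(events)) stop("empty event table")
  pct <- 100 * events$peak_area / cell_areas[events$cell]
  ms <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  list(duration = ms(events$duration),
       peak_area = ms(events$peak_area),
       pct_apical = ms(pct),
       fraction_junctional = mean(events$location == "junctional"),
       n = nrow(events))
}
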