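# Reproducibility plumbing: seed handling, mesh JSON round-trip, run
# configuration, table schemas.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' generators never perturb surrounding random streams.
#'
#' @param seed integer seed (NULL evaluates without touching the RNG).
#' @param code expression.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a named per-module seed from a base seed
#'
#' A single global seed is expanded into independent named streams so
#' adding analysis steps never perturbs simulation trajectories.  The
#' derived seed is a deterministic 31-bit hash of `(base, name, index)`.
#'
#' @param base integer base seed.
#' @param name character stream name.
#' @param index optional replicate index.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
seed_stream <- function(base, name, index = 0L) {
  h <- as.double(base %% 2147483647)
  for (ch in c(utf8ToInt(name), index)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Write a mesh to a JSON document
#'
#' The document stores vertices (x, y pairs), directed edges (tail, head,
#' 1-based), and per-cell signed edge loops plus cell state, at full float
#' precision; [read_mesh()] restores it losslessly.
#'
#' @param mesh an `epi_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  # floats are stored as 17-significant-digit decimal strings, which
  # round-trip IEEE doubles exactly
  num <- function(x) sprintf("%.17g", x)
  doc <- list(
    format = "epivertex-mesh",
    version = 1L,
    vertices = unname(lapply(seq_len(nrow(mesh$vertices)), function(i)
      list(num(mesh$vertices[i, 1]), num(mesh$vertices[i, 2])))),
    edges = unname(apply(mesh$edges, 1, as.list)),
    cells = lapply(seq_len(n_cells(mesh)), function(ci) {
      st <- mesh$cells[ci, ]
      list(edges = as.list(mesh$cell_edges[[ci]]), age = num(st$age),
           A0 = num(st$A0), sigma = num(st$sigma), is_mcc = st$is_mcc,
           can_divide = st$can_divide, cycle_time = num(st$cycle_time))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mesh from a JSON document
#'
#' @param path file written by [write_mesh()].
#' @return an `epi_mesh`.
#' @export
read_mesh <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "epivertex-mesh"))
    stop("not an epivertex mesh document: ", path)
  verts <- do.call(rbind, lapply(doc$vertices, function(v)
    as.numeric(unlist(v))))
  edges <- do.call(rbind, lapply(doc$edges, function(e)
    as.integer(unlist(e))))
  if (any(is.na(edges)) || any(edges < 1) || any(edges > nrow(verts)))
    stop("corrupt edge table: endpoint out of range at edge ",
         which(apply(edges, 1, function(r)
           any(is.na(r) | r < 1 | r > nrow(verts))))[1])
  cell_edges <- lapply(doc$cells, function(cl) {
    v <- as.integer(unlist(cl$edges))
    if (any(is.na(v)) || any(abs(v) < 1) || any(abs(v) > nrow(edges)))
      stop("corrupt cell loop: edge index out of range")
    v
  })
  cells <- do.call(rbind, lapply(doc$cells, function(cl)
    data.frame(age = as.numeric(cl$age), A0 = as.numeric(cl$A0),
               sigma = as.numeric(cl$sigma),
               is_mcc = as.logical(cl$is_mcc),
               can_divide = as.logical(cl$can_divide),
               cycle_time = as.numeric(cl$cycle_time))))
  rownames(cells) <- NULL
  new_mesh(verts, edges, cell_edges, cells)
}

#' Read a run configuration from a YAML file
#'
#' Keys `mechanics`, `protocol` and `events` override the corresponding
#' defaults of [mech_params()], [protocol_config()] and
#' [event_gen_params()]; `seed` sets the base seed.  Unknown keys raise an
#' error naming them.
#'
#' @param path YAML file.
#' @return list with `params`, `protocol`, `events`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("mechanics", "protocol", "events", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  params <- do.call(mech_params, as.list(raw$mechanics))
  prot <- as.list(raw$protocol)
  prot$params <- params
  list(params = params,
       protocol = do.call(protocol_config, prot),
       events = do.call(event_gen_params, as.list(raw$events)),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' Validate an event table against the package schema
#'
#' @param events data frame.
#' @return `TRUE` invisibly; otherwise an error listing the violations.
#' @export
validate_event_table <- function(events) {
  problems <- character()
  need <- c("event", "cell", "onset", "duration", "end", "peak_area",
            "loss_frac", "location", "junction", "adjacency")
  miss <- setdiff(need, names(events))
  if (length(miss))
    problems <- c(problems, paste("missing columns:",
                                  paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(events)) {
    if (any(events$duration <= 0)) problems <- c(problems,
                                                 "non-positive duration")
    if (any(events$peak_area <= 0)) problems <- c(problems,
                                                  "non-positive peak area")
    if (!all(events$location %in% c("junctional", "medial")))
      problems <- c(problems, "location outside {junctional, medial}")
  }
  if (length(problems))
    stop("invalid event table: ", paste(problems, collapse = "; "))
  invisible(TRUE)
}

#' Validate a cell-tracks object against the package schema
#'
#' @param tracks a `cell_tracks`.
#' @return `TRUE` invisibly; otherwise an error listing the violations.
#' @export
validate_cell_tracks <- function(tracks) {
  problems <- character()
  if (!all(c("cells", "junctions", "frame_interval") %in% names(tracks)))
    problems <- c(problems, "missing components")
  if (!length(problems)) {
    if (any(tracks$cells$area <= 0, na.rm = TRUE))
      problems <- c(problems, "non-positive area")
    dtu <- diff(sort(unique(tracks$cells$time)))
    if (length(dtu) && max(abs(dtu - tracks$frame_interval)) > 1e-9)
      problems <- c(problems, "non-uniform frame interval")
  }
  if (length(problems))
    stop("invalid cell tracks: ", paste(problems, collapse = "; "))
  invisible(TRUE)
}
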