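#' @name boolean_engine
#' @title Synchronous simulation and attractor analysis
#'
#' @description
#' The engine applies all update rules simultaneously (synchronous
#' deterministic scheme; asynchronous updating of the source and product
#' states of one reaction would create simulation artefacts). Attractors
#' are detected exactly, by hashing every visited state vector: the state
#' space is finite, so every trajectory ends in a point attractor
#' (period 1) or a cyclic attractor (period > 1).
NULL

#' One synchronous update step
#'
#' @param m a `bbm` model.
#' @param v named logical vector over the model's target symbols.
#' @return the successor state vector.
#' @export
step_bbm <- function(m, v) {
  stopifnot(inherits(m, "bbm"))
  out <- vapply(m$targets$symbol, function(sym)
    bx_eval(m$rules[[sym]], v), TRUE)
  names(out) <- m$targets$symbol
  out
}

vec_key <- function(v) paste0("k", paste(as.integer(v), collapse = ""))

#' Simulate to an attractor
#'
#' Iterates [step_bbm()] from `v0` until a state vector recurs, recording
#' the full trajectory. `attractor_start` is the first index (1-based into
#' `trajectory`) whose state recurs; the attractor is the slice
#' `trajectory[attractor_start : (attractor_start + period - 1)]`.
#'
#' @param m a `bbm` model.
#' @param v0 initial state vector; defaults to the model's default initial
#'   state.
#' @param max_steps safety bound on trajectory length.
#' @return an object of class `simulation_result` with fields `trajectory`
#'   (list of named logical vectors), `attractor_start`, `period`, and
#'   `attractor` (the list of attractor states).
#' @export
simulate_to_attractor <- function(m, v0 = m$init, max_steps = 100000L) {
  stopifnot(inherits(m, "bbm"))
  v0 <- v0[m$targets$symbol]
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  trajectory <- list()
  v <- v0
  for (t in seq_len(max_steps)) {
    key <- vec_key(v)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      period <- length(trajectory) - prev + 1L
      res <- structure(list(
        trajectory = trajectory,
        attractor_start = prev,
        period = period,
        attractor = trajectory[seq(prev, length.out = period)]),
        class = "simulation_result")
      return(res)
    }
    trajectory[[length(trajectory) + 1L]] <- v
    seen[[key]] <- length(trajectory)
    v <- step_bbm(m, v)
  }
  stop("no attractor within ", max_steps, " steps")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$trajectory), " states, attractor at t=",
      x$attractor_start - 1L, ", period ", x$period,
      if (x$period == 1L) " (point)" else " (cyclic)", "\n", sep = "")
  invisible(x)
}

#' Is the attractor a point attractor?
#' @param res a `simulation_result`.
#' @return logical scalar.
#' @export
is_point_attractor <- function(res) res$period == 1L

canonical_attractor_key <- function(res) {
  keys <- vapply(res$attractor, vec_key, "")
  n <- length(keys)
  rots <- vapply(seq_len(n), function(i)
    paste(keys[((seq_len(n) + i - 2L) %% n) + 1L], collapse = "|"), "")
  min(rots)
}

#' Input-toggling analysis workflow
#'
#' Simulates from the model's default initial state (inputs false) to a
#' first attractor — the model's natural "off state" — then iteratively
#' flips the named inputs and re-simulates from the attractor, until an
#' attractor recurs or `max_phases` is reached. When a phase ends in a
#' cyclic attractor (a point attractor is what the toggling step expects),
#' the workflow continues from the first attractor state and records the
#' event in the termination reason.
#'
#' @param m a `bbm` model.
#' @param inputs character vector of input names to toggle (without
#'   brackets); defaults to all inputs of the model.
#' @param max_phases maximum number of phases.
#' @param v0 optional starting vector for phase 1.
#' @return an object of class `workflow_result`: `phases` (list of
#'   `list(inputs = named logical, result = simulation_result)`) and
#'   `termination` (one of `"attractor_revisited"`, `"max_phases"`).
#' @export
input_toggle_workflow <- function(m, inputs = NULL, max_phases = 10L,
                                  v0 = m$init) {
  stopifnot(inherits(m, "bbm"))
  all_inputs <- m$targets$symbol[m$targets$kind == "input"]
  input_names <- sub("^\\[(.*)\\]$", "\\1",
                     m$targets$name[m$targets$kind == "input"])
  if (is.null(inputs)) {
    syms <- all_inputs
  } else {
    idx <- match(inputs, input_names)
    if (anyNA(idx)) stop("unknown input(s): ",
                         paste(inputs[is.na(idx)], collapse = ", "))
    syms <- all_inputs[idx]
  }

  phases <- list()
  seen <- character(0)
  termination <- "max_phases"
  value <- FALSE  # phase 1 runs with inputs at their default (false)
  v <- v0
  v[syms] <- value
  cyclic_seen <- FALSE
  for (ph in seq_len(max_phases)) {
    res <- simulate_to_attractor(m, v)
    phase_inputs <- rep(value, length(syms))
    names(phase_inputs) <- syms
    phases[[ph]] <- list(inputs = phase_inputs, result = res)
    # attractors are compared with the toggled inputs masked out, so a
    # model that ignores its inputs terminates after two phases
    key <- canonical_attractor_key(structure(list(
      attractor = lapply(res$attractor, function(v)
        v[setdiff(names(v), syms)])), class = "simulation_result"))
    if (key %in% seen) {
      termination <- "attractor_revisited"
      break
    }
    seen <- c(seen, key)
    if (!is_point_attractor(res)) cyclic_seen <- TRUE
    value <- !value
    v <- res$attractor[[1]]
    v[syms] <- value
  }
  structure(list(phases = phases,
                 termination = termination,
                 cyclic_phase_encountered = cyclic_seen),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("<workflow_result> ", length(x$phases), " phase(s), termination: ",
      x$termination, "\n", sep = "")
  for (i in seq_along(x$phases)) {
    p <- x$phases[[i]]
    cat("  phase ", i, ": inputs {",
        paste(names(p$inputs), as.integer(p$inputs), sep = "=", collapse = ", "),
        "}, period ", p$result$period, "\n", sep = "")
  }
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' First column the target symbol, subsequent columns the time points
#' `t0, t1, ...` with values 0/1 (targets as rows, time as columns, the
#' orientation of the usual trajectory heatmaps).
#'
#' @param res a `simulation_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(res, path) {
  mat <- vapply(res$trajectory, as.integer,
                integer(length(res$trajectory[[1]])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  df <- data.frame(target = names(res$trajectory[[1]]), mat,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("target", paste0("t", seq_along(res$trajectory) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
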