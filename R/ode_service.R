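#' Solver-instance management strategy
#'
#' How intracellular solver objects are allocated across cell agents:
#' `"singleton"` keeps one shared instance reinitialized on every call,
#' `"per_cell"` keeps a persistent instance per agent, and `"pool"` checks
#' instances out of a fixed-size pool. Because every strategy reinitializes
#' the model state from the calling cell's current inputs, all three return
#' identical outputs; they differ only in memory/instantiation cost, which
#' the cost metrics expose.
#'
#' @param kind `"singleton"`, `"per_cell"` or `"pool"`.
#' @param pool_size pool size (pool strategy only), at least 1.
#' @return an object of class `solver_strategy`.
#' @export
solver_strategy <- function(kind = c("singleton", "per_cell", "pool"),
                            pool_size = 1L) {
  kind <- match.arg(kind)
  pool_size <- as.integer(pool_size)
  if (kind == "pool" && pool_size < 1L) stop("pool_size must be at least 1")
  structure(list(kind = kind, pool_size = pool_size),
            class = "solver_strategy")
}

# One solver instance: holds its own copy of the model handle plus the
# "current cell" settings it was last initialized to.
.new_solver_instance <- function(model) {
  inst <- new.env(parent = emptyenv())
  inst$model <- model
  inst$inputs <- NULL
  inst$state <- numeric(length(model$state_names))
  inst$solves <- 0L
  inst
}

#' Intracellular ODE service
#'
#' Wraps an [build_reduced_model()]-style model behind a solver-instance
#' strategy and bookkeeping counters. Results for repeated identical input
#' triples are memoized by default (the integration is deterministic, so
#' cached and recomputed values are identical); `memoize = FALSE` forces an
#' integration per call. A surrogate function `inputs -> outputs` can be
#' plugged in place of the integrator (hook for learned input--output
#' replacements of the kinetic model).
#'
#' @param model an `ode_model`.
#' @param strategy a [solver_strategy()].
#' @param memoize cache results per unique input triple.
#' @param surrogate optional function taking the named 3-vector of inputs
#'   and returning a named vector containing at least IFNg, IL17, IL10.
#' @return an environment of class `ode_service`.
#' @export
ode_service <- function(model, strategy = solver_strategy("singleton"),
                        memoize = TRUE, surrogate = NULL) {
  stopifnot(inherits(model, "ode_model"), inherits(strategy, "solver_strategy"))
  sv <- new.env(parent = emptyenv())
  sv$model <- model
  sv$strategy <- strategy
  sv$memoize <- isTRUE(memoize)
  sv$surrogate <- surrogate
  sv$cache <- new.env(parent = emptyenv())
  sv$instances <- new.env(parent = emptyenv())
  sv$pool <- NULL
  sv$pool_next <- 1L
  sv$calls <- 0L
  sv$integrations <- 0L
  sv$instances_created <- 0L
  if (strategy$kind == "singleton") {
    sv$singleton <- .new_solver_instance(model)
    sv$instances_created <- 1L
  } else if (strategy$kind == "pool") {
    sv$pool <- lapply(seq_len(strategy$pool_size),
                      function(i) .new_solver_instance(model))
    sv$instances_created <- strategy$pool_size
  }
  class(sv) <- "ode_service"
  sv
}

.checkout_instance <- function(service, agent_id) {
  st <- service$strategy
  if (st$kind == "singleton") return(service$singleton)
  if (st$kind == "pool") {
    inst <- service$pool[[service$pool_next]]
    service$pool_next <- (service$pool_next %% st$pool_size) + 1L
    return(inst)
  }
  key <- as.character(if (is.null(agent_id)) "anonymous" else agent_id)
  if (!exists(key, envir = service$instances, inherits = FALSE)) {
    assign(key, .new_solver_instance(service$model), envir = service$instances)
    service$instances_created <- service$instances_created + 1L
  }
  get(key, envir = service$instances, inherits = FALSE)
}

#' Run one per-cell time course through the service
#'
#' Checks a solver instance out according to the strategy, reinitializes it
#' to the calling cell's current cytokine inputs, integrates (or retrieves
#' the memoized result / calls the surrogate), and returns the terminal
#' state. Output values are strategy-invariant by contract.
#'
#' @param service an [ode_service()].
#' @param inputs numeric 3-vector (IL12, TGFb, IL6).
#' @param agent_id calling agent's id (required bookkeeping for the
#'   per-cell strategy).
#' @return named numeric vector of dynamic species at the horizon.
#' @export
solve_for_cell <- function(service, inputs, agent_id = NULL) {
  stopifnot(inherits(service, "ode_service"))
  inputs <- .check_inputs(inputs)
  service$calls <- service$calls + 1L
  inst <- .checkout_instance(service, agent_id)
  # reinitialize to the current cell's settings
  inst$inputs <- inputs
  inst$state <- numeric(length(service$model$state_names))
  inst$solves <- inst$solves + 1L
  if (!is.null(service$surrogate)) {
    out <- service$surrogate(inputs)
    service$integrations <- service$integrations + 1L
    return(out)
  }
  key <- paste(sprintf("%.17g", inputs), collapse = "|")
  if (service$memoize &&
      exists(key, envir = service$cache, inherits = FALSE)) {
    out <- get(key, envir = service$cache, inherits = FALSE)
  } else {
    out <- time_course(service$model, inputs)
    service$integrations <- service$integrations + 1L
    if (service$memoize) assign(key, out, envir = service$cache)
  }
  inst$state <- out
  out
}

#' Service bookkeeping counters
#'
#' @param service an [ode_service()].
#' @return list with `calls` (service invocations), `integrations` (actual
#'   ODE integrations, i.e. cache misses), `instances_created` and
#'   `peak_instances` (live solver instances; equals 1 for singleton, the
#'   pool size for pool, and the number of distinct calling agents for
#'   per-cell).
#' @export
service_counters <- function(service) {
  stopifnot(inherits(service, "ode_service"))
  live <- switch(service$strategy$kind,
    singleton = 1L,
    pool = service$strategy$pool_size,
    per_cell = length(ls(service$instances)))
  list(calls = service$calls, integrations = service$integrations,
       instances_created = service$instances_created, peak_instances = live)
}

#' @export
print.ode_service <- function(x, ...) {
  ct <- service_counters(x)
  cat(sprintf("<ode_service> strategy=%s calls=%d integrations=%d instances=%d\n",
              x$strategy$kind, ct$calls, ct$integrations, ct$peak_instances))
  invisible(x)
}
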