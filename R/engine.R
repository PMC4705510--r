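#' Is a scale due on a given cycle?
#'
#' A scale with simulation frequency `f` executes once every
#' `round(1 / f)` cycles, starting at cycle 0; `f = 1` executes every
#' cycle. A frequency of 0.1 therefore yields exactly 10 executions over
#' cycles 0..99 (cycles 0, 10, ..., 90). Non-reciprocal frequencies are
#' honoured approximately through the rounded period.
#'
#' @param cycle 0-based cycle index.
#' @param frequency per-cycle simulation frequency in `(0, 1]`.
#' @return logical.
#' @export
is_due <- function(cycle, frequency) {
  if (!is.numeric(frequency) || frequency <= 0 || frequency > 1) {
    stop("frequency must lie in (0, 1]")
  }
  period <- max(1L, as.integer(round(1 / frequency)))
  as.integer(cycle) %% period == 0L
}

#' Initialize a simulation from a configuration
#'
#' Builds the grid and compartments, all-zero value layers, the agent
#' populations placed uniformly at random ("evenly distributed in the
#' square area"), the intracellular ODE service, seeded RNG streams and
#' empty cost metrics, and records the cycle-0 report.
#'
#' @param config a [scenario_config()].
#' @return an environment of class `sim_state`.
#' @export
init_scenario <- function(config) {
  validate_scenario(config)
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$space <- grid_space(config$grid[1L], config$grid[2L],
                            config$compartments)
  state$rng <- rng_streams(config$seed)

  lay <- list()
  for (ls in config$layers) {
    args <- utils::modifyList(
      list(width = config$grid[1L], height = config$grid[2L]),
      ls[names(ls) %in% c("name", "ce", "cd", "neighborhood", "boundary",
                          "mode", "clamp_nonnegative")])
    lay[[ls$name]] <- do.call(value_layer, args)
  }
  state$layers <- lay
  state$running_max <- stats::setNames(numeric(length(lay)), names(lay))

  agents <- NULL
  next_id <- 1L
  for (p in config$populations) {
    cnt <- as.integer(p$count)
    pos <- with_stream(state$rng, "placement", function() runif(2L * cnt))
    a <- cell_agents(
      p$type, p$state, cnt,
      x = pos[seq_len(cnt)] * config$grid[1L],
      y = pos[cnt + seq_len(cnt)] * config$grid[2L],
      speed_max = if (is.null(p$speed_max)) 1.0 else p$speed_max,
      chemo_layer = if (is.null(p$chemo_layer)) NA_character_ else
        p$chemo_layer,
      chemo_w = if (is.null(p$chemo_w)) 0 else p$chemo_w,
      id_start = next_id)
    if (cnt > 0) {
      a$compartment <- compartment_at(state$space, a$x, a$y)
    }
    agents <- if (is.null(agents)) a else rbind(agents, a)
    next_id <- next_id + cnt
  }
  if (is.null(agents)) agents <- cell_agents("generic", "idle", 0L, 0, 0)
  state$agents <- agents

  model <- if (!is.null(config$ode$model_file)) {
    read_model_definition(config$ode$model_file)
  } else {
    build_reduced_model(config$ode$params)
  }
  if (!is.null(config$ode$inflate)) {
    model <- inflate_model(model, config$ode$inflate)
  }
  state$model <- model
  state$service <- ode_service(model, config$ode$strategy,
                               memoize = config$ode$memoize,
                               surrogate = config$ode$surrogate)

  m <- new.env(parent = emptyenv())
  m$executions <- c(cellular = 0L, intercellular = 0L, intracellular = 0L)
  m$time <- c(cellular = 0, intercellular = 0, intracellular = 0)
  m$init_time <- 0
  state$metrics <- m
  state$cycle <- 0L
  state$reports <- list()
  class(state) <- "sim_state"
  .record_report(state)
  state
}

#' @export
print.sim_state <- function(x, ...) {
  ct <- table(paste(x$agents$type, x$agents$state))
  cat(sprintf("<sim_state> cycle %d, %d agents, %d layers\n",
              x$cycle, nrow(x$agents), length(x$layers)))
  print(ct)
  invisible(x)
}

#' @export
summary.sim_state <- function(object, ...) {
  rep <- object$reports[[length(object$reports)]]
  cat(sprintf("Simulation at cycle %d (%d report(s))\n", object$cycle,
              length(object$reports)))
  print(rep$counts)
  cm <- cost_metrics(object)
  cat("Scale executions: ",
      paste(names(cm$executions), cm$executions, sep = "=",
            collapse = "  "), "\n")
  invisible(cm)
}

.record_report <- function(state) {
  ag <- state$agents
  counts <- if (nrow(ag) == 0L) {
    data.frame(type = character(0), state = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  } else {
    tb <- as.data.frame(table(type = ag$type, state = ag$state),
                        stringsAsFactors = FALSE)
    tb <- tb[tb$Freq > 0, , drop = FALSE]
    names(tb)[3L] <- "count"
    tb
  }
  counts <- counts[order(counts$type, counts$state), , drop = FALSE]
  rownames(counts) <- NULL
  lsum <- vapply(state$layers, function(l) sum(l$values), 0)
  lmax <- vapply(state$layers, function(l) max(l$values), 0)
  state$running_max <- pmax(state$running_max, lmax)
  state$reports[[length(state$reports) + 1L]] <- list(
    cycle = state$cycle, counts = counts, layer_sum = lsum,
    layer_max = lmax, metrics = cost_metrics(state))
  invisible(state)
}

# Vectorized application of buffered deposits, preserving row order for the
# overwrite ("set") semantics: later rows win, matching sequential
# application.
.apply_deposits <- function(layers, dep) {
  if (nrow(dep) == 0L) return(layers)
  for (lname in unique(dep$layer)) {
    ly <- layers[[lname]]
    if (is.null(ly)) stop("deposit references unknown layer: ", lname)
    d <- dep[dep$layer == lname, , drop = FALSE]
    for (sem in unique(d$semantics)) {
      ds <- d[d$semantics == sem, , drop = FALSE]
      idx <- cbind(ds$y + 1L, ds$x + 1L)
      if (sem == "set") {
        ly$values[idx] <- ds$value
      } else if (sem == "add") {
        add <- rowsum(ds$value, group = paste(ds$y, ds$x))
        key <- strsplit(rownames(add), " ", fixed = TRUE)
        yy <- vapply(key, function(k) as.integer(k[1L]), 0L)
        xx <- vapply(key, function(k) as.integer(k[2L]), 0L)
        ly$values[cbind(yy + 1L, xx + 1L)] <-
          ly$values[cbind(yy + 1L, xx + 1L)] + add[, 1L]
      } else {
        mx <- tapply(ds$value, paste(ds$y, ds$x), max)
        key <- strsplit(names(mx), " ", fixed = TRUE)
        yy <- vapply(key, function(k) as.integer(k[1L]), 0L)
        xx <- vapply(key, function(k) as.integer(k[2L]), 0L)
        ly$values[cbind(yy + 1L, xx + 1L)] <-
          pmax(ly$values[cbind(yy + 1L, xx + 1L)], mx)
      }
    }
    layers[[lname]] <- ly
  }
  layers
}

#' Advance the simulation by one cycle
#'
#' Executes the three phases in order. (a) Movement: all living agents
#' move, and every value layer performs one diffusion--evaporation step
#' (order within the phase is configurable). (b) Computing and updating:
#' in uniformly shuffled order each agent inspects its grid cell --
#' immature dendritic cells apply the bacterial contact rule, naive T
#' cells invoke the intracellular service when the intracellular scale is
#' due this cycle, generic rules fire -- with all secretions buffered and
#' applied at the end of the phase, so agent order cannot change what
#' co-located agents sense; concentrations read in this phase are the
#' phase-(a) field, i.e. the diffused deposits of earlier cycles.
#' (c) Reporting: population counts, layer statistics and cost metrics are
#' recorded and the cycle counter increments.
#'
#' @param state a `sim_state` from [init_scenario()]; modified in place.
#' @return the state, invisibly.
#' @export
run_cycle <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  cfg <- state$config
  cyc <- state$cycle
  m <- state$metrics
  due_cell <- is_due(cyc, cfg$frequencies$cellular)
  due_pde <- is_due(cyc, cfg$frequencies$intercellular)
  due_ode <- is_due(cyc, cfg$frequencies$intracellular)

  do_move <- function() {
    if (due_cell && cfg$movement && nrow(state$agents) > 0L) {
      t0 <- proc.time()[[3L]]
      state$agents <- move_agents(state$agents, state$space, state$rng,
                                  state$layers)
      m$time[["cellular"]] <- m$time[["cellular"]] + proc.time()[[3L]] - t0
    }
  }
  do_diffuse <- function() {
    if (due_pde) {
      t0 <- proc.time()[[3L]]
      state$layers <- lapply(state$layers, diffuse_step)
      m$executions[["intercellular"]] <- m$executions[["intercellular"]] + 1L
      m$time[["intercellular"]] <-
        m$time[["intercellular"]] + proc.time()[[3L]] - t0
    }
  }
  if (cfg$movement_first) {
    do_move(); do_diffuse()
  } else {
    do_diffuse(); do_move()
  }

  if (due_cell) {
    t0 <- proc.time()[[3L]]
    m$executions[["cellular"]] <- m$executions[["cellular"]] + 1L
    ag <- state$agents
    n <- nrow(ag)
    dep <- list()
    if (n > 0L) {
      perm <- with_stream(state$rng, "shuffle",
                          function() sample.int(n))
      type0 <- ag$type
      state0 <- ag$state
      alive0 <- ag$alive
      st <- ag$state
      alive <- ag$alive
      ax <- as.integer(floor(ag$x))
      ay <- as.integer(floor(ag$y))
      cellid <- ax + cfg$grid[1L] * ay
      invperm <- integer(n)
      invperm[perm] <- seq_len(n)

      # --- dendritic-cell contact rule -------------------------------
      inf_cells <- unique(cellid[alive0 & type0 == "bacterium" &
                                   state0 == "infectious"])
      tol_cells <- unique(cellid[alive0 & type0 == "bacterium" &
                                   state0 == "tolerogenic"])
      idc <- alive0 & type0 == "dendritic_cell" & state0 == "immature"
      near_inf <- idc & cellid %in% inf_cells
      near_tol <- idc & cellid %in% tol_cells
      if (cfg$dc_tie_break == "effector") {
        to_eff <- near_inf
        to_tol <- near_tol & !near_inf
      } else {
        to_tol <- near_tol
        to_eff <- near_inf & !near_tol
      }
      st[to_eff] <- "effector"
      st[to_tol] <- "tolerogenic"

      # --- dendritic-cell secretion ----------------------------------
      secretors_e <- if (cfg$secretion_recurs) {
        alive & type0 == "dendritic_cell" & st == "effector"
      } else to_eff
      secretors_t <- if (cfg$secretion_recurs) {
        alive & type0 == "dendritic_cell" & st == "tolerogenic"
      } else to_tol
      if (any(secretors_e)) {
        i <- which(secretors_e)
        dep[[length(dep) + 1L]] <- data.frame(
          layer = rep(c("IL6", "IL12"), each = length(i)),
          x = rep(ax[i], 2L), y = rep(ay[i], 2L),
          value = cfg$deposit_value, semantics = cfg$deposit_semantics)
      }
      if (any(secretors_t)) {
        i <- which(secretors_t)
        dep[[length(dep) + 1L]] <- data.frame(
          layer = "TGFb", x = ax[i], y = ay[i],
          value = cfg$tdc_deposit_value, semantics = cfg$deposit_semantics)
      }

      # --- naive T-cell differentiation (intracellular scale) --------
      if (due_ode) {
        m$executions[["intracellular"]] <- m$executions[["intracellular"]] + 1L
        t_ode <- proc.time()[[3L]]
        naive <- which(alive0 & type0 == "t_cell" & state0 == "naive")
        if (length(naive) > 0L) {
          naive <- naive[order(invperm[naive])]
          v12 <- state$layers$IL12$values[cbind(ay[naive] + 1L,
                                                ax[naive] + 1L)]
          vtg <- state$layers$TGFb$values[cbind(ay[naive] + 1L,
                                                ax[naive] + 1L)]
          v6 <- state$layers$IL6$values[cbind(ay[naive] + 1L,
                                              ax[naive] + 1L)]
          theta <- state$model$params$theta_out
          fixed <- if (identical(cfg$tcell_deposit, "ode")) NULL else
            cfg$tcell_deposit
          t_lay <- character(0); t_x <- integer(0); t_y <- integer(0)
          t_val <- numeric(0)
          for (j in seq_along(naive)) {
            i <- naive[j]
            out <- tryCatch(
              solve_for_cell(state$service, c(v12[j], vtg[j], v6[j]),
                             agent_id = ag$id[i]),
              error = function(e) {
                stop("cycle ", cyc, ", agent ", ag$id[i], ": ",
                     conditionMessage(e))
              })
            ph <- classify_outputs(out[.MODEL_OUTPUTS], theta)
            if (ph != "naive") {
              st[i] <- ph
              marker <- .PHENOTYPE_MARKER[[ph]]
              t_lay <- c(t_lay, marker)
              t_x <- c(t_x, ax[i])
              t_y <- c(t_y, ay[i])
              t_val <- c(t_val, if (is.null(fixed)) unname(out[[marker]])
                         else fixed)
            }
          }
          if (length(t_lay) > 0L) {
            dep[[length(dep) + 1L]] <- data.frame(
              layer = t_lay, x = t_x, y = t_y, value = t_val,
              semantics = cfg$deposit_semantics)
          }
        }
        dt <- proc.time()[[3L]] - t_ode
        m$time[["intracellular"]] <- m$time[["intracellular"]] + dt
        t0 <- t0 + dt  # keep the ODE time out of the cellular account
      }

      # --- generic declarative rules ---------------------------------
      if (length(cfg$rules) > 0L) {
        ruled_types <- unique(vapply(cfg$rules, `[[`, "", "agent_type"))
        cand <- which(alive0 & type0 %in% ruled_types)
        cand <- cand[order(invperm[cand])]
        snap <- data.frame(type = type0, state = state0, alive = alive0)
        for (i in cand) {
          coh <- snap[cellid == cellid[i] & seq_len(n) != i, ,
                      drop = FALSE]
          local <- vapply(state$layers, function(l)
            l$values[ay[i] + 1L, ax[i] + 1L], 0)
          res <- apply_generic_rules(
            list(id = ag$id[i], type = type0[i], state = st[i],
                 x = ag$x[i], y = ag$y[i], alive = alive[i]),
            cfg$rules, coh, local, state$rng)
          st[i] <- res$agent$state
          if (nrow(res$deposits) > 0L) dep[[length(dep) + 1L]] <- res$deposits
        }
      }

      # --- optional per-type death -----------------------------------
      if (!is.null(cfg$death_prob)) {
        for (tp in names(cfg$death_prob)) {
          idx <- which(alive & type0 == tp)
          if (length(idx) == 0L) next
          idx <- idx[order(invperm[idx])]
          u <- with_stream(state$rng, "rules",
                           function() runif(length(idx)))
          dies <- idx[u < cfg$death_prob[[tp]]]
          st[dies] <- "dead"
          alive[dies] <- FALSE
        }
      }

      ag$state <- st
      ag$alive <- alive
      state$agents <- ag
      if (length(dep) > 0L) {
        state$layers <- .apply_deposits(state$layers, do.call(rbind, dep))
      }
    }
    m$time[["cellular"]] <- m$time[["cellular"]] + proc.time()[[3L]] - t0
  }

  state$cycle <- state$cycle + 1L
  .record_report(state)
  invisible(state)
}

#' Run a scenario for a number of cycles
#'
#' @param x a [scenario_config()] or an existing `sim_state`.
#' @param cycles number of cycles to execute; defaults to the config's
#'   `cycles`.
#' @return the final `sim_state` (one report per cycle plus the initial
#'   cycle-0 report).
#' @export
run_scenario <- function(x, cycles = NULL) {
  if (inherits(x, "scenario_config")) {
    t0 <- proc.time()[[3L]]
    state <- init_scenario(x)
    state$metrics$init_time <- proc.time()[[3L]] - t0
    if (is.null(cycles)) cycles <- x$cycles
  } else if (inherits(x, "sim_state")) {
    state <- x
    if (is.null(cycles)) cycles <- state$config$cycles
  } else {
    stop("x must be a scenario_config or sim_state")
  }
  for (k in seq_len(cycles)) run_cycle(state)
  state
}

#' Cost-accounting metrics of a simulation
#'
#' @param state a `sim_state`.
#' @return list with per-scale execution counts and cumulative measured
#'   costs (elapsed seconds, hardware-dependent and therefore reported in
#'   arbitrary units), the solver-service counters of
#'   [service_counters()], and the initialization cost.
#' @export
cost_metrics <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  list(executions = state$metrics$executions,
       time = state$metrics$time,
       init_time = state$metrics$init_time,
       solver = service_counters(state$service))
}

#' Estimated cost of one simulation cycle
#'
#' Implements the frequency-weighted cost model of hybrid scheduling: if
#' scale `i` costs `c_i` per execution and runs with frequency `f_i`, one
#' cycle costs `sum_i f_i * c_i`. The per-execution costs are the measured
#' means from the metrics.
#'
#' @param metrics a [cost_metrics()] list (or a `sim_state`).
#' @param frequencies named frequencies per scale; scales absent from the
#'   metrics (or with zero executions) contribute zero.
#' @return the estimated per-cycle cost (arbitrary time units).
#' @export
estimate_cycle_cost <- function(metrics, frequencies) {
  if (inherits(metrics, "sim_state")) metrics <- cost_metrics(metrics)
  ex <- metrics$executions
  if (is.null(ex) || sum(ex) == 0) stop("metrics are empty: nothing executed")
  total <- 0
  for (sc in names(frequencies)) {
    f <- frequencies[[sc]]
    if (is.null(f) || f == 0) next
    cnt <- if (sc %in% names(ex)) ex[[sc]] else 0L
    if (cnt == 0L) next
    total <- total + f * metrics$time[[sc]] / cnt
  }
  total
}
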