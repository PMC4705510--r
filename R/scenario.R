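.CYTOKINES <- c("IL12", "TGFb", "IL6", "IFNg", "IL17", "IL10")

#' Scenario configuration
#'
#' Complete specification of a simulation: grid and compartments, cytokine
#' layers, agent populations, intracellular model and solver strategy,
#' per-scale update frequencies, cycle count and master seed. A
#' configuration plus a seed fully determines every output artifact.
#'
#' @param grid integer `c(width, height)`.
#' @param compartments list of [compartment()]s, or `NULL` for a single
#'   generic compartment.
#' @param layers list of per-layer settings `list(name, ce, cd,
#'   neighborhood, boundary, mode)`; missing fields take the defaults of
#'   [value_layer()]. `NULL` creates the six cytokine layers (IL-12,
#'   TGF-beta, IL-6, IFN-gamma, IL-17, IL-10) with `ce = 0.98`,
#'   `cd = 0.6`.
#' @param populations list of `list(type, state, count, speed_max,
#'   chemo_layer, chemo_w)` entries placed uniformly at random.
#' @param ode list: `params` ([kinetic_params()]), `strategy`
#'   ([solver_strategy()]), `inflate` (`NULL` or target counts
#'   `c(species, reactions, odes)`), `memoize`, `model_file` (optional
#'   path to a [read_model_definition()] file overriding the built model).
#' @param frequencies named list of per-scale simulation frequencies in
#'   `(0, 1]` for `cellular`, `intercellular`, `intracellular`; a scale
#'   with frequency `f` executes on cycles that are multiples of
#'   `round(1 / f)`.
#' @param cycles default number of cycles for [run_scenario()].
#' @param seed master RNG seed.
#' @param deposit_value concentration released by converting dendritic
#'   cells (relative units).
#' @param tdc_deposit_value concentration released by tolerogenic
#'   dendritic cells (defaults to `deposit_value`).
#' @param deposit_semantics default deposit semantics.
#' @param tcell_deposit either `"ode"` (release the ODE-predicted output
#'   concentration) or a fixed non-negative number.
#' @param secretion_recurs effector/tolerogenic dendritic cells keep
#'   depositing every cycle while alive (`TRUE`, default) or only at the
#'   differentiation event.
#' @param movement enable agent movement.
#' @param movement_first within the movement phase, move agents before
#'   diffusing layers (`TRUE`) or after (`FALSE`).
#' @param dc_tie_break conversion winning when both bacterial subtypes
#'   share a dendritic cell's grid cell.
#' @param rules list of [transition_rule()]s for generic cell types.
#' @param death_prob optional named numeric: per-cycle death probability
#'   per agent type (death disabled by default).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(grid = c(100L, 100L), compartments = NULL,
                            layers = NULL, populations = list(),
                            ode = list(), frequencies = list(),
                            cycles = 100L, seed = 1L, deposit_value = 70,
                            tdc_deposit_value = NULL,
                            deposit_semantics = "set",
                            tcell_deposit = "ode", secretion_recurs = TRUE,
                            movement = TRUE, movement_first = TRUE,
                            dc_tie_break = "effector", rules = list(),
                            death_prob = NULL) {
  if (is.null(layers)) {
    layers <- lapply(.CYTOKINES, function(nm) list(name = nm, ce = 0.98,
                                                   cd = 0.6))
  }
  ode_defaults <- list(params = kinetic_params(),
                       strategy = solver_strategy("singleton"),
                       inflate = NULL, memoize = TRUE, model_file = NULL,
                       surrogate = NULL)
  ode <- utils::modifyList(ode_defaults, ode)
  freq_defaults <- list(cellular = 1, intercellular = 1, intracellular = 1)
  frequencies <- utils::modifyList(freq_defaults, frequencies)
  cfg <- structure(
    list(grid = as.integer(grid), compartments = compartments,
         layers = layers, populations = populations, ode = ode,
         frequencies = frequencies, cycles = as.integer(cycles),
         seed = as.integer(seed), deposit_value = deposit_value,
         tdc_deposit_value = if (is.null(tdc_deposit_value)) deposit_value
           else tdc_deposit_value,
         deposit_semantics = deposit_semantics,
         tcell_deposit = tcell_deposit,
         secretion_recurs = isTRUE(secretion_recurs),
         movement = isTRUE(movement),
         movement_first = isTRUE(movement_first),
         dc_tie_break = dc_tie_break, rules = rules,
         death_prob = death_prob),
    class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' @param config a [scenario_config()].
#' @return the config, invisibly; errors name the offending field.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(config$grid) != 2L || any(config$grid < 1L)) {
    stop("config field 'grid' must be two positive cell counts")
  }
  if (config$cycles < 0L) stop("config field 'cycles' must be >= 0")
  layer_names <- vapply(config$layers, `[[`, "", "name")
  if (anyDuplicated(layer_names)) {
    stop("config field 'layers' has duplicate names")
  }
  for (f in names(config$frequencies)) {
    v <- config$frequencies[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop("config field 'frequencies$", f, "' must lie in (0, 1]")
    }
  }
  for (p in config$populations) {
    if (is.null(p$type) || is.null(p$state) || is.null(p$count) ||
        p$count < 0) {
      stop("config field 'populations' entries need type, state, count >= 0")
    }
    if (!p$type %in% .AGENT_TYPES) {
      stop("config field 'populations': unknown agent type ", p$type)
    }
    known <- .AGENT_STATES[[p$type]]
    if (!is.null(known) && !p$state %in% known) {
      stop("config field 'populations': invalid state ", p$state, " for ",
           p$type)
    }
  }
  if (!config$deposit_semantics %in% c("set", "add", "set_max")) {
    stop("config field 'deposit_semantics' must be set, add or set_max")
  }
  if (!identical(config$tcell_deposit, "ode") &&
      (!is.numeric(config$tcell_deposit) || config$tcell_deposit < 0)) {
    stop("config field 'tcell_deposit' must be \"ode\" or a non-negative number")
  }
  for (rule in config$rules) {
    if (!inherits(rule, "transition_rule")) {
      stop("config field 'rules' must contain transition_rule objects")
    }
    trg <- rule$trigger
    if (identical(trg$kind, "local_cytokine") &&
        !trg$layer %in% layer_names) {
      stop("config field 'rules': trigger references unknown layer ",
           trg$layer)
    }
    for (s in rule$secretions) {
      if (!s$layer %in% layer_names) {
        stop("config field 'rules': secretion references unknown layer ",
             s$layer)
      }
    }
  }
  invisible(config)
}

#' @export
print.scenario_config <- function(x, ...) {
  npop <- sum(vapply(x$populations, function(p) as.numeric(p$count), 0))
  cat(sprintf(
    "<scenario_config> grid %dx%d, %d layer(s), %d agent(s), %d cycle(s), seed %d\n",
    x$grid[1L], x$grid[2L], length(x$layers), npop, x$cycles, x$seed))
  cat(sprintf("  solver: %s%s, intracellular frequency %g, model %s\n",
              x$ode$strategy$kind,
              if (x$ode$strategy$kind == "pool")
                paste0("(", x$ode$strategy$pool_size, ")") else "",
              x$frequencies$intracellular,
              if (is.null(x$ode$inflate)) "reduced" else
                paste0("inflated(", paste(x$ode$inflate, collapse = ","), ")")))
  invisible(x)
}

.RM_POPULATIONS <- list(
  list(type = "bacterium", state = "infectious", count = 500L),
  list(type = "bacterium", state = "tolerogenic", count = 500L),
  list(type = "t_cell", state = "naive", count = 2000L),
  list(type = "dendritic_cell", state = "immature", count = 2000L)
)

#' Reference scenario presets
#'
#' Four benchmark scenarios sharing the same biology on a 100 x 100 grid:
#' 500 infectious plus 500 tolerogenic bacteria, 2,000 naive T cells and
#' 2,000 immature dendritic cells placed uniformly at random; six cytokine
#' layers with evaporation 0.98 and diffusion 0.6; all scale frequencies 1.
#' \describe{
#'   \item{RM}{reduced intracellular model, singleton solver.}
#'   \item{BM}{RM with the model inflated to 108 species / 46 reactions /
#'     60 ODEs (cost stand-in for a comprehensive network).}
#'   \item{MS}{RM with one persistent solver instance per T cell.}
#'   \item{DF}{RM with the intracellular frequency lowered from 1 to 0.1
#'     (the ODE layer runs once every 10 cycles).}
#' }
#'
#' @param name `"RM"`, `"BM"`, `"MS"` or `"DF"`.
#' @param seed master seed.
#' @param cycles cycle count.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(name = c("RM", "BM", "MS", "DF"), seed = 1L,
                            cycles = 100L) {
  if (!is.character(name) || !name[1L] %in% c("RM", "BM", "MS", "DF")) {
    stop("unknown preset '", name[1L], "'; valid presets: RM, BM, MS, DF")
  }
  name <- name[1L]
  ode <- switch(name,
    RM = list(),
    BM = list(inflate = c(108L, 46L, 60L)),
    MS = list(strategy = solver_strategy("per_cell")),
    DF = list())
  freq <- if (name == "DF") list(intracellular = 0.1) else list()
  scenario_config(grid = c(100L, 100L), populations = .RM_POPULATIONS,
                  ode = ode, frequencies = freq, cycles = cycles,
                  seed = seed)
}

#' Write a scenario configuration file
#'
#' Structured key-value (YAML) serialization; [read_scenario()] is the
#' inverse. Transition rules and surrogates are not serialized.
#'
#' @param config a [scenario_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  doc <- list(
    grid = as.list(stats::setNames(config$grid, c("width", "height"))),
    layers = config$layers,
    populations = config$populations,
    ode = list(params = unclass(config$ode$params),
               strategy = unclass(config$ode$strategy),
               inflate = config$ode$inflate,
               memoize = config$ode$memoize),
    frequencies = config$frequencies,
    cycles = config$cycles, seed = config$seed,
    deposit_value = config$deposit_value,
    tdc_deposit_value = config$tdc_deposit_value,
    deposit_semantics = config$deposit_semantics,
    tcell_deposit = config$tcell_deposit,
    secretion_recurs = config$secretion_recurs,
    movement = config$movement, movement_first = config$movement_first,
    dc_tie_break = config$dc_tie_break)
  if (!is.null(config$compartments)) {
    doc$compartments <- lapply(config$compartments, unclass)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' @param path YAML file written by [write_scenario()] (or hand-written in
#'   the same schema).
#' @return a [scenario_config()].
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  grid <- if (is.list(doc$grid)) c(doc$grid$width, doc$grid$height) else
    doc$grid
  ode <- doc$ode
  if (!is.null(ode$params)) {
    ode$params <- do.call(kinetic_params,
                          ode$params[names(ode$params) %in%
                                       names(formals(kinetic_params))])
  }
  if (!is.null(ode$strategy)) {
    ode$strategy <- solver_strategy(ode$strategy$kind,
                                    ode$strategy$pool_size)
  }
  if (!is.null(ode$inflate)) ode$inflate <- as.integer(unlist(ode$inflate))
  compartments <- if (!is.null(doc$compartments)) {
    lapply(doc$compartments, function(cp)
      compartment(cp$name, cp$xmin, cp$xmax, cp$ymin, cp$ymax,
                  if (is.null(cp$permeable)) character(0) else
                    unlist(cp$permeable)))
  } else NULL
  args <- list(grid = grid, compartments = compartments,
               layers = doc$layers, populations = doc$populations,
               ode = if (is.null(ode)) list() else ode,
               frequencies = if (is.null(doc$frequencies)) list() else
                 doc$frequencies)
  for (nm in c("cycles", "seed", "deposit_value", "tdc_deposit_value",
               "deposit_semantics", "tcell_deposit", "secretion_recurs",
               "movement", "movement_first", "dc_tie_break")) {
    if (!is.null(doc[[nm]])) args[[nm]] <- doc[[nm]]
  }
  do.call(scenario_config, args)
}
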