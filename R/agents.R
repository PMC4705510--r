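.AGENT_STATES <- list(
  bacterium = c("infectious", "tolerogenic", "dead"),
  dendritic_cell = c("immature", "effector", "tolerogenic", "dead"),
  t_cell = c("naive", "Th1", "Th17", "Treg", "dead")
)

.AGENT_TYPES <- c("bacterium", "dendritic_cell", "t_cell", "epithelial",
                  "macrophage", "neutrophil", "b_cell", "generic")

#' Construct a table of cell agents
#'
#' Agents live in one data frame (one row per agent) with continuous
#' positions; this is the container every engine phase operates on. The
#' built-in types carry fixed state vocabularies (bacteria: infectious /
#' tolerogenic / dead; dendritic cells: immature / effector / tolerogenic /
#' dead; T cells: naive / Th1 / Th17 / Treg / dead); the remaining types
#' are free-form and driven by user-configured [transition_rule()]s.
#'
#' @param type agent type, one of `r paste(.AGENT_TYPES, collapse = ", ")`.
#' @param state initial state label.
#' @param n number of agents.
#' @param x,y continuous positions (recycled to length `n`).
#' @param compartment compartment index.
#' @param speed_max maximum per-cycle displacement, in cell sides.
#' @param chemo_layer optional layer name biasing movement direction.
#' @param chemo_w chemotaxis bias weight in `[0, 1]`.
#' @param id_start first agent id.
#' @return data frame with columns id, type, state, x, y, compartment,
#'   alive, speed_max, chemo_layer, chemo_w.
#' @export
cell_agents <- function(type, state, n, x, y, compartment = 1L,
                        speed_max = 1.0, chemo_layer = NA_character_,
                        chemo_w = 0, id_start = 1L) {
  type <- match.arg(type, .AGENT_TYPES)
  if (!is.null(.AGENT_STATES[[type]]) && !all(state %in% .AGENT_STATES[[type]])) {
    stop("invalid state '", state, "' for agent type ", type)
  }
  stopifnot(n >= 0, chemo_w >= 0, chemo_w <= 1, speed_max >= 0)
  data.frame(
    id = seq.int(id_start, length.out = n),
    type = rep_len(type, n),
    state = rep_len(state, n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    compartment = rep_len(as.integer(compartment), n),
    alive = rep_len(TRUE, n),
    speed_max = rep_len(as.numeric(speed_max), n),
    chemo_layer = rep_len(chemo_layer, n),
    chemo_w = rep_len(as.numeric(chemo_w), n),
    stringsAsFactors = FALSE
  )
}

#' Move agents one cycle
#'
#' Brownian step: each living agent draws a direction uniformly on
#' `[0, 2*pi)` and a speed uniformly on `[0, speed_max]`, so displacement
#' magnitudes are evenly distributed between 0 and one maximum step. With
#' chemotaxis enabled the direction is the renormalized blend
#' `(1 - w) * u + w * g_hat` of a random unit vector `u` and the local
#' layer gradient direction `g_hat`. Candidate positions are reflected off
#' impermeable compartment walls (or the grid boundary) so agents stay in
#' bounds; agents whose type may cross their compartment's boundary are
#' reflected at the grid boundary only and reassigned to the compartment
#' they land in. Dead agents never move.
#'
#' @param agents agent data frame from [cell_agents()].
#' @param space a [grid_space()].
#' @param rng an [rng_streams()] object (uses the `movement` stream).
#' @param layers named list of [value_layer()]s (needed only for
#'   chemotaxis).
#' @return the updated agent data frame.
#' @export
move_agents <- function(agents, space, rng, layers = NULL) {
  n <- nrow(agents)
  if (n == 0L) return(agents)
  act <- agents$alive & agents$speed_max > 0
  draws <- with_stream(rng, "movement", function() runif(2L * n))
  theta <- draws[seq_len(n)] * 2 * pi
  s <- draws[n + seq_len(n)] * agents$speed_max
  ux <- cos(theta)
  uy <- sin(theta)
  chem <- act & !is.na(agents$chemo_layer) & agents$chemo_w > 0
  if (any(chem) && !is.null(layers)) {
    for (i in which(chem)) {
      ly <- layers[[agents$chemo_layer[i]]]
      if (is.null(ly)) stop("chemotaxis layer not found: ",
                            agents$chemo_layer[i])
      g <- gradient_at(ly, c(floor(agents$x[i]), floor(agents$y[i])))
      gn <- sqrt(sum(g^2))
      if (gn > 0) {
        w <- agents$chemo_w[i]
        bx <- (1 - w) * ux[i] + w * g[1L] / gn
        by <- (1 - w) * uy[i] + w * g[2L] / gn
        bn <- sqrt(bx^2 + by^2)
        if (bn > 0) {
          ux[i] <- bx / bn
          uy[i] <- by / bn
        }
      }
    }
  }
  cx <- agents$x + ifelse(act, s * ux, 0)
  cy <- agents$y + ifelse(act, s * uy, 0)
  # reflect per compartment; permeable types bounce off the grid instead
  for (ci in unique(agents$compartment[act])) {
    cp <- space$compartments[[ci]]
    rows <- which(act & agents$compartment == ci)
    perm <- vapply(agents$type[rows], .compartment_permeable_for,
                   logical(1L), comp = cp)
    inside <- rows[!perm]
    if (length(inside) > 0) {
      cx[inside] <- .reflect_into(cx[inside], cp$xmin, cp$xmax)
      cy[inside] <- .reflect_into(cy[inside], cp$ymin, cp$ymax)
    }
    crossers <- rows[perm]
    if (length(crossers) > 0) {
      cx[crossers] <- .reflect_into(cx[crossers], 0, space$width)
      cy[crossers] <- .reflect_into(cy[crossers], 0, space$height)
      agents$compartment[crossers] <-
        compartment_at(space, cx[crossers], cy[crossers])
    }
  }
  agents$x <- cx
  agents$y <- cy
  agents
}

.as_agent <- function(agent) {
  if (is.data.frame(agent)) {
    stopifnot(nrow(agent) == 1L)
    agent <- as.list(agent)
  }
  agent
}

# Contact decision for one immature dendritic cell: effector conversion on
# infectious contact dominates by default when both bacterial subtypes
# co-occupy the cell (tie_break flips this).
.dc_decide <- function(has_infectious, has_tolerogenic,
                       tie_break = "effector") {
  if (!has_infectious && !has_tolerogenic) return(NULL)
  if (has_infectious && has_tolerogenic) {
    return(if (tie_break == "effector") "effector" else "tolerogenic")
  }
  if (has_infectious) "effector" else "tolerogenic"
}

#' Dendritic-cell contact rule
#'
#' An immature dendritic cell sharing its grid cell with an infectious
#' bacterium differentiates into the effector subtype and releases IL-6 and
#' IL-12 at that cell (concentration set to 70, relative units, by
#' default); with a tolerogenic bacterium it becomes tolerogenic and
#' releases TGF-beta. When both bacterial subtypes co-occupy the cell the
#' effector conversion wins by default (`tie_break`). Non-immature
#' dendritic cells are returned unchanged. Layer updates are returned as a
#' deposit table rather than applied, so the engine can buffer them until
#' the end of the update phase.
#'
#' @param dc one agent (single-row data frame or list), a dendritic cell.
#' @param cohabitants agent data frame of the agents sharing `dc`'s grid
#'   cell.
#' @param rng an [rng_streams()] object (uses the `rules` stream); only
#'   consulted when `probability < 1`.
#' @param deposit_value concentration released (relative units).
#' @param semantics deposit semantics (see [deposit()]).
#' @param probability rule firing probability.
#' @param tie_break `"effector"` or `"tolerogenic"`.
#' @return `list(agent = updated agent, deposits = data.frame(layer, x, y,
#'   value, semantics))`.
#' @export
dc_contact_update <- function(dc, cohabitants, rng = NULL,
                              deposit_value = 70, semantics = "set",
                              probability = 1,
                              tie_break = c("effector", "tolerogenic")) {
  tie_break <- match.arg(tie_break)
  dc <- .as_agent(dc)
  empty <- list(agent = dc, deposits = .empty_deposits())
  if (!identical(dc$type, "dendritic_cell") ||
      !identical(dc$state, "immature") || !isTRUE(dc$alive)) {
    return(empty)
  }
  live <- cohabitants$alive & cohabitants$type == "bacterium"
  has_inf <- any(live & cohabitants$state == "infectious")
  has_tol <- any(live & cohabitants$state == "tolerogenic")
  new_state <- .dc_decide(has_inf, has_tol, tie_break)
  if (is.null(new_state)) return(empty)
  if (probability < 1) {
    if (is.null(rng)) stop("rng required for probabilistic rules")
    u <- with_stream(rng, "rules", function() runif(1L))
    if (u >= probability) return(empty)
  }
  cx <- floor(dc$x)
  cy <- floor(dc$y)
  dc$state <- new_state
  deps <- if (new_state == "effector") {
    data.frame(layer = c("IL6", "IL12"), x = cx, y = cy,
               value = deposit_value, semantics = semantics)
  } else {
    data.frame(layer = "TGFb", x = cx, y = cy, value = deposit_value,
               semantics = semantics)
  }
  list(agent = dc, deposits = deps)
}

.empty_deposits <- function() {
  data.frame(layer = character(0), x = integer(0), y = integer(0),
             value = numeric(0), semantics = character(0))
}

.PHENOTYPE_MARKER <- c(Th1 = "IFNg", Th17 = "IL17", Treg = "IL10")

#' Naive T-cell differentiation step
#'
#' A naive CD4+ T cell senses the three input cytokine concentrations in
#' its grid cell, sends them to the intracellular ODE service, classifies
#' the returned output cytokines into a phenotype ([classify_outputs()]),
#' and -- if it differentiates -- releases the matching marker cytokine
#' (Th1 -> IFN-gamma, Th17 -> IL-17, Treg -> IL-10) at its grid cell. By
#' default the released concentration is the ODE-predicted output value;
#' a fixed value can be configured instead. Differentiation is
#' irreversible; non-naive T cells are returned unchanged.
#'
#' @param tc one agent (single-row data frame or list), a T cell.
#' @param local named numeric vector of local concentrations, containing
#'   IL12, TGFb, IL6.
#' @param service an [ode_service()].
#' @param semantics deposit semantics for the released cytokine.
#' @param fixed_value optional fixed release concentration overriding the
#'   ODE-predicted value.
#' @return `list(agent, deposits)` as in [dc_contact_update()].
#' @export
tcell_update <- function(tc, local, service, semantics = "set",
                         fixed_value = NULL) {
  tc <- .as_agent(tc)
  empty <- list(agent = tc, deposits = .empty_deposits())
  if (!identical(tc$type, "t_cell") || !identical(tc$state, "naive") ||
      !isTRUE(tc$alive)) {
    return(empty)
  }
  out <- tryCatch(
    solve_for_cell(service, local[c("IL12", "TGFb", "IL6")],
                   agent_id = tc$id),
    error = function(e) {
      stop("intracellular service failed for agent ", tc$id, ": ",
           conditionMessage(e))
    })
  ph <- classify_outputs(out[.MODEL_OUTPUTS],
                         service$model$params$theta_out)
  if (ph == "naive") return(empty)
  tc$state <- ph
  marker <- .PHENOTYPE_MARKER[[ph]]
  value <- if (is.null(fixed_value)) unname(out[[marker]]) else fixed_value
  list(agent = tc,
       deposits = data.frame(layer = marker, x = floor(tc$x),
                             y = floor(tc$y), value = value,
                             semantics = semantics))
}

#' Declarative state-transition rule
#'
#' Generic stochastic rules for the cell types whose behaviour is not
#' hard-coded (epithelial cells, macrophages, neutrophils, B cells, and
#' any `generic` type): when the trigger holds, the transition fires with
#' probability `p`, changing the state and depositing the listed
#' secretions at the agent's grid cell. Example: an immature macrophage
#' becoming M1 on contact with a Th1 cell.
#'
#' @param agent_type,from_state which agents the rule applies to.
#' @param trigger a [trigger_contact()] or [trigger_cytokine()].
#' @param to_state resulting state.
#' @param probability firing probability in `[0, 1]`.
#' @param secretions list of `list(layer =, value =, semantics =)` entries.
#' @return an object of class `transition_rule`.
#' @export
transition_rule <- function(agent_type, from_state, trigger, to_state,
                            probability = 1, secretions = list()) {
  stopifnot(probability >= 0, probability <= 1)
  for (s in secretions) {
    if (is.null(s$layer) || is.null(s$value) || s$value < 0) {
      stop("each secretion needs a layer and a non-negative value")
    }
  }
  structure(list(agent_type = agent_type, from_state = from_state,
                 trigger = trigger, to_state = to_state,
                 probability = probability, secretions = secretions),
            class = "transition_rule")
}

#' Contact trigger
#'
#' Holds when any living cohabitant of the agent's grid cell has the given
#' type (and state, if specified).
#'
#' @param type cohabitant agent type.
#' @param state optional cohabitant state.
#' @return a trigger specification.
#' @export
trigger_contact <- function(type, state = NULL) {
  list(kind = "contact_with", type = type, state = state)
}

#' Local-cytokine trigger
#'
#' Holds when the named layer's concentration at the agent's grid cell
#' exceeds the threshold. The default threshold defines "positive" for
#' cytokine-driven rules; it is small so that diffusion tails do not count
#' as stimulation.
#'
#' @param layer layer name.
#' @param threshold positivity threshold (relative units).
#' @return a trigger specification.
#' @export
trigger_cytokine <- function(layer, threshold = 1e-3) {
  list(kind = "local_cytokine", layer = layer, threshold = threshold)
}

.trigger_holds <- function(trigger, cohabitants, local) {
  switch(trigger$kind,
    contact_with = {
      hit <- cohabitants$alive & cohabitants$type == trigger$type
      if (!is.null(trigger$state)) hit <- hit & cohabitants$state == trigger$state
      any(hit)
    },
    local_cytokine = {
      v <- local[[trigger$layer]]
      if (is.null(v)) stop("trigger references unknown layer: ",
                           trigger$layer)
      isTRUE(v > trigger$threshold)
    },
    stop("unknown trigger kind: ", trigger$kind)
  )
}

#' Apply generic transition rules to one agent
#'
#' Rules are evaluated in configured order; the first rule matching the
#' agent's type and state whose trigger holds gets a single chance to fire
#' with its probability. Dead agents never transition.
#'
#' @param agent one agent (single-row data frame or list).
#' @param rules list of [transition_rule()]s.
#' @param cohabitants agent data frame sharing the agent's grid cell.
#' @param local named numeric vector of local layer concentrations.
#' @param rng an [rng_streams()] object (uses the `rules` stream).
#' @return `list(agent, deposits)` as in [dc_contact_update()].
#' @export
apply_generic_rules <- function(agent, rules, cohabitants, local, rng) {
  agent <- .as_agent(agent)
  empty <- list(agent = agent, deposits = .empty_deposits())
  if (!isTRUE(agent$alive)) return(empty)
  for (rule in rules) {
    if (!identical(rule$agent_type, agent$type) ||
        !identical(rule$from_state, agent$state)) next
    if (!.trigger_holds(rule$trigger, cohabitants, local)) next
    fires <- if (rule$probability >= 1) TRUE else if (rule$probability <= 0)
      FALSE else with_stream(rng, "rules",
                             function() runif(1L)) < rule$probability
    if (!fires) return(empty)
    agent$state <- rule$to_state
    deps <- .empty_deposits()
    for (s in rule$secretions) {
      deps <- rbind(deps, data.frame(
        layer = s$layer, x = floor(agent$x), y = floor(agent$y),
        value = s$value,
        semantics = if (is.null(s$semantics)) "set" else s$semantics))
    }
    return(list(agent = agent, deposits = deps))
  }
  empty
}
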