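#' Kinetic parameters of the reduced CD4+ T cell differentiation model
#'
#' The published network gives the topology (three cytokine inputs driving
#' three phenotype branches that secrete three marker cytokines) and the
#' qualitative rules; the rate laws and constants here are this package's
#' own calibration, chosen as the simplest linear kinetics that realize the
#' rules and admit closed-form solutions for testing.
#'
#' @param ka1,ka2,ka3 induction rates of the Th1, Th17 and Treg activities
#'   (per time unit per concentration unit).
#' @param kd first-order decay rate of all three phenotype activities.
#' @param ks1,ks2,ks3 secretion rates of IFN-gamma, IL-17 and IL-10.
#' @param Ki IL-6 inhibition constant for Treg induction: the Treg drive is
#'   `ka3 * TGFb / (1 + IL6 / Ki)`.
#' @param bilinear_scale divisor of the bilinear Th17 drive
#'   `ka2 * TGFb * IL6 / bilinear_scale`. The default 10 makes the Th17
#'   branch outcompete the Th1 branch wherever TGF-beta exceeds
#'   `bilinear_scale` alongside IL-6, which is what lets Th17 cells emerge
#'   (and eventually dominate) in tissue regions where effector and
#'   tolerogenic dendritic-cell secretions overlap: IL-6 and IL-12 are
#'   co-released by the same cells, so a scale as large as the release
#'   concentration (70) would make `TGFb*IL6/scale > IL12` unsatisfiable
#'   and suppress Th17 everywhere except the pure-input corner.
#' @param theta_out output-positivity threshold used by
#'   [classify_outputs()].
#' @param horizon default integration time of a per-cell time course.
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(ka1 = 0.01, ka2 = 0.01, ka3 = 0.01, kd = 0.1,
                           ks1 = 0.1, ks2 = 0.1, ks3 = 0.1, Ki = 1,
                           bilinear_scale = 10, theta_out = 1e-3,
                           horizon = 50) {
  p <- list(ka1 = ka1, ka2 = ka2, ka3 = ka3, kd = kd,
            ks1 = ks1, ks2 = ks2, ks3 = ks3, Ki = Ki,
            bilinear_scale = bilinear_scale, theta_out = theta_out,
            horizon = horizon)
  rates <- unlist(p[c("ka1", "ka2", "ka3", "kd", "ks1", "ks2", "ks3",
                      "Ki", "bilinear_scale", "horizon")])
  if (!all(is.finite(rates)) || any(rates <= 0)) {
    stop("all kinetic parameters must be strictly positive and finite")
  }
  if (!is.finite(theta_out) || theta_out < 0) {
    stop("theta_out must be non-negative")
  }
  structure(p, class = "kinetic_params")
}

.LAW_CODES <- c(inert = 0, induction = 1, bilinear_induction = 2,
                inhibited_induction = 3, decay = 4, secretion = 5)

.MODEL_INPUTS <- c("IL12", "TGFb", "IL6")
.MODEL_OUTPUTS <- c("IFNg", "IL17", "IL10")

#' Build the reduced CD4+ T cell differentiation model
#'
#' Nine species (three constant cytokine inputs IL-12, TGF-beta, IL-6;
#' three phenotype activities; three output cytokines IFN-gamma, IL-17,
#' IL-10), nine reactions, six ODEs:
#' \itemize{
#'   \item Th1 branch: `dA_Th1/dt = ka1*IL12 - kd*A_Th1`,
#'     `dIFNg/dt = ks1*A_Th1`
#'   \item Th17 branch: `dA_Th17/dt = ka2*TGFb*IL6/scale - kd*A_Th17`,
#'     `dIL17/dt = ks2*A_Th17`
#'   \item Treg branch: `dA_Treg/dt = ka3*TGFb/(1 + IL6/Ki) - kd*A_Treg`,
#'     `dIL10/dt = ks3*A_Treg`
#' }
#' Inputs are held constant over each solve, so IL-12 alone drives Th1,
#' TGF-beta alone drives Treg, and TGF-beta with IL-6 drives Th17 while
#' suppressing Treg -- the three qualitative differentiation rules.
#'
#' @param params a [kinetic_params()] object.
#' @return an object of class `ode_model`.
#' @export
build_reduced_model <- function(params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  species <- data.frame(
    name = c(.MODEL_INPUTS, "A_Th1", "A_Th17", "A_Treg", .MODEL_OUTPUTS),
    role = c(rep("input", 3L), rep("activity", 3L), rep("output", 3L)),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    name = paste0("r", 1:9),
    law = c("induction", "decay", "bilinear_induction", "decay",
            "inhibited_induction", "decay", "secretion", "secretion",
            "secretion"),
    k = c(params$ka1, params$kd, params$ka2, params$kd, params$ka3,
          params$kd, params$ks1, params$ks2, params$ks3),
    target = c("A_Th1", "A_Th1", "A_Th17", "A_Th17", "A_Treg", "A_Treg",
               "IFNg", "IL17", "IL10"),
    src1 = c("IL12", "", "TGFb", "", "TGFb", "", "A_Th1", "A_Th17",
             "A_Treg"),
    src2 = c("", "", "IL6", "", "IL6", "", "", "", ""),
    extra = c(NA, NA, params$bilinear_scale, NA, params$Ki, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  .new_ode_model(species, reactions, params, params$horizon)
}

# Assemble the internal model object and the numeric term matrix consumed
# by the compiled integrator.
.new_ode_model <- function(species, reactions, params, horizon) {
  dynamic <- species$name[species$role %in% c("activity", "output",
                                              "dummy_dynamic")]
  state_idx <- stats::setNames(seq_along(dynamic) - 1L, dynamic)
  input_idx <- stats::setNames(seq_along(.MODEL_INPUTS) - 1L, .MODEL_INPUTS)
  n <- nrow(reactions)
  terms <- matrix(0, nrow = n, ncol = 6L,
                  dimnames = list(NULL, c("type", "k", "tgt", "s1", "s2",
                                          "extra")))
  for (i in seq_len(n)) {
    law <- reactions$law[i]
    code <- .LAW_CODES[[law]]
    terms[i, "type"] <- code
    terms[i, "k"] <- reactions$k[i]
    terms[i, "tgt"] <- if (code == 0) -1 else state_idx[[reactions$target[i]]]
    terms[i, "s1"] <- switch(law,
      induction = , bilinear_induction = ,
      inhibited_induction = input_idx[[reactions$src1[i]]],
      secretion = state_idx[[reactions$src1[i]]],
      0)
    terms[i, "s2"] <- if (law %in% c("bilinear_induction",
                                     "inhibited_induction")) {
      input_idx[[reactions$src2[i]]]
    } else 0
    terms[i, "extra"] <- if (is.na(reactions$extra[i])) 1 else
      reactions$extra[i]
  }
  structure(
    list(species = species, reactions = reactions, terms = terms,
         state_names = dynamic, params = params, horizon = horizon),
    class = "ode_model"
  )
}

#' Model size metadata
#'
#' @param model an `ode_model`.
#' @return named integer vector `c(species, reactions, odes)`; the reduced
#'   model reports `c(9, 9, 6)`.
#' @export
model_counts <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  c(species = nrow(model$species),
    reactions = length(unique(model$reactions$name)),
    odes = length(model$state_names))
}

#' @export
print.ode_model <- function(x, ...) {
  ct <- model_counts(x)
  cat(sprintf("<ode_model> %d species, %d reactions, %d ODEs; horizon = %g\n",
              ct["species"], ct["reactions"], ct["odes"], x$horizon))
  invisible(x)
}

#' Pad a model with inert species to a target size
#'
#' Emulates the cost profile of a comprehensive kinetic network: extra
#' dynamic species (each a first-order decay starting at zero) enlarge the
#' integrated state vector, and extra constant species and reaction names
#' enlarge the metadata, while the cytokine input-to-output mapping is
#' untouched because the padding is dynamically decoupled from it.
#'
#' @param model a reduced `ode_model`.
#' @param target integer vector `c(n_species, n_reactions, n_odes)`, each at
#'   least the reduced model's count; every extra ODE needs one extra
#'   species and at least one extra reaction name to carry the decays.
#' @return the inflated `ode_model`.
#' @export
inflate_model <- function(model, target) {
  stopifnot(inherits(model, "ode_model"), length(target) == 3L)
  base <- model_counts(model)
  extra_sp <- target[[1L]] - base[["species"]]
  extra_rx <- target[[2L]] - base[["reactions"]]
  extra_ode <- target[[3L]] - base[["odes"]]
  if (extra_sp < 0 || extra_rx < 0 || extra_ode < 0) {
    stop("target counts must be at least the reduced model's (",
         paste(base, collapse = ", "), ")")
  }
  if (extra_sp < extra_ode) {
    stop("infeasible target: each extra ODE needs an extra species")
  }
  if (extra_ode > 0 && extra_rx < 1) {
    stop("infeasible target: extra ODEs need at least one extra reaction")
  }
  if (extra_sp == 0 && extra_rx == 0 && extra_ode == 0) return(model)

  species <- model$species
  reactions <- model$reactions
  kd <- model$params$kd
  if (extra_ode > 0) {
    dyn_names <- sprintf("PAD_D%03d", seq_len(extra_ode))
    species <- rbind(species, data.frame(name = dyn_names,
                                         role = "dummy_dynamic"))
    rx_names <- sprintf("pad_r%03d", seq_len(extra_rx))
    reactions <- rbind(reactions, data.frame(
      name = rx_names[((seq_len(extra_ode) - 1L) %% extra_rx) + 1L],
      law = "decay", k = kd, target = dyn_names, src1 = "", src2 = "",
      extra = NA))
    unused <- setdiff(rx_names, reactions$name)
  } else {
    unused <- sprintf("pad_r%03d", seq_len(extra_rx))
  }
  n_inert <- extra_sp - extra_ode
  if (n_inert > 0) {
    species <- rbind(species, data.frame(
      name = sprintf("PAD_C%03d", seq_len(n_inert)), role = "inert"))
  }
  if (length(unused) > 0) {
    # reaction names with no dynamic content: recorded as inert reactions
    reactions <- rbind(reactions, data.frame(
      name = unused, law = "inert", k = 0, target = "", src1 = "",
      src2 = "", extra = NA))
  }
  out <- .new_ode_model(species, reactions, model$params, model$horizon)
  got <- model_counts(out)
  stopifnot(identical(unname(got), as.integer(unname(target))))
  out
}

#' Integrate one per-cell time course
#'
#' Solves the model's ODE system from an all-zero phenotype/output state
#' with the three cytokine inputs held constant, using the package's
#' embedded adaptive Dormand-Prince 4(5) integrator, and returns the state
#' at the horizon.
#'
#' @param model an `ode_model`.
#' @param inputs numeric vector of the three input concentrations, in the
#'   order IL-12, TGF-beta, IL-6 (names, if present, are checked).
#' @param horizon integration time; defaults to the model's horizon.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return named numeric vector of all dynamic species at the horizon.
#' @export
time_course <- function(model, inputs, horizon = model$horizon,
                        rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(model, "ode_model"))
  inputs <- .check_inputs(inputs)
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be positive")
  y0 <- numeric(length(model$state_names))
  out <- tryCatch(
    .ode_time_course_cpp(model$terms, unname(inputs), y0, horizon, rtol,
                         atol),
    error = function(e) {
      stop("time course failed for inputs (",
           paste(signif(inputs, 6), collapse = ", "), "): ",
           conditionMessage(e))
    })
  stats::setNames(out, model$state_names)
}

.check_inputs <- function(inputs) {
  if (length(inputs) != 3L) stop("inputs must have length 3 (IL12, TGFb, IL6)")
  if (!is.null(names(inputs)) && all(nzchar(names(inputs)))) {
    if (!all(.MODEL_INPUTS %in% names(inputs))) {
      stop("named inputs must be IL12, TGFb, IL6")
    }
    inputs <- inputs[.MODEL_INPUTS]
  }
  inputs <- as.numeric(inputs)
  if (!all(is.finite(inputs)) || any(inputs < 0)) {
    stop("inputs must be finite and non-negative")
  }
  stats::setNames(inputs, .MODEL_INPUTS)
}

#' Decide a phenotype from the output cytokines
#'
#' If no output exceeds the positivity threshold the cell stays naive;
#' otherwise the phenotype of the largest output wins (IFN-gamma for Th1,
#' IL-17 for Th17, IL-10 for Treg), with exact ties broken by the fixed
#' priority Th1 > Th17 > Treg.
#'
#' @param outputs numeric vector of the three outputs in the order
#'   IFN-gamma, IL-17, IL-10 (names, if present, are checked).
#' @param theta_out positivity threshold (relative units).
#' @return one of `"Th1"`, `"Th17"`, `"Treg"`, `"naive"`.
#' @export
classify_outputs <- function(outputs, theta_out = 1e-3) {
  if (length(outputs) != 3L) {
    stop("outputs must have length 3 (IFNg, IL17, IL10)")
  }
  if (!is.null(names(outputs)) && all(nzchar(names(outputs)))) {
    if (!all(.MODEL_OUTPUTS %in% names(outputs))) {
      stop("named outputs must be IFNg, IL17, IL10")
    }
    outputs <- outputs[.MODEL_OUTPUTS]
  }
  outputs <- as.numeric(outputs)
  if (any(!is.finite(outputs)) || any(outputs < 0)) {
    stop("outputs must be finite and non-negative")
  }
  if (max(outputs) <= theta_out) return("naive")
  c("Th1", "Th17", "Treg")[which.max(outputs)]
}
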