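#' Write a declarative model definition file
#'
#' Serializes an [build_reduced_model()]-style model as structured YAML:
#' the species list with roles (input / activity / output / padding), the
#' reaction list (name, rate-law name, rate constant, target, sources and
#' law-specific constants), the integration horizon and the kinetic
#' parameters. The file round-trips through [read_model_definition()].
#'
#' @param model an `ode_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_definition <- function(model, path) {
  stopifnot(inherits(model, "ode_model"))
  rx <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- as.list(model$reactions[i, ])
    r$extra <- if (is.na(r$extra)) NULL else r$extra
    r$src1 <- if (nzchar(r$src1)) r$src1 else NULL
    r$src2 <- if (nzchar(r$src2)) r$src2 else NULL
    r$target <- if (nzchar(r$target)) r$target else NULL
    r
  })
  doc <- list(
    horizon = model$horizon,
    params = unclass(model$params),
    species = lapply(seq_len(nrow(model$species)), function(i)
      as.list(model$species[i, ])),
    reactions = rx
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a declarative model definition file
#'
#' @param path file written by [write_model_definition()] (or hand-written
#'   in the same schema).
#' @return an `ode_model`.
#' @export
read_model_definition <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || is.null(doc$reactions)) {
    stop("model definition must list species and reactions: ", path)
  }
  species <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(name = s$name, role = s$role)))
  reactions <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(name = r$name, law = r$law, k = as.numeric(r$k),
               target = if (is.null(r$target)) "" else r$target,
               src1 = if (is.null(r$src1)) "" else r$src1,
               src2 = if (is.null(r$src2)) "" else r$src2,
               extra = if (is.null(r$extra)) NA_real_ else as.numeric(r$extra))
  }))
  bad <- setdiff(reactions$law, names(.LAW_CODES))
  if (length(bad) > 0) stop("unknown rate law(s): ", paste(bad, collapse = ", "))
  params <- if (is.null(doc$params)) kinetic_params() else
    do.call(kinetic_params, doc$params[names(doc$params) %in%
                                         names(formals(kinetic_params))])
  horizon <- if (is.null(doc$horizon)) params$horizon else doc$horizon
  .new_ode_model(species, reactions, params, horizon)
}

#' Export a model as SBML Level 3
#'
#' Minimal SBML Level 3 Version 1 serialization of the reaction network:
#' one compartment, constant boundary species for the inputs, one global
#' parameter per rate constant, and each reaction's rate law as MathML.
#' Intended for exchange with kinetic-modeling tools; no SBML import is
#' provided.
#'
#' @param model an `ode_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "ode_model"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sp <- vapply(seq_len(nrow(model$species)), function(i) {
    s <- model$species[i, ]
    bc <- if (s$role %in% c("input", "inert")) "true" else "false"
    sprintf(paste0('      <species id="%s" compartment="cell" ',
                   'initialConcentration="0" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="%s" constant="%s"/>'),
            esc(s$name), bc, bc)
  }, "")
  mathml <- function(r) {
    ci <- function(x) sprintf("<ci> %s </ci>", x)
    k <- sprintf("<cn> %.17g </cn>", r$k)
    body <- switch(r$law,
      induction = sprintf("<apply><times/>%s%s</apply>", k, ci(r$src1)),
      bilinear_induction = sprintf(
        "<apply><divide/><apply><times/>%s%s%s</apply><cn> %.17g </cn></apply>",
        k, ci(r$src1), ci(r$src2), r$extra),
      inhibited_induction = sprintf(paste0(
        "<apply><divide/><apply><times/>%s%s</apply>",
        "<apply><plus/><cn> 1 </cn><apply><divide/>%s<cn> %.17g </cn>",
        "</apply></apply></apply>"), k, ci(r$src1), ci(r$src2), r$extra),
      decay = sprintf("<apply><times/>%s%s</apply>", k, ci(r$target)),
      secretion = sprintf("<apply><times/>%s%s</apply>", k, ci(r$src1)),
      "<cn> 0 </cn>")
    sprintf('        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">%s</math></kineticLaw>',
            body)
  }
  rx <- vapply(seq_len(nrow(model$reactions)), function(i) {
    r <- as.list(model$reactions[i, ])
    prod <- if (nzchar(r$target)) sprintf(
      '        <listOfProducts><speciesReference species="%s" stoichiometry="1" constant="true"/></listOfProducts>\n',
      esc(r$target)) else ""
    # decay removes its target instead of producing it
    if (identical(r$law, "decay")) {
      prod <- sprintf(
        '        <listOfReactants><speciesReference species="%s" stoichiometry="1" constant="true"/></listOfReactants>\n',
        esc(r$target))
    }
    sprintf(paste0('      <reaction id="%s_%d" reversible="false">\n%s%s\n',
                   '      </reaction>'),
            esc(r$name), i, prod, mathml(r))
  }, "")
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="cd4_tcell_differentiation_reduced">',
    '    <listOfCompartments>',
    '      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>', sp, '    </listOfSpecies>',
    '    <listOfReactions>', rx, '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  writeLines(doc, path)
  invisible(path)
}
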