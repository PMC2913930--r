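#' Export the model as an SBML Level 3 Version 2 document
#'
#' Writes a reaction-based encoding (not rate rules): four species, the
#' model parameters, and the ten elementary reactions of the stochastic
#' channel decomposition, with kinetic laws that reproduce the
#' deterministic right-hand side exactly (single compartment of size 1,
#' concentrations in nM, time in hours).  Using one reaction set for both
#' the SBML document and the Gillespie channels keeps a single source of
#' truth for both layers.
#'
#' @param params A [p53_parameters()] object; its `variant` decides whether
#'   Mdm2 degradation in the complex releases free p53 (`"release"`) or
#'   destroys the complex outright (`"codegrade"`).
#' @param file Optional path; when given the document is written there.
#' @return An `xml_document` (invisibly when `file` is given).
#' @examples
#' doc <- sbml_export(p53_parameters())
#' @export
sbml_export <- function(params, file = NULL) {
  validate_parameters(params)
  h <- params$hill
  rel_products <- if (params$variant == "release") "p" else character(0)

  reactions <- list(
    list(id = "p53_production", reactants = character(0), products = "p",
         modifiers = character(0), law = "sigma"),
    list(id = "p53_removal", reactants = "p", products = character(0),
         modifiers = character(0), law = "alpha * p"),
    list(id = "complex_formation", reactants = c("p", "m"), products = "c",
         modifiers = character(0), law = "k_f * p * m"),
    list(id = "complex_dissociation", reactants = "c", products = c("p", "m"),
         modifiers = character(0), law = "k_b * c"),
    list(id = "p53_degradation_in_complex", reactants = "c", products = "m",
         modifiers = character(0), law = "delta * c"),
    list(id = "mdm2_degradation_in_complex", reactants = "c",
         products = rel_products, modifiers = character(0), law = "gamma * c"),
    list(id = "mdm2_transcription", reactants = character(0), products = "mm",
         modifiers = "p", law = sprintf("k_t * p^%g", h)),
    list(id = "mrna_decay", reactants = "mm", products = character(0),
         modifiers = character(0), law = "beta * mm"),
    list(id = "translation", reactants = character(0), products = "m",
         modifiers = "mm", law = "k_tl * mm"),
    list(id = "free_mdm2_removal", reactants = "m", products = character(0),
         modifiers = character(0), law = "gamma * m"))

  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "p53_mdm2_feedback_loop",
                               name = "p53-Mdm2 negative feedback loop",
                               timeUnits = "hour")

  units <- xml2::xml_add_child(model, "listOfUnitDefinitions")
  ud <- xml2::xml_add_child(units, "unitDefinition", id = "hour")
  lu <- xml2::xml_add_child(ud, "listOfUnits")
  xml2::xml_add_child(lu, "unit", kind = "second", exponent = "1",
                      scale = "0", multiplier = "3600")
  ud <- xml2::xml_add_child(units, "unitDefinition", id = "nanomolar")
  lu <- xml2::xml_add_child(ud, "listOfUnits")
  xml2::xml_add_child(lu, "unit", kind = "mole", exponent = "1",
                      scale = "-9", multiplier = "1")
  xml2::xml_add_child(lu, "unit", kind = "litre", exponent = "-1",
                      scale = "0", multiplier = "1")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "nucleus", size = "1",
                      spatialDimensions = "3", constant = "true")

  species_names <- c(p = "free nuclear p53", mm = "Mdm2 mRNA",
                     m = "free Mdm2", c = "p53-Mdm2 complex")
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (id in names(species_names))
    xml2::xml_add_child(sp, "species", id = id, name = species_names[[id]],
                        compartment = "nucleus", initialConcentration = "0",
                        substanceUnits = "nanomolar",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in .rate_names)
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = format(params[[nm]], digits = 17),
                        constant = "true")
  xml2::xml_add_child(pars, "parameter", id = "hill",
                      value = format(h, digits = 17), constant = "true")

  rx <- xml2::xml_add_child(model, "listOfReactions")
  for (r in reactions) {
    rn <- xml2::xml_add_child(rx, "reaction", id = r$id, reversible = "false")
    if (length(r$reactants)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in r$reactants)
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    if (length(r$products)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in r$products)
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    if (length(r$modifiers)) {
      lm <- xml2::xml_add_child(rn, "listOfModifiers")
      for (s in r$modifiers)
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = s)
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    .expr_to_mathml(math, str2lang(r$law))
  }

  # serialize and re-parse so the namespace declaration set during node
  # construction is registered on the returned document
  doc <- xml2::read_xml(as.character(doc))
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

# recursive translation of a restricted R expression into content MathML
.expr_to_mathml <- function(parent, e) {
  if (is.name(e)) {
    xml2::xml_add_child(parent, "ci", as.character(e))
  } else if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", format(e, digits = 17))
  } else if (is.call(e)) {
    op <- as.character(e[[1L]])
    tag <- switch(op, `*` = "times", `+` = "plus", `-` = "minus",
                  `/` = "divide", `^` = "power",
                  stop("unsupported operator in kinetic law: ", op,
                       call. = FALSE))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, tag)
    for (arg in as.list(e)[-1L]) .expr_to_mathml(ap, arg)
  } else stop("unsupported kinetic-law expression", call. = FALSE)
  invisible(parent)
}

# recursive parse of content MathML into an R expression
.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- .mathml_children(node)
    if (length(kids) != 1L) stop("malformed <math> element", call. = FALSE)
    return(.mathml_to_expr(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- .mathml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    fun <- switch(op, times = "*", plus = "+", minus = "-",
                  divide = "/", power = "^",
                  stop("unsupported MathML operator: ", op, call. = FALSE))
    args <- lapply(kids[-1L], .mathml_to_expr)
    if (length(args) == 1L && fun == "-")
      return(call("-", args[[1L]]))
    out <- args[[1L]]
    for (a in args[-1L]) out <- call(fun, out, a)
    return(out)
  }
  stop("unsupported MathML node: ", nm, call. = FALSE)
}

.mathml_children <- function(node)
  Filter(function(n) inherits(n, "xml_node"),
         as.list(xml2::xml_children(node)))

#' Import an SBML document of the feedback-loop model
#'
#' Reads parameter values and the reaction network (stoichiometry plus
#' kinetic laws) from an SBML file or document.  Parameters are validated
#' (a non-positive rate is rejected naming the parameter); the model
#' variant is recognised from the products of the reaction degrading
#' complexed Mdm2.
#'
#' @param x Path to an SBML file or an `xml_document`.
#' @return A list with `params` (a [p53_parameters()] object), `reactions`
#'   (list of `id`, `reactants`, `products`, `law` expression) and
#'   `species` (ids in document order).
#' @examples
#' imp <- sbml_import(sbml_export(p53_parameters()))
#' imp$params$k_f
#' @export
sbml_import <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  # namespace-agnostic queries: foreign SBML files may use any prefix
  q <- function(node, ...) {
    path <- paste(vapply(c(...), function(el)
      sprintf("*[local-name()='%s']", el), character(1)), collapse = "/")
    xml2::xml_find_all(node, paste0(".//", path))
  }

  pnodes <- q(doc, "listOfParameters", "parameter")
  vals <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id"))
  missing_p <- setdiff(.rate_names, names(vals))
  if (length(missing_p))
    stop("SBML document lacks parameter(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  for (nm in .rate_names) {
    lo_ok <- if (nm == "sigma") vals[[nm]] >= 0 else vals[[nm]] > 0
    if (!is.finite(vals[[nm]]) || !lo_ok)
      stop(sprintf("invalid value for parameter '%s' in SBML document: %s",
                   nm, vals[[nm]]), call. = FALSE)
  }

  rnodes <- q(doc, "listOfReactions", "reaction")
  reactions <- lapply(rnodes, function(rn) {
    math <- xml2::xml_find_first(
      rn, ".//*[local-name()='kineticLaw']//*[local-name()='math']")
    list(id = xml2::xml_attr(rn, "id"),
         reactants = xml2::xml_attr(q(rn, "listOfReactants",
                                      "speciesReference"), "species"),
         products = xml2::xml_attr(q(rn, "listOfProducts",
                                     "speciesReference"), "species"),
         law = .mathml_to_expr(math))
  })

  # recognise the degradation convention from the gamma*c reaction products
  variant <- "release"
  for (r in reactions) {
    law_txt <- paste(deparse(r$law), collapse = "")
    if (identical(r$reactants, "c") && grepl("gamma", law_txt))
      variant <- if ("p" %in% r$products) "release" else "codegrade"
  }

  params <- p53_parameters(
    sigma = vals[["sigma"]], alpha = vals[["alpha"]], delta = vals[["delta"]],
    k_t = vals[["k_t"]], k_tl = vals[["k_tl"]], beta = vals[["beta"]],
    gamma = vals[["gamma"]], k_b = vals[["k_b"]], k_f = vals[["k_f"]],
    hill = if ("hill" %in% names(vals)) vals[["hill"]] else 2,
    variant = variant)

  snodes <- q(doc, "listOfSpecies", "species")
  list(params = params, reactions = reactions,
       species = xml2::xml_attr(snodes, "id"))
}

#' Evaluate the right-hand side encoded by an imported SBML model
#'
#' Sums stoichiometry times kinetic-law rate over the document's reactions,
#' giving the concentration rates implied by the SBML encoding; used to
#' verify round trips and to reconcile externally supplied documents.
#'
#' @param imported Result of [sbml_import()].
#' @param state A [p53_state()].
#' @return Named rate vector in the order `p`, `mm`, `m`, `c`.
#' @export
sbml_rhs <- function(imported, state) {
  validate_state(state)
  env <- as.list(imported$params[.rate_names])
  env$hill <- imported$params$hill
  env$p <- state[[1L]]; env$mm <- state[[2L]]
  env$m <- state[[3L]]; env$c <- state[[4L]]
  out <- c(p = 0, mm = 0, m = 0, c = 0)
  for (r in imported$reactions) {
    rate <- eval(r$law, env)
    for (s in r$reactants) out[[s]] <- out[[s]] - rate
    for (s in r$products) out[[s]] <- out[[s]] + rate
  }
  out
}

#' Term-level comparison of an SBML model against a parameter set
#'
#' Evaluates each reaction of an imported document and each channel of
#' [build_reactions()] at randomly drawn states and reports, per species,
#' the relative discrepancy between the two right-hand sides, plus
#' reactions that could not be matched to a channel by rate agreement.
#' Intended for reconciling externally deposited model files: differences
#' are reported, never silently overwritten.
#'
#' @param imported Result of [sbml_import()].
#' @param params Reference parameters (defaults to the imported ones).
#' @param n_states Number of random test states.
#' @param seed Seed for the test-state draw.
#' @return A list with `rhs_diff` (data frame: per state and species, both
#'   rates and the relative difference), `max_rel_diff`, and `agrees`
#'   (logical: all relative differences below `1e-9`).
#' @export
sbml_diff <- function(imported, params = imported$params, n_states = 10,
                      seed = 1) {
  validate_parameters(params)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_states)) {
    st <- p53_state(stats::runif(1, 0, 200), stats::runif(1, 0, 50),
                    stats::runif(1, 0, 50), stats::runif(1, 0, 200))
    ours <- .rhs(st, params)
    theirs <- sbml_rhs(imported, st)
    rel <- abs(theirs - ours) / pmax(abs(ours), 1e-8)
    rows[[i]] <- data.frame(state = i, species = names(ours),
                            rate_reference = unname(ours),
                            rate_sbml = unname(theirs),
                            rel_diff = unname(rel))
  }
  df <- do.call(rbind, rows)
  list(rhs_diff = df, max_rel_diff = max(df$rel_diff),
       agrees = max(df$rel_diff) < 1e-9)
}
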