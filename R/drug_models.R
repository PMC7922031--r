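# Drug-dependent parameter sets: physicochemistry, metabolic/elimination
# processes, interaction actions, formulations. Containers are plain lists
# with light S3 classes and strict validation, serializable to/from JSON.

#' Michaelis-Menten metabolic process
#'
#' @param enzyme Enzyme identifier (one of CYP3A4, CYP2C8, CYP2B6, UGT2B7,
#'   EPHX1).
#' @param K_m Michaelis constant, uM. @param k_cat Catalytic constant, 1/min.
#' @param product Optional metabolite drug name receiving the molar flux.
#' @param stoichiometry mol product per mol substrate (default 1).
#' @param label Optional process label.
#' @return A `process` list of kind `"mm"`.
#' @export
process_mm <- function(enzyme, K_m, k_cat, product = NULL,
                       stoichiometry = 1, label = NULL) {
  if (!enzyme %in% ENZYME_NAMES)
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  if (!is.numeric(K_m) || K_m <= 0)
    stop("validation error: 'K_m' must be > 0", call. = FALSE)
  if (!is.numeric(k_cat) || k_cat < 0)
    stop("validation error: 'k_cat' must be >= 0", call. = FALSE)
  structure(list(kind = "mm", enzyme = enzyme, K_m = K_m, k_cat = k_cat,
                 product = product, stoichiometry = stoichiometry,
                 label = label %||% paste0(enzyme, if (!is.null(product))
                   paste0("->", product))),
            class = "process")
}

#' First-order specific-clearance process
#'
#' @inheritParams process_mm
#' @param CL_spec Specific clearance, 1/min.
#' @return A `process` list of kind `"specific_cl"`.
#' @export
process_specific_cl <- function(enzyme, CL_spec, product = NULL,
                                stoichiometry = 1, label = NULL) {
  if (!enzyme %in% ENZYME_NAMES)
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  if (!is.numeric(CL_spec) || CL_spec < 0)
    stop("validation error: 'CL_spec' must be >= 0", call. = FALSE)
  structure(list(kind = "specific_cl", enzyme = enzyme, CL_spec = CL_spec,
                 product = product, stoichiometry = stoichiometry,
                 label = label %||% enzyme),
            class = "process")
}

#' Unspecific hepatic clearance process
#'
#' First-order clearance on the unbound intracellular liver amount, covering
#' metabolic routes not attributed to a named enzyme.
#'
#' @param CL_hep Rate constant, 1/min.
#' @return A `process` list of kind `"hepatic_cl"`.
#' @export
process_hepatic_cl <- function(CL_hep) {
  if (!is.numeric(CL_hep) || CL_hep < 0)
    stop("validation error: 'CL_hep' must be >= 0", call. = FALSE)
  structure(list(kind = "hepatic_cl", CL_hep = CL_hep, label = "CL_hep"),
            class = "process")
}

#' Renal filtration process with a GFR fraction
#'
#' @param gfr_fraction Net filtration fraction in `[0, 1]`.
#' @return A `process` list of kind `"gfr"`.
#' @export
process_gfr <- function(gfr_fraction) {
  if (!is.numeric(gfr_fraction) || gfr_fraction < 0 || gfr_fraction > 1)
    stop("validation error: 'gfr_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(kind = "gfr", gfr_fraction = gfr_fraction, label = "GFR"),
            class = "process")
}

#' Emax enzyme-induction action
#'
#' @param target_enzyme Induced enzyme identifier.
#' @param EC_50 Half-maximal unbound inducer concentration, uM.
#' @param E_max Maximum fold-increase of enzyme synthesis.
#' @return An `interaction` of mode `"induction"`.
#' @export
action_induction <- function(target_enzyme, EC_50, E_max) {
  if (!target_enzyme %in% ENZYME_NAMES)
    stop("unknown enzyme: ", target_enzyme, call. = FALSE)
  if (!is.numeric(EC_50) || EC_50 <= 0)
    stop("validation error: 'EC_50' must be > 0", call. = FALSE)
  if (!is.numeric(E_max) || E_max < 0)
    stop("validation error: 'E_max' must be >= 0", call. = FALSE)
  structure(list(mode = "induction", target_enzyme = target_enzyme,
                 EC_50 = EC_50, E_max = E_max), class = "interaction")
}

#' Competitive inhibition action
#'
#' @param target_enzyme Inhibited enzyme identifier.
#' @param K_i Competitive inhibition constant, uM.
#' @return An `interaction` of mode `"competitive"`.
#' @export
action_competitive_inhibition <- function(target_enzyme, K_i) {
  if (!target_enzyme %in% ENZYME_NAMES)
    stop("unknown enzyme: ", target_enzyme, call. = FALSE)
  if (!is.numeric(K_i) || K_i <= 0)
    stop("validation error: 'K_i' must be > 0", call. = FALSE)
  structure(list(mode = "competitive", target_enzyme = target_enzyme,
                 K_i = K_i), class = "interaction")
}

#' Mechanism-based inhibition action
#'
#' @param target_enzyme Inactivated enzyme identifier.
#' @param K_I Half-maximal inactivation concentration, uM.
#' @param k_inact Maximum inactivation rate constant, 1/min.
#' @return An `interaction` of mode `"mechanism-based"`.
#' @export
action_mbi <- function(target_enzyme, K_I, k_inact) {
  if (!target_enzyme %in% ENZYME_NAMES)
    stop("unknown enzyme: ", target_enzyme, call. = FALSE)
  if (!is.numeric(K_I) || K_I <= 0 || !is.numeric(k_inact) || k_inact <= 0)
    stop("validation error: 'K_I' and 'k_inact' must be > 0", call. = FALSE)
  structure(list(mode = "mechanism-based", target_enzyme = target_enzyme,
                 K_I = K_I, k_inact = k_inact), class = "interaction")
}

#' Formulation specifications
#'
#' `formulation_dissolved()` models solutions/suspensions (dose enters the
#' stomach already in solution). `formulation_weibull()` models solid dosage
#' forms releasing drug with a Weibull profile; `t_50` is the time to 50%
#' released and distinct parameters may be attached for fasted vs fed state.
#'
#' @param name Formulation identifier referenced by dose events.
#' @param t_50 Time to 50% released, min. @param shape Weibull shape (> 0).
#' @param lag Lag time before release starts, min.
#' @param food_state `"fasted"` or `"fed"` (gastric-emptying selector).
#' @return A `formulation` object.
#' @export
formulation_weibull <- function(name, t_50, shape, lag = 0,
                                food_state = "fasted") {
  if (!is.numeric(t_50) || t_50 <= 0 || !is.numeric(shape) || shape <= 0 ||
      !is.numeric(lag) || lag < 0)
    stop("validation error: weibull formulation requires t_50 > 0, ",
         "shape > 0, lag >= 0", call. = FALSE)
  food_state <- match.arg(food_state, c("fasted", "fed"))
  structure(list(name = name, kind = "weibull", t_50 = t_50, shape = shape,
                 lag = lag, food_state = food_state), class = "formulation")
}

#' @rdname formulation_weibull
#' @export
formulation_dissolved <- function(name = "solution",
                                  food_state = "fasted") {
  food_state <- match.arg(food_state, c("fasted", "fed"))
  structure(list(name = name, kind = "dissolved", food_state = food_state),
            class = "formulation")
}

#' Assemble a drug parameter set
#'
#' @param name Drug identifier.
#' @param molecular_weight g/mol. @param lipophilicity log units.
#' @param solubility ug/mL (aqueous/FaHIF). @param fraction_unbound (0, 1].
#' @param intestinal_permeability cm/s.
#' @param partition_method Only `"rodgers_rowland"` is implemented.
#' @param processes List of `process` objects (at most one GFR entry).
#' @param interactions List of `interaction` objects this drug exerts on
#'   enzymes (including its own autoinduction).
#' @param formulations List of `formulation` objects.
#' @return A validated `drug_parameters` object.
#' @export
drug_parameters <- function(name, molecular_weight, lipophilicity,
                            solubility, fraction_unbound,
                            intestinal_permeability,
                            partition_method = "rodgers_rowland",
                            processes = list(), interactions = list(),
                            formulations = list(formulation_dissolved())) {
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("validation error: 'molecular_weight' must be > 0", call. = FALSE)
  if (!is.numeric(fraction_unbound) || fraction_unbound <= 0 ||
      fraction_unbound > 1)
    stop("validation error: 'fraction_unbound' must be in (0, 1]",
         call. = FALSE)
  if (!is.numeric(solubility) || solubility <= 0)
    stop("validation error: 'solubility' must be > 0", call. = FALSE)
  if (!is.numeric(intestinal_permeability) || intestinal_permeability < 0)
    stop("validation error: 'intestinal_permeability' must be >= 0",
         call. = FALSE)
  partition_method <- match.arg(partition_method, "rodgers_rowland")
  if (!all(vapply(processes, inherits, logical(1), "process")))
    stop("validation error: 'processes' must be process objects",
         call. = FALSE)
  if (sum(vapply(processes, function(p) p$kind == "gfr", logical(1))) > 1)
    stop("validation error: at most one GFR-fraction process", call. = FALSE)
  if (!all(vapply(interactions, inherits, logical(1), "interaction")))
    stop("validation error: 'interactions' must be interaction objects",
         call. = FALSE)
  if (!all(vapply(formulations, inherits, logical(1), "formulation")))
    stop("validation error: 'formulations' must be formulation objects",
         call. = FALSE)
  names(formulations) <- vapply(formulations, `[[`, character(1), "name")
  structure(list(name = name, molecular_weight = molecular_weight,
                 lipophilicity = lipophilicity, solubility = solubility,
                 fraction_unbound = fraction_unbound,
                 intestinal_permeability = intestinal_permeability,
                 partition_method = partition_method,
                 processes = processes, interactions = interactions,
                 formulations = formulations),
            class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s | MW %.2f g/mol, logP %.2f, fu %.3f\n",
              x$name, x$molecular_weight, x$lipophilicity,
              x$fraction_unbound))
  cat(sprintf("  %d processes, %d interactions, formulations: %s\n",
              length(x$processes), length(x$interactions),
              paste(names(x$formulations), collapse = ", ")))
  invisible(x)
}

#' Packaged carbamazepine model
#'
#' The parent-drug parameter set: five Michaelis-Menten metabolic pathways
#' (CYP3A4 and CYP2C8 forming the 10,11-epoxide, a second CYP3A4 route to
#' hydroxylated metabolites, CYP2B6, UGT2B7), an unspecific hepatic
#' clearance, renal filtration with GFR fraction 0.03, and Emax
#' autoinduction of CYP3A4, CYP2B6 and EPHX1 (shared EC50 of 20 uM).
#' Formulations: oral solution/suspension plus immediate- and
#' extended-release Weibull fits for fasted and fed state (the Weibull
#' numbers are package defaults fitted to qualitative release behaviour,
#' not literature values).
#'
#' @return A `drug_parameters` object named `"carbamazepine"`.
#' @export
#' @examples
#' cbz <- carbamazepine_model()
#' cbz$fraction_unbound
carbamazepine_model <- function() {
  drug_parameters(
    name = "carbamazepine",
    molecular_weight = 236.27,
    lipophilicity = 2.00,
    solubility = 336,
    fraction_unbound = 0.25,
    intestinal_permeability = 4.3e-4,
    processes = list(
      process_mm("CYP3A4", K_m = 248, k_cat = 0.75,
                 product = "carbamazepine-10,11-epoxide",
                 label = "CYP3A4->CBZ-E"),
      process_mm("CYP2C8", K_m = 757, k_cat = 0.67,
                 product = "carbamazepine-10,11-epoxide",
                 label = "CYP2C8->CBZ-E"),
      process_mm("CYP3A4", K_m = 282, k_cat = 0.20, label = "CYP3A4-OH"),
      process_mm("CYP2B6", K_m = 420, k_cat = 0.43, label = "CYP2B6"),
      process_mm("UGT2B7", K_m = 214, k_cat = kcat_from_vmax(0.79, 82.9),
                 label = "UGT2B7"),
      process_hepatic_cl(0.02),
      process_gfr(0.03)
    ),
    interactions = list(
      action_induction("CYP3A4", EC_50 = 20.0, E_max = 6.00),
      action_induction("CYP2B6", EC_50 = 20.0, E_max = 17.00),
      action_induction("EPHX1", EC_50 = 20.0, E_max = 3.25)
    ),
    formulations = list(
      formulation_dissolved("solution"),
      formulation_weibull("tablet_ir", t_50 = 60, shape = 1.2, lag = 5,
                          food_state = "fasted"),
      formulation_weibull("tablet_ir_fed", t_50 = 40, shape = 1.4, lag = 5,
                          food_state = "fed"),
      formulation_weibull("tablet_xr", t_50 = 300, shape = 1.0, lag = 10,
                          food_state = "fasted"),
      formulation_weibull("tablet_xr_fed", t_50 = 220, shape = 1.1,
                          lag = 10, food_state = "fed")
    )
  )
}

#' Packaged carbamazepine-10,11-epoxide model
#'
#' The metabolite parameter set: first-order EPHX1 clearance
#' (CL_spec 0.01 1/min) and renal filtration with GFR fraction 0.21. The
#' model is independently administrable (oral solution formulation), so the
#' metabolite can be simulated both as a formed metabolite and as a dosed
#' compound.
#'
#' @return A `drug_parameters` object named `"carbamazepine-10,11-epoxide"`.
#' @export
carbamazepine_epoxide_model <- function() {
  drug_parameters(
    name = "carbamazepine-10,11-epoxide",
    molecular_weight = 252.27,
    lipophilicity = 1.00,
    solubility = 1340,
    fraction_unbound = 0.518,
    intestinal_permeability = 5.0e-3,
    processes = list(
      process_specific_cl("EPHX1", CL_spec = 0.01, label = "EPHX1"),
      process_gfr(0.21)
    ),
    formulations = list(formulation_dissolved("solution"))
  )
}

# ---- serialization ---------------------------------------------------------

.drug_schema_keys <- c("name", "molecular_weight", "lipophilicity",
                       "solubility", "fraction_unbound",
                       "intestinal_permeability", "partition_method",
                       "processes", "interactions", "formulations")

#' Serialize a drug model to JSON
#'
#' @param drug A `drug_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(drug, path) {
  stopifnot(inherits(drug, "drug_parameters"))
  x <- unclass(drug)
  x$processes <- lapply(x$processes, unclass)
  x$interactions <- lapply(x$interactions, unclass)
  x$formulations <- unname(lapply(x$formulations, unclass))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load and validate a drug model config
#'
#' Reads a JSON drug config (schema: `name`, physicochemistry scalars,
#' `processes[]`, `interactions[]`, `formulations[]`) and rebuilds a fully
#' validated [drug_parameters()] object. Unknown top-level or entry keys are
#' rejected.
#'
#' @param path Path to a JSON file.
#' @return A `drug_parameters` object.
#' @export
load_drug_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  extra <- setdiff(names(x), .drug_schema_keys)
  if (length(extra))
    stop("schema error: unknown keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  procs <- lapply(x$processes %||% list(), function(p) {
    switch(p$kind %||% stop("schema error: process without 'kind'",
                            call. = FALSE),
      mm = process_mm(p$enzyme, p$K_m, p$k_cat, product = p$product,
                      stoichiometry = p$stoichiometry %||% 1,
                      label = p$label),
      specific_cl = process_specific_cl(p$enzyme, p$CL_spec,
                                        product = p$product,
                                        stoichiometry = p$stoichiometry %||% 1,
                                        label = p$label),
      hepatic_cl = process_hepatic_cl(p$CL_hep),
      gfr = process_gfr(p$gfr_fraction),
      stop("schema error: unknown process kind: ", p$kind, call. = FALSE))
  })
  acts <- lapply(x$interactions %||% list(), function(a) {
    switch(a$mode %||% stop("schema error: interaction without 'mode'",
                            call. = FALSE),
      induction = action_induction(a$target_enzyme, a$EC_50, a$E_max),
      competitive = action_competitive_inhibition(a$target_enzyme, a$K_i),
      `mechanism-based` = action_mbi(a$target_enzyme, a$K_I, a$k_inact),
      stop("schema error: unknown interaction mode: ", a$mode,
           call. = FALSE))
  })
  forms <- lapply(x$formulations %||% list(formulation_dissolved()),
                  function(f) {
    if (inherits(f, "formulation")) return(f)
    switch(f$kind %||% stop("schema error: formulation without 'kind'",
                            call. = FALSE),
      dissolved = formulation_dissolved(f$name %||% "solution",
                                        food_state = f$food_state %||%
                                          "fasted"),
      weibull = formulation_weibull(f$name, f$t_50, f$shape,
                                    lag = f$lag %||% 0,
                                    food_state = f$food_state %||% "fasted"),
      stop("schema error: unknown formulation kind: ", f$kind,
           call. = FALSE))
  })
  drug_parameters(
    name = x$name %||% stop("schema error: 'name' is required",
                            call. = FALSE),
    molecular_weight = x$molecular_weight,
    lipophilicity = x$lipophilicity,
    solubility = x$solubility,
    fraction_unbound = x$fraction_unbound,
    intestinal_permeability = x$intestinal_permeability,
    partition_method = x$partition_method %||% "rodgers_rowland",
    processes = procs, interactions = acts, formulations = forms
  )
}

#' Metabolite drug names referenced by a parent model
#'
#' @param drug A `drug_parameters` object.
#' @return Character vector of metabolite names (parent-metabolite links).
#' @export
metabolite_links <- function(drug) {
  unique(unlist(lapply(drug$processes, function(p) p$product)))
}
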