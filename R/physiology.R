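#' @keywords internal
"_PACKAGE"

# Organ identifiers used throughout the engine. Order is the state-vector
# order: blood pools first, then lung, then the arterially supplied organs.
ORGAN_NAMES <- c(
  "venous_blood", "arterial_blood", "lung", "liver", "kidney", "gut_wall",
  "adipose", "muscle", "skin", "bone", "brain", "heart", "spleen", "rest"
)

ENZYME_NAMES <- c("CYP3A4", "CYP2C8", "CYP2B6", "UGT2B7", "EPHX1")

# Reference adult male (30 y, European, 73 kg, 176 cm): organ volumes [L],
# regional blood flows [L/min] and fractional tissue composition used by the
# partition model (extracellular water, intracellular water, neutral lipid,
# neutral phospholipid). Values are reference-man scale constants; the
# composition fractions follow published tissue-composition tables for the
# neutral-species partition equations. All are config-overridable.
.reference_organ_table <- function() {
  tab <- data.frame(
    name = ORGAN_NAMES,
    volume = c(3.60, 1.70, 0.50, 1.80, 0.31, 1.10, 14.50, 29.00, 3.30,
               10.50, 1.45, 0.33, 0.15, 4.90),
    blood_flow = c(0, 0, 5.600, 0.364, 1.064, 0.896, 0.280, 0.952, 0.280,
                   0.280, 0.672, 0.224, 0.168, 0.420),
    f_ew = c(0.04, 0.04, 0.336, 0.161, 0.273, 0.282, 0.135, 0.118, 0.382,
             0.100, 0.162, 0.320, 0.207, 0.118),
    f_iw = c(0.76, 0.76, 0.446, 0.573, 0.483, 0.475, 0.017, 0.630, 0.291,
             0.346, 0.620, 0.456, 0.579, 0.630),
    f_nl = c(0.0033, 0.0033, 0.022, 0.014, 0.012, 0.0487, 0.846, 0.010,
             0.060, 0.017, 0.039, 0.014, 0.0077, 0.010),
    f_np = c(0.0012, 0.0012, 0.0128, 0.024, 0.0242, 0.0163, 0.0016, 0.0072,
             0.0044, 0.0017, 0.0015, 0.0111, 0.0113, 0.0072),
    fraction_intracellular = c(0, 0, 0.55, 0.70, 0.60, 0.60, 0.15, 0.80,
                               0.45, 0.45, 0.80, 0.60, 0.70, 0.60),
    stringsAsFactors = FALSE
  )
  # residual (proteins, other solids) completes each organ to unit volume
  tab$f_residual <- 1 - (tab$f_ew + tab$f_iw + tab$f_nl + tab$f_np)
  tab
}

# Baseline enzyme tissue concentrations [umol/L] and turnover half-lives.
# The expression pattern (which organs express which enzyme) is the part that
# matters structurally; the absolute levels are declared defaults.
.reference_enzyme_table <- function() {
  list(
    CYP3A4 = list(organ_concentration = c(liver = 4.32, gut_wall = 0.30),
                  half_life_h = c(liver = 36, gut_wall = 23)),
    CYP2C8 = list(organ_concentration = c(liver = 2.56),
                  half_life_h = c(liver = 36)),
    CYP2B6 = list(organ_concentration = c(liver = 1.56),
                  half_life_h = c(liver = 32)),
    UGT2B7 = list(organ_concentration = c(liver = 2.00, kidney = 0.50,
                                          gut_wall = 0.50),
                  half_life_h = c(liver = 36, kidney = 36, gut_wall = 36)),
    EPHX1 = list(organ_concentration = c(liver = 2.00),
                 half_life_h = c(liver = 36))
  )
}

.reference_demographics <- list(
  age = 30, sex = "male", ethnicity = "European",
  body_weight = 73, height = 176, hematocrit = 0.45, gfr_ml_min = 120
)

#' Create a virtual individual
#'
#' Builds the system-dependent half of the PBPK model: organ volumes and
#' blood flows, tissue composition for the partition model, glomerular
#' filtration rate and baseline enzyme expression. Omitted demographics
#' default to the reference individual (30-year-old male European, 73 kg,
#' 176 cm). Supplying a body weight rescales organ volumes linearly and
#' blood flows / GFR allometrically (exponent 0.75).
#'
#' @param age Age in years (0-120).
#' @param sex `"male"` or `"female"` (metadata only; the default physiology
#'   table is not sex-specific).
#' @param ethnicity Free-text metadata, default `"European"`.
#' @param body_weight Body weight in kg (20-200).
#' @param height Height in cm.
#' @param gfr_ml_min Glomerular filtration rate in mL/min.
#' @param hematocrit Hematocrit as a fraction in (0, 1).
#' @param physiology Optional override list (parsed from
#'   [load_physiology_config()]) with elements `organs`, `enzymes`,
#'   `gfr_ml_min`, `hematocrit`.
#' @return An object of class `individual`.
#' @export
#' @examples
#' ind <- create_individual()
#' ind$gfr_ml_min
create_individual <- function(age = NULL, sex = NULL, ethnicity = NULL,
                              body_weight = NULL, height = NULL,
                              gfr_ml_min = NULL, hematocrit = NULL,
                              physiology = NULL) {
  ref <- .reference_demographics
  age <- age %||% ref$age
  sex <- sex %||% ref$sex
  ethnicity <- ethnicity %||% ref$ethnicity
  body_weight <- body_weight %||% ref$body_weight
  height <- height %||% ref$height

  if (!is.numeric(age) || age < 0 || age > 120)
    stop("validation error: 'age' must be in [0, 120] years", call. = FALSE)
  if (!is.numeric(body_weight) || body_weight < 20 || body_weight > 200)
    stop("validation error: 'body_weight' must be in [20, 200] kg",
         call. = FALSE)
  if (!is.numeric(height) || height <= 0)
    stop("validation error: 'height' must be positive", call. = FALSE)

  organs <- .reference_organ_table()
  enzymes <- .reference_enzyme_table()
  gfr <- gfr_ml_min %||% ref$gfr_ml_min
  hct <- hematocrit %||% ref$hematocrit

  if (!is.null(physiology)) {
    if (!is.null(physiology$organs)) {
      for (ov in physiology$organs) {
        i <- match(ov$name, organs$name)
        if (is.na(i))
          stop("unknown organ in physiology override: ", ov$name,
               call. = FALSE)
        for (fld in intersect(names(ov), setdiff(names(organs), "name")))
          organs[[fld]][i] <- ov[[fld]]
      }
      organs$f_residual <-
        1 - (organs$f_ew + organs$f_iw + organs$f_nl + organs$f_np)
    }
    if (!is.null(physiology$enzymes)) {
      for (ev in physiology$enzymes) {
        if (!ev$name %in% ENZYME_NAMES)
          stop("unknown enzyme in physiology override: ", ev$name,
               call. = FALSE)
        if (!is.null(ev$organ_concentration))
          enzymes[[ev$name]]$organ_concentration <-
            unlist(ev$organ_concentration)
        if (!is.null(ev$half_life_h))
          enzymes[[ev$name]]$half_life_h <- unlist(ev$half_life_h)
      }
    }
    gfr <- physiology$gfr_ml_min %||% gfr
    hct <- physiology$hematocrit %||% hct
  }

  if (gfr <= 0)
    stop("validation error: 'gfr_ml_min' must be positive", call. = FALSE)
  if (hct <= 0 || hct >= 1)
    stop("validation error: 'hematocrit' must be in (0, 1)", call. = FALSE)

  ind <- structure(
    list(age = age, sex = sex, ethnicity = ethnicity,
         body_weight = ref$body_weight, height = height,
         hematocrit = hct, gfr_ml_min = gfr,
         organs = organs, enzymes = enzymes),
    class = "individual"
  )
  if (!isTRUE(all.equal(body_weight, ref$body_weight)))
    ind <- scale_physiology(ind, weight = body_weight, height = height)
  ind
}

#' Allometric rescaling of a virtual individual
#'
#' Organ volumes scale linearly with the body-weight ratio; blood flows and
#' GFR scale with the 0.75 power (cardiac-output allometry). Composition
#' fractions are intensive and unchanged.
#'
#' @param reference An `individual` to rescale.
#' @param weight Target body weight, kg.
#' @param height Target height, cm (metadata; does not alter organs).
#' @return A rescaled `individual`.
#' @export
scale_physiology <- function(reference, weight, height = reference$height) {
  stopifnot(inherits(reference, "individual"))
  if (!is.numeric(weight) || weight <= 0)
    stop("validation error: 'weight' must be positive", call. = FALSE)
  if (!is.numeric(height) || height <= 0)
    stop("validation error: 'height' must be positive", call. = FALSE)
  r <- weight / reference$body_weight
  out <- reference
  out$body_weight <- weight
  out$height <- height
  out$organs$volume <- reference$organs$volume * r
  out$organs$blood_flow <- reference$organs$blood_flow * r^0.75
  out$gfr_ml_min <- reference$gfr_ml_min * r^0.75
  out
}

#' Load a physiology override file
#'
#' JSON file with optional keys `organs` (array of objects keyed by organ
#' `name`), `enzymes` (array keyed by enzyme `name`), `gfr_ml_min`,
#' `hematocrit`. Returns the parsed list for the `physiology` argument of
#' [create_individual()].
#'
#' @param path Path to a JSON file.
#' @export
load_physiology_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf(
    "<individual> %s, %g y, %s, %.1f kg, %.0f cm | GFR %.0f mL/min, Hct %.2f\n",
    x$sex, x$age, x$ethnicity, x$body_weight, x$height, x$gfr_ml_min,
    x$hematocrit))
  cat(sprintf("  %d organs, cardiac output %.2f L/min, enzymes: %s\n",
              nrow(x$organs), cardiac_output(x),
              paste(names(x$enzymes), collapse = ", ")))
  invisible(x)
}

#' Cardiac output of an individual
#'
#' Sum of the regional arterial blood flows (equivalently, the lung flow).
#'
#' @param individual An `individual`.
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(individual) {
  org <- individual$organs
  sum(org$blood_flow[!org$name %in% c("venous_blood", "arterial_blood",
                                      "lung")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
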