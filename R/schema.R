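#' Define a categorical feature schema for an arrest registry
#'
#' A `feature_schema` fixes the ordered vocabulary of a registry: every
#' model input is categorical, each with a closed, ordered level set.
#' The schema also marks which features feed the coronary-angiography
#' (CA) decision model and which feed the neurologic-outcome (survival)
#' model.  The survival input set is always the decision set plus the CA
#' feature itself — the CA decision is the only new information available
#' to the outcome model.
#'
#' @param features named list; each element is a character vector of >= 2
#'   distinct level strings, in a fixed order.  Names are feature names.
#' @param decision_inputs character vector of feature names used by the
#'   decision model.
#' @param ca_feature name of the CA feature (must be in `features`, must
#'   not be in `decision_inputs`).
#' @param hospital_field,outcome_field column names carrying the receiving
#'   hospital id and the binarized CPC outcome class (0 = CPC 1/2
#'   functional, 1 = CPC 3/4/5).  Neither is a model input.
#' @return an object of class `feature_schema`.
#' @export
feature_schema <- function(features, decision_inputs, ca_feature,
                           hospital_field = "hospital_id",
                           outcome_field = "outcome_class") {
  stopifnot(is.list(features), length(features) >= 1)
  fnames <- names(features)
  if (is.null(fnames) || anyDuplicated(fnames) || any(fnames == ""))
    stop("features must be a uniquely named list")
  for (f in fnames) {
    lv <- features[[f]]
    if (!is.character(lv) || length(lv) < 2 || anyDuplicated(lv))
      stop(sprintf("feature '%s' needs >= 2 distinct character levels", f))
  }
  if (!all(decision_inputs %in% fnames))
    stop("decision_inputs must all be declared features")
  if (!ca_feature %in% fnames)
    stop("ca_feature must be a declared feature")
  if (ca_feature %in% decision_inputs)
    stop("the CA feature cannot be a decision-model input")
  if (hospital_field %in% fnames || outcome_field %in% fnames)
    stop("hospital_field and outcome_field must not be model features")
  structure(list(
    features = features,
    decision_inputs = as.character(decision_inputs),
    survival_inputs = c(as.character(decision_inputs), ca_feature),
    ca_feature = ca_feature,
    hospital_field = hospital_field,
    outcome_field = outcome_field
  ), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema>\n")
  cat(sprintf("  %d features (%d decision inputs + CA '%s')\n",
              length(x$features), length(x$decision_inputs), x$ca_feature))
  cat(sprintf("  hospital field: %s, outcome field: %s\n",
              x$hospital_field, x$outcome_field))
  invisible(x)
}

# Input-feature names for one of the two modeling tasks.
schema_inputs <- function(schema, input_set = c("decision", "survival")) {
  input_set <- match.arg(input_set)
  if (input_set == "decision") schema$decision_inputs else schema$survival_inputs
}

#' Default synthetic registry schema
#'
#' Twenty-three categorical decision-model inputs modeled on the fields an
#' OHCA registry records about demographics, arrest circumstances and
#' prehospital care, plus a binary coronary-angiography feature used only
#' by the outcome model.  The real registry's exact feature list is not
#' public, so these are documented stand-ins with realistic vocabularies;
#' the CPR-initiation feature carries the canonical three-level vocabulary
#' (Lay Person / First Responder / EMS Personnel).
#'
#' @return a `feature_schema` with 23 decision inputs and 24 survival inputs.
#' @export
default_schema <- function() {
  features <- list(
    age_group          = c("18-34", "35-49", "50-64", "65-79", "80+"),
    sex                = c("Male", "Female", "Unknown"),
    race_ethnicity     = c("White", "Black", "Hispanic", "Asian", "Other"),
    arrest_location    = c("Home", "Public", "Healthcare Facility"),
    witnessed_status   = c("Unwitnessed", "Bystander Witnessed", "EMS Witnessed"),
    cpr_initiation     = c("Lay Person", "First Responder", "EMS Personnel"),
    bystander_cpr      = c("None", "Compression Only", "Conventional"),
    aed_use            = c("No AED", "Bystander AED", "Responder AED"),
    initial_rhythm     = c("VF/VT", "PEA", "Asystole", "Unknown Shockable",
                           "Unknown Unshockable"),
    presumed_etiology  = c("Cardiac", "Respiratory", "Overdose", "Other"),
    response_time_band = c("<4 min", "4-8 min", "8-12 min", ">12 min"),
    defibrillation     = c("None", "Single Shock", "Multiple Shocks"),
    airway_management  = c("None", "Bag Valve Mask", "Supraglottic",
                           "Endotracheal"),
    epinephrine_doses  = c("0", "1-2", "3+"),
    antiarrhythmic     = c("None", "Amiodarone", "Lidocaine"),
    cpr_mode           = c("Manual", "Mechanical", "Mixed"),
    rosc_location      = c("Field", "En Route", "Emergency Department"),
    prehospital_ecg    = c("Not Obtained", "Normal", "Abnormal"),
    ttm_initiated      = c("None", "Prehospital", "Hospital"),
    arrest_time_of_day = c("Night", "Morning", "Afternoon", "Evening"),
    day_type           = c("Weekday", "Weekend", "Holiday"),
    transport_interval = c("<10 min", "10-20 min", ">20 min"),
    arrival_status     = c("Alert", "Responsive to Pain", "Unresponsive"),
    coronary_angiography = c("0", "1")
  )
  feature_schema(
    features = features,
    decision_inputs = setdiff(names(features), "coronary_angiography"),
    ca_feature = "coronary_angiography"
  )
}

#' Write / read a schema as JSON
#'
#' The JSON layout keeps feature and level order, so a schema round-trips
#' exactly; files are human-auditable.
#'
#' @param schema a `feature_schema`.
#' @param path file path.
#' @return `read_schema` returns a `feature_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  obj <- list(
    features = schema$features,
    decision_inputs = schema$decision_inputs,
    ca_feature = schema$ca_feature,
    hospital_field = schema$hospital_field,
    outcome_field = schema$outcome_field
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_schema(
    features = as.list(obj$features),
    decision_inputs = obj$decision_inputs,
    ca_feature = obj$ca_feature,
    hospital_field = obj$hospital_field,
    outcome_field = obj$outcome_field
  )
}
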