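#' Read and write simulation configurations as YAML
#'
#' A `clinic_config` round-trips through a plain YAML file so that scenario
#' presets and calibrated parameters can be shipped and version-controlled.
#' `read_clinic_config()` validates the result before returning it. The
#' packaged baseline (calibrated to the audited standard-care overspill
#' count) is available via
#' `read_clinic_config(clinicflow_example("baseline_config.yaml"))`.
#'
#' @param path File path.
#' @param config A [clinic_config()].
#' @return `read_clinic_config()`: a validated `clinic_config`;
#'   `write_clinic_config()`: `path`, invisibly.
#' @export
read_clinic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tri <- raw$triage
  pw <- raw$pathway
  du <- raw$durations
  ro <- raw$roster_full
  roa <- raw$roster_addon
  cfg <- clinic_config(
    triage = do.call(triage_config, tri),
    disable_sessions = as.character(raw$disable_sessions %||% character()),
    annual_volume = raw$annual_volume,
    demand_multiplier = raw$demand_multiplier %||% 1,
    prevalence = raw$prevalence,
    pathway = pathway_table(
      probs_noncancer = as.numeric(pw$probs_noncancer),
      probs_cancer = as.numeric(pw$probs_cancer),
      mammogram_first = pw$mammogram_first,
      discharge_noncancer = pw$discharge_noncancer
    ),
    durations = duration_model(
      initial_assessment = du$initial_assessment,
      mammogram = du$mammogram, ultrasound = du$ultrasound,
      biopsy = as.numeric(du$biopsy),
      biopsy_long_prob = du$biopsy_long_prob %||% 0.5,
      dispersion = du$dispersion, prep = du$prep
    ),
    rule = do.call(booking_rule, raw$booking_rule),
    rooms = do.call(clinic_rooms, raw$rooms),
    roster_full = do.call(clinic_roster, c(
      as.list(ro$counts),
      list(availability = unlist(ro$availability))
    )),
    roster_addon = do.call(clinic_roster, c(
      as.list(roa$counts),
      list(availability = unlist(roa$availability))
    )),
    warmup_weeks = raw$warmup_weeks %||% 12,
    collection_weeks = raw$collection_weeks %||% 52,
    arrival_convention = raw$arrival_convention %||% "poisson"
  )
  cfg
}

#' @rdname read_clinic_config
#' @export
write_clinic_config <- function(config, path) {
  validate_clinic_config(config)
  roster_block <- function(r) {
    list(
      counts = as.list(r$counts), availability = as.list(r$availability)
    )
  }
  out <- list(
    triage = unclass(config$triage),
    disable_sessions = as.list(config$disable_sessions),
    annual_volume = config$annual_volume,
    demand_multiplier = config$demand_multiplier,
    prevalence = config$prevalence,
    pathway = list(
      probs_noncancer = config$pathway$p_noncancer,
      probs_cancer = config$pathway$p_cancer,
      mammogram_first = attr(config$pathway, "mammogram_first"),
      discharge_noncancer = attr(config$pathway, "discharge_noncancer")
    ),
    durations = unclass(config$durations),
    booking_rule = unclass(config$rule),
    rooms = as.list(config$rooms),
    roster_full = roster_block(config$roster_full),
    roster_addon = roster_block(config$roster_addon),
    warmup_weeks = config$warmup_weeks,
    collection_weeks = config$collection_weeks,
    arrival_convention = config$arrival_convention
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; `NULL` lists them.
#' @return A file path, or a character vector of available files.
#' @export
clinicflow_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "clinicflow")))
  }
  path <- system.file("extdata", file, package = "clinicflow")
  if (path == "") abort(paste0("No packaged file named `", file, "`."))
  path
}
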