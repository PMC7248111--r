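## Shared I/O: the drying-record CSV schema, the YAML run configuration,
## and schema-versioned JSON reports with full provenance.

## CSV schema (one row per observation). Field units are the lab's
## (g, mm^2, s); everything is converted to SI on read.
.csvColumns <- c("time_s", "mass_g", "total_area_mm2", "wet_area_mm2")

## Recognised configuration keys, by section.
.configKeys <- list(
  constants = c("boltzmann", "gas_constant", "gravity"),
  fluid = c("density", "surface_tension", "molar_mass",
            "molecular_diameter", "haematocrit_percent",
            "residual_mass_fraction"),
  environment = c("temperature_C", "rh_percent", "pressure_Pa"),
  model = c("d_blood", "mass_area_alpha", "mass_area_beta"),
  surface = c("label", "height_mean_mm", "height_sd_mm"),
  metadata = c("surface", "hct_percent", "initial_mass_g",
               "temperature_C", "rh_percent", "pressure_Pa"),
  seed = NULL, verbosity = NULL)

#' Read a drying-record CSV
#'
#' Reads the package's observation schema: columns `time_s` and at
#' least one of `mass_g`, `total_area_mm2`, `wet_area_mm2`, with an
#' optional YAML metadata sidecar (same path with extension `.yaml`)
#' declaring `temperature_C`, `rh_percent`, `pressure_Pa`, `surface`,
#' `hct_percent` and `initial_mass_g`. All quantities are converted to
#' SI. Non-physical mass increases beyond the noise level are flagged
#' (`"mass-increase"`), not rejected.
#'
#' @param path CSV file path.
#' @param metaPath optional metadata YAML path; default replaces the
#'   CSV extension with `.yaml` and is used only if the file exists.
#' @return a [DryingRecord-class].
#' @export
readDryingCsv <- function(path, metaPath = NULL) {
  if (!file.size(path) > 0) stop("empty file: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = TRUE),
                 error = function(e)
                   stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (!nrow(df)) stop("no observations in ", path)
  if (!"time_s" %in% names(df))
    stop("missing required column 'time_s' in ", path)
  unknown <- setdiff(names(df), .csvColumns)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  if (anyNA(df$time_s) || !is.numeric(df$time_s))
    stop("column 'time_s' must be numeric without missing values")
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("time_s not strictly increasing at row ", bad[1] + 1L)
  if (is.null(metaPath)) {
    cand <- sub("\\.[^.]*$", ".yaml", path)
    metaPath <- if (file.exists(cand)) cand else NA
  }
  meta <- list()
  if (!is.na(metaPath) && !is.null(metaPath)) {
    meta <- yaml::read_yaml(metaPath)
    unknownMeta <- setdiff(names(meta), .configKeys$metadata)
    if (length(unknownMeta))
      stop("unknown metadata key(s): ", paste(unknownMeta, collapse = ", "))
  }
  env <- ambientConditions(
    temperatureC = meta$temperature_C %||% 23,
    rhPercent = meta$rh_percent %||% 20,
    pressurePa = meta$pressure_Pa %||% 101325)
  flags <- character()
  masses <- numeric()
  if ("mass_g" %in% names(df)) {
    masses <- df$mass_g * 1e-3
    inc <- diff(masses)
    if (any(inc > 0.02 * masses[1]))
      flags <- c(flags, "mass-increase")
  }
  im <- if (!is.null(meta$initial_mass_g)) meta$initial_mass_g * 1e-3
        else numeric()
  dryingRecord(
    times = df$time_s, masses = masses,
    totalAreas = if ("total_area_mm2" %in% names(df))
      df$total_area_mm2 * 1e-6 else numeric(),
    wetAreas = if ("wet_area_mm2" %in% names(df))
      df$wet_area_mm2 * 1e-6 else numeric(),
    environment = env, initialMass = im,
    surfaceLabel = meta$surface %||% "unknown", qualityFlags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a drying record as CSV (+ YAML metadata sidecar)
#'
#' Inverse of [readDryingCsv()]: field units (g, mm^2) in the CSV, the
#' ambient conditions and pool metadata in a YAML sidecar.
#'
#' @param record a [DryingRecord-class].
#' @param path output CSV path.
#' @param metaPath output YAML path (default: CSV path with `.yaml`).
#' @return `path`, invisibly.
#' @export
writeDryingCsv <- function(record, path,
                           metaPath = sub("\\.[^.]*$", ".yaml", path)) {
  df <- data.frame(time_s = record@times)
  if (length(record@masses)) df$mass_g <- record@masses * 1e3
  if (length(record@totalAreas))
    df$total_area_mm2 <- record@totalAreas * 1e6
  if (length(record@wetAreas)) df$wet_area_mm2 <- record@wetAreas * 1e6
  utils::write.csv(format(df, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(
    temperature_C = record@environment@temperature - 273.15,
    rh_percent = 100 * record@environment@relativeHumidity,
    pressure_Pa = record@environment@pressure,
    surface = record@surfaceLabel)
  if (length(record@initialMass))
    meta$initial_mass_g <- record@initialMass * 1e3
  yaml::write_yaml(meta, metaPath)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML configuration overriding any default constant, fluid property,
#' environment, model calibration or surface prior. Unknown keys are
#' rejected (a misspelled override must not pass silently). The parsed
#' configuration round-trips losslessly through [writeRunConfig()].
#'
#' @param path YAML file path.
#' @return named list of configuration sections.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(.configKeys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(cfg), names(.configKeys))) {
    keys <- .configKeys[[sec]]
    if (is.null(keys)) next
    bad <- setdiff(names(cfg[[sec]]), keys)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

#' Write a run configuration
#'
#' @param config list as returned by [readRunConfig()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' Applies configuration overrides on top of the package defaults and
#' returns ready-to-use objects.
#'
#' @param config list (possibly empty) as from [readRunConfig()].
#' @return list with `constants`, `fluid`, `environment`, `model`,
#'   `surface` and `seed`.
#' @export
configToObjects <- function(config = list()) {
  cs <- config$constants %||% list()
  fl <- config$fluid %||% list()
  en <- config$environment %||% list()
  mo <- config$model %||% list()
  su <- config$surface %||% list()
  list(
    constants = physicalConstants(
      boltzmann = cs$boltzmann %||% 1.380649e-23,
      gasConstant = cs$gas_constant %||% 8.314462618,
      gravity = cs$gravity %||% 9.80665),
    fluid = bloodProperties(
      density = fl$density %||% 1060,
      surfaceTension = fl$surface_tension %||% 0.058,
      molarMass = fl$molar_mass %||% 0.018015,
      molecularDiameter = fl$molecular_diameter %||% 2.75e-10,
      haematocrit = (fl$haematocrit_percent %||% 42) / 100,
      residualMassFraction = fl$residual_mass_fraction %||% 0.23),
    environment = ambientConditions(
      temperatureC = en$temperature_C %||% 23,
      rhPercent = en$rh_percent %||% 20,
      pressurePa = en$pressure_Pa %||% 101325),
    model = calibratedModel(
      dBlood = mo$d_blood %||% 1e-9,
      massAreaAlpha = mo$mass_area_alpha %||% 0.78,
      massAreaBeta = mo$mass_area_beta %||% 0.16),
    surface = surfacePrior(
      surfaceLabel = su$label %||% "tile",
      heightMean = (su$height_mean_mm %||% 1.44) * 1e-3,
      heightSd = (su$height_sd_mm %||% 0.19) * 1e-3),
    seed = config$seed %||% 1L)
}

#' Schema-versioned JSON report
#'
#' Serialises an analysis result together with every input, constant
#' and flag that produced it (forensic provenance requirement). An
#' [AgeEstimate-class] serialises its complete `inputsSnapshot`;
#' fits and plateau estimates serialise their parameters and
#' diagnostics. `jsonlite::fromJSON` on the written file restores the
#' report list.
#'
#' @param result an [AgeEstimate-class], [MassAreaFit-class],
#'   [ShapeLinearFit-class], plateau list, or any named list.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the report list, invisibly (or the JSON string if
#'   `path = NULL`).
#' @export
reportJson <- function(result, path = NULL) {
  body <- if (is(result, "AgeEstimate")) {
    list(type = "age_estimate",
         elapsed_time_s = result@elapsedTime,
         elapsed_time_hms = formatHMS(result@elapsedTime),
         interval_s = result@interval,
         coverage = result@coverage,
         method = result@method,
         inputs = result@inputsSnapshot)
  } else if (is(result, "MassAreaFit")) {
    list(type = "mass_area_fit", alpha = result@alpha,
         beta = result@beta, residual_norm = result@residualNorm)
  } else if (is(result, "ShapeLinearFit")) {
    list(type = "shape_linear_fit", slope = result@slope,
         intercept = result@intercept, r_squared = result@rSquared)
  } else if (is.list(result)) {
    result
  } else stop("cannot serialise object of class ", class(result)[1])
  report <- c(list(schema = "poolage/report/v1"), body)
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(report)
}
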