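# File I/O: measurement CSVs, cohort ground-truth JSON, run configuration.

CSV_HEADER <- c("vessel_id", "replicate", "Q_ml_min", "Pa_mmHg", "Pd_mmHg")

#' Read a pressure-flow measurements CSV
#'
#' Expects the schema `vessel_id,replicate,Q_ml_min,Pa_mmHg,Pd_mmHg`. Rows
#' with non-numeric cells are reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A [pf_dataset()] when the file holds one vessel, otherwise a
#'   named list of `pf_dataset` objects (one per `vessel_id`, in order of
#'   first appearance).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("parse error: empty file: ", path, call. = FALSE)
  miss <- setdiff(CSV_HEADER, names(raw))
  if (length(miss) > 0)
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  num <- raw[c("replicate", "Q_ml_min", "Pa_mmHg", "Pd_mmHg")]
  conv <- lapply(num, function(col) suppressWarnings(as.numeric(col)))
  bad <- Reduce(`|`, lapply(conv, is.na))
  if (any(bad))
    stop("parse error: non-numeric cell(s) at data line(s) ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
         " of ", path, call. = FALSE)
  df <- data.frame(vessel_id = raw$vessel_id,
                   replicate = conv$replicate,
                   q = conv$Q_ml_min, p_a = conv$Pa_mmHg, p_d = conv$Pd_mmHg)
  ids <- unique(df$vessel_id)
  if (length(ids) == 1L) return(pf_dataset(df))
  out <- lapply(ids, function(id) pf_dataset(df[df$vessel_id == id, ]))
  names(out) <- ids
  out
}

#' Write a pressure-flow dataset to CSV
#'
#' Inverse of [read_measurements()]; writes the schema
#' `vessel_id,replicate,Q_ml_min,Pa_mmHg,Pd_mmHg`.
#'
#' @param dataset A [pf_dataset()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path) {
  if (inherits(dataset, "pf_dataset")) dataset <- list(dataset)
  df <- do.call(rbind, lapply(dataset, as.data.frame))
  out <- data.frame(vessel_id = df$vessel_id, replicate = df$replicate,
                    Q_ml_min = df$q, Pa_mmHg = df$p_a, Pd_mmHg = df$p_d)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cohort ground truth as JSON
#'
#' One entry per vessel: geometry, dP-Q coefficients, aortic pressure, the
#' vessel's true CFR line and true FFR, plus a `meta` block with the seed and
#' config hash so any report is regenerable.
#'
#' @param cohort List of [synthetic_vessel()] objects.
#' @param path Output JSON path.
#' @param meta Optional named list merged into the `meta` block.
#' @return `path`, invisibly.
#' @export
write_cohort_truth <- function(cohort, path, meta = list()) {
  vessels <- lapply(cohort, function(v) list(
    id = v$id,
    geometry = list(reference_diameter_mm = v$geometry$reference_diameter_mm,
                    percent_stenosis = v$geometry$percent_stenosis,
                    stenosis_length_mm = v$geometry$stenosis_length_mm),
    coefficients = list(a = v$coefficients$a, b = v$coefficients$b),
    p_a = v$p_a,
    cfr_line = list(slope = v$true_cfr_line$slope,
                    p_zf = v$true_cfr_line$p_zf,
                    q_rest = v$true_cfr_line$q_rest),
    true_ffr = v$true_ffr))
  names(vessels) <- vapply(cohort, `[[`, character(1), "id")
  jsonlite::write_json(list(meta = meta, vessels = vessels), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read cohort ground truth written by [write_cohort_truth()]
#'
#' @param path JSON path.
#' @return A data.frame with one row per vessel: `vessel_id`, geometry
#'   columns, `a`, `b`, `p_a`, `slope`, `p_zf`, `q_rest`, `true_ffr`.
#' @export
read_cohort_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$vessels, function(v) data.frame(
    vessel_id = v$id,
    reference_diameter_mm = v$geometry$reference_diameter_mm,
    percent_stenosis = v$geometry$percent_stenosis,
    stenosis_length_mm = v$geometry$stenosis_length_mm,
    a = v$coefficients$a, b = v$coefficients$b, p_a = v$p_a,
    slope = v$cfr_line$slope, p_zf = v$cfr_line$p_zf,
    q_rest = v$cfr_line$q_rest, true_ffr = v$true_ffr))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run configuration with validated defaults
#'
#' Assembles the full pipeline configuration, optionally overlaid with a
#' YAML or JSON file. Every default is either a documented physiological
#' value (fluid 4.5 cP / 1.04 g/cm^3, P_zf 20 mmHg, resting flow 50 mL/min)
#' or a flagged modelling choice (setpoint range, noise levels, cohort
#' distributions).
#'
#' @param path Optional path to a YAML or JSON config file whose top-level
#'   keys override the defaults (unknown keys are an error).
#' @param ... Named overrides applied after the file.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    fluid = list(viscosity_cp = 4.5, density_g_cm3 = 1.04),
    cfr = list(q_rest = 50, cfr_normal = 3.5, p_normal = 90, p_zf = 20),
    noise = list(flow_relative_sd = 0.005, pressure_relative_sd = 0.005),
    setpoints = list(n = 7, q_min = 20, q_max = 220, max_dp_fraction = 0.8),
    cohort = list(ds_mean = 53.7, ds_sd = 17.1,
                  diameter_mean = 3, diameter_sd = 0.4,
                  length_mean = 20, length_sd = 5,
                  pa_mean = 90, pa_sd = 10,
                  slope_jitter_sd = 0.15, pzf_jitter_sd = 2),
    n_replicates = 3,
    seed = 1L,
    reference_cutoff = 0.80
  )
  cfg <- defaults
  apply_overrides <- function(cfg, over, where) {
    for (key in names(over)) {
      if (!key %in% names(cfg))
        stop("configuration error: unknown key `", key, "` in ", where,
             call. = FALSE)
      cfg[[key]] <- if (is.list(cfg[[key]]) && is.list(over[[key]]))
        apply_overrides(cfg[[key]], over[[key]], where) else over[[key]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    over <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- apply_overrides(cfg, over, path)
  }
  dots <- list(...)
  if (length(dots) > 0) cfg <- apply_overrides(cfg, dots, "overrides")
  # validate by constructing the typed objects
  fluid_properties(cfg$fluid$viscosity_cp, cfg$fluid$density_g_cm3)
  cfr_line(cfg$cfr$q_rest, cfg$cfr$cfr_normal, cfg$cfr$p_normal, cfg$cfr$p_zf)
  noise_model(cfg$noise$flow_relative_sd, cfg$noise$pressure_relative_sd)
  structure(cfg, class = "run_config")
}

#' Hash of a configuration, for artifact provenance
#'
#' MD5 of the canonical (sorted-key) JSON serialization.
#'
#' @param cfg A `run_config` (or any list).
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
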