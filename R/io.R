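# --- file formats and configuration ---------------------------------------
#
# Point-cloud CSV dialect: header `x_mm,y_mm,z_mm,label,scan_id`, comma
# separated, period decimal, UTF-8. Coordinates are written with 17
# significant digits so a write/read cycle is bitwise exact.

PC_COLUMNS <- c("x_mm", "y_mm", "z_mm", "label", "scan_id")

#' Read labelled point clouds from CSV
#'
#' Parses a point-cloud CSV (columns `x_mm,y_mm,z_mm,label,scan_id`) and
#' groups rows into one [point_cloud] per `(scan_id, label)` pair, row
#' order preserved. Parse problems are reported with the offending line
#' number (header = line 1).
#'
#' @param path CSV file path
#' @return named list of [point_cloud]s (names `"<scan_id>:<label>"`);
#'   empty (with a warning) for a header-only file
#' @seealso [write_point_clouds], [as_scan_data]
#' @export
read_point_clouds <- function(path) {
  if (!file.exists(path)) abort_parse("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_parse(path, ": ", conditionMessage(e)))
  missing_cols <- setdiff(PC_COLUMNS, names(df))
  if (length(missing_cols)) {
    abort_parse(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("no data rows in ", path)
    return(structure(list(), names = character(0)))
  }
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort_parse(path, " line ", bad[1] + 1L, ": non-numeric ", col,
                  " value '", df[[col]][bad[1]], "'")
    }
    df[[col]] <- v
  }
  bad <- which(!df$label %in% SURFACE_LABELS)
  if (length(bad)) {
    abort_parse(path, " line ", bad[1] + 1L, ": unknown label '",
                df$label[bad[1]], "'")
  }
  key <- paste(df$scan_id, df$label, sep = ":")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(i) point_cloud(as.matrix(df[i, c("x_mm", "y_mm", "z_mm")]),
                                        label = df$label[i[1]],
                                        scan_id = df$scan_id[i[1]]))
  out[unique(key)]
}

#' Write point clouds to CSV
#'
#' Inverse of [read_point_clouds]; coordinates are written at full (17
#' significant digit) precision so the round trip is bitwise exact.
#'
#' @param clouds a [point_cloud] or list of them
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_point_clouds <- function(clouds, path) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  rows <- lapply(clouds, function(cl) {
    data.frame(x_mm = sprintf("%.17g", cl$points[, 1]),
               y_mm = sprintf("%.17g", cl$points[, 2]),
               z_mm = sprintf("%.17g", cl$points[, 3]),
               label = cl$label, scan_id = cl$scan_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(x_mm = character(0), y_mm = character(0),
                     z_mm = character(0), label = character(0),
                     scan_id = character(0), stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble scan data from a cloud collection
#'
#' Picks the clouds of one `scan_id` out of a [read_point_clouds] result
#' and bundles them into a [scan_data].
#'
#' @param clouds named list from [read_point_clouds]
#' @param scan_id the scan to assemble
#' @return a [scan_data]
#' @export
as_scan_data <- function(clouds, scan_id) {
  get_cl <- function(label) clouds[[paste(scan_id, label, sep = ":")]]
  needed <- c("cup_outer", "head", "plane1", "plane2")
  have <- vapply(needed, function(l) !is.null(get_cl(l)), logical(1))
  if (!all(have)) {
    abort_parse("scan '", scan_id, "' is missing surface(s): ",
                paste(needed[!have], collapse = ", "))
  }
  scan_data(cup_outer = get_cl("cup_outer"), head = get_cl("head"),
            plane1 = get_cl("plane1"), plane2 = get_cl("plane2"),
            cup_inner = get_cl("cup_inner"), scan_id = scan_id)
}

# drop S3 classes so nested objects (fits, specs) serialize as plain lists
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

# display rounding per reporting convention: mm to 2 dp, degrees to integers
display_fields <- function(result) {
  if (inherits(result, "wear_result")) {
    list(linear_wear_mm = format(round(result$linear_wear, 2), nsmall = 2),
         theta_deg = as.character(round(result$theta)),
         phi_deg = as.character(round(result$phi)))
  } else {
    list(mean_difference = format(round(result$mean_difference, 2), nsmall = 2))
  }
}

#' Write a wear result or agreement summary as JSON
#'
#' Keys are written in a fixed order with full-precision numbers, plus a
#' `display` block rounded to the reporting granularity (mm to 2 decimal
#' places, degrees to integers; round-half-even).
#'
#' @param result a `wear_result` or `agreement_summary`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_result <- function(result, path) {
  if (inherits(result, "wear_result")) {
    payload <- list(kind = "wear_result",
                    method = result$method,
                    linear_wear_mm = result$linear_wear,
                    wear_vector_mm = result$wear_vector,
                    theta_deg = result$theta,
                    phi_deg = result$phi,
                    angles_defined = result$angles_defined,
                    display = display_fields(result),
                    diagnostics = strip_classes(result$diagnostics))
  } else if (inherits(result, "agreement_summary")) {
    payload <- list(kind = "agreement_summary",
                    n = result$n,
                    mean_difference = result$mean_difference,
                    sd_difference = result$sd_difference,
                    loa_low = result$loa_low, loa_high = result$loa_high,
                    bias_ci_low = result$bias_ci_low,
                    bias_ci_high = result$bias_ci_high,
                    confidence = result$confidence,
                    repeatability = result$repeatability,
                    accuracy = result$accuracy,
                    display = display_fields(result))
  } else {
    abort_parse("write_result handles wear_result or agreement_summary objects")
  }
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a result JSON
#' @param path JSON path written by [write_result]
#' @return a list mirroring the JSON structure
#' @export
read_result <- function(path) {
  if (!file.exists(path)) abort_parse("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run configuration
#'
#' Central defaults shared by the CLI and pipeline: the artifact filter
#' threshold (0.5 mm, about 1 SD of CT surface noise), the UHMWPE density
#' (0.935 mg/mm^3), the elimination pass cap, worn-side convention, seed
#' and verbosity.
#'
#' @param filter_threshold mm, > 0
#' @param density_mg_mm3 mg/mm^3, > 0
#' @param max_fit_iterations elimination passes per fit
#' @param worn_sign worn hemisphere side for the CMM variant (+1 or -1)
#' @param seed integer or NULL
#' @param verbose logical
#' @return object of class `run_config`
#' @export
run_config <- function(filter_threshold = 0.5, density_mg_mm3 = 0.935,
                       max_fit_iterations = 10L, worn_sign = 1,
                       seed = NULL, verbose = FALSE) {
  if (filter_threshold <= 0) abort_parse("filter_threshold must be > 0")
  if (density_mg_mm3 <= 0) abort_parse("density_mg_mm3 must be > 0")
  structure(list(filter_threshold = filter_threshold,
                 density_mg_mm3 = density_mg_mm3,
                 max_fit_iterations = as.integer(max_fit_iterations),
                 worn_sign = worn_sign,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the [run_config]
#' defaults.
#'
#' @param path YAML file path
#' @return a [run_config]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_parse("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_parse("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Reference measurement tables from the phantom validation study
#'
#' `wear_measurements()` returns the per-cup linear-wear table of the
#' hip-simulator study used to validate this package: 12 UHMWPE cups
#' measured by the CT method and by the CMM reference (per-cup mean and
#' replicate SD, mm), with the soak-control flag (controls were soaked but
#' never wear-tested) and the difference column as originally reported.
#' `diameter_measurements()` returns the companion table of CT-measured
#' outer cup and femoral head diameters before and after wear.
#'
#' @return a data frame
#' @export
wear_measurements <- function() {
  read.csv(system.file("extdata", "linear_wear_ct_cmm.csv",
                       package = "cupwear"),
           stringsAsFactors = FALSE)
}

#' @rdname wear_measurements
#' @export
diameter_measurements <- function() {
  read.csv(system.file("extdata", "ct_diameters.csv", package = "cupwear"),
           stringsAsFactors = FALSE)
}
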