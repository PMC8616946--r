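# Materials-table file format (CSV / JSON), funnel-report writers, and the
# YAML run-configuration reader.
#
# All potentials in files are V vs HE at pH 7 and all energies eV; the
# units are baked into the column names. Empty cells mean "absent".
# Numbers are read and written in the C locale (dot decimal separator).

MATERIALS_COLUMNS <- c(
  "material_id", "formula", "n_elements", "is_metal",
  "fermi_potential_V", "vbm_potential_V", "cbm_potential_V",
  "occupied_midgap_V", "unoccupied_midgap_V",
  "delta_h_hull_eV_per_atom", "omega2_min_eV_per_A2", "e_gap_hse_eV",
  "e_ads_ho_eV", "e_ads_h_eV", "e_ads_o_eV"
)

.fmt_num <- function(x) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return("")
  paste(vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                     trim = TRUE),
               character(1L)), collapse = ";")
}

.record_row <- function(r) {
  b <- r$band
  c(material_id = r$material_id,
    formula = r$formula,
    n_elements = .fmt_num(r$n_elements),
    is_metal = if (is.null(b)) "" else tolower(as.character(b$is_metal)),
    fermi_potential_V = .fmt_num(if (is.null(b)) NULL else b$fermi_potential),
    vbm_potential_V = .fmt_num(if (is.null(b)) NULL else b$vbm_potential),
    cbm_potential_V = .fmt_num(if (is.null(b)) NULL else b$cbm_potential),
    occupied_midgap_V = .fmt_num(if (is.null(b)) NULL else b$occupied_midgap),
    unoccupied_midgap_V = .fmt_num(if (is.null(b)) NULL
                                   else b$unoccupied_midgap),
    delta_h_hull_eV_per_atom = .fmt_num(r$delta_h_hull),
    omega2_min_eV_per_A2 = .fmt_num(r$omega2_min),
    e_gap_hse_eV = .fmt_num(r$e_gap_hse),
    e_ads_ho_eV = .fmt_num(r$e_ads_ho),
    e_ads_h_eV = .fmt_num(r$e_ads_h),
    e_ads_o_eV = .fmt_num(r$e_ads_o))
}

#' Write a materials table to CSV or JSON
#'
#' @param records a `materials_table` or list of [material_record()]s.
#' @param path output file path.
#' @param format `"csv"` (UTF-8, header row) or `"json"` (array of
#'   objects); guessed from the file extension when missing.
#' @return invisibly, `path`.
#' @export
write_materials_table <- function(records, path,
                                  format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (inherits(records, "material_record")) records <- list(records)
  rows <- lapply(records, .record_row)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- MATERIALS_COLUMNS
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    objs <- lapply(rows, function(row) {
      row <- as.list(row)
      row[!nzchar(unlist(row))] <- NULL
      row
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

.parse_num <- function(x, field, line, errors, vector = FALSE) {
  if (is.null(x) || !nzchar(x)) {
    return(if (vector) numeric(0) else NA_real_)
  }
  parts <- if (vector) strsplit(x, ";", fixed = TRUE)[[1L]] else x
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals))) {
    errors$add(sprintf("line %d: unparsable number in %s: '%s'",
                       line, field, x))
    return(if (vector) numeric(0) else NA_real_)
  }
  vals
}

.row_to_record <- function(row, line, errors) {
  get_chr <- function(field) {
    v <- row[[field]]
    if (is.null(v) || length(v) == 0L || is.na(v)) "" else as.character(v)
  }
  id <- get_chr("material_id")
  if (!nzchar(id)) {
    errors$add(sprintf("line %d: empty material_id", line))
    return(NULL)
  }
  num <- function(field) .parse_num(get_chr(field), field, line, errors)
  vec <- function(field) .parse_num(get_chr(field), field, line, errors,
                                    vector = TRUE)
  is_metal_raw <- tolower(get_chr("is_metal"))
  band <- NULL
  if (nzchar(is_metal_raw)) {
    if (!is_metal_raw %in% c("true", "false")) {
      errors$add(sprintf("line %d: is_metal must be true/false, got '%s'",
                         line, is_metal_raw))
      return(NULL)
    }
    is_metal <- identical(is_metal_raw, "true")
    fermi <- num("fermi_potential_V")
    vbm <- num("vbm_potential_V")
    cbm <- num("cbm_potential_V")
    band <- tryCatch(
      band_summary(id, is_metal = is_metal,
                   fermi_potential = if (is.na(fermi)) NULL else fermi,
                   vbm_potential = if (is.na(vbm)) NULL else vbm,
                   cbm_potential = if (is.na(cbm)) NULL else cbm,
                   occupied_midgap = vec("occupied_midgap_V"),
                   unoccupied_midgap = vec("unoccupied_midgap_V")),
      sodscreen_error = function(e) {
        errors$add(sprintf("line %d: %s", line, conditionMessage(e)))
        NULL
      })
    if (is.null(band)) return(NULL)
  }
  tryCatch(
    material_record(
      material_id = id, formula = get_chr("formula"),
      n_elements = num("n_elements"),
      delta_h_hull = num("delta_h_hull_eV_per_atom"),
      omega2_min = num("omega2_min_eV_per_A2"),
      e_gap_hse = num("e_gap_hse_eV"), band = band,
      e_ads_ho = num("e_ads_ho_eV"), e_ads_h = num("e_ads_h_eV"),
      e_ads_o = num("e_ads_o_eV"),
      provenance = paste0("file")),
    sodscreen_error = function(e) {
      errors$add(sprintf("line %d: %s", line, conditionMessage(e)))
      NULL
    })
}

.error_collector <- function() {
  msgs <- character(0)
  list(add = function(m) msgs <<- c(msgs, m),
       messages = function() msgs)
}

#' Read a materials table from CSV or JSON
#'
#' CSV files must carry the exact (case-sensitive) header; a missing or
#' misspelled column is a hard format error naming the column. Row-level
#' problems (unparsable numbers, frontier-level convention violations)
#' are collected with their line numbers and raised together as a format
#' error.
#'
#' @param path input file.
#' @param format `"csv"`, `"json"`, or `"auto"` (extension-based).
#' @return a list of [material_record()]s of class `materials_table`.
#' @export
read_materials_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    sod_abort(sprintf("file not found: %s", path),
              class = "sodscreen_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  errors <- .error_collector()
  if (format == "csv") {
    header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"),
                       ",", fixed = TRUE)[[1L]]
    header <- gsub('^"|"$', "", trimws(header))
    missing_cols <- setdiff(MATERIALS_COLUMNS, header)
    if (length(missing_cols)) {
      sod_abort(paste("materials table header missing column(s):",
                      paste(missing_cols, collapse = ", ")),
                class = "sodscreen_format_error")
    }
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8",
                          na.strings = character(0))
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    lines <- seq_len(nrow(df)) + 1L    # +1 for the header line
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(objs)) {
      sod_abort("JSON materials table must be an array of objects",
                class = "sodscreen_format_error")
    }
    rows <- lapply(objs, function(o) {
      lapply(o, function(v) if (is.null(v)) "" else as.character(v))
    })
    unknown <- unique(unlist(lapply(rows, function(r)
      setdiff(names(r), MATERIALS_COLUMNS))))
    if (length(unknown)) {
      sod_abort(paste("unknown field(s) in JSON materials table:",
                      paste(unknown, collapse = ", ")),
                class = "sodscreen_format_error")
    }
    lines <- seq_along(rows)
  }
  records <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    records[[i]] <- .row_to_record(rows[[i]], lines[i], errors)
  }
  msgs <- errors$messages()
  if (length(msgs)) {
    sod_abort(paste0("materials table has invalid row(s):\n  ",
                     paste(msgs, collapse = "\n  ")),
              class = "sodscreen_format_error")
  }
  structure(records, class = "materials_table")
}

.report_json_payload <- function(report) {
  cfg <- report$config
  list(
    input_count = report$input_count,
    counts = as.list(report$counts),
    results = report$results,
    config = list(
      max_elements = cfg$max_elements, hull_max = cfg$hull_max,
      omega2_min_threshold = cfg$omega2_min_threshold,
      gap_min = cfg$gap_min,
      window = list(phi1 = cfg$window$phi1, phi2 = cfg$window$phi2,
                    tolerance = cfg$window$tolerance),
      allowed_types = cfg$allowed_types,
      adsorption_mode = cfg$adsorption_mode,
      conditions = list(temperature = cfg$conditions$temperature,
                        ph = cfg$conditions$ph,
                        nernst_slope = cfg$conditions$nernst_slope),
      scaling = list(slope = cfg$relation$slope,
                     intercept = cfg$relation$intercept)),
    metadata = report$metadata
  )
}

#' Write a funnel report
#'
#' `"json"` emits the full machine-readable report (counts, per-material
#' results, config snapshot, metadata); `"csv"` one row per material with
#' the stage outcomes and fail reasons; `"markdown"` the funnel summary
#' table.
#'
#' @param report a `funnel_report` from [run_screen()].
#' @param path output file path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path,
                         format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "funnel_report"))
  if (format == "json") {
    jsonlite::write_json(.report_json_payload(report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  } else if (format == "csv") {
    utils::write.csv(report$results, path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    lab <- c("input", "stability", "energy level", "adsorption")
    lines <- c("| stage | surviving |", "| --- | --- |",
               sprintf("| %s | %d |", lab, report$counts))
    writeLines(lines, path)
  }
  invisible(path)
}

# Allowed keys of the YAML run configuration, by section.
.CONFIG_SCHEMA <- list(
  screen = c("max_elements", "hull_max", "omega2_min_threshold", "gap_min",
             "allowed_types", "adsorption_mode"),
  window = c("phi1", "phi2", "tolerance"),
  conditions = c("temperature", "ph", "nernst_slope",
                 "proton_coefficients"),
  scaling = c("slope", "intercept"),
  constants = c("drG1", "drG2_offset", "drG3_offset", "drG4_const",
                "drG5_const", "reference_intercept")
)

#' Read a screening configuration from YAML
#'
#' The document mirrors [screen_config()]: optional sections `screen`,
#' `window`, `conditions`, `scaling` and `constants`, each holding the
#' corresponding constructor arguments. Unknown sections or keys are
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return a validated [screen_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    sod_abort(sprintf("config file not found: %s", path),
              class = "sodscreen_io_error")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  unknown_sections <- setdiff(names(doc), names(.CONFIG_SCHEMA))
  if (length(unknown_sections)) {
    sod_abort(paste("unknown config section(s):",
                    paste(unknown_sections, collapse = ", ")),
              class = "sodscreen_config_error")
  }
  for (sec in names(doc)) {
    unknown <- setdiff(names(doc[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(unknown)) {
      sod_abort(sprintf("unknown key(s) in config section '%s': %s",
                        sec, paste(unknown, collapse = ", ")),
                class = "sodscreen_config_error")
    }
  }
  window <- do.call(potential_window, doc$window %||% list())
  conditions <- do.call(reaction_conditions, doc$conditions %||% list())
  relation <- do.call(scaling_relation, doc$scaling %||% list())
  constants <- do.call(energy_constants, doc$constants %||% list())
  args <- c(doc$screen %||% list(),
            list(window = window, conditions = conditions,
                 relation = relation, constants = constants))
  do.call(screen_config, args)
}
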