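# Three-stage high-throughput screening funnel over a materials table,
# plus the supercell-sizing planner for downstream adsorption calculations.

#' One screening candidate material
#'
#' Bundles the stability descriptors, composition, bandgap, frontier-level
#' summary and adsorption energies of one candidate. Missing numeric
#' fields are `NA` and surface as `missing_data` fail reasons during
#' screening, never as exceptions or silent passes.
#'
#' @param material_id unique identifier.
#' @param formula chemical formula (free text).
#' @param n_elements number of distinct elements (>= 1).
#' @param delta_h_hull energy above the convex hull, eV/atom.
#' @param omega2_min minimum phonon-frequency-squared proxy, eV/A^2.
#' @param e_gap_hse HSE bandgap, eV (0 for metals).
#' @param band a [band_summary()] or `NULL`.
#' @param e_ads_ho,e_ads_h,e_ads_o adsorption energies, eV (`NA` if
#'   unknown; `e_ads_o` may be filled from the scaling relation).
#' @param provenance free-text origin note.
#' @return an object of class `material_record`.
#' @export
material_record <- function(material_id, formula = "", n_elements = NA,
                            delta_h_hull = NA, omega2_min = NA,
                            e_gap_hse = NA, band = NULL,
                            e_ads_ho = NA, e_ads_h = NA, e_ads_o = NA,
                            provenance = "") {
  material_id <- as.character(material_id)
  if (!nzchar(material_id)) sod_abort("`material_id` must be non-empty")
  if (!is.na(n_elements)) {
    n_elements <- check_number(n_elements, "n_elements")
    if (n_elements < 1) sod_abort("`n_elements` must be >= 1")
  }
  if (!is.null(band)) stopifnot(inherits(band, "band_summary"))
  num_or_na <- function(x, nm) {
    if (length(x) != 1L) sod_abort(sprintf("`%s` must be length 1", nm))
    if (is.na(x)) return(NA_real_)
    check_number(x, nm)
  }
  structure(
    list(material_id = material_id, formula = as.character(formula),
         n_elements = if (is.na(n_elements)) NA_real_ else n_elements,
         delta_h_hull = num_or_na(delta_h_hull, "delta_h_hull"),
         omega2_min = num_or_na(omega2_min, "omega2_min"),
         e_gap_hse = num_or_na(e_gap_hse, "e_gap_hse"),
         band = band,
         e_ads_ho = num_or_na(e_ads_ho, "e_ads_ho"),
         e_ads_h = num_or_na(e_ads_h, "e_ads_h"),
         e_ads_o = num_or_na(e_ads_o, "e_ads_o"),
         provenance = as.character(provenance)),
    class = "material_record"
  )
}

#' Screening configuration
#'
#' Thresholds and model settings for the three-stage funnel. Comparison
#' strictness follows the screening protocol: element count `<=`, hull
#' energy `<`, phonon proxy `>`, bandgap `>`, adsorption energies `>`.
#'
#' @param max_elements maximum number of distinct elements (default 2).
#' @param hull_max maximum energy above the hull, eV/atom (default 0.2,
#'   strict `<`).
#' @param omega2_min_threshold kinetic-stability threshold, eV/A^2
#'   (default 1e-5, strict `>`).
#' @param gap_min minimum HSE bandgap, eV (default 0, strict `>`).
#' @param window a [potential_window()].
#' @param allowed_types band types admitted by stage 2 (default
#'   `c("I", "II")`: a single edge-type iFMO).
#' @param adsorption_mode `"rectangle"` or `"full_x1"` for stage 3.
#' @param conditions a [reaction_conditions()].
#' @param relation a [scaling_relation()].
#' @param constants an [energy_constants()].
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(max_elements = 2, hull_max = 0.2,
                          omega2_min_threshold = 1e-5, gap_min = 0,
                          window = potential_window(),
                          allowed_types = c("I", "II"),
                          adsorption_mode = c("rectangle", "full_x1"),
                          conditions = reaction_conditions(),
                          relation = scaling_relation(),
                          constants = energy_constants()) {
  adsorption_mode <- match.arg(adsorption_mode)
  allowed_types <- as.character(allowed_types)
  if (!length(allowed_types) || !all(allowed_types %in% BAND_TYPES)) {
    sod_abort("`allowed_types` must be a non-empty subset of the band types")
  }
  # thresholds may be +/-Inf to disable a filter entirely
  for (nm in c("max_elements", "hull_max", "omega2_min_threshold",
               "gap_min")) {
    assign(nm, check_number(get(nm), nm, finite = FALSE))
  }
  stopifnot(inherits(window, "potential_window"),
            inherits(conditions, "sod_conditions"),
            inherits(relation, "scaling_relation"),
            inherits(constants, "sod_energy_constants"))
  structure(
    list(max_elements = max_elements, hull_max = hull_max,
         omega2_min_threshold = omega2_min_threshold, gap_min = gap_min,
         window = window, allowed_types = allowed_types,
         adsorption_mode = adsorption_mode, conditions = conditions,
         relation = relation, constants = constants),
    class = "screen_config"
  )
}

.stage_result <- function(id, stage, reasons, extra = list()) {
  structure(c(list(material_id = id, stage = stage,
                   passed = length(reasons) == 0L,
                   fail_reasons = reasons), extra),
            class = "stage_result")
}

#' Stage 1: stability and composition filter
#'
#' Passes iff `n_elements <= max_elements`, `delta_h_hull < hull_max`,
#' `omega2_min > omega2_min_threshold` and `e_gap_hse > gap_min`. Every
#' violated condition contributes its own fail reason; a missing required
#' field yields a `missing_data:<field>` reason.
#'
#' @param r a [material_record()].
#' @param cfg a [screen_config()].
#' @return a `stage_result` (fields `material_id`, `stage`, `passed`,
#'   `fail_reasons`).
#' @export
stage_stability <- function(r, cfg = screen_config()) {
  stopifnot(inherits(r, "material_record"), inherits(cfg, "screen_config"))
  reasons <- character(0)
  chk <- function(value, field, fail_code, ok) {
    if (is.na(value)) {
      reasons <<- c(reasons, paste0("missing_data:", field))
      sod_log("warning", sprintf("%s: missing %s", r$material_id, field))
    } else if (!ok(value)) {
      reasons <<- c(reasons, fail_code)
    }
  }
  chk(r$n_elements, "n_elements", "too_many_elements",
      function(v) v <= cfg$max_elements)
  chk(r$delta_h_hull, "delta_h_hull", "hull_exceeded",
      function(v) v < cfg$hull_max)
  chk(r$omega2_min, "omega2_min", "not_kinetically_stable",
      function(v) v > cfg$omega2_min_threshold)
  chk(r$e_gap_hse, "e_gap_hse", "zero_gap",
      function(v) v > cfg$gap_min)
  .stage_result(r$material_id, 1L, reasons)
}

#' Stage 2: energy-level filter
#'
#' Classifies the frontier levels against the window and passes iff the
#' band type is in `cfg$allowed_types` (default types I and II: exactly
#' one edge-type iFMO, either a VBM or a CBM).
#'
#' @inheritParams stage_stability
#' @return a `stage_result`, additionally carrying `band_type`.
#' @export
stage_energy_level <- function(r, cfg = screen_config()) {
  stopifnot(inherits(r, "material_record"), inherits(cfg, "screen_config"))
  if (is.null(r$band)) {
    sod_log("warning", sprintf("%s: missing band summary", r$material_id))
    return(.stage_result(r$material_id, 2L, "missing_data:band_summary",
                         list(band_type = NA_character_)))
  }
  cls <- classify_band_structure(r$band, cfg$window)
  reasons <- character(0)
  if (!cls$passes_energy_criterion) {
    reasons <- "no_ifmo"
  } else if (!cls$band_type %in% cfg$allowed_types) {
    reasons <- "disallowed_type"
  }
  .stage_result(r$material_id, 2L, reasons,
                list(band_type = cls$band_type, mechanism = cls$mechanism))
}

#' Stage 3: adsorption-energy filter
#'
#' Delegates to [evaluate_adsorption_criterion()] under the configured
#' mode and conditions. In `"rectangle"` mode the violated inequality is
#' reported (`ho_below_threshold` / `h_below_threshold`); in `"full_x1"`
#' mode a failing partition fraction reports `x1_not_dominant`.
#'
#' @inheritParams stage_stability
#' @return a `stage_result`, additionally carrying `x1`.
#' @export
stage_adsorption <- function(r, cfg = screen_config()) {
  stopifnot(inherits(r, "material_record"), inherits(cfg, "screen_config"))
  reasons <- character(0)
  for (field in c("e_ads_ho", "e_ads_h")) {
    if (is.na(r[[field]])) {
      reasons <- c(reasons, paste0("missing_data:", field))
      sod_log("warning", sprintf("%s: missing %s", r$material_id, field))
    }
  }
  if (length(reasons)) {
    return(.stage_result(r$material_id, 3L, reasons, list(x1 = NA_real_)))
  }
  ads <- adsorption_energies(r$e_ads_ho, r$e_ads_h,
                             e_ads_o = if (is.na(r$e_ads_o)) NULL
                                       else r$e_ads_o,
                             relation = cfg$relation)
  ev <- evaluate_adsorption_criterion(ads, cfg$conditions,
                                      mode = cfg$adsorption_mode,
                                      constants = cfg$constants)
  if (!ev$passes) {
    if (cfg$adsorption_mode == "rectangle") {
      if (ads$e_ads_ho <= ev$thresholds[["ho_threshold"]]) {
        reasons <- c(reasons, "ho_below_threshold")
      }
      if (ads$e_ads_h <= ev$thresholds[["h_threshold"]]) {
        reasons <- c(reasons, "h_below_threshold")
      }
    } else {
      reasons <- c(reasons, "x1_not_dominant")
    }
  }
  .stage_result(r$material_id, 3L, reasons, list(x1 = ev$x1))
}

#' Run the three-stage screening funnel
#'
#' Applies stage 1 (stability/composition), stage 2 (energy level) and
#' stage 3 (adsorption energy) in order; a material reaches stage k only
#' if it passed stage k-1. The run is deterministic for a fixed table and
#' invariant to record order.
#'
#' @param records a list of [material_record()]s (class `materials_table`
#'   as produced by [generate_materials_table()] or
#'   [read_materials_table()], or a bare list).
#' @param cfg a [screen_config()].
#' @return an object of class `funnel_report`: `input_count`, `counts`
#'   (survivors after each stage), `results` (one data-frame row per
#'   material with stage outcomes, band type, x1 and collapsed fail
#'   reasons), `stage_results` (per-material `stage_result` lists),
#'   `config` and `metadata`.
#' @examples
#' tab <- generate_materials_table(fixture_spec(n_materials = 50, seed = 1))
#' run_screen(tab)
#' @export
run_screen <- function(records, cfg = screen_config()) {
  if (inherits(records, "material_record")) records <- list(records)
  records <- unclass(records)
  if (!length(records)) {
    sod_abort("empty materials table", class = "sodscreen_invalid_table")
  }
  ids <- vapply(records, function(r) r$material_id, character(1L))
  if (anyDuplicated(ids)) {
    sod_abort(paste("duplicate material ids:",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              class = "sodscreen_invalid_table")
  }
  n <- length(records)
  res <- data.frame(material_id = ids,
                    stage1_passed = NA, stage2_passed = NA,
                    stage3_passed = NA,
                    band_type = NA_character_, x1 = NA_real_,
                    fail_reasons = "", stringsAsFactors = FALSE)
  stage_results <- vector("list", n)
  names(stage_results) <- ids
  for (k in seq_len(n)) {
    r <- records[[k]]
    sr <- list()
    s1 <- stage_stability(r, cfg)
    sr$stability <- s1
    res$stage1_passed[k] <- s1$passed
    reasons <- s1$fail_reasons
    if (s1$passed) {
      s2 <- stage_energy_level(r, cfg)
      sr$energy_level <- s2
      res$stage2_passed[k] <- s2$passed
      res$band_type[k] <- s2$band_type %||% NA_character_
      reasons <- c(reasons, s2$fail_reasons)
      if (s2$passed) {
        s3 <- stage_adsorption(r, cfg)
        sr$adsorption <- s3
        res$stage3_passed[k] <- s3$passed
        res$x1[k] <- s3$x1
        reasons <- c(reasons, s3$fail_reasons)
      }
    }
    res$fail_reasons[k] <- paste(reasons, collapse = ";")
    stage_results[[k]] <- sr
  }
  counts <- c(input = n,
              stability = sum(res$stage1_passed, na.rm = TRUE),
              energy_level = sum(res$stage2_passed, na.rm = TRUE),
              adsorption = sum(res$stage3_passed, na.rm = TRUE))
  missing_counts <- sum(grepl("missing_data:", res$fail_reasons, fixed = TRUE))
  if (missing_counts > 0) {
    sod_log("info", sprintf("%d record(s) carried missing_data fail reasons",
                            missing_counts))
  }
  structure(
    list(input_count = n, counts = counts, results = res,
         stage_results = stage_results, config = cfg,
         metadata = list(
           seed = attr(records, "seed", exact = TRUE),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           package_version = as.character(utils::packageVersion("sodscreen")))),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel:\n")
  lab <- c("input", "after stability filter", "after energy-level filter",
           "after adsorption filter")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-27s %d\n", lab[i], x$counts[i]))
  }
  invisible(x)
}

#' @export
summary.funnel_report <- function(object, ...) {
  print(object)
  reasons <- unlist(strsplit(object$results$fail_reasons, ";", fixed = TRUE))
  reasons <- reasons[nzchar(reasons)]
  if (length(reasons)) {
    cat("Fail reasons:\n")
    tb <- sort(table(reasons), decreasing = TRUE)
    for (nm in names(tb)) cat(sprintf("  %-25s %d\n", nm, tb[[nm]]))
  }
  invisible(object)
}

#' Plan the supercell multipliers for an adsorption calculation
#'
#' Single-pass sizing of a 2D surface cell before adsorbate placement.
#' First the aspect check: if one in-plane vector is strictly longer than
#' 1.5 times the other, the shorter one is doubled. Then, on the updated
#' lengths, the minimum-length check: if either length is no larger than
#' 5 A, both are doubled. Multipliers are therefore in {1, 2, 4}.
#'
#' @param a_length,b_length in-plane cell vector lengths, Angstrom (> 0).
#' @return named integer vector `c(multiplier_a, multiplier_b)`.
#' @examples
#' supercell_plan(10, 4)   # c(1, 2)
#' supercell_plan(4, 4)    # c(2, 2)
#' @export
supercell_plan <- function(a_length, b_length) {
  a_length <- check_number(a_length, "a_length")
  b_length <- check_number(b_length, "b_length")
  if (a_length <= 0 || b_length <= 0) {
    sod_abort("cell vector lengths must be positive")
  }
  ma <- 1L; mb <- 1L
  if (a_length > 1.5 * b_length) {
    mb <- 2L; b_length <- 2 * b_length
  } else if (b_length > 1.5 * a_length) {
    ma <- 2L; a_length <- 2 * a_length
  }
  if (a_length <= 5 || b_length <= 5) {
    ma <- 2L * ma; mb <- 2L * mb
  }
  c(multiplier_a = ma, multiplier_b = mb)
}
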