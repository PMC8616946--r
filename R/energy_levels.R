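# Energy-level principle: frontier-level classification against the
# superoxide dismutation redox window, mechanism prediction, and
# reference-potential conversions.
#
# Canonical scale: V vs the hydrogen electrode (HE) at pH 7. On this scale
# a gapped material has vbm_potential > cbm_potential (the valence edge is
# the deeper, more oxidizing level); mid-gap levels lie strictly between
# the conduction and valence edges.

#' Redox window of the superoxide dismutation half-reactions
#'
#' The potential window (phi1, phi2) spanned by the reduction potentials
#' of the two half-reactions of superoxide dismutation, O2/O2^- and
#' O2^-,H+/H2O2. Defaults are the pH-7 values (-0.16 V, 0.94 V) vs the
#' hydrogen electrode. A frontier level strictly inside the (optionally
#' tolerance-widened) open interval is an intermediate frontier molecular
#' orbital (iFMO) and makes both half-reactions thermodynamically
#' spontaneous.
#'
#' @param phi1 lower window edge, V vs HE at pH 7 (default -0.16).
#' @param phi2 upper window edge, V vs HE at pH 7 (default 0.94).
#' @param tolerance non-negative widening of the window on both sides, V
#'   (default 0; strict open-interval membership).
#' @return an object of class `potential_window`.
#' @export
potential_window <- function(phi1 = -0.16, phi2 = 0.94, tolerance = 0) {
  phi1 <- check_number(phi1, "phi1")
  phi2 <- check_number(phi2, "phi2")
  tolerance <- check_number(tolerance, "tolerance")
  if (phi1 >= phi2) sod_abort("`phi1` must be below `phi2`")
  if (tolerance < 0) sod_abort("`tolerance` must be >= 0")
  structure(list(phi1 = phi1, phi2 = phi2, tolerance = tolerance),
            class = "potential_window")
}

#' Frontier-level summary of one material
#'
#' The frontier electronic levels of a candidate material on the canonical
#' V-vs-HE (pH 7) potential scale: the Fermi level for metals, or both
#' band edges plus any mid-gap levels for gapped materials.
#'
#' @param material_id identifier string.
#' @param is_metal logical; metals carry only `fermi_potential`.
#' @param fermi_potential Fermi level, V vs HE pH 7 (metals only).
#' @param vbm_potential,cbm_potential band edges, V vs HE pH 7 (gapped
#'   only); the convention requires `vbm_potential > cbm_potential`.
#' @param occupied_midgap,unoccupied_midgap numeric vectors of mid-gap
#'   level potentials, each strictly between `cbm_potential` and
#'   `vbm_potential`.
#' @param work_function optional work function, eV vs vacuum.
#' @return an object of class `band_summary`.
#' @export
band_summary <- function(material_id, is_metal = FALSE,
                         fermi_potential = NULL,
                         vbm_potential = NULL, cbm_potential = NULL,
                         occupied_midgap = numeric(0),
                         unoccupied_midgap = numeric(0),
                         work_function = NULL) {
  check_flag(is_metal, "is_metal")
  if (is_metal) {
    if (is.null(fermi_potential)) {
      sod_abort("metallic summaries require `fermi_potential`",
                class = "sodscreen_invalid_summary")
    }
    fermi_potential <- check_number(fermi_potential, "fermi_potential")
    if (!is.null(vbm_potential) || !is.null(cbm_potential) ||
        length(occupied_midgap) || length(unoccupied_midgap)) {
      sod_abort("metallic summaries carry no band edges or mid-gap levels",
                class = "sodscreen_invalid_summary")
    }
  } else {
    if (is.null(vbm_potential) || is.null(cbm_potential)) {
      sod_abort("gapped summaries require both `vbm_potential` and `cbm_potential`",
                class = "sodscreen_invalid_summary")
    }
    vbm_potential <- check_number(vbm_potential, "vbm_potential")
    cbm_potential <- check_number(cbm_potential, "cbm_potential")
    if (vbm_potential <= cbm_potential) {
      sod_abort(paste("on the V-vs-HE scale a gapped material must have",
                      "vbm_potential > cbm_potential (positive gap)"),
                class = "sodscreen_invalid_summary")
    }
    mg <- c(occupied_midgap, unoccupied_midgap)
    if (length(mg) && (any(!is.finite(mg)) ||
                       any(mg <= cbm_potential) || any(mg >= vbm_potential))) {
      sod_abort("mid-gap levels must lie strictly between CBM and VBM potentials",
                class = "sodscreen_invalid_summary")
    }
    if (!is.null(fermi_potential)) {
      sod_abort("gapped summaries carry no `fermi_potential`",
                class = "sodscreen_invalid_summary")
    }
  }
  if (!is.null(work_function)) {
    work_function <- check_number(work_function, "work_function")
  }
  structure(
    list(material_id = as.character(material_id), is_metal = is_metal,
         fermi_potential = fermi_potential,
         vbm_potential = vbm_potential, cbm_potential = cbm_potential,
         occupied_midgap = as.numeric(occupied_midgap),
         unoccupied_midgap = as.numeric(unoccupied_midgap),
         work_function = work_function),
    class = "band_summary"
  )
}

#' Classify a material's frontier levels against the redox window
#'
#' Assigns one of eleven band-structure types by open-interval membership
#' of the frontier levels in the (tolerance-widened) window:
#' \describe{
#'   \item{I}{gapped, only the VBM inside (occupied iFMO).}
#'   \item{II}{gapped, only the CBM inside (unoccupied iFMO).}
#'   \item{III}{gapped, both edges inside.}
#'   \item{IV}{edges outside, an occupied mid-gap level inside.}
#'   \item{V}{edges outside, an unoccupied mid-gap level inside.}
#'   \item{VI}{gapped, no level inside, the window lying inside the gap.}
#'   \item{VII}{gapped, all levels below the window.}
#'   \item{VIII}{gapped, all levels above the window.}
#'   \item{IX}{metal, Fermi level inside.}
#'   \item{X}{metal, Fermi level below the window.}
#'   \item{XI}{metal, Fermi level above the window.}
#' }
#' Every level inside the window is listed as an iFMO with its occupancy
#' (a metallic Fermi level counts as occupancy `"metallic"`, acting as
#' both). When a band edge and a mid-gap level are both inside, the type
#' reports the edge case and the extra levels appear in `ifmo_levels`.
#'
#' @param s a [band_summary()].
#' @param w a [potential_window()].
#' @return an object of class `fmo_classification` with fields
#'   `material_id`, `band_type`, `ifmo_levels` (data frame of `potential`,
#'   `occupancy`), `mechanism` and `passes_energy_criterion`.
#' @examples
#' m <- band_summary("V2C", is_metal = TRUE, fermi_potential = -0.11)
#' classify_band_structure(m)$band_type   # "IX"
#' @export
classify_band_structure <- function(s, w = potential_window()) {
  stopifnot(inherits(s, "band_summary"), inherits(w, "potential_window"))
  lo <- w$phi1 - w$tolerance
  hi <- w$phi2 + w$tolerance
  inside <- function(x) x > lo & x < hi

  levels <- data.frame(potential = numeric(0), occupancy = character(0),
                       stringsAsFactors = FALSE)
  add <- function(pot, occ) {
    rbind(levels, data.frame(potential = pot,
                             occupancy = rep(occ, length(pot)),
                             stringsAsFactors = FALSE))
  }

  if (s$is_metal) {
    if (inside(s$fermi_potential)) {
      band_type <- "IX"
      levels <- add(s$fermi_potential, "metallic")
    } else if (s$fermi_potential <= lo) {
      band_type <- "X"
    } else {
      band_type <- "XI"
    }
  } else {
    vbm_in <- inside(s$vbm_potential)
    cbm_in <- inside(s$cbm_potential)
    omg_in <- s$occupied_midgap[inside(s$occupied_midgap)]
    umg_in <- s$unoccupied_midgap[inside(s$unoccupied_midgap)]
    if (vbm_in && cbm_in) {
      band_type <- "III"
    } else if (vbm_in) {
      band_type <- "I"
    } else if (cbm_in) {
      band_type <- "II"
    } else if (length(omg_in)) {
      band_type <- "IV"      # occupied listed first when both kinds inside
    } else if (length(umg_in)) {
      band_type <- "V"
    } else {
      all_levels <- c(s$cbm_potential, s$vbm_potential,
                      s$occupied_midgap, s$unoccupied_midgap)
      if (all(all_levels <= lo)) {
        band_type <- "VII"
      } else if (all(all_levels >= hi)) {
        band_type <- "VIII"
      } else {
        band_type <- "VI"    # the window lies inside the gap
      }
    }
    if (vbm_in) levels <- add(s$vbm_potential, "occupied")
    if (cbm_in) levels <- add(s$cbm_potential, "unoccupied")
    if (length(omg_in)) levels <- add(omg_in, "occupied")
    if (length(umg_in)) levels <- add(umg_in, "unoccupied")
  }

  out <- structure(
    list(material_id = s$material_id, band_type = band_type,
         ifmo_levels = levels, mechanism = NA_character_,
         passes_energy_criterion = nrow(levels) > 0L),
    class = "fmo_classification"
  )
  out$mechanism <- predict_mechanism(out)
  out
}

#' Predict the catalytic mechanism from the iFMO occupancies
#'
#' Occupied iFMOs only: the material is first oxidized by superoxide
#' (HOMO-mediated). Unoccupied only: first reduced (LUMO-mediated). Both
#' kinds, or a metallic Fermi level: both mechanisms operate with an
#' overall neutral intermediate. No iFMO: no mechanism (`"none"`).
#'
#' @param c an `fmo_classification` from [classify_band_structure()].
#' @return one of `"HOMO-mediated"`, `"LUMO-mediated"`, `"both"`, `"none"`.
#' @export
predict_mechanism <- function(c) {
  stopifnot(inherits(c, "fmo_classification"))
  occ <- c$ifmo_levels$occupancy
  if (length(occ) == 0L) return("none")
  if (any(occ == "metallic")) return("both")
  has_occ <- any(occ == "occupied")
  has_unocc <- any(occ == "unoccupied")
  if (has_occ && has_unocc) "both"
  else if (has_occ) "HOMO-mediated"
  else "LUMO-mediated"
}

#' Test the energy-level screening criterion
#'
#' `TRUE` iff the material has at least one frontier level strictly inside
#' the window, i.e. [classify_band_structure()] finds an iFMO.
#'
#' @inheritParams classify_band_structure
#' @return logical.
#' @export
evaluate_energy_criterion <- function(s, w = potential_window()) {
  classify_band_structure(s, w)$passes_energy_criterion
}

#' @export
print.fmo_classification <- function(x, ...) {
  cat(sprintf("%s: band type %s, mechanism %s (%s)\n",
              x$material_id, x$band_type, x$mechanism,
              if (x$passes_energy_criterion) "passes energy-level criterion"
              else "no iFMO"))
  if (nrow(x$ifmo_levels)) {
    cat("iFMO levels (V vs HE pH 7):\n")
    print(x$ifmo_levels, row.names = FALSE)
  }
  invisible(x)
}

#' Proximity of a frontier level to the window midpoint
#'
#' Catalytic activity is expected to peak when the iFMO sits at the window
#' midpoint `(phi1 + phi2)/2` (0.39 V for the default window), where both
#' half-reactions share the driving force equally. The score is the
#' absolute distance of the level from the midpoint; smaller ranks higher.
#'
#' @param level frontier-level potential, V vs HE pH 7; vectorized.
#' @param w a [potential_window()].
#' @return list with `midpoint` (V) and `score` (V, same length as
#'   `level`).
#' @examples
#' midpoint_proximity_score(c(0.31, 0.28))$score   # 0.08, 0.11
#' @export
midpoint_proximity_score <- function(level, w = potential_window()) {
  if (!is.numeric(level) || any(!is.finite(level))) {
    sod_abort("`level` must be finite")
  }
  midpoint <- (w$phi1 + w$phi2) / 2
  list(midpoint = midpoint, score = abs(level - midpoint))
}

#' Electrode measurement to be converted between reference scales
#'
#' A measured potential with its reference electrode and measurement pH,
#' used by [convert_potential()].
#'
#' @param value measured potential, V.
#' @param reference `"SCE"` (saturated calomel) or `"HE"` (hydrogen
#'   electrode).
#' @param measured_ph pH of the measurement solution, in `[0, 14]`.
#' @param sce_offset SCE-to-HE offset, V (default 0.245).
#' @param nernst_slope Nernst slope, V per pH unit (default 0.0592).
#' @return an object of class `electrode_measurement`.
#' @export
electrode_measurement <- function(value, reference = c("HE", "SCE"),
                                  measured_ph, sce_offset = 0.245,
                                  nernst_slope = 0.0592) {
  value <- check_number(value, "value")
  if (!is.character(reference)) {
    sod_abort("unknown reference electrode",
              class = "sodscreen_invalid_reference")
  }
  reference <- toupper(reference[1L])
  if (!reference %in% c("HE", "SCE")) {
    sod_abort(sprintf("unknown reference electrode '%s' (use 'SCE' or 'HE')",
                      reference),
              class = "sodscreen_invalid_reference")
  }
  measured_ph <- check_number(measured_ph, "measured_ph")
  if (measured_ph < 0 || measured_ph > 14) {
    sod_abort("`measured_ph` must lie in [0, 14]")
  }
  structure(list(value = value, reference = reference,
                 measured_ph = measured_ph,
                 sce_offset = check_number(sce_offset, "sce_offset"),
                 nernst_slope = check_number(nernst_slope, "nernst_slope")),
            class = "electrode_measurement")
}

#' Convert a measured potential to the HE scale at a target pH
#'
#' `phi_HE(target) = value - nernst_slope * (target_pH - measured_pH) +
#' sce_offset` (the offset applied only for SCE-referenced measurements).
#' For the common laboratory case of an SCE measurement at pH 4.5
#' converted to pH 7, `delta_pH = 2.5`.
#'
#' @param m an [electrode_measurement()].
#' @param target_ph target pH (default 7, the canonical package scale).
#' @param details if `TRUE`, return a list with the converted `value`,
#'   `delta_ph` and `offset_applied` instead of a bare number.
#' @return converted potential (V vs HE at `target_ph`), or a list when
#'   `details = TRUE`.
#' @examples
#' m <- electrode_measurement(0.0, "SCE", measured_ph = 4.5)
#' convert_potential(m, 7)   # 0.097 V
#' @export
convert_potential <- function(m, target_ph = 7, details = FALSE) {
  stopifnot(inherits(m, "electrode_measurement"))
  target_ph <- check_number(target_ph, "target_ph")
  delta_ph <- target_ph - m$measured_ph
  offset <- if (m$reference == "SCE") m$sce_offset else 0
  value <- m$value - m$nernst_slope * delta_ph + offset
  if (details) {
    list(value = value, delta_ph = delta_ph, offset_applied = offset)
  } else {
    value
  }
}

#' Map a vacuum-referenced electron level onto the HE potential scale
#'
#' An electron level at energy `level_vs_vacuum` (eV, negative below the
#' vacuum level) corresponds to the potential
#' `phi = -level_vs_vacuum - absolute_she - nernst_slope * target_ph`
#' (V vs HE at `target_ph`), using the absolute potential of the standard
#' hydrogen electrode (default 4.44 V). For a metal of work function `W`
#' pass `level_vs_vacuum = -W`. [he_to_vacuum()] is the exact inverse.
#'
#' @param level_vs_vacuum electron energy vs vacuum, eV.
#' @param absolute_she absolute SHE potential, V (default 4.44;
#'   configurable because literature values differ by a few tens of mV).
#' @param target_ph target pH of the HE reference (default 0).
#' @param nernst_slope V per pH unit.
#' @return potential, V vs HE at `target_ph`.
#' @examples
#' vacuum_to_he(-4.83)   # work function 4.83 eV -> 0.39 V vs SHE
#' @export
vacuum_to_he <- function(level_vs_vacuum, absolute_she = 4.44,
                         target_ph = 0, nernst_slope = 0.0592) {
  level_vs_vacuum <- check_number(level_vs_vacuum, "level_vs_vacuum")
  absolute_she <- check_number(absolute_she, "absolute_she")
  target_ph <- check_number(target_ph, "target_ph")
  -level_vs_vacuum - absolute_she - nernst_slope * target_ph
}

#' @rdname vacuum_to_he
#' @param potential potential, V vs HE at `target_ph`.
#' @export
he_to_vacuum <- function(potential, absolute_she = 4.44,
                         target_ph = 0, nernst_slope = 0.0592) {
  potential <- check_number(potential, "potential")
  -(potential + nernst_slope * target_ph + absolute_she)
}

#' Band summary for a measured reduction potential
#'
#' Ingests a single measured reduction potential (e.g. from cyclic
#' voltammetry of a metal-organic framework) as the lone unoccupied
#' frontier level of a gapped material: the potential at which the
#' material accepts an electron. The band edges are synthetic
#' placeholders positioned `edge_margin` volts outside the window so that
#' classification is driven by the measured level alone.
#'
#' @param material_id identifier.
#' @param reduction_potential measured potential, V vs HE pH 7.
#' @param w a [potential_window()] used to place the placeholder edges.
#' @param edge_margin distance of the placeholder edges outside the
#'   window, V (default 1).
#' @return a [band_summary()] whose `unoccupied_midgap` holds the level.
#' @export
reduction_potential_summary <- function(material_id, reduction_potential,
                                        w = potential_window(),
                                        edge_margin = 1) {
  reduction_potential <- check_number(reduction_potential,
                                      "reduction_potential")
  lo <- min(w$phi1 - edge_margin, reduction_potential - edge_margin)
  hi <- max(w$phi2 + edge_margin, reduction_potential + edge_margin)
  band_summary(material_id, is_metal = FALSE,
               vbm_potential = hi, cbm_potential = lo,
               unoccupied_midgap = reduction_potential)
}
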