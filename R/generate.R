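# Synthetic materials-table generator emulating a C2DB-like property table.
#
# The generator draws each screening descriptor independently, so the
# expected pass fraction of every funnel stage is an analytic product of
# per-criterion probabilities and can be tuned directly. Defaults emulate
# the proportions of the published 2D-materials screen: roughly 10% of the
# library survives the stability stage, about a third of those carry a
# single edge-type iFMO, and nearly all of the remainder satisfy the
# adsorption criterion.

#' Specification for a synthetic materials table
#'
#' Field distributions for [generate_materials_table()]. Stage-pass
#' tuning: stage 1 passes with probability
#' `p_binary * p_hull_pass * p_omega2_pass * (1 - metal_fraction)`
#' (metals carry a zero HSE gap and always fail the gap filter; see
#' [stage1_pass_rate()]); the stage-2 pass fraction among gapped
#' materials is `type_probs["I"] + type_probs["II"]`; the stage-3 pass
#' fraction follows from the normal tails of the adsorption-energy
#' distributions beyond (-2.7, -3.4) eV.
#'
#' @param n_materials number of records (>= 1).
#' @param seed integer RNG seed; a fixed seed gives byte-identical tables.
#' @param metal_fraction fraction of metallic records, in `[0, 1]`.
#' @param p_binary probability that a record has <= 2 elements.
#' @param p_hull_pass probability that `delta_h_hull < 0.2` eV/atom
#'   (hull energies are exponential with the matching rate).
#' @param p_omega2_pass probability that the phonon proxy exceeds 1e-5.
#' @param type_probs named probabilities over gapped band types
#'   I-VIII (must sum to 1).
#' @param p_metal_ifmo probability that a metallic Fermi level falls
#'   inside the window.
#' @param ads_ho_mean,ads_ho_sd normal parameters of `E_ads,HO`, eV.
#' @param ads_h_mean,ads_h_sd normal parameters of `E_ads,H`, eV.
#' @param scaling_noise_sd Gaussian spread of `E_ads,O` about the scaling
#'   line, eV.
#' @param relation a [scaling_relation()] the O energies are drawn around.
#' @param missing_rate probability, per optional field, of an `NA`
#'   (applied to the adsorption energies), in `[0, 1)`.
#' @param window the [potential_window()] band edges are placed against.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_materials = 500L, seed = 1L,
                         metal_fraction = 0.1,
                         p_binary = 0.35, p_hull_pass = 0.45,
                         p_omega2_pass = 0.70,
                         type_probs = c(I = 0.14, II = 0.20, III = 0.04,
                                        IV = 0.04, V = 0.04, VI = 0.18,
                                        VII = 0.18, VIII = 0.18),
                         p_metal_ifmo = 0.5,
                         ads_ho_mean = -1.3, ads_ho_sd = 0.7,
                         ads_h_mean = -1.8, ads_h_sd = 0.9,
                         scaling_noise_sd = 0.15,
                         relation = scaling_relation(),
                         missing_rate = 0,
                         window = potential_window()) {
  n_materials <- as.integer(check_number(n_materials, "n_materials"))
  if (n_materials < 1L) sod_abort("`n_materials` must be >= 1",
                                  class = "sodscreen_invalid_spec")
  seed <- as.integer(check_number(seed, "seed"))
  probs <- c(metal_fraction = metal_fraction, p_binary = p_binary,
             p_hull_pass = p_hull_pass, p_omega2_pass = p_omega2_pass,
             p_metal_ifmo = p_metal_ifmo, missing_rate = missing_rate)
  if (any(probs < 0) || any(probs > 1) || missing_rate >= 1) {
    sod_abort("probabilities must lie in [0, 1] (missing_rate in [0, 1))",
              class = "sodscreen_invalid_spec")
  }
  if (length(type_probs) != 8L ||
      !setequal(names(type_probs), BAND_TYPES[1:8]) ||
      any(type_probs < 0) || abs(sum(type_probs) - 1) > 1e-8) {
    sod_abort("`type_probs` must be probabilities over types I-VIII summing to 1",
              class = "sodscreen_invalid_spec")
  }
  structure(
    list(n_materials = n_materials, seed = seed,
         metal_fraction = metal_fraction, p_binary = p_binary,
         p_hull_pass = p_hull_pass, p_omega2_pass = p_omega2_pass,
         type_probs = type_probs[BAND_TYPES[1:8]],
         p_metal_ifmo = p_metal_ifmo,
         ads_ho_mean = ads_ho_mean, ads_ho_sd = ads_ho_sd,
         ads_h_mean = ads_h_mean, ads_h_sd = ads_h_sd,
         scaling_noise_sd = scaling_noise_sd, relation = relation,
         missing_rate = missing_rate, window = window),
    class = "fixture_spec"
  )
}

#' Analytic stage-1 pass rate of a fixture specification
#'
#' The probability that a generated record passes the stability stage:
#' the four stage-1 criteria are drawn independently, so the rate is the
#' product `p_binary * p_hull_pass * p_omega2_pass * (1 - metal_fraction)`.
#'
#' @param spec a [fixture_spec()].
#' @return a probability.
#' @export
stage1_pass_rate <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  spec$p_binary * spec$p_hull_pass * spec$p_omega2_pass *
    (1 - spec$metal_fraction)
}

# Band-edge placement for one gapped record of the requested type,
# relative to the window. Returns band_summary arguments.
.place_band <- function(type, w) {
  phi1 <- w$phi1; phi2 <- w$phi2
  inside <- function() stats::runif(1L, phi1 + 0.02, phi2 - 0.02)
  below <- function(min_off = 0.05, max_off = 1.5)
    phi1 - stats::runif(1L, min_off, max_off)
  above <- function(min_off = 0.05, max_off = 1.5)
    phi2 + stats::runif(1L, min_off, max_off)
  switch(type,
    I = list(vbm = inside(), cbm = below()),
    II = list(vbm = above(), cbm = inside()),
    III = {
      x <- sort(c(inside(), inside()))
      if (diff(x) < 1e-3) x[2L] <- x[2L] + 1e-3
      list(vbm = x[2L], cbm = x[1L])
    },
    IV = list(vbm = above(), cbm = below(), omg = inside()),
    V = list(vbm = above(), cbm = below(), umg = inside()),
    VI = list(vbm = above(), cbm = below()),
    VII = {
      vbm <- below(0.05, 0.5)
      list(vbm = vbm, cbm = vbm - stats::runif(1L, 0.3, 2))
    },
    VIII = {
      cbm <- above(0.05, 0.5)
      list(vbm = cbm + stats::runif(1L, 0.3, 2), cbm = cbm)
    }
  )
}

#' Generate a synthetic C2DB-like materials table
#'
#' Draws `n_materials` records per the [fixture_spec()] distributions:
#' stability descriptors, composition size, band-edge placement relative
#' to the window (per-type probabilities), and adsorption energies
#' correlated through the scaling relation plus Gaussian noise. The RNG
#' state of the caller is preserved; a fixed seed yields an identical
#' table.
#'
#' @param spec a [fixture_spec()].
#' @return a list of [material_record()]s of class `materials_table`,
#'   with the seed and spec attached as attributes.
#' @export
generate_materials_table <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_materials
  w <- spec$window
  hull_rate <- -log(1 - spec$p_hull_pass) / 0.2   # P(Exp < 0.2) = p_hull_pass
  records <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("SYN-%05d", i)
    is_metal <- stats::runif(1L) < spec$metal_fraction
    n_elements <- if (stats::runif(1L) < spec$p_binary) {
      sample(1:2, 1L, prob = c(0.15, 0.85))
    } else {
      sample(3:5, 1L, prob = c(0.6, 0.3, 0.1))
    }
    delta_h_hull <- stats::rexp(1L, rate = hull_rate)
    omega2 <- if (stats::runif(1L) < spec$p_omega2_pass) {
      stats::runif(1L, 1e-4, 0.02)
    } else {
      stats::runif(1L, -0.02, 0)
    }
    if (is_metal) {
      fermi <- if (stats::runif(1L) < spec$p_metal_ifmo) {
        stats::runif(1L, w$phi1 + 0.02, w$phi2 - 0.02)
      } else if (stats::runif(1L) < 0.5) {
        w$phi1 - stats::runif(1L, 0.05, 1.5)
      } else {
        w$phi2 + stats::runif(1L, 0.05, 1.5)
      }
      band <- band_summary(id, is_metal = TRUE, fermi_potential = fermi)
      gap <- 0
    } else {
      type <- sample(names(spec$type_probs), 1L, prob = spec$type_probs)
      p <- .place_band(type, w)
      band <- band_summary(id, is_metal = FALSE,
                           vbm_potential = p$vbm, cbm_potential = p$cbm,
                           occupied_midgap = p$omg %||% numeric(0),
                           unoccupied_midgap = p$umg %||% numeric(0))
      gap <- p$vbm - p$cbm
    }
    e_ads_ho <- stats::rnorm(1L, spec$ads_ho_mean, spec$ads_ho_sd)
    e_ads_h <- stats::rnorm(1L, spec$ads_h_mean, spec$ads_h_sd)
    e_ads_o <- o_from_oh(e_ads_ho, spec$relation) +
      stats::rnorm(1L, 0, spec$scaling_noise_sd)
    if (spec$missing_rate > 0) {
      if (stats::runif(1L) < spec$missing_rate) e_ads_ho <- NA_real_
      if (stats::runif(1L) < spec$missing_rate) e_ads_h <- NA_real_
      if (stats::runif(1L) < spec$missing_rate) e_ads_o <- NA_real_
    }
    records[[i]] <- material_record(
      material_id = id,
      formula = sprintf("A%dB%d", n_elements, i %% 7 + 1),
      n_elements = n_elements, delta_h_hull = delta_h_hull,
      omega2_min = omega2, e_gap_hse = gap, band = band,
      e_ads_ho = e_ads_ho, e_ads_h = e_ads_h, e_ads_o = e_ads_o,
      provenance = "synthetic")
  }
  structure(records, class = "materials_table",
            seed = spec$seed, spec = spec)
}

#' @export
print.materials_table <- function(x, ...) {
  cat(sprintf("Synthetic materials table: %d records", length(x)))
  seed <- attr(x, "seed", exact = TRUE)
  if (!is.null(seed)) cat(sprintf(" (seed %d)", seed))
  cat("\n")
  invisible(x)
}

#' Generate synthetic points on the O-vs-HO scaling line
#'
#' Draws `e_ads_ho` uniformly over `ho_range` and sets
#' `e_ads_o = slope * e_ads_ho + intercept + N(0, noise_sd)`. Useful for
#' exercising [fit_scaling_relation()].
#'
#' @param n number of points (>= 2).
#' @param slope,intercept line parameters (defaults: the reference
#'   relation, 1.87 and 1.42 eV).
#' @param noise_sd Gaussian noise standard deviation, eV.
#' @param seed integer RNG seed.
#' @param ho_range range of `e_ads_ho`, eV.
#' @return a data frame with columns `e_ads_ho`, `e_ads_o`.
#' @export
generate_scaling_points <- function(n, slope = 1.87, intercept = 1.42,
                                    noise_sd = 0, seed = 1L,
                                    ho_range = c(-4, 0)) {
  n <- as.integer(check_number(n, "n"))
  if (n < 2L) sod_abort("`n` must be >= 2", class = "sodscreen_invalid_spec")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  e_ads_ho <- stats::runif(n, min(ho_range), max(ho_range))
  e_ads_o <- slope * e_ads_ho + intercept + stats::rnorm(n, 0, noise_sd)
  data.frame(e_ads_ho = e_ads_ho, e_ads_o = e_ads_o)
}
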