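# Shared builders for band summaries and material records.

gapped_summary <- function(id = "m", vbm, cbm, omg = numeric(0),
                           umg = numeric(0)) {
  band_summary(id, is_metal = FALSE, vbm_potential = vbm,
               cbm_potential = cbm, occupied_midgap = omg,
               unoccupied_midgap = umg)
}

metal_summary <- function(id = "m", fermi) {
  band_summary(id, is_metal = TRUE, fermi_potential = fermi)
}

# A record passing all three stages at default config.
passing_record <- function(id = "ok", band_type = c("I", "II")) {
  band_type <- match.arg(band_type)
  band <- if (band_type == "I") {
    gapped_summary(id, vbm = 0.3, cbm = -0.5)
  } else {
    gapped_summary(id, vbm = 1.5, cbm = 0.3)
  }
  material_record(id, formula = "AB", n_elements = 2, delta_h_hull = 0.05,
                  omega2_min = 1e-3, e_gap_hse = band$vbm_potential -
                    band$cbm_potential,
                  band = band, e_ads_ho = -1.0, e_ads_h = -1.0)
}

# Random valid band summary spanning all eleven types, for property tests.
random_summary <- function(id) {
  if (runif(1) < 0.25) {
    metal_summary(id, fermi = runif(1, -2.5, 3))
  } else {
    cbm <- runif(1, -2.5, 2)
    vbm <- cbm + runif(1, 0.05, 3)
    omg <- umg <- numeric(0)
    if (vbm - cbm > 0.2) {
      if (runif(1) < 0.4) omg <- runif(1, cbm + 0.01, vbm - 0.01)
      if (runif(1) < 0.4) umg <- runif(1, cbm + 0.01, vbm - 0.01)
    }
    gapped_summary(id, vbm = vbm, cbm = cbm, omg = omg, umg = umg)
  }
}
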