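#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data .env abort warn `%||%`
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n across all_of row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# decays per MBq.h (1e6 decays/s * 3600 s)
.DECAYS_PER_MBQ_H <- 3.6e9
# J per keV
.J_PER_KEV <- 1.602176634e-16

#' Radionuclide physical data
#'
#' Constructs a radionuclide description used by the self-dose model:
#' physical half-life and mean electron (beta + conversion + Auger) energy
#' emitted per decay. An optional photon self-dose table supplies the
#' fractional photon contribution as a function of source mass; the sphere
#' self-dose model assumes electrons are absorbed locally, and photons add
#' the tabulated fraction (log-log interpolated in mass).
#'
#' Defaults are read from the packaged Lu-177 constants file
#' (`system.file("extdata", "lu177.yaml", package = "rltdosim")`), which can
#' be overridden per call.
#'
#' @param name Nuclide label.
#' @param physical_half_life_h Physical half-life in hours (> 0).
#' @param electron_energy_keV Mean energy of all electron emissions per
#'   decay, in keV (> 0).
#' @param photon_fraction_table Optional data frame with columns `mass_g`
#'   (strictly increasing, > 0) and `fraction` (in `[0, 1)`): photon
#'   self-dose expressed as a fraction of the local electron dose.
#' @return An object of class `radionuclide`.
#' @examples
#' lu <- radionuclide()
#' lu$physical_half_life_h
#' @export
radionuclide <- function(name = NULL,
                         physical_half_life_h = NULL,
                         electron_energy_keV = NULL,
                         photon_fraction_table = NULL) {
  defaults <- nuclide_defaults()
  name <- name %||% defaults$name
  physical_half_life_h <- physical_half_life_h %||% defaults$physical_half_life_h
  electron_energy_keV <- electron_energy_keV %||% defaults$electron_energy_keV
  if (!is.numeric(physical_half_life_h) || physical_half_life_h <= 0) {
    abort("`physical_half_life_h` must be a positive number.")
  }
  if (!is.numeric(electron_energy_keV) || electron_energy_keV <= 0) {
    abort("`electron_energy_keV` must be a positive number.")
  }
  if (!is.null(photon_fraction_table)) {
    tab <- as_tibble(photon_fraction_table)
    stopifnot(all(c("mass_g", "fraction") %in% names(tab)))
    if (any(diff(tab$mass_g) <= 0) || any(tab$mass_g <= 0)) {
      abort("photon table masses must be positive and strictly increasing.")
    }
    if (any(tab$fraction < 0 | tab$fraction >= 1)) {
      abort("photon fractions must lie in [0, 1).")
    }
    photon_fraction_table <- tab
  }
  structure(
    list(
      name = name,
      physical_half_life_h = physical_half_life_h,
      electron_energy_keV = electron_energy_keV,
      photon_fraction_table = photon_fraction_table
    ),
    class = "radionuclide"
  )
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf(
    "<radionuclide> %s: T1/2 = %.2f h, mean electron energy = %.1f keV/decay%s\n",
    x$name, x$physical_half_life_h, x$electron_energy_keV,
    if (is.null(x$photon_fraction_table)) "" else ", photon table attached"
  ))
  invisible(x)
}

#' Packaged nuclide and density defaults
#'
#' Reads the versioned plain-text constants file shipped with the package
#' (Lu-177 half-life and electron energy, tissue densities, ICRP salivary
#' gland masses).
#'
#' @return A named list.
#' @export
nuclide_defaults <- function() {
  path <- system.file("extdata", "lu177.yaml", package = "rltdosim")
  if (path == "") { # during development before installation
    path <- file.path("inst", "extdata", "lu177.yaml")
  }
  yaml::read_yaml(path)
}

#' Decay constant from half-life
#'
#' @param half_life_h Half-life in hours (> 0).
#' @return Decay constant \eqn{\lambda = \ln 2 / T_{1/2}} in 1/h.
#' @examples
#' decay_constant(159.53) # Lu-177 physical decay
#' @export
decay_constant <- function(half_life_h) {
  if (!is.numeric(half_life_h) || any(half_life_h <= 0)) {
    abort("`half_life_h` must be positive.")
  }
  log(2) / half_life_h
}

#' Convert region volume to mass
#'
#' @param volume_ml Volume in millilitres (> 0).
#' @param density_g_per_ml Density in g/cm^3 (> 0).
#' @return Mass in grams.
#' @examples
#' mass_from_volume(150, 1.06) # CT-derived kidney volume
#' @export
mass_from_volume <- function(volume_ml, density_g_per_ml) {
  if (!is.numeric(volume_ml) || any(volume_ml <= 0)) {
    abort("`volume_ml` must be positive.")
  }
  if (!is.numeric(density_g_per_ml) || any(density_g_per_ml <= 0)) {
    abort("`density_g_per_ml` must be positive.")
  }
  volume_ml * density_g_per_ml
}

.REGION_KINDS <- c("kidney", "parotid", "submandibular", "lesion_bone", "lesion_soft")

.default_density <- function(kind) {
  d <- nuclide_defaults()$densities
  unname(c(
    kidney = d$kidney, parotid = d$soft_tissue, submandibular = d$soft_tissue,
    lesion_bone = d$bone_lesion, lesion_soft = d$soft_tissue_lesion
  )[kind])
}

#' Dosimetry source region
#'
#' A source region is anything dose is computed for: a (paired) kidney, a
#' parotid or submandibular gland, or a tumor lesion (bone or soft tissue).
#' Mass may be given directly or derived from a volume and density; default
#' densities per kind are 1.06 g/cm^3 (kidney), 1.92 g/cm^3 (bone lesion,
#' cortical bone) and 1.03 g/cm^3 (soft-tissue lesion); default masses for
#' the salivary glands are the ICRP reference values (parotid 25.0 g,
#' submandibular 12.5 g).
#'
#' @param region_id Region label.
#' @param kind One of `"kidney"`, `"parotid"`, `"submandibular"`,
#'   `"lesion_bone"`, `"lesion_soft"`.
#' @param volume_ml Optional volume in ml; combined with `density_g_per_ml`
#'   to give the mass.
#' @param density_g_per_ml Density; defaults by kind.
#' @param mass_g Mass in grams; required unless derivable from volume or a
#'   per-kind default mass exists (salivary glands).
#' @return An object of class `source_region`.
#' @examples
#' source_region("K", "kidney", volume_ml = 300)
#' source_region("P", "parotid")
#' @export
source_region <- function(region_id, kind, volume_ml = NULL,
                          density_g_per_ml = NULL, mass_g = NULL) {
  kind <- match.arg(kind, .REGION_KINDS)
  density_g_per_ml <- density_g_per_ml %||% .default_density(kind)
  if (is.null(mass_g)) {
    if (!is.null(volume_ml)) {
      mass_g <- mass_from_volume(volume_ml, density_g_per_ml)
    } else {
      gm <- nuclide_defaults()$gland_masses_g
      mass_g <- switch(kind, parotid = gm$parotid, submandibular = gm$submandibular,
                       abort(sprintf("`mass_g` or `volume_ml` required for kind '%s'.", kind)))
    }
  }
  if (!is.numeric(mass_g) || mass_g <= 0) abort("`mass_g` must be positive.")
  if (!is.null(volume_ml) && abs(mass_g - volume_ml * density_g_per_ml) > 1e-9 * mass_g) {
    abort("`mass_g` inconsistent with `volume_ml` * `density_g_per_ml`.")
  }
  structure(
    list(region_id = as.character(region_id), kind = kind,
         volume_ml = volume_ml, density_g_per_ml = density_g_per_ml,
         mass_g = mass_g),
    class = "source_region"
  )
}

#' @export
print.source_region <- function(x, ...) {
  cat(sprintf("<source_region> %s [%s], mass %.2f g\n", x$region_id, x$kind, x$mass_g))
  invisible(x)
}

#' Sphere-model self-dose factor
#'
#' Absorbed dose to a uniform region per unit time-integrated activity in
#' that region, assuming complete local absorption of electron emissions:
#' \deqn{S(m) = \frac{3.6\times10^{9}\,\mathrm{decay/(MBq\,h)} \times E_e}{m}}
#' with \eqn{E_e} the mean electron energy per decay and \eqn{m} the region
#' mass. An optional photon contribution multiplies by
#' \eqn{1 + f_\gamma(m)} with \eqn{f_\gamma} log-log interpolated from the
#' nuclide's photon table (constant beyond the table ends). For Lu-177 the
#' photon term is small and off by default.
#'
#' @param region A [source_region()] (or anything with a positive `mass_g`).
#' @param nuclide A [radionuclide()]; defaults to packaged Lu-177.
#' @return Self-dose factor in mGy/(MBq h); strictly decreasing in mass.
#' @examples
#' self_dose_factor(source_region("L", "lesion_soft", mass_g = 1))
#' @export
self_dose_factor <- function(region, nuclide = radionuclide()) {
  mass_g <- if (is.list(region)) region$mass_g else region
  if (!is.numeric(mass_g) || any(mass_g <= 0)) abort("region mass must be positive.")
  e_joule <- nuclide$electron_energy_keV * .J_PER_KEV
  s_gy <- .DECAYS_PER_MBQ_H * e_joule / (mass_g * 1e-3) # Gy/(MBq.h)
  s <- s_gy * 1e3
  tab <- nuclide$photon_fraction_table
  if (!is.null(tab)) {
    f <- exp(stats::approx(log(tab$mass_g), log(pmax(tab$fraction, 1e-12)),
                           xout = log(mass_g), rule = 2)$y)
    s <- s * (1 + f)
  }
  s
}
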