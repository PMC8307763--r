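# Derived physical quantities of the raw material and the packed extraction
# bed. These parameterize every mass-transfer model in the package: the bed
# is a cylinder of milled seed of porosity eps, and the charge splits into
# extractable oil and insoluble solid.

#' Dried charge mass
#'
#' Mass of the charge after removing moisture, i.e. the total of oil plus
#' insoluble solid available to the extraction.
#'
#' @param charge_mass Charge mass loaded into the extractor (g).
#' @param moisture_pct Moisture content as a percentage of the charge.
#' @return Dried mass in grams.
#' @examples
#' dry_mass(130, 8.6) # 118.82 g
#' @export
dry_mass <- function(charge_mass, moisture_pct) {
  check_positive(charge_mass, "charge_mass")
  if (!is.numeric(moisture_pct) || any(moisture_pct < 0) || any(moisture_pct >= 100)) {
    stop_invalid("moisture_pct must lie in [0, 100)")
  }
  charge_mass * (1 - moisture_pct / 100)
}

#' Apparent density of the packed bed
#'
#' Charge mass divided by the cylinder volume pi*D^2/4*L of the bed.
#'
#' @param charge_mass_kg Charge mass (kg).
#' @param D Inner diameter of the extractor (m).
#' @param L Bed length (m).
#' @return Apparent density in kg/m^3.
#' @export
apparent_density <- function(charge_mass_kg, D, L) {
  check_positive(charge_mass_kg, "charge_mass_kg")
  check_positive(D, "D")
  check_positive(L, "L")
  charge_mass_kg / (pi * D^2 / 4 * L)
}

#' Real (skeletal) density of the particles
#'
#' @param da Apparent density (kg/m^3).
#' @param eps Bed porosity, in (0, 1).
#' @return Real density in kg/m^3, `da / (1 - eps)`.
#' @export
real_density <- function(da, eps) {
  check_positive(da, "da")
  check_fraction(eps, "eps")
  da / (1 - eps)
}

#' Specific particle surface area per bed volume
#'
#' Sphere-equivalent area of the solid phase, `6 * (1 - eps) / dp`.
#'
#' @param eps Bed porosity, in (0, 1).
#' @param dp Mean particle diameter (m).
#' @return Specific area in 1/m.
#' @export
specific_area <- function(eps, dp) {
  check_fraction(eps, "eps")
  check_positive(dp, "dp")
  6 * (1 - eps) / dp
}

#' Oil-to-solid ratio from oil mass fraction
#'
#' Converts the oil fraction of the dried charge, c_u, to the oil load per
#' unit insoluble solid, x_u = c_u / (1 - c_u).
#'
#' @param cu Oil fraction of the dried mass, in (0, 1).
#' @return Dimensionless kg oil / kg insoluble solid.
#' @seealso [oil_fraction_from_ratio()] for the inverse.
#' @export
oil_ratio_from_fraction <- function(cu) {
  check_fraction(cu, "cu")
  cu / (1 - cu)
}

#' Oil mass fraction from oil-to-solid ratio
#'
#' Inverse of [oil_ratio_from_fraction()]: c_u = x_u / (1 + x_u).
#'
#' @param xu Oil load per unit insoluble solid (dimensionless, >= 0).
#' @return Oil fraction of the dried mass.
#' @export
oil_fraction_from_ratio <- function(xu) {
  if (!is.numeric(xu) || any(!is.finite(xu)) || any(xu < 0)) {
    stop_invalid("xu must be finite and non-negative")
  }
  xu / (1 + xu)
}

#' Insoluble solid mass of the charge
#'
#' @param Ng Total dried mass, oil plus insoluble solid (g).
#' @param xu Oil load per unit insoluble solid.
#' @return Insoluble solid mass `Ng / (1 + xu)` in grams.
#' @export
insoluble_mass <- function(Ng, xu) {
  check_positive(Ng, "Ng")
  if (!is.numeric(xu) || any(!is.finite(xu)) || any(xu < 0)) {
    stop_invalid("xu must be finite and non-negative")
  }
  Ng / (1 + xu)
}

#' CO2-to-solid mass ratio held in the bed
#'
#' Ratio of solvent mass in the void volume to particle mass,
#' `eps * rho / ((1 - eps) * dr)`.
#'
#' @param rho_co2 Solvent density at the operating point (kg/m^3).
#' @param dr Real density of the particles (kg/m^3).
#' @param eps Bed porosity, in (0, 1).
#' @return Dimensionless solvent-to-solid ratio (gamma).
#' @export
solvent_to_solid_ratio <- function(rho_co2, dr, eps) {
  check_positive(rho_co2, "rho_co2")
  check_positive(dr, "dr")
  check_fraction(eps, "eps")
  eps * rho_co2 / ((1 - eps) * dr)
}

#' Packed-bed specification
#'
#' Bundles extractor geometry and raw-material constants and derives the
#' dependent quantities (dried mass, apparent and real density, specific
#' area). Masses are stored in grams; densities in kg/m^3.
#'
#' @param inner_diameter Inner diameter of the extractor (m).
#' @param bed_length Bed length (m).
#' @param porosity Bed porosity, in (0, 1).
#' @param particle_diameter Mean particle diameter (m).
#' @param charge_mass Charge mass loaded (g).
#' @param moisture_pct Moisture content, percent of charge.
#' @return An object of class `bed_spec`: a list with the inputs plus
#'   `dried_mass` (g), `apparent_density`, `real_density` (kg/m^3),
#'   `specific_area` (1/m), `cross_section` and `bed_volume` (m^2, m^3).
#' @examples
#' bed <- cherry_bed()
#' bed$real_density # 2015.11 kg/m^3
#' @export
bed_spec <- function(inner_diameter, bed_length, porosity, particle_diameter,
                     charge_mass, moisture_pct) {
  check_positive(inner_diameter, "inner_diameter")
  check_positive(bed_length, "bed_length")
  check_fraction(porosity, "porosity")
  check_positive(particle_diameter, "particle_diameter")
  da <- apparent_density(charge_mass / 1000, inner_diameter, bed_length)
  out <- list(
    inner_diameter = inner_diameter,
    bed_length = bed_length,
    porosity = porosity,
    particle_diameter = particle_diameter,
    charge_mass = charge_mass,
    moisture_pct = moisture_pct,
    dried_mass = dry_mass(charge_mass, moisture_pct),
    apparent_density = da,
    real_density = real_density(da, porosity),
    specific_area = specific_area(porosity, particle_diameter),
    cross_section = pi * inner_diameter^2 / 4,
    bed_volume = pi * inner_diameter^2 / 4 * bed_length
  )
  structure(out, class = "bed_spec")
}

#' @export
print.bed_spec <- function(x, ...) {
  cat("Packed-bed specification\n")
  cat(sprintf("  geometry: D = %g m, L = %g m, porosity = %g\n",
              x$inner_diameter, x$bed_length, x$porosity))
  cat(sprintf("  charge: %g g (moisture %g%%), dried mass %g g\n",
              x$charge_mass, x$moisture_pct, x$dried_mass))
  cat(sprintf("  densities: apparent %.3f, real %.3f kg/m^3\n",
              x$apparent_density, x$real_density))
  cat(sprintf("  particles: dp = %g um, specific area %.1f 1/m\n",
              x$particle_diameter * 1e6, x$specific_area))
  invisible(x)
}

#' Charge composition
#'
#' Splits the dried charge into extractable oil and insoluble solid from
#' the oil fraction c_u.
#'
#' @param Ng Total dried mass (g).
#' @param cu Oil fraction of the dried mass, in (0, 1).
#' @return An object of class `charge_composition`: list with `Ng`, `cu`,
#'   `xu` (oil per insoluble solid), `Nmg` (insoluble solid, g) and
#'   `oil_mass` (g). `Nmg + oil_mass == Ng` exactly.
#' @export
charge_composition <- function(Ng, cu) {
  check_positive(Ng, "Ng")
  check_fraction(cu, "cu")
  xu <- oil_ratio_from_fraction(cu)
  Nmg <- insoluble_mass(Ng, xu)
  structure(list(Ng = Ng, cu = cu, xu = xu, Nmg = Nmg, oil_mass = Ng - Nmg),
            class = "charge_composition")
}

#' @export
print.charge_composition <- function(x, ...) {
  cat(sprintf("Charge: %.3f g dried = %.3f g oil + %.3f g insoluble solid (x_u = %.3f)\n",
              x$Ng, x$oil_mass, x$Nmg, x$xu))
  invisible(x)
}

#' Reference cherry-seed bed
#'
#' The laboratory bed used throughout the package's examples: 130 g of
#' milled cherry seed (8.6% moisture, mean particle size 741 um) packed at
#' porosity 0.5 into a 37 mm x 120 mm extractor.
#'
#' @return A [bed_spec()] object.
#' @export
cherry_bed <- function() {
  bed_spec(inner_diameter = 0.037, bed_length = 0.12, porosity = 0.5,
           particle_diameter = 741e-6, charge_mass = 130, moisture_pct = 8.6)
}

# -- flat key/value serialization ------------------------------------------

#' Write / read a bed configuration file
#'
#' Serializes a [bed_spec()] as a flat key/value block with keys `D_m`,
#' `L_m`, `porosity`, `dp_um`, `m_in_g`, `moisture_pct`. Format is chosen
#' from the file extension: `.json` or `.yaml`/`.yml`.
#'
#' @param bed A `bed_spec` object.
#' @param path Output (or input) file path.
#' @return `read_bed_config()` returns a `bed_spec`; `write_bed_config()`
#'   returns `path` invisibly.
#' @export
write_bed_config <- function(bed, path) {
  stopifnot(inherits(bed, "bed_spec"))
  rec <- list(D_m = bed$inner_diameter, L_m = bed$bed_length,
              porosity = bed$porosity, dp_um = bed$particle_diameter * 1e6,
              m_in_g = bed$charge_mass, moisture_pct = bed$moisture_pct)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_bed_config
#' @export
read_bed_config <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  need <- c("D_m", "L_m", "porosity", "dp_um", "m_in_g", "moisture_pct")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    stop_invalid("bed config is missing keys: ", paste(missing, collapse = ", "))
  }
  bed_spec(rec$D_m, rec$L_m, rec$porosity, rec$dp_um * 1e-6,
           rec$m_in_g, rec$moisture_pct)
}
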