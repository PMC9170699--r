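#' Define a nanoparticle material
#'
#' A `material_spec` bundles the physicochemical constants every downstream
#' conversion needs: stoichiometric formula, bulk density, optional specific
#' surface area (SSA, from nitrogen adsorption / BET) and which elements of
#' the formula are counted as "metal" when translating elemental analysis
#' (ICP-MS) masses back to particle masses.
#'
#' @param name Material label, e.g. `"HfO2"`.
#' @param formula Named numeric vector of stoichiometric counts,
#'   e.g. `c(Hf = 1, O = 2)`. Element symbols must be known to the package.
#' @param bulk_density Bulk density in g/cm^3.
#' @param ssa Specific surface area in m^2/g, or `NULL` when not measured.
#' @param metal_elements Character vector naming the formula elements treated
#'   as metal in elemental-mass bookkeeping. Defaults to every element that
#'   is not H, C, N or O; for a nitride such as TiN pass `"Ti"` explicitly
#'   (the default already excludes N).
#'
#' @return An object of class `material_spec`.
#' @examples
#' hfo2 <- material_spec("HfO2", c(Hf = 1, O = 2), 9.68, ssa = 114.0)
#' metal_mass_fraction(hfo2)
#' @export
material_spec <- function(name, formula, bulk_density, ssa = NULL,
                          metal_elements = NULL) {
  if (!is.character(name) || length(name) != 1L)
    stop_domain("name must be a single string")
  if (length(formula) == 0L || is.null(names(formula)))
    stop_domain("formula must be a non-empty named numeric vector")
  if (any(formula <= 0))
    stop_domain("stoichiometric counts must be positive")
  atomic_weight(names(formula))  # validates symbols
  check_scalar_positive(bulk_density, "bulk_density")
  if (!is.null(ssa)) check_scalar_positive(ssa, "ssa")
  if (is.null(metal_elements))
    metal_elements <- setdiff(names(formula), c("H", "C", "N", "O"))
  if (length(metal_elements) > 0 &&
      !all(metal_elements %in% names(formula)))
    stop_domain("metal_elements must be a subset of the formula elements")
  out <- structure(list(
    name = name,
    formula = formula,
    bulk_density = bulk_density,
    ssa = ssa,
    metal_elements = metal_elements
  ), class = "material_spec")
  mf <- metal_mass_fraction(out)
  if (length(metal_elements) > 0 && (mf <= 0 || mf > 1))
    stop_domain("metal mass fraction must lie in (0, 1]")
  out
}

#' @export
print.material_spec <- function(x, ...) {
  cat("<material_spec> ", x$name, "\n", sep = "")
  cat("  formula:     ",
      paste0(names(x$formula), ifelse(x$formula == 1, "", x$formula),
             collapse = " "), "\n", sep = "")
  cat("  density:     ", x$bulk_density, " g/cm^3\n", sep = "")
  if (!is.null(x$ssa))
    cat("  SSA:         ", x$ssa, " m^2/g  (d_BET ",
        round(bet_diameter(x$ssa, x$bulk_density), 1), " nm)\n", sep = "")
  if (length(x$metal_elements))
    cat("  metal frac.: ", round(metal_mass_fraction(x), 3), " (",
        paste(x$metal_elements, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Built-in material registry
#'
#' The six nanoparticle types of the study design, with bulk densities and
#' measured specific surface areas. Densities are standard bulk values chosen
#' to reproduce the reported BET-equivalent diameters where checkable; they
#' can be overridden by constructing your own [material_spec()] or via the
#' YAML config (see [read_run_config()]).
#'
#' @return Named list of [material_spec()] objects:
#'   SiO2, TiO2, TiN, WO3, HfO2, Au.
#' @examples
#' sapply(default_materials(), function(m) bet_diameter(m$ssa, m$bulk_density))
#' @export
default_materials <- function() {
  list(
    SiO2 = material_spec("SiO2", c(Si = 1, O = 2), 2.65, ssa = 343.6),
    TiO2 = material_spec("TiO2", c(Ti = 1, O = 2), 4.30, ssa = 235),
    TiN  = material_spec("TiN",  c(Ti = 1, N = 1), 5.40, ssa = 62.7),
    WO3  = material_spec("WO3",  c(W = 1, O = 3), 7.16, ssa = 78.6),
    HfO2 = material_spec("HfO2", c(Hf = 1, O = 2), 9.68, ssa = 114.0),
    Au   = material_spec("Au",   c(Au = 1), 19.3, ssa = 5.9)
  )
}

#' Look up a material by name
#'
#' @param material A `material_spec`, or the name of a registry entry.
#' @param registry List of materials to search, default [default_materials()].
#' @return A `material_spec`.
#' @export
get_material <- function(material, registry = default_materials()) {
  if (inherits(material, "material_spec")) return(material)
  if (is.character(material) && length(material) == 1L) {
    if (material %in% names(registry)) return(registry[[material]])
    if (identical(tolower(material), "water")) return(water_material())
    stop_domain("unknown material '", material, "'")
  }
  stop_domain("material must be a material_spec or a registry name")
}

#' @rdname get_material
#' @export
water_material <- function() {
  material_spec("water", c(H = 2, O = 1), 1.0, metal_elements = character())
}

#' BET-equivalent particle diameter
#'
#' Diameter of the monodisperse sphere with the same specific surface area:
#' `d_BET [nm] = 6000 / (SSA [m^2/g] * rho [g/cm^3])`.
#'
#' @param ssa Specific surface area in m^2/g.
#' @param density Bulk density in g/cm^3.
#' @return Diameter in nm. Strictly decreasing in both arguments.
#' @examples
#' bet_diameter(114.0, 9.68) # ~5.4 nm
#' bet_diameter(62.7, 5.40)  # ~17.7 nm
#' @export
bet_diameter <- function(ssa, density) {
  check_scalar_positive(ssa, "ssa")
  check_scalar_positive(density, "density")
  6000 / (ssa * density)
}

#' Convert a mass fraction to a volume fraction
#'
#' For a nanoparticle of density `rho_np` suspended in a medium of density
#' `rho_medium`. `"dilute"` approximates the mixture density by the medium
#' density (`wt * rho_medium / rho_np`); `"exact"` uses the two-component
#' mixture rule `(wt/rho_np) / (wt/rho_np + (1 - wt)/rho_medium)`. The dilute
#' form is the default because it is the convention used when quoting
#' correspondences such as 5 wt% Au = 0.26 vol% in water.
#'
#' @param wt Mass fraction in `[0, 1]`.
#' @param rho_np,rho_medium Densities in g/cm^3.
#' @param mode `"dilute"` or `"exact"`.
#' @return Volume fraction (dimensionless fraction, not percent).
#' @examples
#' mass_frac_to_vol_frac(0.05, 19.3, 1.0)  # 0.0026 (0.26 vol%)
#' @export
mass_frac_to_vol_frac <- function(wt, rho_np, rho_medium,
                                  mode = c("dilute", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(wt) || any(wt < 0 | wt > 1))
    stop_domain("wt must lie in [0, 1]")
  check_scalar_positive(rho_np, "rho_np")
  check_scalar_positive(rho_medium, "rho_medium")
  if (mode == "dilute") {
    wt * rho_medium / rho_np
  } else {
    v <- wt / rho_np
    ifelse(wt == 0, 0, v / (v + (1 - wt) / rho_medium))
  }
}

#' @rdname mass_frac_to_vol_frac
#' @param vol Volume fraction in `[0, 1]` (exact-mode inverse).
#' @export
vol_frac_to_mass_frac <- function(vol, rho_np, rho_medium) {
  if (!is.numeric(vol) || any(vol < 0 | vol > 1))
    stop_domain("vol must lie in [0, 1]")
  check_scalar_positive(rho_np, "rho_np")
  check_scalar_positive(rho_medium, "rho_medium")
  m <- vol * rho_np
  ifelse(vol == 0, 0, m / (m + (1 - vol) * rho_medium))
}

#' Convert a surface-area concentration to a mass concentration
#'
#' Acellular ROS exposures are dosed at constant exposed nanoparticle surface
#' area; `mass [ug/mL] = 100 * sa_conc [cm^2/mL] / SSA [m^2/g]`.
#'
#' @param sa_conc Surface-area concentration in cm^2/mL (scalar or vector).
#' @param ssa Specific surface area in m^2/g.
#' @return Mass concentration in ug/mL, linear in `sa_conc`.
#' @examples
#' surface_conc_to_mass_conc(1840, 114.0) # HfO2: ~1614 ug/mL
#' @export
surface_conc_to_mass_conc <- function(sa_conc, ssa) {
  check_scalar_positive(ssa, "ssa")
  if (any(sa_conc < 0)) stop_domain("sa_conc must be nonnegative")
  100 * sa_conc / ssa
}

#' Nanoparticle packing fraction of a spherical vesicle
#'
#' `100 * n * (d_np / d_vesicle)^3` volume percent for `n` spheres of
#' diameter `d_np` inside a vesicle of diameter `d_vesicle`. Warns above the
#' random-close-packing limit (~74 vol%) and errors above 100 vol%.
#'
#' @param n_np Number of nanoparticles.
#' @param d_np,d_vesicle Diameters (same unit, typically nm).
#' @return Packing fraction in vol%.
#' @examples
#' vesicle_packing_fraction(166, 50, 400) # 32.4 vol%
#' @export
vesicle_packing_fraction <- function(n_np, d_np, d_vesicle) {
  if (n_np < 0) stop_domain("n_np must be nonnegative")
  check_scalar_positive(d_np, "d_np")
  check_scalar_positive(d_vesicle, "d_vesicle")
  if (d_np >= d_vesicle)
    stop_domain("d_np must be smaller than d_vesicle")
  p <- 100 * n_np * (d_np / d_vesicle)^3
  if (p > 100)
    stop_domain("packing fraction ", round(p, 1),
                " vol% exceeds 100%: geometrically impossible")
  if (p > 74)
    warning("packing fraction ", round(p, 1),
            " vol% exceeds the random-close-packing limit (~74 vol%)")
  p
}

#' Volume of a sphere from its diameter
#'
#' @param diameter Diameter (any length unit; volume in that unit cubed).
#' @return `(pi/6) * diameter^3`.
#' @examples
#' sphere_volume(17.5) # ~2800 um^3, the reference cell volume
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter <= 0)) stop_domain("diameter must be positive")
  pi / 6 * diameter^3
}

#' Metal mass fraction of a material
#'
#' Mass of the metal elements over the total formula mass, from standard
#' atomic weights. Used to translate ICP-MS elemental masses into particle
#' masses.
#'
#' @param material A [material_spec()].
#' @return Fraction in `[0, 1]` (1 for an elemental particle such as Au,
#'   0 for water).
#' @examples
#' metal_mass_fraction(default_materials()$HfO2) # 0.848
#' @export
metal_mass_fraction <- function(material) {
  material <- get_material(material)
  w <- atomic_weight(names(material$formula)) * material$formula
  if (length(material$metal_elements) == 0L) return(0)
  sum(w[names(material$formula) %in% material$metal_elements]) / sum(w)
}

#' Concentration records with basis conversion
#'
#' Represents one concentration in one of four bases and converts between
#' them for a given material. Round-trips are exact to numerical precision.
#'
#' @param value Nonnegative number.
#' @param basis One of `"mass_ug_mL"`, `"surface_cm2_mL"`, `"wt_percent"`,
#'   `"vol_percent"`.
#' @param material A [material_spec()].
#' @param rho_medium Suspension medium density g/cm^3 (for wt/vol bases).
#' @return A `concentration_record` list.
#' @export
concentration_record <- function(value, basis = c("mass_ug_mL",
                                                  "surface_cm2_mL",
                                                  "wt_percent",
                                                  "vol_percent"),
                                 material, rho_medium = 1.0) {
  basis <- match.arg(basis)
  if (value < 0) stop_domain("value must be nonnegative")
  material <- get_material(material)
  structure(list(value = value, basis = basis, material = material,
                 rho_medium = rho_medium),
            class = "concentration_record")
}

#' @rdname concentration_record
#' @param x A `concentration_record`.
#' @param to Target basis.
#' @export
convert_concentration <- function(x, to = c("mass_ug_mL", "surface_cm2_mL",
                                            "wt_percent", "vol_percent")) {
  to <- match.arg(to)
  stopifnot(inherits(x, "concentration_record"))
  m <- x$material
  # funnel through mass concentration in ug/mL
  to_mass <- switch(x$basis,
    mass_ug_mL = x$value,
    surface_cm2_mL = {
      if (is.null(m$ssa)) stop_domain("material has no SSA")
      surface_conc_to_mass_conc(x$value, m$ssa)
    },
    # wt% of suspension: ug/mL = wt/100 * rho_medium * 1e6 (dilute basis)
    wt_percent = x$value / 100 * x$rho_medium * 1e6,
    vol_percent = x$value / 100 * m$bulk_density * 1e6
  )
  value <- switch(to,
    mass_ug_mL = to_mass,
    surface_cm2_mL = {
      if (is.null(m$ssa)) stop_domain("material has no SSA")
      to_mass * m$ssa / 100
    },
    wt_percent = to_mass * 100 / (x$rho_medium * 1e6),
    vol_percent = to_mass * 100 / (m$bulk_density * 1e6)
  )
  concentration_record(value, to, m, x$rho_medium)
}
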