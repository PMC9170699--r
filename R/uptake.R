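# ICP-MS uptake analysis: per-cell metal masses, the Hill-type saturation
# fit, and intracellular nanoparticle volume fractions.

#' Fit the uptake saturation curve
#'
#' Least-squares fit of the Hill-type saturation
#' `f(x) = A * x^p / (B^p + x^p)` relating per-cell metal mass to nominal
#' nanoparticle concentration: `A` is the plateau (ng/cell), `B` the
#' half-saturation concentration (f(B) = A/2 for any p), `p` the
#' cooperativity exponent. Noise-free data is recovered exactly; an
#' all-zero input returns the degenerate `A = 0` flag without fitting.
#'
#' @param conc Nominal concentrations in ug/mL (>= 4 distinct levels).
#' @param mass_per_cell Metal mass per cell in ng/cell (>= 0).
#' @return List with `A`, `B`, `p`, `converged`, `degenerate`, and the
#'   per-concentration means `means`.
#' @examples
#' x <- c(10, 20, 40, 80, 160, 320)
#' fit_uptake(x, 1.2 * x^2 / (40^2 + x^2))
#' @export
fit_uptake <- function(conc, mass_per_cell) {
  if (length(conc) != length(mass_per_cell))
    stop_domain("conc and mass_per_cell must have equal length")
  if (length(unique(conc)) < 4)
    stop_domain("need >= 4 concentration levels")
  if (any(mass_per_cell < 0)) stop_domain("masses must be >= 0")
  means <- stats::aggregate(
    list(mass = mass_per_cell), list(conc = conc), mean)
  if (all(mass_per_cell == 0))
    return(list(A = 0, B = NA_real_, p = NA_real_, converged = FALSE,
                degenerate = TRUE, means = means))
  st <- list(A = max(mass_per_cell), B = stats::median(conc[conc > 0]),
             p = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(mass ~ A * conc^p / (B^p + conc^p),
                      data = data.frame(conc = conc,
                                        mass = mass_per_cell),
                      start = st, lower = c(0, 1e-9, 1e-3),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = NA_real_, B = NA_real_, p = NA_real_,
                converged = FALSE, degenerate = FALSE, means = means))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 3), c("A", "B", "p")))
  list(A = unname(cf["A"]), B = unname(cf["B"]), p = unname(cf["p"]),
       se = se[c("A", "B", "p")],
       converged = TRUE, degenerate = FALSE, means = means)
}

#' Intracellular nanoparticle volume fraction from per-cell metal mass
#'
#' Translates an elemental (ICP-MS) mass per cell into the nanoparticle
#' volume fraction of the cell: particle mass = metal mass / metal mass
#' fraction of the material; particle volume = mass / bulk density;
#' volume fraction = volume / cell volume. The result is divided by the
#' sham viability at the same condition (the surviving cells carry the
#' measured load); pass `sham_viability = 1` (default) for no correction.
#'
#' @param metal_ng_per_cell Metal mass per cell in ng.
#' @param material A [material_spec()] or registry name.
#' @param cell_volume Cell volume in um^3 (default 2800, from the 17.5 um
#'   reference diameter).
#' @param sham_viability Normalized sham viability in (0, 1.5].
#' @return Volume fraction in vol%.
#' @examples
#' mass_to_volume_fraction(1, "Au")    # ~1.85 vol%
#' mass_to_volume_fraction(1, "HfO2")  # ~4.35 vol%
#' @export
mass_to_volume_fraction <- function(metal_ng_per_cell, material,
                                    cell_volume = 2800,
                                    sham_viability = 1) {
  if (any(metal_ng_per_cell < 0)) stop_domain("metal mass must be >= 0")
  check_scalar_positive(cell_volume, "cell_volume")
  if (sham_viability <= 0 || sham_viability > 1.5)
    stop_domain("sham_viability must lie in (0, 1.5]")
  material <- get_material(material)
  mmf <- metal_mass_fraction(material)
  if (mmf <= 0) stop_domain("material has no metal elements")
  particle_ng <- metal_ng_per_cell / mmf
  # ng -> g (1e-9), / (g/cm^3) -> cm^3, -> um^3 (1e12): net factor 1e3
  vol_um3 <- particle_ng * 1e3 / material$bulk_density
  100 * vol_um3 / cell_volume / sham_viability
}

#' Analyze an ICP-MS uptake table
#'
#' From well-level totals (`material`, `conc_ug_mL`, `replicate`,
#' `metal_ng_total`, `cells_counted`) computes per-cell masses, fits the
#' saturation curve per material and derives volume fractions.
#'
#' @param uptake data.frame with the columns above.
#' @param cell_volume,sham_viability Passed to
#'   [mass_to_volume_fraction()]; `sham_viability` may be a function of
#'   concentration (e.g. a toxicity fit) or a single number.
#' @return List with `per_cell` (ng/cell and vol% rows) and `fits` (per
#'   material A, B, p).
#' @export
analyze_uptake_table <- function(uptake, cell_volume = 2800,
                                 sham_viability = 1) {
  .check_plate_columns(uptake, c("material", "conc_ug_mL", "replicate",
                                 "metal_ng_total", "cells_counted"))
  if (any(uptake$cells_counted <= 0))
    stop_format("cells_counted must be positive")
  uptake$ng_per_cell <- uptake$metal_ng_total / uptake$cells_counted
  via <- if (is.function(sham_viability))
    sham_viability(uptake$conc_ug_mL) else rep(sham_viability, nrow(uptake))
  uptake$vol_percent <- mapply(function(m, ng, v)
    mass_to_volume_fraction(ng, m, cell_volume, v),
    uptake$material, uptake$ng_per_cell, via)
  fits <- do.call(rbind, lapply(split(uptake, uptake$material), function(d) {
    f <- fit_uptake(d$conc_ug_mL, d$ng_per_cell)
    data.frame(material = d$material[1], A = f$A, B = f$B, p = f$p,
               converged = f$converged)
  }))
  rownames(fits) <- NULL
  list(per_cell = uptake, fits = fits)
}
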