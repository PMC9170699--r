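#' Photon spectra
#'
#' A `photon_spectrum` is a discrete fluence spectrum: a strictly increasing
#' energy grid (keV) with nonnegative relative weights, normalized to sum 1.
#'
#' @param energies Energies in keV, strictly increasing, within (1, 20000).
#' @param weights Relative fluence per bin, nonnegative, not all zero.
#' @param id Optional label.
#' @return A `photon_spectrum` object.
#' @examples
#' mono <- photon_spectrum(100, 1)
#' kv <- load_spectrum("kv150")
#' @export
photon_spectrum <- function(energies, weights, id = "custom") {
  if (length(energies) != length(weights) || length(energies) == 0L)
    stop_format("energies and weights must be equal-length, non-empty")
  if (any(!is.finite(energies)) || any(!is.finite(weights)))
    stop_format("energies and weights must be finite")
  if (is.unsorted(energies, strictly = TRUE))
    stop_format("energies must be strictly increasing")
  if (any(energies <= 1) || any(energies >= 20000))
    stop_format("energies must lie within (1, 20000) keV")
  if (any(weights < 0)) stop_format("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop_format("weights must not all be zero")
  structure(list(energies = energies, weights = weights / s, id = id),
            class = "photon_spectrum")
}

#' @export
print.photon_spectrum <- function(x, ...) {
  cat("<photon_spectrum> ", x$id, ": ", length(x$energies), " bins, ",
      format(min(x$energies)), "-", format(max(x$energies)), " keV, ",
      "mean ", round(sum(x$energies * x$weights), 1), " keV\n", sep = "")
  invisible(x)
}

#' Load a photon spectrum from file or built-in
#'
#' Files are headered two-column CSVs (`energy_keV,weight`). Two built-ins
#' are provided:
#' \describe{
#'   \item{`kv150`}{A 150 kV tube spectrum from a filtered Kramers-law
#'     model: bremsstrahlung `(E_max - E)/E` hardened by the inherent
#'     filtration plus 3 cm of PMMA phantom material (water-equivalent
#'     attenuation, 3.57 g/cm^2). Maximum energy 150 keV.}
#'   \item{`mv6`}{A coarse tabulation of the in-phantom photon fluence shape
#'     of a 6 MV linac beam (bins 250 keV - 6 MeV, mode near 500 keV).}
#' }
#'
#' @param source Path to a CSV file, or `"kv150"` / `"mv6"`.
#' @return A [photon_spectrum()].
#' @export
load_spectrum <- function(source) {
  if (source %in% c("kv150", "mv6")) return(.builtin_spectrum(source))
  if (!file.exists(source)) stop_format("spectrum file not found: ", source)
  df <- utils::read.csv(source)
  need <- c("energy_keV", "weight")
  if (!all(need %in% names(df)))
    stop_format("spectrum CSV must have columns ",
                paste(need, collapse = ", "))
  if (!is.numeric(df$energy_keV) || !is.numeric(df$weight))
    stop_format("spectrum columns must be numeric")
  photon_spectrum(df$energy_keV, df$weight, id = basename(source))
}

.builtin_spectrum <- function(id) {
  if (id == "kv150") {
    E <- seq(12, 150, by = 2)
    raw <- (150 - E) / E
    # 3 cm PMMA (rho 1.19) treated as water-equivalent; the 7 mm Be window
    # is essentially transparent above ~12 keV.
    filt <- exp(-.mu_rho_water_atten(E) * 3 * 1.19)
    w <- raw * filt
    keep <- w > max(w) * 1e-8
    photon_spectrum(E[keep], w[keep], id = "kv150")
  } else {
    # In-phantom fluence: bremsstrahlung bulk plus the low-energy
    # phantom-scatter tail below ~250 keV.
    E <- c(100, 150, 200, 250, 400, 500, 650, 800, 1000, 1250, 1500, 1750,
           2000, 2500, 3000, 3500, 4000, 4500, 5000, 5500, 6000)
    w <- c(0.010, 0.018, 0.030, 0.055, 0.105, 0.120, 0.125, 0.120, 0.110,
           0.095, 0.078, 0.062, 0.048, 0.032, 0.020, 0.012, 0.008, 0.005,
           0.003, 0.0015, 0.0005)
    photon_spectrum(E, w, id = "mv6")
  }
}

#' Spectrum-averaged mass energy-absorption coefficient
#'
#' Dose in a thin detector is proportional to energy fluence times
#' mu_en/rho, so the default average weights each bin by fluence times
#' energy (`"energy_fluence"`); plain `"fluence"` weighting is available
#' for comparison.
#'
#' @param material A [material_spec()] or registry name.
#' @param spectrum A [photon_spectrum()].
#' @param weighting `"energy_fluence"` (default) or `"fluence"`.
#' @return Scalar averaged mu_en/rho in cm^2/g.
#' @export
spectrum_mean_mu <- function(material, spectrum,
                             weighting = c("energy_fluence", "fluence")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(spectrum, "photon_spectrum"))
  mu <- mu_en_rho(material, spectrum$energies)
  wt <- if (weighting == "energy_fluence")
    spectrum$weights * spectrum$energies else spectrum$weights
  sum(wt * mu) / sum(wt)
}

#' Analytic macroscopic dose-enhancement factor
#'
#' The homogeneous-mixture estimate of the dose-enhancement factor for a
#' mass fraction `f_mass` of material dispersed in water:
#' \describe{
#'   \item{`as_printed`}{`DEF = 1 + f * <mu_Z> / <mu_w>` — the conventional
#'     reported form (always >= 1).}
#'   \item{`mixture`}{`DEF = 1 + f * (<mu_Z>/<mu_w> - 1)` — the exact
#'     two-component mixture rule; can fall below 1 for materials whose
#'     averaged coefficient is below water's (low-Z materials at MV
#'     energies), which is physical and not clamped.}
#' }
#' `<...>` is the spectrum-averaged coefficient of [spectrum_mean_mu()].
#'
#' @param material A [material_spec()] or registry name.
#' @param f_mass Mass fraction of the material in the mixture, in `[0, 1]`.
#' @param spectrum A [photon_spectrum()].
#' @param mode `"as_printed"` (default) or `"mixture"`.
#' @param weighting Passed to [spectrum_mean_mu()].
#' @return Scalar DEF; exactly 1 at `f_mass = 0`.
#' @examples
#' macroscopic_def("Au", 0.05, load_spectrum("kv150"))
#' @export
macroscopic_def <- function(material, f_mass, spectrum,
                            mode = c("as_printed", "mixture"),
                            weighting = c("energy_fluence", "fluence")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  if (!is.numeric(f_mass) || any(f_mass < 0 | f_mass > 1))
    stop_domain("f_mass must lie in [0, 1]")
  ratio <- spectrum_mean_mu(material, spectrum, weighting) /
    spectrum_mean_mu("water", spectrum, weighting)
  if (mode == "as_printed") 1 + f_mass * ratio else 1 + f_mass * (ratio - 1)
}

#' Dose-enhancement efficiency per volume-fraction percent
#'
#' Fits `DEF - 1 = chi * f_vol` by least squares with the intercept fixed
#' at zero (no nanoparticles, no enhancement), giving the enhancement
#' efficiency chi in DEF-excess per volume percent, with a symmetric 95%
#' confidence half-width from the t distribution on `n - 1` degrees of
#' freedom.
#'
#' @param def_values DEF values (>= 0), one per volume fraction.
#' @param vol_fractions Nanoparticle volume fractions in vol%, nonnegative,
#'   not all zero; at least two points.
#' @param compartment Optional label (`"cytoplasm"`, `"nucleus"`,
#'   `"vesicle"`).
#' @return List of class `enhancement_efficiency` with elements `chi`,
#'   `ci95`, `n`, `compartment`.
#' @examples
#' chi_fit(c(1.5, 2.0, 3.0), c(0.1, 0.2, 0.4))
#' @export
chi_fit <- function(def_values, vol_fractions, compartment = NA_character_) {
  if (length(def_values) != length(vol_fractions) || length(def_values) < 2)
    stop_domain("need >= 2 matched (DEF, f_vol) points")
  if (any(vol_fractions < 0)) stop_domain("vol_fractions must be >= 0")
  if (all(vol_fractions == 0))
    stop_domain("degenerate design: all volume fractions are zero")
  y <- def_values - 1
  x <- vol_fractions
  chi <- sum(x * y) / sum(x^2)
  n <- length(x)
  resid <- y - chi * x
  se <- if (n > 1) sqrt(sum(resid^2) / (n - 1) / sum(x^2)) else NA_real_
  ci95 <- stats::qt(0.975, df = n - 1) * se
  structure(list(chi = chi, ci95 = ci95, n = n, compartment = compartment),
            class = "enhancement_efficiency")
}

#' @export
print.enhancement_efficiency <- function(x, ...) {
  cat("<enhancement_efficiency> chi =", signif(x$chi, 4), "+/-",
      signif(x$ci95, 3), "(95% CI) per vol%",
      if (!is.na(x$compartment)) paste0("[", x$compartment, "]"), "\n")
  invisible(x)
}
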