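# Seeded synthetic-data generators emulating every experimental input of
# the study design, so the full pipeline is testable without measurements.
# All generators are pure functions of their configuration (which includes
# the seed).

#' Synthetic-experiment configuration
#'
#' Ground-truth parameters and design constants for the generators. The
#' defaults encode the study conditions: 2000 cells seeded per well growing
#' to ~2e4 by readout, doses {0, 2, 4, 6, 8} Gy, triplicate nanoparticle
#' wells and sextuplicate controls on the inner 24 wells of a 48-well
#' plate, DMSO grid {0, 0.11, 0.334, 0.667, 1} M, multiplicative lognormal
#' plate-reader noise with CV 5%, and per-material truths: the reference
#' no-DMSO enhancement ratios at 6 Gy (from which the dose-scaling factors
#' k, the ground-truth DMRs, are solved), indirect-damage fractions phi,
#' and sham-toxicity LC50s. The control LQ truth (alpha0 = 0.04/Gy,
#' beta0 = 0.0013/Gy^2) reproduces a control surviving fraction of ~0.75
#' at 6 Gy.
#'
#' @param seed Integer seed; every generator output is reproducible from it.
#' @param alpha0,beta0 Control LQ truth (1/Gy, 1/Gy^2).
#' @param cells0 Expected unirradiated control cell count at readout.
#' @param doses Dose design in Gy.
#' @param cv Multiplicative lognormal noise CV for plate readers.
#' @param n_batches Independent cell batches.
#' @param materials data.frame of per-material truths: `material`,
#'   `conc_ug_mL`, `ner` (no-DMSO enhancement ratio at 6 Gy), `phi`
#'   (DMSO-quenchable fraction of the enhancement), `lc50` (ug/mL),
#'   `b_tox` (sigmoid steepness 1/(ug/mL)).
#' @param dmso_grid DMSO concentrations in M.
#' @param psi_control Fraction of baseline (no-nanoparticle) radiation
#'   damage removed by saturating DMSO.
#' @param dmso_tau Saturation constant (M) of the protection curve, which
#'   reaches its plateau at 0.5 M.
#' @param curve [standard_curve()] used in both directions.
#' @param ros_sa_concs,ros_n_rep,ros_fi0,ros_blank_gain ROS plate design:
#'   surface-area concentrations (cm^2/mL), replicates, baseline
#'   fluorescence and blank radiolysis gain (arbitrary units).
#' @param ros_slopes data.frame `material`, `beam`, `slope`: true DEF_ROS
#'   slope per surface-area concentration. Defaults follow the observed
#'   ordering WO3 > TiO2 > HfO2 at kV, TiO2 ~ WO3 > HfO2 at MV and proton,
#'   with the HfO2 efficiencies scaling ~1:2:4 (proton:MV:kV).
#' @param uptake data.frame `material`, `A` (ng/cell), `B` (ug/mL), `p`;
#'   W is two orders of magnitude lower than the others (dissolution).
#' @param uptake_conc,uptake_n_rep,uptake_cv Uptake design.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1,
    alpha0 = 0.04, beta0 = 0.0013,
    cells0 = 2e4,
    doses = c(0, 2, 4, 6, 8),
    cv = 0.05,
    n_batches = 2,
    materials = data.frame(
      material = c("SiO2", "TiO2", "TiN", "WO3", "HfO2", "Au"),
      conc_ug_mL = c(160, 160, 80, 160, 320, 40),
      ner = c(1.0, 2.0, 1.3, 1.6, 2.1, 1.6),
      phi = c(0, 0.73, 1.0, 0, 0.52, 0.34),
      lc50 = c(1500, 2000, 157, 1200, 3000, 2500),
      b_tox = 0.025),
    dmso_grid = c(0, 0.11, 0.334, 0.667, 1),
    psi_control = 0.6,
    dmso_tau = 0.15,
    curve = standard_curve(),
    ros_sa_concs = c(36.8, 368, 1840),
    ros_n_rep = 6,
    ros_fi0 = 100,
    ros_blank_gain = 200,
    ros_slopes = data.frame(
      material = rep(c("SiO2", "TiO2", "TiN", "WO3", "HfO2"), 3),
      beam = rep(c("kv", "mv", "proton"), each = 5),
      slope = c(0, 5e-4, 0, 8e-4, 2.5e-4,
                0, 5e-4, 0, 4e-4, 1.25e-4,
                0, 2e-4, 0, 2e-4, 0.625e-4)),
    uptake = data.frame(
      material = c("SiO2", "TiO2", "TiN", "WO3", "HfO2", "Au"),
      A = c(1.2, 1.2, 1.0, 0.012, 1.2, 1.0),
      B = c(40, 40, 40, 40, 40, 40),
      p = c(2, 2, 2, 2, 2, 2)),
    uptake_conc = c(20, 40, 80, 160, 320),
    uptake_n_rep = 4,
    uptake_cv = 0.15) {
  if (any(materials$ner < 1)) stop_domain("reference NER must be >= 1")
  if (any(materials$phi < 0 | materials$phi > 1))
    stop_domain("phi must lie in [0, 1]")
  if (cv < 0 || uptake_cv < 0) stop_domain("CVs must be >= 0")
  materials$k <- vapply(materials$ner, .k_from_ner,
                        numeric(1), alpha0 = alpha0, beta0 = beta0)
  structure(list(
    seed = seed, alpha0 = alpha0, beta0 = beta0, cells0 = cells0,
    doses = doses, cv = cv, n_batches = n_batches, materials = materials,
    dmso_grid = dmso_grid, psi_control = psi_control, dmso_tau = dmso_tau,
    curve = curve, ros_sa_concs = ros_sa_concs, ros_n_rep = ros_n_rep,
    ros_fi0 = ros_fi0, ros_blank_gain = ros_blank_gain,
    ros_slopes = ros_slopes, uptake = uptake, uptake_conc = uptake_conc,
    uptake_n_rep = uptake_n_rep, uptake_cv = uptake_cv
  ), class = "generator_config")
}

# Dose-scaling factor k reproducing a target enhancement ratio at 6 Gy:
# exp(alpha*6(k-1) + beta*36(k^2-1)) = ner.
.k_from_ner <- function(ner, alpha0, beta0) {
  if (ner == 1) return(1)
  rhs <- log(ner) + 6 * alpha0 + 36 * beta0
  if (beta0 == 0) return(rhs / (6 * alpha0))
  (-6 * alpha0 + sqrt(36 * alpha0^2 + 4 * 36 * beta0 * rhs)) /
    (2 * 36 * beta0)
}

# DMSO protection curve: saturating, exactly 1 from 0.5 M on.
.dmso_protection <- function(dmso_M, tau) {
  pmin(1, (1 - exp(-dmso_M / tau)) / (1 - exp(-0.5 / tau)))
}

.lq_sf <- function(D, alpha, beta) exp(-(alpha * D + beta * D^2))

.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

.sham_viability <- function(conc, lc50, b) {
  a <- exp(b * lc50)
  1 - 1 / (1 + a * exp(-b * conc))
}

#' Generate a synthetic survival plate table
#'
#' Forward-simulates the in-vitro experiment: expected cell counts are
#' `cells0 * viability(conc) * SF(k_eff * d(dmso) * D)` with the control
#' LQ truth, the per-material dose-scaling factor k (the ground-truth
#' DMR), DMSO dose-sparing `d(c) = 1 - psi_control * P(c)` for every well
#' and `k_eff(c) = 1 + (k - 1) * (1 - phi * P(c))` scaling only the
#' nanoparticle-attributable enhancement; counts are pushed through the
#' luminescence standard curve and multiplicative lognormal noise.
#'
#' @param cfg A [generator_config()].
#' @param design `"dose_response"`: full dose grid, no DMSO, triplicate
#'   nanoparticle wells and sextuplicate controls per batch;
#'   `"quench"`: doses {0, reference}, the DMSO grid, quadruplicates.
#' @param reference_dose Fixed dose of the quench design (6 Gy).
#' @return data.frame with columns `batch`, `material`, `conc_ug_mL`,
#'   `dose_Gy`, `dmso_M`, `replicate`, `luminescence` — the schema
#'   [run_survival_pipeline()] consumes.
#' @examples
#' plate <- gen_survival_plate(generator_config(seed = 7, cv = 0))
#' @export
gen_survival_plate <- function(cfg,
                               design = c("dose_response", "quench"),
                               reference_dose = 6) {
  design <- match.arg(design)
  stopifnot(inherits(cfg, "generator_config"))
  mats <- cfg$materials
  rows <- list()
  if (design == "dose_response") {
    dmso <- 0
    doses <- cfg$doses
    for (b in seq_len(cfg$n_batches)) {
      for (i in c(0, seq_len(nrow(mats)))) {    # 0 = control
        nrep <- if (i == 0) 6 else 3
        m <- if (i == 0) "none" else mats$material[i]
        cc <- if (i == 0) 0 else mats$conc_ug_mL[i]
        for (D in doses) rows[[length(rows) + 1]] <- data.frame(
          batch = b, material = m, conc_ug_mL = cc, dose_Gy = D,
          dmso_M = dmso, replicate = seq_len(nrep))
      }
    }
  } else {
    for (b in seq_len(cfg$n_batches)) {
      for (i in c(0, seq_len(nrow(mats)))) {
        m <- if (i == 0) "none" else mats$material[i]
        cc <- if (i == 0) 0 else mats$conc_ug_mL[i]
        for (dm in cfg$dmso_grid) for (D in c(0, reference_dose))
          rows[[length(rows) + 1]] <- data.frame(
            batch = b, material = m, conc_ug_mL = cc, dose_Gy = D,
            dmso_M = dm, replicate = seq_len(4))
      }
    }
  }
  out <- do.call(rbind, rows)
  # expected counts
  idx <- match(out$material, mats$material)       # NA for control
  is_np <- !is.na(idx)
  k <- ifelse(is_np, mats$k[idx], 1)
  phi <- ifelse(is_np, mats$phi[idx], 0)
  ner0 <- ifelse(is_np, mats$ner[idx], 1)
  via <- ifelse(is_np,
                .sham_viability(out$conc_ug_mL,
                                mats$lc50[ifelse(is_np, idx, 1)],
                                mats$b_tox[ifelse(is_np, idx, 1)]),
                1)
  P <- .dmso_protection(out$dmso_M, cfg$dmso_tau)
  d_spare <- 1 - cfg$psi_control * P
  # Without DMSO, nanoparticles scale the dose by k. With DMSO the baseline
  # dose is spared by d(c) and the nanoparticle-attributable enhancement
  # ratio at the reference dose scales to 1 + (NER0 - 1)(1 - phi P(c));
  # survival in DMSO-bearing nanoparticle wells is constructed from that
  # target ratio (exact at 0 Gy and the reference dose, the quench design).
  sf <- .lq_sf(out$dose_Gy * d_spare, cfg$alpha0, cfg$beta0)
  no_dmso_np <- is_np & out$dmso_M == 0
  sf[no_dmso_np] <- .lq_sf(out$dose_Gy[no_dmso_np] * k[no_dmso_np],
                           cfg$alpha0, cfg$beta0)
  dmso_np <- is_np & out$dmso_M > 0
  ner_t <- 1 + (ner0 - 1) * (1 - phi * P)
  sf[dmso_np] <- sf[dmso_np] /
    ner_t[dmso_np]^(out$dose_Gy[dmso_np] / reference_dose)
  cells <- cfg$cells0 * via * sf
  out$luminescence <- with_seed(cfg$seed, {
    .cells_to_luminescence(cells, cfg$curve) * .lognoise(nrow(out), cfg$cv)
  })
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ROS plate
#'
#' Paired 0 Gy / 12 Gy DCF fluorescence wells: the radiation-induced gain
#' of blank wells is `ros_blank_gain`; nanoparticle wells gain
#' `ros_blank_gain * (1 + slope * sa_conc)`, i.e. the true DEF_ROS grows
#' linearly in surface-area concentration.
#'
#' @param cfg A [generator_config()].
#' @param beam `"kv"`, `"mv"` or `"proton"` (selects the slope truth).
#' @param dose_Gy Irradiated-plate dose (12 Gy).
#' @return data.frame `material`, `sa_conc_cm2_mL`, `dose_Gy`,
#'   `replicate`, `fi` — the schema [analyze_ros_plate()] consumes.
#' @export
gen_ros_plate <- function(cfg, beam = c("kv", "mv", "proton"),
                          dose_Gy = 12) {
  beam <- match.arg(beam)
  stopifnot(inherits(cfg, "generator_config"))
  sl <- cfg$ros_slopes[cfg$ros_slopes$beam == beam, ]
  rows <- list()
  for (m in c("none", unique(sl$material))) {
    scs <- if (m == "none") 0 else cfg$ros_sa_concs
    for (sc in scs) {
      slope <- if (m == "none") 0 else sl$slope[sl$material == m]
      gain <- cfg$ros_blank_gain * (1 + slope * sc)
      for (D in c(0, dose_Gy)) rows[[length(rows) + 1]] <- data.frame(
        material = m, sa_conc_cm2_mL = sc, dose_Gy = D,
        replicate = seq_len(cfg$ros_n_rep),
        fi_expected = cfg$ros_fi0 + if (D > 0) gain else 0)
    }
  }
  out <- do.call(rbind, rows)
  out$fi <- with_seed(cfg$seed + 1000L,
                      out$fi_expected * .lognoise(nrow(out), cfg$cv))
  out$fi_expected <- NULL
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ICP-MS uptake table
#'
#' Per-cell metal masses follow the Hill-type saturation truth per
#' material; well totals are per-cell mass times the pooled cell count.
#'
#' @param cfg A [generator_config()].
#' @param cells_counted Pooled hemocytometer count per replicate.
#' @return data.frame `material`, `conc_ug_mL`, `replicate`,
#'   `metal_ng_total`, `cells_counted` — the schema
#'   [analyze_uptake_table()] consumes.
#' @export
gen_uptake_table <- function(cfg, cells_counted = 3e4) {
  stopifnot(inherits(cfg, "generator_config"))
  up <- cfg$uptake
  grid <- expand.grid(replicate = seq_len(cfg$uptake_n_rep),
                      conc_ug_mL = cfg$uptake_conc,
                      material = up$material,
                      stringsAsFactors = FALSE)
  i <- match(grid$material, up$material)
  mu <- up$A[i] * grid$conc_ug_mL^up$p[i] /
    (up$B[i]^up$p[i] + grid$conc_ug_mL^up$p[i])
  ng_cell <- with_seed(cfg$seed + 2000L,
                       mu * .lognoise(nrow(grid), cfg$uptake_cv))
  data.frame(material = grid$material, conc_ug_mL = grid$conc_ug_mL,
             replicate = grid$replicate,
             metal_ng_total = ng_cell * cells_counted,
             cells_counted = cells_counted)
}

#' Generate a small spectrum fixture
#'
#' A three-line test spectrum, optionally written as a spectrum CSV.
#'
#' @param path Optional file path to write `energy_keV,weight` CSV.
#' @return A [photon_spectrum()] (invisibly when written to file).
#' @export
gen_spectrum_fixture <- function(path = NULL) {
  sp <- photon_spectrum(c(30, 60, 120), c(1, 2, 1), id = "fixture")
  if (!is.null(path)) {
    utils::write.csv(data.frame(energy_keV = sp$energies,
                                weight = sp$weights),
                     path, row.names = FALSE)
    return(invisible(sp))
  }
  sp
}
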