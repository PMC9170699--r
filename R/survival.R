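# In-vitro survival analysis: luminescence -> cell counts -> surviving
# fractions -> linear-quadratic fits -> LD50 -> dose-modifying ratios,
# plus sigmoid sham-toxicity with the 60% inclusion cutoff and the DMSO
# radical-quenching decomposition (NER / DoP).

#' Luminescence standard curve
#'
#' Parameters of the CellTiter-Glo standard curve converting luminescence
#' counts to cell numbers. Two algebraic forms are supported:
#' `"as_printed"`, the linear conversion `cells = y * b / (a - b)`, and
#' `"saturation"`, the rectangular-hyperbola inversion
#' `cells = y * b / (a - y)` that treats `a` as the luminescence plateau.
#' The defaults are the fitted values of the reference experiment
#' (a = 3.872e6, b = 3.431e5).
#'
#' @param a,b Curve parameters (luminescence and count scales).
#' @param form `"as_printed"` (default) or `"saturation"`.
#' @return A `standard_curve` object.
#' @export
standard_curve <- function(a = 3.872e6, b = 3.431e5,
                           form = c("as_printed", "saturation")) {
  form <- match.arg(form)
  check_scalar_positive(a, "a")
  check_scalar_positive(b, "b")
  if (form == "as_printed" && a <= b)
    stop_domain("as_printed form requires a > b")
  structure(list(a = a, b = b, form = form), class = "standard_curve")
}

#' Convert luminescence to cell counts
#'
#' @param y Luminescence counts (nonnegative; `saturation` form requires
#'   `y < a`).
#' @param curve A [standard_curve()].
#' @return Cell counts, nonnegative and monotone in `y`.
#' @examples
#' luminescence_to_cells(1e5, standard_curve())
#' @export
luminescence_to_cells <- function(y, curve = standard_curve()) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(y < 0)) stop_domain("luminescence must be nonnegative")
  if (curve$form == "as_printed") {
    y * curve$b / (curve$a - curve$b)
  } else {
    if (any(y >= curve$a))
      stop_domain("luminescence at or above the saturation plateau a")
    y * curve$b / (curve$a - y)
  }
}

# Forward direction, used by the synthetic generator.
.cells_to_luminescence <- function(cells, curve = standard_curve()) {
  if (curve$form == "as_printed") {
    cells * (curve$a - curve$b) / curve$b
  } else {
    curve$a * cells / (curve$b + cells)
  }
}

#' Surviving fraction
#'
#' Ratio of cell counts after dose to the unirradiated count of the same
#' condition. Values above 1 are retained (not clipped) to keep downstream
#' estimators unbiased; they are only flagged in pipeline QC.
#'
#' @param cells_dose Cell count (or vector) at dose.
#' @param cells_0gy Unirradiated cell count (> 0).
#' @return `cells_dose / cells_0gy`.
#' @export
surviving_fraction <- function(cells_dose, cells_0gy) {
  if (any(cells_0gy <= 0))
    stop_domain("unirradiated cell count must be positive")
  cells_dose / cells_0gy
}

#' Dose at 50% survival for a linear-quadratic model
#'
#' Solves `alpha * D + beta * D^2 = ln 2`. Continuous in `beta` at 0.
#'
#' @param alpha Linear coefficient (1/Gy), >= 0.
#' @param beta Quadratic coefficient (1/Gy^2), >= 0.
#' @return Dose in Gy.
#' @examples
#' ld50(log(2) / 2, 0)  # 2 Gy
#' @export
ld50 <- function(alpha, beta) {
  if (alpha < 0 || beta < 0) stop_domain("alpha and beta must be >= 0")
  if (alpha == 0 && beta == 0)
    stop_domain("ld50 undefined for alpha = beta = 0")
  l2 <- log(2)
  # rationalized root: numerically stable as beta -> 0, where the naive
  # (-a + sqrt(a^2 + 4 b ln2)) / (2 b) form cancels catastrophically
  2 * l2 / (alpha + sqrt(alpha^2 + 4 * beta * l2))
}

#' Fit the linear-quadratic survival model
#'
#' Unweighted nonlinear least squares of `SF = exp(-(alpha*D + beta*D^2))`
#' on the survival scale, with `alpha, beta >= 0` enforced. Starting values
#' come from the log-linear regression of `-log SF` on `(D, D^2)` plus a
#' fixed fallback start (0.1, 0.01); the better converged fit wins.
#' Noise-free LQ data is recovered to numerical precision.
#'
#' @param doses Doses in Gy, >= 3 distinct levels including 0.
#' @param sf Surviving fractions (> 0), same length as `doses`; replicates
#'   are passed as repeated dose entries.
#' @return An `lq_fit`: list with `alpha`, `beta`, `cov` (2x2, NA for
#'   boundary fits), `ld50` (Inf when alpha = beta = 0), `extrapolated`
#'   (TRUE when ld50 exceeds the largest design dose), `doses`,
#'   `residual_ss`.
#' @examples
#' d <- rep(c(0, 2, 4, 6, 8), each = 3)
#' fit_lq(d, exp(-(0.2 * d + 0.03 * d^2)))
#' @export
fit_lq <- function(doses, sf) {
  if (length(doses) != length(sf))
    stop_domain("doses and sf must have equal length")
  if (length(unique(doses)) < 3 || !any(doses == 0))
    stop_domain("need >= 3 dose levels including 0 Gy")
  if (any(sf <= 0)) stop_domain("surviving fractions must be positive")
  df <- data.frame(D = doses, sf = sf)
  # log-linear seed (clamped to the admissible quadrant)
  ll <- stats::lm(I(-log(sf)) ~ 0 + D + I(D^2), data = df)
  s1 <- pmax(unname(stats::coef(ll)), 0)
  starts <- list(c(alpha = s1[1], beta = s1[2]),
                 c(alpha = 0.1, beta = 0.01))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(sf ~ exp(-(alpha * D + beta * D^2)),
                        data = df, start = as.list(st),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop(structure(class = c("radnano_fit_error", "error", "condition"),
                   list(message = paste0(
                     "LQ fit did not converge (n = ", nrow(df),
                     ", SF range ", signif(min(sf), 3), "-",
                     signif(max(sf), 3), ")"), call = sys.call())))
  cf <- stats::coef(best$fit)
  alpha <- max(unname(cf["alpha"]), 0)
  beta <- max(unname(cf["beta"]), 0)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e)
    matrix(NA_real_, 2, 2))
  l50 <- if (alpha == 0 && beta == 0) Inf else ld50(alpha, beta)
  structure(list(alpha = alpha, beta = beta, cov = vc,
                 doses = sort(unique(doses)), ld50 = l50,
                 extrapolated = !is.finite(l50) || l50 > max(doses),
                 residual_ss = best$rss),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("<lq_fit> alpha =", signif(x$alpha, 4), "/Gy, beta =",
      signif(x$beta, 4), "/Gy^2, LD50 =", signif(x$ld50, 4), "Gy",
      if (x$extrapolated) "(extrapolated)", "\n")
  invisible(x)
}

#' Dose-modifying ratio at 50% survival
#'
#' `DMR_50% = LD50(without nanoparticles) / LD50(with nanoparticles)`.
#'
#' @param lq_control,lq_np [fit_lq()] results without / with nanoparticles.
#' @return List with `dmr50` (NA when undefined), `ld50_control`,
#'   `ld50_np`, `defined` (FALSE when either LD50 is infinite),
#'   `extrapolated` (TRUE when either fit extrapolates beyond its design).
#' @export
dmr50 <- function(lq_control, lq_np) {
  stopifnot(inherits(lq_control, "lq_fit"), inherits(lq_np, "lq_fit"))
  defined <- is.finite(lq_control$ld50) && is.finite(lq_np$ld50)
  list(dmr50 = if (defined) lq_control$ld50 / lq_np$ld50 else NA_real_,
       ld50_control = lq_control$ld50, ld50_np = lq_np$ld50,
       defined = defined,
       extrapolated = lq_control$extrapolated || lq_np$extrapolated)
}

#' Sham-irradiation viability and sigmoid toxicity fit
#'
#' `normalized_viability` is the 0 Gy cell count with nanoparticles over
#' the 0 Gy control count. `fit_toxicity` fits the sigmoid
#' `viability = 1 - 1/(1 + a * exp(-b * x))` by least squares and reports
#' `lc50 = log(a) / b` (the concentration at 50% viability, infinite when
#' the curve never crosses 0.5 within reach), plus the per-concentration
#' inclusion flag `viability >= cutoff` used to gate DMR analyses.
#'
#' @param cells_np_0gy,cells_ctrl_0gy Unirradiated counts with / without
#'   nanoparticles.
#' @return `normalized_viability`: the ratio.
#' @export
normalized_viability <- function(cells_np_0gy, cells_ctrl_0gy) {
  surviving_fraction(cells_np_0gy, cells_ctrl_0gy)
}

#' @rdname normalized_viability
#' @param conc Nanoparticle concentrations (ug/mL), >= 3 distinct levels.
#' @param viability Normalized viabilities in (0, 1.5].
#' @param cutoff Inclusion cutoff (default 0.60).
#' @return `fit_toxicity`: list with `a`, `b`, `lc50`, `converged`, and a
#'   data.frame `inclusion` (conc, mean viability, included flag). When the
#'   sigmoid fit fails, `a`, `b`, `lc50` are NA and raw viabilities are
#'   still reported.
#' @examples
#' v <- 1 - 1 / (1 + exp(2) * exp(-0.01 * c(0, 50, 150, 300)))
#' fit_toxicity(c(0, 50, 150, 300), v)
#' @export
fit_toxicity <- function(conc, viability, cutoff = 0.60) {
  if (length(conc) != length(viability))
    stop_domain("conc and viability must have equal length")
  if (length(unique(conc)) < 3)
    stop_domain("need >= 3 concentration levels")
  if (any(viability <= 0 | viability > 1.5))
    stop_domain("viability must lie in (0, 1.5]")
  vbar <- tapply(viability, conc, mean)
  inclusion <- data.frame(conc = as.numeric(names(vbar)),
                          viability = as.numeric(vbar),
                          included = as.numeric(vbar) >= cutoff,
                          row.names = NULL)
  # logit-linear seed
  vc <- pmin(pmax(viability, 1e-6), 1 - 1e-6)
  sl <- stats::lm(log(vc / (1 - vc)) ~ conc)
  st <- list(a = exp(unname(stats::coef(sl)[1])),
             b = max(-unname(stats::coef(sl)[2]), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(viability ~ 1 - 1 / (1 + a * exp(-b * conc)),
                      data = data.frame(conc = conc,
                                        viability = viability),
                      start = st, lower = c(1e-12, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # a flat, fully viable series has no 50% crossing to fit
    lc <- if (all(inclusion$viability >= 0.5)) Inf else NA_real_
    return(list(a = NA_real_, b = NA_real_, lc50 = lc,
                converged = FALSE, inclusion = inclusion))
  }
  cf <- stats::coef(fit)
  a <- unname(cf["a"]); b <- unname(cf["b"])
  lc50 <- if (a > 1 && b > 0) log(a) / b else Inf
  list(a = a, b = b, lc50 = lc50, converged = TRUE, inclusion = inclusion)
}

#' Monodose nanoparticle enhancement ratio and degree of DMSO protection
#'
#' `ner` is the fixed-dose (6 Gy) enhancement ratio
#' `SF(control) / SF(nanoparticles)`. `dop` decomposes the enhancement
#' into its hydroxyl-radical-mediated ("indirect") part:
#' `DoP = 1 - (NER_DMSO - 1) / (NER_noDMSO - 1)`,
#' 0 when DMSO changes nothing and 1 at full protection. It is undefined
#' (NA with a warning) when there is no enhancement to protect against
#' (`NER_noDMSO <= 1`), and is invariant under rescaling all four
#' surviving fractions by a common factor.
#'
#' @param sf_ctrl,sf_np Surviving fractions at the reference dose without /
#'   with nanoparticles (> 0).
#' @return `ner`: the ratio.
#' @examples
#' ner(0.75, 0.375)        # 2.0
#' dop_from_ner(1.3, 2.0)  # 0.70
#' @export
ner <- function(sf_ctrl, sf_np) {
  if (any(sf_ctrl <= 0) || any(sf_np <= 0))
    stop_domain("surviving fractions must be positive")
  sf_ctrl / sf_np
}

#' @rdname ner
#' @param sf_dmso_ctrl,sf_dmso_np,sf_nodmso_ctrl,sf_nodmso_np The four
#'   surviving fractions at the reference dose.
#' @export
dop <- function(sf_dmso_ctrl, sf_dmso_np, sf_nodmso_ctrl, sf_nodmso_np) {
  dop_from_ner(ner(sf_dmso_ctrl, sf_dmso_np),
               ner(sf_nodmso_ctrl, sf_nodmso_np))
}

#' @rdname ner
#' @param ner_dmso,ner_nodmso Enhancement ratios with / without DMSO.
#' @export
dop_from_ner <- function(ner_dmso, ner_nodmso) {
  out <- 1 - (ner_dmso - 1) / (ner_nodmso - 1)
  undef <- ner_nodmso <= 1
  if (any(undef)) {
    warning("DoP undefined where NER without DMSO <= 1 ",
            "(no enhancement to protect against)")
    out[undef] <- NA_real_
  }
  out
}

# --- plate-level pipeline ---------------------------------------------------

#' Run the in-vitro survival pipeline on a plate table
#'
#' Takes well-level luminescence data (columns `batch`, `material`,
#' `conc_ug_mL`, `dose_Gy`, `dmso_M`, `replicate`, `luminescence`;
#' control wells have `material = "none"`), converts to cell counts,
#' computes per-condition surviving fractions, fits the LQ model per
#' (batch, material, concentration), derives dose-modifying ratios against
#' the matched control, applies the sham-viability inclusion cutoff, and
#' computes the NER/DoP quenching decomposition for DMSO-bearing wells at
#' the reference dose.
#'
#' @param plate A data.frame as described (see [read_plate()]).
#' @param curve A [standard_curve()].
#' @param cutoff Sham-viability inclusion cutoff (default 0.60).
#' @param reference_dose Dose for NER/DoP (default 6 Gy).
#' @return List of data.frames: `lq_fits` (batch, material, conc, alpha,
#'   beta, ld50, extrapolated), `dmr` (material, conc, dmr50, sd across
#'   batches, viability, included), `toxicity` (per material: a, b, lc50),
#'   `quench` (material, conc, dmso_M, ner, dop), and `qc` notes.
#' @export
run_survival_pipeline <- function(plate, curve = standard_curve(),
                                  cutoff = 0.60, reference_dose = 6) {
  .check_plate_columns(plate, c("batch", "material", "conc_ug_mL",
                                "dose_Gy", "dmso_M", "replicate",
                                "luminescence"))
  plate$cells <- luminescence_to_cells(plate$luminescence, curve)
  qc <- character(0)
  base <- plate[plate$dmso_M == 0, ]

  # per-condition mean cell counts and surviving fractions
  sf_of <- function(d) {
    m0 <- mean(d$cells[d$dose_Gy == 0])
    ag <- stats::aggregate(cells ~ dose_Gy, data = d, FUN = mean)
    data.frame(dose_Gy = ag$dose_Gy, sf = surviving_fraction(ag$cells, m0),
               cells0 = m0)
  }

  conds <- unique(base[c("batch", "material", "conc_ug_mL")])
  lq_rows <- list(); lq_fits <- list()
  for (i in seq_len(nrow(conds))) {
    cd <- conds[i, ]
    d <- base[base$batch == cd$batch & base$material == cd$material &
                base$conc_ug_mL == cd$conc_ug_mL, ]
    if (length(unique(d$dose_Gy)) < 3) next
    # fit on replicate-level SF
    m0 <- mean(d$cells[d$dose_Gy == 0])
    sfr <- surviving_fraction(d$cells, m0)
    if (any(sfr > 1 & d$dose_Gy > 0))
      qc <- c(qc, sprintf("SF > 1 retained: %s/%s/%g ug/mL",
                          cd$batch, cd$material, cd$conc_ug_mL))
    fit <- fit_lq(d$dose_Gy, sfr)
    key <- paste(cd$batch, cd$material, cd$conc_ug_mL, sep = "|")
    lq_fits[[key]] <- fit
    lq_rows[[key]] <- data.frame(
      batch = cd$batch, material = cd$material,
      conc_ug_mL = cd$conc_ug_mL, alpha = fit$alpha, beta = fit$beta,
      ld50 = fit$ld50, extrapolated = fit$extrapolated,
      cells0 = m0)
  }
  lq_df <- .rbind_rows(lq_rows)

  # sham viability per (batch, material, conc) vs matched control
  via <- NULL
  if (!is.null(lq_df)) {
    via <- lq_df[c("batch", "material", "conc_ug_mL")]
    via$viability <- NA_real_
    for (i in seq_len(nrow(via))) {
      ctrl0 <- lq_df$cells0[lq_df$batch == via$batch[i] &
                              lq_df$material == "none"]
      if (length(ctrl0) == 1)
        via$viability[i] <- lq_df$cells0[i] / ctrl0
    }
  }

  # toxicity sigmoids per material (>= 3 concentrations incl. control 0)
  tox_rows <- list()
  if (!is.null(via)) {
    for (m in setdiff(unique(via$material), "none")) {
      vm <- via[via$material == m | via$material == "none", ]
      vm$conc_ug_mL[vm$material == "none"] <- 0
      vm$viability[vm$material == "none"] <- 1
      if (length(unique(vm$conc_ug_mL)) >= 3) {
        tf <- fit_toxicity(vm$conc_ug_mL, vm$viability, cutoff)
        tox_rows[[m]] <- data.frame(material = m, a = tf$a, b = tf$b,
                                    lc50 = tf$lc50,
                                    converged = tf$converged)
      }
    }
  }
  tox_df <- .rbind_rows(tox_rows)

  # DMR per (material, conc): per-batch ratios vs the batch control
  dmr_rows <- list()
  if (!is.null(lq_df)) {
    nps <- unique(lq_df[lq_df$material != "none",
                        c("material", "conc_ug_mL")])
    for (i in seq_len(nrow(nps))) {
      m <- nps$material[i]; cc <- nps$conc_ug_mL[i]
      vals <- c(); via_mc <- c()
      for (b in unique(lq_df$batch)) {
        kc <- paste(b, "none", 0, sep = "|")
        kn <- paste(b, m, cc, sep = "|")
        if (!is.null(lq_fits[[kc]]) && !is.null(lq_fits[[kn]])) {
          r <- dmr50(lq_fits[[kc]], lq_fits[[kn]])
          if (r$defined) vals <- c(vals, r$dmr50)
          via_mc <- c(via_mc, via$viability[via$batch == b &
                                              via$material == m &
                                              via$conc_ug_mL == cc])
        }
      }
      if (length(vals)) {
        vbar <- mean(via_mc, na.rm = TRUE)
        dmr_rows[[paste(m, cc)]] <- data.frame(
          material = m, conc_ug_mL = cc, dmr50 = mean(vals),
          sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
          n_batches = length(vals), viability = vbar,
          included = is.finite(vbar) && vbar >= cutoff)
      }
    }
  }
  dmr_df <- .rbind_rows(dmr_rows)

  # quenching: NER and DoP at the reference dose per (material, conc, dmso)
  quench_df <- NULL
  qd <- plate[plate$dose_Gy %in% c(0, reference_dose), ]
  if (any(qd$dmso_M > 0)) {
    qrows <- list()
    for (m in setdiff(unique(qd$material), "none")) {
      for (cc in unique(qd$conc_ug_mL[qd$material == m])) {
        ners <- c(); dms <- sort(unique(qd$dmso_M))
        for (dm in dms) {
          sf6 <- function(mat, conc) {
            d <- qd[qd$material == mat & qd$conc_ug_mL == conc &
                      qd$dmso_M == dm, ]
            if (!all(c(0, reference_dose) %in% d$dose_Gy)) return(NA_real_)
            mean(d$cells[d$dose_Gy == reference_dose]) /
              mean(d$cells[d$dose_Gy == 0])
          }
          s_ctrl <- sf6("none", 0); s_np <- sf6(m, cc)
          ners <- c(ners, if (is.na(s_ctrl) || is.na(s_np)) NA_real_ else
            ner(s_ctrl, s_np))
        }
        ner0 <- ners[dms == 0]
        dops <- rep(NA_real_, length(dms))
        if (length(ner0) == 1 && is.finite(ner0) && ner0 > 1) {
          dops <- 1 - (ners - 1) / (ner0 - 1)
        } else if (length(ner0) == 1 && is.finite(ner0)) {
          qc <- c(qc, sprintf(
            "DoP undefined for %s/%g ug/mL: no-DMSO NER <= 1", m, cc))
        }
        qrows[[paste(m, cc)]] <- data.frame(
          material = m, conc_ug_mL = cc, dmso_M = dms, ner = ners,
          dop = dops)
      }
    }
    quench_df <- .rbind_rows(qrows)
  }

  list(lq_fits = lq_df, dmr = dmr_df, toxicity = tox_df,
       quench = quench_df, qc = qc)
}

.rbind_rows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

.check_plate_columns <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_format("plate table missing column(s): ",
                paste(miss, collapse = ", "))
  invisible(df)
}
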