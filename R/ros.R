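# Acellular ROS (DCF) assay quantification: chemical dose-enhancement
# factors from paired 0 Gy / 12 Gy fluorescence plates and their
# regression on surface-area concentration.

#' Chemical dose-enhancement factor from DCF fluorescence
#'
#' `DEF_ROS = (FI_12Gy,NP - FI_0Gy,NP) / (FI_12Gy,blank - FI_0Gy,blank)`:
#' the radiation-induced fluorescence gain with nanoparticles over the
#' gain without. Equals 1 when nanoparticle wells behave like blanks, and
#' is invariant under a common rescaling of the fluorometer gain.
#'
#' @param fi_12_np,fi_0_np Mean fluorescence with nanoparticles at 12/0 Gy.
#' @param fi_12_blank,fi_0_blank Mean blank fluorescence at 12/0 Gy.
#' @return The enhancement ratio.
#' @examples
#' def_ros(500, 100, 300, 100)  # 2.0
#' @export
def_ros <- function(fi_12_np, fi_0_np, fi_12_blank, fi_0_blank) {
  denom <- fi_12_blank - fi_0_blank
  if (any(denom <= 0))
    stop_domain("assay failure: no blank radiolysis signal ",
                "(FI_12Gy,blank must exceed FI_0Gy,blank)")
  (fi_12_np - fi_0_np) / denom
}

#' Regression of DEF_ROS on surface-area concentration
#'
#' Least squares of `DEF_ROS - 1` on the exposed surface-area
#' concentration with the intercept fixed at `DEF_ROS = 1` at zero surface
#' (no nanoparticles, no enhancement — physically forced); a free-intercept
#' variant is available. The 95% confidence interval uses the t quantile
#' with `n - 1` degrees of freedom (`n - 2` with a free intercept).
#'
#' @param def_ros_values DEF_ROS values.
#' @param sa_conc Surface-area concentrations in cm^2/mL (>= 2, ideally 3,
#'   distinct positive levels).
#' @param free_intercept Fit an intercept instead of anchoring at 1.
#' @return List with `slope` (per cm^2/mL), `ci95_lo`, `ci95_hi`, `se`,
#'   `n`, `intercept`.
#' @examples
#' sa <- rep(c(36.8, 368, 1840), each = 6)
#' ros_slope(1 + 0.002 * sa, sa)
#' @export
ros_slope <- function(def_ros_values, sa_conc, free_intercept = FALSE) {
  if (length(def_ros_values) != length(sa_conc))
    stop_domain("def_ros_values and sa_conc must have equal length")
  if (length(unique(sa_conc)) < 2)
    stop_domain("degenerate design: need >= 2 distinct concentrations")
  if (length(unique(sa_conc)) < 3)
    warning("fewer than 3 distinct concentration levels")
  n <- length(sa_conc)
  y <- def_ros_values - 1
  if (free_intercept) {
    fit <- stats::lm(y ~ sa_conc)
    slope <- unname(stats::coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    icpt <- 1 + unname(stats::coef(fit)[1])
    dfree <- n - 2
  } else {
    slope <- sum(sa_conc * y) / sum(sa_conc^2)
    resid <- y - slope * sa_conc
    se <- sqrt(sum(resid^2) / (n - 1) / sum(sa_conc^2))
    icpt <- 1
    dfree <- n - 1
  }
  hw <- stats::qt(0.975, df = dfree) * se
  list(slope = slope, ci95_lo = slope - hw, ci95_hi = slope + hw,
       se = se, n = n, intercept = icpt)
}

#' Analyze a full ROS plate
#'
#' Aggregates replicates (mean fluorescence per material, concentration and
#' dose, subtracting the average 0 Gy signal as in the assay protocol),
#' computes per-concentration DEF_ROS against the blank wells
#' (`material = "none"`), and regresses DEF_ROS on surface-area
#' concentration per material. Gold is accepted but flagged: strong DCF
#' assay interference makes its values unreliable.
#'
#' @param ros_plate data.frame with columns `material`, `sa_conc_cm2_mL`,
#'   `dose_Gy` (0 and the irradiated dose), `replicate`, `fi`.
#' @param free_intercept Passed to [ros_slope()].
#' @param ci Confidence-interval method for the slope.
#'   `"propagated"` (default): delta-method propagation of the replicate
#'   variances of every well-group mean, including the covariance all
#'   DEF_ROS values share through the common blank denominator, with a
#'   t quantile on `n_rep - 1` degrees of freedom.
#'   `"bootstrap"`: percentile interval from resampling replicates of
#'   every well group (blanks included).
#'   `"residual"`: the analytic t interval of [ros_slope()], blind to the
#'   shared blank noise.
#' @param n_boot Bootstrap resamples.
#' @return List with `def_ros` (per material x concentration, replicate
#'   level) and `slopes` (per material: slope, ci95_lo, ci95_hi, n).
#' @export
analyze_ros_plate <- function(ros_plate, free_intercept = FALSE,
                              ci = c("propagated", "bootstrap",
                                     "residual"),
                              n_boot = 500) {
  ci <- match.arg(ci)
  .check_plate_columns(ros_plate, c("material", "sa_conc_cm2_mL",
                                    "dose_Gy", "replicate", "fi"))
  if (any(ros_plate$fi < 0)) stop_format("fluorescence must be >= 0")
  doses <- sort(unique(ros_plate$dose_Gy))
  if (length(doses) != 2 || doses[1] != 0)
    stop_format("expect exactly doses 0 and one irradiated level")
  dhi <- doses[2]
  if ("Au" %in% ros_plate$material)
    warning("Au wells present: DCF assay interference makes Au DEF_ROS ",
            "unreliable")
  blanks <- ros_plate[ros_plate$material == "none", ]
  if (nrow(blanks) == 0) stop_format("no blank wells (material = 'none')")
  bl0 <- mean(blanks$fi[blanks$dose_Gy == 0])
  bl12 <- mean(blanks$fi[blanks$dose_Gy == dhi])
  rows <- list()
  for (m in setdiff(unique(ros_plate$material), "none")) {
    for (sc in unique(ros_plate$sa_conc_cm2_mL[ros_plate$material == m])) {
      d <- ros_plate[ros_plate$material == m &
                       ros_plate$sa_conc_cm2_mL == sc, ]
      f0 <- mean(d$fi[d$dose_Gy == 0])
      reps <- d[d$dose_Gy == dhi, ]
      rows[[paste(m, sc)]] <- data.frame(
        material = m, sa_conc_cm2_mL = sc, replicate = reps$replicate,
        def_ros = def_ros(reps$fi, f0, bl12, bl0))
    }
  }
  dr <- .rbind_rows(rows)
  slopes <- do.call(rbind, lapply(split(dr, dr$material), function(d) {
    s <- ros_slope(d$def_ros, d$sa_conc_cm2_mL, free_intercept)
    if (ci == "bootstrap") {
      b <- .ros_boot_slope(ros_plate, d$material[1], dhi, free_intercept,
                           n_boot)
      s$ci95_lo <- b[1]; s$ci95_hi <- b[2]
    } else if (ci == "propagated") {
      b <- .ros_delta_ci(ros_plate, d$material[1], dhi)
      s$ci95_lo <- s$slope - b; s$ci95_hi <- s$slope + b
    }
    data.frame(material = d$material[1], slope = s$slope,
               ci95_lo = s$ci95_lo, ci95_hi = s$ci95_hi, n = s$n)
  }))
  rownames(slopes) <- NULL
  list(def_ros = dr, slopes = slopes)
}

# Delta-method half-width for the fixed-intercept slope: propagates the
# replicate variance of every well-group mean, including the covariance
# all DEF_ROS values inherit from the shared blank denominator.
.ros_delta_ci <- function(ros_plate, material, dhi) {
  grab <- function(m, sc, D)
    ros_plate$fi[ros_plate$material == m &
                   ros_plate$sa_conc_cm2_mL == sc &
                   ros_plate$dose_Gy == D]
  vm <- function(x) stats::var(x) / length(x)  # variance of the mean
  bl0 <- grab("none", 0, 0); bl12 <- grab("none", 0, dhi)
  Gb <- mean(bl12) - mean(bl0)
  vGb <- vm(bl12) + vm(bl0)
  scs <- sort(unique(
    ros_plate$sa_conc_cm2_mL[ros_plate$material == material]))
  G <- vG <- numeric(length(scs))
  nmin <- min(length(bl0), length(bl12))
  for (j in seq_along(scs)) {
    f0 <- grab(material, scs[j], 0); f12 <- grab(material, scs[j], dhi)
    G[j] <- mean(f12) - mean(f0)
    vG[j] <- vm(f12) + vm(f0)
    nmin <- min(nmin, length(f0), length(f12))
  }
  # Cov(DEF_j, DEF_k) = [j==k] vG_j / Gb^2 + G_j G_k vGb / Gb^4
  cov_def <- outer(G, G) * vGb / Gb^4 + diag(vG / Gb^2,
                                             length(scs), length(scs))
  a <- scs / sum(scs^2)  # slope = sum(a_j (DEF_j - 1))
  v_slope <- drop(t(a) %*% cov_def %*% a)
  stats::qt(0.975, df = max(nmin - 1, 1)) * sqrt(v_slope)
}

# Percentile bootstrap of the DEF_ROS slope: resamples replicates within
# every (material, concentration, dose) well group, blanks included, so
# the blank-denominator noise shared by all DEF_ROS values is propagated.
.ros_boot_slope <- function(ros_plate, material, dhi, free_intercept,
                            n_boot) {
  grab <- function(m, sc, D)
    ros_plate$fi[ros_plate$material == m &
                   ros_plate$sa_conc_cm2_mL == sc &
                   ros_plate$dose_Gy == D]
  bl0 <- grab("none", 0, 0); bl12 <- grab("none", 0, dhi)
  scs <- sort(unique(
    ros_plate$sa_conc_cm2_mL[ros_plate$material == material]))
  np <- lapply(scs, function(sc)
    list(f0 = grab(material, sc, 0), f12 = grab(material, sc, dhi)))
  rs <- function(x) mean(x[sample.int(length(x), replace = TRUE)])
  boots <- vapply(seq_len(n_boot), function(i) {
    denom <- rs(bl12) - rs(bl0)
    if (denom <= 0) return(NA_real_)
    defs <- vapply(np, function(g) (rs(g$f12) - rs(g$f0)) / denom,
                   numeric(1))
    if (free_intercept)
      unname(stats::coef(stats::lm(defs - 1 ~ scs))[2])
    else sum(scs * (defs - 1)) / sum(scs^2)
  }, numeric(1))
  unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
}
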