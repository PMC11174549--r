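# Method-comparison statistics for paired step counts / distances:
# error metrics, Lin's CCC, repeated-measures limits of agreement via a
# mixed model on paired differences, the total deviation index, the
# coefficient of individual agreement, the variance-components model for
# device comparison, and inter-unit reliability summaries.

#' Basic error metrics
#'
#' @param estimated,reference Equal-length numeric vectors.
#' @return List with `mae`, `rmse`, `mape` (percent; requires nonzero
#'   reference values).
#' @export
#' @examples
#' error_metrics(c(110, 90), c(100, 100)) # MAE 10, RMSE 10, MAPE 10%
error_metrics <- function(estimated, reference) {
  if (length(estimated) != length(reference) || length(estimated) < 1L) {
    stop("estimated and reference must have equal length >= 1")
  }
  e <- estimated - reference
  mape <- if (any(reference == 0)) {
    stop("MAPE undefined: reference contains zeros")
  } else {
    100 * mean(abs(e) / abs(reference))
  }
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), mape = mape)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the identity line, penalising both location and scale
#' shifts: `CCC = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with
#' population (1/n) moments. The confidence interval uses the Fisher
#' z-transform with Lin's asymptotic variance.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `n`.
#' @export
ccc <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("zero total variance: CCC undefined")
  est <- 2 * sxy / denom
  # Lin (1989) variance of the z-transformed estimate
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^(1 / 4) # location shift in scale-free units
  C <- est
  lower <- upper <- NA_real_
  if (abs(C) < 1 && r != 0 && n > 2) {
    se_z2 <- ((1 - r^2) * C^2 / ((1 - C^2) * r^2) +
                2 * C^3 * (1 - C) * u^2 / (r * (1 - C^2)^2) -
                C^4 * u^4 / (2 * r^2 * (1 - C^2)^2)) / (n - 2)
    if (is.finite(se_z2) && se_z2 > 0) {
      z <- atanh(C)
      q <- stats::qnorm(1 - (1 - conf_level) / 2)
      lower <- tanh(z - q * sqrt(se_z2))
      upper <- tanh(z + q * sqrt(se_z2))
    }
  }
  list(estimate = est, lower = lower, upper = upper, n = n)
}

# cluster (subject-level) bootstrap helper: resamples subjects with
# replacement, relabelling duplicates so they stay distinct clusters
cluster_bootstrap <- function(subjects, values, n_boot, stat_fun, seed = NULL) {
  ids <- unique(subjects)
  with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      pick <- sample(ids, length(ids), replace = TRUE)
      d <- do.call(rbind, lapply(seq_along(pick), function(i) {
        sel <- subjects == pick[i]
        data.frame(subject = paste0("bs", i), value = values[sel])
      }))
      stat_fun(d$value, d$subject)
    }, numeric(length(stat_fun(values, subjects)))))
  })
}

#' Repeated-measures limits of agreement
#'
#' Bland-Altman limits of agreement adapted to repeated measures: a mixed
#' model `d_it = mu + a_i + e_it` (random subject intercept) is fitted to the
#' per-replicate paired differences, and the limits are
#' `mu +/- 1.96 * sqrt(sigma_a^2 + sigma_e^2)`, so between- and within-subject
#' difference variability both widen the interval. Confidence intervals come
#' from a subject-level (cluster) nonparametric bootstrap. With a single
#' subject (or single replicates) the estimator falls back to the classical
#' Bland-Altman `mean +/- 1.96 * SD` with a warning.
#'
#' @param differences Numeric vector of paired differences.
#' @param subject Subject identifier per difference.
#' @param n_boot Bootstrap resamples for the CIs (0 skips CIs).
#' @param seed Seed for the bootstrap.
#' @param conf_level CI level.
#' @return List with `bias`, `lower_loa`, `upper_loa`, `sigma_subject`,
#'   `sigma_resid`, and a `ci` data frame (or `NULL`).
#' @export
loa_repeated <- function(differences, subject = rep("s1", length(differences)),
                         n_boot = 2000, seed = NULL, conf_level = 0.95) {
  stopifnot(length(differences) == length(subject))
  point <- function(d, subj) {
    reps <- table(subj)
    if (length(reps) < 2L || max(reps) < 2L) {
      mu <- mean(d)
      sd_tot <- stats::sd(d)
      return(c(bias = mu, lower = mu - 1.96 * sd_tot,
               upper = mu + 1.96 * sd_tot,
               sigma_subject = NA_real_, sigma_resid = sd_tot))
    }
    df <- data.frame(d = d, subject = factor(subj))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(d ~ 1 + (1 | subject), data = df, REML = TRUE)
    ))
    mu <- unname(lme4::fixef(fit)[1])
    vc <- as.data.frame(lme4::VarCorr(fit))
    sa2 <- vc$vcov[vc$grp == "subject"]
    se2 <- vc$vcov[vc$grp == "Residual"]
    half <- 1.96 * sqrt(sa2 + se2)
    c(bias = mu, lower = mu - half, upper = mu + half,
      sigma_subject = sqrt(sa2), sigma_resid = sqrt(se2))
  }
  reps <- table(subject)
  if (length(reps) < 2L || max(reps) < 2L) {
    warning("degenerate design: falling back to classical Bland-Altman",
            call. = FALSE)
  }
  est <- point(differences, subject)
  ci <- NULL
  if (n_boot > 0 && length(unique(subject)) >= 2L) {
    boots <- cluster_bootstrap(subject, differences, n_boot,
                               function(v, s) point(v, s)[1:3], seed = seed)
    alpha <- (1 - conf_level) / 2
    qs <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    ci <- data.frame(
      quantity = c("bias", "lower_loa", "upper_loa"),
      lower = qs[1, ], upper = qs[2, ]
    )
  }
  list(bias = unname(est["bias"]), lower_loa = unname(est["lower"]),
       upper_loa = unname(est["upper"]),
       sigma_subject = unname(est["sigma_subject"]),
       sigma_resid = unname(est["sigma_resid"]), ci = ci)
}

#' Total deviation index under a normal model
#'
#' The boundary `kappa` such that `|difference| <= kappa` with probability
#' `p` when differences are N(mu, sigma^2):
#' `Phi((kappa - mu)/sigma) - Phi((-kappa - mu)/sigma) = p`, solved
#' numerically.
#'
#' @param mu,sigma Normal parameters (`sigma > 0`).
#' @param p Containment probability in (0, 1).
#' @return The boundary `kappa` (>= 0).
#' @export
#' @examples
#' tdi_normal(0, 1, 0.95) # 1.96
tdi_normal <- function(mu, sigma, p = 0.95) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)")
  f <- function(k) {
    stats::pnorm((k - mu) / sigma) - stats::pnorm((-k - mu) / sigma) - p
  }
  upper <- abs(mu) + sigma * (stats::qnorm((1 + p) / 2) + 10)
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Total deviation index of observed differences
#'
#' Estimates the normal-model TDI from the sample mean and SD of the
#' differences; the CI is a nonparametric bootstrap percentile interval.
#'
#' @param differences Numeric vector, length >= 3.
#' @param p Containment probability.
#' @param n_boot Bootstrap resamples (0 skips the CI).
#' @param seed Bootstrap seed.
#' @param conf_level CI level.
#' @return List with `estimate`, `lower`, `upper`, `mu`, `sigma`.
#' @export
tdi <- function(differences, p = 0.95, n_boot = 2000, seed = NULL,
                conf_level = 0.95) {
  if (length(differences) < 3L) stop("need at least 3 differences")
  mu <- mean(differences)
  sigma <- stats::sd(differences)
  if (sigma == 0) stop("zero variance: TDI degenerate")
  est <- tdi_normal(mu, sigma, p)
  lower <- upper <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        d <- sample(differences, replace = TRUE)
        s <- stats::sd(d)
        if (s == 0) return(abs(mean(d)))
        tdi_normal(mean(d), s, p)
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    lower <- qs[1]; upper <- qs[2]
  }
  list(estimate = est, lower = lower, upper = upper, mu = mu, sigma = sigma)
}

#' Coefficient of individual agreement
#'
#' Compares disagreement *between* devices to disagreement *within* devices
#' for repeated measurements under the same conditions in the same subject.
#' Per subject-activity cell with replicate values `y_j1..y_jn` for device
#' `j`: the within-device mean squared deviation is the mean of
#' `(y_jt - y_jt')^2` over all unordered replicate pairs (equal to twice the
#' sample variance), the between-device MSD is the mean of
#' `(y_1t - y_2t')^2` over all replicate pairs. CIA is the ratio of the two
#' MSDs averaged over cells (within averaged over the two devices). A value
#' of 1 means device identity makes no difference; values above 1 are
#' reported with a warning, not clipped.
#'
#' @param table Data frame with columns `subject`, `device`, `value` and
#'   optionally `activity` (cells are subject x activity).
#' @param n_boot Bootstrap resamples over subjects for the CI (0 skips).
#' @param seed Bootstrap seed.
#' @param conf_level CI level.
#' @return List with `estimate`, `lower`, `upper`, `n_cells`.
#' @export
cia <- function(table, n_boot = 2000, seed = NULL, conf_level = 0.95) {
  need <- c("subject", "device", "value")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"activity" %in% names(table)) table$activity <- "all"
  devs <- unique(table$device)
  if (length(devs) != 2L) stop("exactly two devices required")
  cell_msds <- function(tab) {
    cells <- split(tab, interaction(tab$subject, tab$activity, drop = TRUE))
    res <- lapply(cells, function(cc) {
      v1 <- cc$value[cc$device == devs[1]]
      v2 <- cc$value[cc$device == devs[2]]
      if (length(v1) < 2L || length(v2) < 2L) return(NULL)
      # mean over unordered replicate pairs of squared differences = 2 * var
      within <- (2 * stats::var(v1) + 2 * stats::var(v2)) / 2
      pop_var <- function(v) mean((v - mean(v))^2)
      between <- pop_var(v1) + pop_var(v2) + (mean(v1) - mean(v2))^2
      c(within = within, between = between)
    })
    res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(res) || !nrow(res)) {
      stop("no cell has >= 2 replicates per device")
    }
    res
  }
  msds <- cell_msds(table)
  est <- mean(msds[, "within"]) / mean(msds[, "between"])
  if (est > 1) warning("CIA estimate exceeds 1 (within-device disagreement ",
                       "larger than between-device)", call. = FALSE)
  lower <- upper <- NA_real_
  if (n_boot > 0 && length(unique(table$subject)) >= 2L) {
    ids <- unique(table$subject)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(ids, length(ids), replace = TRUE)
        tab <- do.call(rbind, lapply(seq_along(pick), function(i) {
          d <- table[table$subject == pick[i], , drop = FALSE]
          d$subject <- paste0("bs", i)
          d
        }))
        m <- cell_msds(tab)
        mean(m[, "within"]) / mean(m[, "between"])
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    lower <- qs[1]; upper <- qs[2]
  }
  list(estimate = est, lower = lower, upper = upper, n_cells = nrow(msds))
}

#' Variance-components model for paired device counts
#'
#' Fits the device-comparison mixed model
#' `y = mu + alpha_i + beta_j + gamma_l + (alpha gamma)_il + (alpha beta)_ij
#' [+ (beta gamma)_jl] + e` with a fixed device effect `beta_j` and random
#' subject, activity and interaction terms, by REML (via lme4). Variants:
#' `"final"` keeps subject-activity and subject-device interactions (the
#' structure favoured by AIC/BIC on the validation data), `"full"` adds the
#' device-activity interaction, `"additive"` drops all interactions.
#'
#' @param table Data frame with columns `subject`, `device` (2 levels),
#'   `activity`, `value` (and optionally `rep`).
#' @param variant `"final"`, `"full"` or `"additive"`.
#' @param reml Fit by REML (default) or ML.
#' @return A `steps_lmm` list: `varcomp` (named vector: `subject`,
#'   `activity`, `subject_activity`, `subject_device`, `device_activity`,
#'   `residual`; `NA` where absent), `fixed`, `logLik`, `aic`, `bic`,
#'   `variant`, `fit` (the merMod object).
#' @export
fit_steps_lmm <- function(table, variant = c("final", "full", "additive"),
                          reml = TRUE) {
  variant <- match.arg(variant)
  need <- c("subject", "device", "activity", "value")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "))
  }
  df <- data.frame(
    value = table$value,
    subject = factor(table$subject),
    device = factor(table$device),
    activity = factor(table$activity)
  )
  if (nlevels(df$subject) < 2L || nlevels(df$activity) < 2L ||
      nlevels(df$device) != 2L) {
    stop("need >= 2 subjects, >= 2 activities and exactly 2 devices")
  }
  form <- switch(variant,
    additive = value ~ device + (1 | subject) + (1 | activity),
    final = value ~ device + (1 | subject) + (1 | activity) +
      (1 | subject:activity) + (1 | subject:device),
    full = value ~ device + (1 | subject) + (1 | activity) +
      (1 | subject:activity) + (1 | subject:device) + (1 | device:activity)
  )
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(form, data = df, REML = reml))),
    error = function(e) stop("LMM fit failed: ", conditionMessage(e))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else NA_real_
  }
  varcomp <- c(
    subject = get_vc("subject"),
    activity = get_vc("activity"),
    subject_activity = get_vc("subject:activity"),
    subject_device = get_vc("subject:device"),
    device_activity = get_vc("device:activity"),
    residual = get_vc("Residual")
  )
  structure(list(
    varcomp = varcomp,
    fixed = lme4::fixef(fit),
    logLik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    bic = stats::BIC(fit),
    variant = variant,
    converged = is.null(fit@optinfo$conv$lme4$messages),
    fit = fit
  ), class = "steps_lmm")
}

#' @export
print.steps_lmm <- function(x, ...) {
  cat(sprintf("<steps_lmm> variant '%s'  AIC %.1f  BIC %.1f\n",
              x$variant, x$aic, x$bic))
  cat("  variance components:\n")
  print(round(x$varcomp, 3))
  invisible(x)
}

#' Rank nested variance-component models
#'
#' Fits the requested variants by maximum likelihood (so information criteria
#' are comparable across random-effects structures) and ranks them by AIC,
#' ties broken by BIC.
#'
#' @param table As for [fit_steps_lmm()].
#' @param variants Character vector of variants to compare.
#' @return Data frame sorted best-first with columns `variant`, `aic`, `bic`,
#'   `logLik`.
#' @export
compare_models <- function(table, variants = c("additive", "final", "full")) {
  rows <- lapply(variants, function(v) {
    f <- fit_steps_lmm(table, variant = v, reml = FALSE)
    data.frame(variant = v, aic = f$aic, bic = f$bic, logLik = f$logLik,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$aic, out$bic), , drop = FALSE]
}

#' Inter-unit reliability of paired per-lap outputs
#'
#' Summarises the agreement of two devices worn simultaneously: mean
#' difference and repeated-measures limits of agreement (via
#' [loa_repeated()]), and a coefficient of variation. The CV definition for
#' this context is ambiguous in the literature; the default is the SD of the
#' within-pair differences divided by the grand mean of the paired values
#' (`cv = "sd_diff_over_mean"`); `"rms_pairwise"` gives the classical
#' within-pair RMS CV `sqrt(mean((d_k / mean_k)^2 / 2))`.
#'
#' @param unit1,unit2 Paired per-lap values from the two devices.
#' @param subject Optional subject id per pair (enables the mixed-model LoA).
#' @param cv CV definition (see above).
#' @param n_boot,seed Passed to [loa_repeated()].
#' @return List with `mean_difference`, `lower_loa`, `upper_loa`, `cv`, `loa`
#'   (full [loa_repeated()] output).
#' @export
inter_unit_reliability <- function(unit1, unit2,
                                   subject = rep("s1", length(unit1)),
                                   cv = c("sd_diff_over_mean", "rms_pairwise"),
                                   n_boot = 0, seed = NULL) {
  cv <- match.arg(cv)
  keep <- is.finite(unit1) & is.finite(unit2)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " unpaired/non-finite row(s)",
            call. = FALSE)
  }
  u1 <- unit1[keep]; u2 <- unit2[keep]; subj <- subject[keep]
  d <- u2 - u1
  loa <- suppressWarnings(loa_repeated(d, subj, n_boot = n_boot, seed = seed))
  cv_val <- if (length(d) < 2L || all(d == d[1])) {
    if (stats::sd(d) == 0 || length(d) < 2L) 0 else NA_real_
  } else if (cv == "sd_diff_over_mean") {
    stats::sd(d) / mean(c(u1, u2))
  } else {
    m <- (u1 + u2) / 2
    sqrt(mean((d / m)^2) / 2)
  }
  list(mean_difference = mean(d), lower_loa = loa$lower_loa,
       upper_loa = loa$upper_loa, cv = cv_val, loa = loa)
}

#' Full agreement report for an estimated-vs-reference table
#'
#' Computes the whole validation suite on a long table of paired step counts
#' (or distances): overall and per-activity error metrics, CCC,
#' repeated-measures LoA on the paired differences, TDI and CIA (laps are the
#' replicates), plus Bland-Altman plot data (pair means vs differences).
#'
#' @param table Long data frame with columns `subject`, `activity`, `lap`,
#'   `method` (`"reference"`/`"estimated"`), `value`.
#' @param p TDI containment probability.
#' @param n_boot Bootstrap resamples for all CIs.
#' @param seed Bootstrap seed.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(table, p = 0.95, n_boot = 200, seed = 1L) {
  need <- c("subject", "activity", "lap", "method", "value")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("reference", "estimated") %in% table$method)) {
    stop("method must contain both 'reference' and 'estimated'")
  }
  wide <- merge(
    table[table$method == "estimated",
          c("subject", "activity", "lap", "value")],
    table[table$method == "reference",
          c("subject", "activity", "lap", "value")],
    by = c("subject", "activity", "lap"), suffixes = c("_est", "_ref")
  )
  if (!nrow(wide)) stop("no paired rows")
  d <- wide$value_est - wide$value_ref
  overall <- error_metrics(wide$value_est, wide$value_ref)
  by_act <- lapply(split(wide, wide$activity), function(g) {
    c(error_metrics(g$value_est, g$value_ref),
      list(mean_difference = mean(g$value_est - g$value_ref), n = nrow(g)))
  })
  cia_tab <- rbind(
    data.frame(subject = wide$subject, activity = wide$activity,
               device = "reference", value = wide$value_ref),
    data.frame(subject = wide$subject, activity = wide$activity,
               device = "estimated", value = wide$value_est)
  )
  structure(list(
    n_pairs = nrow(wide),
    ccc = ccc(wide$value_est, wide$value_ref),
    loa = loa_repeated(d, wide$subject, n_boot = n_boot, seed = seed),
    tdi = tdi(d, p = p, n_boot = n_boot, seed = seed),
    cia = tryCatch(cia(cia_tab, n_boot = min(n_boot, 200), seed = seed),
                   error = function(e) NULL),
    errors = overall,
    errors_by_activity = by_act,
    bland_altman = data.frame(
      subject = wide$subject, activity = wide$activity, lap = wide$lap,
      mean = (wide$value_est + wide$value_ref) / 2, difference = d
    )
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d pairs\n", x$n_pairs))
  cat(sprintf("  CCC %.3f [%.3f, %.3f]\n",
              x$ccc$estimate, x$ccc$lower, x$ccc$upper))
  cat(sprintf("  bias %.2f, LoA [%.2f, %.2f]\n",
              x$loa$bias, x$loa$lower_loa, x$loa$upper_loa))
  cat(sprintf("  TDI(%.0f%%) %.2f\n", 95, x$tdi$estimate))
  if (!is.null(x$cia)) cat(sprintf("  CIA %.3f\n", x$cia$estimate))
  cat(sprintf("  MAE %.2f  RMSE %.2f  MAPE %.1f%%\n",
              x$errors$mae, x$errors$rmse, x$errors$mape))
  invisible(x)
}
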