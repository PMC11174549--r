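test_that("error metrics match hand computation", {
  m <- error_metrics(c(110, 90), c(100, 100))
  expect_equal(m$mape, 10)
  expect_equal(m$mae, 10)
  expect_equal(m$rmse, 10)
  z <- error_metrics(1:5, 1:5)
  expect_equal(c(z$mae, z$rmse, z$mape), c(0, 0, 0))
  h <- error_metrics(c(3, 5), c(1, 1))
  expect_equal(h$mae, 3)
  expect_equal(h$rmse, sqrt(10))
  expect_equal(h$mape, 300)
  expect_error(error_metrics(1, 0), "zeros")
  expect_error(error_metrics(1:3, 1:2), "equal length")
})

test_that("ccc matches its defining formula and bounds", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 2.0, 2.9, 4.2)
  # independent oracle: direct evaluation of Lin's formula with 1/n moments
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  oracle <- 2 * sxy / (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n +
                         (mean(x) - mean(y))^2)
  est <- ccc(x, y)
  expect_equal(est$estimate, oracle, tolerance = 1e-12)
  expect_equal(est$estimate, 0.9942, tolerance = 5e-4)
  expect_true(est$lower < est$estimate && est$estimate < est$upper)

  expect_equal(ccc(1:10, 1:10)$estimate, 1)
  expect_equal(ccc(-4:5 - 0.5, -(-4:5 - 0.5))$estimate, -1)
  expect_error(ccc(rep(1, 5), rep(1, 5)), "zero total variance")

  # |CCC| <= |Pearson|, equality when means and variances match
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- 0.8 * a + rnorm(30, sd = 0.5) + runif(1, -1, 1)
    expect_lte(abs(ccc(a, b)$estimate), abs(stats::cor(a, b)) + 1e-12)
  }
  a <- rnorm(50)
  b <- sample(a) # same moments exactly
  expect_equal(ccc(a, b)$estimate,
               stats::cor(a, b) * 1, tolerance = 1e-9)
})

test_that("loa_repeated handles degenerate and classical designs", {
  expect_warning(r <- loa_repeated(rep(2.5, 10), rep("s1", 10), n_boot = 0),
                 "classical")
  expect_equal(r$bias, 2.5)
  expect_equal(r$upper_loa - r$lower_loa, 0)

  # with one replicate per subject it reduces to classical Bland-Altman
  set.seed(12)
  d <- rnorm(40, 1, 2)
  expect_warning(r1 <- loa_repeated(d, paste0("s", 1:40), n_boot = 0),
                 "classical")
  expect_equal(r1$bias, mean(d))
  expect_equal(r1$upper_loa, mean(d) + 1.96 * sd(d))
})

test_that("loa_repeated matches the balanced ANOVA oracle", {
  # balanced one-way layout with clearly positive between-subject variance:
  # REML equals the method-of-moments ANOVA estimator
  set.seed(5)
  ns <- 8; nr <- 6
  subj <- rep(paste0("s", 1:ns), each = nr)
  d <- rep(rnorm(ns, 1.2, 2.0), each = nr) + rnorm(ns * nr, 0, 1.0)
  r <- loa_repeated(d, subj, n_boot = 0)
  gm <- mean(tapply(d, subj, mean))
  msb <- nr * sum((tapply(d, subj, mean) - gm)^2) / (ns - 1)
  msw <- sum((d - ave(d, subj))^2) / (ns * (nr - 1))
  sa2 <- (msb - msw) / nr
  expect_equal(r$bias, gm, tolerance = 1e-6)
  expect_equal(r$sigma_resid^2, msw, tolerance = 1e-4)
  expect_equal(r$sigma_subject^2, sa2, tolerance = 1e-4)
  expect_equal(r$upper_loa, gm + 1.96 * sqrt(sa2 + msw), tolerance = 1e-4)
})

test_that("loa_repeated bootstrap CIs are seed-stable", {
  set.seed(9)
  d <- rep(rnorm(6, 1, 1.5), each = 5) + rnorm(30, 0, 2)
  subj <- rep(paste0("s", 1:6), each = 5)
  a <- loa_repeated(d, subj, n_boot = 50, seed = 4)
  b <- loa_repeated(d, subj, n_boot = 50, seed = 4)
  expect_identical(a$ci, b$ci)
  expect_true(all(a$ci$lower <= a$ci$upper))
})

test_that("tdi solves the normal containment equation", {
  expect_equal(tdi_normal(0, 1, 0.95), qnorm(0.975), tolerance = 1e-6)
  expect_equal(tdi_normal(1, 1, 0.95), 2.65, tolerance = 2e-3)
  # containment at the solution is exactly p
  for (mu in c(-2, 0, 0.5)) for (sig in c(0.3, 1, 4)) {
    k <- tdi_normal(mu, sig, 0.9)
    expect_equal(pnorm((k - mu) / sig) - pnorm((-k - mu) / sig), 0.9,
                 tolerance = 1e-8)
  }
  # scale equivariance at mu = 0
  expect_equal(tdi_normal(0, 3, 0.8), 3 * tdi_normal(0, 1, 0.8),
               tolerance = 1e-8)
  # Monte-Carlo containment oracle (1e5 draws here; 1e6 in acceptance)
  set.seed(2)
  draws <- rnorm(1e5, 1, 1)
  expect_equal(mean(abs(draws) <= tdi_normal(1, 1, 0.95)), 0.95,
               tolerance = 0.01)

  set.seed(3)
  d <- rnorm(50, 0.5, 1.2)
  est <- tdi(d, n_boot = 50, seed = 7)
  expect_equal(est$estimate, tdi_normal(mean(d), sd(d), 0.95))
  expect_true(est$lower <= est$estimate && est$estimate <= est$upper)
  expect_error(tdi(rep(1, 10)), "zero variance")
})

test_that("cia equals the exhaustive pair-enumeration oracle", {
  # 3-subject toy table with hand-sized replicates
  tab <- data.frame(
    subject = rep(c("s1", "s2", "s3"), each = 6),
    device = rep(rep(c("u1", "u2"), each = 3), 3),
    value = c(10, 12, 11, 13, 14, 12,
              20, 19, 21, 24, 23, 26,
              5, 6, 4, 5, 7, 6)
  )
  oracle_cell <- function(v1, v2) {
    within <- function(v) {
      s <- 0; npairs <- 0
      for (i in seq_along(v)) for (j in seq_along(v)) if (i < j) {
        s <- s + (v[i] - v[j])^2; npairs <- npairs + 1
      }
      s / npairs
    }
    between <- 0
    for (i in seq_along(v1)) for (j in seq_along(v2)) {
      between <- between + (v1[i] - v2[j])^2
    }
    c(w = (within(v1) + within(v2)) / 2,
      b = between / (length(v1) * length(v2)))
  }
  cells <- lapply(split(tab, tab$subject), function(cc) {
    oracle_cell(cc$value[cc$device == "u1"], cc$value[cc$device == "u2"])
  })
  m <- do.call(rbind, cells)
  oracle <- mean(m[, "w"]) / mean(m[, "b"])
  est <- cia(tab, n_boot = 0)
  expect_equal(est$estimate, oracle, tolerance = 1e-12)

  # interchangeable devices: CIA tends to 1
  set.seed(8)
  big <- data.frame(
    subject = rep(paste0("s", 1:10), each = 40),
    device = rep(rep(c("u1", "u2"), each = 20), 10),
    value = rnorm(400, 50, 3)
  )
  expect_equal(suppressWarnings(cia(big, n_boot = 0))$estimate, 1,
               tolerance = 0.1)

  # a large constant offset drives CIA towards 0
  off <- big
  off$value[off$device == "u2"] <- off$value[off$device == "u2"] + 100
  expect_lt(cia(off, n_boot = 0)$estimate, 0.02)

  expect_error(cia(tab[tab$device == "u1", ]), "two devices")
})

test_that("fit_steps_lmm returns the requested variance components", {
  sim_lmm_table <- function(ns = 8, na = 4, nr = 4, seed = 1,
                            vc = c(s = 25, a = 100, sa = 16, sd_ = 1, e = 9),
                            beta = 1.3) {
    set.seed(seed)
    d <- expand.grid(subject = paste0("s", 1:ns),
                     activity = paste0("a", 1:na),
                     device = c("reference", "estimated"), rep = 1:nr,
                     stringsAsFactors = FALSE)
    a <- rnorm(ns, 0, sqrt(vc["s"])); names(a) <- paste0("s", 1:ns)
    g <- rnorm(na, 0, sqrt(vc["a"])); names(g) <- paste0("a", 1:na)
    ag <- rnorm(ns * na, 0, sqrt(vc["sa"]))
    names(ag) <- as.vector(outer(paste0("s", 1:ns), paste0("a", 1:na),
                                 paste, sep = ":"))
    ab <- rnorm(ns * 2, 0, sqrt(vc["sd_"]))
    names(ab) <- as.vector(outer(paste0("s", 1:ns),
                                 c("reference", "estimated"), paste, sep = ":"))
    d$value <- 100 + a[d$subject] + g[d$activity] +
      ag[paste(d$subject, d$activity, sep = ":")] +
      ab[paste(d$subject, d$device, sep = ":")] +
      ifelse(d$device == "estimated", beta, 0) +
      rnorm(nrow(d), 0, sqrt(vc["e"]))
    d
  }
  tab <- sim_lmm_table()
  fit <- fit_steps_lmm(tab, "final")
  expect_named(fit$varcomp, c("subject", "activity", "subject_activity",
                              "subject_device", "device_activity", "residual"))
  expect_true(all(fit$varcomp[c("subject", "activity", "residual")] >= 0))
  expect_true(is.na(fit$varcomp["device_activity"]))
  expect_equal(unname(fit$varcomp["residual"]), 9, tolerance = 0.35)
  full <- fit_steps_lmm(tab, "full")
  expect_false(is.na(full$varcomp["device_activity"]))

  # constant data: every component collapses to zero
  flat <- tab
  flat$value <- 100
  f0 <- suppressWarnings(fit_steps_lmm(flat, "final"))
  expect_lt(max(f0$varcomp[c("subject", "activity", "subject_activity",
                             "subject_device")], na.rm = TRUE), 1e-8)

  # model comparison: AIC prefers the smaller model when the interactions
  # are absent from the generating process
  wins <- 0L
  for (s in 1:20) {
    tab0 <- sim_lmm_table(ns = 6, na = 4, nr = 3, seed = 100 + s,
                          vc = c(s = 25, a = 100, sa = 0, sd_ = 0, e = 9))
    cmp <- compare_models(tab0, c("additive", "final"))
    wins <- wins + (cmp$variant[1] == "additive")
  }
  expect_gte(wins, 18L) # >= 90% of null repeats
})

test_that("inter_unit_reliability summarises paired outputs", {
  r0 <- suppressWarnings(inter_unit_reliability(rep(100, 8), rep(100, 8)))
  expect_equal(r0$mean_difference, 0)
  expect_equal(r0$cv, 0)

  rc <- suppressWarnings(inter_unit_reliability(rep(100, 8), rep(102, 8)))
  expect_equal(rc$mean_difference, 2)
  expect_equal(rc$upper_loa - rc$lower_loa, 0)

  set.seed(77)
  u1 <- rnorm(30, 200, 10)
  u2 <- u1 + rnorm(30, 1, 1.5)
  r <- suppressWarnings(inter_unit_reliability(u1, u2))
  expect_equal(r$mean_difference, 1, tolerance = 0.6)
  expect_equal(r$upper_loa - r$lower_loa, 2 * 1.96 * 1.5, tolerance = 0.35)
  expect_equal(r$cv, sd(u2 - u1) / mean(c(u1, u2)), tolerance = 1e-12)

  expect_warning(inter_unit_reliability(c(1, NA, 3), c(1, 2, 3)), "dropping")
})

test_that("agreement_report assembles the full suite", {
  set.seed(14)
  tab <- expand.grid(subject = paste0("s", 1:6), activity = c("walk", "run"),
                     lap = 1:5, method = c("reference", "estimated"),
                     stringsAsFactors = FALSE)
  base <- 100 + 10 * as.integer(factor(tab$subject)) +
    25 * (tab$activity == "run")
  tab$value <- base + ifelse(tab$method == "estimated", rnorm(nrow(tab), 1, 3),
                             rnorm(nrow(tab), 0, 1))
  rep1 <- agreement_report(tab, n_boot = 25, seed = 3)
  expect_s3_class(rep1, "agreement_report")
  expect_equal(rep1$n_pairs, 60)
  expect_gt(rep1$ccc$estimate, 0.9)
  expect_true(rep1$loa$lower_loa <= rep1$loa$bias &&
                rep1$loa$bias <= rep1$loa$upper_loa)
  expect_gte(rep1$tdi$estimate, 0)
  expect_true(!is.null(rep1$cia))
  expect_named(rep1$errors_by_activity, c("run", "walk"))
  expect_output(print(rep1), "CCC")
})
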