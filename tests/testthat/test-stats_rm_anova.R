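test_that("two-way RM-ANOVA matches the aov() error-strata oracle", {
  tab <- random_outcome_table(n_subjects = 9, seed = 42)
  res <- rm_anova_2way(tab)
  fit <- aov_oracle(tab)
  for (case in list(
    list("visual", "subject:visual", "visual"),
    list("platform", "subject:platform", "platform"),
    list("visual x platform", "subject:visual:platform", "visual:platform"))) {
    mine <- res[res$term == case[[1]], ]
    orac <- aov_effect(fit, case[[2]], case[[3]])
    expect_equal(mine$df, unname(orac["df"]))
    expect_equal(mine$F, unname(orac["F"]), tolerance = 1e-10)
    expect_equal(mine$p, unname(orac["p"]), tolerance = 1e-10)
  }
  # published df structure for 9 subjects, 4 x 4 within factors
  expect_equal(res$df, c(3, 24, 3, 24, 9, 72))
})

test_that("small 3-subject 2x2 table matches the oracle too", {
  tab <- random_outcome_table(n_subjects = 3, visual = c("EO", "EC"),
                              platform = c("P1", "P2"), seed = 7)
  res <- rm_anova_2way(tab)
  fit <- aov_oracle(tab)
  orac <- aov_effect(fit, "subject:visual", "visual")
  expect_equal(res$F[res$term == "visual"], unname(orac["F"]),
               tolerance = 1e-10)
  expect_equal(res$df, c(1, 2, 1, 2, 1, 2))
})

test_that("SS decomposition is exact and degenerate inputs error", {
  tab <- random_outcome_table(n_subjects = 5, seed = 9)
  res <- rm_anova_2way(tab)
  expect_equal(sum(res$SS) + attr(res, "ss_subject"), attr(res, "ss_total"),
               tolerance = 1e-10)
  # constant outcome -> all effect SS zero
  tab0 <- tab; tab0$value <- 1
  res0 <- rm_anova_2way(tab0)
  expect_equal(res0$SS[res0$term != "Residual"], rep(0, 3), tolerance = 1e-12)
  # missing cell -> explicit balance error
  expect_error(rm_anova_2way(tab[-1, ]), "unbalanced")
  expect_error(rm_anova_2way(tab[0, ]), "single level")
})

test_that("F is invariant to affine transforms of the outcome", {
  tab <- random_outcome_table(n_subjects = 6, seed = 11)
  f0 <- rm_anova_2way(tab)$F
  tab$value <- 3.7 * tab$value + 42
  expect_equal(rm_anova_2way(tab)$F, f0, tolerance = 1e-9)
})

test_that("eta squared uses total SS including the subject stratum", {
  tab <- random_outcome_table(n_subjects = 8, seed = 13)
  res <- rm_anova_2way(tab)
  i <- which(res$term == "visual")
  expect_equal(res$eta_squared[i], res$SS[i] / attr(res, "ss_total"))
  expect_true(all(res$eta_squared[!is.na(res$eta_squared)] >= 0))
})

test_that("simple contrasts recover known offsets with pooled SE", {
  tab <- random_outcome_table(n_subjects = 9, seed = 17, effect = 0)
  delta <- 0.45
  tab$value[tab$visual == "ABS"] <- tab$value[tab$visual == "ABS"] + delta
  ct <- simple_contrasts(tab, reference = "EO")
  est <- ct$estimate[ct$comparison == "ABS - EO"]
  # estimate is a difference of per-subject means; recover delta up to noise
  man <- tapply(tab$value, list(tab$subject, tab$visual), mean)
  expect_equal(est, mean(man[, "ABS"] - man[, "EO"]), tolerance = 1e-10)
  expect_equal(ct$df, rep(24, 3))           # (9-1) x (4-1)
  expect_equal(length(unique(ct$SE)), 1L)   # pooled across comparisons
  # identical level -> zero estimate and t
  tab2 <- tab
  tab2$value[tab2$visual == "LAB"] <- tab2$value[tab2$visual == "EO"]
  ct2 <- simple_contrasts(tab2, reference = "EO")
  expect_equal(ct2$estimate[ct2$comparison == "LAB - EO"], 0)
  expect_equal(ct2$t[ct2$comparison == "LAB - EO"], 0)
  expect_error(simple_contrasts(tab, reference = "XX"), "not found")
})

test_that("contrast estimates are antisymmetric in level and reference", {
  tab <- random_outcome_table(n_subjects = 5, seed = 19)
  a <- simple_contrasts(tab, reference = "EO")
  b <- simple_contrasts(tab, reference = "EC")
  expect_equal(a$estimate[a$comparison == "EC - EO"],
               -b$estimate[b$comparison == "EO - EC"])
})

test_that("two-level contrast equals the paired t-test", {
  tab <- random_outcome_table(n_subjects = 9, visual = c("EO", "EC"),
                              platform = paste0("P", 1:3), seed = 23)
  ct <- simple_contrasts(tab, reference = "EO")
  m <- tapply(tab$value, list(tab$subject, tab$visual), mean)
  tt <- t.test(m[, "EC"], m[, "EO"], paired = TRUE)
  expect_equal(ct$estimate, unname(tt$estimate), tolerance = 1e-10)
  expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-10)
})

test_that("single-level post-hoc restricts and matches the one-way ANOVA", {
  tab <- random_outcome_table(n_subjects = 9, seed = 29)
  ph <- single_level_posthoc(tab, "P2")
  sub <- tab[tab$platform == "P2", ]
  direct <- rm_anova_2way(sub, factors = "visual")
  expect_equal(as.data.frame(ph$anova), as.data.frame(direct))
  expect_equal(ph$anova$df, c(3, 24))
  # identical values at a level -> zero effect SS
  sub0 <- sub; sub0$value <- 2
  tab0 <- rbind(sub0, tab[tab$platform != "P2", ])
  ph0 <- single_level_posthoc(tab0, "P2")
  expect_equal(ph0$anova$SS[1], 0, tolerance = 1e-12)
  expect_error(single_level_posthoc(tab, "P9"), "not present")
})

test_that("normalisation makes platform levels commensurable", {
  tab <- random_outcome_table(n_subjects = 6, seed = 31)
  tab$value <- tab$value + 100 * (tab$platform == "P3")   # wild unit mismatch
  z <- normalize_outcomes(tab)
  for (lev in unique(z$platform)) {
    expect_equal(mean(z$value[z$platform == lev]), 0, tolerance = 1e-12)
    expect_equal(sd(z$value[z$platform == lev]), 1, tolerance = 1e-12)
  }
  expect_identical(normalize_outcomes(tab, "raw"), tab)
  expect_error(normalize_outcomes(tab, "log"), "positive")
  tabpos <- tab; tabpos$value <- abs(tabpos$value) + 0.1
  zl <- normalize_outcomes(tabpos, "log")
  expect_equal(sd(zl$value[zl$platform == "P1"]), 1, tolerance = 1e-12)
})

test_that("Greenhouse-Geisser correction only shrinks p-value df", {
  tab <- random_outcome_table(n_subjects = 9, seed = 37)
  p0 <- rm_anova_2way(tab)
  p1 <- rm_anova_2way(tab, gg_correction = TRUE)
  expect_equal(p1$F, p0$F)               # F itself unchanged
  # for F > 1 shrinking both df via epsilon <= 1 makes the test conservative
  keep <- !is.na(p0$p) & p0$F > 1
  expect_true(all(p1$p[keep] >= p0$p[keep] - 1e-12))
})
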