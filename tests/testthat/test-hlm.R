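test_that("assemble_dataset joins and enforces the dyadic design", {
  rec <- tiny_records(n_pairs = 4)
  manifest <- rec[, c("participant_id", "pair_id", "gender", "country",
                      "age", "cr", "aq")]
  features <- data.frame(participant_id = rec$participant_id,
                         area_px = rec$area_px,
                         articulation_time_s = rec$duration)
  out <- assemble_dataset(features, manifest)
  expect_equal(nrow(out), nrow(rec))
  expect_true(all(c("area_px", "duration", "aq_missing") %in% names(out)))

  expect_error(assemble_dataset(features, rbind(manifest, manifest[1, ])),
               "duplicate participant_id")
  expect_error(assemble_dataset(features[-1, ], manifest),
               "without feature rows")
  bad <- manifest
  bad$gender[1] <- setdiff(c("male", "female"), bad$gender[1])
  expect_error(assemble_dataset(features, bad), "mixed gender")
})

test_that("the study-sized design yields 85 pairs and 170 records", {
  coh <- generate_cohort(seed = 1)
  expect_equal(nrow(coh$records), 170)
  expect_equal(length(unique(coh$records$pair_id)), 85)
  expect_equal(sum(coh$records$country == "India"), 44)
  expect_equal(sum(coh$records$country == "Italy"), 40)
  expect_equal(sum(coh$records$country == "UK"), 86)
})

test_that("a noiseless cohort is recovered to 1e-3", {
  coh <- generate_cohort(sd_pair = 0, sd_resid = 1e-6, seed = 3)
  fit <- suppressMessages(fit_hlm(coh$records))
  b <- coh$truth$betas
  est <- stats::setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  expect_equal(est[["(Intercept)"]], b[["intercept"]], tolerance = 1e-3)
  for (nm in c("gender", "country_india", "country_uk", "age",
               "duration", "cr", "aq")) {
    expect_equal(est[[nm]], b[[nm]], tolerance = 1e-3)
  }
})

test_that("with the pair variance at the boundary, REML equals the OLS oracle", {
  # seed chosen so the REML random-intercept variance lands at exactly 0
  coh <- generate_cohort(sd_pair = 0, sd_resid = 50, seed = 4)
  fit <- suppressMessages(fit_hlm(coh$records))
  expect_equal(fit$var_pair, 0)
  des <- artispace:::hlm_design(coh$records, "simple")
  ols <- stats::lm(coh$records$area_px ~ ., data = des$X)
  expect_equal(unname(fit$fixed_effects$estimate), unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("REML fixed effects match a hand-written GLS at the fitted variances", {
  coh <- generate_cohort(seed = 11)
  fit <- fit_hlm(coh$records)
  rec <- coh$records
  X <- cbind(1, as.matrix(artispace:::hlm_design(rec, "simple")$X))
  Z <- stats::model.matrix(~ 0 + factor(rec$pair_id))
  V <- fit$var_resid * diag(nrow(X)) + fit$var_pair * tcrossprod(Z)
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, rec$area_px)))
  expect_equal(unname(fit$fixed_effects$estimate), as.numeric(beta),
               tolerance = 1e-8)
})

test_that("row order does not change the fit, and a shift moves only the intercept", {
  coh <- generate_cohort(seed = 21)
  f1 <- fit_hlm(coh$records)
  shuf <- coh$records[sample(nrow(coh$records)), ]
  f2 <- fit_hlm(shuf)
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-8)
  shifted <- coh$records
  shifted$area_px <- shifted$area_px + 100
  f3 <- fit_hlm(shifted)
  expect_equal(f3$fixed_effects$estimate[1],
               f1$fixed_effects$estimate[1] + 100, tolerance = 1e-6)
  expect_equal(f3$fixed_effects$estimate[-1], f1$fixed_effects$estimate[-1],
               tolerance = 1e-6)
})

test_that("the fixed-effects report is Table-2 shaped", {
  coh <- generate_cohort(missing_aq_pairs = 4, seed = 8)
  fit <- fit_hlm(coh$records)
  fe <- fit$fixed_effects
  expect_equal(fe$label,
               c("(Intercept)", "2-1", "India-Italy", "UK-Italy",
                 "Age", "Duration", "CR", "AQ"))
  expect_true(all(fe$ci_lo <= fe$estimate & fe$estimate <= fe$ci_hi))
  expect_true(all(fe$p > 0 & fe$p <= 1))
  expect_true(all(fe$df > 0))
  # Satterthwaite df are fractional, not integer design df
  expect_true(any(abs(fe$df - round(fe$df)) > 1e-6))
  expect_identical(fit$fit_meta$method, "REML")
  expect_equal(fit$n_dropped, 8)   # 4 pairs listwise-deleted at fit time
  expect_equal(fit$n_obs, 170 - 8)
})

test_that("degenerate model inputs fail loudly", {
  coh <- generate_cohort(seed = 5)
  two_pairs <- coh$records[coh$records$pair_id %in% c("P001", "P002"), ]
  expect_error(fit_hlm(two_pairs), "at least 3 pairs")
  rec <- coh$records
  rec$duration <- rec$age * 2            # perfectly collinear
  expect_error(fit_hlm(rec), "collinear")
})

test_that("descriptives reproduce generator cell means and handle degenerate cells", {
  coh <- generate_cohort(seed = 31)
  d <- descriptives(coh$records)
  area_tot <- d[d$group == "total" & d$measure == "area_px", ]
  # truth-implied expectation per record (same coding and centers as the
  # generator), against which cell means are checked to Monte-Carlo error
  des <- artispace:::hlm_design(coh$records, "simple")
  b <- coh$truth$betas
  eta <- b[["intercept"]] + as.numeric(as.matrix(des$X) %*%
    b[c("gender", "country_india", "country_uk", "age", "duration", "cr", "aq")])
  noise_sd <- sqrt(coh$truth$sd_pair^2 + coh$truth$sd_resid^2)
  for (ctry in c("India", "Italy", "UK")) {
    rows <- coh$records$country == ctry
    expect_equal(area_tot$mean[area_tot$country == ctry],
                 mean(coh$records$area_px[rows]), tolerance = 1e-9)
    expect_equal(area_tot$n[area_tot$country == ctry], sum(rows))
    expect_lt(abs(mean(coh$records$area_px[rows]) - mean(eta[rows])),
              3 * noise_sd / sqrt(sum(rows)))
  }
  one <- coh$records[1, ]
  d1 <- descriptives(one)
  expect_true(all(is.na(d1$sd[d1$n == 1])))
})

test_that("generated areas match the coded linear predictor plus noise structure", {
  coh <- generate_cohort(sd_pair = 0, sd_resid = 0, seed = 13)
  des <- artispace:::hlm_design(coh$records, "simple")
  b <- coh$truth$betas
  eta <- b[["intercept"]] + as.matrix(des$X) %*%
    b[c("gender", "country_india", "country_uk", "age", "duration", "cr", "aq")]
  expect_equal(coh$records$area_px, as.numeric(eta), tolerance = 1e-9)
})
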