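ref <- reference_study()

test_that("noiseless data recover the generating coefficients exactly", {
  beta <- full_beta(ref$region)
  y <- sim_response(ref$design, beta, sigma = 0, reps = 2, seed = 1)
  fit <- scheffe_fit(ref$design, y)
  expect_equal(fit$coefficients, beta, tolerance = 1e-8)
  expect_equal(unname(predict(fit, c(0.2, 0.3, 3.5))),
               unname(predict(scheffe_model(beta, ref$region), c(0.2, 0.3, 3.5))),
               tolerance = 1e-8)
})

test_that("a constant response is pure linear blending on the coded scale", {
  cc <- 7.3
  yc <- response_set("const", data.frame(
    formulation_id = ref$design$points$formulation_id,
    value = rep(cc, 11)))
  fit <- scheffe_fit(ref$design, yc, scale = "coded")
  expect_equal(unname(fit$coefficients[1:3]), rep(cc, 3), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[4:6]), rep(0, 3), tolerance = 1e-7)
  expect_equal(unname(fitted(fit$lm)), rep(cc, 11), tolerance = 1e-9)
})

test_that("summary-level weighted fitting equals replicate-level OLS", {
  beta <- full_beta(ref$region)
  for (reps in c(3, 5)) {
    y <- sim_response(ref$design, beta, sigma = 0.4, reps = reps, seed = reps)
    fit_rep <- scheffe_fit(ref$design, y)
    fit_sum <- scheffe_fit(ref$design, summarize_response(y))
    expect_equal(fit_rep$coefficients, fit_sum$coefficients, tolerance = 1e-9)
  }
  # unbalanced replication: weights follow the counts
  y <- sim_response(ref$design, beta, sigma = 0.4, reps = 4, seed = 9)
  drop_rows <- c(1, 6, 7, 20)
  yu <- response_set("y", y$data[-drop_rows, ])
  fit_rep <- scheffe_fit(ref$design, yu)
  fit_sum <- scheffe_fit(ref$design, summarize_response(yu))
  expect_equal(fit_rep$coefficients, fit_sum$coefficients, tolerance = 1e-9)
})

test_that("mixture ANOVA matches a from-scratch sub-model oracle", {
  beta <- full_beta(ref$region)
  y <- sim_response(ref$design, beta, sigma = 0.5, reps = 4, seed = 21)
  fit <- scheffe_fit(ref$design, y)
  an <- suppressMessages(anova(fit))
  comps <- ref$region$components
  pts <- ref$design$points
  idx <- match(y$data$formulation_id, pts$formulation_id)
  Xfull <- scheffe_model_matrix(pts[idx, comps], ref$region)
  yy <- y$data$value
  rss <- function(X) sum(stats::lsfit(X, yy, intercept = FALSE)$residuals^2)
  ss_tot <- sum((yy - mean(yy))^2)
  ss_res <- rss(Xfull)
  # whole model and linear mixture
  expect_equal(an$ss[an$source == "model"], ss_tot - ss_res, tolerance = 1e-8)
  expect_equal(an$ss[an$source == "linear mixture"],
               ss_tot - rss(Xfull[, 1:3]), tolerance = 1e-8)
  # Type III interaction sums of squares
  for (tm in c("xanthan:guar", "xanthan:hpmc", "guar:hpmc")) {
    expect_equal(an$ss[an$source == tm],
                 rss(Xfull[, setdiff(colnames(Xfull), tm)]) - ss_res,
                 tolerance = 1e-8, label = tm)
  }
  # pure error pooled within formulations; lack of fit is the remainder
  ss_pe <- sum(unlist(lapply(split(yy, y$data$formulation_id),
                             function(g) (g - mean(g))^2)))
  expect_equal(an$ss[an$source == "pure error"], ss_pe, tolerance = 1e-8)
  expect_equal(an$ss[an$source == "lack of fit"], ss_res - ss_pe,
               tolerance = 1e-8)
  expect_equal(an$df[an$source == "pure error"], 44 - 11)
  expect_equal(an$df[an$source == "lack of fit"], 11 - 6)
  # decomposition conserves the corrected total
  expect_equal(an$ss[an$source == "model"] + an$ss[an$source == "residual"],
               ss_tot, tolerance = 1e-8)
})

test_that("a saturated model has zero lack of fit", {
  reg <- mixture_region(c(a = 0, b = 0, c = 0), c(4, 4, 4), total = 4)
  pts <- data.frame(a = c(4, 0, 0, 2, 2, 0), b = c(0, 4, 0, 2, 0, 2),
                    c = c(0, 0, 4, 0, 2, 2))
  des <- mixture_design(pts, reg)
  y <- sim_response(des, full_beta(reg), sigma = 0.3, reps = 3, seed = 4)
  an <- anova(scheffe_fit(des, y))
  expect_equal(an$ss[an$source == "lack of fit"], 0, tolerance = 1e-8)
})

test_that("zero within-formulation variance flags an infinite lack-of-fit F", {
  y0 <- response_set("y", data.frame(
    formulation_id = rep(ref$design$points$formulation_id, each = 2),
    value = rep(c(2.7, 2.4, 2.4, 2.9, 2.8, 2.6, 2.7, 2.7, 2.5, 2.9, 2.6),
                each = 2)))
  an <- anova(scheffe_fit(ref$design, y0))
  expect_true(is.infinite(an$f[an$source == "lack of fit"]))
})

test_that("PRESS equals explicit leave-one-out refitting", {
  beta <- full_beta(ref$region)
  y <- sim_response(ref$design, beta, sigma = 0.5, reps = 4, seed = 31)
  fit <- scheffe_fit(ref$design, y)
  fq <- fit_quality(fit)
  comps <- ref$region$components
  pts <- ref$design$points
  idx <- match(y$data$formulation_id, pts$formulation_id)
  X <- scheffe_model_matrix(pts[idx, comps], ref$region)
  yy <- y$data$value
  press_loo <- sum(vapply(seq_along(yy), function(i) {
    b <- stats::lsfit(X[-i, ], yy[-i], intercept = FALSE)$coefficients
    (yy[i] - sum(X[i, ] * b))^2
  }, numeric(1)))
  expect_equal(fq$press, press_loo, tolerance = 1e-8)
  expect_equal(fq$pred_r2, 1 - press_loo / sum((yy - mean(yy))^2),
               tolerance = 1e-8)
})

test_that("fit-quality invariants hold and a perfect fit is recognized", {
  beta <- full_beta(ref$region)
  y <- sim_response(ref$design, beta, sigma = 0, reps = 3, seed = 2)
  fq0 <- fit_quality(scheffe_fit(ref$design, y))
  expect_equal(fq0$r2, 1, tolerance = 1e-9)
  expect_equal(fq0$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fq0$pred_r2, 1, tolerance = 1e-9)
  expect_lt(fq0$press, 1e-12)
  yn <- sim_response(ref$design, beta, sigma = 0.5, reps = 4, seed = 3)
  fq <- fit_quality(scheffe_fit(ref$design, yn))
  expect_gte(fq$r2, fq$adj_r2)
  expect_lte(fq$pred_r2, fq$r2)
  expect_gte(fq$press, 0)
})

test_that("backward elimination removes interactions absent from the truth", {
  beta <- full_beta(ref$region, int = c(0.8, 0, 0.9))
  beta[c("xanthan:guar", "guar:hpmc")] <- c(3, 3) # strong true interactions
  dropped <- vapply(1:100, function(s) {
    y <- sim_response(ref$design, beta, sigma = 0.05, reps = 6, seed = 1000 + s)
    fit <- backward_eliminate(scheffe_fit(ref$design, y))
    "xanthan:hpmc" %in% fit$removed_terms$term
  }, logical(1))
  expect_gte(mean(dropped), 0.95)
})

test_that("elimination keeps all terms when every interaction is real", {
  beta <- full_beta(ref$region, int = c(5, -5, 5))
  y <- sim_response(ref$design, beta, sigma = 0.05, reps = 4, seed = 8)
  fit <- backward_eliminate(scheffe_fit(ref$design, y))
  expect_equal(nrow(fit$removed_terms), 0)
  expect_equal(length(fit$terms), 6)
})

test_that("confidence intervals cover the truth at the nominal rate", {
  beta <- ref_beta_svo
  beta <- c(beta[1:3], "xanthan:guar" = unname(beta[4]),
            "xanthan:hpmc" = 0, "guar:hpmc" = unname(beta[5]))
  covered <- matrix(NA, 500, 6)
  for (s in 1:500) {
    y <- sim_response(ref$design, beta, sigma = 0.06, reps = 3,
                      seed = 5000 + s)
    fit <- scheffe_fit(ref$design, y)
    ci <- stats::confint(fit$lm)
    covered[s, ] <- beta >= ci[, 1] & beta <= ci[, 2]
  }
  rate <- colMeans(covered)
  expect_true(all(rate > 0.90 & rate <= 1))
})

test_that("planted outliers beyond |t| = 4 are removed, clean data untouched", {
  beta <- full_beta(ref$region)
  y <- sim_response(ref$design, beta, sigma = 0.3, reps = 4, seed = 77)
  clean_fit <- screen_outliers(scheffe_fit(ref$design, y))
  expect_equal(nrow(clean_fit$outliers), 0)
  y2 <- y
  y2$data$value[17] <- y2$data$value[17] + 20 * 0.3
  fit2 <- screen_outliers(scheffe_fit(ref$design, response_set("y", y2$data)))
  expect_equal(fit2$outliers$row, 17)
  expect_equal(nrow(fit2$outliers), 1)
  # an infinite threshold is the identity
  fit3 <- screen_outliers(scheffe_fit(ref$design, response_set("y", y2$data)),
                          threshold = Inf)
  expect_equal(nrow(fit3$outliers), 0)
})

test_that("predictions warn outside the region but stay finite", {
  m <- ref$models$SVO
  expect_warning(p <- predict(m, c(1.0, 1.0, 2.0)), "outside")
  expect_true(is.finite(p))
})
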