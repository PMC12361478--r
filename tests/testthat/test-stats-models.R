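sim_scores <- function(cfg, tpl = small_template()) {
  sim <- simulate_study(cfg, tpl)
  st <- apply_exclusions(sim$study)$study
  score_table(count_clicks_by_region(st, tpl), st)
}

test_that("null data give null coefficients and a sane intercept", {
  uniform <- c(Head = 0, Chest = 0, Abdomen = 0, UpperLimbs = 0,
               LowerLimbs = 0)
  cfg <- sim_config(n_per_condition = c(Museum = 12, Commercial = 12,
                                        Mixed = 12),
                    act_logits = uniform, deact_logits = uniform,
                    sd_participant = 0, sd_image = 0, seed = 71)
  tbl <- sim_scores(cfg)
  fit <- fit_embodiment_lmm(tbl)
  co <- fit$coefficients
  # all non-intercept effects are noise
  expect_true(all(abs(co$estimate[-1]) < 3 * co$se[-1]))
  # the intercept estimates the planted Mixed/NotArt/Head cell mean
  truth <- expected_region_score(cfg, "Mixed", "NotArt", region = "Head")
  expect_lt(abs(co$estimate[1] - truth), 3 * co$se[1])
  # variance partition invariants
  expect_gte(fit$R2_conditional, fit$R2_marginal)
  expect_gte(fit$R2_marginal, 0)
  expect_lte(fit$R2_conditional, 1)
  expect_identical(fit$df_residual,
                   fit$n_obs - nrow(co) - 3L)
})

test_that("a planted image-type effect is recovered at small n", {
  shift <- c(Head = 0.8, Chest = 0, Abdomen = 0, UpperLimbs = 0,
             LowerLimbs = 0)
  cfg <- sim_config(n_per_condition = c(Museum = 15, Commercial = 15,
                                        Mixed = 15),
                    art_act_shift = shift, sd_participant = 0.2,
                    sd_image = 0.2, seed = 73)
  truth <- expected_region_score(cfg, "Mixed", "Art", region = "Head") -
    expected_region_score(cfg, "Mixed", "NotArt", region = "Head")
  tbl <- sim_scores(cfg)
  fit <- fit_embodiment_lmm(tbl)
  est <- fit$coefficients[fit$coefficients$term == "image_typeArt", ]
  expect_gt(truth, 0)
  expect_lt(abs(est$estimate - truth), 4 * est$se)
})

test_that("variance components are recovered from score-scale data", {
  # additive random intercepts planted directly on the score scale, at the
  # study's sample sizes, so the ML variance estimates can be checked
  # against their true values
  set.seed(87)
  n_p <- 265; n_i <- 68
  sd_p <- 0.12; sd_i <- 0.15; sd_e <- 0.6
  pres <- do.call(rbind, lapply(seq_len(n_p), function(p)
    data.frame(participant_id = sprintf("p%03d", p),
               image_id = sprintf("i%02d", sample(n_i, 34)))))
  d <- pres[rep(seq_len(nrow(pres)), each = 5), ]
  d$body_part <- rep(bsm_regions(), nrow(pres))
  d$condition <- rep(c("Mixed", "Commercial", "Museum"), length.out = n_p)[
    as.integer(substring(d$participant_id, 2))]
  d$image_type <- ifelse(as.integer(substring(d$image_id, 2)) <= 34,
                         "Art", "NotArt")
  u <- rnorm(n_p, 0, sd_p); names(u) <- sprintf("p%03d", 1:n_p)
  w <- rnorm(n_i, 0, sd_i); names(w) <- sprintf("i%02d", 1:n_i)
  d$score <- 0.2 + u[d$participant_id] + w[d$image_id] +
    rnorm(nrow(d), 0, sd_e)
  fit <- fit_embodiment_lmm(d)
  expect_lt(abs(fit$varcomp[["participant"]] - sd_p^2) / sd_p^2, 0.2)
  expect_lt(abs(fit$varcomp[["image"]] - sd_i^2) / sd_i^2, 0.2)
  expect_lt(abs(fit$varcomp[["residual"]] - sd_e^2) / sd_e^2, 0.2)
})

test_that("rank-deficient designs fail loudly with the empty cells named", {
  tbl <- sim_scores(sim_config(
    n_per_condition = c(Museum = 4, Commercial = 4, Mixed = 4), seed = 77))
  broken <- tbl[!(tbl$condition == "Museum" & tbl$image_type == "Art"), ]
  expect_error(fit_embodiment_lmm(broken), "empty factor cells.*Museum:Art")
})

test_that("EMM contrasts equal the prediction-grid averaging oracle", {
  cfg <- sim_config(n_per_condition = c(Museum = 8, Commercial = 8,
                                        Mixed = 8),
                    art_act_shift = c(Head = 0.5, Chest = 0, Abdomen = 0,
                                      UpperLimbs = 0, LowerLimbs = 0),
                    seed = 79)
  fit <- fit_embodiment_lmm(sim_scores(cfg))
  emm <- emmeans_pairwise(fit, "image_type_by_body_part")
  expect_identical(nrow(emm), 5L)
  expect_identical(unique(emm$family_size), 5L)
  expect_true(all(emm$p_adjusted >= emm$p - 1e-15))
  expect_equal(emm$p_adjusted, pmin(1, emm$p * 5))

  # oracle: average the fixed-effect cell predictions over conditions
  beta <- coef(fit)
  X <- function(cond, ty, bp) {
    d <- data.frame(condition = factor(cond, c("Mixed", "Commercial",
                                               "Museum")),
                    image_type = factor(ty, c("NotArt", "Art")),
                    body_part = factor(bp, bsm_regions()))
    stats::model.matrix(~ condition * image_type * body_part, d)
  }
  for (bp in bsm_regions()) {
    cell <- function(ty) mean(X(c("Mixed", "Commercial", "Museum"),
                                ty, bp) %*% beta)
    oracle <- cell("NotArt") - cell("Art")
    got <- emm$estimate[emm$grouping == bp]
    expect_equal(got, oracle, tolerance = 1e-8)
  }

  emc <- emmeans_pairwise(fit, "condition_by_body_part")
  expect_identical(nrow(emc), 15L)
  expect_identical(unique(emc$family_size), 15L)
})

test_that("EMM contrast equals the raw group difference for balanced toy
           data", {
  # balanced one-factor design: the marginal mean is the raw mean
  set.seed(83)
  toy <- expand.grid(participant_id = sprintf("p%02d", 1:12),
                     image_id = sprintf("i%02d", 1:10),
                     body_part = bsm_regions(),
                     stringsAsFactors = FALSE)
  toy$condition <- rep(c("Mixed", "Commercial", "Museum"), length.out = 12)[
    match(toy$participant_id, sprintf("p%02d", 1:12))]
  toy$image_type <- ifelse(as.integer(substring(toy$image_id, 2)) <= 5,
                           "Art", "NotArt")
  toy$score <- rnorm(nrow(toy), sd = 0.3) +
    ifelse(toy$image_type == "Art", 0.25, 0)
  fit <- fit_embodiment_lmm(toy)
  emm <- emmeans_pairwise(fit, "image_type_by_body_part")
  raw_diff <- mean(toy$score[toy$image_type == "NotArt"]) -
    mean(toy$score[toy$image_type == "Art"])
  expect_equal(mean(emm$estimate), raw_diff, tolerance = 1e-6)
})

test_that("guess analysis reproduces the Yates chi-squared by hand", {
  # 2x2 table [[10, 0], [0, 10]]: every NotArt guessed seller, every Art
  # guessed artist -> Yates chi2 = 16.2
  trials <- data.frame(
    image_id = sprintf("i%02d", 1:20), object_name = sprintf("o%02d", 1:20),
    activity = "eating",
    image_type = rep(c("Art", "NotArt"), each = 10))
  participants <- data.frame(participant_id = "m1", condition = "Mixed",
                             attention_checks_passed = TRUE)
  clicks <- data.frame(participant_id = "m1", image_id = "i01",
                       silhouette_kind = "Activation", x = 1L, y = 1L)
  guesses <- data.frame(
    participant_id = "m1", image_id = trials$image_id,
    guess = rep(c("ProfessionalArtist", "SellerOfProducts"), each = 10))
  st <- as_bsm_study(clicks, trials, participants, guesses)
  gs <- guess_analysis(st)
  expect_equal(gs$by_type$percent_correct, c(100, 100))
  expect_equal(gs$df, 1)
  # hand computation of the Yates formula on the 2x2 table
  O <- matrix(c(10, 0, 0, 10), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  yates <- sum((abs(O - E) - 0.5)^2 / E)
  expect_equal(gs$chi2, yates)
  expect_equal(gs$chi2, 16.2)

  # identical guess distributions -> chi2 ~ 0, equal percentages
  g2 <- guesses
  g2$guess <- rep(c("ProfessionalArtist", "SellerOfProducts"), 10)
  gs2 <- guess_analysis(as_bsm_study(clicks, trials, participants, g2))
  expect_equal(gs2$by_type$percent_correct[1],
               100 - gs2$by_type$percent_correct[2])
  expect_lt(gs2$chi2, 1e-10)

  # Yates-corrected statistic never exceeds the uncorrected one
  uncorr <- suppressWarnings(stats::chisq.test(gs$table, correct = FALSE))
  expect_lte(gs$chi2, unname(uncorr$statistic))
  # missing guesses are an error
  expect_error(guess_analysis(tiny_study()), "no guesses")
})
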