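# Mixed-effects analysis of embodiment scores, estimated marginal means
# with Bonferroni post-hocs, and the Mixed-condition guess analysis.

score_factors <- function(tbl, include_activity = FALSE) {
  # reference levels fix the meaning of the intercept: Mixed, NotArt, Head
  tbl$condition <- factor(tbl$condition, levels = CONDITIONS)
  tbl$image_type <- factor(tbl$image_type, levels = IMAGE_TYPES)
  tbl$body_part <- factor(tbl$body_part, levels = bsm_regions())
  if (include_activity) tbl$activity <- factor(tbl$activity)
  tbl$participant_id <- factor(tbl$participant_id)
  tbl$image_id <- factor(tbl$image_id)
  tbl
}

#' Fit the crossed mixed-effects model of embodiment scores
#'
#' Linear mixed model of the signed-log embodiment score on the full
#' Condition x ImageType x BodyPart factorial with crossed random
#' intercepts for participant and image, estimated by maximum likelihood
#' with the BOBYQA optimiser. Reference levels are Condition = Mixed,
#' ImageType = NotArt, BodyPart = Head (treatment coding), so the intercept
#' is the expected score for that cell. The input table must be dense over
#' participant x image x region, zero-filled where no clicks occurred
#' (see [score_table()]).
#'
#' Reported per-coefficient df follow the residual-df convention
#' `n_obs - n_fixed_coefficients - n_variance_components` (two random
#' intercepts plus the residual), with Wald t tests and normal-theory 95%
#' confidence intervals (beta +/- 1.96 SE). Marginal and conditional R2 are
#' the variance-partition (Nakagawa-style) quantities: fixed-effect
#' variance alone, and fixed plus both random-intercept variances, each
#' over the total including the residual.
#'
#' @param tbl A score table from [score_table()].
#' @param include_activity Also model Activity (main effect plus
#'   Activity x ImageType interaction).
#' @return A `bsm_lmm` object: `coefficients` data frame (term, estimate,
#'   se, ci_lo, ci_hi, t, df, p), `varcomp` (participant, image, residual
#'   variances), `R2_marginal`, `R2_conditional`, `n_obs`, `df_residual`,
#'   and the underlying `lme4` fit in `$model`.
#' @export
fit_embodiment_lmm <- function(tbl, include_activity = FALSE) {
  tbl <- score_factors(tbl, include_activity)
  cells <- table(tbl$condition, tbl$image_type, tbl$body_part)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)
    nm <- apply(idx, 1, function(r)
      paste(dimnames(cells)[[1]][r[1]], dimnames(cells)[[2]][r[2]],
            dimnames(cells)[[3]][r[3]], sep = ":"))
    stop("design has empty factor cells: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  form <- if (include_activity) {
    score ~ condition * image_type * body_part + activity +
      activity:image_type + (1 | participant_id) + (1 | image_id)
  } else {
    score ~ condition * image_type * body_part +
      (1 | participant_id) + (1 | image_id)
  }
  fit <- lme4::lmer(form, data = tbl, REML = FALSE,
                    control = lme4::lmerControl(optimizer = "bobyqa",
                                                calc.derivs = FALSE))
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    stop("mixed model did not converge (optimizer code ",
         fit@optinfo$conv$opt, ")", call. = FALSE)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  var_p <- as.numeric(vc$participant_id)
  var_i <- as.numeric(vc$image_id)
  var_e <- stats::sigma(fit)^2
  n <- nrow(tbl)
  df_res <- n - length(beta) - 3L   # 2 RE variances + residual variance
  tval <- beta / se
  coef_tab <- data.frame(
    term = names(beta), estimate = as.numeric(beta), se = se,
    ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
    t = tval, df = df_res, p = 2 * stats::pt(-abs(tval), df_res),
    row.names = NULL, stringsAsFactors = FALSE)

  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.vector(X %*% beta))
  tot <- var_f + var_p + var_i + var_e
  structure(list(
    model = fit, coefficients = coef_tab,
    varcomp = c(participant = var_p, image = var_i, residual = var_e),
    R2_marginal = var_f / tot,
    R2_conditional = (var_f + var_p + var_i) / tot,
    n_obs = n, df_residual = df_res,
    include_activity = include_activity),
    class = "bsm_lmm")
}

#' @export
print.bsm_lmm <- function(x, digits = 4, ...) {
  cat("Embodiment score mixed model (ML, BOBYQA): ", x$n_obs,
      " observations\n", sep = "")
  cat("  R2 marginal = ", round(x$R2_marginal, 2),
      ", R2 conditional = ", round(x$R2_conditional, 2), "\n", sep = "")
  cat("  variance components: participant ",
      signif(x$varcomp["participant"], 3), ", image ",
      signif(x$varcomp["image"], 3), ", residual ",
      signif(x$varcomp["residual"], 3), "\n\n", sep = "")
  tab <- x$coefficients
  num <- setdiff(names(tab), c("term", "df"))
  tab[num] <- lapply(tab[num], function(col) signif(col, digits))
  print(utils::head(tab, 12), row.names = FALSE)
  if (nrow(tab) > 12) cat("  ... and", nrow(tab) - 12, "more terms\n")
  invisible(x)
}

#' @export
summary.bsm_lmm <- function(object, ...) {
  object$coefficients
}

#' @export
coef.bsm_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Estimated marginal means pairwise contrasts with Bonferroni correction
#'
#' Post-hoc contrasts on a fitted embodiment model: either the ImageType
#' contrast within each body part (averaged with equal weights over
#' Condition) or all Condition pairs within each body part (averaged over
#' ImageType). Tests are asymptotic z tests; the Bonferroni family is the
#' full set of contrasts returned (5 for ImageType by body part, 15 for
#' Condition pairs by body part).
#'
#' @param fit A `bsm_lmm`.
#' @param contrast `"image_type_by_body_part"` or
#'   `"condition_by_body_part"`.
#' @return Data frame with columns grouping, contrast, estimate, se, z, p,
#'   p_adjusted, family_size, averaged_over.
#' @export
emmeans_pairwise <- function(fit,
                             contrast = c("image_type_by_body_part",
                                          "condition_by_body_part")) {
  stopifnot(inherits(fit, "bsm_lmm"))
  contrast <- match.arg(contrast)
  spec <- if (contrast == "image_type_by_body_part")
    ~ image_type | body_part else ~ condition | body_part
  averaged <- if (contrast == "image_type_by_body_part")
    "Condition" else "ImageType"
  emm <- emmeans::emmeans(fit$model, spec, lmer.df = "asymptotic")
  pr <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  raw <- as.data.frame(summary(pr))
  fam <- nrow(raw)
  data.frame(
    grouping = as.character(raw$body_part),
    contrast = as.character(raw$contrast),
    estimate = raw$estimate, se = raw$SE, z = raw$z.ratio,
    p = raw$p.value,
    p_adjusted = pmin(1, raw$p.value * fam),
    family_size = fam,
    averaged_over = averaged,
    stringsAsFactors = FALSE)
}

#' Yates-corrected chi-squared guess analysis for the Mixed condition
#'
#' Computes, per image type, how often Mixed-condition participants
#' correctly identified the image's origin (correct = SellerOfProducts for
#' NotArt images, ProfessionalArtist for Art images), and tests the
#' association between image type and guess with Pearson's chi-squared with
#' Yates' continuity correction on the trial-level 2 x 2 table.
#'
#' @param study A `bsm_study` whose Mixed participants carry guesses.
#' @return A `bsm_guess_summary`: `by_type` data frame (image_type,
#'   n_trials, n_correct, percent_correct), `table` (2 x 2 counts),
#'   `chi2`, `df`, `p`, `n_participants`.
#' @export
guess_analysis <- function(study) {
  stopifnot(inherits(study, "bsm_study"))
  g <- study$guesses
  if (is.null(g) || !nrow(g))
    stop("study has no guesses (only Mixed-condition participants are ",
         "asked for them)", call. = FALSE)
  itype <- study$trials$image_type[match(g$image_id, study$trials$image_id)]
  correct <- (itype == "NotArt" & g$guess == "SellerOfProducts") |
    (itype == "Art" & g$guess == "ProfessionalArtist")
  by_type <- do.call(rbind, lapply(IMAGE_TYPES, function(ty) {
    sel <- itype == ty
    data.frame(image_type = ty, n_trials = sum(sel),
               n_correct = sum(correct[sel]),
               percent_correct = 100 * mean(correct[sel]),
               stringsAsFactors = FALSE)
  }))
  tab <- table(image_type = factor(itype, IMAGE_TYPES),
               guess = factor(g$guess, GUESS_LEVELS))
  ct <- stats::chisq.test(tab, correct = TRUE)
  structure(list(by_type = by_type, table = tab,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value,
                 n_participants = length(unique(g$participant_id))),
            class = "bsm_guess_summary")
}

#' @export
print.bsm_guess_summary <- function(x, ...) {
  cat("Guess analysis (Mixed condition, ", x$n_participants,
      " participants):\n", sep = "")
  print(x$by_type, row.names = FALSE)
  cat("Chi-squared (Yates) = ", round(x$chi2, 2), ", df = ", x$df,
      ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}
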