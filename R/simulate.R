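# Synthetic-study generator. Emulates the study design: three
# between-participant conditions, 34 objects x 2 image types with 17 + 17
# counterbalanced images per participant (never both types of one object),
# up to 10 clicks per silhouette per trial drawn from a truncated Poisson,
# click placement by region-preference probabilities on the logit scale,
# participant- and image-level random effects, and Mixed-condition guesses
# with configurable accuracy.

trunc_pois_pmf <- function(lambda, max = 10L) {
  p <- stats::dpois(0:max, lambda)
  p / sum(p)
}

softmax <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

#' Build a simulation configuration
#'
#' Region preferences are specified as logits over the five regions,
#' separately for activation and deactivation clicks; effect structure is
#' planted as additive logit shifts (per image type, per condition, per
#' activity) on the activation logits. Participant and image random
#' effects are scalar perturbations of the activation Head logit.
#'
#' @param n_per_condition Named integer vector of participants per
#'   condition, names Museum/Commercial/Mixed.
#' @param n_objects Number of stimulus objects (even image count per
#'   participant requires an even number).
#' @param activities Activity labels assigned round-robin to objects.
#' @param lambda_clicks Mean of the truncated-Poisson(max 10) click-count
#'   distribution per silhouette.
#' @param act_logits,deact_logits Named numeric vectors of baseline region
#'   logits (names = [bsm_regions()]).
#' @param art_act_shift Named numeric vector added to the activation logits
#'   for Art images (planted image-type effect).
#' @param condition_act_shift Matrix (condition x region) of activation
#'   logit shifts, zero by default.
#' @param activity_act_shift Matrix (activity x region) of activation logit
#'   shifts, zero by default.
#' @param sd_participant,sd_image Standard deviations of the scalar random
#'   effects on the activation Head logit.
#' @param guess_accuracy Named probabilities (NotArt, Art) that a
#'   Mixed-condition participant guesses an image's origin correctly.
#' @param planted_exclusions Named integer vector: participants per
#'   condition planted to violate inclusion rules (half fail attention
#'   checks, half report no clicks).
#' @param seed Integer seed; fully determines the generated study.
#' @return A validated `bsm_sim_config`.
#' @export
sim_config <- function(n_per_condition = c(Museum = 30, Commercial = 30,
                                           Mixed = 30),
                       n_objects = 34L,
                       activities = bsm_activities(),
                       lambda_clicks = 3,
                       act_logits = c(Head = 1, Chest = 0, Abdomen = 0,
                                      UpperLimbs = 0, LowerLimbs = 0),
                       deact_logits = c(Head = 0, Chest = 0, Abdomen = 0,
                                        UpperLimbs = 0, LowerLimbs = 0),
                       art_act_shift = c(Head = 0, Chest = 0, Abdomen = 0,
                                         UpperLimbs = 0, LowerLimbs = 0),
                       condition_act_shift = NULL,
                       activity_act_shift = NULL,
                       sd_participant = 0.3, sd_image = 0.3,
                       guess_accuracy = c(NotArt = 0.7149, Art = 0.4962),
                       planted_exclusions = c(Museum = 0, Commercial = 0,
                                              Mixed = 0),
                       seed = 1L) {
  regions <- bsm_regions()
  if (is.null(condition_act_shift))
    condition_act_shift <- matrix(0, 3, 5,
                                  dimnames = list(CONDITIONS, regions))
  if (is.null(activity_act_shift))
    activity_act_shift <- matrix(0, length(activities), 5,
                                 dimnames = list(activities, regions))
  cfg <- structure(list(
    n_per_condition = n_per_condition, n_objects = as.integer(n_objects),
    activities = activities, lambda_clicks = lambda_clicks,
    act_logits = act_logits[regions], deact_logits = deact_logits[regions],
    art_act_shift = art_act_shift[regions],
    condition_act_shift = condition_act_shift[CONDITIONS, regions],
    activity_act_shift = activity_act_shift[, regions, drop = FALSE],
    sd_participant = sd_participant, sd_image = sd_image,
    guess_accuracy = guess_accuracy,
    planted_exclusions = planted_exclusions,
    seed = as.integer(seed)), class = "bsm_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "bsm_sim_config"))
  if (!all(sort(names(cfg$n_per_condition)) == sort(CONDITIONS)))
    stop("n_per_condition must name the three conditions", call. = FALSE)
  if (cfg$n_objects %% 2L != 0L)
    stop("counterbalancing 17+17 image types needs an even object count",
         call. = FALSE)
  if (anyNA(cfg$act_logits) || anyNA(cfg$deact_logits))
    stop("region logits must name all five regions", call. = FALSE)
  if (cfg$sd_participant < 0 || cfg$sd_image < 0)
    stop("random-effect SDs must be >= 0", call. = FALSE)
  if (cfg$lambda_clicks <= 0)
    stop("lambda_clicks must be > 0", call. = FALSE)
  if (any(cfg$guess_accuracy < 0 | cfg$guess_accuracy > 1))
    stop("guess accuracies must be probabilities", call. = FALSE)
  if (any(cfg$planted_exclusions > cfg$n_per_condition[
        names(cfg$planted_exclusions)]))
    stop("cannot plant more exclusions than participants", call. = FALSE)
  invisible(TRUE)
}

#' The study-shaped default configuration
#'
#' Condition sizes 92 (Museum), 93 (Commercial), 92 (Mixed) — 277
#' participants in total — with 12 planted inclusion-rule violations
#' (3/2/7 per condition, so 89/91/85 remain after exclusion), 34 objects
#' over the 11 everyday activities (68 images), a modest Head-dominant
#' baseline activation preference, and Mixed-condition guess accuracies of
#' 71.49% for NotArt and 49.62% for Art images.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `bsm_sim_config`.
#' @export
default_study_config <- function(seed = 1L, ...) {
  args <- list(
    n_per_condition = c(Museum = 92L, Commercial = 93L, Mixed = 92L),
    planted_exclusions = c(Museum = 3L, Commercial = 2L, Mixed = 7L),
    seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

region_pixel_index <- function(template) {
  lapply(seq_along(bsm_regions()), function(i) {
    which(template$label_matrix == i)  # column-major linear indices
  })
}

#' Simulate a complete synthetic study
#'
#' Generates participants (with condition assignment and planted
#' exclusions), a counterbalanced 17 + 17 trial list per participant that
#' never shows both image types of one object, per-trial activation and
#' deactivation click counts (truncated Poisson, max 10), click coordinates
#' placed uniformly within the mask of a region drawn from the
#' logit-perturbed region preferences, and Mixed-condition guesses with the
#' configured accuracy. A single seeded random stream drives everything, so
#' a fixed config reproduces the dataset exactly.
#'
#' @param config A `bsm_sim_config`.
#' @param template A `bsm_template` clicks are placed on.
#' @return List with `study` (a validated `bsm_study` including the
#'   presentations table) and `truth` (the planted parameters: the config
#'   plus the drawn participant and image random effects).
#' @export
simulate_study <- function(config, template = make_default_template()) {
  validate_sim_config(config)
  stopifnot(inherits(template, "bsm_template"))
  regions <- bsm_regions()
  with_seed(config$seed, {
    n_act_levels <- length(config$activities)
    objs <- sprintf("obj%02d", seq_len(config$n_objects))
    activity <- config$activities[(seq_len(config$n_objects) - 1L) %%
                                    n_act_levels + 1L]
    trials <- data.frame(
      image_id = c(paste0(objs, "_Art"), paste0(objs, "_NotArt")),
      object_name = c(objs, objs),
      activity = c(activity, activity),
      image_type = rep(IMAGE_TYPES[c(2, 1)], each = config$n_objects),
      stringsAsFactors = FALSE)

    conds <- rep(names(config$n_per_condition), config$n_per_condition)
    n_p <- length(conds)
    pid <- sprintf("P%03d", seq_len(n_p))
    # plant inclusion-rule violations: alternately attention failures and
    # zero-click participants, chosen at random within each condition
    attention <- rep(TRUE, n_p); silent <- rep(FALSE, n_p)
    for (cn in names(config$planted_exclusions)) {
      k <- config$planted_exclusions[[cn]]
      if (k > 0) {
        pick <- sample(which(conds == cn), k)
        fail_att <- pick[seq_len(ceiling(k / 2))]
        attention[fail_att] <- FALSE
        silent[setdiff(pick, fail_att)] <- TRUE
      }
    }
    participants <- data.frame(participant_id = pid, condition = conds,
                               attention_checks_passed = attention,
                               stringsAsFactors = FALSE)

    u_p <- stats::rnorm(n_p, 0, config$sd_participant)
    u_i <- stats::rnorm(nrow(trials), 0, config$sd_image)
    names(u_p) <- pid; names(u_i) <- trials$image_id

    half <- config$n_objects %/% 2L
    # per participant: which objects appear as Art (the rest as NotArt)
    pres <- do.call(rbind, lapply(seq_len(n_p), function(p) {
      art_objs <- sample(config$n_objects, half)
      img <- ifelse(seq_len(config$n_objects) %in% art_objs,
                    paste0(objs, "_Art"), paste0(objs, "_NotArt"))
      data.frame(participant_id = pid[p], image_id = sample(img),
                 stringsAsFactors = FALSE)
    }))

    # trial table with everything click generation needs
    ti <- match(pres$image_id, trials$image_id)
    ppos <- match(pres$participant_id, pid)
    trial <- data.frame(
      participant_id = pres$participant_id, image_id = pres$image_id,
      condition = conds[ppos], image_type = trials$image_type[ti],
      activity = trials$activity[ti],
      re = u_p[ppos] + u_i[ti], stringsAsFactors = FALSE)
    trial <- trial[!silent[ppos], , drop = FALSE]  # planted zero-click ppts

    pmf <- trunc_pois_pmf(config$lambda_clicks, 10L)
    n_tr <- nrow(trial)
    n_act <- sample(0:10, n_tr, replace = TRUE, prob = pmf)
    n_deact <- sample(0:10, n_tr, replace = TRUE, prob = pmf)

    # activation logits per trial: baseline + planted shifts + RE on Head
    act_log <- matrix(config$act_logits, n_tr, 5, byrow = TRUE)
    is_art <- trial$image_type == "Art"
    act_log[is_art, ] <- act_log[is_art, , drop = FALSE] +
      matrix(config$art_act_shift, sum(is_art), 5, byrow = TRUE)
    act_log <- act_log + config$condition_act_shift[trial$condition, ,
                                                    drop = FALSE]
    act_log <- act_log + config$activity_act_shift[trial$activity, ,
                                                   drop = FALSE]
    act_log[, 1] <- act_log[, 1] + trial$re
    deact_log <- matrix(config$deact_logits, n_tr, 5, byrow = TRUE)

    pix <- region_pixel_index(template)
    h <- template$height
    make_clicks <- function(n_clicks, logits, kind) {
      idx <- rep(seq_len(n_tr), n_clicks)
      if (!length(idx)) return(NULL)
      el <- exp(logits - apply(logits, 1, max))
      prob <- el / rowSums(el)
      cum <- t(apply(prob, 1, cumsum))[idx, , drop = FALSE]
      u <- stats::runif(length(idx))
      region <- 1L + rowSums(u > cum[, 1:4, drop = FALSE])
      lin <- integer(length(region))
      for (r in 1:5) {
        sel <- region == r
        if (any(sel))
          lin[sel] <- pix[[r]][sample.int(length(pix[[r]]), sum(sel),
                                          replace = TRUE)]
      }
      data.frame(participant_id = trial$participant_id[idx],
                 image_id = trial$image_id[idx],
                 silhouette_kind = kind,
                 x = (lin - 1L) %/% h,       # column-major index -> 0-based
                 y = (lin - 1L) %% h,
                 stringsAsFactors = FALSE)
    }
    clicks <- rbind(make_clicks(n_act, act_log, "Activation"),
                    make_clicks(n_deact, deact_log, "Deactivation"))
    if (is.null(clicks))
      clicks <- data.frame(participant_id = character(),
                           image_id = character(),
                           silhouette_kind = character(),
                           x = integer(), y = integer())

    mixed_tr <- pres[conds[ppos] == "Mixed", , drop = FALSE]
    guesses <- NULL
    if (nrow(mixed_tr)) {
      ity <- trials$image_type[match(mixed_tr$image_id, trials$image_id)]
      acc <- config$guess_accuracy[ity]
      correct <- stats::runif(nrow(mixed_tr)) < acc
      right <- ifelse(ity == "Art", "ProfessionalArtist", "SellerOfProducts")
      wrong <- ifelse(ity == "Art", "SellerOfProducts", "ProfessionalArtist")
      guesses <- data.frame(participant_id = mixed_tr$participant_id,
                            image_id = mixed_tr$image_id,
                            guess = ifelse(correct, right, wrong),
                            stringsAsFactors = FALSE)
    }

    study <- as_bsm_study(clicks, trials, participants, guesses, pres)
    truth <- list(config = config, re_participant = u_p, re_image = u_i)
    list(study = study, truth = truth)
  })
}

#' Expected embodiment score implied by a simulation configuration
#'
#' The calibration helper mapping planted logit shifts to score-scale
#' effects: computes, exactly up to quadrature, the expected signed-log
#' score of one participant x image x region cell under a configuration.
#' Click counts are integrated over the truncated-Poisson budget and the
#' binomial region allocation by direct convolution; the participant and
#' image random effects (which enter as one Gaussian shift of the
#' activation Head logit) are integrated by Gauss-Hermite quadrature.
#'
#' @param config A `bsm_sim_config`.
#' @param condition,image_type,activity Cell labels; `activity` defaults to
#'   the first configured activity.
#' @param region One of the five region labels.
#' @param n_quad Number of Gauss-Hermite nodes.
#' @return The expected score (a scalar).
#' @export
expected_region_score <- function(config, condition, image_type,
                                  activity = config$activities[1],
                                  region = "Head", n_quad = 41L) {
  validate_sim_config(config)
  regions <- bsm_regions()
  r <- match(region, regions)
  stopifnot(!is.na(r), condition %in% CONDITIONS,
            image_type %in% IMAGE_TYPES)
  base <- config$act_logits +
    (if (image_type == "Art") config$art_act_shift else 0) +
    config$condition_act_shift[condition, ] +
    config$activity_act_shift[activity, ]
  pmf_n <- trunc_pois_pmf(config$lambda_clicks, 10L)
  count_pmf <- function(p) {
    # P(j clicks in region) for j = 0..10 under budget ~ truncated Poisson
    sapply(0:10, function(j)
      sum(pmf_n * stats::dbinom(j, 0:10, p)))
  }
  p_deact <- softmax(config$deact_logits)[r]
  pmf_d <- count_pmf(p_deact)
  scores <- embodiment_score(-10:10)
  sd_tot <- sqrt(config$sd_participant^2 + config$sd_image^2)
  gh <- gauss_hermite(n_quad)
  nodes <- if (sd_tot > 0) gh$nodes * sqrt(2) * sd_tot else 0
  wts <- if (sd_tot > 0) gh$weights / sqrt(pi) else 1
  val <- 0
  for (q in seq_along(nodes)) {
    l <- base
    l[1] <- l[1] + nodes[q]
    p_act <- softmax(l)[r]
    pmf_a <- count_pmf(p_act)
    # pmf of x = n_act - n_deact on -10..10
    pmf_x <- sapply(-10:10, function(x) {
      j <- 0:10
      keep <- j - x >= 0 & j - x <= 10
      sum(pmf_a[j[keep] + 1] * pmf_d[j[keep] - x + 1])
    })
    val <- val + wts[q] * sum(pmf_x * scores)
  }
  val
}

gauss_hermite <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Hermite Jacobi matrix
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' @export
print.bsm_sim_config <- function(x, ...) {
  cat("Simulation config: ", sum(x$n_per_condition), " participants (",
      paste(names(x$n_per_condition), x$n_per_condition, sep = "=",
            collapse = ", "), "), ", x$n_objects, " objects, ",
      2 * x$n_objects, " images, seed ", x$seed, "\n", sep = "")
  cat("  clicks ~ truncPois(", x$lambda_clicks, ", max 10); RE sd: ",
      "participant ", x$sd_participant, ", image ", x$sd_image, "\n",
      sep = "")
  invisible(x)
}
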