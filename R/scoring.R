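#' Signed-log embodiment score
#'
#' Transforms a net click count x = activations - deactivations per body
#' region into the embodiment score sign(x) * log(1 + |x|) (natural log).
#' The transform normalises the -10..10 click-difference distribution while
#' preserving direction; it is odd and strictly increasing, with range
#' [-log(11), log(11)].
#'
#' @param x Integer net click counts in -10..10 (vectorised).
#' @return Numeric scores.
#' @examples
#' embodiment_score(c(-3, 0, 10))  # -log(4), 0, log(11)
#' @export
embodiment_score <- function(x) {
  if (any(is.na(x)) || any(x != round(x)))
    stop("x must be integer click differences", call. = FALSE)
  if (any(abs(x) > 10))
    stop("click difference out of range: |x| must be <= 10 ",
         "(at most 10 clicks per silhouette)", call. = FALSE)
  sign(x) * log(1 + abs(x))
}

#' Tally clicks by body region
#'
#' Summarises activation and deactivation click frequencies separately for
#' each participant and image across the five body regions, zero-filling
#' cells without clicks. Clicks landing outside the silhouette are excluded
#' from the tallies and reported separately.
#'
#' @param study A `bsm_study`.
#' @param template A `bsm_template`.
#' @return List with `counts` — a data frame of participant_id, image_id,
#'   region, n_act, n_deact, one row per participant x seen image x region —
#'   and `outside` — a data frame tallying excluded outside clicks per
#'   participant, image and silhouette kind.
#' @export
count_clicks_by_region <- function(study, template) {
  stopifnot(inherits(study, "bsm_study"), inherits(template, "bsm_template"))
  cl <- study$clicks
  reg <- assign_region(template, cl$x, cl$y)

  # dense grid over the trials: the study's presentation list when recorded,
  # otherwise every (participant, image) pair observed in clicks or guesses.
  pair <- if (!is.null(study$presentations)) {
    study$presentations[, c("participant_id", "image_id")]
  } else {
    unique(rbind(cl[, c("participant_id", "image_id")],
                 if (!is.null(study$guesses))
                   study$guesses[, c("participant_id", "image_id")]))
  }
  pair <- pair[order(pair$participant_id, pair$image_id), , drop = FALSE]
  grid <- data.frame(
    participant_id = rep(pair$participant_id, each = 5L),
    image_id = rep(pair$image_id, each = 5L),
    region = rep(bsm_regions(), times = nrow(pair)),
    stringsAsFactors = FALSE)
  key <- function(p, i, r) paste(p, i, r, sep = "\r")
  inside <- reg != "Outside"
  act <- cl$silhouette_kind == "Activation"
  tally <- function(sel) {
    t <- table(key(cl$participant_id[sel], cl$image_id[sel], reg[sel]))
    n <- as.vector(t[key(grid$participant_id, grid$image_id, grid$region)])
    ifelse(is.na(n), 0L, as.integer(n))
  }
  grid$n_act <- tally(inside & act)
  grid$n_deact <- tally(inside & !act)

  out_sel <- !inside
  outside <- if (any(out_sel)) {
    agg <- stats::aggregate(list(n = rep(1L, sum(out_sel))),
      by = list(participant_id = cl$participant_id[out_sel],
                image_id = cl$image_id[out_sel],
                silhouette_kind = cl$silhouette_kind[out_sel]), FUN = sum)
    agg
  } else {
    data.frame(participant_id = character(), image_id = character(),
               silhouette_kind = character(), n = integer())
  }
  list(counts = grid, outside = outside)
}

#' Build the long analysis table of embodiment scores
#'
#' Joins region counts to trial and participant metadata and computes the
#' net click difference `x` and its signed-log `score` for each
#' participant x image x region cell. Cells are dense over the trials each
#' participant completed (zero-filled), which is what the downstream
#' mixed-effects model expects.
#'
#' @param counts The `counts` data frame from [count_clicks_by_region()],
#'   or the list it returns.
#' @param study A `bsm_study` supplying trial and participant metadata.
#' @return Data frame with columns participant_id, image_id, condition,
#'   image_type, activity, object_name, body_part, n_act, n_deact, x, score.
#' @export
score_table <- function(counts, study) {
  if (is.list(counts) && !is.data.frame(counts)) counts <- counts$counts
  stopifnot(inherits(study, "bsm_study"))
  ti <- match(counts$image_id, study$trials$image_id)
  pi <- match(counts$participant_id, study$participants$participant_id)
  if (anyNA(ti)) stop("score_table: image_id without trial metadata: ",
    paste(utils::head(unique(counts$image_id[is.na(ti)])), collapse = ", "),
    call. = FALSE)
  if (anyNA(pi)) stop("score_table: participant_id without metadata: ",
    paste(utils::head(unique(counts$participant_id[is.na(pi)])), collapse = ", "),
    call. = FALSE)
  x <- counts$n_act - counts$n_deact
  data.frame(
    participant_id = counts$participant_id,
    image_id = counts$image_id,
    condition = study$participants$condition[pi],
    image_type = study$trials$image_type[ti],
    activity = study$trials$activity[ti],
    object_name = study$trials$object_name[ti],
    body_part = counts$region,
    n_act = counts$n_act, n_deact = counts$n_deact,
    x = x, score = embodiment_score(x),
    stringsAsFactors = FALSE)
}
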