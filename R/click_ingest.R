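# Study container: clicks (participant_id, image_id, silhouette_kind, x, y),
# trials (image_id, object_name, activity, image_type, source_url), participants
# (participant_id, condition, attention_checks_passed), optional guesses
# (participant_id, image_id, guess). All CSV, header row, UTF-8.

CONDITIONS <- c("Mixed", "Commercial", "Museum")
IMAGE_TYPES <- c("NotArt", "Art")
SILHOUETTE_KINDS <- c("Activation", "Deactivation")
GUESS_LEVELS <- c("ProfessionalArtist", "SellerOfProducts")

#' The eleven everyday activities of the study design
#'
#' Activities most frequently associated with everyday objects, used to
#' label the 34 stimulus objects.
#'
#' @return Character vector of length 11.
#' @export
bsm_activities <- function() {
  c("eating", "walking", "sleeping", "working", "showering", "dressing",
    "watching media", "drinking", "reading", "cleaning", "observing")
}

new_bsm_study <- function(clicks, trials, participants, guesses = NULL,
                          presentations = NULL) {
  structure(list(clicks = clicks, trials = trials,
                 participants = participants, guesses = guesses,
                 presentations = presentations),
            class = "bsm_study")
}

fail_rows <- function(msg, rows) {
  stop(msg, if (length(rows)) paste0(" (rows: ",
       paste(utils::head(rows, 10), collapse = ", "),
       if (length(rows) > 10) ", ..." else "", ")"),
       call. = FALSE)
}

validate_study <- function(clicks, trials, participants, guesses = NULL,
                           presentations = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(clicks, c("participant_id", "image_id", "silhouette_kind", "x", "y"),
       "clicks")
  need(trials, c("image_id", "object_name", "activity", "image_type"), "trials")
  need(participants, c("participant_id", "condition",
                       "attention_checks_passed"), "participants")

  bad <- which(!(participants$condition %in% CONDITIONS))
  if (length(bad)) fail_rows(paste0("unknown condition label(s): ",
      paste(unique(participants$condition[bad]), collapse = ", ")), bad)
  bad <- which(!(trials$image_type %in% IMAGE_TYPES))
  if (length(bad)) fail_rows("unknown image_type label(s)", bad)
  bad <- which(!(clicks$silhouette_kind %in% SILHOUETTE_KINDS))
  if (length(bad)) fail_rows("malformed silhouette_kind", bad)
  if (anyDuplicated(participants$participant_id))
    stop("duplicated participant_id in participants table", call. = FALSE)
  if (anyDuplicated(trials$image_id))
    stop("duplicated image_id in trials table", call. = FALSE)

  bad <- which(!(clicks$participant_id %in% participants$participant_id))
  if (length(bad)) fail_rows("clicks reference unknown participant_id", bad)
  bad <- which(!(clicks$image_id %in% trials$image_id))
  if (length(bad)) fail_rows("clicks reference unknown image_id", bad)
  if (!is.numeric(clicks$x) || !is.numeric(clicks$y))
    stop("click coordinates must be numeric", call. = FALSE)

  # interface cap: more than 10 clicks per silhouette indicates corrupt data
  key <- paste(clicks$participant_id, clicks$image_id, clicks$silhouette_kind,
               sep = "\r")
  tab <- table(key)
  over <- names(tab)[tab > 10L]
  if (length(over)) {
    parts <- strsplit(over[1], "\r", fixed = TRUE)[[1]]
    stop("more than 10 clicks on one silhouette for participant '", parts[1],
         "', image '", parts[2], "' (", parts[3], "): ", max(tab),
         " clicks; ", length(over), " silhouette(s) affected", call. = FALSE)
  }

  if (!is.null(guesses)) {
    need(guesses, c("participant_id", "image_id", "guess"), "guesses")
    bad <- which(!(guesses$guess %in% GUESS_LEVELS))
    if (length(bad)) fail_rows("unknown guess label(s)", bad)
    cond <- participants$condition[match(guesses$participant_id,
                                         participants$participant_id)]
    bad <- which(is.na(cond) | cond != "Mixed")
    if (length(bad))
      fail_rows("guesses present for non-Mixed or unknown participants", bad)
    bad <- which(!(guesses$image_id %in% trials$image_id))
    if (length(bad)) fail_rows("guesses reference unknown image_id", bad)
  }
  if (!is.null(presentations)) {
    need(presentations, c("participant_id", "image_id"), "presentations")
    bad <- which(!(presentations$participant_id %in%
                     participants$participant_id) |
                 !(presentations$image_id %in% trials$image_id))
    if (length(bad)) fail_rows("presentations reference unknown ids", bad)
    if (anyDuplicated(presentations[, c("participant_id", "image_id")]))
      stop("duplicated (participant, image) presentation", call. = FALSE)
    pk <- paste(presentations$participant_id, presentations$image_id)
    bad <- which(!(paste(clicks$participant_id, clicks$image_id) %in% pk))
    if (length(bad)) fail_rows("clicks on trials not in presentations", bad)
  }
  invisible(TRUE)
}

#' Read and validate a click-level study from CSV files
#'
#' Enforces referential integrity, the controlled vocabularies for
#' condition / image type / silhouette kind / guess, and the interface cap
#' of at most 10 clicks per silhouette per trial (excess clicks are an
#' ingest error, never truncated). Guesses, recorded only for the Mixed
#' condition, live in their own optional file since they are keyed by
#' participant and image.
#'
#' @param clicks_file CSV with columns participant_id, image_id,
#'   silhouette_kind (Activation/Deactivation), x, y (0-based pixels).
#' @param trials_file CSV with columns image_id, object_name, activity,
#'   image_type (Art/NotArt), optional source_url.
#' @param participants_file CSV with columns participant_id, condition
#'   (Museum/Commercial/Mixed), attention_checks_passed (TRUE/FALSE).
#' @param guesses_file Optional CSV with columns participant_id, image_id,
#'   guess (ProfessionalArtist/SellerOfProducts).
#' @param presentations_file Optional CSV with columns participant_id,
#'   image_id, one row per trial actually shown. When present it lets the
#'   scoring table include trials with no clicks at all; without it the
#'   trials a participant saw are inferred from their clicks (and guesses).
#' @return A validated `bsm_study` object.
#' @export
read_study <- function(clicks_file, trials_file, participants_file,
                       guesses_file = NULL, presentations_file = NULL) {
  rd <- function(f) utils::read.csv(f, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  clicks <- rd(clicks_file); trials <- rd(trials_file)
  participants <- rd(participants_file)
  participants$attention_checks_passed <-
    as.logical(participants$attention_checks_passed)
  guesses <- if (!is.null(guesses_file)) rd(guesses_file)
  presentations <- if (!is.null(presentations_file)) rd(presentations_file)
  validate_study(clicks, trials, participants, guesses, presentations)
  new_bsm_study(clicks, trials, participants, guesses, presentations)
}

#' Assemble a study object from in-memory tables
#'
#' Same validation as [read_study()], for data frames already in memory
#' (e.g. straight out of [simulate_study()]).
#'
#' @param clicks,trials,participants,guesses,presentations Data frames in
#'   the documented layouts; `guesses` and `presentations` may be `NULL`.
#' @return A validated `bsm_study`.
#' @export
as_bsm_study <- function(clicks, trials, participants, guesses = NULL,
                         presentations = NULL) {
  validate_study(clicks, trials, participants, guesses, presentations)
  new_bsm_study(clicks, trials, participants, guesses, presentations)
}

#' Write a study to CSV files
#'
#' @param study A `bsm_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (clicks.csv, trials.csv,
#'   participants.csv and, when present, guesses.csv).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "bsm_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clicks.csv", "trials.csv", "participants.csv"))
  utils::write.csv(study$clicks, paths[1], row.names = FALSE)
  utils::write.csv(study$trials, paths[2], row.names = FALSE)
  utils::write.csv(study$participants, paths[3], row.names = FALSE)
  if (!is.null(study$guesses)) {
    p <- file.path(dir, "guesses.csv")
    utils::write.csv(study$guesses, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(study$presentations)) {
    p <- file.path(dir, "presentations.csv")
    utils::write.csv(study$presentations, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Apply the study's participant exclusion rules
#'
#' Removes participants who reported no clicks at all or failed the
#' attention checks. The operation is idempotent and never touches clicks
#' of retained participants.
#'
#' @param study A `bsm_study`.
#' @return List with `study` (the retained `bsm_study`) and `report`, a list
#'   holding an `exclusions` data frame (participant_id, condition, reason)
#'   and `retained_by_condition` counts.
#' @examples
#' sim <- simulate_study(default_study_config(seed = 1))
#' res <- apply_exclusions(sim$study)
#' res$report$retained_by_condition
#' @export
apply_exclusions <- function(study) {
  stopifnot(inherits(study, "bsm_study"))
  p <- study$participants
  n_clicks <- table(factor(study$clicks$participant_id,
                           levels = p$participant_id))
  no_clicks <- as.vector(n_clicks) == 0L
  failed <- !p$attention_checks_passed
  reason <- ifelse(failed & no_clicks, "failed attention checks; no clicks",
            ifelse(failed, "failed attention checks",
            ifelse(no_clicks, "no clicks", NA_character_)))
  excl <- !is.na(reason)
  report <- list(
    exclusions = data.frame(participant_id = p$participant_id[excl],
                            condition = p$condition[excl],
                            reason = reason[excl],
                            stringsAsFactors = FALSE),
    n_input = nrow(p), n_retained = sum(!excl),
    retained_by_condition = table(factor(p$condition[!excl],
                                         levels = CONDITIONS)))
  keep_ids <- p$participant_id[!excl]
  retained <- new_bsm_study(
    study$clicks[study$clicks$participant_id %in% keep_ids, , drop = FALSE],
    study$trials,
    p[!excl, , drop = FALSE],
    if (!is.null(study$guesses))
      study$guesses[study$guesses$participant_id %in% keep_ids, , drop = FALSE],
    if (!is.null(study$presentations))
      study$presentations[study$presentations$participant_id %in% keep_ids, ,
                          drop = FALSE])
  list(study = retained, report = report)
}

#' @export
print.bsm_study <- function(x, ...) {
  cat("BSM study:", nrow(x$participants), "participants,",
      nrow(x$trials), "images,", nrow(x$clicks), "clicks")
  if (!is.null(x$guesses)) cat(",", nrow(x$guesses), "guesses")
  cat("\n")
  print(table(x$participants$condition))
  invisible(x)
}
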