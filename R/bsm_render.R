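# Density fields and red/blue map rendering.
#
# A density map is the sum of truncated Gaussian kernels centred at
# activation clicks minus the same sum over deactivation clicks, evaluated
# on the pixel grid and masked to the silhouette. Rendering divides by a
# scale maximum and applies a diverging palette: neutral grey at zero inside
# the body, pure red at +1, pure blue at -1, white background. The palette
# is built so that the red-minus-blue channel difference of a body pixel
# equals the normalised field value exactly, which makes downstream pixel
# classification a thresholding of that difference.

NEUTRAL_GREY <- 0.85

gaussian_stamp <- function(sigma) {
  r <- ceiling(3 * sigma)  # truncate at 3 sigma
  d <- (-r):r
  k <- exp(-(d^2) / (2 * sigma^2))
  outer(k, k)
}

#' Aggregate clicks into a smoothed net activation field
#'
#' Places a truncated Gaussian kernel (3-sigma support) at every click,
#' adding activation kernels and subtracting deactivation kernels, then
#' masks the field to the silhouette. The result is linear in the click
#' multiset, so densities of disjoint click sets add pixelwise.
#'
#' @param clicks Data frame with columns silhouette_kind, x, y (a subset of
#'   a study's clicks; may be empty, giving an all-zero field).
#' @param template A `bsm_template`.
#' @param bandwidth Kernel standard deviation in pixels (> 0); default 5.
#' @param n_trials Number of trials the subset represents, stored as
#'   provenance (defaults to the number of distinct participant-image pairs
#'   when those columns are present).
#' @return A `bsm_density` object: `field` (height x width numeric matrix,
#'   positive = net activation), `template`, `bandwidth`,
#'   `n_trials_aggregated`.
#' @export
aggregate_density <- function(clicks, template, bandwidth = 5,
                              n_trials = NULL) {
  stopifnot(inherits(template, "bsm_template"))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("bandwidth must be a positive number of pixels", call. = FALSE)
  h <- template$height; w <- template$width
  field <- matrix(0, h, w)
  if (nrow(clicks)) {
    stamp <- gaussian_stamp(bandwidth)
    r <- (nrow(stamp) - 1L) %/% 2L
    sgn <- ifelse(clicks$silhouette_kind == "Activation", 1, -1)
    cx <- as.integer(round(clicks$x)); cy <- as.integer(round(clicks$y))
    for (i in seq_len(nrow(clicks))) {
      rows <- (cy[i] + 1L - r):(cy[i] + 1L + r)
      cols <- (cx[i] + 1L - r):(cx[i] + 1L + r)
      rok <- rows >= 1L & rows <= h; cok <- cols >= 1L & cols <= w
      if (!any(rok) || !any(cok)) next
      field[rows[rok], cols[cok]] <- field[rows[rok], cols[cok]] +
        sgn[i] * stamp[rok, cok, drop = FALSE]
    }
  }
  field[!template$silhouette_mask] <- 0
  if (is.null(n_trials)) {
    n_trials <- if (all(c("participant_id", "image_id") %in% names(clicks))) {
      nrow(unique(clicks[, c("participant_id", "image_id")]))
    } else 0L
  }
  structure(list(field = field, template = template, bandwidth = bandwidth,
                 n_trials_aggregated = n_trials),
            class = "bsm_density")
}

diverging_rgb <- function(v) {
  # v in [-1, 1]; returns list of R, G, B matrices. Red channel minus blue
  # channel equals v exactly; v and -v swap the red and blue channels.
  g <- NEUTRAL_GREY
  pos <- pmax(v, 0); neg <- pmax(-v, 0)
  list(r = g + pos * (1 - g) - neg * g,
       g = g - abs(v) * g,
       b = g + neg * (1 - g) - pos * g)
}

#' Render a density map as a red/blue Bodily Sensation Map
#'
#' Applies a symmetric diverging colour map after dividing the field by a
#' scale maximum: reds mark net activation, blues net deactivation, neutral
#' grey zero sensation inside the body, and white the background. With
#' `scale_mode = "fixed"` the caller supplies the maximum so that several
#' maps share one colour scale (required for colour-distance comparison);
#' `"per_map"` scales each map by its own absolute maximum.
#'
#' @param density A `bsm_density`.
#' @param scale_mode `"per_map"` or `"fixed"`.
#' @param scale_max Positive scale maximum, required for `"fixed"`.
#' @param provenance Optional character description of the filter that
#'   produced the map.
#' @return A `bsm_image`: `rgb` (height x width x 3 array in [0,1]),
#'   `template`, `scale_mode`, `scale_max`, `provenance`.
#' @export
render_bsm <- function(density, scale_mode = c("per_map", "fixed"),
                       scale_max = NULL, provenance = "") {
  stopifnot(inherits(density, "bsm_density"))
  scale_mode <- match.arg(scale_mode)
  if (any(!is.finite(density$field)))
    stop("density field contains non-finite values", call. = FALSE)
  if (scale_mode == "fixed") {
    if (is.null(scale_max) || !is.numeric(scale_max) || scale_max <= 0)
      stop("fixed scale mode needs a positive scale_max", call. = FALSE)
  } else {
    scale_max <- max(abs(density$field))
    if (scale_max == 0) scale_max <- 1  # zero field renders neutral
  }
  v <- density$field / scale_max
  v <- pmin(pmax(v, -1), 1)
  ch <- diverging_rgb(v)
  tpl <- density$template
  rgb <- array(1, dim = c(tpl$height, tpl$width, 3))  # white background
  m <- tpl$silhouette_mask
  for (i in 1:3) {
    plane <- rgb[, , i]
    plane[m] <- ch[[i]][m]
    rgb[, , i] <- plane
  }
  structure(list(rgb = rgb, template = tpl, scale_mode = scale_mode,
                 scale_max = scale_max, provenance = provenance),
            class = "bsm_image")
}

#' Write a BSM image to a PNG file
#'
#' @param image A `bsm_image`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bsm_png <- function(image, path) {
  stopifnot(inherits(image, "bsm_image"))
  png::writePNG(image$rgb, path)
  invisible(path)
}

#' Read an RGB image back as a `bsm_image`
#'
#' For re-analysing externally produced maps; dimensions must match the
#' template.
#'
#' @param path PNG file path.
#' @param template The `bsm_template` the image was rendered on.
#' @param scale_mode,scale_max,provenance Provenance fields to attach.
#' @return A `bsm_image`.
#' @export
read_bsm_png <- function(path, template, scale_mode = "fixed",
                         scale_max = 1, provenance = basename(path)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  if (nrow(img) != template$height || ncol(img) != template$width)
    stop("image size does not match template", call. = FALSE)
  structure(list(rgb = img, template = template, scale_mode = scale_mode,
                 scale_max = scale_max, provenance = provenance),
            class = "bsm_image")
}

subset_clicks <- function(study, filter) {
  cl <- study$clicks
  keep <- rep(TRUE, nrow(cl))
  for (var in names(filter)) {
    val <- filter[[var]]
    if (var %in% names(study$participants)) {
      ids <- study$participants$participant_id[
        study$participants[[var]] %in% val]
      keep <- keep & cl$participant_id %in% ids
    } else if (var %in% names(study$trials)) {
      ids <- study$trials$image_id[study$trials[[var]] %in% val]
      keep <- keep & cl$image_id %in% ids
    } else if (var == "participant_id") {
      keep <- keep & cl$participant_id %in% val
    } else {
      stop("unknown filter variable '", var, "'", call. = FALSE)
    }
  }
  cl[keep, , drop = FALSE]
}

#' Render a grid of BSMs filtered by study variables
#'
#' The flexible filtering loop: renders one map per combination of the
#' requested variable levels (e.g. condition x image_type gives six maps on
#' the full design), all on a shared fixed colour scale so the set is
#' comparable and clusterable. Maps are named, and optionally written,
#' following the pattern `bsm_<var1>-<val1>_<var2>-<val2>.png`.
#'
#' @param study A `bsm_study`.
#' @param by Character vector of filter variables; each must be a column of
#'   the participants table (e.g. `condition`) or the trials table (e.g.
#'   `image_type`, `activity`). Levels default to the values present.
#' @param levels Optional named list fixing the levels per variable.
#' @param template A `bsm_template`.
#' @param bandwidth Kernel bandwidth in pixels.
#' @param per_trial Normalise each field by its number of aggregated trials
#'   before scaling (default TRUE), so cells with different trial counts
#'   are comparable.
#' @param out_dir Optional directory; when given, each map is written as a
#'   PNG there.
#' @return Named list of `bsm_image` objects. A combination selecting zero
#'   trials yields an all-neutral map with a warning.
#' @export
render_filtered_grid <- function(study, by, levels = NULL,
                                 template = make_default_template(),
                                 bandwidth = 5, per_trial = TRUE,
                                 out_dir = NULL) {
  stopifnot(inherits(study, "bsm_study"), length(by) >= 1L)
  lv <- lapply(by, function(var) {
    if (!is.null(levels[[var]])) return(levels[[var]])
    if (var %in% names(study$participants))
      sort(unique(study$participants[[var]]))
    else if (var %in% names(study$trials))
      sort(unique(study$trials[[var]]))
    else stop("unknown filter variable '", var, "'", call. = FALSE)
  })
  names(lv) <- by
  combos <- expand.grid(lv, stringsAsFactors = FALSE)
  densities <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    filter <- as.list(combos[i, , drop = FALSE])
    cl <- subset_clicks(study, filter)
    if (!nrow(cl))
      warning("filter ", paste(by, unlist(filter), sep = "=", collapse = ", "),
              " selects zero clicks; map is empty", call. = FALSE)
    d <- aggregate_density(cl, template, bandwidth)
    if (per_trial && d$n_trials_aggregated > 0)
      d$field <- d$field / d$n_trials_aggregated
    densities[[i]] <- d
  }
  global_max <- max(c(1e-12, vapply(densities,
                                    function(d) max(abs(d$field)), 0)))
  out <- vector("list", nrow(combos))
  names(out) <- apply(combos, 1, function(row)
    paste0("bsm_", paste(by, gsub("[^A-Za-z0-9.-]", "-", row),
                         sep = "-", collapse = "_")))
  for (i in seq_len(nrow(combos))) {
    prov <- paste(by, unlist(combos[i, ]), sep = "=", collapse = ", ")
    out[[i]] <- render_bsm(densities[[i]], "fixed", scale_max = global_max,
                           provenance = prov)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bsm_png(out[[i]], file.path(out_dir,
                                        paste0(names(out)[i], ".png")))
    }
  }
  out
}

#' @export
print.bsm_density <- function(x, ...) {
  cat("BSM density field:", x$template$width, "x", x$template$height,
      "px, bandwidth", x$bandwidth, "px,", x$n_trials_aggregated,
      "trial(s); range [", signif(min(x$field), 3), ",",
      signif(max(x$field), 3), "]\n")
  invisible(x)
}

#' @export
print.bsm_image <- function(x, ...) {
  cat("BSM image", if (nzchar(x$provenance)) paste0("[", x$provenance, "]"),
      ":", x$template$width, "x", x$template$height, "px, scale",
      x$scale_mode, "max", signif(x$scale_max, 4), "\n")
  invisible(x)
}

#' @export
plot.bsm_image <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 1, 0)); on.exit(graphics::par(op))
  graphics::plot(c(0, x$template$width), c(0, x$template$height),
                 type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1, main = x$provenance, ...)
  graphics::rasterImage(x$rgb, 0, 0, x$template$width, x$template$height)
  invisible(x)
}
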