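#' Region labels used throughout the package
#'
#' The five analysis regions every click and pixel statistic is referred to,
#' in their canonical order.
#'
#' @return Character vector of the five region labels.
#' @export
bsm_regions <- function() {
  c("Head", "Chest", "Abdomen", "UpperLimbs", "LowerLimbs")
}

# Masks are logical matrices indexed [row = y + 1, col = x + 1]: 0-based pixel
# coordinates, origin top-left, y increasing downward (raster convention).

new_bsm_template <- function(width, height, silhouette, labels) {
  structure(
    list(width = as.integer(width), height = as.integer(height),
         silhouette_mask = silhouette, label_matrix = labels,
         regions = bsm_regions()),
    class = "bsm_template")
}

#' Construct the default frontal body silhouette template
#'
#' Draws a programmatic frontal human silhouette (head ellipse with neck,
#' torso split into chest and abdomen bands, two arms, two legs) and
#' partitions it into the five analysis regions. Hands belong to UpperLimbs,
#' feet to LowerLimbs, and the neck to Head. The drawing is deterministic
#' for fixed dimensions.
#'
#' @param width Template width in pixels (>= 50).
#' @param height Template height in pixels (>= 150).
#' @return A `bsm_template` object: width, height, a logical
#'   `silhouette_mask`, and an integer `label_matrix` (0 = background,
#'   1..5 indexing [bsm_regions()]).
#' @examples
#' tpl <- make_default_template(200, 600)
#' sapply(region_masks(tpl), sum)
#' @export
make_default_template <- function(width = 200L, height = 600L) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 50L || height < 150L) {
    stop("template dimensions too small: need width >= 50 and height >= 150 ",
         "to draw all five regions", call. = FALSE)
  }
  w <- width; h <- height
  # pixel-centre coordinate grids, 0-based
  x <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  u <- (x + 0.5) / w   # 0..1 across
  v <- (y + 0.5) / h   # 0..1 down

  in_ellipse <- function(cx, cy, rx, ry) ((u - cx) / rx)^2 + ((v - cy) / ry)^2 <= 1
  in_rect <- function(x0, x1, y0, y1) u >= x0 & u < x1 & v >= y0 & v < y1

  head <- in_ellipse(0.5, 0.083, 0.14, 0.058) |
    in_rect(0.44, 0.56, 0.11, 0.15)                       # cranium + neck
  chest <- in_rect(0.30, 0.70, 0.15, 0.30)
  abdomen <- in_rect(0.30, 0.70, 0.30, 0.45)
  arms <- in_rect(0.16, 0.28, 0.16, 0.52) | in_rect(0.72, 0.84, 0.16, 0.52)
  legs <- in_rect(0.32, 0.47, 0.45, 0.97) | in_rect(0.53, 0.68, 0.45, 0.97)

  # assign with fixed precedence so touching shapes can never overlap
  lab <- matrix(0L, h, w)
  for (i in seq_along(bsm_regions())) {
    m <- switch(i, head, chest, abdomen, arms, legs)
    lab[m & lab == 0L] <- i
  }
  new_bsm_template(w, h, lab > 0L, lab)
}

#' Extract the five region masks of a template
#'
#' @param template A `bsm_template`.
#' @return Named list of logical matrices, one per region.
#' @export
region_masks <- function(template) {
  stopifnot(inherits(template, "bsm_template"))
  out <- lapply(seq_along(template$regions),
                function(i) template$label_matrix == i)
  names(out) <- template$regions
  out
}

#' Map a pixel to its body region
#'
#' Total function over all integer coordinates: out-of-bounds and background
#' pixels map to `"Outside"`.
#'
#' @param template A `bsm_template`.
#' @param x,y Integer 0-based pixel coordinates (vectorised; origin top-left,
#'   y increases downward).
#' @return Character vector of region labels or `"Outside"`.
#' @examples
#' tpl <- make_default_template()
#' assign_region(tpl, 0, 0)  # corner is background
#' @export
assign_region <- function(template, x, y) {
  stopifnot(inherits(template, "bsm_template"))
  x <- as.integer(round(x)); y <- as.integer(round(y))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- rep("Outside", n)
  ok <- !is.na(x) & !is.na(y) &
    x >= 0L & x < template$width & y >= 0L & y < template$height
  idx <- template$label_matrix[cbind(y[ok] + 1L, x[ok] + 1L)]
  out[ok][idx > 0L] <- template$regions[idx[idx > 0L]]
  out
}

#' Write a template to disk as PNG masks plus a label key
#'
#' Writes `<stem>_silhouette.png` (black/white), `<stem>_regions.png`
#' (grayscale, pixel value = region index / 255) and `<stem>_regions.txt`
#' (index to label map, tab-separated).
#'
#' @param template A `bsm_template`.
#' @param stem File path stem (directories must exist).
#' @return Invisibly, the three file paths.
#' @export
write_template <- function(template, stem) {
  stopifnot(inherits(template, "bsm_template"))
  sil_path <- paste0(stem, "_silhouette.png")
  reg_path <- paste0(stem, "_regions.png")
  key_path <- paste0(stem, "_regions.txt")
  png::writePNG(template$silhouette_mask * 1, sil_path)
  png::writePNG(template$label_matrix / 255, reg_path)
  utils::write.table(
    data.frame(index = seq_along(template$regions), label = template$regions),
    key_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(sil_path, reg_path, key_path))
}

#' Load a template from silhouette and region images
#'
#' Reads the files written by [write_template()] (or equivalents produced
#' elsewhere) and validates the partition invariants. Violations are
#' reported with offending pixel counts, never repaired silently.
#'
#' @param silhouette_path PNG with non-zero pixels marking the body.
#' @param regions_path Grayscale PNG whose pixel values encode region index
#'   / 255 (0 = background).
#' @param key_path Tab-separated file with columns `index` and `label`
#'   labelling exactly the five regions.
#' @return A validated `bsm_template`.
#' @export
load_template <- function(silhouette_path, regions_path, key_path) {
  sil_img <- png::readPNG(silhouette_path)
  if (length(dim(sil_img)) == 3L) sil_img <- sil_img[, , 1L]
  reg_img <- png::readPNG(regions_path)
  if (length(dim(reg_img)) == 3L) reg_img <- reg_img[, , 1L]
  key <- utils::read.table(key_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("index", "label") %in% names(key))) {
    stop("region key file must have columns 'index' and 'label'", call. = FALSE)
  }
  missing <- setdiff(bsm_regions(), key$label)
  extra <- setdiff(key$label, bsm_regions())
  if (length(missing) || length(extra)) {
    stop("region key must label exactly the five regions; missing: ",
         paste(missing, collapse = ", "), "; unknown: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!identical(dim(sil_img), dim(reg_img))) {
    stop("silhouette and region images differ in size: ",
         paste(dim(sil_img), collapse = "x"), " vs ",
         paste(dim(reg_img), collapse = "x"), call. = FALSE)
  }
  sil <- sil_img > 0.5
  idx_raw <- as.integer(round(reg_img * 255))
  # remap file indices to canonical region order
  lab <- matrix(0L, nrow(reg_img), ncol(reg_img))
  for (r in seq_len(nrow(key))) {
    canon <- match(key$label[r], bsm_regions())
    lab[idx_raw == key$index[r]] <- canon
  }
  unknown_idx <- sum(idx_raw != 0L & !(idx_raw %in% key$index))
  uncovered <- sum(sil & lab == 0L)
  spill <- sum(!sil & lab > 0L)
  if (unknown_idx || uncovered || spill) {
    stop("region map does not partition the silhouette: ",
         unknown_idx, " pixel(s) with unknown region index, ",
         uncovered, " silhouette pixel(s) uncovered, ",
         spill, " region pixel(s) outside the silhouette", call. = FALSE)
  }
  new_bsm_template(ncol(sil), nrow(sil), sil, lab)
}

#' @export
print.bsm_template <- function(x, ...) {
  cat("Body template:", x$width, "x", x$height, "px,",
      sum(x$silhouette_mask), "body pixels\n")
  counts <- vapply(seq_along(x$regions),
                   function(i) sum(x$label_matrix == i), integer(1))
  cat(paste0("  ", format(x$regions, width = 11), " ", counts, " px",
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.bsm_template <- function(x, ...) {
  graphics::image(t(x$label_matrix)[, x$height:1],
                  col = c("white", grDevices::hcl.colors(5, "Zissou 1")),
                  axes = FALSE, asp = x$height / x$width, ...)
  invisible(x)
}
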