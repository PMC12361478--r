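# Colour-distribution comparison of BSMs: k-means binning of body-pixel RGB
# values, Earth Mover's Distance between the binned distributions, and
# agglomerative clustering of the resulting distance matrix.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

new_color_distribution <- function(centroids, weights) {
  structure(list(centroids = centroids, weights = as.numeric(weights),
                 k = nrow(centroids)),
            class = "bsm_color_distribution")
}

#' Bin a BSM's body-pixel colours with k-means
#'
#' Clusters the RGB values of all pixels inside the silhouette (background
#' always excluded, neutral body pixels included — they carry the
#' "no sensation" information that distinguishes sparse from dense maps)
#' into `k` bins. Bin weight is the fraction of body pixels in the bin.
#' When the image has fewer distinct colours than `k`, the bin count is
#' reduced to the distinct-colour count with a warning, and the bins are
#' then exact.
#'
#' @param image A `bsm_image`.
#' @param template A `bsm_template`.
#' @param k Number of colour bins (>= 1); default 10.
#' @param seed Integer seed making the k-means start deterministic.
#' @param nstart Random restarts for k-means; default 10.
#' @return A `bsm_color_distribution`: `centroids` (k x 3 RGB in [0,1]),
#'   `weights` (non-negative, summing to 1), `k`.
#' @export
bin_colors <- function(image, template, k = 10L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(image, "bsm_image"), inherits(template, "bsm_template"),
            k >= 1L)
  m <- template$silhouette_mask
  px <- cbind(image$rgb[, , 1][m], image$rgb[, , 2][m], image$rgb[, , 3][m])
  colnames(px) <- c("r", "g", "b")
  distinct <- unique(px)
  if (nrow(distinct) <= k) {
    if (nrow(distinct) < k)
      warning("only ", nrow(distinct), " distinct colour(s); reducing k from ",
              k, call. = FALSE)
    key <- paste(px[, 1], px[, 2], px[, 3])
    dkey <- paste(distinct[, 1], distinct[, 2], distinct[, 3])
    w <- as.numeric(table(factor(key, levels = dkey))) / nrow(px)
    return(new_color_distribution(distinct, w))
  }
  # MacQueen update: Hartigan-Wong's Quick-TRANSfer stage stalls on rasters
  # whose colour values are massively duplicated
  km <- with_seed(seed,
    stats::kmeans(px, centers = k, nstart = nstart, iter.max = 1000L,
                  algorithm = "MacQueen"))
  new_color_distribution(km$centers, as.numeric(km$size) / nrow(px))
}

#' Earth Mover's Distance between two colour distributions
#'
#' Minimum-cost transport between the weighted colour bins with Euclidean
#' RGB ground distance, solved exactly by the transportation simplex
#' ([solve_transport()]). With both weight vectors summing to one this is a
#' metric on colour distributions.
#'
#' @param a,b `bsm_color_distribution` objects.
#' @return Non-negative EMD value.
#' @export
emd <- function(a, b) {
  stopifnot(inherits(a, "bsm_color_distribution"),
            inherits(b, "bsm_color_distribution"))
  if (!length(a$weights) || !length(b$weights) ||
      sum(a$weights) <= 0 || sum(b$weights) <= 0)
    stop("degenerate (empty) colour distribution", call. = FALSE)
  # exact pairwise Euclidean distances (bin counts are tiny)
  ground <- matrix(0, nrow(a$centroids), nrow(b$centroids))
  for (j in seq_len(nrow(b$centroids)))
    ground[, j] <- sqrt(colSums((t(a$centroids) - b$centroids[j, ])^2))
  solve_transport(a$weights / sum(a$weights),
                  b$weights / sum(b$weights), ground)$cost
}

#' Pairwise EMD distance matrix for a set of BSMs
#'
#' Bins each image with [bin_colors()] under the same `k` and seed and
#' computes all pairwise EMDs. All images must have been rendered under a
#' shared fixed colour scale — comparing maps with per-map or differing
#' scales is refused as meaningless.
#'
#' @param images Named list of `bsm_image` objects (>= 2), all with
#'   `scale_mode = "fixed"` and a common `scale_max`.
#' @param template A `bsm_template`.
#' @param k Colour bins per image.
#' @param seed Integer seed for the binning.
#' @return A `bsm_distmat`: `labels` and the symmetric `values` matrix with
#'   zero diagonal.
#' @export
distance_matrix <- function(images, template, k = 10L, seed = 1L) {
  stopifnot(length(images) >= 2L)
  modes <- vapply(images, function(x) x$scale_mode, "")
  scales <- vapply(images, function(x) x$scale_max, 0)
  if (any(modes != "fixed") || length(unique(signif(scales, 12))) != 1L)
    stop("distance_matrix needs images rendered under one shared fixed ",
         "colour scale", call. = FALSE)
  labels <- names(images)
  if (is.null(labels))
    labels <- vapply(images, function(x) x$provenance, "")
  dists <- lapply(images, bin_colors, template = template, k = k, seed = seed)
  n <- length(images)
  vals <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    vals[i, j] <- vals[j, i] <- emd(dists[[i]], dists[[j]])
  }
  structure(list(labels = labels, values = vals, k = k, seed = seed),
            class = "bsm_distmat")
}

#' Agglomerative clustering of a BSM distance matrix
#'
#' Hierarchical clustering (via [stats::hclust()]) of the pairwise EMD
#' structure; the dendrogram is the exploratory view of recurring
#' embodiment patterns.
#'
#' @param distmat A `bsm_distmat`.
#' @param linkage One of "average" (default), "complete", "single".
#' @return A `bsm_clustertree` wrapping the `hclust` object (or, for a
#'   single map, a degenerate one-leaf tree).
#' @export
hierarchical_cluster <- function(distmat,
                                 linkage = c("average", "complete",
                                             "single")) {
  stopifnot(inherits(distmat, "bsm_distmat"))
  linkage <- match.arg(linkage)
  if (length(distmat$labels) == 1L) {
    return(structure(list(hclust = NULL, labels = distmat$labels,
                          linkage = linkage),
                     class = "bsm_clustertree"))
  }
  hc <- stats::hclust(stats::as.dist(distmat$values), method = linkage)
  structure(list(hclust = hc, labels = distmat$labels, linkage = linkage),
            class = "bsm_clustertree")
}

#' Export a cluster tree in Newick format
#'
#' @param tree A `bsm_clustertree`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "bsm_clustertree"))
  if (is.null(tree$hclust)) {
    nwk <- paste0(tree$labels, ";")
  } else {
    nwk <- ape::write.tree(ape::as.phylo(tree$hclust))
  }
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Plot a distance matrix as a similarity heatmap
#'
#' Low distances (similar maps) are drawn in dark blue, high distances in
#' bright pink.
#'
#' @param x A `bsm_distmat`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.bsm_distmat <- function(x, ...) {
  n <- length(x$labels)
  pal <- grDevices::colorRampPalette(c("#08306B", "#4292C6", "#F768A1"))(64)
  op <- graphics::par(mar = c(8, 8, 1, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(n), seq_len(n), t(x$values[n:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(n), x$labels, las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(n), rev(x$labels), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' @export
print.bsm_distmat <- function(x, ...) {
  cat("BSM colour distance matrix:", length(x$labels), "maps, k =", x$k,
      "bins\n")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
print.bsm_color_distribution <- function(x, ...) {
  cat("Colour distribution:", x$k, "bins\n")
  print(cbind(round(x$centroids, 3), weight = round(x$weights, 4)))
  invisible(x)
}

#' @export
plot.bsm_clustertree <- function(x, ...) {
  if (is.null(x$hclust)) {
    graphics::plot.new(); graphics::text(0.5, 0.5, x$labels)
  } else {
    graphics::plot(x$hclust, hang = -1, cex = 0.6,
                   main = paste("BSM clustering,", x$linkage, "linkage"),
                   xlab = "", sub = "", ...)
  }
  invisible(x)
}

#' @export
print.bsm_clustertree <- function(x, ...) {
  cat("BSM cluster tree (", x$linkage, " linkage, ",
      length(x$labels), " leaves)\n", sep = "")
  invisible(x)
}
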