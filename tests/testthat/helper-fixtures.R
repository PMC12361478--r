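# Shared fixtures and independent oracles.

# small template used where geometry details do not matter (fast)
small_template <- function() make_default_template(80, 240)

# a minimal hand-built study: 2 participants x 2 images
tiny_study <- function(clicks = NULL) {
  trials <- data.frame(
    image_id = c("imgA", "imgB"),
    object_name = c("cup", "cup"),
    activity = c("drinking", "drinking"),
    image_type = c("Art", "NotArt"),
    stringsAsFactors = FALSE)
  participants <- data.frame(
    participant_id = c("p1", "p2"),
    condition = c("Mixed", "Museum"),
    attention_checks_passed = c(TRUE, TRUE),
    stringsAsFactors = FALSE)
  if (is.null(clicks))
    clicks <- data.frame(participant_id = "p1", image_id = "imgA",
                         silhouette_kind = "Activation", x = 40L, y = 15L,
                         stringsAsFactors = FALSE)
  as_bsm_study(clicks, trials, participants)
}

# centroid pixel of a mask (rounded, guaranteed in-mask for convex shapes)
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = round(mean(idx[, 2])) - 1L, y = round(mean(idx[, 1])) - 1L)
}

# independent LP oracle for the transportation problem (two-phase simplex
# from the boot package; completely separate from solve_transport)
emd_lp_oracle <- function(a, b, cost) {
  m <- length(a); n <- length(b)
  A3 <- rbind(
    t(vapply(seq_len(m), function(i) as.numeric(rep(seq_len(m), n) == i),
             numeric(m * n))),
    t(vapply(seq_len(n), function(j)
      as.numeric(rep(seq_len(n), each = m) == j), numeric(m * n))))
  # drop one redundant balance constraint
  s <- boot::simplex(a = -as.vector(cost), A3 = A3[-(m + n), , drop = FALSE],
                     b3 = c(a, b)[-(m + n)], maxi = TRUE)
  unname(-s$value)
}

# brute-force oracle: enumerate every candidate basis (all cell subsets of
# size m+n-1), solve the flow equations, keep feasible solutions, minimise
emd_enumeration_oracle <- function(a, b, cost) {
  m <- length(a); n <- length(b)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  nb <- m + n - 1L
  combos <- utils::combn(nrow(cells), nb)
  A_full <- matrix(0, m + n, nrow(cells))
  for (k in seq_len(nrow(cells)))
    A_full[c(cells$i[k], m + cells$j[k]), k] <- 1
  rhs <- c(a, b)[-(m + n)]
  best <- Inf
  for (c_idx in seq_len(ncol(combos))) {
    sel <- combos[, c_idx]
    A <- A_full[-(m + n), sel, drop = FALSE]
    flow <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(flow) || any(flow < -1e-9)) next
    val <- sum(flow * cost[cbind(cells$i[sel], cells$j[sel])])
    if (val < best) best <- val
  }
  best
}

random_color_distribution <- function(k) {
  w <- stats::runif(k); w <- w / sum(w)
  d <- structure(list(centroids = matrix(stats::runif(3 * k), k, 3),
                      weights = w, k = k),
                 class = "bsm_color_distribution")
  d
}

# paint a flat-coloured rectangular patch into a bsm_image
paint_patch <- function(image, x0, x1, y0, y1, rgb) {
  for (ch in 1:3)
    image$rgb[(y0:y1) + 1L, (x0:x1) + 1L, ch] <- rgb[ch]
  image
}

neutral_image <- function(template) {
  d <- aggregate_density(
    data.frame(participant_id = character(), image_id = character(),
               silhouette_kind = character(), x = integer(), y = integer()),
    template)
  render_bsm(d, "fixed", scale_max = 1)
}
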