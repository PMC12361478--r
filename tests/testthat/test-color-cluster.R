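test_that("transport solver matches the independent LP oracle", {
  skip_if_not_installed("boot")
  set.seed(17)
  for (rep in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    a <- runif(m); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    cost <- matrix(runif(m * n), m, n)
    res <- solve_transport(a, b, cost)
    expect_equal(res$cost, emd_lp_oracle(a, b, cost), tolerance = 1e-9)
    expect_equal(rowSums(res$plan), a, tolerance = 1e-9)
    expect_equal(colSums(res$plan), b, tolerance = 1e-9)
  }
  # degenerate ties (equal masses) must not trip the pivoting
  res <- solve_transport(c(.25, .25, .25, .25), c(.5, .5),
                         matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2))
  expect_equal(res$cost, emd_lp_oracle(c(.25, .25, .25, .25), c(.5, .5),
                                       matrix(c(1, 2, 3, 4, 4, 3, 2, 1),
                                              4, 2)), tolerance = 1e-9)
  expect_error(solve_transport(c(1, 1), c(1), matrix(1, 2, 1)),
               "balanced")
})

test_that("transport solver matches exhaustive basis enumeration", {
  set.seed(23)
  for (rep in 1:4) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    a <- runif(m); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    cost <- matrix(runif(m * n), m, n)
    expect_equal(solve_transport(a, b, cost)$cost,
                 emd_enumeration_oracle(a, b, cost), tolerance = 1e-9)
  }
})

test_that("colour binning is exact for simple palettes and seeded for
           natural maps", {
  tpl <- small_template()
  img <- neutral_image(tpl)
  one <- bin_colors(img, tpl, k = 1)
  expect_identical(one$k, 1L)
  expect_equal(one$weights, 1)
  g <- img$rgb[, , 1][tpl$silhouette_mask][1]
  expect_equal(as.numeric(one$centroids), c(g, g, g))

  # half the body red, half blue, k = 2 -> weights 0.5 / 0.5
  half <- img
  body <- which(tpl$silhouette_mask)
  n_half <- length(body) %/% 2
  for (ch in 1:3) {
    plane <- half$rgb[, , ch]
    plane[body] <- c(1, 0, 0)[ch]
    plane[body[seq_len(n_half)]] <- c(0, 0, 1)[ch]
    half$rgb[, , ch] <- plane
  }
  two <- bin_colors(half, tpl, k = 2)
  expect_equal(sort(two$weights), c(n_half, length(body) - n_half) /
                 length(body))
  expect_equal(sum(two$weights), 1, tolerance = 1e-9)

  # fewer distinct colours than k reduces k with a warning
  expect_warning(red <- bin_colors(half, tpl, k = 5), "reducing k")
  expect_identical(red$k, 2L)

  # natural map, fixed seed, run twice -> identical distributions
  sim <- simulate_study(sim_config(
    n_per_condition = c(Museum = 2, Commercial = 2, Mixed = 2), seed = 2),
    tpl)
  nat <- render_filtered_grid(sim$study, "image_type", template = tpl)[[1]]
  b1 <- bin_colors(nat, tpl, k = 10, seed = 99)
  b2 <- bin_colors(nat, tpl, k = 10, seed = 99)
  expect_identical(b1, b2)
  expect_equal(sum(b1$weights), 1, tolerance = 1e-9)
})

test_that("EMD is a metric with Euclidean ground distance", {
  set.seed(41)
  # identity, symmetry, triangle inequality over random triples
  for (rep in 1:50) {
    k <- sample(2:5, 3, replace = TRUE)
    a <- random_color_distribution(k[1])
    b <- random_color_distribution(k[2])
    c3 <- random_color_distribution(k[3])
    expect_equal(emd(a, a), 0, tolerance = 1e-9)
    expect_equal(emd(a, b), emd(b, a), tolerance = 1e-9)
    expect_lte(emd(a, c3), emd(a, b) + emd(b, c3) + 1e-9)
  }
  # single-bin distributions: EMD is the Euclidean colour distance
  p1 <- structure(list(centroids = matrix(c(.1, .2, .3), 1), weights = 1,
                       k = 1L), class = "bsm_color_distribution")
  p2 <- structure(list(centroids = matrix(c(.5, .9, .3), 1), weights = 1,
                       k = 1L), class = "bsm_color_distribution")
  expect_equal(emd(p1, p2), sqrt(sum((c(.1, .2, .3) - c(.5, .9, .3))^2)))
  bad <- structure(list(centroids = matrix(0, 0, 3), weights = numeric(),
                        k = 0L), class = "bsm_color_distribution")
  expect_error(emd(p1, bad), "degenerate")
})

test_that("EMD scales linearly with the ground distance", {
  set.seed(43)
  a <- random_color_distribution(4)
  b <- random_color_distribution(3)
  base <- emd(a, b)
  for (s in c(0.25, 0.5, 2)) {
    as <- a; as$centroids <- a$centroids * s
    bs <- b; bs$centroids <- b$centroids * s
    expect_equal(emd(as, bs), s * base, tolerance = 1e-9)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and honest about
           scales", {
  tpl <- small_template()
  sim <- simulate_study(sim_config(
    n_per_condition = c(Museum = 2, Commercial = 2, Mixed = 2), seed = 3),
    tpl)
  imgs <- render_filtered_grid(sim$study, c("condition", "image_type"),
                               template = tpl)
  dm <- distance_matrix(imgs[1:4], tpl, k = 6, seed = 4)
  expect_equal(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
  expect_true(all(dm$values >= 0))

  # duplicated maps are at distance zero
  dup <- c(imgs[1], imgs[1], imgs[2])
  names(dup) <- c("a", "a2", "c")
  dmd <- distance_matrix(dup, tpl, k = 6, seed = 4)
  expect_equal(dmd$values["a", "a2"], 0, tolerance = 1e-12)
  expect_gt(dmd$values["a", "c"], dmd$values["a", "a2"])
  expect_lt(dmd$values["a", "a2"], dmd$values["a2", "c"])

  # refusing mixed colour scales
  odd <- imgs[1:3]
  odd[[2]] <- render_bsm(aggregate_density(sim$study$clicks, tpl), "per_map")
  expect_error(distance_matrix(odd, tpl), "shared fixed")
})

test_that("hierarchical clustering follows a brute-force agglomeration
           oracle", {
  # 5-map distance structure with two tight pairs and an outlier
  labs <- c("A1", "A2", "B1", "B2", "OUT")
  set.seed(51)
  pts <- rbind(c(0, 0), c(0.01, 0), c(1, 1), c(1, 1.01), c(5, 5))
  vals <- as.matrix(stats::dist(pts))
  dimnames(vals) <- list(labs, labs)
  dm <- structure(list(labels = labs, values = vals, k = NA, seed = NA),
                  class = "bsm_distmat")
  tree <- hierarchical_cluster(dm, "average")
  expect_s3_class(tree$hclust, "hclust")

  # brute-force average-linkage agglomeration, step by step
  clusters <- as.list(seq_along(labs))
  heights <- numeric(0)
  merges <- list()
  d <- vals
  avg <- function(ci, cj) mean(vals[ci, cj])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- avg(clusters[[i]], clusters[[j]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merges <- c(merges, list(sort(unlist(clusters[best[2:3]]))))
    clusters <- c(clusters[-best[2:3]],
                  list(sort(unlist(clusters[best[2:3]]))))
  }
  expect_equal(tree$hclust$height, heights, tolerance = 1e-12)
  # members of each merged cluster agree at every step
  got <- lapply(seq_len(nrow(tree$hclust$merge)), function(s) {
    members <- function(step) {
      m <- tree$hclust$merge[step, ]
      unlist(lapply(m, function(v) if (v < 0) -v else members(v)))
    }
    sort(members(s))
  })
  expect_equal(got, merges)
  # the two duplicates merge before anything else
  expect_setequal(got[[1]], c(1, 2))

  # newick export keeps all leaves
  nwk <- write_newick(tree)
  expect_true(all(vapply(labs, grepl, TRUE, x = nwk, fixed = TRUE)))

  # single-element input gives a single-leaf tree
  single <- structure(list(labels = "solo",
                           values = matrix(0, 1, 1,
                                           dimnames = list("solo", "solo")),
                           k = NA, seed = NA), class = "bsm_distmat")
  st <- hierarchical_cluster(single)
  expect_null(st$hclust)
  expect_identical(write_newick(st), "solo;")
})
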