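test_that("dtw_align recovers hand-checked alignments", {
  s <- matrix(c(0, 1, 2, 3), ncol = 1)
  res <- dtw_align(s, s)
  expect_equal(res$cost, 0)
  expect_equal(res$path, cbind(i = 1:4, j = 1:4))

  res <- dtw_align(c(0, 1, 2), c(0, 2))
  expect_equal(res$cost, 1)
  expect_true(identical(unname(res$path), cbind(c(1, 2, 3), c(1, 1, 2))) ||
              identical(unname(res$path), cbind(c(1, 2, 3), c(1, 2, 2))))

  expect_error(dtw_align(numeric(0), 1), "empty")
})

test_that("dtw paths satisfy the alignment-path invariants", {
  set.seed(31)
  for (rep in 1:20) {
    a <- stats::rnorm(sample(2:8, 1))
    b <- stats::rnorm(sample(2:8, 1))
    p <- dtw_align(a, b)$path
    expect_equal(unname(p[1, ]), c(1, 1))
    expect_equal(unname(p[nrow(p), ]), c(length(a), length(b)))
    expect_true(all(diff(p[, 1]) >= 0) && all(diff(p[, 2]) >= 0))
    steps <- diff(p[, 1]) + diff(p[, 2])
    expect_true(all(steps >= 1) && all(diff(p[, 1]) <= 1) && all(diff(p[, 2]) <= 1))
  }
})

test_that("dtw cost is minimal over all monotone paths (exhaustive oracle)", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(2:5, 1)
    m <- sample(2:5, 1)
    a <- stats::rnorm(n)
    b <- stats::rnorm(m)
    d <- abs(outer(a, b, "-"))
    expect_equal(dtw_align(a, b)$cost, dtw_bruteforce_cost(d))
  }
})

test_that("abwap matches its closed-form identities", {
  pt <- c(0, 0.5, 1)
  # identity alignment of identical pseudotimes
  expect_equal(abwap(cbind(1:3, 1:3), pt, pt), 1)
  # worst path: first series fully consumed before the second starts
  worst <- cbind(c(1, 2, 3, 3, 3), c(1, 1, 1, 2, 3))
  expect_equal(abwap(worst, pt, pt), 0)
  # hand-worked three-point example
  path <- cbind(c(1, 2, 2, 3, 3), c(1, 1, 2, 2, 3))
  expect_equal(abwap(path, pt, pt), 0.5)
})

test_that("abwap is bounded and symmetric in the two series", {
  set.seed(23)
  for (rep in 1:20) {
    pt1 <- sort(stats::runif(5)); pt1 <- (pt1 - min(pt1)) / diff(range(pt1))
    pt2 <- sort(stats::runif(4)); pt2 <- (pt2 - min(pt2)) / diff(range(pt2))
    p <- dtw_align(pt1, pt2)$path
    s <- abwap(p, pt1, pt2)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(abwap(p[, 2:1], pt2, pt1), s)
  }
})

test_that("velocity correlation reproduces the rank-difference formula", {
  gt <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = 1:4)
  pred <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(10, 30, 20, 40))
  rho <- velocity_correlation(gt, pred)
  expect_equal(unname(rho), c(1, -1, 1 - 6 * 2 / (4 * 15)))

  gt0 <- cbind(x = rep(1, 4))
  expect_true(is.na(velocity_correlation(gt0, cbind(x = 1:4))))
  expect_error(velocity_correlation(gt, pred[, 1:2]), "dimensions differ")
})

test_that("auroc and aupr agree with pair counting on worked examples", {
  scores <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(grnsim:::auroc_score(scores, labels), 0.75)
  expect_equal(grnsim:::auroc_score(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(grnsim:::auroc_score(1:4, c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_equal(grnsim:::aupr_score(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1)

  set.seed(47)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    labels <- stats::runif(n) < 0.4
    if (sum(labels) %in% c(0, n)) next
    expect_equal(grnsim:::auroc_score(scores, labels), auroc_paircount(scores, labels))
  }
})

test_that("cellwise scoring filters to top-k and excludes cells without positives", {
  truth <- tibble::tibble(
    cell = rep(c("c1", "c2"), each = 3),
    regulator = rep(c("r1", "r2", "r3"), 2),
    target = rep("t", 6),
    active = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  pred <- tibble::tibble(
    cell = rep(c("c1", "c2"), each = 3),
    regulator = rep(c("r1", "r2", "r3"), 2),
    target = rep("t", 6),
    score = c(0.9, 0.5, 0.1, 0.2, 0.4, 0.3)
  )
  expect_warning(res <- cellwise_auroc_aupr(truth, pred), "excluded")
  expect_identical(nrow(res$per_cell), 2L)
  expect_equal(res$mean_auroc, 1)  # only c1 counts; perfect ranking
  expect_equal(res$mean_aupr, 1)

  # top_k = 1 drops the lower-scored predictions to the bottom
  truth2 <- truth[truth$cell == "c1", ]
  truth2$active <- c(FALSE, TRUE, FALSE)
  res2 <- cellwise_auroc_aupr(truth2, pred[pred$cell == "c1", ], top_k = 1)
  # the positive r2 (score 0.5) is cut, ties with r3 below the kept r1
  expect_equal(res2$mean_auroc, 0.25)
})

test_that("velocity arrow cosine is signed correctly on a straight trajectory", {
  # hand-built 2-gene linear gold standard: expression moves along (1, 2)
  genes <- tibble::tibble(gene = c("g1", "g2"), kind = "tf", module = "A",
                          burn = TRUE, basal = 1)
  tt <- seq(0, 1, length.out = 11)
  ymat <- cbind(10 + 20 * tt, 5 + 40 * tt)
  mat <- cbind(matrix(0, 11, 2), ymat, matrix(0, 11, 2))
  gs <- structure(list(
    edges = tibble::tibble(from = "S0", to = "S1", length = 1, dist_from = 0),
    mats = list(mat), progressions = list(tt), genes = genes,
    species = c("x_g1", "x_g2", "y_g1", "y_g2", "z_g1", "z_g2"),
    total_length = 1, backbone = NULL
  ), class = "gold_standard")

  n <- 30
  set.seed(3)
  pct <- stats::runif(n)
  ds <- structure(list(
    gold_standard = gs,
    cell_info = tibble::tibble(edge = 1L, percentage = pct),
    true_spliced = ymat[sample.int(11, n, replace = TRUE), ]
  ), class = "sc_dataset")

  dir <- c(20, 40)  # true displacement in gene space
  emb <- list(rotation = diag(2), center = c(0, 0))
  along <- matrix(dir, n, 2, byrow = TRUE)
  cos_along <- velocity_arrow_cosine(ds, along, embedding = emb, n_waypoints = 10)
  expect_equal(cos_along, rep(1, 10))
  expect_equal(velocity_arrow_cosine(ds, -along, embedding = emb, n_waypoints = 10),
               rep(-1, 10))
  perp <- matrix(c(-40, 20), n, 2, byrow = TRUE)
  expect_equal(velocity_arrow_cosine(ds, perp, embedding = emb, n_waypoints = 10),
               rep(0, 10), tolerance = 1e-8)
})
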