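#' Dynamic time warping alignment
#'
#' Classical dynamic-programming DTW: finds the monotone alignment path
#' with minimal accumulated pointwise distance, dilating or contracting
#' the two series to best match each other. Steps are (+1, 0), (0, +1)
#' and (+1, +1); the path starts at `(1, 1)` and ends at the last
#' indices of both series.
#'
#' @param series_a,series_b Numeric vectors or matrices (rows = time
#'   points, columns = features; feature spaces must match).
#' @param distance Pointwise distance, `"euclidean"` (default) or
#'   `"manhattan"`.
#' @return A list with `path` (two-column integer matrix of index pairs,
#'   1-based) and `cost` (total accumulated distance).
#' @export
dtw_align <- function(series_a, series_b, distance = c("euclidean", "manhattan")) {
  distance <- match.arg(distance)
  if (is.vector(series_a)) series_a <- matrix(series_a, ncol = 1)
  if (is.vector(series_b)) series_b <- matrix(series_b, ncol = 1)
  n <- nrow(series_a)
  m <- nrow(series_b)
  if (n == 0 || m == 0) stop("cannot align empty series", call. = FALSE)
  stopifnot(ncol(series_a) == ncol(series_b))

  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    diffs <- sweep(series_a, 2, series_b[j, ], "-")
    d[, j] <- if (distance == "euclidean") sqrt(rowSums(diffs^2)) else rowSums(abs(diffs))
  }

  D <- matrix(Inf, n, m)
  D[1, 1] <- d[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1 && j > 1) best <- min(best, D[i - 1, j - 1])
      if (i > 1) best <- min(best, D[i - 1, j])
      if (j > 1) best <- min(best, D[i, j - 1])
      D[i, j] <- d[i, j] + best
    }
  }

  # backtrack, preferring the diagonal step on ties
  path <- list(c(n, m))
  i <- n; j <- m
  while (i > 1 || j > 1) {
    cand <- list()
    if (i > 1 && j > 1) cand$diag <- D[i - 1, j - 1]
    if (i > 1) cand$up <- D[i - 1, j]
    if (j > 1) cand$left <- D[i, j - 1]
    step <- names(cand)[which.min(unlist(cand))]
    if (step == "diag") { i <- i - 1; j <- j - 1 }
    else if (step == "up") i <- i - 1
    else j <- j - 1
    path[[length(path) + 1L]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("i", "j")
  list(path = path, cost = D[n, m])
}

#' Trajectory-alignment accuracy (area between worst and prediction)
#'
#' Scores an alignment path of two unit-pseudotime series. Along the
#' path, the curve `x = pt1[i] + pt2[j]`, `y = |pt1[i] - pt2[j]|` is
#' integrated by the trapezoid rule; the score is one minus that area.
#' A perfect alignment (identical pseudotimes matched index by index)
#' scores 1; the worst possible path — one series fully consumed before
#' the other starts — scores 0. The score is symmetric in the two
#' series.
#'
#' @param path Two-column matrix of (1-based) index pairs, as produced by
#'   [dtw_align()].
#' @param pt1,pt2 Pseudotime vectors rescaled to `[0, 1]`.
#' @return A score in `[0, 1]`.
#' @export
abwap <- function(path, pt1, pt2) {
  stopifnot(ncol(path) == 2, max(path[, 1]) <= length(pt1), max(path[, 2]) <= length(pt2))
  a <- pt1[path[, 1]]
  b <- pt2[path[, 2]]
  1 - trapz(a + b, abs(a - b))
}

#' Per-gene velocity correlation
#'
#' Spearman rank correlation, per gene across cells, between the
#' ground-truth velocity and a predicted velocity matrix. Genes with
#' zero variance in either matrix get `NA`.
#'
#' @param gt,pred Matrices (cells x genes) with matching dimensions.
#' @return Named numeric vector of per-gene correlations.
#' @export
velocity_correlation <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stop("ground truth and prediction dimensions differ", call. = FALSE)
  res <- vapply(seq_len(ncol(gt)), function(j) {
    x <- gt[, j]; y <- pred[, j]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, 0)
  names(res) <- colnames(gt)
  res
}

# geodesic distance between trajectory positions (edge index, percentage)
# and a set of waypoint positions, following state-edge lengths
geodesic_to_waypoints <- function(gs, cell_edge, cell_pct, wp_edge, wp_pct) {
  sn <- gs$edges
  states <- unique(c(sn$from, sn$to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = sn$from, to = sn$to, weight = sn$length),
    directed = FALSE, vertices = data.frame(name = states)
  )
  Dn <- igraph::distances(g)
  D <- matrix(0, length(cell_edge), length(wp_edge))
  for (ci in seq_along(cell_edge)) {
    e1 <- cell_edge[ci]; p1 <- cell_pct[ci]; L1 <- sn$length[e1]
    for (wi in seq_along(wp_edge)) {
      e2 <- wp_edge[wi]; p2 <- wp_pct[wi]; L2 <- sn$length[e2]
      if (e1 == e2) {
        D[ci, wi] <- abs(p1 - p2) * L1
      } else {
        ends1 <- c(p1 * L1, (1 - p1) * L1)                    # to from / to to
        ends2 <- c(p2 * L2, (1 - p2) * L2)
        nodes1 <- c(sn$from[e1], sn$to[e1])
        nodes2 <- c(sn$from[e2], sn$to[e2])
        best <- Inf
        for (u in 1:2) for (v in 1:2) {
          best <- min(best, ends1[u] + Dn[nodes1[u], nodes2[v]] + ends2[v])
        }
        D[ci, wi] <- best
      }
    }
  }
  D
}

# place n waypoints uniformly over the trajectory, proportionally to
# edge lengths
make_waypoints <- function(gs, n_waypoints = 100) {
  alloc <- largest_remainder(gs$edges$length, n_waypoints)
  edge <- rep(seq_len(nrow(gs$edges)), alloc)
  pct <- unlist(lapply(alloc, function(k) {
    if (k == 0) numeric() else (seq_len(k) - 0.5) / k
  }))
  tibble::tibble(edge = edge, percentage = pct)
}

# linear interpolation of a gold-standard branch matrix at progression p
gs_interpolate <- function(gs, edge, p) {
  mat <- gs$mats[[edge]]
  prog <- gs$progressions[[edge]]
  p <- min(max(p, 0), 1)
  i <- findInterval(p, prog, all.inside = TRUE)
  w <- (p - prog[i]) / (prog[i + 1] - prog[i])
  mat[i, ] * (1 - w) + mat[i + 1, ] * w
}

#' Velocity arrow cosine
#'
#' Compares the direction of predicted velocities with the known
#' direction of the trajectory in a 2-D embedding. Waypoints are spread
#' uniformly over the trajectory; each waypoint weights every cell with a
#' Gaussian kernel on its geodesic distance, averages the cells' embedded
#' velocity vectors with those weights, and takes the cosine similarity
#' between that average and the local direction of the reference
#' trajectory (the embedded displacement of the gold standard around the
#' waypoint). Waypoints with no weight or a degenerate true direction
#' yield `NA`.
#'
#' @param dataset An `sc_dataset` (provides the gold standard, cell
#'   positions and the default embedding).
#' @param pred_velocity Matrix (cells x genes) of predicted mRNA
#'   velocities.
#' @param embedding Optional list with `rotation` (genes x 2 projection)
#'   and `center` (length genes); defaults to a PCA projection of the
#'   true spliced counts.
#' @param n_waypoints Number of trajectory waypoints.
#' @param bandwidth Gaussian kernel bandwidth on geodesic distance;
#'   defaults to the median nearest-waypoint spacing.
#' @param delta Half-window (in progression units) for the local true
#'   direction.
#' @return Numeric vector of per-waypoint cosine similarities.
#' @export
velocity_arrow_cosine <- function(dataset, pred_velocity, embedding = NULL,
                                  n_waypoints = 100, bandwidth = NULL, delta = 0.05) {
  gs <- dataset$gold_standard
  ci <- dataset$cell_info
  stopifnot(nrow(pred_velocity) == nrow(ci))

  if (is.null(embedding)) embedding <- default_embedding(dataset)
  W <- embedding$rotation
  stopifnot(nrow(W) == ncol(pred_velocity))

  emb_vel <- as.matrix(pred_velocity) %*% W

  wp <- make_waypoints(gs, n_waypoints)
  D <- geodesic_to_waypoints(gs, ci$edge, ci$percentage, wp$edge, wp$percentage)

  if (is.null(bandwidth)) {
    wd <- geodesic_to_waypoints(gs, wp$edge, wp$percentage, wp$edge, wp$percentage)
    diag(wd) <- Inf
    bandwidth <- stats::median(apply(wd, 1, min))
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- gs$total_length / n_waypoints
  }
  K <- exp(-D^2 / (2 * bandwidth^2))

  G <- nrow(W)
  genes <- nrow(gs$genes)
  y_cols <- genes + seq_len(genes)  # spliced block of the gold standard

  vapply(seq_len(nrow(wp)), function(i) {
    wts <- K[, i]
    if (sum(wts) <= 0) return(NA_real_)
    avg <- colSums(emb_vel * wts) / sum(wts)
    e_hi <- gs_interpolate(gs, wp$edge[i], wp$percentage[i] + delta)[y_cols]
    e_lo <- gs_interpolate(gs, wp$edge[i], wp$percentage[i] - delta)[y_cols]
    truedir <- as.numeric(e_hi - e_lo) %*% W
    na <- sqrt(sum(avg^2)); nt <- sqrt(sum(truedir^2))
    if (na == 0 || nt == 0) return(NA_real_)
    sum(avg * truedir) / (na * nt)
  }, 0)
}

# rank-based AUROC (ties contribute 1/2, equivalent to pair counting)
auroc_score <- function(scores, labels) {
  P <- sum(labels); Nn <- sum(!labels)
  if (P == 0 || Nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - P * (P + 1) / 2) / (P * Nn)
}

# average precision (step-wise precision-recall integration)
aupr_score <- function(scores, labels) {
  P <- sum(labels)
  if (P == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / P
}

#' Cell-wise AUROC and AUPR of a predicted cell-specific network
#'
#' For every cell the top `top_k` predicted interactions (by score) are
#' retained — interactions of the ground-truth universe left unscored
#' rank below every scored one — and rank-based AUROC and average
#' precision are computed against the binarised ground truth. Cells
#' without positives (or without negatives) are excluded from the means
#' with a warning.
#'
#' @param truth Tibble with columns `cell`, `regulator`, `target`,
#'   `active` (see [compute_cell_specific_grn()]).
#' @param pred Tibble with columns `cell`, `regulator`, `target`,
#'   `score`.
#' @param top_k Number of predictions retained per cell.
#' @return A list with `per_cell` (tibble of per-cell scores),
#'   `mean_auroc` and `mean_aupr`.
#' @export
cellwise_auroc_aupr <- function(truth, pred, top_k = 10000) {
  key <- function(d) paste(d$regulator, d$target, sep = "\r")
  pred_by_cell <- split(pred, pred$cell)
  cells <- unique(truth$cell)
  res <- lapply(cells, function(cl) {
    tr <- truth[truth$cell == cl, ]
    scores <- rep(-Inf, nrow(tr))
    pc <- pred_by_cell[[cl]]
    if (!is.null(pc)) {
      if (nrow(pc) > top_k) {
        pc <- pc[order(pc$score, decreasing = TRUE)[seq_len(top_k)], ]
      }
      m <- match(key(tr), key(pc))
      scores[!is.na(m)] <- pc$score[m[!is.na(m)]]
    }
    tibble::tibble(
      cell = cl,
      auroc = auroc_score(scores, tr$active),
      aupr = aupr_score(scores, tr$active),
      n_positive = sum(tr$active)
    )
  })
  per_cell <- do.call(rbind, res)
  bad <- is.na(per_cell$auroc) | is.na(per_cell$aupr)
  if (any(bad)) {
    warning(sum(bad), " cell(s) without positives/negatives excluded from the means",
            call. = FALSE)
  }
  list(
    per_cell = per_cell,
    mean_auroc = mean(per_cell$auroc[!bad]),
    mean_aupr = mean(per_cell$aupr[!bad])
  )
}
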