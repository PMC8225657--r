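#' Gold-standard configuration
#'
#' @param tau_per_length Simulated time units per unit of state-edge
#'   length; each transition of length `L` is integrated for
#'   `L * tau_per_length` time units.
#' @param burn_time Warm-up integration time preceding the start state
#'   (should match the SSA configuration).
#' @param census_interval Time spacing of the recorded reference points
#'   along each transition.
#' @return A list of class `gs_config`.
#' @export
gs_config <- function(tau_per_length = 3, burn_time = 2, census_interval = 0.05) {
  stopifnot(tau_per_length > 0, burn_time >= 0, census_interval > 0)
  structure(list(tau_per_length = tau_per_length, burn_time = burn_time,
                 census_interval = census_interval), class = "gs_config")
}

# gene-level transcription mask given a set of active modules:
# TFs follow their module's activity, targets and housekeeping genes are
# driven by their regulators and stay enabled
gene_mask_for_modules <- function(genes, active_modules) {
  ifelse(genes$kind == "tf", genes$module %in% active_modules, TRUE)
}

# deterministic mean-field integration of the propensity functions:
# dx = f_transcription - (splice + deg_x) x ; dy = splice x - deg_y y ;
# dz = transl y - deg_z z
meanfield_integrate <- function(system, state0, duration, mask, census_interval) {
  a <- system$arr
  G <- system$num_genes
  deriv <- function(t, state, parms) {
    state <- pmax(state, 0)
    f <- transcription_propensities(system, state, mask)
    x <- state[seq_len(G)]
    y <- state[G + seq_len(G)]
    z <- state[2 * G + seq_len(G)]
    list(c(
      f - (a$splice + a$deg_x) * x,
      a$splice * x - a$deg_y * y,
      a$transl * y - a$deg_z * z
    ))
  }
  times <- unique(c(seq(0, duration, by = census_interval), duration))
  out <- deSolve::ode(y = as.numeric(state0), times = times, func = deriv,
                      parms = NULL, method = "lsoda")
  mat <- unname(out[, -1, drop = FALSE])
  colnames(mat) <- system$species
  mat
}

#' Construct the noise-free reference trajectory
#'
#' For each transition of the state network a deterministic mean-field
#' integration of the same propensity functions used by the SSA is run,
#' starting from the end state of the upstream transition and with only
#' the modules prescribed by the transition switched on or off. The warm-up
#' phase (modules marked `burn`) provides the expression vector of the
#' start state. For each transition an expression matrix and the
#' progression (0 to 1) along the transition are retained.
#'
#' @param system A `reaction_system`.
#' @param b The [backbone()] the system was generated from.
#' @param config A [gs_config()].
#' @return An object of class `gold_standard`.
#' @export
simulate_gold_standard <- function(system, b, config = gs_config()) {
  sn <- b$state_network
  genes <- system$genes
  G <- system$num_genes

  burn_mask <- genes$burn
  burn_mat <- meanfield_integrate(system, rep(0, 3 * G), config$burn_time,
                                  burn_mask, config$census_interval)
  state_expr <- list()
  state_expr[[b$start_state]] <- burn_mat[nrow(burn_mat), ]
  active_modules <- list()
  active_modules[[b$start_state]] <- b$modules$module[b$modules$burn]

  n_edges <- nrow(sn)
  mats <- vector("list", n_edges)
  progressions <- vector("list", n_edges)
  done <- rep(FALSE, n_edges)

  # process edges in breadth-first order from the start state
  repeat {
    ready <- which(!done & sn$from %in% names(state_expr))
    if (length(ready) == 0) break
    for (i in ready) {
      active <- union(active_modules[[sn$from[i]]], sn$on[[i]])
      active <- setdiff(active, sn$off[[i]])
      mask <- gene_mask_for_modules(genes, active)
      duration <- sn$length[i] * config$tau_per_length
      mat <- meanfield_integrate(system, state_expr[[sn$from[i]]], duration,
                                 mask, config$census_interval)
      mats[[i]] <- mat
      progressions[[i]] <- seq(0, 1, length.out = nrow(mat))
      if (!sn$to[i] %in% names(state_expr)) {
        state_expr[[sn$to[i]]] <- mat[nrow(mat), ]
        active_modules[[sn$to[i]]] <- active
      }
      done[i] <- TRUE
    }
  }
  if (!all(done)) {
    stop("state network edges unreachable from start_state: ",
         paste(sprintf("%s->%s", sn$from[!done], sn$to[!done]), collapse = ", "),
         call. = FALSE)
  }

  # geodesic distance of every state from the start, following edge lengths
  g <- igraph::graph_from_data_frame(
    data.frame(from = sn$from, to = sn$to, weight = sn$length),
    directed = TRUE,
    vertices = data.frame(name = unique(c(sn$from, sn$to)))
  )
  dist_from_start <- igraph::distances(g, v = b$start_state, mode = "out")[1, ]
  edges <- tibble::tibble(
    from = sn$from, to = sn$to, length = sn$length,
    dist_from = unname(dist_from_start[sn$from])
  )
  total_length <- max(edges$dist_from + edges$length)

  structure(
    list(
      edges = edges,
      mats = mats,
      progressions = progressions,
      burn_state = burn_mat[nrow(burn_mat), ],
      genes = genes,
      species = system$species,
      total_length = total_length,
      backbone = b
    ),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> ", nrow(x$edges), " transitions, ",
      sum(vapply(x$mats, nrow, 0L)), " reference points, total path length ",
      x$total_length, "\n", sep = "")
  invisible(x)
}

# indices (into the species vector) of the mature-mRNA columns of TF genes
tf_mrna_features <- function(gs_or_system) {
  genes <- gs_or_system$genes
  G <- nrow(genes)
  G + which(genes$kind == "tf")
}

# flatten all gold-standard points into one feature matrix + metadata
gs_points <- function(gs) {
  meta <- do.call(rbind, lapply(seq_along(gs$mats), function(i) {
    data.frame(
      edge = i,
      row = seq_len(nrow(gs$mats[[i]])),
      percentage = gs$progressions[[i]]
    )
  }))
  meta$pseudotime_raw <- gs$edges$dist_from[meta$edge] +
    meta$percentage * gs$edges$length[meta$edge]
  mat <- do.call(rbind, gs$mats)
  list(meta = meta, mat = mat)
}

#' Map cells onto the reference trajectory
#'
#' Each cell is assigned the reference point with the highest Spearman
#' correlation between the cell's TF mature-mRNA abundances and the
#' reference expression. Correlation ties (frequent on expression
#' plateaus, where rank patterns repeat) are broken by the smallest
#' Euclidean distance in the same feature space, remaining ties towards
#' the earliest pseudotime. Zero-variance cells are mapped to the
#' trajectory start with a warning.
#'
#' @param cells Matrix (cells x species) of true molecule counts, with
#'   the species layout of the reaction system.
#' @param gs A `gold_standard`.
#' @return A tibble with one row per cell: `edge` (index into
#'   `gs$edges`), `from`, `to`, `percentage` and `pseudotime_raw`
#'   (geodesic distance from the start, in state-length units).
#' @export
map_cells_to_trajectory <- function(cells, gs) {
  feats <- tf_mrna_features(gs)
  pts <- gs_points(gs)
  cf <- cells[, feats, drop = FALSE]
  gf <- pts$mat[, feats, drop = FALSE]

  zero_var <- apply(cf, 1, function(r) stats::var(r) == 0 || !is.finite(stats::var(r)))
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance cell(s) mapped to the trajectory start",
            call. = FALSE)
  }
  co <- suppressWarnings(stats::cor(t(cf), t(gf), method = "spearman"))

  ord <- order(pts$meta$pseudotime_raw)  # earliest-pseudotime tie-break
  best <- vapply(seq_len(nrow(cf)), function(i) {
    if (zero_var[i]) return(ord[1])
    row <- co[i, ord]
    row[is.na(row)] <- -2  # zero-variance reference points rank last
    cand <- which(row >= max(row) - 1e-12)
    if (length(cand) > 1) {
      d2 <- rowSums(sweep(gf[ord[cand], , drop = FALSE], 2, cf[i, ])^2)
      cand <- cand[d2 <= min(d2) + 1e-9]  # which.min-style, earliest kept
    }
    ord[cand[1]]
  }, 0L)

  meta <- pts$meta[best, ]
  tibble::tibble(
    edge = meta$edge,
    from = gs$edges$from[meta$edge],
    to = gs$edges$to[meta$edge],
    percentage = meta$percentage,
    pseudotime_raw = meta$pseudotime_raw
  )
}

#' Compute unit pseudotime for mapped positions
#'
#' The pseudotime of a cell is its geodesic distance from the trajectory
#' start — the summed lengths of the transitions upstream of its edge
#' plus its fractional progress along that edge — rescaled by the total
#' path length so pseudotime lies in `[0, 1]`.
#'
#' @param positions Tibble from [map_cells_to_trajectory()].
#' @param gs A `gold_standard`.
#' @return Numeric vector of pseudotimes in `[0, 1]`.
#' @export
compute_pseudotime <- function(positions, gs) {
  d <- gs$edges$dist_from[positions$edge]
  if (any(!is.finite(d))) stop("position on an edge disconnected from the start state", call. = FALSE)
  pt <- (d + positions$percentage * gs$edges$length[positions$edge]) / gs$total_length
  pmin(pmax(pt, 0), 1)
}

#' Export the gold standard
#'
#' Writes one expression TSV per transition plus a progression table.
#'
#' @param gs A `gold_standard`.
#' @param dir Output directory (created if needed).
#' @export
write_gold_standard <- function(gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(gs$mats)) {
    utils::write.table(
      data.frame(percentage = gs$progressions[[i]], gs$mats[[i]], check.names = FALSE),
      file.path(dir, sprintf("branch_%s_%s.tsv", gs$edges$from[i], gs$edges$to[i])),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  utils::write.table(as.data.frame(gs$edges), file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
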