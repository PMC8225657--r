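#' Library-size model
#'
#' Models the distribution of total transcript counts per cell. Either a
#' parametric log-normal over totals (default: median 5000 counts,
#' coefficient of variation 0.6, typical of droplet-based protocols) or
#' the empirical distribution of per-cell totals of a user-supplied count
#' matrix, so library sizes can be matched to a real dataset.
#'
#' @param type `"lognormal"` or `"empirical"`.
#' @param median_size Median library size (lognormal).
#' @param cv Coefficient of variation of library sizes (lognormal).
#' @param counts For `"empirical"`: a matrix / sparse Matrix with cells
#'   as columns, or the path to a Matrix Market `.mtx` file.
#' @return A list of class `library_size_model`.
#' @export
library_size_model <- function(type = c("lognormal", "empirical"),
                               median_size = 5000, cv = 0.6, counts = NULL) {
  type <- match.arg(type)
  if (type == "empirical") {
    if (is.character(counts)) counts <- Matrix::readMM(counts)
    if (is.null(counts)) stop("empirical model needs a count matrix", call. = FALSE)
    totals <- Matrix::colSums(counts)
    totals <- totals[totals > 0]
    if (length(totals) == 0) stop("count matrix has no non-empty cells", call. = FALSE)
    structure(list(type = type, totals = as.numeric(totals)), class = "library_size_model")
  } else {
    stopifnot(median_size > 0, cv > 0)
    structure(list(type = type, meanlog = log(median_size),
                   sdlog = sqrt(log(1 + cv^2))), class = "library_size_model")
  }
}

#' Draw library sizes from a model
#'
#' @param model A [library_size_model()].
#' @param n Number of cells.
#' @param seed Optional seed.
#' @return Integer vector of positive library sizes.
#' @export
draw_library_sizes <- function(model, n, seed = NULL) {
  with_seed(seed, {
    ls <- if (model$type == "empirical") {
      sample(model$totals, n, replace = TRUE)
    } else {
      stats::rlnorm(n, model$meanlog, model$sdlog)
    }
    pmax(1L, as.integer(round(ls)))
  })
}

# pool the main-phase (non warm-up) census rows of a list of traces
collect_census <- function(traces, max_rows = Inf, seed = NULL) {
  meta <- do.call(rbind, lapply(traces, function(tr) {
    keep <- !tr$burn
    data.frame(sim = tr$sim_index, row = which(keep), time = tr$times[keep])
  }))
  if (nrow(meta) > max_rows) {
    meta <- with_seed(seed, meta[sort(sample.int(nrow(meta), max_rows)), ])
  }
  counts <- do.call(rbind, lapply(seq_along(traces), function(i) {
    traces[[i]]$counts[meta$row[meta$sim == traces[[i]]$sim_index], , drop = FALSE]
  }))
  props <- do.call(rbind, lapply(seq_along(traces), function(i) {
    traces[[i]]$propensities[meta$row[meta$sim == traces[[i]]$sim_index], , drop = FALSE]
  }))
  list(meta = meta, counts = counts, propensities = props)
}

finish_sampled_cells <- function(pool, pick, positions, gs) {
  meta <- tibble::tibble(
    cell_id = sprintf("cell%d", seq_along(pick)),
    sim = pool$meta$sim[pick],
    sim_time = pool$meta$time[pick],
    edge = positions$edge,
    from = positions$from,
    to = positions$to,
    percentage = positions$percentage
  )
  meta$pseudotime <- compute_pseudotime(positions, gs)
  structure(
    list(
      meta = meta,
      counts = pool$counts[pick, , drop = FALSE],
      propensities = pool$propensities[pick, , drop = FALSE]
    ),
    class = "sampled_cells"
  )
}

#' Sample cells as an unsynchronised snapshot
#'
#' Census states of all simulations are mapped onto the reference
#' trajectory; each transition of length `L_i` then receives
#' `N_i = N * L_i / sum(L)` cells (largest-remainder rounding so the
#' allocations sum to `N` exactly) sampled uniformly from the states
#' mapped to it. Warm-up states are never sampled. Transitions to which
#' no state mapped are dropped from the allocation with a warning.
#'
#' @param traces List of `simulation_trace` objects.
#' @param gs A `gold_standard`.
#' @param N Number of cells.
#' @param seed Optional seed.
#' @param max_pool Cap on the number of census states mapped (the pool is
#'   subsampled uniformly first when larger).
#' @return A `sampled_cells` object: cell metadata plus the true count
#'   and propensity matrices at the sampled states.
#' @export
sample_cells_snapshot <- function(traces, gs, N, seed = NULL, max_pool = max(20 * N, 2000)) {
  stopifnot(N >= 1)
  pool <- collect_census(traces, max_rows = max_pool, seed = derive_seed(seed %||% 0, "pool"))
  positions <- map_cells_to_trajectory(pool$counts, gs)
  with_seed(seed, {
    n_edges <- nrow(gs$edges)
    have <- tabulate(positions$edge, nbins = n_edges) > 0
    if (!all(have)) {
      warning("no simulated states mapped to transition(s) ",
              paste(sprintf("%s->%s", gs$edges$from[!have], gs$edges$to[!have]), collapse = ", "),
              "; reallocating their cells", call. = FALSE)
    }
    weights <- gs$edges$length * have
    alloc <- largest_remainder(weights, N)
    pick <- unlist(lapply(seq_len(n_edges), function(i) {
      if (alloc[i] == 0) return(integer())
      cand <- which(positions$edge == i)
      sample(cand, alloc[i], replace = alloc[i] > length(cand))
    }))
    finish_sampled_cells(pool, pick, positions[pick, ], gs)
  })
}

#' Sample cells as a synchronised time series
#'
#' The main-phase interval `[0, T]` is divided into `k` sampling windows
#' of width `w = (T - (k - 1) * g) / k` separated by `k - 1` gaps of
#' width `g`; window `i` covers `[i * (w + g), i * (w + g) + w]`. Each
#' window receives `N / k` cells (largest-remainder rounding), sampled
#' uniformly from the census states falling inside it.
#'
#' @param traces List of `simulation_trace` objects.
#' @param gs A `gold_standard` (used to attach trajectory positions).
#' @param N Number of cells.
#' @param T Final time of the main phase.
#' @param k Number of sampling windows.
#' @param g Gap width between windows.
#' @param seed Optional seed.
#' @param max_pool Cap on the number of census states considered.
#' @return A `sampled_cells` object.
#' @export
sample_cells_timeseries <- function(traces, gs, N, T, k = 8, g = 0.75,
                                    seed = NULL, max_pool = max(20 * N, 2000)) {
  stopifnot(N >= 1, k >= 1)
  if (T <= (k - 1) * g) {
    stop("total time T = ", T, " is too small for ", k, " windows with gap ", g, call. = FALSE)
  }
  w <- (T - (k - 1) * g) / k
  pool <- collect_census(traces, max_rows = max_pool, seed = derive_seed(seed %||% 0, "pool"))
  with_seed(seed, {
    window <- floor(pool$meta$time / (w + g))
    inside <- pool$meta$time - window * (w + g) <= w & window < k & pool$meta$time >= 0
    have <- vapply(seq_len(k) - 1, function(i) any(inside & window == i), TRUE)
    if (!all(have)) {
      warning("no simulated states in sampling window(s) ",
              paste(which(!have) - 1, collapse = ", "), "; reallocating", call. = FALSE)
    }
    alloc <- largest_remainder(rep(1, k) * have, N)
    pick <- unlist(lapply(seq_len(k) - 1, function(i) {
      if (alloc[i + 1] == 0) return(integer())
      cand <- which(inside & window == i)
      sample(cand, alloc[i + 1], replace = alloc[i + 1] > length(cand))
    }))
    positions <- map_cells_to_trajectory(pool$counts[pick, , drop = FALSE], gs)
    finish_sampled_cells(pool, pick, positions, gs)
  })
}

#' Sample observed molecules for each cell
#'
#' Emulates the sequencing protocol: each molecular species `j` gets a
#' capture rate `cr_j` drawn once from `N(1, capture_rate_sd)` (truncated
#' at 0), each cell `i` draws its library size `ls_i` from the
#' library-size model, and `ls_i` molecules are then drawn from the
#' multinomial with probabilities proportional to `cr_j * ab_ij`, with
#' `ab_ij` the true abundance. Per-cell observed totals equal the drawn
#' library sizes exactly; cells with all-zero abundance get zero counts
#' with a warning.
#'
#' @param true_abundances Matrix (cells x species) of true molecule
#'   counts.
#' @param lib_model A [library_size_model()].
#' @param capture_rate_sd Standard deviation of the capture rates.
#' @param seed Optional seed.
#' @return A list with `counts` (cells x species matrix), `library_sizes`
#'   and `capture_rates`.
#' @export
sample_molecules <- function(true_abundances, lib_model = library_size_model(),
                             capture_rate_sd = 0.05, seed = NULL) {
  stopifnot(all(true_abundances >= 0))
  n_cells <- nrow(true_abundances)
  n_species <- ncol(true_abundances)
  with_seed(seed, {
    cr <- pmax(stats::rnorm(n_species, 1, capture_rate_sd), 0)
    ls <- draw_library_sizes(lib_model, n_cells)
    counts <- matrix(0L, n_cells, n_species, dimnames = dimnames(true_abundances))
    empty <- 0L
    for (i in seq_len(n_cells)) {
      p <- cr * true_abundances[i, ]
      if (sum(p) <= 0) {
        empty <- empty + 1L
        ls[i] <- 0L
        next
      }
      counts[i, ] <- stats::rmultinom(1, ls[i], p)[, 1]
    }
    if (empty > 0) {
      warning(empty, " cell(s) with all-zero abundance received zero counts", call. = FALSE)
    }
    list(counts = counts, library_sizes = ls, capture_rates = cr)
  })
}

#' Simulate batch effects
#'
#' Batches share the module network and the GRN but each batch draws its
#' own kinetics and runs all downstream steps independently, so the
#' combined dataset carries batch-specific kinetic differences — the
#' mechanism behind real batch effects in this model.
#'
#' @param grn A `grn`.
#' @param config A [generation_config()]; `config$num_cells` is split
#'   evenly over the batches.
#' @param num_batches Number of batches (1 gives a plain dataset).
#' @param seed Master seed.
#' @return An `sc_dataset` whose cell metadata carries a `batch` label.
#' @export
simulate_batches <- function(grn, config = generation_config(), num_batches = 2, seed = 1) {
  stopifnot(num_batches >= 1)
  per_batch <- largest_remainder(rep(1, num_batches), config$num_cells)
  parts <- lapply(seq_len(num_batches), function(b) {
    cfg <- config
    cfg$num_cells <- per_batch[b]
    ds <- run_experiment(grn, cfg, seed = derive_seed(seed, "batch", b))
    ds$cell_info$batch <- sprintf("batch%d", b)
    ds
  })
  combine_datasets(parts, label_col = "batch")
}

#' Generate a paired-trajectory dataset
#'
#' One GRN is generated from the backbone; kinetics, gold standard and
#' cells are then produced twice with different kinetics draws, and the
#' two sub-datasets are combined. The result contains two trajectories
#' over the same genes — the setting used to evaluate trajectory
#' alignment methods. Pseudotimes are rescaled to `[0, 1]` within each
#' sub-dataset.
#'
#' @param b A [backbone()].
#' @param config A [generation_config()]; each sub-dataset receives
#'   `config$num_cells` cells.
#' @param seed Master seed.
#' @return An `sc_dataset` whose cell metadata carries a `trajectory`
#'   label (`"traj1"` / `"traj2"`).
#' @export
generate_paired_dataset <- function(b, config = generation_config(), seed = 1) {
  grn <- generate_grn(
    b, num_tfs = config$num_tfs %||% default_num_tfs(b),
    num_targets = config$num_targets, num_hks = config$num_hks,
    ref = config$reference_network, seed = derive_seed(seed, "grn")
  )
  parts <- lapply(1:2, function(r) {
    ds <- run_experiment(grn, config, seed = derive_seed(seed, "pair", r))
    ds$cell_info$trajectory <- sprintf("traj%d", r)
    ds
  })
  combine_datasets(parts, label_col = "trajectory")
}
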