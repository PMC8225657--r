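default_num_tfs <- function(b) 2L * nrow(b$modules)

#' Configuration of a full dataset generation run
#'
#' Collects all knobs of the pipeline. A fixed `seed` makes the whole run
#' reproducible: every stage derives its own sub-seed from it.
#'
#' @param backbone A backbone name (see [list_backbones()]), a
#'   [backbone()] object, or the path to a backbone JSON file.
#' @param backbone_params Optional size parameters for a named backbone.
#' @param num_tfs,num_targets,num_hks Gene counts; `num_tfs` defaults to
#'   two TFs per module.
#' @param num_cells Number of cells to sample.
#' @param mode Cell sampling mode, `"snapshot"` (unsynchronised
#'   population) or `"time_series"` (synchronised windows).
#' @param ts_k,ts_gap Number of windows and gap width for time-series
#'   sampling.
#' @param ssa An [ssa_config()].
#' @param kinetics A [kinetics_config()].
#' @param tau_per_length,gs_census_interval Gold-standard integration
#'   settings (see [gs_config()]).
#' @param library_size A [library_size_model()].
#' @param capture_rate_sd Capture-rate spread for [sample_molecules()].
#' @param reference_network Optional reference network for
#'   [generate_grn()].
#' @param activity_threshold Binarisation threshold of the cell-specific
#'   ground-truth network.
#' @param seed Master seed.
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(backbone = "linear", backbone_params = list(),
                              num_tfs = NULL, num_targets = 20, num_hks = 10,
                              num_cells = 500,
                              mode = c("snapshot", "time_series"),
                              ts_k = 8, ts_gap = 0.75,
                              ssa = ssa_config(),
                              kinetics = kinetics_config(),
                              tau_per_length = 3, gs_census_interval = 0.05,
                              library_size = library_size_model(),
                              capture_rate_sd = 0.05,
                              reference_network = NULL,
                              activity_threshold = 1e-4,
                              seed = 1) {
  mode <- match.arg(mode)
  structure(
    list(backbone = backbone, backbone_params = backbone_params,
         num_tfs = num_tfs, num_targets = num_targets, num_hks = num_hks,
         num_cells = num_cells, mode = mode, ts_k = ts_k, ts_gap = ts_gap,
         ssa = ssa, kinetics = kinetics,
         tau_per_length = tau_per_length, gs_census_interval = gs_census_interval,
         library_size = library_size, capture_rate_sd = capture_rate_sd,
         reference_network = reference_network,
         activity_threshold = activity_threshold, seed = seed),
    class = "generation_config"
  )
}

resolve_backbone <- function(x, params = list()) {
  if (inherits(x, "backbone")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (file.exists(x)) return(read_backbone(x))
    return(predefined_backbone(x, params))
  }
  stop("cannot interpret 'backbone': give a name, a backbone object or a JSON path",
       call. = FALSE)
}

# one kinetics draw -> reactions -> gold standard -> SSA runs -> cells ->
# molecules -> ground truths; shared by plain, batch and paired datasets
run_experiment <- function(grn, config, seed) {
  kin <- sample_kinetics(grn, config$kinetics, seed = derive_seed(seed, "kinetics"))
  system <- build_reaction_system(grn, kin)
  gscfg <- gs_config(tau_per_length = config$tau_per_length,
                     burn_time = config$ssa$burn_time,
                     census_interval = config$gs_census_interval)
  gs <- simulate_gold_standard(system, grn$backbone, gscfg)

  ssa_cfg <- config$ssa
  ssa_cfg$seed <- derive_seed(seed, "ssa_master")
  traces <- run_simulations(system, ssa_cfg)

  cells <- if (config$mode == "snapshot") {
    sample_cells_snapshot(traces, gs, config$num_cells,
                          seed = derive_seed(seed, "cells"))
  } else {
    sample_cells_timeseries(traces, gs, config$num_cells, config$ssa$total_time,
                            k = config$ts_k, g = config$ts_gap,
                            seed = derive_seed(seed, "cells"))
  }

  mol <- sample_molecules(cells$counts, config$library_size, config$capture_rate_sd,
                          seed = derive_seed(seed, "molecules"))

  velocity_gt <- compute_velocity_ground_truth(cells)
  csni <- compute_cell_specific_grn(cells, system, config$activity_threshold)

  G <- system$num_genes
  genes <- grn$genes$gene
  block <- function(m, b) {
    m <- m[, (b - 1) * G + seq_len(G), drop = FALSE]
    dimnames(m) <- list(cells$meta$cell_id, genes)
    Matrix::Matrix(m, sparse = TRUE)
  }
  cell_info <- cells$meta
  cell_info$library_size <- mol$library_sizes
  dimnames(velocity_gt) <- list(cells$meta$cell_id, genes)

  structure(
    list(
      counts_unspliced = block(mol$counts, 1),
      counts_spliced = block(mol$counts, 2),
      counts_protein = block(mol$counts, 3),
      true_unspliced = block(cells$counts, 1),
      true_spliced = block(cells$counts, 2),
      true_protein = block(cells$counts, 3),
      cell_info = cell_info,
      gene_info = grn$genes,
      velocity_gt = velocity_gt,
      csni = csni,
      gold_standard = gs,
      grn = grn,
      kinetics = kin,
      system = system,
      capture_rates = mol$capture_rates,
      config = config,
      seed = seed
    ),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("<sc_dataset> ", nrow(x$cell_info), " cells x ", nrow(x$gene_info),
      " genes (seed ", x$seed, ")\n", sep = "")
  cat("  assays: spliced/unspliced/protein, observed + true\n")
  cat("  ground truths: trajectory positions, RNA velocity, cell-specific GRN (",
      nrow(x$csni), " entries)\n", sep = "")
  invisible(x)
}

#' Generate a complete in silico single-cell dataset
#'
#' Runs the whole pipeline: backbone to GRN to kinetics to gold standard
#' to SSA simulations to experiment emulation to ground truths. The
#' result bundles observed and true count matrices (spliced, unspliced,
#' protein), cell and gene metadata, the reference trajectory, the RNA
#' velocity ground truth and the cell-specific ground-truth network.
#'
#' @param config A [generation_config()].
#' @param out Optional directory; when given the dataset bundle is
#'   written there with [write_dataset()].
#' @return An `sc_dataset`.
#' @export
#' @examples
#' \donttest{
#' cfg <- generation_config(
#'   backbone = "linear", num_tfs = 10, num_targets = 15, num_hks = 5,
#'   num_cells = 100, ssa = ssa_config(num_simulations = 8), seed = 1
#' )
#' ds <- generate_dataset(cfg)
#' ds
#' }
generate_dataset <- function(config = generation_config(), out = NULL) {
  b <- resolve_backbone(config$backbone, config$backbone_params)
  v <- validate_backbone(b)
  if (length(v) > 0) stop("invalid backbone: ", paste(v, collapse = "; "), call. = FALSE)
  grn <- generate_grn(
    b, num_tfs = config$num_tfs %||% default_num_tfs(b),
    num_targets = config$num_targets, num_hks = config$num_hks,
    ref = config$reference_network, seed = derive_seed(config$seed, "grn")
  )
  ds <- run_experiment(grn, config, seed = config$seed)
  if (!is.null(out)) write_dataset(ds, out)
  ds
}

# combine per-batch / per-trajectory datasets over the same genes
combine_datasets <- function(parts, label_col) {
  stopifnot(length(parts) >= 1)
  if (length(parts) == 1) return(parts[[1]])
  for (i in seq_along(parts)) {
    old <- parts[[i]]$cell_info$cell_id
    new <- sprintf("d%d_%s", i, old)
    parts[[i]]$cell_info$cell_id <- new
    parts[[i]]$csni$cell <- sprintf("d%d_%s", i, parts[[i]]$csni$cell)
    for (nm in c("counts_unspliced", "counts_spliced", "counts_protein",
                 "true_unspliced", "true_spliced", "true_protein", "velocity_gt")) {
      rownames(parts[[i]][[nm]]) <- new
    }
  }
  base <- parts[[1]]
  stopifnot(all(vapply(parts, function(p) identical(p$gene_info$gene, base$gene_info$gene), TRUE)))
  out <- base
  for (nm in c("counts_unspliced", "counts_spliced", "counts_protein",
               "true_unspliced", "true_spliced", "true_protein", "velocity_gt")) {
    out[[nm]] <- do.call(rbind, lapply(parts, `[[`, nm))
  }
  out$cell_info <- do.call(rbind, lapply(parts, `[[`, "cell_info"))
  out$csni <- do.call(rbind, lapply(parts, `[[`, "csni"))
  out$gold_standards <- lapply(parts, `[[`, "gold_standard")
  names(out$gold_standards) <- vapply(parts, function(p) p$cell_info[[label_col]][1], "")
  out
}

# deterministic PCA-style 2-D projection of the true spliced counts
default_embedding <- function(dataset) {
  X <- as.matrix(dataset$true_spliced)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  list(rotation = pc$rotation, center = pc$center)
}

# ---- bundle I/O --------------------------------------------------------

#' Write / read a dataset bundle
#'
#' The on-disk bundle is plain text: Matrix Market files for the six
#' count matrices and the velocity ground truth, TSV tables for cell and
#' gene metadata, the cell-specific ground-truth network, the GRN and
#' kinetics provenance, the gold standard, a backbone JSON and a
#' `manifest.json` with seeds and configuration.
#'
#' @param ds An `sc_dataset`.
#' @param dir Bundle directory.
#' @return `read_dataset` returns an `sc_dataset` (the reaction system is
#'   rebuilt from the stored GRN and kinetics tables).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wmm <- function(m, name) Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(dir, name))
  wmm(ds$counts_spliced, "counts_spliced.mtx")
  wmm(ds$counts_unspliced, "counts_unspliced.mtx")
  wmm(ds$counts_protein, "counts_protein.mtx")
  wmm(ds$true_spliced, "counts_spliced_true.mtx")
  wmm(ds$true_unspliced, "counts_unspliced_true.mtx")
  wmm(ds$true_protein, "counts_protein_true.mtx")
  wmm(ds$velocity_gt, "velocity_gt.mtx")
  wtsv <- function(d, name) utils::write.table(as.data.frame(d), file.path(dir, name),
                                               sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(ds$cell_info, "cells.tsv")
  wtsv(ds$gene_info, "genes.tsv")
  wtsv(ds$csni, "csni_gt.tsv")
  write_grn(ds$grn, file.path(dir, "grn"))
  write_kinetics(ds$kinetics, file.path(dir, "kinetics"))
  write_backbone(ds$grn$backbone, file.path(dir, "backbone.json"))
  write_gold_standard(ds$gold_standard, file.path(dir, "gold_standard"))
  cfg <- ds$config
  jsonlite::write_json(
    list(
      seed = ds$seed,
      num_cells = nrow(ds$cell_info),
      num_genes = nrow(ds$gene_info),
      mode = cfg$mode,
      ssa = unclass(cfg$ssa),
      kinetics_config = unclass(cfg$kinetics),
      tau_per_length = cfg$tau_per_length,
      gs_census_interval = cfg$gs_census_interval,
      activity_threshold = cfg$activity_threshold,
      capture_rates = ds$capture_rates
    ),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  rmm <- function(name) as(Matrix::readMM(file.path(dir, name)), "CsparseMatrix")
  rtsv <- function(name) tibble::as_tibble(utils::read.delim(file.path(dir, name), stringsAsFactors = FALSE))
  cell_info <- rtsv("cells.tsv")
  gene_info <- rtsv("genes.tsv")
  b <- read_backbone(file.path(dir, "backbone.json"))
  grn <- new_grn(gene_info, rtsv("grn_interactions.tsv"), b)
  kin_cfg <- do.call(kinetics_config, man$kinetics_config[
    setdiff(names(man$kinetics_config), character())])
  kin <- structure(
    list(genes = rtsv("kinetics_gene_kinetics.tsv"),
         interactions = rtsv("kinetics_interaction_kinetics.tsv"),
         config = kin_cfg),
    class = "kinetics"
  )
  system <- build_reaction_system(grn, kin)
  gs_edges <- rtsv("gold_standard/edges.tsv")
  mats <- vector("list", nrow(gs_edges))
  progressions <- vector("list", nrow(gs_edges))
  for (i in seq_len(nrow(gs_edges))) {
    d <- utils::read.delim(
      file.path(dir, "gold_standard",
                sprintf("branch_%s_%s.tsv", gs_edges$from[i], gs_edges$to[i])),
      check.names = FALSE
    )
    progressions[[i]] <- d$percentage
    mats[[i]] <- as.matrix(d[, -1, drop = FALSE])
  }
  gs <- structure(
    list(edges = gs_edges, mats = mats, progressions = progressions,
         genes = gene_info, species = system$species,
         total_length = max(gs_edges$dist_from + gs_edges$length),
         backbone = b),
    class = "gold_standard"
  )
  set_dn <- function(m) {
    dimnames(m) <- list(cell_info$cell_id, gene_info$gene)
    m
  }
  structure(
    list(
      counts_unspliced = set_dn(rmm("counts_unspliced.mtx")),
      counts_spliced = set_dn(rmm("counts_spliced.mtx")),
      counts_protein = set_dn(rmm("counts_protein.mtx")),
      true_unspliced = set_dn(rmm("counts_unspliced_true.mtx")),
      true_spliced = set_dn(rmm("counts_spliced_true.mtx")),
      true_protein = set_dn(rmm("counts_protein_true.mtx")),
      cell_info = cell_info, gene_info = gene_info,
      velocity_gt = as.matrix(set_dn(rmm("velocity_gt.mtx"))),
      csni = rtsv("csni_gt.tsv"),
      gold_standard = gs, grn = grn, kinetics = kin, system = system,
      capture_rates = man$capture_rates,
      config = NULL, seed = man$seed
    ),
    class = "sc_dataset"
  )
}

#' Score a prediction against a dataset's ground truth
#'
#' Dispatches to the evaluation metrics. `metric = "velocity"` expects a
#' cells x genes velocity matrix (or `.mtx` path) and returns per-gene
#' Spearman correlations with the ground truth plus the mean;
#' `metric = "csni"` expects a long table (`cell`, `regulator`, `target`,
#' `score`) (or TSV path) and returns per-cell and mean AUROC/AUPR;
#' `metric = "abwap"` expects a paired-trajectory dataset and an optional
#' alignment path (two-column index matrix; when omitted, DTW is run on
#' the two pseudotime-ordered expression series) and returns the
#' alignment score.
#'
#' @param ds An `sc_dataset` or a bundle directory path.
#' @param prediction See details per metric.
#' @param metric One of `"velocity"`, `"csni"`, `"abwap"`.
#' @return A tibble of per-unit scores with a `summary` attribute, or a
#'   list for `"csni"`.
#' @export
score_prediction <- function(ds, prediction = NULL, metric = c("velocity", "csni", "abwap")) {
  metric <- match.arg(metric)
  if (is.character(ds)) ds <- read_dataset(ds)
  switch(metric,
    velocity = {
      if (is.character(prediction)) prediction <- as.matrix(Matrix::readMM(prediction))
      stopifnot(!is.null(prediction))
      rho <- velocity_correlation(ds$velocity_gt, as.matrix(prediction))
      out <- tibble::tibble(gene = colnames(ds$velocity_gt), velocity_correlation = unname(rho))
      attr(out, "summary") <- c(mean_velocity_correlation = mean(rho, na.rm = TRUE))
      out
    },
    csni = {
      if (is.character(prediction)) {
        prediction <- utils::read.delim(prediction, stringsAsFactors = FALSE)
      }
      stopifnot(!is.null(prediction))
      cellwise_auroc_aupr(ds$csni, prediction)
    },
    abwap = {
      lab <- ds$cell_info[["trajectory"]]
      if (is.null(lab) || length(unique(lab)) != 2) {
        stop("abwap needs a paired dataset with two trajectory labels", call. = FALSE)
      }
      labs <- unique(lab)
      ord1 <- which(lab == labs[1])[order(ds$cell_info$pseudotime[lab == labs[1]])]
      ord2 <- which(lab == labs[2])[order(ds$cell_info$pseudotime[lab == labs[2]])]
      pt1 <- ds$cell_info$pseudotime[ord1]
      pt2 <- ds$cell_info$pseudotime[ord2]
      path <- if (is.null(prediction)) {
        expr <- log1p(as.matrix(ds$counts_spliced))
        dtw_align(expr[ord1, , drop = FALSE], expr[ord2, , drop = FALSE])$path
      } else {
        as.matrix(prediction)
      }
      out <- tibble::tibble(
        alignment = paste(labs, collapse = " vs "),
        abwap = abwap(path, pt1, pt2)
      )
      attr(out, "summary") <- c(abwap = out$abwap)
      out
    }
  )
}

#' Convert a dataset to a SingleCellExperiment
#'
#' Spliced/unspliced/protein observed counts become assays (cells as
#' columns), cell metadata becomes `colData` and gene metadata `rowData`.
#' Requires the `SingleCellExperiment` package.
#'
#' @param ds An `sc_dataset`.
#' @return A `SingleCellExperiment`.
#' @export
as_sce <- function(ds) {
  if (!requireNamespace("SingleCellExperiment", quietly = TRUE)) {
    stop("the SingleCellExperiment package is required for as_sce()", call. = FALSE)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(
      spliced = Matrix::t(ds$counts_spliced),
      unspliced = Matrix::t(ds$counts_unspliced),
      protein = Matrix::t(ds$counts_protein)
    ),
    colData = as.data.frame(ds$cell_info, row.names = ds$cell_info$cell_id),
    rowData = as.data.frame(ds$gene_info, row.names = ds$gene_info$gene)
  )
}
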