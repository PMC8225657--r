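#' RNA velocity ground truth
#'
#' The true velocity of a gene at a recorded state is the propensity of
#' mRNA production minus the propensity of mRNA decay at that state; it
#' is positive when expression is about to increase and negative when it
#' is about to decrease. By default the mature-mRNA layer is used
#' (transcription propensity minus mature-mRNA degradation propensity);
#' `layer = "premrna"` uses the pre-mRNA degradation propensity instead.
#'
#' @param x A `simulation_trace`, a `sampled_cells` object, or a
#'   propensity matrix (rows x 6 reactions per gene, in system order).
#' @param layer `"mature"` (default) or `"premrna"`.
#' @return Matrix (rows x genes) of ground-truth velocities.
#' @export
compute_velocity_ground_truth <- function(x, layer = c("mature", "premrna")) {
  layer <- match.arg(layer)
  p <- if (is.matrix(x)) x else x$propensities
  if (is.null(p)) stop("no propensity trace available; enable propensity tracking", call. = FALSE)
  M <- ncol(p)
  stopifnot(M %% 6 == 0)
  G <- M %/% 6
  trans <- p[, 6 * (seq_len(G) - 1) + 1, drop = FALSE]
  decay_col <- if (layer == "mature") 5 else 4
  decay <- p[, 6 * (seq_len(G) - 1) + decay_col, drop = FALSE]
  v <- trans - decay
  cn <- colnames(p)
  if (!is.null(cn)) colnames(v) <- sub("^transcription_", "", cn[6 * (seq_len(G) - 1) + 1])
  v
}

#' Regulatory effect of one interaction in one state
#'
#' The contribution of regulator `R` to the transcription of target `T`
#' at state `S`: the drop in transcription propensity when the
#' regulator's abundance is zeroed, scaled by the inverse of the target's
#' pre-mRNA production rate,
#' `regeffect = (proptrans(S) - proptrans(S[R <- 0])) / xpr`.
#' It lies in `[-1, 1]`: positive for an active activator, negative for
#' an active repressor, 0 when the regulator is absent.
#'
#' @param state Numeric state vector (length 3 x genes, system species
#'   order).
#' @param regulator,target Gene names of an interaction present in the
#'   system.
#' @param system A `reaction_system`.
#' @return The scalar regulatory effect.
#' @export
compute_regulatory_effect <- function(state, regulator, target, system) {
  a <- system$arr
  gi <- match(target, system$genes$gene)
  if (is.na(gi)) stop("unknown target gene '", target, "'", call. = FALSE)
  idx <- if (a$reg_ptr[gi + 1L] > a$reg_ptr[gi]) (a$reg_ptr[gi] + 1L):a$reg_ptr[gi + 1L] else integer()
  r <- idx[a$reg_regulator[idx] == regulator]
  if (length(r) == 0) stop("no interaction ", regulator, " -> ", target, " in the system", call. = FALSE)
  f1 <- transcription_propensities(system, state)[gi]
  state0 <- state
  state0[a$reg_sp[r] + 1L] <- 0
  f0 <- transcription_propensities(system, state0)[gi]
  (f1 - f0) / a$xpr[gi]
}

# vectorised over cells: nu matrix per target, recompute with one
# regulator zeroed at a time
regeffects_for_target <- function(states, system, gi) {
  a <- system$arr
  if (a$reg_ptr[gi + 1L] <= a$reg_ptr[gi]) return(NULL)
  idx <- (a$reg_ptr[gi] + 1L):a$reg_ptr[gi + 1L]
  m <- length(idx)
  abund <- states[, a$reg_sp[idx] + 1L, drop = FALSE]
  nu <- sweep(abund, 2, a$reg_k[idx], "/")
  nu <- sweep(nu, 2, a$reg_n[idx], "^")
  eff <- a$reg_eff[idx]
  act <- eff > 0
  sy <- a$sy[gi]
  ba <- a$ba[gi]
  f_of <- function(numat) {
    actprod <- if (any(act)) apply(numat[, act, drop = FALSE] + sy, 1, prod) else rep(1, nrow(numat))
    denom <- apply(numat + 1, 1, prod)
    pmax((ba - sy^sum(act) + actprod) / denom, 0)  # f / xpr
  }
  base <- f_of(nu)
  out <- matrix(0, nrow(states), m)
  for (j in seq_len(m)) {
    nu0 <- nu
    nu0[, j] <- 0
    out[, j] <- base - f_of(nu0)
  }
  list(idx = idx, regeffect = out)
}

#' Cell-specific ground-truth regulatory network
#'
#' Evaluates the regulatory effect of every interaction of the static
#' GRN in every cell, yielding the complete cell-specific ground-truth
#' network, and binarises it: an interaction is active in a cell iff its
#' absolute regulatory effect reaches `activity_threshold`.
#'
#' @param states Matrix (cells x species) of true molecule counts, or a
#'   `sampled_cells` object.
#' @param system A `reaction_system`.
#' @param activity_threshold Minimum `|regeffect|` for an interaction to
#'   count as active.
#' @return A tibble with columns `cell`, `regulator`, `target`,
#'   `regeffect`, `active`.
#' @export
compute_cell_specific_grn <- function(states, system, activity_threshold = 1e-4) {
  if (inherits(states, "sampled_cells")) {
    cells <- states$meta$cell_id
    states <- states$counts
  } else {
    cells <- rownames(states) %||% sprintf("cell%d", seq_len(nrow(states)))
  }
  a <- system$arr
  G <- system$num_genes
  parts <- list()
  for (gi in seq_len(G)) {
    re <- regeffects_for_target(states, system, gi)
    if (is.null(re)) next
    parts[[length(parts) + 1L]] <- tibble::tibble(
      cell = rep(cells, times = length(re$idx)),
      regulator = rep(a$reg_regulator[re$idx], each = length(cells)),
      target = rep(a$reg_target[re$idx], each = length(cells)),
      regeffect = as.vector(re$regeffect)
    )
  }
  out <- do.call(rbind, parts)
  out$active <- abs(out$regeffect) >= activity_threshold & out$regeffect != 0
  out
}

#' Export ground truths
#'
#' Writes the velocity ground truth as Matrix Market and the
#' cell-specific network as a long-format TSV.
#'
#' @param velocity Matrix (cells x genes).
#' @param csni Tibble from [compute_cell_specific_grn()].
#' @param dir Output directory.
#' @export
write_ground_truths <- function(velocity, csni, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(velocity, sparse = TRUE), file.path(dir, "velocity_gt.mtx"))
  utils::write.table(as.data.frame(csni), file.path(dir, "csni_gt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
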