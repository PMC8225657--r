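#' @useDynLib grnsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' SSA configuration
#'
#' @param total_time Length `T` of the recorded (post warm-up) phase;
#'   usual simulations use `10 <= T <= 20`.
#' @param burn_time Length of the warm-up phase preceding time 0. During
#'   the warm-up only genes of warm-up-marked modules and housekeeping
#'   genes are transcribed; cells are never sampled from it.
#' @param census_interval Minimum simulated-time spacing between recorded
#'   snapshots; `0` records every single reaction event.
#' @param num_simulations Number of independent SSA runs backing one
#'   dataset.
#' @param seed Master seed; each run derives its own sub-seed.
#' @param max_events Safety cap on the number of reaction events per run.
#' @return A list of class `ssa_config`.
#' @export
ssa_config <- function(total_time = 15, burn_time = 2, census_interval = 0.01,
                       num_simulations = 32, seed = 1, max_events = 1e8) {
  stopifnot(total_time > 0, burn_time >= 0, census_interval >= 0, num_simulations >= 1)
  structure(
    list(total_time = total_time, burn_time = burn_time,
         census_interval = census_interval, num_simulations = num_simulations,
         seed = seed, max_events = max_events),
    class = "ssa_config"
  )
}

#' One step of the direct-method SSA
#'
#' Given the current propensities, draws the waiting time
#' `tau = ln(1/r) / P` (with `P` the total propensity and `r` uniform on
#' (0, 1)) and selects reaction `j` with probability `prop_j / P`. When
#' all propensities are zero the state is absorbing: `tau` is infinite
#' and no reaction is returned.
#'
#' @param propensities Non-negative numeric vector.
#' @param u_time,u_reaction Uniform(0,1) draws; supplied for testability,
#'   drawn from the session RNG by default.
#' @return A list with `tau` (time increment) and `reaction` (index, or
#'   `NA` if absorbing).
#' @export
ssa_step <- function(propensities, u_time = stats::runif(1), u_reaction = stats::runif(1)) {
  stopifnot(all(propensities >= 0))
  P <- sum(propensities)
  if (P <= 0) {
    return(list(tau = Inf, reaction = NA_integer_))
  }
  tau <- log(1 / u_time) / P
  j <- findInterval(u_reaction * P, cumsum(propensities), left.open = TRUE) + 1L
  list(tau = tau, reaction = as.integer(j))
}

new_trace <- function(res, system, burn_rows, sim_index) {
  colnames(res$counts) <- system$species
  rn <- paste0(system$reactions$kind, "_", system$reactions$gene)
  colnames(res$propensities) <- rn
  colnames(res$firings) <- rn
  structure(
    list(
      times = res$times,
      counts = res$counts,
      propensities = res$propensities,
      firings = res$firings,
      burn = burn_rows,
      final_state = res$final_state,
      sim_index = sim_index,
      species = system$species
    ),
    class = "simulation_trace"
  )
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace> sim ", x$sim_index, ": ", length(x$times),
      " census rows over t = [", round(min(x$times), 3), ", ",
      round(max(x$times), 3), "], ", length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Simulate one cell lineage with the exact SSA
#'
#' Runs the warm-up phase first (transcription restricted to
#' warm-up-marked and housekeeping genes, reported at negative times),
#' then the main phase from the warm-up end state. At every census the
#' molecule counts, the propensity of every reaction, and the number of
#' firings of every reaction since the previous census are recorded.
#'
#' @param system A `reaction_system`.
#' @param config An [ssa_config()].
#' @param seed Optional seed for this run (defaults to `config$seed`).
#' @param sim_index Index tag stored in the trace.
#' @return A `simulation_trace`.
#' @export
simulate_ssa <- function(system, config = ssa_config(), seed = NULL, sim_index = 1L) {
  a <- system$arr
  G <- system$num_genes
  run <- function(state0, t0, t1, mask) {
    ssa_run_core(
      as.numeric(state0), t0, t1, config$census_interval,
      a$xpr, a$ba, a$sy, a$splice, a$transl, a$deg_x, a$deg_y, a$deg_z,
      a$reg_ptr, a$reg_sp, a$reg_k, a$reg_n, a$reg_eff,
      mask, config$max_events
    )
  }
  with_seed(seed %||% config$seed, {
    state0 <- rep(0, 3L * G)
    if (config$burn_time > 0) {
      burn <- run(state0, -config$burn_time, 0, a$burn)
      main <- run(burn$final_state, 0, config$total_time, rep(TRUE, G))
      res <- list(
        times = c(burn$times, main$times[-1]),
        counts = rbind(burn$counts, main$counts[-1, , drop = FALSE]),
        propensities = rbind(burn$propensities, main$propensities[-1, , drop = FALSE]),
        firings = rbind(burn$firings, main$firings[-1, , drop = FALSE]),
        final_state = main$final_state
      )
      burn_rows <- c(rep(TRUE, length(burn$times)), rep(FALSE, length(main$times) - 1L))
    } else {
      main <- run(state0, 0, config$total_time, rep(TRUE, G))
      res <- main
      burn_rows <- rep(FALSE, length(main$times))
    }
    new_trace(res, system, burn_rows, sim_index)
  })
}

#' Run several independent SSA simulations
#'
#' Each run gets a sub-seed derived from the master seed, so the whole
#' set is reproducible while runs stay independent.
#'
#' @inheritParams simulate_ssa
#' @return A list of `simulation_trace` objects.
#' @export
run_simulations <- function(system, config = ssa_config()) {
  lapply(seq_len(config$num_simulations), function(i) {
    simulate_ssa(system, config, seed = derive_seed(config$seed, "ssa", i), sim_index = i)
  })
}

#' Export a simulation trace
#'
#' Writes the census times, counts, propensities and firing counts as
#' TSV tables plus a JSON manifest with the configuration.
#'
#' @param trace A `simulation_trace`.
#' @param prefix Path prefix.
#' @param config Optional [ssa_config()] recorded in the manifest.
#' @export
write_trace <- function(trace, prefix, config = NULL) {
  write_mat <- function(m, suffix) {
    df <- data.frame(time = trace$times, burn = trace$burn, m, check.names = FALSE)
    utils::write.table(df, paste0(prefix, "_", suffix, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_mat(trace$counts, "counts")
  write_mat(trace$propensities, "propensities")
  write_mat(trace$firings, "firings")
  jsonlite::write_json(
    list(sim_index = trace$sim_index, config = config),
    paste0(prefix, "_manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}
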