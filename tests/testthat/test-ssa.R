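test_that("ssa_step implements the direct-method update", {
  st <- ssa_step(c(2), u_time = exp(-1), u_reaction = 0.5)
  expect_equal(st$tau, 0.5)
  expect_identical(st$reaction, 1L)

  st <- ssa_step(c(0, 0, 0))
  expect_identical(st$tau, Inf)
  expect_true(is.na(st$reaction))

  # reaction chosen proportionally to propensity: (3, 1) -> 0.75
  set.seed(99)
  n <- 1e5
  u <- stats::runif(n)
  picks <- vapply(u, function(ui) ssa_step(c(3, 1), u_time = 0.5, u_reaction = ui)$reaction, 0L)
  phat <- mean(picks == 1L)
  ci_half <- stats::qnorm(0.995) * sqrt(0.75 * 0.25 / n)
  expect_lt(abs(phat - 0.75), ci_half)
})

test_that("inter-event times of a frozen system are exponential", {
  set.seed(123)
  props <- c(2, 3, 5)  # total 10
  taus <- vapply(seq_len(1e4), function(i) ssa_step(props)$tau, 0)
  ks <- stats::ks.test(taus, "pexp", rate = sum(props))
  expect_gt(ks$p.value, 0.01)
})

test_that("a constitutive gene reaches its birth-death stationary state", {
  # expected pre-mRNA copy number xpr / (splicing + degradation) >= 100,
  # translation kept slow so the run stays cheap
  cfg <- kinetics_config(base_mrna_production = 30, splicing_rate = 1,
                         translation_rate = 0.05)
  ts <- toy_system(tf_gene("G1"), config = cfg)
  sys <- ts$system
  kin <- ts$kinetics
  expected <- kin$genes$transcription_rate[1] /
    (kin$genes$splicing_rate[1] + kin$genes$degradation_premrna[1])
  expect_gt(expected, 100)

  tr <- simulate_ssa(sys, ssa_config(total_time = 600, burn_time = 20,
                                     census_interval = 2, num_simulations = 1),
                     seed = 4)
  x <- tr$counts[!tr$burn, 1]
  expect_lt(abs(mean(x) - expected) / expected, 0.05)
  # Poisson stationary distribution: variance tracks the mean
  expect_gt(stats::var(x) / mean(x), 0.8)
  expect_lt(stats::var(x) / mean(x), 1.25)
})

test_that("burn phase silences genes outside warm-up modules", {
  b <- backbone(
    modules = tibble::tibble(module = c("A", "B"), basal = c(1, 0), burn = c(TRUE, FALSE)),
    module_interactions = tibble::tibble(from = "A", to = "B", effect = 1, strength = 4),
    state_network = tibble::tibble(from = "S0", to = "S1", on = list("B"),
                                   off = list(character()), length = 1),
    start_state = "S0"
  )
  genes <- rbind(tf_gene("A_TF1", "A", TRUE, 1), tf_gene("B_TF1", "B", FALSE, 0))
  ints <- generate_tf_interactions(b, genes)
  ts <- toy_system(genes, ints, bb = b)
  tr <- simulate_ssa(ts$system, ssa_config(total_time = 10, burn_time = 3,
                                           census_interval = 0.1), seed = 8)
  b_cols <- grep("_B_TF1$", colnames(tr$counts))
  expect_true(all(tr$counts[tr$burn, b_cols] == 0))
  # A was expressed during the warm-up
  expect_gt(sum(tr$counts[tr$burn, "x_A_TF1"]), 0)
  # B becomes expressed in the main phase (driven by A)
  expect_gt(sum(tr$counts[!tr$burn, "x_B_TF1"]), 0)
})

test_that("census bookkeeping is consistent with the fired reactions", {
  ts <- toy_system(tf_gene("G1"))
  sys <- ts$system

  # census_interval = 0 records every event
  tr <- simulate_ssa(sys, ssa_config(total_time = 1, burn_time = 0,
                                     census_interval = 0), seed = 2)
  expect_true(all(diff(tr$times) >= 0))
  expect_true(all(rowSums(tr$firings[-1, , drop = FALSE]) == 1))

  # abundance deltas follow the state-change vectors of the firings
  S <- matrix(0L, nrow(sys$reactions), length(sys$species))
  for (r in seq_len(nrow(sys$reactions))) {
    eff <- grnsim:::reaction_effect(sys, r)
    S[r, eff$species] <- eff$delta
  }
  tr2 <- simulate_ssa(sys, ssa_config(total_time = 5, burn_time = 0,
                                      census_interval = 0.25), seed = 3)
  deltas <- diff(tr2$counts)
  implied <- tr2$firings[-1, , drop = FALSE] %*% S
  expect_equal(unname(deltas), unname(implied))
  expect_true(all(tr2$counts >= 0))
})

test_that("multiple runs are independent but reproducible", {
  ts <- toy_system(tf_gene("G1"))
  cfg <- ssa_config(total_time = 2, burn_time = 0, census_interval = 0.5,
                    num_simulations = 8, seed = 77)
  traces <- run_simulations(ts$system, cfg)
  expect_length(traces, 8)
  expect_identical(vapply(traces, function(t) t$sim_index, 0L), 1:8)
  expect_true(all(vapply(traces, function(t) identical(t$species, ts$system$species), TRUE)))
  # distinct sub-seeds give distinct realisations
  expect_false(identical(traces[[1]]$counts, traces[[2]]$counts))
  traces2 <- run_simulations(ts$system, cfg)
  expect_identical(lapply(traces2, `[[`, "counts"), lapply(traces, `[[`, "counts"))
})
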