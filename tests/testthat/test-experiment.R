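test_that("proportional allocation uses largest-remainder rounding", {
  expect_identical(grnsim:::largest_remainder(c(1, 3), 8), c(2L, 6L))
  expect_identical(grnsim:::largest_remainder(c(1), 5), 5L)
  set.seed(1)
  for (i in 1:20) {
    w <- stats::runif(sample(2:6, 1))
    n <- sample(1:100, 1)
    alloc <- grnsim:::largest_remainder(w, n)
    expect_identical(sum(alloc), n)
    expect_true(all(abs(alloc - n * w / sum(w)) < 1))
  }
})

test_that("library-size models draw positive integers, empirically or parametrically", {
  m <- library_size_model()
  ls <- draw_library_sizes(m, 500, seed = 1)
  expect_true(all(ls >= 1) && is.integer(ls))
  expect_lt(abs(stats::median(ls) - 5000) / 5000, 0.15)

  ref <- Matrix::Matrix(matrix(stats::rpois(200, 20), nrow = 10), sparse = TRUE)
  me <- library_size_model("empirical", counts = ref)
  ls <- draw_library_sizes(me, 100, seed = 2)
  expect_true(all(ls %in% Matrix::colSums(ref)))
})

test_that("molecule sampling conserves library sizes and abundance structure", {
  set.seed(5)
  ab <- matrix(stats::rpois(50 * 30, 8), 50, 30)
  ab[, 7] <- 0  # a silent species
  res <- sample_molecules(ab, library_size_model(median_size = 2000), seed = 9)
  expect_identical(unname(rowSums(res$counts)), as.numeric(res$library_sizes))
  expect_true(all(res$counts[, 7] == 0))

  # with capture sd 0, expected counts are proportional to abundance
  ab1 <- matrix(c(1, 2, 5), 1, 3)
  res1 <- sample_molecules(ab1[rep(1, 200), ],
                           library_size_model(median_size = 5000, cv = 1e-6),
                           capture_rate_sd = 0, seed = 1)
  prop <- colSums(res1$counts) / sum(res1$counts)
  expect_equal(prop, c(1, 2, 5) / 8, tolerance = 0.02)

  expect_warning(
    res0 <- sample_molecules(matrix(0, 2, 3), library_size_model(), seed = 1),
    "all-zero"
  )
  expect_true(all(res0$counts == 0))
})

test_that("time-series sampling honours the window partition", {
  ts <- toy_system(rbind(tf_gene("G1", basal = 1), tf_gene("G2", basal = 0.6),
                         tf_gene("G3", basal = 0.3)))
  cfg <- ssa_config(total_time = 10, burn_time = 1, census_interval = 0.02,
                    num_simulations = 2, seed = 3)
  traces <- run_simulations(ts$system, cfg)
  gs <- simulate_gold_standard(ts$system, toy_backbone(),
                               gs_config(burn_time = 1, census_interval = 0.5))

  k <- 8; g <- 0.75; T <- 10
  w <- (T - (k - 1) * g) / k
  expect_equal(w, 0.59375)
  cells <- sample_cells_timeseries(traces, gs, N = 16, T = T, k = k, g = g, seed = 4)
  expect_identical(nrow(cells$meta), 16L)
  win <- floor(cells$meta$sim_time / (w + g))
  offset <- cells$meta$sim_time - win * (w + g)
  expect_true(all(offset <= w + 1e-9))
  expect_true(all(table(factor(win, levels = 0:7)) == 2))

  # k = 1: uniform over [0, T]
  cells1 <- sample_cells_timeseries(traces, gs, N = 10, T = T, k = 1, seed = 5)
  expect_true(all(cells1$meta$sim_time >= 0 & cells1$meta$sim_time <= T))

  expect_error(sample_cells_timeseries(traces, gs, 10, T = 5, k = 8, g = 0.75),
               "too small")
})

test_that("snapshot sampling allocates cells proportionally to edge length", {
  m_b <- predefined_backbone("linear")
  grn <- generate_grn(m_b, 10, 5, 3, seed = 2)
  kin <- sample_kinetics(grn, seed = 3)
  sys <- build_reaction_system(grn, kin)
  gs <- simulate_gold_standard(sys, m_b, gs_config(census_interval = 0.25))
  traces <- run_simulations(sys, ssa_config(total_time = 15, census_interval = 0.1,
                                            num_simulations = 4, seed = 6))
  cells <- sample_cells_snapshot(traces, gs, N = 97, seed = 7)
  expect_identical(nrow(cells$meta), 97L)
  alloc <- table(factor(cells$meta$edge, levels = seq_len(nrow(gs$edges))))
  expect_true(all(abs(alloc - 97 * gs$edges$length / sum(gs$edges$length)) < 1))
  # never sampled from the warm-up phase
  expect_true(all(cells$meta$sim_time >= 0))
  expect_true(all(cells$meta$pseudotime >= 0 & cells$meta$pseudotime <= 1))
})

test_that("batch simulation shares the GRN but redraws kinetics", {
  cfg <- small_config(num_cells = 40)
  grn <- generate_grn(predefined_backbone("linear"), 6, 6, 4, seed = 21)
  ds <- simulate_batches(grn, cfg, num_batches = 2, seed = 31)
  expect_setequal(unique(ds$cell_info$batch), c("batch1", "batch2"))
  expect_identical(nrow(ds$cell_info), 40L)
  expect_equal(as.vector(table(ds$cell_info$batch)), c(20, 20))
  expect_identical(rownames(ds$counts_spliced), ds$cell_info$cell_id)
  expect_identical(ds$gene_info$gene, grn$genes$gene)

  ds1 <- simulate_batches(grn, cfg, num_batches = 1, seed = 31)
  expect_true(all(ds1$cell_info$batch == "batch1"))
})

test_that("paired datasets share one GRN and carry two trajectories", {
  cfg <- small_config(num_cells = 30)
  ds <- generate_paired_dataset(predefined_backbone("linear"), cfg, seed = 41)
  expect_setequal(unique(ds$cell_info$trajectory), c("traj1", "traj2"))
  expect_identical(colnames(ds$counts_spliced), ds$gene_info$gene)
  for (lab in c("traj1", "traj2")) {
    pt <- ds$cell_info$pseudotime[ds$cell_info$trajectory == lab]
    expect_true(all(pt >= 0 & pt <= 1))
  }
  # the two sub-datasets used different kinetics: different gold standards
  expect_length(ds$gold_standards, 2)
  expect_false(identical(ds$gold_standards[[1]]$mats, ds$gold_standards[[2]]$mats))
})
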