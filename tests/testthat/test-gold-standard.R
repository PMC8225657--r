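make_small_model <- function(backbone_name = "linear", seed = 1) {
  b <- predefined_backbone(backbone_name)
  grn <- generate_grn(b, num_tfs = 2 * nrow(b$modules), num_targets = 6,
                      num_hks = 4, seed = seed)
  kin <- sample_kinetics(grn, seed = seed + 1)
  sys <- build_reaction_system(grn, kin)
  list(b = b, grn = grn, sys = sys)
}

test_that("gold-standard branches are continuous across states", {
  m <- make_small_model("linear")
  gs <- simulate_gold_standard(m$sys, m$b, gs_config(census_interval = 0.25))
  # first branch starts at the warm-up end state
  expect_equal(unname(gs$mats[[1]][1, ]), unname(gs$burn_state))
  # each downstream branch starts at its upstream branch's final row
  for (i in 2:nrow(gs$edges)) {
    up <- which(gs$edges$to == gs$edges$from[i])[1]
    expect_equal(unname(gs$mats[[i]][1, ]),
                 unname(gs$mats[[up]][nrow(gs$mats[[up]]), ]))
  }
  # progression is strictly increasing per branch
  for (p in gs$progressions) expect_true(all(diff(p) > 0))
})

test_that("a module switched off along an edge decays along that branch", {
  m <- make_small_model("converging")
  gs <- simulate_gold_standard(m$sys, m$b, gs_config(census_interval = 0.25))
  # edge 1 switches off the warm-up-resolved B modules
  off_mods <- gs$backbone$state_network$off[[1]]
  expect_true(length(off_mods) > 0)
  off_genes <- which(m$grn$genes$kind == "tf" & m$grn$genes$module %in% off_mods)
  x_off <- rowSums(gs$mats[[1]][, off_genes, drop = FALSE])  # pre-mRNA block
  expect_lt(x_off[length(x_off)], 0.05 * max(x_off[1], 1))
})

test_that("mapping the gold standard onto itself is the identity", {
  m <- make_small_model("linear")
  gs <- simulate_gold_standard(m$sys, m$b, gs_config(census_interval = 0.5))
  pts <- grnsim:::gs_points(gs)
  pos <- map_cells_to_trajectory(pts$mat, gs)
  # identity up to branch boundaries (the end of one branch and the start
  # of the next are the same trajectory position)
  expect_equal(pos$pseudotime_raw, pts$meta$pseudotime_raw)
})

test_that("ties are broken towards the earliest pseudotime", {
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"), kind = "tf",
                          module = "A", burn = TRUE, basal = 1)
  ramp <- cbind(0, seq(1, 3, length.out = 5), 0)  # only y_g2 varies
  mat1 <- cbind(matrix(0, 5, 3), ramp, matrix(0, 5, 3))
  gs <- structure(list(
    edges = tibble::tibble(from = c("S0", "S1"), to = c("S1", "S2"),
                           length = c(1, 1), dist_from = c(0, 1)),
    mats = list(mat1, mat1),  # duplicated branch: identical columns
    progressions = list(seq(0, 1, length.out = 5), seq(0, 1, length.out = 5)),
    genes = genes,
    species = c(paste0("x_", genes$gene), paste0("y_", genes$gene), paste0("z_", genes$gene)),
    total_length = 2,
    backbone = NULL
  ), class = "gold_standard")
  pos <- map_cells_to_trajectory(mat1[3, , drop = FALSE], gs)
  expect_identical(pos$edge, 1L)  # not the identical later copy

  expect_warning(pos0 <- map_cells_to_trajectory(matrix(1, 1, 9), gs), "zero-variance")
  expect_equal(pos0$pseudotime_raw, 0)
})

test_that("pseudotime is the rescaled geodesic distance from the start", {
  gs <- structure(list(
    edges = tibble::tibble(from = c("S0", "S1"), to = c("S1", "S2"),
                           length = c(1, 3), dist_from = c(0, 1)),
    total_length = 4
  ), class = "gold_standard")
  pos <- tibble::tibble(edge = c(1L, 2L, 2L), percentage = c(0, 0.5, 1))
  expect_equal(compute_pseudotime(pos, gs), c(0, (1 + 1.5) / 4, 1))
})
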