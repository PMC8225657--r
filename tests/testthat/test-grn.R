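test_that("TF sampling respects the per-module minimum and totals", {
  b <- predefined_backbone("bifurcating")  # 6 modules
  n_mod <- nrow(b$modules)

  tfs <- sample_tfs(b, n_mod, seed = 1)
  expect_identical(as.integer(table(tfs$module)[b$modules$module]), rep(1L, n_mod))

  tfs <- sample_tfs(b, 15, seed = 1)
  cnt <- table(tfs$module)
  expect_identical(sum(cnt), 15L)
  expect_true(all(cnt >= 1))
  # burn/basal inherited from the module
  m <- match(tfs$module, b$modules$module)
  expect_identical(tfs$burn, b$modules$burn[m])
  expect_identical(tfs$basal, b$modules$basal[m])

  expect_error(sample_tfs(b, n_mod - 1), "too small")
})

test_that("TF interactions inherit effect and strength from the backbone", {
  b <- backbone(
    modules = tibble::tibble(module = c("A", "B"), basal = c(1, 0), burn = c(TRUE, FALSE)),
    module_interactions = tibble::tibble(from = "A", to = "B", effect = -1, strength = 7),
    state_network = tibble::tibble(from = "S0", to = "S1", on = list("B"),
                                   off = list(character()), length = 1),
    start_state = "S0"
  )
  tfs <- sample_tfs(b, 5, seed = 1)
  ints <- generate_tf_interactions(b, tfs)
  expect_true(all(ints$effect == -1))
  expect_true(all(ints$strength == 7))
  # every TF of B has at least one regulator from A
  b_tfs <- tfs$gene[tfs$module == "B"]
  expect_true(all(b_tfs %in% ints$target))
  expect_true(all(ints$regulator %in% tfs$gene[tfs$module == "A"]))

  # a module self-loop expands to edges within the module's TFs
  b$module_interactions <- tibble::tibble(from = "A", to = "A", effect = 1, strength = 2)
  ints <- generate_tf_interactions(b, tfs)
  a_tfs <- tfs$gene[tfs$module == "A"]
  expect_setequal(unique(c(ints$regulator, ints$target)), a_tfs)

  # no backbone interactions -> no TF interactions
  b$module_interactions <- b$module_interactions[0, ]
  expect_identical(nrow(generate_tf_interactions(b, tfs)), 0L)
})

test_that("the synthetic reference network is seeded, capped and loop-free", {
  ref <- generate_reference_network(100, max_in_degree = 5, seed = 42)
  expect_setequal(unique(c(ref$regulator, ref$target)), sprintf("N%d", 1:100))
  expect_true(all(ref$regulator != ref$target))
  expect_true(all(table(ref$target) <= 5))
  expect_identical(generate_reference_network(100, max_in_degree = 5, seed = 42), ref)
  # heavy-tailed out-degree: a few hubs dominate
  outdeg <- table(ref$regulator)
  expect_gt(max(outdeg), 3 * stats::median(outdeg))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_network(ref, path)
  expect_equal(tibble::as_tibble(read_reference_network(path)), tibble::as_tibble(ref))
})

test_that("target subnetwork keeps every target downstream of a TF", {
  b <- predefined_backbone("linear")
  ref <- generate_reference_network(200, seed = 7)
  tfs <- sample_tfs(b, 8, seed = 1)
  grn0 <- grnsim:::new_grn(tfs, generate_tf_interactions(b, tfs), b)

  grn <- sample_target_subnetwork(grn0, ref, num_targets = 50, seed = 2)
  targets <- grn$genes$gene[grn$genes$kind == "target"]
  expect_length(targets, 50)
  # reachability from the TF set
  reach <- grn$genes$gene[grn$genes$kind == "tf"]
  repeat {
    nxt <- union(reach, grn$interactions$target[grn$interactions$regulator %in% reach])
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_true(all(targets %in% reach))

  grn1 <- sample_target_subnetwork(grn0, ref, num_targets = 30,
                                   max_regs_per_target = 1, seed = 3)
  tgt <- grn1$genes$gene[grn1$genes$kind == "target"]
  indeg <- table(grn1$interactions$target[grn1$interactions$target %in% tgt])
  expect_true(all(indeg == 1))
  expect_length(indeg, 30)
})

test_that("housekeeping subnetwork is weakly connected and separate", {
  ref <- generate_reference_network(50, seed = 5)
  hk <- sample_housekeeping_subnetwork(ref, 10, seed = 1)
  expect_identical(nrow(hk$genes), 10L)
  expect_true(all(hk$genes$kind == "housekeeping"))
  g <- igraph::graph_from_data_frame(
    as.data.frame(hk$interactions[, c("regulator", "target")]),
    vertices = data.frame(name = hk$genes$gene)
  )
  expect_true(igraph::is_connected(g, mode = "weak"))
  expect_true(all(table(hk$interactions$target) <= 5))

  expect_identical(nrow(sample_housekeeping_subnetwork(ref, 0)$genes), 0L)
})

test_that("the full GRN pipeline is reproducible and structurally sound", {
  b <- predefined_backbone("bifurcating")
  grn <- generate_grn(b, num_tfs = 10, num_targets = 20, num_hks = 8, seed = 11)
  expect_identical(nrow(grn$genes), 10L + 20L + 8L)

  grn2 <- generate_grn(b, num_tfs = 10, num_targets = 20, num_hks = 8, seed = 11)
  expect_equal(grn2$genes, grn$genes)
  expect_equal(grn2$interactions, grn$interactions)

  kind <- stats::setNames(grn$genes$kind, grn$genes$gene)
  rk <- kind[grn$interactions$regulator]
  tk <- kind[grn$interactions$target]
  # no edge crosses the housekeeping boundary
  expect_identical(unname(rk == "housekeeping"), unname(tk == "housekeeping"))
  # TFs are only regulated by TFs
  expect_true(all(rk[tk == "tf"] == "tf"))
})
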