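test_that("hill_part follows the Hill occupancy definition", {
  expect_equal(hill_part(3, 3, 4), 1)       # half-occupation: nu/(1+nu) = 0.5
  expect_equal(hill_part(0, 2, 3), 0)
  expect_equal(hill_part(4, 2, 2), 4)       # (2k/k)^2
  expect_error(hill_part(-1, 2, 2), "non-negative")
})

test_that("sampled kinetics follow the configured rates", {
  grn <- generate_grn(predefined_backbone("linear"), 6, 6, 4, seed = 1)
  cfg <- kinetics_config(base_mrna_production = 3, mrna_halflife = 4,
                         premrna_halflife = 1.5, protein_halflife = 8)
  kin <- sample_kinetics(grn, cfg, seed = 5)
  expect_true(all(kin$genes$transcription_rate == 10 * 3))
  expect_equal(unique(kin$genes$degradation_mrna), log(2) / 4)
  expect_equal(unique(kin$genes$degradation_premrna), log(2) / 1.5)
  expect_equal(unique(kin$genes$degradation_protein), log(2) / 8)
  expect_true(all(kin$interactions$k > 0))
  expect_true(all(kin$interactions$n >= 1))

  kin2 <- sample_kinetics(grn, cfg, seed = 5)
  expect_equal(kin2$genes, kin$genes)
  expect_equal(kin2$interactions, kin$interactions)

  expect_error(kinetics_config(mrna_halflife = -1), "positive")
})

test_that("transcription propensity matches hand-evaluated cases", {
  expect_equal(transcription_propensity(numeric(), numeric(), xpr = 7, ba = 1), 7)
  expect_equal(transcription_propensity(numeric(), numeric(), xpr = 7, ba = 0.3), 7 * 0.3)
  # one activator at half-occupation, no basal
  expect_equal(transcription_propensity(1, +1, xpr = 10, ba = 0, sy = 1), 5)
  # one repressor at nu = 3, full basal
  expect_equal(transcription_propensity(3, -1, xpr = 10, ba = 1, sy = 1), 2.5)
  # all nu = 0 -> xpr * ba regardless of synergism
  expect_equal(transcription_propensity(c(0, 0), c(1, -1), xpr = 4, ba = 0.5, sy = 0.2), 2)
  # out-of-range basal strengths are clamped defensively
  expect_warning(
    out <- transcription_propensity(numeric(), numeric(), xpr = 10, ba = -0.5),
    "clamped"
  )
  expect_identical(out, 0)
})

test_that("the collapsed propensity equals the 2^N-state thermodynamic sum", {
  set.seed(101)
  for (rep in 1:200) {
    N <- sample(0:10, 1)
    nu <- stats::rexp(N)
    effect <- sample(c(-1, 1), N, replace = TRUE)
    xpr <- stats::runif(1, 0.5, 20)
    fast <- transcription_propensity(nu, effect, xpr, ba = 1, sy = 1)
    slow <- propensity_bruteforce(nu, effect, xpr)
    expect_lt(abs(fast - slow) / max(slow, .Machine$double.eps), 1e-12)
    # and equals the closed product form
    act <- effect > 0
    closed <- xpr * prod(nu[act] + 1) / prod(nu + 1)
    expect_equal(fast, closed, tolerance = 1e-12)
  }
})

test_that("propensity is monotone in each regulator's abundance", {
  set.seed(7)
  for (rep in 1:25) {
    N <- sample(1:6, 1)
    effect <- sample(c(-1, 1), N, replace = TRUE)
    nu <- stats::rexp(N)
    ba <- stats::runif(1)
    sy <- stats::runif(1, 0.5, 1)
    for (i in seq_len(N)) {
      lo <- suppressWarnings(transcription_propensity(nu, effect, 10, ba, sy))
      nu_hi <- nu; nu_hi[i] <- nu[i] * 2 + 0.5
      hi <- suppressWarnings(transcription_propensity(nu_hi, effect, 10, ba, sy))
      if (effect[i] > 0) expect_gte(hi, lo - 1e-12) else expect_lte(hi, lo + 1e-12)
    }
  }
})

test_that("the reaction system has six reactions per gene with correct effects", {
  grn <- generate_grn(predefined_backbone("linear"), 6, 6, 4, seed = 2)
  kin <- sample_kinetics(grn, seed = 3)
  sys <- build_reaction_system(grn, kin)
  G <- nrow(grn$genes)
  expect_identical(nrow(sys$reactions), 6L * G)
  expect_length(sys$species, 3L * G)

  # splicing of gene 1: x - 1, y + 1
  eff <- grnsim:::reaction_effect(sys, 2L)
  expect_identical(eff$species, c(1L, G + 1L))
  expect_identical(eff$delta, c(-1L, 1L))
  # transcription adds one pre-mRNA only
  eff <- grnsim:::reaction_effect(sys, 1L)
  expect_identical(eff$species, 1L)
  expect_identical(eff$delta, 1L)

  # linear propensities vanish at zero molecule counts
  p <- grnsim:::propensities(sys, rep(0, 3 * G))
  kinds <- rep(grnsim:::REACTION_KINDS, G)
  expect_true(all(p[kinds != "transcription"] == 0))
  expect_true(all(p >= 0) && all(is.finite(p)))

  # translation propensity is linear in y
  st <- rep(0, 3 * G); st[G + 1] <- 5
  p <- grnsim:::propensities(sys, st)
  expect_equal(p[3], kin$genes$translation_rate[1] * 5)
})
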