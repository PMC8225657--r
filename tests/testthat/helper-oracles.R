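# Independent brute-force oracle for the transcription propensity:
# enumerate all 2^N promoter states, weight each state by the product of
# the Hill occupancies of its bound regulators, set the relative
# activation to 0 when any bound regulator is a repressor and 1
# otherwise, and average.
propensity_bruteforce <- function(nu, effect, xpr) {
  N <- length(nu)
  num <- 0
  den <- 0
  for (j in 0:(2^N - 1)) {
    bits <- if (N > 0) as.integer(intToBits(j))[seq_len(N)] else integer()
    w <- prod(ifelse(bits == 1, nu, 1))
    alpha <- if (any(bits == 1 & effect < 0)) 0 else 1
    num <- num + alpha * w
    den <- den + w
  }
  xpr * num / den
}

# pair-counting AUROC oracle: fraction of (positive, negative) pairs
# ranked concordantly, ties counting one half
auroc_paircount <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# enumerate all monotone DTW paths on an n x m grid and return the
# minimal accumulated cost (exponential; only for tiny grids)
dtw_bruteforce_cost <- function(d) {
  n <- nrow(d)
  m <- ncol(d)
  rec <- function(i, j) {
    if (i == n && j == m) return(d[i, j])
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    d[i, j] + best
  }
  rec(1, 1)
}

# a minimal one-module backbone whose single gene is constitutively
# transcribed; used for single-gene reaction systems
toy_backbone <- function(basal = 1) {
  backbone(
    modules = tibble::tibble(module = "A", basal = basal, burn = TRUE),
    module_interactions = tibble::tibble(
      from = character(), to = character(), effect = numeric(), strength = numeric()
    ),
    state_network = tibble::tibble(
      from = "S0", to = "S1", on = list("A"), off = list(character()), length = 1
    ),
    start_state = "S0"
  )
}

# hand-built reaction system: `genes` / `interactions` as in a grn;
# kinetics sampled then optionally overridden (e.g. fixed k, n)
toy_system <- function(genes, interactions = NULL, config = kinetics_config(),
                       k = NULL, n = NULL, seed = 1, bb = toy_backbone()) {
  if (is.null(interactions)) {
    interactions <- tibble::tibble(
      regulator = character(), target = character(),
      effect = numeric(), strength = numeric()
    )
  }
  grn <- grnsim:::new_grn(genes, interactions, bb)
  kin <- sample_kinetics(grn, config, seed = seed)
  if (!is.null(k)) kin$interactions$k <- k
  if (!is.null(n)) kin$interactions$n <- n
  list(grn = grn, kinetics = kin, system = build_reaction_system(grn, kin))
}

tf_gene <- function(name, module = "A", burn = TRUE, basal = 1) {
  tibble::tibble(gene = name, kind = "tf", module = module, burn = burn, basal = basal)
}

# small standard dataset config used by several integration tests
small_config <- function(num_cells = 60, ...) {
  generation_config(
    backbone = "linear", num_tfs = 6, num_targets = 6, num_hks = 4,
    num_cells = num_cells,
    ssa = ssa_config(total_time = 15, burn_time = 2, census_interval = 0.05,
                     num_simulations = 4),
    ...
  )
}
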