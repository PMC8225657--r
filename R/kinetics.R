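#' Kinetics configuration
#'
#' Default per-gene constants. Rates are expressed per simulation time
#' unit; one time unit corresponds roughly to an hour of real time, so
#' the defaults mirror typical mammalian medians: an mRNA half-life of
#' 2.5, a protein half-life of 5, and a splicing/translation rate of 2
#' events per molecule per time unit. The pre-mRNA production rate `xpr`
#' is the base mRNA production rate amplified by a factor of 10.
#'
#' @param base_mrna_production Base mRNA production rate
#'   (molecules/time); `xpr = 10 * base_mrna_production`.
#' @param mrna_halflife,premrna_halflife,protein_halflife Half-lives
#'   (time units); degradation rates are `ln(2) / halflife`.
#' @param splicing_rate,translation_rate Per-molecule rates (1/time).
#' @param hill_min,hill_max Range of the uniformly drawn Hill
#'   coefficients (the model is well behaved for coefficients up to ~10;
#'   the default range keeps responses smooth but switch-capable).
#' @param k_jitter_sd Log-normal s.d. of the multiplicative jitter
#'   applied to half-occupation constants; this is the only place where
#'   two kinetics draws for the same network differ besides the Hill
#'   coefficients, and is what makes batch/paired simulations diverge.
#' @param synergism Default per-target synergism `sy` in `[0, 1]`
#'   (1 = fully synergistic regulators).
#' @param regulator_layer Which molecule layer of the regulator drives
#'   transcription: `"protein"` (default; proteins are the acting
#'   species) or `"mrna"`.
#' @return A named list of class `kinetics_config`.
#' @export
kinetics_config <- function(base_mrna_production = 1,
                            mrna_halflife = 2.5,
                            premrna_halflife = 2.5,
                            protein_halflife = 5,
                            splicing_rate = 2,
                            translation_rate = 2,
                            hill_min = 1, hill_max = 2,
                            k_jitter_sd = 0.25,
                            synergism = 1,
                            regulator_layer = c("protein", "mrna")) {
  regulator_layer <- match.arg(regulator_layer)
  cfg <- list(
    base_mrna_production = base_mrna_production,
    mrna_halflife = mrna_halflife,
    premrna_halflife = premrna_halflife,
    protein_halflife = protein_halflife,
    splicing_rate = splicing_rate,
    translation_rate = translation_rate,
    hill_min = hill_min, hill_max = hill_max,
    k_jitter_sd = k_jitter_sd,
    synergism = synergism,
    regulator_layer = regulator_layer
  )
  num <- vapply(cfg[1:6], identity, 0)
  if (any(num <= 0)) stop("kinetics rates and half-lives must be positive", call. = FALSE)
  if (hill_min < 1 || hill_max < hill_min) stop("invalid Hill coefficient range", call. = FALSE)
  structure(cfg, class = "kinetics_config")
}

#' Sample kinetic constants for a GRN
#'
#' Produces the per-gene table (production, splicing, translation and
#' degradation rates, basal expression `ba`, synergism `sy`) and the
#' per-interaction table (half-occupation constant `k`, Hill coefficient
#' `n`, effect, strength). The half-occupation constant of an interaction
#' is the regulator's expected steady-state abundance divided by the
#' interaction strength (jittered log-normally), so stronger interactions
#' respond at lower regulator abundance.
#'
#' @param grn A `grn`.
#' @param config A [kinetics_config()].
#' @param seed Optional seed; the same seed yields identical tables.
#' @return A list of class `kinetics` with elements `genes`,
#'   `interactions` and `config`.
#' @export
sample_kinetics <- function(grn, config = kinetics_config(), seed = NULL) {
  with_seed(seed, {
    g <- grn$genes
    xpr <- 10 * config$base_mrna_production
    deg_x <- log(2) / config$premrna_halflife
    deg_y <- log(2) / config$mrna_halflife
    deg_z <- log(2) / config$protein_halflife
    genes <- tibble::tibble(
      gene = g$gene,
      transcription_rate = xpr,
      splicing_rate = config$splicing_rate,
      translation_rate = config$translation_rate,
      degradation_premrna = deg_x,
      degradation_mrna = deg_y,
      degradation_protein = deg_z,
      ba = g$basal,
      sy = config$synergism
    )
    # expected plateau abundances of a fully expressed gene
    x_ss <- xpr / (config$splicing_rate + deg_x)
    y_ss <- config$splicing_rate * x_ss / deg_y
    z_ss <- config$translation_rate * y_ss / deg_z
    reg_ss <- if (config$regulator_layer == "protein") z_ss else y_ss

    ia <- grn$interactions
    interactions <- tibble::tibble(
      regulator = ia$regulator,
      target = ia$target,
      effect = ia$effect,
      strength = ia$strength,
      k = reg_ss / ia$strength *
        stats::rlnorm(nrow(ia), meanlog = 0, sdlog = config$k_jitter_sd),
      n = stats::runif(nrow(ia), config$hill_min, config$hill_max)
    )
    structure(list(genes = genes, interactions = interactions, config = config),
              class = "kinetics")
  })
}

#' Export kinetics tables
#'
#' Writes `<prefix>_gene_kinetics.tsv` and
#' `<prefix>_interaction_kinetics.tsv` for full provenance of a dataset.
#'
#' @param kin A `kinetics` object.
#' @param prefix Path prefix.
#' @export
write_kinetics <- function(kin, prefix) {
  utils::write.table(as.data.frame(kin$genes), paste0(prefix, "_gene_kinetics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(kin$interactions), paste0(prefix, "_interaction_kinetics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Hill occupancy term
#'
#' `nu = (y / k)^n`, the simplified Hill term of a single regulator, so
#' that `nu / (1 + nu)` is the occupation probability and `y = k` gives
#' half-occupation.
#'
#' @param y Regulator abundance (>= 0).
#' @param k Half-occupation constant (> 0).
#' @param n Hill coefficient.
#' @return The dimensionless occupancy `nu`.
#' @export
hill_part <- function(y, k, n) {
  if (any(y < 0)) stop("regulator abundance must be non-negative", call. = FALSE)
  stopifnot(all(k > 0))
  (y / k)^n
}

#' Transcription propensity of a regulated gene
#'
#' The promoter of a gene with `N` regulators can be in `2^N` bound
#' states; averaging the promoter activity over the thermodynamic
#' equilibrium of those states and allowing a basal activity `ba` and a
#' regulator synergism `sy` collapses the `2^N`-term sum to
#' \deqn{f = xpr \cdot \frac{ba - sy^{|R^+|} + \prod_{i \in R^+}(\nu_i + sy)}
#'   {\prod_{i \in R}(\nu_i + 1)}}
#' where `R` indexes all regulators, `R+` the activating ones and
#' `nu_i = (y_i/k_i)^{n_i}` is each regulator's Hill occupancy. With
#' `ba = 1, sy = 1` this reduces to
#' `xpr * prod(nu[act] + 1) / prod(nu + 1)`, and with all `nu = 0` to
#' `xpr * ba`. Parameter combinations that would make the propensity
#' negative are clamped to zero with a warning.
#'
#' @param nu Numeric vector of Hill occupancies, one per regulator (see
#'   [hill_part()]).
#' @param effect Signed vector (+1 activator / -1 repressor), same
#'   length.
#' @param xpr Pre-mRNA production rate.
#' @param ba Basal expression in `[0, 1]`.
#' @param sy Synergism in `[0, 1]`.
#' @return The propensity (1/time), always >= 0.
#' @export
transcription_propensity <- function(nu, effect, xpr, ba = 1, sy = 1) {
  stopifnot(length(nu) == length(effect))
  act <- effect > 0
  f <- xpr * (ba - sy^sum(act) + prod(nu[act] + sy)) / prod(nu + 1)
  if (f < 0) {
    warning("negative transcription propensity clamped to zero (ba = ", ba,
            ", sy = ", sy, ")", call. = FALSE)
    f <- 0
  }
  f
}

REACTION_KINDS <- c("transcription", "splicing", "translation",
                    "degrade_premrna", "degrade_mrna", "degrade_protein")

#' Build the reaction system for a GRN
#'
#' Each gene contributes six reactions. Transcription creates one
#' pre-mRNA (`x + 1`) at the regulated propensity; splicing converts one
#' pre-mRNA into one mature mRNA (`x - 1`, `y + 1`); translation reads a
#' mature mRNA catalytically and adds one protein (`z + 1`); the three
#' degradations each remove one molecule. All non-transcription
#' propensities are linear: rate constant times molecule count.
#'
#' Species are ordered as all pre-mRNAs (`x_<gene>`), then all mature
#' mRNAs (`y_<gene>`), then all proteins (`z_<gene>`).
#'
#' @param grn A `grn`.
#' @param kinetics A `kinetics` object from [sample_kinetics()].
#' @return A list of class `reaction_system`.
#' @export
build_reaction_system <- function(grn, kinetics) {
  genes <- grn$genes$gene
  G <- length(genes)
  stopifnot(identical(kinetics$genes$gene, genes))
  species <- c(paste0("x_", genes), paste0("y_", genes), paste0("z_", genes))

  reg_layer_offset <- if (kinetics$config$regulator_layer == "protein") 2L * G else G
  gene_index <- stats::setNames(seq_len(G), genes)

  ia <- kinetics$interactions
  missing <- setdiff(c(ia$regulator, ia$target), genes)
  if (length(missing) > 0) {
    stop("kinetics references unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ord <- order(gene_index[ia$target])
  ia <- ia[ord, ]
  n_per_gene <- tabulate(gene_index[ia$target], nbins = G)
  reg_ptr <- c(0L, cumsum(n_per_gene))  # 0-based CSR offsets into ia rows

  reactions <- tibble::tibble(
    kind = rep(REACTION_KINDS, G),
    gene = rep(genes, each = 6)
  )

  kg <- kinetics$genes
  structure(
    list(
      genes = grn$genes,
      species = species,
      reactions = reactions,
      kinetics = kinetics,
      num_genes = G,
      # flat arrays consumed by both the R evaluator and the compiled core
      arr = list(
        xpr = kg$transcription_rate,
        ba = kg$ba,
        sy = kg$sy,
        splice = kg$splicing_rate,
        transl = kg$translation_rate,
        deg_x = kg$degradation_premrna,
        deg_y = kg$degradation_mrna,
        deg_z = kg$degradation_protein,
        reg_ptr = reg_ptr,
        reg_sp = unname(reg_layer_offset + gene_index[ia$regulator] - 1L),  # 0-based
        reg_k = ia$k,
        reg_n = ia$n,
        reg_eff = ia$effect,
        reg_regulator = ia$regulator,
        reg_target = ia$target,
        burn = grn$genes$burn
      )
    ),
    class = "reaction_system"
  )
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system> ", x$num_genes, " genes, ", length(x$species),
      " species, ", nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

# transcription propensities of all genes at `state` (length 3G vector);
# transcription_on masks genes whose transcription is disabled
transcription_propensities <- function(system, state, transcription_on = NULL) {
  a <- system$arr
  G <- system$num_genes
  f <- numeric(G)
  for (g in seq_len(G)) {
    i0 <- a$reg_ptr[g] + 1L
    i1 <- a$reg_ptr[g + 1L]
    if (i1 >= i0) {
      idx <- i0:i1
      nu <- (state[a$reg_sp[idx] + 1L] / a$reg_k[idx])^a$reg_n[idx]
      f[g] <- transcription_propensity(nu, a$reg_eff[idx], a$xpr[g], a$ba[g], a$sy[g])
    } else {
      f[g] <- a$xpr[g] * a$ba[g]
    }
  }
  if (!is.null(transcription_on)) f <- f * as.numeric(transcription_on)
  f
}

#' Evaluate all reaction propensities at a state
#'
#' Returns the propensity of every reaction of the system (six per gene,
#' ordered transcription, splicing, translation, pre-mRNA/mRNA/protein
#' degradation) at the given molecule counts.
#'
#' @param system A `reaction_system`.
#' @param state Numeric vector of molecule counts (length `3 * genes`,
#'   system species order).
#' @param transcription_on Optional logical mask per gene; masked genes
#'   get transcription propensity 0 (used for the warm-up phase).
#' @return Numeric vector of length `6 * genes`.
#' @export
reaction_propensities <- function(system, state, transcription_on = NULL) {
  propensities(system, state, transcription_on)
}

# full propensity vector (length 6G), reaction order per gene:
# transcription, splicing, translation, degrade x, degrade y, degrade z
propensities <- function(system, state, transcription_on = NULL) {
  a <- system$arr
  G <- system$num_genes
  x <- state[seq_len(G)]
  y <- state[G + seq_len(G)]
  z <- state[2L * G + seq_len(G)]
  p <- matrix(0, nrow = 6, ncol = G)
  p[1, ] <- transcription_propensities(system, state, transcription_on)
  p[2, ] <- a$splice * x
  p[3, ] <- a$transl * y
  p[4, ] <- a$deg_x * x
  p[5, ] <- a$deg_y * y
  p[6, ] <- a$deg_z * z
  as.vector(p)
}

# sparse state-change: reaction r affects which species by how much
# returns list(species = int vector, delta = int vector) for reaction index r (1-based)
reaction_effect <- function(system, r) {
  G <- system$num_genes
  g <- ((r - 1L) %/% 6L) + 1L
  kind <- (r - 1L) %% 6L + 1L
  switch(kind,
    list(species = g, delta = 1L),                       # transcription: x+1
    list(species = c(g, G + g), delta = c(-1L, 1L)),     # splicing: x-1, y+1
    list(species = 2L * G + g, delta = 1L),              # translation: z+1
    list(species = g, delta = -1L),                      # degrade pre-mRNA
    list(species = G + g, delta = -1L),                  # degrade mRNA
    list(species = 2L * G + g, delta = -1L)              # degrade protein
  )
}
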