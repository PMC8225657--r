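#' Construct a backbone
#'
#' A backbone is the coarse description of the dynamic process to be
#' simulated. It consists of a *module network* — modules of co-regulated
#' genes connected by signed regulatory interactions — and a *state
#' network* describing which modules switch on or off along each
#' transition of the process. The module network determines the dynamics a
#' simulation can exhibit (chains give linear progressions, mutual
#' antagonism gives bifurcations, a repressive feedback loop gives
#' cycles); the state network is the scaffold on which the noise-free
#' reference trajectory is constructed.
#'
#' @param modules A data frame with columns `module` (unique identifier),
#'   `basal` (basal expression strength in `[0, 1]`: how strongly genes of
#'   the module are transcribed with no transcription factor bound) and
#'   `burn` (logical: is the module allowed to generate expression during
#'   the warm-up phase?).
#' @param module_interactions A data frame with columns `from`, `to`,
#'   `effect` (`+1` upregulating, `-1` downregulating) and `strength`
#'   (positive integer; larger values make the target respond at lower
#'   regulator abundance).
#' @param state_network A data frame with columns `from`, `to`, `on` and
#'   `off` (list-columns of module names switched on/off along the
#'   transition) and `length` (positive relative duration of the
#'   transition, used for pseudotime geodesics and cell allocation).
#' @param start_state Identifier of the state the process starts from
#'   (the state reached at the end of the warm-up phase).
#'
#' @return An object of class `backbone`.
#' @seealso [predefined_backbone()], [validate_backbone()],
#'   [read_backbone()], [write_backbone()]
#' @export
#' @examples
#' bb <- predefined_backbone("linear")
#' bb
#' validate_backbone(bb)
backbone <- function(modules, module_interactions, state_network, start_state) {
  modules <- tibble::as_tibble(modules)
  module_interactions <- tibble::as_tibble(module_interactions)
  state_network <- tibble::as_tibble(state_network)
  if (!is.list(state_network$on)) state_network$on <- strsplit(as.character(state_network$on), ",", fixed = TRUE)
  if (!is.list(state_network$off)) state_network$off <- strsplit(as.character(state_network$off), ",", fixed = TRUE)
  state_network$on <- lapply(state_network$on, function(x) setdiff(trimws(x), ""))
  state_network$off <- lapply(state_network$off, function(x) setdiff(trimws(x), ""))
  structure(
    list(
      modules = modules,
      module_interactions = module_interactions,
      state_network = state_network,
      start_state = as.character(start_state)
    ),
    class = "backbone"
  )
}

#' @export
print.backbone <- function(x, ...) {
  cat(
    "<backbone> ", nrow(x$modules), " modules, ",
    nrow(x$module_interactions), " module interactions, ",
    nrow(x$state_network), " state transitions (start: ", x$start_state, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Validate a backbone
#'
#' Checks every structural invariant of a backbone and returns the
#' violations found instead of raising an error, so that partially built
#' backbones can be inspected.
#'
#' @param b A [backbone()].
#' @return A character vector of violations; empty if the backbone is
#'   valid.
#' @export
validate_backbone <- function(b) {
  v <- character()
  viol <- function(msg) v <<- c(v, msg)

  m <- b$modules
  if (anyDuplicated(m$module)) viol("module names are not unique")
  if (any(m$basal < 0 | m$basal > 1)) viol("module basal expression outside [0, 1]")
  if (!is.logical(m$burn)) viol("module 'burn' flag is not logical")

  mi <- b$module_interactions
  if (nrow(mi) > 0) {
    if (!all(mi$effect %in% c(-1, 1))) viol("module interaction effect not in {-1, +1}")
    if (any(mi$strength < 1)) viol("module interaction strength < 1 (must be a positive integer)")
    if (any(mi$strength != round(mi$strength))) viol("module interaction strength is not an integer")
    bad <- setdiff(c(mi$from, mi$to), m$module)
    if (length(bad) > 0) viol(paste0("module interaction references unknown module(s): ", paste(bad, collapse = ", ")))
  }

  sn <- b$state_network
  states <- unique(c(sn$from, sn$to, b$start_state))
  if (!b$start_state %in% c(sn$from, sn$to)) viol("start_state does not appear in the state network")
  if (any(sn$length <= 0)) viol("state transition length must be > 0")
  for (i in seq_len(nrow(sn))) {
    if (length(intersect(sn$on[[i]], sn$off[[i]])) > 0) {
      viol(sprintf("state edge %s->%s switches a module both on and off", sn$from[i], sn$to[i]))
    }
    bad <- setdiff(c(sn$on[[i]], sn$off[[i]]), m$module)
    if (length(bad) > 0) {
      viol(sprintf("state edge %s->%s references unknown module(s): %s", sn$from[i], sn$to[i], paste(bad, collapse = ", ")))
    }
  }
  # reachability of every state from start_state (directed)
  if (nrow(sn) > 0 && b$start_state %in% c(sn$from, sn$to)) {
    reach <- b$start_state
    repeat {
      nxt <- unique(c(reach, sn$to[sn$from %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    unreach <- setdiff(states, reach)
    if (length(unreach) > 0) {
      viol(paste0("state(s) not reachable from start_state: ", paste(unreach, collapse = ", ")))
    }
  }
  v
}

# ---- catalogue ---------------------------------------------------------

bb_modules <- function(names, basal = 0, burn = FALSE) {
  tibble::tibble(module = names, basal = rep_len(basal, length(names)), burn = rep_len(burn, length(names)))
}

bb_edges <- function(...) {
  rows <- list(...)
  tibble::tibble(
    from = vapply(rows, `[[`, "", 1),
    to = vapply(rows, `[[`, "", 2),
    effect = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    strength = vapply(rows, function(r) as.numeric(r[[4]]), 0)
  )
}

bb_states <- function(...) {
  rows <- list(...)
  tibble::tibble(
    from = vapply(rows, `[[`, "", 1),
    to = vapply(rows, `[[`, "", 2),
    on = lapply(rows, function(r) as.character(r[[3]])),
    off = lapply(rows, function(r) as.character(r[[4]])),
    length = vapply(rows, function(r) as.numeric(r[[5]]), 0)
  )
}

# default interaction strengths: chain activations switch the next module
# on once the regulator reaches ~1/4 of its plateau; antagonistic and
# feedback repressions are much stronger so decisions latch.
STR_CHAIN <- 4
STR_REPRESS <- 20

bb_chain <- function(n, prefix = "M") {
  mods <- paste0(prefix, seq_len(n))
  modules <- bb_modules(mods)
  modules$basal[1] <- 1
  modules$burn[1] <- TRUE
  ints <- if (n > 1) {
    tibble::tibble(
      from = mods[-n], to = mods[-1],
      effect = 1, strength = STR_CHAIN
    )
  } else {
    bb_edges()[0, ]
  }
  list(modules = modules, interactions = ints, mods = mods)
}

bb_linear <- function(num_modules = 5) {
  ch <- bb_chain(num_modules)
  states <- paste0("S", seq_len(num_modules) - 1)
  sn <- tibble::tibble(
    from = states[-num_modules], to = states[-1],
    on = lapply(ch$mods[-1], identity), off = rep(list(character()), num_modules - 1),
    length = 1
  )
  backbone(ch$modules, ch$interactions, sn, "S0")
}

bb_cyclic <- function(num_modules = 5) {
  ch <- bb_chain(num_modules)
  mods <- ch$mods
  ints <- rbind(ch$interactions, tibble::tibble(from = mods[num_modules], to = mods[1], effect = -1, strength = STR_REPRESS))
  states <- paste0("S", seq_len(num_modules) - 1)
  sn <- tibble::tibble(
    from = states[-num_modules], to = states[-1],
    on = lapply(mods[-1], identity), off = rep(list(character()), num_modules - 1),
    length = 1
  )
  sn <- rbind(sn, tibble::tibble(
    from = states[num_modules], to = "S0",
    on = list(mods[1]), off = list(mods[-1]), length = 2
  ))
  backbone(ch$modules, ints, sn, "S0")
}

bb_bifurcating <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B", "C1", "C2", "D1", "D2"))
  )
  ints <- bb_edges(
    list("A", "B", 1, STR_CHAIN),
    list("B", "C1", 1, STR_CHAIN), list("B", "C2", 1, STR_CHAIN),
    list("C1", "C2", -1, STR_REPRESS), list("C2", "C1", -1, STR_REPRESS),
    list("C1", "D1", 1, STR_CHAIN), list("C2", "D2", 1, STR_CHAIN)
  )
  sn <- bb_states(
    list("S0", "S1", "B", character(), 1),
    list("S1", "S2", "C1", "C2", 1),
    list("S1", "S3", "C2", "C1", 1),
    list("S2", "S4", "D1", character(), 1),
    list("S3", "S5", "D2", character(), 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_converging <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B1", "B2"), basal = 0.5, burn = TRUE),
    bb_modules(c("C", "D"))
  )
  ints <- bb_edges(
    list("A", "B1", 1, STR_CHAIN), list("A", "B2", 1, STR_CHAIN),
    list("B1", "B2", -1, STR_REPRESS), list("B2", "B1", -1, STR_REPRESS),
    list("B1", "C", 1, STR_CHAIN), list("B2", "C", 1, STR_CHAIN),
    list("C", "D", 1, STR_CHAIN)
  )
  sn <- bb_states(
    list("S0", "S1", "C", c("B1", "B2"), 1),
    list("S1", "S2", "D", character(), 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_disconnected <- function() {
  modules <- rbind(
    bb_modules(c("K1", "K2"), basal = 0.5, burn = TRUE),
    bb_modules(c("A1", "A2", "A3", "B1", "B2", "B3"))
  )
  ints <- bb_edges(
    list("K1", "K2", -1, STR_REPRESS), list("K2", "K1", -1, STR_REPRESS),
    list("K1", "A1", 1, STR_CHAIN), list("A1", "A2", 1, STR_CHAIN), list("A2", "A3", 1, STR_CHAIN),
    list("K2", "B1", 1, STR_CHAIN), list("B1", "B2", 1, STR_CHAIN), list("B2", "B3", 1, STR_CHAIN)
  )
  sn <- bb_states(
    list("S0", "SA1", "A1", "K2", 1),
    list("SA1", "SA2", "A2", character(), 1),
    list("SA2", "SA3", "A3", character(), 1),
    list("S0", "SB1", "B1", "K1", 1),
    list("SB1", "SB2", "B2", character(), 1),
    list("SB2", "SB3", "B3", character(), 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_trifurcating <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B", "C1", "C2", "C3", "D1", "D2", "D3"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B", 1, STR_CHAIN),
      list("B", "C1", 1, STR_CHAIN), list("B", "C2", 1, STR_CHAIN), list("B", "C3", 1, STR_CHAIN),
      list("C1", "D1", 1, STR_CHAIN), list("C2", "D2", 1, STR_CHAIN), list("C3", "D3", 1, STR_CHAIN)
    ),
    mutual("C1", "C2"), mutual("C2", "C3"), mutual("C1", "C3")
  )
  sn <- bb_states(
    list("S0", "S1", "B", character(), 1),
    list("S1", "S2", "C1", c("C2", "C3"), 1),
    list("S1", "S3", "C2", c("C1", "C3"), 1),
    list("S1", "S4", "C3", c("C1", "C2"), 1),
    list("S2", "S5", "D1", character(), 1),
    list("S3", "S6", "D2", character(), 1),
    list("S4", "S7", "D3", character(), 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_binary_tree <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B1", "B2", "C1", "C2", "C3", "C4"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B1", 1, STR_CHAIN), list("A", "B2", 1, STR_CHAIN),
      list("B1", "C1", 1, STR_CHAIN), list("B1", "C2", 1, STR_CHAIN),
      list("B2", "C3", 1, STR_CHAIN), list("B2", "C4", 1, STR_CHAIN)
    ),
    mutual("B1", "B2"), mutual("C1", "C2"), mutual("C3", "C4")
  )
  sn <- bb_states(
    list("S0", "S1", "B1", "B2", 1),
    list("S0", "S2", "B2", "B1", 1),
    list("S1", "S3", "C1", "C2", 1),
    list("S1", "S4", "C2", "C1", 1),
    list("S2", "S5", "C3", "C4", 1),
    list("S2", "S6", "C4", "C3", 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_branching <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B1", "B2", "D1", "C1", "C2"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B1", 1, STR_CHAIN), list("A", "B2", 1, STR_CHAIN),
      list("B1", "D1", 1, STR_CHAIN),
      list("B2", "C1", 1, STR_CHAIN), list("B2", "C2", 1, STR_CHAIN)
    ),
    mutual("B1", "B2"), mutual("C1", "C2")
  )
  sn <- bb_states(
    list("S0", "S1", "B1", "B2", 1),
    list("S0", "S2", "B2", "B1", 1),
    list("S1", "S3", "D1", character(), 1),
    list("S2", "S4", "C1", "C2", 1),
    list("S2", "S5", "C2", "C1", 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_consecutive_bifurcating <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B", "B1", "B2", "E", "C1", "C2", "D1"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B", 1, STR_CHAIN),
      list("B", "B1", 1, STR_CHAIN), list("B", "B2", 1, STR_CHAIN),
      list("B1", "D1", 1, STR_CHAIN),
      list("B2", "E", 1, STR_CHAIN),
      list("E", "C1", 1, STR_CHAIN), list("E", "C2", 1, STR_CHAIN)
    ),
    mutual("B1", "B2"), mutual("C1", "C2")
  )
  sn <- bb_states(
    list("S0", "S1", "B", character(), 1),
    list("S1", "S2", "B1", "B2", 1),
    list("S1", "S3", "B2", "B1", 1),
    list("S2", "S4", "D1", character(), 1),
    list("S3", "S5", "E", character(), 1),
    list("S5", "S6", "C1", "C2", 1),
    list("S5", "S7", "C2", "C1", 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_bifurcating_converging <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B", "C1", "C2", "D", "E"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B", 1, STR_CHAIN),
      list("B", "C1", 1, STR_CHAIN), list("B", "C2", 1, STR_CHAIN),
      list("C1", "D", 1, STR_CHAIN), list("C2", "D", 1, STR_CHAIN),
      list("D", "E", 1, STR_CHAIN)
    ),
    mutual("C1", "C2")
  )
  sn <- bb_states(
    list("S0", "S1", "B", character(), 1),
    list("S1", "S2", "C1", "C2", 1),
    list("S1", "S3", "C2", "C1", 1),
    list("S2", "S4", "D", "C1", 1),
    list("S3", "S4", "D", "C2", 1),
    list("S4", "S5", "E", character(), 1)
  )
  backbone(modules, ints, sn, "S0")
}

bb_bifurcating_cycle <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B1", "B2", "C"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B1", 1, STR_CHAIN), list("A", "B2", 1, STR_CHAIN),
      list("B1", "C", 1, STR_CHAIN), list("B2", "C", 1, STR_CHAIN),
      list("C", "A", -1, STR_REPRESS),
      list("C", "B1", -1, STR_REPRESS), list("C", "B2", -1, STR_REPRESS)
    ),
    mutual("B1", "B2")
  )
  sn <- bb_states(
    list("S0", "S1", "B1", "B2", 1),
    list("S0", "S2", "B2", "B1", 1),
    list("S1", "S3", "C", character(), 1),
    list("S2", "S3", "C", character(), 1),
    list("S3", "S0", "A", c("B1", "B2", "C"), 2)
  )
  backbone(modules, ints, sn, "S0")
}

bb_bifurcating_loop <- function() {
  modules <- rbind(
    bb_modules("A", basal = 1, burn = TRUE),
    bb_modules(c("B1", "B2", "C", "D"))
  )
  mutual <- function(a, b) bb_edges(list(a, b, -1, STR_REPRESS), list(b, a, -1, STR_REPRESS))
  ints <- rbind(
    bb_edges(
      list("A", "B1", 1, STR_CHAIN), list("A", "B2", 1, STR_CHAIN),
      list("B1", "C", 1, STR_CHAIN),
      list("C", "A", -1, STR_REPRESS), list("C", "B1", -1, STR_REPRESS),
      list("B2", "D", 1, STR_CHAIN)
    ),
    mutual("B1", "B2")
  )
  sn <- bb_states(
    list("S0", "S1", "B1", "B2", 1),
    list("S0", "S2", "B2", "B1", 1),
    list("S1", "S3", "C", character(), 1),
    list("S3", "S0", "A", c("B1", "C"), 2),
    list("S2", "S4", "D", character(), 1)
  )
  backbone(modules, ints, sn, "S0")
}

BACKBONE_CATALOGUE <- list(
  linear = function(params) bb_linear(params$num_modules %||% 5),
  linear_simple = function(params) bb_linear(params$num_modules %||% 2),
  cyclic = function(params) bb_cyclic(params$num_modules %||% 5),
  cycle_simple = function(params) bb_cyclic(params$num_modules %||% 3),
  bifurcating = function(params) bb_bifurcating(),
  bifurcating_converging = function(params) bb_bifurcating_converging(),
  bifurcating_cycle = function(params) bb_bifurcating_cycle(),
  bifurcating_loop = function(params) bb_bifurcating_loop(),
  binary_tree = function(params) bb_binary_tree(),
  branching = function(params) bb_branching(),
  consecutive_bifurcating = function(params) bb_consecutive_bifurcating(),
  converging = function(params) bb_converging(),
  disconnected = function(params) bb_disconnected(),
  trifurcating = function(params) bb_trifurcating()
)

#' List the predefined backbones
#'
#' @return Character vector with the names of the 14 predefined backbones.
#' @export
list_backbones <- function() names(BACKBONE_CATALOGUE)

#' Retrieve a predefined backbone
#'
#' The catalogue covers the canonical trajectory topologies: linear
#' chains, cycles (a chain whose last module represses the first),
#' bifurcations (built on two mutually repressing modules), convergence
#' (a bifurcation resolved during the warm-up phase), disconnected
#' lineages, trees, and loops. The same name with the same parameters
#' always returns the same backbone.
#'
#' @param name One of [list_backbones()].
#' @param params Optional named list of size parameters (e.g.
#'   `num_modules` for `"linear"` and `"cyclic"`).
#' @return A [backbone()].
#' @export
predefined_backbone <- function(name, params = list()) {
  if (!name %in% names(BACKBONE_CATALOGUE)) {
    stop("unknown backbone '", name, "'; see list_backbones()", call. = FALSE)
  }
  BACKBONE_CATALOGUE[[name]](params)
}

# ---- serialization -----------------------------------------------------

#' Read and write backbones
#'
#' Backbones are stored as a single JSON file with `modules`,
#' `module_interactions`, `state_network` arrays and a `start_state`
#' string, so custom backbones can be defined outside R. In the
#' `state_network` array the `on` and `off` fields are arrays of module
#' names.
#'
#' @param b A [backbone()].
#' @param path File path.
#' @return `read_backbone` returns a [backbone()]; `write_backbone`
#'   returns `path` invisibly.
#' @export
write_backbone <- function(b, path) {
  sn <- b$state_network
  obj <- list(
    modules = b$modules,
    module_interactions = b$module_interactions,
    state_network = data.frame(
      from = sn$from, to = sn$to,
      on = I(sn$on), off = I(sn$off),
      length = sn$length
    ),
    start_state = b$start_state
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_backbone
#' @export
read_backbone <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  sn <- obj$state_network
  on <- sn$on
  off <- sn$off
  if (!is.list(on)) on <- as.list(on)
  if (!is.list(off)) off <- as.list(off)
  backbone(
    modules = obj$modules,
    module_interactions = obj$module_interactions,
    state_network = tibble::tibble(
      from = sn$from, to = sn$to,
      on = lapply(on, as.character), off = lapply(off, as.character),
      length = sn$length
    ),
    start_state = obj$start_state
  )
}
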