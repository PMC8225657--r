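# run `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

new_grn <- function(genes, interactions, backbone) {
  structure(
    list(genes = genes, interactions = interactions, backbone = backbone),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  k <- table(factor(x$genes$kind, levels = c("tf", "target", "housekeeping")))
  cat(
    "<grn> ", nrow(x$genes), " genes (", k[["tf"]], " TFs, ", k[["target"]],
    " targets, ", k[["housekeeping"]], " housekeeping), ",
    nrow(x$interactions), " interactions\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a synthetic reference regulatory network
#'
#' Stands in for a large experimentally derived regulatory network from
#' which target and housekeeping subnetworks are sampled. Nodes are added
#' one at a time and wired to existing nodes chosen preferentially by
#' their current out-degree, which produces the hub-dominated
#' (heavy-tailed out-degree) structure typical of real transcription
#' factor networks while keeping every in-degree bounded.
#'
#' @param num_nodes Number of nodes (>= 2).
#' @param max_in_degree Maximum in-degree of any node.
#' @param seed Optional seed for reproducibility.
#' @return A `reference_network`: a tibble with columns `regulator` and
#'   `target` (class attribute added), no self-loops.
#' @export
generate_reference_network <- function(num_nodes, max_in_degree = 5, seed = NULL) {
  stopifnot(num_nodes >= 2, max_in_degree >= 1)
  with_seed(seed, {
    nodes <- sprintf("N%d", seq_len(num_nodes))
    outdeg <- rep(0, num_nodes)
    regs <- integer()
    tgts <- integer()
    for (i in 2:num_nodes) {
      d <- min(i - 1L, sample.int(max_in_degree, 1))
      parents <- sample.int(i - 1L, d, prob = outdeg[seq_len(i - 1L)] + 1)
      regs <- c(regs, parents)
      tgts <- c(tgts, rep(i, d))
      outdeg[parents] <- outdeg[parents] + 1
    }
    structure(
      tibble::tibble(regulator = nodes[regs], target = nodes[tgts]),
      class = c("reference_network", class(tibble::tibble()))
    )
  })
}

#' Read/write a reference network as a two-column edge list
#'
#' @param path TSV file with columns `regulator` and `target`.
#' @param ref A reference network.
#' @export
read_reference_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target") %in% names(df)))
  df <- df[df$regulator != df$target, c("regulator", "target")]
  df <- df[!duplicated(df), ]
  structure(tibble::as_tibble(df), class = c("reference_network", class(tibble::tibble())))
}

#' @rdname read_reference_network
#' @export
write_reference_network <- function(ref, path) {
  utils::write.table(as.data.frame(ref), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ref_nodes <- function(ref) unique(c(ref$regulator, ref$target))

ref_igraph <- function(ref) {
  igraph::graph_from_data_frame(as.data.frame(ref), directed = TRUE)
}

#' Sample transcription factors for a backbone
#'
#' Each module receives at least `min_per_module` TFs and the remainder is
#' assigned to modules uniformly at random. A TF inherits the warm-up
#' (`burn`) flag and basal expression from its module.
#'
#' @param b A [backbone()].
#' @param num_tfs Total number of TFs; must be at least
#'   `min_per_module * nrow(b$modules)`.
#' @param min_per_module Minimum number of TFs per module.
#' @param seed Optional seed.
#' @return A gene tibble (columns `gene`, `kind`, `module`, `burn`,
#'   `basal`).
#' @export
sample_tfs <- function(b, num_tfs, min_per_module = 1, seed = NULL) {
  mods <- b$modules
  n_mod <- nrow(mods)
  if (num_tfs < min_per_module * n_mod) {
    stop("num_tfs (", num_tfs, ") is too small: need at least ",
         min_per_module, " TF(s) for each of the ", n_mod, " modules",
         call. = FALSE)
  }
  with_seed(seed, {
    counts <- rep(min_per_module, n_mod)
    extra <- num_tfs - sum(counts)
    if (extra > 0) {
      add <- table(factor(sample.int(n_mod, extra, replace = TRUE), levels = seq_len(n_mod)))
      counts <- counts + as.integer(add)
    }
    tibble::tibble(
      gene = unlist(lapply(seq_len(n_mod), function(i) {
        sprintf("%s_TF%d", mods$module[i], seq_len(counts[i]))
      })),
      kind = "tf",
      module = rep(mods$module, counts),
      burn = rep(mods$burn, counts),
      basal = rep(mods$basal, counts)
    )
  })
}

#' Generate the TF-level interactions from the module network
#'
#' Every module-level interaction A -> B is expanded deterministically to
#' the full bipartite set of TF-level edges: each TF of B is regulated by
#' every TF of A, inheriting the module interaction's effect and
#' strength. This guarantees each TF of a regulated module has at least
#' one regulator from the upstream module. Module self-loops expand to
#' all ordered pairs (including self-edges) within the module's TFs.
#'
#' @param b A [backbone()].
#' @param tfs Gene tibble from [sample_tfs()].
#' @return An interaction tibble (`regulator`, `target`, `effect`,
#'   `strength`).
#' @export
generate_tf_interactions <- function(b, tfs) {
  mi <- b$module_interactions
  out <- vector("list", nrow(mi))
  for (i in seq_len(nrow(mi))) {
    from_tfs <- tfs$gene[tfs$module == mi$from[i]]
    to_tfs <- tfs$gene[tfs$module == mi$to[i]]
    if (length(from_tfs) == 0 || length(to_tfs) == 0) {
      stop("module '", mi$from[i], "' or '", mi$to[i], "' has no TFs", call. = FALSE)
    }
    grid <- expand.grid(regulator = from_tfs, target = to_tfs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$effect <- mi$effect[i]
    grid$strength <- mi$strength[i]
    out[[i]] <- grid
  }
  res <- if (length(out) > 0) do.call(rbind, out) else {
    data.frame(regulator = character(), target = character(), effect = numeric(), strength = numeric())
  }
  tibble::as_tibble(res)
}

# effect/strength policy for interactions induced from the reference
# network: activating with probability 0.75, strength log-uniform on
# [1, 10] rounded up to an integer
sample_induced_params <- function(n) {
  tibble::tibble(
    effect = ifelse(stats::runif(n) < 0.75, 1, -1),
    strength = ceiling(exp(stats::runif(n, 0, log(10))))
  )
}

#' Sample the target subnetwork from a reference network
#'
#' The existing TFs are mapped onto high-out-degree regulators of the
#' reference network, target genes are then drawn weighted by their
#' PageRank value (damping 0.85), and the subgraph induced by the mapped
#' TFs and the drawn targets supplies the regulatory edges. Each target
#' keeps at most `max_regs_per_target` regulators and is guaranteed to be
#' downstream of at least one TF (targets left unreachable are attached
#' to a random TF or reachable target).
#'
#' @param grn A `grn` object holding TFs (and their interactions).
#' @param ref A reference network.
#' @param num_targets Number of target genes to add.
#' @param max_regs_per_target Maximum regulators per target.
#' @param seed Optional seed.
#' @return The updated `grn`.
#' @export
sample_target_subnetwork <- function(grn, ref, num_targets, max_regs_per_target = 5, seed = NULL) {
  if (num_targets == 0) return(grn)
  nodes <- ref_nodes(ref)
  tf_names <- grn$genes$gene[grn$genes$kind == "tf"]
  if (length(nodes) < length(tf_names) + num_targets) {
    stop("reference network exhausted: ", length(nodes), " nodes cannot supply ",
         length(tf_names), " TFs + ", num_targets, " targets", call. = FALSE)
  }
  with_seed(seed, {
    g <- ref_igraph(ref)
    outdeg <- igraph::degree(g, mode = "out")[nodes]
    pr <- igraph::page_rank(g, damping = 0.85)$vector[nodes]

    # map TFs onto reference regulators, preferring hubs
    tf_map_nodes <- sample(nodes, length(tf_names), prob = outdeg + 1)
    names(tf_map_nodes) <- tf_names
    remaining <- setdiff(nodes, tf_map_nodes)

    target_nodes <- sample(remaining, num_targets, prob = pr[remaining])
    target_names <- sprintf("T%d", seq_len(num_targets))
    node2gene <- c(stats::setNames(tf_names, tf_map_nodes),
                   stats::setNames(target_names, target_nodes))

    # induced edges whose target is one of the drawn target nodes
    sel <- ref$target %in% target_nodes & ref$regulator %in% names(node2gene)
    ind <- ref[sel, ]
    edges <- data.frame(
      regulator = unname(node2gene[ind$regulator]),
      target = unname(node2gene[ind$target]),
      stringsAsFactors = FALSE
    )
    # cap the number of regulators per target
    if (nrow(edges) > 0) {
      keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$target), function(idx) {
        if (length(idx) > max_regs_per_target) sample(idx, max_regs_per_target) else idx
      }))
      edges <- edges[sort(keep), , drop = FALSE]
    }

    # every target must be downstream of at least one TF
    repeat {
      reachable <- unique(c(tf_names, edges$target[edges$regulator %in% tf_names]))
      repeat {
        nxt <- unique(c(reachable, edges$target[edges$regulator %in% reachable]))
        if (length(nxt) == length(reachable)) break
        reachable <- nxt
      }
      orphans <- setdiff(target_names, reachable)
      # also drop regulators that are themselves orphaned targets
      if (length(orphans) == 0) break
      anchors <- c(tf_names, setdiff(intersect(target_names, reachable), orphans))
      fix <- orphans[1]
      edges <- rbind(edges, data.frame(regulator = sample(anchors, 1), target = fix))
    }
    # re-cap after fixes
    keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$target), function(idx) {
      head(idx, max_regs_per_target)
    }))
    edges <- edges[sort(keep), , drop = FALSE]

    params <- sample_induced_params(nrow(edges))
    interactions <- tibble::tibble(
      regulator = edges$regulator, target = edges$target,
      effect = params$effect, strength = params$strength
    )

    # a target without an activating regulator falls back on basal expression
    has_act <- unique(interactions$target[interactions$effect > 0])
    genes <- tibble::tibble(
      gene = target_names, kind = "target", module = NA_character_,
      burn = FALSE, basal = ifelse(target_names %in% has_act, 0, 1)
    )
    new_grn(
      genes = rbind(grn$genes, genes),
      interactions = rbind(grn$interactions, interactions),
      backbone = grn$backbone
    )
  })
}

#' Sample the housekeeping subnetwork from a reference network
#'
#' The reference network is first subsampled so that no gene exceeds the
#' maximum in-degree, then a random root is drawn and a breadth-first
#' search over the underlying undirected graph collects the requested
#' number of housekeeping genes, so the housekeeping subnetwork is weakly
#' connected. Housekeeping genes are completely separate from TFs and
#' targets: no edge crosses the boundary.
#'
#' @param ref A reference network.
#' @param num_hks Number of housekeeping genes.
#' @param max_in_degree Maximum in-degree after subsampling.
#' @param seed Optional seed.
#' @return A list with `genes` and `interactions` tibbles.
#' @export
sample_housekeeping_subnetwork <- function(ref, num_hks, max_in_degree = 5, seed = NULL) {
  empty <- list(
    genes = tibble::tibble(gene = character(), kind = character(), module = character(),
                           burn = logical(), basal = numeric()),
    interactions = tibble::tibble(regulator = character(), target = character(),
                                  effect = numeric(), strength = numeric())
  )
  if (num_hks == 0) return(empty)
  nodes <- ref_nodes(ref)
  if (length(nodes) < num_hks) {
    stop("reference network has only ", length(nodes), " nodes; cannot sample ",
         num_hks, " housekeeping genes", call. = FALSE)
  }
  with_seed(seed, {
    # enforce the in-degree cap by subsampling incoming edges
    keep <- unlist(lapply(split(seq_len(nrow(ref)), ref$target), function(idx) {
      if (length(idx) > max_in_degree) sample(idx, max_in_degree) else idx
    }))
    sub <- ref[sort(keep), ]
    g <- igraph::graph_from_data_frame(as.data.frame(sub), directed = TRUE,
                                       vertices = data.frame(name = nodes))
    for (attempt in seq_len(10)) {
      root <- sample(nodes, 1)
      ord <- igraph::bfs(g, root = root, mode = "all", unreachable = FALSE, order = TRUE)$order
      ord <- ord[!is.na(ord)]
      visited <- igraph::V(g)$name[ord]
      if (length(visited) >= num_hks) {
        chosen <- visited[seq_len(num_hks)]
        hk_names <- sprintf("HK%d", seq_len(num_hks))
        node2gene <- stats::setNames(hk_names, chosen)
        sel <- sub$regulator %in% chosen & sub$target %in% chosen
        params <- sample_induced_params(sum(sel))
        interactions <- tibble::tibble(
          regulator = unname(node2gene[sub$regulator[sel]]),
          target = unname(node2gene[sub$target[sel]]),
          effect = params$effect, strength = params$strength
        )
        has_act <- unique(interactions$target[interactions$effect > 0])
        genes <- tibble::tibble(
          gene = hk_names, kind = "housekeeping", module = NA_character_,
          burn = TRUE, basal = ifelse(hk_names %in% has_act, 0, 1)
        )
        return(list(genes = genes, interactions = interactions))
      }
    }
    stop("could not find a weakly connected component with ", num_hks,
         " nodes after 10 attempts", call. = FALSE)
  })
}

#' Expand a backbone into a gene regulatory network
#'
#' Runs the four generation steps: sample TFs per module, expand the
#' module interactions to TF-level interactions, sample the target
#' subnetwork from a reference network weighted by PageRank, and sample a
#' weakly connected housekeeping subnetwork disjoint from everything
#' else.
#'
#' @param b A [backbone()].
#' @param num_tfs,num_targets,num_hks Gene counts per class.
#' @param ref Optional reference network (e.g. from
#'   [read_reference_network()]); a synthetic one is generated when
#'   omitted.
#' @param min_tfs_per_module,max_regs_per_target,max_hk_in_degree
#'   Structural bounds, see the individual sampling functions.
#' @param seed Optional master seed for this stage.
#' @return A `grn` object.
#' @export
generate_grn <- function(b, num_tfs, num_targets, num_hks, ref = NULL,
                         min_tfs_per_module = 1, max_regs_per_target = 5,
                         max_hk_in_degree = 5, seed = NULL) {
  if (is.null(ref)) {
    n_ref <- max(2 * (num_targets + num_hks) + num_tfs, 50)
    ref <- generate_reference_network(n_ref, seed = derive_seed(seed %||% 0, "refnet"))
  }
  tfs <- sample_tfs(b, num_tfs, min_tfs_per_module, seed = derive_seed(seed %||% 0, "tfs"))
  tf_ints <- generate_tf_interactions(b, tfs)
  grn <- new_grn(tfs, tf_ints, b)
  grn <- sample_target_subnetwork(grn, ref, num_targets, max_regs_per_target,
                                  seed = derive_seed(seed %||% 0, "targets"))
  hk <- sample_housekeeping_subnetwork(ref, num_hks, max_hk_in_degree,
                                       seed = derive_seed(seed %||% 0, "hk"))
  new_grn(
    genes = rbind(grn$genes, hk$genes),
    interactions = rbind(grn$interactions, hk$interactions),
    backbone = b
  )
}

#' Export a GRN as TSV tables
#'
#' Writes `<prefix>_genes.tsv` (gene metadata) and
#' `<prefix>_interactions.tsv` (regulator, target, effect, strength).
#'
#' @param grn A `grn`.
#' @param prefix Path prefix.
#' @export
write_grn <- function(grn, prefix) {
  utils::write.table(as.data.frame(grn$genes), paste0(prefix, "_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(grn$interactions), paste0(prefix, "_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
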