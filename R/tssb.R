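## Tree-structured stick-breaking inference ----------------------------------
##
## The prior over clone trees is a tree-structured stick-breaking (TSSB)
## Dirichlet process: every node of an infinitely deep, infinitely wide tree
## receives a prior mass pi built from depth sticks nu ~ Beta(1, alpha *
## lambda^depth) and branch sticks psi ~ Beta(1, gamma).  Each non-baseline
## segment is assigned to a node; a node also carries a subpopulation weight
## (the fraction of cells belonging to exactly that clone), and the
## subclonal frequency phi of a node is its subtree weight sum.  The weights
## over instantiated nodes plus the residual (normal cells and
## uninstantiated clones) lie on the probability simplex with a flat
## Dirichlet prior.
##
## The sampler alternates three kernels per cycle:
##   1. Gibbs reassignment of segments over instantiated nodes plus lazily
##      instantiated fresh candidates that carry the residual stick mass
##      (auxiliary-variable slice scheme on the stick representation);
##   2. Metropolis transfers of subpopulation weight between two slots
##      (nodes or the residual), which change phi only along the affected
##      root paths;
##   3. conjugate Beta resampling of the sticks given assignment counts.

#' MCMC configuration
#'
#' @param burnin cycles discarded (default 50).
#' @param samples cycles recorded after burn-in (default 300).
#' @param alpha depth-stick scaling of the TSSB prior (default 1).
#' @param gamma branch-stick scaling (default 1).
#' @param lambda depth decay of alpha (default 0.5).
#' @param seed integer RNG seed; the chain is deterministic given it.
#' @param mode `"tree"` (TSSB prior) or `"flat"` (uniform tree prior,
#'   independent per-segment grid inference; see [flat_infer()]).
#' @param weight_moves Metropolis weight-transfer proposals per slot per
#'   cycle (default 20).
#' @param aux_candidates fresh-node candidates per assignment draw.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(burnin = 50, samples = 300, alpha = 1.0, gamma = 1.0,
                        lambda = 0.5, seed = 1L, mode = c("tree", "flat"),
                        weight_moves = 20, aux_candidates = 8) {
  mode <- match.arg(mode)
  stopifnot(burnin >= 0, samples >= 1, alpha > 0, gamma > 0,
            lambda > 0, lambda <= 1)
  structure(list(burnin = burnin, samples = samples, alpha = alpha,
                 gamma = gamma, lambda = lambda, seed = as.integer(seed),
                 mode = mode, weight_moves = weight_moves,
                 aux_candidates = as.integer(aux_candidates)),
            class = "mcmc_config")
}

node_depth <- function(id) {
  lengths(regmatches(id, gregexpr(".", id, fixed = TRUE)))
}

new_tssb_state <- function(config, root_weight = 0.5) {
  root <- list(id = "r", parent = NA_character_, children = character(),
               weight = root_weight,
               nu = stats::rbeta(1, 1, max(config$alpha, 1e-12)),
               psi = 1)
  list(nodes = list(r = root), assign = character())
}

#' Node prior masses of the instantiated tree
#'
#' The TSSB prior mass `pi` of every instantiated node, and the residual
#' mass on uninstantiated parts of the tree; masses plus residual sum to 1.
#'
#' @param state internal chain state (see [run_mcmc()]).
#' @return list with `pi` (named numeric) and `resid` (scalar).
#' @keywords internal
tssb_masses <- function(state) {
  nodes <- state$nodes
  env <- new.env()
  env$pi <- stats::setNames(numeric(length(nodes)), names(nodes))
  env$resid <- 0
  recurse <- function(id, mass) {
    nd <- nodes[[id]]
    env$pi[[id]] <- nd$nu * mass
    rest <- (1 - nd$nu) * mass
    for (child in nd$children) {
      share <- rest * nodes[[child]]$psi
      recurse(child, share)
      rest <- rest * (1 - nodes[[child]]$psi)
    }
    env$resid <- env$resid + rest
  }
  recurse("r", 1)
  list(pi = env$pi, resid = env$resid)
}

#' Subclonal frequency of every instantiated node
#'
#' `phi(node) = weight(node) + sum of descendant weights`.
#'
#' @param state internal chain state.
#' @return named numeric vector.
#' @keywords internal
node_phis <- function(state) {
  nodes <- state$nodes
  phi <- stats::setNames(
    vapply(nodes, `[[`, 0, "weight"), names(nodes))
  # accumulate bottom-up: order ids by decreasing depth
  ids <- names(nodes)[order(node_depth(names(nodes)), decreasing = TRUE)]
  for (id in ids) {
    parent <- nodes[[id]]$parent
    if (!is.na(parent)) phi[[parent]] <- phi[[parent]] + phi[[id]]
  }
  phi
}

root_path <- function(state, id) {
  path <- character()
  while (!is.na(id)) {
    path <- c(path, id)
    id <- state$nodes[[id]]$parent
  }
  path
}

seg_ll <- function(cache, phi, ctx) {
  log_sum_exp(segment_ll_terms(cache, phi, ctx))
}

add_child <- function(state, parent, weight, config) {
  k <- length(state$nodes[[parent]]$children) + 1L
  nid <- paste0(parent, ".", k)
  while (!is.null(state$nodes[[nid]])) {
    k <- k + 1L
    nid <- paste0(parent, ".", k)
  }
  d <- node_depth(nid)
  state$nodes[[nid]] <- list(
    id = nid, parent = parent, children = character(), weight = weight,
    nu = stats::rbeta(1, 1, max(config$alpha * config$lambda^d, 1e-12)),
    psi = stats::rbeta(1, 1, config$gamma))
  state$nodes[[parent]]$children <- c(state$nodes[[parent]]$children, nid)
  state$nodes[[parent]]$weight <- state$nodes[[parent]]$weight - weight
  list(state = state, id = nid)
}

prune_empty_leaves <- function(state) {
  repeat {
    occupied <- unique(unname(state$assign))
    removable <- names(state$nodes)[vapply(state$nodes, function(nd) {
      nd$id != "r" && length(nd$children) == 0 && !(nd$id %in% occupied)
    }, TRUE)]
    if (length(removable) == 0) break
    for (nid in removable) {
      parent <- state$nodes[[nid]]$parent
      state$nodes[[parent]]$weight <-
        state$nodes[[parent]]$weight + state$nodes[[nid]]$weight
      state$nodes[[parent]]$children <-
        setdiff(state$nodes[[parent]]$children, nid)
      state$nodes[[nid]] <- NULL
    }
  }
  state
}

#' One Gibbs sweep of segment-to-node assignments
#'
#' Each segment is redrawn over the instantiated nodes (probability
#' proportional to prior mass times its marginal likelihood at the node's
#' phi) plus `aux_candidates` fresh nodes carrying equal shares of the
#' residual stick mass.  A chosen fresh node becomes a child of a randomly
#' selected parent and is funded by a uniform slice of that parent's own
#' subpopulation weight, which leaves every existing node's phi unchanged.
#' Empty leaves are pruned afterwards, returning their weight to their
#' parent.
#'
#' @param state internal chain state.
#' @param caches per-segment likelihood caches.
#' @param ctx a [likelihood_context].
#' @param config an [mcmc_config].
#' @return the updated state.
#' @keywords internal
sample_assignments <- function(state, caches, ctx, config) {
  for (sid in names(caches)) {
    m <- tssb_masses(state)
    phis <- node_phis(state)
    ids <- names(state$nodes)
    logw <- vapply(ids, function(nid) {
      log(max(m$pi[[nid]], 1e-300)) + seg_ll(caches[[sid]], phis[[nid]], ctx)
    }, 0)
    n_aux <- config$aux_candidates
    aux <- vector("list", n_aux)
    logw_aux <- rep(-Inf, n_aux)
    if (m$resid > 1e-12) {
      w_all <- vapply(ids, function(nid) state$nodes[[nid]]$weight, 0)
      for (k in seq_len(n_aux)) {
        if (sum(w_all) <= 1e-9) break
        parent <- ids[sample.int(length(ids), 1, prob = pmax(w_all, 1e-12))]
        w_parent <- state$nodes[[parent]]$weight
        if (w_parent <= 1e-9) next
        w_new <- stats::runif(1, 0, w_parent)
        aux[[k]] <- list(parent = parent, weight = w_new)
        logw_aux[k] <- log(m$resid / n_aux) +
          seg_ll(caches[[sid]], w_new, ctx)
      }
    }
    all_logw <- c(logw, logw_aux)
    pr <- exp(all_logw - max(all_logw))
    pick <- sample.int(length(pr), 1, prob = pr)
    if (pick <= length(ids)) {
      state$assign[[sid]] <- ids[pick]
    } else {
      a <- aux[[pick - length(ids)]]
      res <- add_child(state, a$parent, a$weight, config)
      state <- res$state
      state$assign[[sid]] <- res$id
    }
  }
  prune_empty_leaves(state)
}

#' Metropolis resampling of subpopulation weights
#'
#' Random pairwise transfers of weight between two slots (instantiated
#' nodes or the residual normal-cell mass) under the flat Dirichlet prior,
#' accepted by the likelihood ratio of the segments whose phi changes (those
#' assigned along the two root paths, outside their common prefix).  Step
#' sizes are drawn from a fixed ladder so both fine conditioning and mode
#' jumps are proposed.
#'
#' @inheritParams sample_assignments
#' @return the updated state.
#' @keywords internal
resample_weights <- function(state, caches, ctx, config) {
  slots <- c(names(state$nodes), ".rest")
  n_moves <- config$weight_moves * length(slots)
  steps <- c(0.002, 0.01, 0.05, 0.2)
  # current ll per segment
  phis <- node_phis(state)
  ll <- vapply(names(caches), function(sid) {
    seg_ll(caches[[sid]], phis[[state$assign[[sid]]]], ctx)
  }, 0)
  w_rest <- 1 - sum(vapply(state$nodes, `[[`, 0, "weight"))
  for (mv in seq_len(n_moves)) {
    pair <- sample.int(length(slots), 2)
    from <- slots[pair[1]]; to <- slots[pair[2]]
    delta <- stats::runif(1, 0, steps[sample.int(length(steps), 1)])
    w_from <- if (from == ".rest") w_rest else state$nodes[[from]]$weight
    if (delta > w_from) next
    path_from <- if (from == ".rest") character() else root_path(state, from)
    path_to <- if (to == ".rest") character() else root_path(state, to)
    affected <- c(setdiff(path_from, path_to), setdiff(path_to, path_from))
    seg_affected <- names(state$assign)[state$assign %in% affected]
    phis_new <- phis
    for (nid in setdiff(path_from, path_to)) {
      phis_new[[nid]] <- phis_new[[nid]] - delta
    }
    for (nid in setdiff(path_to, path_from)) {
      phis_new[[nid]] <- phis_new[[nid]] + delta
    }
    if (length(affected) > 0 &&
        any(phis_new[affected] < -1e-12 | phis_new[affected] > 1 + 1e-12)) next
    if (length(seg_affected) == 0) {
      accept <- TRUE  # phi unchanged on every occupied node: free move
      new_ll <- NULL
    } else {
      new_ll <- vapply(seg_affected, function(sid) {
        seg_ll(caches[[sid]], phis_new[[state$assign[[sid]]]], ctx)
      }, 0)
      accept <- log(stats::runif(1)) < sum(new_ll) - sum(ll[seg_affected])
    }
    if (accept) {
      if (from == ".rest") w_rest <- w_rest - delta
      else state$nodes[[from]]$weight <- state$nodes[[from]]$weight - delta
      if (to == ".rest") w_rest <- w_rest + delta
      else state$nodes[[to]]$weight <- state$nodes[[to]]$weight + delta
      phis <- phis_new
      if (!is.null(new_ll)) ll[seg_affected] <- new_ll
    }
  }
  state
}

## conjugate Beta updates of nu and psi given assignment counts
resample_sticks <- function(state, config) {
  counts <- table(factor(unname(state$assign), levels = names(state$nodes)))
  subtree_count <- function(id) {
    total <- counts[[id]]
    for (child in state$nodes[[id]]$children) {
      total <- total + subtree_count(child)
    }
    total
  }
  for (id in names(state$nodes)) {
    nd <- state$nodes[[id]]
    d <- node_depth(id)
    n_here <- counts[[id]]
    n_below <- subtree_count(id) - n_here
    state$nodes[[id]]$nu <- stats::rbeta(
      1, 1 + n_here, max(config$alpha * config$lambda^d, 1e-12) + n_below)
    kids <- nd$children
    if (length(kids) > 0) {
      sub <- vapply(kids, subtree_count, 0)
      later <- rev(cumsum(rev(sub))) - sub
      for (i in seq_along(kids)) {
        state$nodes[[kids[i]]]$psi <- stats::rbeta(
          1, 1 + sub[i], config$gamma + later[i])
      }
    }
  }
  state
}

record_state <- function(state, caches, ctx, iteration) {
  phis <- node_phis(state)
  m <- tssb_masses(state)
  sids <- names(caches)
  rows <- lapply(sids, function(sid) {
    nid <- state$assign[[sid]]
    phi <- phis[[nid]]
    cache <- caches[[sid]]
    terms <- segment_ll_terms(cache, phi, ctx)
    i <- which.max(terms)
    data.frame(id = sid, node = nid, phi = phi,
               C = cache$combos$C[i], n_m = cache$combos$n_m[i],
               loglik = log_sum_exp(terms), stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  lp <- sum(assignments$loglik) +
    sum(log(pmax(m$pi[unname(state$assign[sids])], 1e-300)))
  nodes <- data.frame(
    id = names(state$nodes),
    parent = vapply(state$nodes, function(nd) nd$parent, ""),
    weight = vapply(state$nodes, `[[`, 0, "weight"),
    phi = unname(phis[names(state$nodes)]),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(iteration = iteration, log_posterior = lp,
       assignments = assignments, nodes = nodes)
}

#' Run the MCMC over clone trees, assignments and frequencies
#'
#' Baseline segments are excluded from inference.  Each cycle runs one
#' assignment Gibbs sweep, one block of Metropolis weight transfers and a
#' conjugate stick update; post-burn-in cycles are recorded.  Every recorded
#' state stores, per segment, the assigned node, its phi, and the
#' maximum-likelihood copy number and genotype at that phi.
#'
#' @param segset a [segment_set] with `corrected_ratio`, `baseline_ids` and
#'   `theta` set (see [set_baseline()]).
#' @param ctx a [likelihood_context].
#' @param config an [mcmc_config].
#' @return list of recorded states (class `tssb_chain`); each state has
#'   `iteration`, `log_posterior`, `assignments` (data.frame `id`, `node`,
#'   `phi`, `C`, `n_m`, `loglik`) and `nodes` (data.frame `id`, `parent`,
#'   `weight`, `phi`).
#' @export
run_mcmc <- function(segset, ctx, config = mcmc_config()) {
  set.seed(config$seed)
  seg <- segset$segments
  infer_ids <- setdiff(seg$id, segset$baseline_ids)
  if (length(infer_ids) == 0) stop("no segments left to infer after baseline removal")
  caches <- stats::setNames(lapply(infer_ids, function(id) {
    segment_cache(seg[seg$id == id, ], segset$snps[segset$snps$segment_id == id, ],
                  ctx)
  }), infer_ids)
  state <- new_tssb_state(config, root_weight = 0.5)
  state$assign <- stats::setNames(rep("r", length(infer_ids)), infer_ids)
  chain <- vector("list", config$samples)
  total <- config$burnin + config$samples
  for (it in seq_len(total)) {
    state <- sample_assignments(state, caches, ctx, config)
    state <- resample_weights(state, caches, ctx, config)
    state <- resample_sticks(state, config)
    if (it > config$burnin) {
      chain[[it - config$burnin]] <- record_state(state, caches, ctx, it)
    }
  }
  structure(chain, class = "tssb_chain")
}

#' Maximum a posteriori state of a chain
#'
#' The recorded state with the largest stored log posterior; ties go to the
#' earliest iteration.
#'
#' @param chain a `tssb_chain` from [run_mcmc()].
#' @return one recorded state.
#' @export
map_state <- function(chain) {
  stopifnot(length(chain) > 0)
  lp <- vapply(chain, `[[`, 0, "log_posterior")
  chain[[which.max(lp)]]
}

## nearest occupied ancestor per occupied node in one state
collapsed_edges <- function(st) {
  occ <- unique(st$assignments$node)
  parent_of <- stats::setNames(st$nodes$parent, st$nodes$id)
  edges <- character(0)
  for (nid in occ) {
    p <- parent_of[[nid]]
    while (!is.na(p) && !(p %in% occ)) p <- parent_of[[p]]
    if (!is.na(p)) edges <- c(edges, paste0(p, ">", nid))
  }
  unique(edges)
}

#' Partial-order edge probabilities across the chain
#'
#' Node identity across MCMC states is defined by segment content: nodes of
#' every recorded state are matched to the MAP state's nodes by maximal
#' Jaccard overlap of their assigned segment sets, and the probability of a
#' directed evolutionary relationship `a -> b` is the fraction of recorded
#' trees containing that (ancestor-collapsed) edge under the matching.
#'
#' @param chain a `tssb_chain`.
#' @return data.frame `node_a`, `node_b`, `probability`, sorted by
#'   decreasing probability.  Node labels are those of the MAP state.
#' @export
edge_probabilities <- function(chain) {
  ref <- map_state(chain)
  ref_sets <- split(ref$assignments$id, ref$assignments$node)
  match_nodes <- function(st) {
    sets <- split(st$assignments$id, st$assignments$node)
    vapply(names(sets), function(nid) {
      jac <- vapply(ref_sets, function(rs) {
        length(intersect(sets[[nid]], rs)) / length(union(sets[[nid]], rs))
      }, 0)
      names(ref_sets)[which.max(jac)]
    }, "")
  }
  tallies <- new.env()
  for (st in chain) {
    lab <- match_nodes(st)
    edges <- collapsed_edges(st)
    mapped <- unique(vapply(edges, function(e) {
      ab <- strsplit(e, ">", fixed = TRUE)[[1]]
      paste0(lab[[ab[1]]], ">", lab[[ab[2]]])
    }, ""))
    for (e in mapped) {
      tallies[[e]] <- (if (is.null(tallies[[e]])) 0 else tallies[[e]]) + 1
    }
  }
  keys <- ls(tallies)
  if (length(keys) == 0) {
    return(data.frame(node_a = character(), node_b = character(),
                      probability = numeric()))
  }
  ab <- do.call(rbind, strsplit(keys, ">", fixed = TRUE))
  out <- data.frame(node_a = ab[, 1], node_b = ab[, 2],
                    probability = vapply(keys, function(k) tallies[[k]], 0) /
                      length(chain),
                    stringsAsFactors = FALSE)
  out <- out[out$node_a != out$node_b, , drop = FALSE]
  out[order(-out$probability), ]
}

#' Probability of one directed evolutionary relationship
#'
#' @param chain a `tssb_chain`.
#' @param a,b node labels of the MAP state.
#' @return fraction of recorded trees containing the edge `a -> b`.
#' @export
edge_probability <- function(chain, a, b) {
  ep <- edge_probabilities(chain)
  hit <- ep$node_a == a & ep$node_b == b
  if (any(hit)) ep$probability[hit][1] else 0
}

#' Flat-mode (uniform tree prior) inference
#'
#' For data violating the infinite-sites assumption (each clone carrying
#' many SCNAs), the tree prior is replaced by a uniform prior and each
#' segment's subclonal frequency is inferred independently on a grid:
#' the marginal log likelihood (copy numbers and genotypes summed out) is
#' evaluated at each grid point and the argmax reported, along with the MAP
#' copy number at that frequency.
#'
#' @param segset a [segment_set] with baseline and theta set.
#' @param ctx a [likelihood_context].
#' @param grid_step grid resolution on (0, 1) (default 0.01).
#' @return list with `assignments` (data.frame `id`, `phi_map`, `c_map`,
#'   `n_m`), `posterior` (matrix of log likelihood, segments by grid) and
#'   `grid` (the phi grid).
#' @export
flat_infer <- function(segset, ctx, grid_step = 0.01) {
  stopifnot(grid_step > 0, grid_step < 0.5)
  seg <- segset$segments
  infer_ids <- setdiff(seg$id, segset$baseline_ids)
  if (length(infer_ids) == 0) stop("no segments left to infer after baseline removal")
  grid <- seq(grid_step, 1 - grid_step / 2, by = grid_step)
  post <- matrix(NA_real_, nrow = length(infer_ids), ncol = length(grid),
                 dimnames = list(infer_ids, NULL))
  rows <- lapply(infer_ids, function(id) {
    cache <- segment_cache(seg[seg$id == id, ],
                           segset$snps[segset$snps$segment_id == id, ], ctx)
    ll <- vapply(grid, function(phi) seg_ll(cache, phi, ctx), 0)
    post[id, ] <<- ll
    phi_map <- grid[which.max(ll)]
    mp <- map_copy_number(seg[seg$id == id, ],
                          segset$snps[segset$snps$segment_id == id, ],
                          phi_map, ctx)
    data.frame(id = id, phi_map = phi_map, c_map = mp$C, n_m = mp$n_m,
               stringsAsFactors = FALSE)
  })
  list(assignments = do.call(rbind, rows), posterior = post, grid = grid)
}

#' Nested-list view of a recorded tree
#'
#' Converts one recorded state's node table into a nested mapping (node ->
#' weight, phi, children) suitable for YAML serialization by
#' [write_results()].
#'
#' @param st a recorded state (element of a `tssb_chain`).
#' @return nested list rooted at the state's root node.
#' @export
tree_to_list <- function(st) {
  nodes <- st$nodes
  build <- function(id) {
    kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
    out <- list(node = id,
                weight = nodes$weight[nodes$id == id],
                phi = nodes$phi[nodes$id == id])
    if (length(kids) > 0) out$children <- lapply(kids, build)
    out
  }
  root <- nodes$id[is.na(nodes$parent)]
  build(root[1])
}
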