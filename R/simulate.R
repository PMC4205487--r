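# Generative model of karyotype evolution along a tree: per branch, the
# number of events of each kind is Poisson with mean rate (times branch
# length when lengths are used), events are applied in uniformly shuffled
# order, and an event that is infeasible at its moment is skipped and logged
# as skipped (it does not alter the state). Skipping rather than resampling
# keeps per-branch counts Poisson-interpretable and avoids rejection loops at
# the lattice boundary.

#' Simulation configuration
#'
#' @param root_state [karyotype_state()] at the root; the default is the
#'   2n = 48 karyotype (8 biarmed + 16 uniarmed pairs) with one CMA3 pair,
#'   the ancestral state inferred for the dwarf cichlid clade.
#' @param rates Named non-negative vector of expected event counts, one per
#'   [event_kinds()], per unit branch length (or per branch, see
#'   `per_branch`). Defaults are illustrative: no event rates are estimated
#'   from data anywhere in this package.
#' @param per_branch If `TRUE`, rates are expected events per branch and
#'   branch lengths are ignored. Trees without branch lengths always behave
#'   this way.
#' @param seed Optional integer seed; a fixed seed makes every simulation
#'   output byte-identical.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(root_state = karyotype_state(8, 16, cma3_pairs = 1),
                       rates = c(fusion = 0.1, fission = 0.1,
                                 inv_m_to_a = 0.1, inv_a_to_m = 0.1,
                                 cma3_gain = 0.05, cma3_loss = 0.05),
                       per_branch = FALSE, seed = NULL) {
  stopifnot(inherits(root_state, "karyotype_state"))
  full <- stats::setNames(rep(0, length(event_kinds())), event_kinds())
  if (is.null(names(rates)) || !all(names(rates) %in% event_kinds())) {
    stop(sprintf("rates must be named by event kind (%s)",
                 paste(event_kinds(), collapse = ", ")))
  }
  full[names(rates)] <- rates
  if (any(is.na(full)) || any(full < 0)) stop("rates must be non-negative")
  structure(list(root_state = root_state, rates = full,
                 per_branch = isTRUE(per_branch), seed = seed),
            class = "sim_config")
}

#' Random rooted tree from a pure-birth (Yule) process
#'
#' @param n_leaves Number of leaves (at least 2).
#' @param seed Optional integer seed.
#' @param birth Speciation rate of the Yule process (default 1).
#' @return A rooted binary `phylo` with positive branch lengths and leaf
#'   labels `t1..tn`.
#' @export
generate_random_tree <- function(n_leaves, seed = NULL, birth = 1) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 2L) stop("n_leaves must be at least 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::rphylo(n_leaves, birth = birth, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_leaves))
  tree
}

#' Simulate karyotype evolution along a tree
#'
#' Walks the tree from the root, drawing per-branch event counts from
#' independent Poisson distributions per event kind, shuffling the drawn
#' events uniformly, and applying them in order; infeasible events are
#' skipped and logged. Returns the full ground-truth history.
#'
#' @param tree A rooted `phylo` tree.
#' @param config A [sim_config()].
#' @return An object of class `simulation_result`: list with `tree`,
#'   `node_states` (data frame: node, label, M, A, cma3), `events` (ordered
#'   per-branch log: branch, parent, child, order, kind, applied), and
#'   `tip_table` (a karyotype table accepted by [sankoff_reconstruct()] and
#'   [write_karyotype_table()]), plus the `config` used.
#' @examples
#' tr <- generate_random_tree(5, seed = 1)
#' sim <- simulate_history(tr, sim_config(seed = 1))
#' sim$tip_table
#' @export
simulate_history <- function(tree, config = sim_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
  root <- .tree_root(pre)
  labels <- .node_labels(tree)
  has_c <- !is.na(config$root_state$cma3)
  states <- vector("list", total)
  states[[root]] <- config$root_state
  use_len <- !config$per_branch && !is.null(tree$edge.length)
  lens <- rep(1, nrow(pre))
  if (use_len) {
    len_of <- stats::setNames(tree$edge.length, tree$edge[, 2L])
    lens <- len_of[as.character(pre[, 2L])]
  }
  kinds_used <- if (has_c) event_kinds() else event_kinds()[1:4]
  log_rows <- vector("list", nrow(pre))
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    counts <- stats::rpois(length(kinds_used),
                           config$rates[kinds_used] * lens[k])
    drawn <- rep(kinds_used, counts)
    if (length(drawn) > 1L) drawn <- sample(drawn)
    st <- states[[p]]
    applied <- logical(length(drawn))
    for (j in seq_along(drawn)) {
      if (event_feasible(st, drawn[j])) {
        st <- apply_event(st, drawn[j])
        applied[j] <- TRUE
      }
    }
    states[[ch]] <- st
    if (length(drawn)) {
      log_rows[[k]] <- data.frame(branch = k, parent = labels[p],
                                  child = labels[ch],
                                  order = seq_along(drawn), kind = drawn,
                                  applied = applied,
                                  stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(branch = integer(0), parent = character(0),
                         child = character(0), order = integer(0),
                         kind = character(0), applied = logical(0))
  }
  node_states <- data.frame(
    node = seq_len(total), label = labels,
    M = vapply(states, `[[`, integer(1), "M"),
    A = vapply(states, `[[`, integer(1), "A"),
    cma3 = vapply(states, `[[`, integer(1), "cma3"))
  tips <- seq_len(ntip)
  tip_table <- data.frame(
    species = tree$tip.label,
    `2n` = 2L * (node_states$M[tips] + node_states$A[tips]),
    karyotype = vapply(tips, function(i)
      format_karyotype_formula(states[[i]]), character(1)),
    cma3 = node_states$cma3[tips],
    M = node_states$M[tips], A = node_states$A[tips],
    check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(tree = tree, node_states = node_states, events = events,
                 tip_table = tip_table, config = config, edge = pre,
                 root = root),
            class = "simulation_result")
}

#' Replay the event log of a simulation
#'
#' Re-applies each branch's logged applied events to the parent state and
#' checks that the child state is reproduced exactly, and that each applied
#' event was feasible at its application moment.
#'
#' @param sim A `simulation_result`.
#' @return Logical vector, one entry per branch (`TRUE` = consistent).
#' @export
replay_events <- function(sim) {
  stopifnot(inherits(sim, "simulation_result"))
  ns <- sim$node_states
  out <- logical(nrow(sim$edge))
  for (k in seq_len(nrow(sim$edge))) {
    p <- sim$edge[k, 1L]; ch <- sim$edge[k, 2L]
    st <- karyotype_state(ns$M[p], ns$A[p], cma3_pairs = ns$cma3[p])
    branch_log <- sim$events[sim$events$branch == k, , drop = FALSE]
    ok <- TRUE
    for (j in seq_len(nrow(branch_log))) {
      if (!branch_log$applied[j]) next
      if (!event_feasible(st, branch_log$kind[j])) { ok <- FALSE; break }
      st <- apply_event(st, branch_log$kind[j])
    }
    out[k] <- ok && st$M == ns$M[ch] && st$A == ns$A[ch] &&
      identical(is.na(st$cma3), is.na(ns$cma3[ch])) &&
      (is.na(st$cma3) || st$cma3 == ns$cma3[ch])
  }
  out
}

#' Simulation/reconstruction recovery experiment
#'
#' For each replicate: simulate a history on a fresh Yule topology (rates
#' interpreted per branch), reconstruct by Sankoff parsimony, and record
#' whether the true root state (and its 2n) falls in the root MPR set, the
#' parsimony total cost against the true number of applied events (parsimony
#' is a lower bound), and the fraction of branches whose minimal event
#' multiset matches the events actually applied. The state space is built
#' from the tip states together with the true node states (so that space
#' truncation never masks the parsimony bound), widened by `slack`.
#'
#' @param n_replicates Number of replicates (at least 1).
#' @param config A [sim_config()]; the default matches a low-rate regime of
#'   0.4 expected events per branch.
#' @param n_leaves Leaves per simulated Yule tree (default 20).
#' @param slack State-space widening (default 4).
#' @param seed Optional seed for the whole experiment (single RNG stream).
#' @return List of class `recovery_result` with `replicates` (one row per
#'   replicate: root_state_recovered, root_2n_recovered, total_cost,
#'   true_events_applied, branch_match_fraction) and `summary` (their means).
#' @export
recovery_experiment <- function(n_replicates,
                                config = sim_config(
                                  rates = c(fusion = 0.12, fission = 0.12,
                                            inv_m_to_a = 0.08,
                                            inv_a_to_m = 0.08),
                                  per_branch = TRUE),
                                n_leaves = 20L, slack = 4L, seed = NULL) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop("n_replicates must be at least 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  config$seed <- NULL   # one global stream for the whole experiment
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    tree <- generate_random_tree(n_leaves)
    sim <- simulate_history(tree, config)
    all_states <- lapply(seq_len(nrow(sim$node_states)), function(i)
      karyotype_state(sim$node_states$M[i], sim$node_states$A[i]))
    space <- build_state_space(all_states, slack = slack)
    rec <- sankoff_reconstruct(tree, sim$tip_table, space = space)
    troot <- sim$root
    true_idx <- .space_index(space, sim$node_states$M[troot],
                             sim$node_states$A[troot])
    root_mpr <- rec$mpr[[rec$root]]
    mpr_2n <- 2L * (rec$states$M[root_mpr] + rec$states$A[root_mpr])
    true_2n <- 2L * (sim$node_states$M[troot] + sim$node_states$A[troot])
    karyo_kinds <- event_kinds()[1:4]
    applied <- sim$events[sim$events$applied &
                            sim$events$kind %in% karyo_kinds, , drop = FALSE]
    dec <- decompose_all_branches(rec)
    match_branch <- logical(nrow(rec$edge))
    for (k in seq_len(nrow(rec$edge))) {
      truth <- table(factor(applied$kind[applied$branch == k],
                            levels = karyo_kinds))
      match_branch[k] <- all(unclass(dec[[k]])[karyo_kinds] ==
                               as.integer(truth))
    }
    rows[[r]] <- data.frame(
      replicate = r,
      root_state_recovered = !is.na(true_idx) && true_idx %in% root_mpr,
      root_2n_recovered = true_2n %in% mpr_2n,
      total_cost = as.integer(rec$total_cost),
      true_events_applied = nrow(applied),
      branch_match_fraction = mean(match_branch))
  }
  reps <- do.call(rbind, rows)
  summary <- data.frame(
    root_state_recovery = mean(reps$root_state_recovered),
    root_2n_recovery = mean(reps$root_2n_recovered),
    mean_total_cost = mean(reps$total_cost),
    mean_true_events = mean(reps$true_events_applied),
    mean_branch_match = mean(reps$branch_match_fraction),
    bound_violations = sum(reps$total_cost > reps$true_events_applied))
  structure(list(replicates = reps, summary = summary),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> %d replicates: root state recovery %.2f, root 2n recovery %.2f\n",
    nrow(x$replicates), x$summary$root_state_recovery,
    x$summary$root_2n_recovery))
  invisible(x)
}
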