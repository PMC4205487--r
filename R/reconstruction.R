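# Sankoff (generalized) parsimony over the karyotype lattice and over the
# ordered CMA3 count character. Costs between states are exact minimal-event
# distances, so the parsimony total is the minimum number of rearrangement
# events explaining the tip data on the tree. Branch lengths are ignored:
# the criterion is event-count parsimony, not likelihood.

.row_mins <- function(mat) {
  do.call(pmin, as.data.frame(mat))
}

.tree_root <- function(edge) {
  setdiff(unique(edge[, 1L]), edge[, 2L])
}

.node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- paste0("node", ntip + seq_len(tree$Nnode))
  if (!is.null(tree$node.label)) {
    has <- nzchar(tree$node.label) & !is.na(tree$node.label)
    internal[has] <- tree$node.label[has]
  }
  c(tree$tip.label, internal)
}

# Core dynamic programme shared by the karyotype and count characters.
# tip_idx: state index per tip (1..ntip); cost: S x S matrix.
.sankoff_engine <- function(tree, tip_idx, cost) {
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  S <- nrow(cost)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  root <- .tree_root(post)
  tab <- matrix(0, total, S)
  tab[seq_len(ntip), ] <- Inf
  tab[cbind(seq_len(ntip), tip_idx)] <- 0
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1L]; ch <- post[k, 2L]
    contrib <- .row_mins(cost + matrix(tab[ch, ], S, S, byrow = TRUE))
    tab[p, ] <- tab[p, ] + contrib
  }
  total_cost <- min(tab[root, ])
  if (!is.finite(total_cost)) {
    stop("no finite-cost reconstruction exists over this state space")
  }
  # top-down pass: a state is in a node's MPR set iff it is optimal beneath
  # at least one MPR state of the parent
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  mpr <- vector("list", total)
  mpr[[root]] <- which(tab[root, ] == total_cost)
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    opts <- integer(0)
    for (s in mpr[[p]]) {
      v <- cost[s, ] + tab[ch, ]
      opts <- c(opts, which(v == min(v)))
    }
    mpr[[ch]] <- sort(unique(opts))
  }
  list(cost_table = tab, total_cost = total_cost, mpr = mpr, root = root,
       edge = pre, edge_post = post)
}

# Deterministic single assignment: root ties broken toward `anchor_dist`
# (smaller first), then by lexicographic state order; below the root the
# lexicographically smallest optimal child state is taken given the parent.
.select_assignment <- function(eng, cost, anchor_dist = NULL) {
  total <- nrow(eng$cost_table)
  sel <- rep(NA_integer_, total)
  cand <- sort(eng$mpr[[eng$root]])
  if (!is.null(anchor_dist) && length(cand) > 1L) {
    cand <- cand[order(anchor_dist[cand], cand)]
  }
  sel[eng$root] <- cand[1L]
  for (k in seq_len(nrow(eng$edge))) {
    p <- eng$edge[k, 1L]; ch <- eng$edge[k, 2L]
    v <- cost[sel[p], ] + eng$cost_table[ch, ]
    sel[ch] <- min(which(v == min(v)))
  }
  sel
}

#' Ancestral karyotype reconstruction by event-count parsimony
#'
#' Runs the Sankoff dynamic programme on a rooted tree with pairwise costs
#' equal to the minimal-event distance ([event_distance()]) between karyotype
#' states of a bounded lattice. Each leaf is fixed to its observed state
#' (cost 0 there, infinite elsewhere); a pre-order backtracking pass marks
#' every state attaining the minimum at each internal node (the MPR set,
#' reported in lexicographic `(M, A)` order).
#'
#' Most-parsimonious root states need not be unique. When `anchor` is given
#' (for the shipped cichlid workflow: the ancestral cichlid karyotype
#' `"48st-a"`, i.e. 24 uniarmed pairs), ties among root MPR states are broken
#' in favour of the state with the smallest event distance to the anchor;
#' remaining ties, and all non-root choices of the selected scenario, are
#' broken lexicographically. The full MPR sets are always reported unchanged.
#'
#' @param tree A rooted `phylo` tree (branch lengths, if any, are ignored).
#' @param records A karyotype table as returned by [read_karyotype_table()]
#'   (or a simulated tip table): one row per leaf label in `species`.
#' @param space A [build_state_space()] lattice; defaults to the tip states
#'   widened by `slack`.
#' @param slack Widening used when `space` is `NULL` (default 4).
#' @param anchor Optional [karyotype_state()] used to break root ties.
#' @return An object of class `karyo_reconstruction`: list with elements
#'   `tree`, `character` (`"karyotype"`), `space`, `states` (lattice as a
#'   data frame), `cost` (pairwise cost matrix), `cost_table` (node-by-state
#'   Sankoff costs), `total_cost`, `mpr` (per-node integer index sets into
#'   `states`), `selected` (the deterministic scenario assignment), `root`,
#'   `edge` (pre-order), `node_labels`, `anchor`.
#' @examples
#' fx <- nic_fixture_files()
#' tr <- read_newick(fx$tree)
#' recs <- read_karyotype_table(fx$karyotypes)
#' rec <- sankoff_reconstruct(tr, recs,
#'                            anchor = parse_karyotype_formula("48st-a"))
#' rec$total_cost
#' @export
sankoff_reconstruct <- function(tree, records, space = NULL, slack = 4L,
                                anchor = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is.data.frame(records) ||
      !all(c("species", "M", "A") %in% names(records))) {
    stop("records must be a karyotype table with species, M and A columns")
  }
  miss <- setdiff(tree$tip.label, records$species)
  if (length(miss)) {
    stop(sprintf("leaf without karyotype record: %s",
                 paste(miss, collapse = ", ")))
  }
  ord <- match(tree$tip.label, records$species)
  tip_states <- lapply(ord, function(i)
    karyotype_state(records$M[i], records$A[i]))
  if (is.null(space)) space <- build_state_space(tip_states, slack = slack)
  stopifnot(inherits(space, "state_space"))
  tip_idx <- .space_index(space, vapply(tip_states, `[[`, integer(1), "M"),
                          vapply(tip_states, `[[`, integer(1), "A"))
  if (anyNA(tip_idx)) {
    stop(sprintf("tip state outside the state space: %s",
                 paste(tree$tip.label[is.na(tip_idx)], collapse = ", ")))
  }
  cost <- .space_cost_matrix(space)
  eng <- .sankoff_engine(tree, tip_idx, cost)
  anchor_dist <- NULL
  if (!is.null(anchor)) {
    stopifnot(inherits(anchor, "karyotype_state"))
    N <- space$states$M + space$states$A
    dN <- (anchor$M + anchor$A) - N
    dM <- anchor$M - space$states$M
    anchor_dist <- abs(dN) + abs(dM + dN)
  }
  sel <- .select_assignment(eng, cost, anchor_dist)
  structure(c(list(tree = tree, character = "karyotype", space = space,
                   states = space$states, cost = cost,
                   node_labels = .node_labels(tree), anchor = anchor),
              eng, list(selected = sel)),
            class = "karyo_reconstruction")
}

#' Ancestral reconstruction of an ordered count character
#'
#' Sankoff parsimony with cost `|dc|` over the integer states
#' `0..max_count`, used for the number of CMA3-signal-bearing chromosome
#' pairs. Same MPR and backtracking contract as [sankoff_reconstruct()].
#'
#' @param tree A rooted `phylo` tree.
#' @param counts Named non-negative integer vector, one entry per leaf label.
#' @param max_count Upper bound of the state space; defaults to the observed
#'   maximum plus 2.
#' @return A `karyo_reconstruction` object with `character = "cma3"` and a
#'   one-column `states` data frame (`c`).
#' @export
reconstruct_count_character <- function(tree, counts, max_count = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  miss <- setdiff(tree$tip.label, names(counts))
  if (length(miss)) {
    stop(sprintf("leaf without count: %s", paste(miss, collapse = ", ")))
  }
  counts <- counts[tree$tip.label]
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (is.null(max_count)) max_count <- max(counts) + 2L
  max_count <- as.integer(max_count)
  if (any(counts > max_count)) stop("counts exceed max_count")
  vals <- 0:max_count
  cost <- abs(outer(vals, vals, "-"))
  eng <- .sankoff_engine(tree, as.integer(counts) + 1L, cost)
  sel <- .select_assignment(eng, cost)
  structure(c(list(tree = tree, character = "cma3", space = NULL,
                   states = data.frame(c = vals), cost = cost,
                   node_labels = .node_labels(tree), anchor = NULL),
              eng, list(selected = sel)),
            class = "karyo_reconstruction")
}

#' @export
print.karyo_reconstruction <- function(x, ...) {
  cat(sprintf("<karyo_reconstruction> %s character, %d leaves, total cost %d\n",
              x$character, length(x$tree$tip.label), as.integer(x$total_cost)))
  rs <- x$selected[x$root]
  if (x$character == "karyotype") {
    st <- karyotype_state(x$states$M[rs], x$states$A[rs])
    cat(sprintf("  root state (selected): %s (2n=%d); root MPR set size %d\n",
                format_karyotype_formula(st), diploid_number(st),
                length(x$mpr[[x$root]])))
  } else {
    cat(sprintf("  root count (selected): %d; root MPR set size %d\n",
                x$states$c[rs], length(x$mpr[[x$root]])))
  }
  invisible(x)
}

# karyotype_state (or count) at a node of an assignment
.assignment_state <- function(result, assignment, node) {
  i <- assignment[node]
  if (result$character == "karyotype") {
    karyotype_state(result$states$M[i], result$states$A[i])
  } else {
    result$states$c[i]
  }
}

#' Minimal event decomposition of every branch under an MPR assignment
#'
#' Maps each branch (in pre-order) to the unique minimal event multiset
#' between the parent and child states of the supplied assignment
#' ([decompose_minimal_events()] for the karyotype character; CMA3 gains and
#' losses for the count character). The per-branch totals sum to
#' `result$total_cost`.
#'
#' @param result A `karyo_reconstruction`.
#' @param assignment Integer vector of state indices, one per node, as found
#'   in `result$selected` or produced by [enumerate_mprs()]; defaults to the
#'   selected scenario. Every state must belong to the node's MPR set.
#' @return Named list of [event_multiset()] objects, one per branch, names
#'   `"parent->child"` using node labels, in pre-order.
#' @export
decompose_all_branches <- function(result, assignment = NULL) {
  stopifnot(inherits(result, "karyo_reconstruction"))
  if (is.null(assignment)) assignment <- result$selected
  for (node in which(!is.na(assignment))) {
    if (!(assignment[node] %in% result$mpr[[node]])) {
      stop(sprintf("assignment state at %s is not in the node's MPR set",
                   result$node_labels[node]))
    }
  }
  out <- vector("list", nrow(result$edge))
  nms <- character(nrow(result$edge))
  for (k in seq_len(nrow(result$edge))) {
    p <- result$edge[k, 1L]; ch <- result$edge[k, 2L]
    if (result$character == "karyotype") {
      out[[k]] <- decompose_minimal_events(
        .assignment_state(result, assignment, p),
        .assignment_state(result, assignment, ch))
    } else {
      dc <- .assignment_state(result, assignment, ch) -
            .assignment_state(result, assignment, p)
      out[[k]] <- event_multiset(cma3_gain = max(0L, dc),
                                 cma3_loss = max(0L, -dc))
    }
    nms[k] <- paste0(result$node_labels[p], "->", result$node_labels[ch])
  }
  names(out) <- nms
  out
}

#' Enumerate all most-parsimonious ancestral state assignments
#'
#' Depth-first enumeration of every full node-state assignment achieving
#' `result$total_cost`, in lexicographic order (pre-order node sequence,
#' states in lexicographic order at each choice point), truncated at `cap`.
#'
#' @param result A `karyo_reconstruction`.
#' @param cap Maximum number of assignments to return (default 1000).
#' @return List with `assignments` (each an integer vector of state indices
#'   per node; `NA`-free) and a logical `truncated` flag.
#' @export
enumerate_mprs <- function(result, cap = 1000L) {
  stopifnot(inherits(result, "karyo_reconstruction"))
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1L) stop("cap must be a positive integer")
  limit <- cap + 1L
  total <- nrow(result$cost_table)
  kids <- split(result$edge[, 2L], factor(result$edge[, 1L], levels = 1:total))
  gen <- function(node, state) {
    base <- rep(NA_integer_, total)
    base[node] <- state
    ch <- kids[[node]]
    if (!length(ch)) return(list(base))
    out <- list(base)
    for (cd in ch) {
      v <- result$cost[state, ] + result$cost_table[cd, ]
      opts <- sort(which(v == min(v)))
      part <- list()
      for (s in opts) {
        part <- c(part, gen(cd, s))
        if (length(part) >= limit) break
      }
      part <- part[seq_len(min(length(part), limit))]
      new <- list()
      for (a in out) {
        for (b in part) {
          m <- a
          m[!is.na(b)] <- b[!is.na(b)]
          new <- c(new, list(m))
          if (length(new) >= limit) break
        }
        if (length(new) >= limit) break
      }
      out <- new
    }
    out
  }
  assignments <- list()
  for (rs in sort(result$mpr[[result$root]])) {
    assignments <- c(assignments, gen(result$root, rs))
    if (length(assignments) >= limit) break
  }
  truncated <- length(assignments) > cap
  assignments <- assignments[seq_len(min(cap, length(assignments)))]
  list(assignments = assignments, truncated = truncated)
}
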