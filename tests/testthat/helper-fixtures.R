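# shared shorthands and independent oracles used across the test files

st <- function(M, A, c3 = NA) karyotype_state(M, A, cma3_pairs = c3)

fixture_tree <- function() read_newick(nic_fixture_files()[["tree"]])
fixture_table <- function() read_karyotype_table(nic_fixture_files()[["karyotypes"]])

# closed-form minimal event distance written independently of the package
oracle_distance <- function(M1, A1, M2, A2) {
  dN <- (M2 + A2) - (M1 + A1)
  abs(dN) + abs((M2 - M1) + dN)
}

# exhaustive parsimony oracle: enumerate every internal-node assignment over
# the given states and return the minimum summed branch distance plus the set
# of root states attaining it
brute_force_parsimony <- function(tree, tip_states, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  S <- nrow(states)
  D <- outer(seq_len(S), seq_len(S), function(i, j)
    oracle_distance(states$M[i], states$A[i], states$M[j], states$A[j]))
  tip_idx <- vapply(tip_states, function(s)
    which(states$M == s$M & states$A == s$A), integer(1))
  edge <- tree$edge
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), nint)))
  assign_of <- function(row) c(tip_idx, row)  # internal ids are ntip+1..
  costs <- apply(combos, 1, function(row) {
    a <- assign_of(row)
    sum(D[cbind(a[edge[, 1]], a[edge[, 2]])])
  })
  best <- min(costs)
  root_states <- sort(unique(combos[costs == best, root - ntip]))
  list(cost = best, root_states = root_states)
}
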