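fixture_reconstruction <- function(...) {
  sankoff_reconstruct(fixture_tree(), fixture_table(),
                      anchor = parse_karyotype_formula("48st-a"), ...)
}

test_that("the state space spans the observed tips widened by the slack", {
  tips <- list(st(7, 18), st(8, 16), st(9, 13), st(9, 13), st(8, 14))
  sp <- build_state_space(tips, slack = 4)
  expect_equal(sp$M_range, c(3L, 13L))
  expect_equal(sp$A_range, c(9L, 22L))
  expect_equal(nrow(sp$states), 11L * 14L)
  sp0 <- build_state_space(list(st(2, 3)), slack = 0)
  expect_equal(nrow(sp0$states), 1L)
  # clipping at zero
  sp2 <- build_state_space(list(st(1, 2)), slack = 4)
  expect_equal(sp2$M_range[1], 0L)
})

test_that("the cichlid fixture reconstructs the 2n=48 ancestor at cost 5", {
  rec <- fixture_reconstruction()
  expect_equal(rec$total_cost, 5)
  root_states <- rec$states[rec$mpr[[rec$root]], ]
  expect_true(any(root_states$M == 8 & root_states$A == 16))
  sel <- rec$selected[rec$root]
  expect_equal(c(rec$states$M[sel], rec$states$A[sel]), c(8L, 16L))
  expect_equal(format_karyotype_formula(st(rec$states$M[sel],
                                           rec$states$A[sel])),
               "16m-sm+32st-a")
})

test_that("root ties are reported honestly and resolved by the anchor", {
  plain <- sankoff_reconstruct(fixture_tree(), fixture_table())
  rooted <- fixture_reconstruction()
  # same MPR sets with and without the anchor; only the selection differs
  expect_identical(plain$mpr, rooted$mpr)
  root_states <- rooted$states[rooted$mpr[[rooted$root]], ]
  expect_equal(nrow(root_states), 2L)  # (7,18) ties with (8,16)
  expect_setequal(2L * (root_states$M + root_states$A), c(48L, 50L))
  # without an anchor the lexicographically smallest tied state is selected
  psel <- plain$selected[plain$root]
  expect_equal(c(plain$states$M[psel], plain$states$A[psel]), c(7L, 18L))
})

test_that("branch decompositions reproduce the published event scenario", {
  rec <- fixture_reconstruction()
  dec <- decompose_all_branches(rec)
  counts <- function(nm) unclass(dec[[grep(nm, names(dec))]])
  mar <- counts("->maronii")
  expect_equal(mar[["fission"]], 1L)
  expect_equal(sum(mar), 1L)
  stem <- counts("node7->node8")  # stem of the three-species 2n=44 clade
  expect_equal(stem[["fusion"]], 2L)
  expect_equal(stem[["inv_m_to_a"]], 1L)
  expect_equal(sum(stem), 3L)
  tae <- counts("->taenia")
  expect_equal(tae[["inv_m_to_a"]], 1L)
  expect_equal(sum(tae), 1L)
  ado <- counts("->adoketa")
  expect_equal(sum(ado), 0L)
  # inversions accumulate to 2 on the root -> taenia path
  path_inv <- stem[["inv_m_to_a"]] + tae[["inv_m_to_a"]]
  expect_equal(path_inv, 2L)
  # branch totals sum to the parsimony optimum
  expect_equal(sum(vapply(dec, multiset_total, integer(1))), 5L)
})

test_that("an inconsistent assignment is rejected", {
  rec <- fixture_reconstruction()
  bad <- rec$selected
  bad[rec$root] <- setdiff(seq_len(nrow(rec$states)),
                           rec$mpr[[rec$root]])[1]
  expect_error(decompose_all_branches(rec, bad), "MPR set")
})

test_that("degenerate trees reconstruct correctly", {
  # single leaf: root equals the leaf state at zero cost
  t1 <- ape::read.tree(text = "(leaf1);")
  recs <- data.frame(species = "leaf1", `2n` = 48L,
                     karyotype = "16m-sm+32st-a", cma3 = 1L,
                     M = 8L, A = 16L, check.names = FALSE)
  r1 <- sankoff_reconstruct(t1, recs, slack = 2)
  expect_equal(r1$total_cost, 0)
  i <- r1$mpr[[r1$root]]
  expect_equal(c(r1$states$M[i], r1$states$A[i]), c(8L, 16L))
  en <- enumerate_mprs(r1)
  expect_length(en$assignments, 1L)

  # two leaves: the optimum equals the pairwise event distance
  set.seed(21)
  t2 <- ape::read.tree(text = "(x,y);")
  for (i in 1:20) {
    s1 <- st(sample(2:10, 1), sample(2:20, 1))
    s2 <- st(sample(2:10, 1), sample(2:20, 1))
    recs2 <- data.frame(
      species = c("x", "y"), `2n` = c(diploid_number(s1), diploid_number(s2)),
      karyotype = c(format_karyotype_formula(s1), format_karyotype_formula(s2)),
      cma3 = c(1L, 1L), M = c(s1$M, s2$M), A = c(s1$A, s2$A),
      check.names = FALSE)
    r2 <- sankoff_reconstruct(t2, recs2)
    expect_equal(r2$total_cost, event_distance(s1, s2))
  }
})

test_that("Sankoff agrees with an exhaustive assignment oracle on 4-leaf trees", {
  set.seed(17)
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  for (rep in 1:5) {
    tip_states <- lapply(1:4, function(i)
      st(sample(4:6, 1), sample(7:10, 1)))
    recs <- data.frame(
      species = c("a", "b", "c", "d"),
      `2n` = vapply(tip_states, diploid_number, integer(1)),
      karyotype = vapply(tip_states, format_karyotype_formula, character(1)),
      cma3 = 1L,
      M = vapply(tip_states, `[[`, integer(1), "M"),
      A = vapply(tip_states, `[[`, integer(1), "A"),
      check.names = FALSE)
    space <- build_state_space(tip_states, slack = 1)
    expect_lte(nrow(space$states), 40L)
    rec <- sankoff_reconstruct(tree, recs, space = space)
    oracle <- brute_force_parsimony(tree, tip_states, space$states)
    expect_equal(rec$total_cost, oracle$cost)
    expect_identical(sort(rec$mpr[[rec$root]]), oracle$root_states)
  }
})

test_that("widening the slack leaves the optimum unchanged once geodesics fit", {
  costs <- vapply(c(0, 2, 4, 6), function(sl) {
    sankoff_reconstruct(fixture_tree(), fixture_table(), slack = sl)$total_cost
  }, numeric(1))
  expect_true(all(costs == 5))
  # at slack 0 the 2n=48 ancestor is still recovered (it lies inside the
  # observed bounds)
  r0 <- sankoff_reconstruct(fixture_tree(), fixture_table(), slack = 0,
                            anchor = parse_karyotype_formula("48st-a"))
  i <- r0$selected[r0$root]
  expect_equal(c(r0$states$M[i], r0$states$A[i]), c(8L, 16L))
})

test_that("re-rooting along a branch leaves the total cost unchanged", {
  recs <- fixture_table()
  base <- sankoff_reconstruct(fixture_tree(), recs)$total_cost
  for (og in c("taenia", "anomala", "adoketa")) {
    re <- ape::root(ape::unroot(fixture_tree()), outgroup = og,
                    resolve.root = TRUE)
    expect_equal(sankoff_reconstruct(re, recs)$total_cost, base)
  }
})

test_that("input validation names the offending leaf or state", {
  tr <- fixture_tree()
  recs <- fixture_table()
  expect_error(sankoff_reconstruct(tr, recs[-1, ]), "maronii")
  tiny_space <- build_state_space(list(st(8, 16)), slack = 0)
  expect_error(sankoff_reconstruct(tr, recs, space = tiny_space),
               "outside the state space")
})

test_that("the CMA3 count character reconstructs one ancestral signal pair", {
  tr <- fixture_tree()
  counts <- stats::setNames(fixture_table()$cma3, fixture_table()$species)
  crec <- reconstruct_count_character(tr, counts)
  expect_equal(crec$total_cost, 2)
  expect_identical(crec$states$c[crec$mpr[[crec$root]]], 1L)

  # all tips equal -> zero cost, root equals the shared count
  ceq <- reconstruct_count_character(tr, stats::setNames(rep(2L, 5),
                                                         names(counts)))
  expect_equal(ceq$total_cost, 0)
  expect_identical(ceq$states$c[ceq$mpr[[ceq$root]]], 2L)

  # two leaves 0 and 4: cost 4, every intermediate count is optimal at the root
  t2 <- ape::read.tree(text = "(x,y);")
  c2 <- reconstruct_count_character(t2, c(x = 0L, y = 4L))
  expect_equal(c2$total_cost, 4)
  expect_identical(c2$states$c[c2$mpr[[c2$root]]], 0:4)
})

test_that("every enumerated MPR assignment has branch distances summing to the optimum", {
  rec <- fixture_reconstruction()
  en <- enumerate_mprs(rec)
  expect_false(en$truncated)
  expect_length(en$assignments, 2L)  # exactly the two tied root states
  for (a in en$assignments) {
    dec <- decompose_all_branches(rec, a)
    expect_equal(sum(vapply(dec, multiset_total, integer(1))),
                 as.integer(rec$total_cost))
  }
  # cap truncation flag
  capped <- enumerate_mprs(rec, cap = 1)
  expect_true(capped$truncated)
  expect_length(capped$assignments, 1L)
})

test_that("an independent Sankoff implementation confirms the fixture optimum", {
  skip_if_not_installed("phangorn")
  tr <- fixture_tree()
  recs <- fixture_table()
  space <- build_state_space(
    lapply(seq_len(nrow(recs)), function(i) st(recs$M[i], recs$A[i])),
    slack = 4)
  labels <- paste(space$states$M, space$states$A, sep = "_")
  D <- outer(seq_len(nrow(space$states)), seq_len(nrow(space$states)),
             function(i, j) oracle_distance(space$states$M[i],
                                            space$states$A[i],
                                            space$states$M[j],
                                            space$states$A[j]))
  dimnames(D) <- list(labels, labels)
  tip_lab <- stats::setNames(paste(recs$M, recs$A, sep = "_"), recs$species)
  pd <- phangorn::phyDat(as.matrix(tip_lab[tr$tip.label]), type = "USER",
                         levels = labels)
  expect_equal(as.numeric(phangorn::parsimony(tr, pd, method = "sankoff",
                                              cost = D)), 5)
  # forcing candidate root states through a zero-length pseudo-tip:
  # attaching a pseudo-leaf with state s at the root keeps the optimum at 5
  # exactly when s belongs to the root MPR set
  tr2 <- ape::read.tree(
    text = "((((anomala,aureocephalus),taenia),adoketa),maronii,pseudo);")
  for (cand in list(c(8, 16, 5), c(7, 18, 5), c(9, 14, 6), c(8, 15, 7))) {
    tl <- c(tip_lab, pseudo = paste(cand[1], cand[2], sep = "_"))
    pd2 <- phangorn::phyDat(as.matrix(tl[tr2$tip.label]), type = "USER",
                            levels = labels)
    expect_equal(as.numeric(phangorn::parsimony(tr2, pd2, method = "sankoff",
                                                cost = D)), cand[3],
                 info = paste(cand, collapse = ","))
  }
  # CMA3 character cross-check
  cvals <- as.character(0:5)
  Dc <- abs(outer(0:5, 0:5, "-")); dimnames(Dc) <- list(cvals, cvals)
  ctips <- stats::setNames(as.character(recs$cma3), recs$species)
  pdc <- phangorn::phyDat(as.matrix(ctips[tr$tip.label]), type = "USER",
                          levels = cvals)
  expect_equal(as.numeric(phangorn::parsimony(tr, pdc, method = "sankoff",
                                              cost = Dc)), 2)
})
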