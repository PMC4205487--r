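# Minimal-event distances on the karyotype lattice.
#
# For the (M, A) component the minimum number of events transforming s1 into
# s2 has a closed form. Writing dN = (M2 + A2) - (M1 + A1) for the change in
# total pair count and dM = M2 - M1:
#
#   distance = |dN| + |dM + dN|
#
# |dN| fusions (dN < 0) or fissions (dN > 0) are forced because only they
# change the pair count, and they overshoot dM by exactly -dN, which |dM + dN|
# pericentric inversions repair. The resulting multiset (never mixing an event
# with its inverse) is unique even though event orderings are not. The closed
# form is attained whenever some ordering of that multiset is feasible under
# the apply_event() preconditions; otherwise the breadth-first-search oracle
# decides (in practice only the isolated empty state (0,0) is affected).

#' Unique minimal event decomposition between two karyotype states
#'
#' Returns the unique minimal multiset of rearrangement events transforming
#' `s1` into `s2`: `|dN|` fusions or fissions plus `|dM + dN|` pericentric
#' inversions (see [event_distance()]), and, when both states carry a CMA3
#' component, `|dc|` CMA3 gains or losses.
#'
#' @param s1,s2 [karyotype_state()] objects.
#' @return An [event_multiset()].
#' @examples
#' decompose_minimal_events(karyotype_state(8, 16), karyotype_state(9, 13))
#' @export
decompose_minimal_events <- function(s1, s2) {
  stopifnot(inherits(s1, "karyotype_state"), inherits(s2, "karyotype_state"))
  dN <- (s2$M + s2$A) - (s1$M + s1$A)
  dM <- s2$M - s1$M
  w <- dM + dN
  dc <- if (!is.na(s1$cma3) && !is.na(s2$cma3)) s2$cma3 - s1$cma3 else 0L
  event_multiset(fusion = max(0L, -dN), fission = max(0L, dN),
                 inv_m_to_a = max(0L, -w), inv_a_to_m = max(0L, w),
                 cma3_gain = max(0L, dc), cma3_loss = max(0L, -dc))
}

# Can the (M,A) part of a minimal multiset be ordered feasibly from s1?
# State after applying a sub-multiset depends only on the counts applied, so
# memoisation on remaining counts suffices. At most one of (x, y) and one of
# (u, v) is nonzero in a minimal multiset, keeping this tiny.
.order_feasible <- function(M, A, x, y, u, v) {
  memo <- new.env(parent = emptyenv())
  x0 <- x; y0 <- y; u0 <- u; v0 <- v; M0 <- M; A0 <- A
  rec <- function(x, y, u, v) {
    if (x + y + u + v == 0L) return(TRUE)
    key <- paste(x, y, u, v)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # current state from counts already applied
    M <- M0 + (x0 - x) - (y0 - y) - (u0 - u) + (v0 - v)
    A <- A0 - 2L * (x0 - x) + 2L * (y0 - y) + (u0 - u) - (v0 - v)
    ok <- (x > 0L && A >= 2L && rec(x - 1L, y, u, v)) ||
          (y > 0L && M >= 1L && rec(x, y - 1L, u, v)) ||
          (u > 0L && M >= 1L && rec(x, y, u - 1L, v)) ||
          (v > 0L && A >= 1L && rec(x, y, u, v - 1L))
    memo[[key]] <- ok
    ok
  }
  rec(x, y, u, v)
}

#' Minimal-event distance between two karyotype states
#'
#' The minimum number of rearrangement events transforming `s1` into `s2`.
#' The `(M, A)` component uses the closed form `|dN| + |dM + dN|` (see
#' [decompose_minimal_events()]); whenever no ordering of the closed-form
#' multiset is feasible under the [apply_event()] preconditions, the function
#' falls back to the breadth-first-search oracle [min_event_path()]. When both
#' states carry a CMA3 component, `|dc|` is added (gains and losses schedule
#' freely along any minimal karyotype path). Returns `Inf` for unreachable
#' pairs (only the chromosome-less state `(0, 0)` is isolated).
#'
#' @param s1,s2 [karyotype_state()] objects.
#' @return Non-negative integer, or `Inf` if `s2` is unreachable from `s1`.
#' @examples
#' event_distance(karyotype_state(8, 16), karyotype_state(7, 18))  # 1 fission
#' @export
event_distance <- function(s1, s2) {
  stopifnot(inherits(s1, "karyotype_state"), inherits(s2, "karyotype_state"))
  ms <- decompose_minimal_events(s1, s2)
  d_ka <- sum(unclass(ms)[c("fusion", "fission", "inv_m_to_a", "inv_a_to_m")])
  d_c <- sum(unclass(ms)[c("cma3_gain", "cma3_loss")])
  if (d_ka > 0L &&
      !.order_feasible(s1$M, s1$A, ms[["fusion"]], ms[["fission"]],
                       ms[["inv_m_to_a"]], ms[["inv_a_to_m"]])) {
    path <- tryCatch(
      min_event_path(karyotype_state(s1$M, s1$A), karyotype_state(s2$M, s2$A)),
      karyevol_unreachable = function(e) NULL)
    if (is.null(path)) return(Inf)
    d_ka <- length(path)
  }
  d_ka + d_c
}

# ---- lattice BFS machinery ------------------------------------------------

# Build the bounded state lattice and a per-kind neighbour index matrix.
# Grid order is lexicographic in (c, M, A) with A fastest, so that for fixed c
# index = M * (A_max + 1) + A + 1 (+ c stratum offset).
.lattice_graph <- function(M_max, A_max, c_max = NULL) {
  nA <- A_max + 1L
  nM <- M_max + 1L
  base <- expand.grid(A = 0:A_max, M = 0:M_max)
  if (is.null(c_max)) {
    st <- data.frame(M = base$M, A = base$A)
    cc <- NULL
  } else {
    st <- data.frame(M = rep(base$M, c_max + 1L),
                     A = rep(base$A, c_max + 1L),
                     c = rep(0:c_max, each = nA * nM))
    cc <- st$c
  }
  n <- nrow(st)
  Mv <- st$M; Av <- st$A
  idx <- function(M, A, c3 = NULL) {
    i <- M * nA + A + 1L
    if (!is.null(cc)) i <- i + c3 * nA * nM
    i
  }
  kinds <- if (is.null(cc)) event_kinds()[1:4] else event_kinds()
  nb <- matrix(NA_integer_, n, length(kinds), dimnames = list(NULL, kinds))
  ok <- Av >= 2L & Mv + 1L <= M_max
  if (!is.null(cc)) ok <- ok & cc <= Mv + Av - 1L
  nb[ok, "fusion"] <- idx(Mv[ok] + 1L, Av[ok] - 2L, cc[ok])
  ok <- Mv >= 1L & Av + 2L <= A_max
  nb[ok, "fission"] <- idx(Mv[ok] - 1L, Av[ok] + 2L, cc[ok])
  ok <- Mv >= 1L & Av + 1L <= A_max
  nb[ok, "inv_m_to_a"] <- idx(Mv[ok] - 1L, Av[ok] + 1L, cc[ok])
  ok <- Av >= 1L & Mv + 1L <= M_max
  nb[ok, "inv_a_to_m"] <- idx(Mv[ok] + 1L, Av[ok] - 1L, cc[ok])
  if (!is.null(cc)) {
    ok <- cc + 1L <= pmin(c_max, Mv + Av)
    nb[ok, "cma3_gain"] <- idx(Mv[ok], Av[ok], cc[ok] + 1L)
    ok <- cc >= 1L
    nb[ok, "cma3_loss"] <- idx(Mv[ok], Av[ok], cc[ok] - 1L)
  }
  list(states = st, nb = nb, idx = idx, kinds = kinds)
}

# Level-synchronous BFS from one source; returns distances and, optionally,
# parent pointers with the event kind leading into each visited state.
.lattice_bfs <- function(graph, from_idx, track_parents = FALSE) {
  n <- nrow(graph$states)
  nk <- length(graph$kinds)
  dist <- rep(Inf, n)
  parent <- if (track_parents) integer(n) else NULL
  pevent <- if (track_parents) character(n) else NULL
  dist[from_idx] <- 0
  frontier <- from_idx
  level <- 0
  while (length(frontier)) {
    level <- level + 1
    cand_to <- as.vector(graph$nb[frontier, , drop = FALSE])
    cand_from <- rep(frontier, times = nk)
    cand_kind <- rep(graph$kinds, each = length(frontier))
    keep <- !is.na(cand_to)
    cand_to <- cand_to[keep]; cand_from <- cand_from[keep]
    cand_kind <- cand_kind[keep]
    keep <- !is.finite(dist[cand_to])
    cand_to <- cand_to[keep]; cand_from <- cand_from[keep]
    cand_kind <- cand_kind[keep]
    if (!length(cand_to)) break
    first <- !duplicated(cand_to)
    new <- cand_to[first]
    dist[new] <- level
    if (track_parents) {
      parent[new] <- cand_from[first]
      pevent[new] <- cand_kind[first]
    }
    frontier <- new
  }
  list(dist = dist, parent = parent, pevent = pevent)
}

.default_bounds <- function(s1, s2) {
  span <- s1$M + s2$M + s1$A + s2$A
  list(M_max = span + 2L,
       A_max = 2L * (s1$M + s2$M) + s1$A + s2$A + 2L,
       c_max = if (!is.na(s1$cma3) && !is.na(s2$cma3))
         max(s1$cma3, s2$cma3) else NULL)
}

#' Shortest feasible event sequence between two karyotype states
#'
#' Breadth-first search over the bounded karyotype lattice; every returned
#' intermediate state satisfies the [apply_event()] preconditions and the
#' sequence length equals [event_distance()]. This is the brute-force oracle
#' backing the closed-form distance. The CMA3 dimension is included when both
#' states carry it.
#'
#' @param s1,s2 [karyotype_state()] objects.
#' @param bounds Optional list with elements `M_max`, `A_max` (and `c_max`)
#'   bounding the searched lattice; defaults are generous enough for any
#'   minimal path.
#' @return Character vector of event kinds (empty when `s1 == s2`), with the
#'   visited states (including endpoints) as a data frame in attribute
#'   `"states"`. Signals a condition of class `karyevol_unreachable` when no
#'   feasible path exists within the bounds.
#' @examples
#' min_event_path(karyotype_state(0, 2), karyotype_state(1, 0))  # "fusion"
#' @export
min_event_path <- function(s1, s2, bounds = NULL) {
  stopifnot(inherits(s1, "karyotype_state"), inherits(s2, "karyotype_state"))
  def <- .default_bounds(s1, s2)
  if (is.null(bounds)) bounds <- def
  if (is.null(bounds$M_max) || is.null(bounds$A_max)) {
    stop("bounds must supply M_max and A_max")
  }
  use_c <- !is.null(bounds$c_max) && !is.na(s1$cma3) && !is.na(s2$cma3)
  if (s1$M > bounds$M_max || s2$M > bounds$M_max ||
      s1$A > bounds$A_max || s2$A > bounds$A_max) {
    stop("states lie outside the supplied lattice bounds")
  }
  g <- .lattice_graph(bounds$M_max, bounds$A_max,
                      c_max = if (use_c) bounds$c_max else NULL)
  i1 <- g$idx(s1$M, s1$A, if (use_c) s1$cma3 else NULL)
  i2 <- g$idx(s2$M, s2$A, if (use_c) s2$cma3 else NULL)
  r <- .lattice_bfs(g, i1, track_parents = TRUE)
  if (!is.finite(r$dist[i2])) {
    cond <- structure(
      class = c("karyevol_unreachable", "error", "condition"),
      list(message = sprintf("no feasible event path from %s to %s within bounds",
                             format_karyotype_formula(s1),
                             format_karyotype_formula(s2)),
           call = sys.call()))
    stop(cond)
  }
  # walk parent pointers back from the target
  kinds <- character(r$dist[i2])
  nodes <- integer(r$dist[i2] + 1L)
  at <- i2
  for (k in rev(seq_along(kinds))) {
    nodes[k + 1L] <- at
    kinds[k] <- r$pevent[at]
    at <- r$parent[at]
  }
  nodes[1L] <- i1
  structure(kinds, states = g$states[nodes, , drop = FALSE])
}

#' Breadth-first-search distances from one state to the whole lattice
#'
#' Companion oracle to [min_event_path()]: one search yields the exact
#' minimal-event distance from `from` to every state of the bounded
#' `(M, A)` lattice, convenient for verifying the closed-form
#' [event_distance()] exhaustively.
#'
#' @param from A [karyotype_state()] (CMA3 component ignored).
#' @param M_max,A_max Lattice bounds (inclusive).
#' @return Data frame with columns `M`, `A`, `distance` (`Inf` = unreachable).
#' @export
bfs_event_distances <- function(from, M_max, A_max) {
  stopifnot(inherits(from, "karyotype_state"))
  if (from$M > M_max || from$A > A_max) {
    stop("'from' lies outside the requested lattice bounds")
  }
  g <- .lattice_graph(as.integer(M_max), as.integer(A_max))
  r <- .lattice_bfs(g, g$idx(from$M, from$A))
  data.frame(M = g$states$M, A = g$states$A, distance = r$dist)
}
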