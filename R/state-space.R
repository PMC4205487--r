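#' Build a bounded karyotype state space
#'
#' The Sankoff recursion runs over a finite lattice of `(M, A)` states. The
#' bounds are the per-axis minima and maxima observed among the tip states,
#' widened by `slack` pairs on each side and clipped at zero. Widening the
#' slack never changes the parsimony optimum once all geodesic intermediate
#' states fit inside the space.
#'
#' @param tips A list of [karyotype_state()] objects (at least one), or a
#'   karyotype table as returned by [read_karyotype_table()].
#' @param slack Non-negative integer widening (default 4 pairs).
#' @return An object of class `state_space`: list with `M_range`, `A_range`
#'   and a data frame `states` enumerating the lattice in lexicographic
#'   `(M, A)` order.
#' @examples
#' build_state_space(list(karyotype_state(8, 16), karyotype_state(9, 13)))
#' @export
build_state_space <- function(tips, slack = 4L) {
  if (is.data.frame(tips)) {
    tips <- lapply(seq_len(nrow(tips)), function(i)
      karyotype_state(tips$M[i], tips$A[i]))
  }
  stopifnot(length(tips) >= 1L,
            all(vapply(tips, inherits, logical(1), "karyotype_state")))
  slack <- as.integer(slack)
  if (is.na(slack) || slack < 0L) stop("slack must be a non-negative integer")
  Ms <- vapply(tips, `[[`, integer(1), "M")
  As <- vapply(tips, `[[`, integer(1), "A")
  M_range <- c(max(0L, min(Ms) - slack), max(Ms) + slack)
  A_range <- c(max(0L, min(As) - slack), max(As) + slack)
  grid <- expand.grid(A = A_range[1]:A_range[2], M = M_range[1]:M_range[2])
  structure(list(M_range = M_range, A_range = A_range,
                 states = data.frame(M = grid$M, A = grid$A)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> M in [%d, %d], A in [%d, %d]: %d states\n",
              x$M_range[1], x$M_range[2], x$A_range[1], x$A_range[2],
              nrow(x$states)))
  invisible(x)
}

# index of a (M, A) state inside the space, NA when outside
.space_index <- function(space, M, A) {
  nA <- space$A_range[2] - space$A_range[1] + 1L
  inside <- M >= space$M_range[1] & M <= space$M_range[2] &
            A >= space$A_range[1] & A <= space$A_range[2]
  ifelse(inside, (M - space$M_range[1]) * nA + (A - space$A_range[1]) + 1L,
         NA_integer_)
}

# Pairwise minimal-event cost matrix over the space, via the closed form.
# The only pairs where the closed form overstates reachability involve the
# isolated empty state (0,0); those entries are forced to Inf.
.space_cost_matrix <- function(space) {
  M <- space$states$M
  A <- space$states$A
  N <- M + A
  dN <- outer(N, N, function(a, b) b - a)
  dM <- outer(M, M, function(a, b) b - a)
  cost <- abs(dN) + abs(dM + dN)
  empty <- which(N == 0L)
  if (length(empty)) {
    cost[empty, ] <- Inf
    cost[, empty] <- Inf
    cost[cbind(empty, empty)] <- 0
  }
  cost
}
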