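# Rearrangement event algebra: each event kind acts on a karyotype state by a
# fixed integer effect vector (dM, dA, dc) in pair units, subject to a
# feasibility precondition. Fusions/fissions change 2n by -2/+2; pericentric
# inversions exchange one pair between arm classes; CMA3 gains/losses move the
# signal-pair count.

.event_effects <- matrix(
  c(+1L, -2L, 0L,   # fusion: two uniarmed pairs -> one biarmed pair
    -1L, +2L, 0L,   # fission: one biarmed pair -> two uniarmed pairs
    -1L, +1L, 0L,   # inv_m_to_a: pericentric inversion, biarmed -> uniarmed
    +1L, -1L, 0L,   # inv_a_to_m: pericentric inversion, uniarmed -> biarmed
    0L, 0L, +1L,    # cma3_gain
    0L, 0L, -1L),   # cma3_loss
  ncol = 3L, byrow = TRUE,
  dimnames = list(c("fusion", "fission", "inv_m_to_a", "inv_a_to_m",
                    "cma3_gain", "cma3_loss"),
                  c("dM", "dA", "dc")))

.event_inverse <- c(fusion = "fission", fission = "fusion",
                    inv_m_to_a = "inv_a_to_m", inv_a_to_m = "inv_m_to_a",
                    cma3_gain = "cma3_loss", cma3_loss = "cma3_gain")

#' Recognised rearrangement event kinds
#'
#' @return Character vector: `fusion`, `fission`, `inv_m_to_a`, `inv_a_to_m`,
#'   `cma3_gain`, `cma3_loss`.
#' @export
event_kinds <- function() rownames(.event_effects)

#' Effect vector of an event kind
#'
#' @param kind One of [event_kinds()].
#' @return Named integer vector `(dM, dA, dc)` in pair units.
#' @export
event_effect <- function(kind) {
  kind <- match.arg(kind, event_kinds())
  .event_effects[kind, ]
}

# returns NULL when feasible, else a message naming the violated precondition
.event_infeasible_reason <- function(state, kind) {
  M <- state$M; A <- state$A; c3 <- state$cma3
  switch(kind,
    fusion = if (A < 2L) "fusion requires at least 2 uniarmed pairs (A >= 2)"
      else if (!is.na(c3) && c3 > M + A - 1L)
        "fusion requires a signal-free pair to absorb (c <= M + A - 1)",
    fission = if (M < 1L) "fission requires at least 1 biarmed pair (M >= 1)",
    inv_m_to_a = if (M < 1L)
      "inversion m-sm->st-a requires at least 1 biarmed pair (M >= 1)",
    inv_a_to_m = if (A < 1L)
      "inversion st-a->m-sm requires at least 1 uniarmed pair (A >= 1)",
    cma3_gain = if (is.na(c3))
      "CMA3 gain requires a scored CMA3 component"
      else if (c3 + 1L > M + A)
        "CMA3 gain requires fewer signal pairs than chromosome pairs (c < M + A)",
    cma3_loss = if (is.na(c3))
      "CMA3 loss requires a scored CMA3 component"
      else if (c3 < 1L) "CMA3 loss requires at least 1 signal pair (c >= 1)"
  )
}

#' Is an event feasible on a state?
#'
#' @param state A [karyotype_state()].
#' @param kind One of [event_kinds()].
#' @return `TRUE` or `FALSE`.
#' @export
event_feasible <- function(state, kind) {
  kind <- match.arg(kind, event_kinds())
  is.null(.event_infeasible_reason(state, kind))
}

#' Apply a rearrangement event to a karyotype state
#'
#' The input state is unmodified; a new state shifted by the event's effect
#' vector is returned. Infeasible events raise an error naming the violated
#' precondition.
#'
#' @param state A [karyotype_state()].
#' @param kind One of [event_kinds()].
#' @return The resulting [karyotype_state()].
#' @examples
#' apply_event(karyotype_state(8, 16), "fission")  # -> 14m-sm+36st-a, 2n = 50
#' @export
apply_event <- function(state, kind) {
  stopifnot(inherits(state, "karyotype_state"))
  kind <- match.arg(kind, event_kinds())
  reason <- .event_infeasible_reason(state, kind)
  if (!is.null(reason)) {
    stop(sprintf("infeasible event '%s' on %s: %s", kind,
                 format_karyotype_formula(state), reason))
  }
  eff <- .event_effects[kind, ]
  karyotype_state(state$M + eff[["dM"]], state$A + eff[["dA"]],
                  cma3_pairs = if (is.na(state$cma3)) NA
                               else state$cma3 + eff[["dc"]])
}

#' Inverse of an event kind
#'
#' @param kind One of [event_kinds()].
#' @return The kind undoing `kind` (fusion <-> fission, the two inversion
#'   directions, CMA3 gain <-> loss).
#' @export
inverse_event <- function(kind) {
  kind <- match.arg(kind, event_kinds())
  .event_inverse[[kind]]
}

#' Construct an event multiset
#'
#' Per-branch (or per-transformation) counts of each event kind. A *minimal*
#' multiset, as produced by [decompose_minimal_events()], never mixes an event
#' with its inverse.
#'
#' @param fusion,fission,inv_m_to_a,inv_a_to_m,cma3_gain,cma3_loss
#'   Non-negative integer counts.
#' @return An object of class `event_multiset` (named integer vector).
#' @export
event_multiset <- function(fusion = 0L, fission = 0L, inv_m_to_a = 0L,
                           inv_a_to_m = 0L, cma3_gain = 0L, cma3_loss = 0L) {
  x <- as.integer(c(fusion = fusion, fission = fission,
                    inv_m_to_a = inv_m_to_a, inv_a_to_m = inv_a_to_m,
                    cma3_gain = cma3_gain, cma3_loss = cma3_loss))
  names(x) <- event_kinds()
  if (any(is.na(x)) || any(x < 0L)) stop("event counts must be non-negative")
  structure(x, class = "event_multiset")
}

#' Total number of events in a multiset
#'
#' @param ms An [event_multiset()].
#' @return Non-negative integer.
#' @export
multiset_total <- function(ms) {
  stopifnot(inherits(ms, "event_multiset"))
  sum(unclass(ms))
}

# human-readable event phrases used in multiset formatting and scenario text
.event_phrase <- c(
  fusion = "fusion", fission = "fission",
  inv_m_to_a = "pericentric inversion (m-sm->st-a)",
  inv_a_to_m = "pericentric inversion (st-a->m-sm)",
  cma3_gain = "CMA3 gain", cma3_loss = "CMA3 loss")

#' @export
format.event_multiset <- function(x, ...) {
  v <- unclass(x)
  nz <- v[v > 0L]
  if (!length(nz)) return("-")
  plural <- c("fusion", "fission", "cma3_gain", "cma3_loss")
  paste(sprintf("%d %s%s", nz, .event_phrase[names(nz)],
                ifelse(nz > 1L & names(nz) %in% plural, "s", "")),
        collapse = " + ")
}

#' @export
print.event_multiset <- function(x, ...) {
  cat("<event_multiset>", format(x), "\n")
  invisible(x)
}
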