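#' Construct a karyotype state
#'
#' A karyotype state summarises a diploid complement as counts of homologous
#' chromosome *pairs* in two arm classes: biarmed (metacentric/submetacentric,
#' the "m-sm" group) and uniarmed (subtelocentric/acrocentric, the "st-a"
#' group). An optional third component counts chromosome pairs bearing
#' CMA3-positive (GC-rich, typically NOR-associated) signals.
#'
#' Working in pair units keeps every rearrangement event integral: a centric
#' fusion joins two uniarmed pairs into one biarmed pair, a fission splits one
#' biarmed pair into two uniarmed pairs, and a pericentric inversion moves one
#' pair between the arm classes. The diploid number is `2n = 2 * (M + A)` and
#' is even by construction.
#'
#' @param biarmed_pairs Non-negative integer, number of m-sm pairs (M).
#' @param uniarmed_pairs Non-negative integer, number of st-a pairs (A).
#' @param cma3_pairs Non-negative integer count of CMA3-signal-bearing pairs,
#'   or `NA` when the character was not scored. Must not exceed `M + A`.
#' @return An object of class `karyotype_state` with fields `M`, `A`, `cma3`.
#' @examples
#' karyotype_state(8, 16, cma3_pairs = 1)   # 2n = 48, 16m-sm+32st-a
#' @export
karyotype_state <- function(biarmed_pairs, uniarmed_pairs, cma3_pairs = NA) {
  M <- as.integer(biarmed_pairs)
  A <- as.integer(uniarmed_pairs)
  c3 <- as.integer(cma3_pairs)
  if (length(M) != 1L || length(A) != 1L || length(c3) != 1L ||
      is.na(M) || is.na(A)) {
    stop("biarmed_pairs and uniarmed_pairs must be single non-missing integers")
  }
  if (M < 0L || A < 0L) {
    stop("pair counts must be non-negative")
  }
  if (!is.na(c3) && (c3 < 0L || c3 > M + A)) {
    stop("cma3_pairs must lie in [0, M + A]")
  }
  structure(list(M = M, A = A, cma3 = c3), class = "karyotype_state")
}

#' Diploid chromosome number of a karyotype state
#'
#' @param state A `karyotype_state`.
#' @return `2 * (M + A)`, always even.
#' @export
diploid_number <- function(state) {
  stopifnot(inherits(state, "karyotype_state"))
  2L * (state$M + state$A)
}

#' Canonical karyotype formula of a state
#'
#' Renders the canonical dialect `"<2M>m-sm+<2A>st-a"`, i.e. diploid
#' chromosome counts per arm class.
#'
#' @param state A `karyotype_state`.
#' @return A single string, e.g. `"16m-sm+32st-a"`.
#' @export
format_karyotype_formula <- function(state) {
  stopifnot(inherits(state, "karyotype_state"))
  sprintf("%dm-sm+%dst-a", 2L * state$M, 2L * state$A)
}

#' @export
print.karyotype_state <- function(x, ...) {
  cat(sprintf("<karyotype_state> %s (2n=%d)", format_karyotype_formula(x),
              diploid_number(x)))
  if (!is.na(x$cma3)) cat(sprintf(", CMA3 pairs: %d", x$cma3))
  cat("\n")
  invisible(x)
}

#' @export
format.karyotype_state <- function(x, ...) {
  format_karyotype_formula(x)
}

# token -> arm class lookup used by the parser; the four Levan-style
# categories are pooled into two arm classes, as comparative tables do
.karyo_token_class <- c(
  "m" = "biarmed", "sm" = "biarmed", "m-sm" = "biarmed",
  "st" = "uniarmed", "a" = "uniarmed", "st-a" = "uniarmed", "t" = "uniarmed"
)

#' Parse a karyotype formula string
#'
#' Accepts `"+"`-separated `<count><category>` terms with diploid chromosome
#' counts, e.g. `"16m-sm+32st-a"`, `"14sm+36st-a"` or `"48st-a"`. Category
#' tokens (case-insensitive): `m`, `sm`, `m-sm` (biarmed) and `st`, `a`,
#' `st-a`, `t` (uniarmed). Counts are summed per arm class and halved into
#' pair units.
#'
#' Because chromosomes of a diploid complement come in homologous pairs, an
#' odd per-class chromosome total is rejected unless `lenient = TRUE`, in
#' which case it is floored to whole pairs with a warning (no support for
#' supernumerary B chromosomes).
#'
#' @param text A single formula string.
#' @param cma3_pairs Optional CMA3 pair count carried into the state.
#' @param lenient If `TRUE`, odd per-class counts are floored to pairs with a
#'   warning instead of raising an error.
#' @return A [karyotype_state()].
#' @examples
#' parse_karyotype_formula("16m-sm+32st-a")  # M = 8, A = 16
#' parse_karyotype_formula("14sm+36st-a")    # M = 7, A = 18
#' @export
parse_karyotype_formula <- function(text, cma3_pairs = NA, lenient = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("karyotype formula must be a single non-empty string")
  }
  tokens <- strsplit(text, "+", fixed = TRUE)[[1L]]
  chrom <- c(biarmed = 0L, uniarmed = 0L)
  for (tok in tokens) {
    m <- regmatches(tolower(trimws(tok)),
                    regexec("^([0-9]+) *(m-sm|st-a|sm|st|m|a|t)$",
                            tolower(trimws(tok))))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse karyotype term '%s' in formula '%s'",
                   trimws(tok), text))
    }
    cls <- .karyo_token_class[[m[3L]]]
    chrom[[cls]] <- chrom[[cls]] + as.integer(m[2L])
  }
  odd <- chrom %% 2L != 0L
  if (any(odd)) {
    if (!lenient) {
      stop(sprintf(
        "odd chromosome count (%s) in formula '%s': diploid complements pair; use lenient = TRUE to floor",
        paste(sprintf("%s=%d", names(chrom)[odd], chrom[odd]), collapse = ", "),
        text))
    }
    warning(sprintf("flooring odd chromosome count(s) in '%s' to whole pairs",
                    text))
  }
  karyotype_state(chrom[["biarmed"]] %/% 2L, chrom[["uniarmed"]] %/% 2L,
                  cma3_pairs = cma3_pairs)
}
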