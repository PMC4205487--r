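# Readers and writers: karyotype tables (TSV mirroring comparative cytogenetics
# tables: species / 2n / karyotype formula / CMA3 signal pairs), Newick trees
# (through ape, with bracketed comment annotations on output so third-party
# viewers still load the files), and the node/branch report of a
# reconstruction.

#' Packaged fixture files for the dwarf cichlid clade
#'
#' Paths to the shipped five-species *Nannacara*--*Ivanacara*--*Cleithracara*
#' dataset: the rooted ingroup topology
#' `((((anomala,aureocephalus),taenia),adoketa),maronii);` and the karyotype
#' table (2n, formula, CMA3 pair count per species).
#'
#' @return Named character vector with elements `tree` and `karyotypes`.
#' @examples
#' nic_fixture_files()
#' @export
nic_fixture_files <- function() {
  c(tree = system.file("extdata", "nic_tree.nwk", package = "karyevol",
                       mustWork = TRUE),
    karyotypes = system.file("extdata", "nic_karyotypes.tsv",
                             package = "karyevol", mustWork = TRUE))
}

#' Read a karyotype table
#'
#' Expects a delimited text file with a header row and columns `species`,
#' `2n`, `karyotype` and `cma3` (case-insensitive, any order). Each formula
#' is parsed with [parse_karyotype_formula()] and validated against the
#' stated diploid number; species labels must be unique.
#'
#' @param path Path to the table.
#' @param sep Field separator; tab by default, use `","` for CSV.
#' @return Data frame with columns `species`, `2n`, `karyotype`, `cma3`,
#'   plus the parsed pair counts `M` and `A`, row order preserved.
#' @examples
#' read_karyotype_table(nic_fixture_files()[["karyotypes"]])
#' @export
read_karyotype_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  names(df) <- tolower(trimws(names(df)))
  need <- c("species", "2n", "karyotype", "cma3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("karyotype table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  df <- df[need]
  if (anyDuplicated(df$species)) {
    stop(sprintf("duplicate species label(s): %s",
                 paste(unique(df$species[duplicated(df$species)]),
                       collapse = ", ")))
  }
  df$`2n` <- as.integer(df$`2n`)
  df$cma3 <- as.integer(df$cma3)
  states <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    st <- tryCatch(parse_karyotype_formula(df$karyotype[i],
                                           cma3_pairs = df$cma3[i]),
                   error = function(e) {
                     stop(sprintf("row %d (%s): %s", i, df$species[i],
                                  conditionMessage(e)), call. = FALSE)
                   })
    if (diploid_number(st) != df$`2n`[i]) {
      stop(sprintf(
        "row %d (%s): formula '%s' totals 2n=%d but the table states 2n=%d",
        i, df$species[i], df$karyotype[i], diploid_number(st), df$`2n`[i]))
    }
    states[[i]] <- st
  }
  df$M <- vapply(states, `[[`, integer(1), "M")
  df$A <- vapply(states, `[[`, integer(1), "A")
  df
}

#' Write a karyotype table
#'
#' Inverse of [read_karyotype_table()]: writes the `species`, `2n`,
#' `karyotype` and `cma3` columns as delimited text with a header row.
#'
#' @param records Data frame with those columns.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_karyotype_table <- function(records, path, sep = "\t") {
  need <- c("species", "2n", "karyotype", "cma3")
  stopifnot(all(need %in% names(records)))
  utils::write.table(records[need], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a single rooted Newick tree
#'
#' Strips bracketed comment blocks (as written by
#' [write_annotated_newick()]), validates the parenthesis structure, and
#' parses with `ape::read.tree`. Leaf labels must be unique and non-empty.
#'
#' @param path Path to a Newick file containing one tree.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]]*\\]", "", text)
  depth <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                         ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (length(depth) && (any(depth < 0L) || depth[length(depth)] != 0L)) {
    pos <- if (any(depth < 0L)) which(depth < 0L)[1L] else length(depth)
    stop(sprintf("unbalanced parentheses in Newick file near character %d",
                 pos))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop(sprintf("cannot parse Newick file '%s'", path))
  if (inherits(tree, "multiPhylo")) {
    stop("Newick file contains more than one tree")
  }
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label in Newick file")
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("duplicate leaf label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  tree
}

# Newick serialisation with optional per-node bracketed annotation strings
# (BEAST-style "[&...]" placed after the label / before the branch length).
.newick_string <- function(tree, annotations = NULL) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], factor(tree$edge[, 1L],
                                        levels = seq_len(ntip + tree$Nnode)))
  lens <- tree$edge.length
  len_of <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(lens)) len_of[tree$edge[, 2L]] <- lens
  labels <- c(tree$tip.label, rep("", tree$Nnode))
  if (!is.null(tree$node.label)) {
    labels[ntip + seq_len(tree$Nnode)] <- tree$node.label
  }
  rec <- function(node) {
    ch <- kids[[node]]
    core <- if (length(ch)) {
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
             labels[node])
    } else {
      labels[node]
    }
    if (!is.null(annotations) && nzchar(annotations[node])) {
      core <- paste0(core, "[&", annotations[node], "]")
    }
    if (!is.na(len_of[node])) core <- paste0(core, ":", len_of[node])
    core
  }
  root <- .tree_root(tree$edge)
  paste0(rec(root), ";")
}

#' Write a Newick tree with reconstruction annotations
#'
#' Embeds per-node reconstructed states (and, optionally, CMA3 counts) as
#' bracketed `[&...]` comment blocks that [read_newick()] and standard tree
#' viewers ignore. Without a reconstruction the plain topology is written.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @param result Optional `karyo_reconstruction` for the karyotype character
#'   (its selected assignment is annotated).
#' @param count_result Optional `karyo_reconstruction` for the CMA3 count.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(tree, path, result = NULL,
                                   count_result = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ann <- NULL
  if (!is.null(result) || !is.null(count_result)) {
    n <- length(tree$tip.label) +
      (if (!is.null(result)) result$tree$Nnode else count_result$tree$Nnode)
    ann <- character(n)
    for (node in seq_len(n)) {
      parts <- character(0)
      if (!is.null(result)) {
        st <- .assignment_state(result, result$selected, node)
        parts <- c(parts, sprintf("karyotype=%s,2n=%d",
                                  format_karyotype_formula(st),
                                  diploid_number(st)))
      }
      if (!is.null(count_result)) {
        parts <- c(parts, sprintf("cma3=%d",
          .assignment_state(count_result, count_result$selected, node)))
      }
      ann[node] <- paste(parts, collapse = ",")
    }
  }
  writeLines(.newick_string(tree, ann), path)
  invisible(path)
}

#' Write the node/branch report of a reconstruction
#'
#' One row per node (MPR state set and the selected canonical formula) in
#' pre-order, followed by one row per branch (minimal event multiset, `-`
#' when empty), as tab-separated text.
#'
#' @param result A `karyo_reconstruction` for the karyotype character.
#' @param path Output path.
#' @param count_result Optional CMA3 `karyo_reconstruction`; adds `cma3`
#'   columns to the node rows and CMA3 events to the branch rows.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(result, path, count_result = NULL) {
  stopifnot(inherits(result, "karyo_reconstruction"))
  fmt_state <- function(i) {
    format_karyotype_formula(karyotype_state(result$states$M[i],
                                             result$states$A[i]))
  }
  # pre-order node sequence: root, then children as the pre-order edges visit
  nodes <- c(result$root, result$edge[, 2L])
  node_rows <- data.frame(
    record = "node",
    label = result$node_labels[nodes],
    state = vapply(nodes, function(n) fmt_state(result$selected[n]),
                   character(1)),
    `2n` = vapply(nodes, function(n) {
      i <- result$selected[n]
      2L * (result$states$M[i] + result$states$A[i])
    }, integer(1)),
    mpr_set = vapply(nodes, function(n)
      paste(vapply(result$mpr[[n]], fmt_state, character(1)), collapse = "|"),
      character(1)),
    events = "-",
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(count_result)) {
    node_rows$cma3 <- vapply(nodes, function(n)
      .assignment_state(count_result, count_result$selected, n), integer(1))
    node_rows$cma3_mpr <- vapply(nodes, function(n)
      paste(count_result$states$c[count_result$mpr[[n]]], collapse = "|"),
      character(1))
  }
  dec <- decompose_all_branches(result)
  if (!is.null(count_result)) {
    dec_c <- decompose_all_branches(count_result)
    dec <- lapply(seq_along(dec), function(k) {
      m <- unclass(dec[[k]]) + unclass(dec_c[[k]])
      do.call(event_multiset, as.list(m))
    })
    names(dec) <- names(decompose_all_branches(result))
  }
  branch_rows <- data.frame(
    record = "branch",
    label = names(dec),
    state = "-", `2n` = NA_integer_, mpr_set = "-",
    events = vapply(dec, format, character(1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(count_result)) {
    branch_rows$cma3 <- NA_integer_
    branch_rows$cma3_mpr <- "-"
  }
  utils::write.table(rbind(node_rows, branch_rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
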