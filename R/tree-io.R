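#' Read a Newick tree
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object. Internal node labels (typically support values) are preserved as
#' opaque strings and single-quoted labels are supported. A light syntactic
#' pre-check reports the character offset of unbalanced parentheses or
#' unterminated quotes before the string is handed to the ape parser.
#'
#' @param text a Newick string.
#' @param file alternatively, path to a file whose first line holds the tree.
#' @return an object of class `phylo`; tip labels are unique.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("provide `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  # ape's parser does not understand single-quoted labels: substitute
  # placeholders, parse, then restore the originals ('' unescapes to ')
  quoted <- regmatches(text,
                       gregexpr("'(?:[^']|'')*'", text, perl = TRUE))[[1L]]
  restore <- character(0)
  if (length(quoted)) {
    tokens <- sprintf("relclockQUOTE%dENDQ", seq_along(quoted))
    restore <- stats::setNames(
      gsub("''", "'", substr(quoted, 2L, nchar(quoted) - 1L)), tokens)
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], tokens[i], text, fixed = TRUE)
    }
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: ape could not parse the string")
  if (length(restore)) {
    swap <- function(x) ifelse(x %in% names(restore), restore[x], x)
    tr$tip.label <- unname(swap(tr$tip.label))
    if (!is.null(tr$node.label)) tr$node.label <- unname(swap(tr$node.label))
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("tip labels are not unique: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  needs_quote <- grepl("[^A-Za-z0-9_.|-]", c(tree$tip.label, tree$node.label))
  if (any(needs_quote)) {
    # quote awkward labels via placeholder substitution around ape's writer
    labs <- c(tree$tip.label, tree$node.label)
    tokens <- sprintf("relclockQUOTE%dENDQ", seq_along(labs))
    ntip <- ape::Ntip(tree)
    tree$tip.label <- ifelse(needs_quote[seq_len(ntip)],
                             tokens[seq_len(ntip)], tree$tip.label)
    if (!is.null(tree$node.label)) {
      idx <- ntip + seq_along(tree$node.label)
      tree$node.label <- ifelse(needs_quote[idx], tokens[idx],
                                tree$node.label)
    }
    s <- ape::write.tree(tree, digits = digits)
    for (i in which(needs_quote)) {
      s <- sub(tokens[i], quote_label(labs[i]), s, fixed = TRUE)
    }
    if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
    return(s)
  }
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# Balanced-parenthesis / quote scan with character offsets. Quoted labels
# ('...', with '' as an escaped quote) hide structural characters.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  quote_start <- 0L
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") {
        if (i < n && chars[i + 1L] == "'") i <- i + 1L else in_quote <- FALSE
      }
    } else if (ch == "'") {
      in_quote <- TRUE
      quote_start <- i
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error: unmatched ')' at character offset ", i)
      }
    }
    i <- i + 1L
  }
  if (in_quote) {
    stop("newick parse error: unterminated quote opened at character offset ",
         quote_start)
  }
  if (depth > 0L) {
    stop("newick parse error: ", depth,
         " unclosed '(' at end of string (length ", n, ")")
  }
  invisible(TRUE)
}

#' Node ages of an ultrametric tree
#'
#' Computes the age (time before present, in the tree's branch-length units)
#' of every node of a rooted tree whose branch lengths are durations. For a
#' chronogram all tips sit at age 0 and the root is the oldest node.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tol tolerance used to verify that all tips are contemporaneous.
#' @param check if `TRUE`, error when the tree is not ultrametric within `tol`
#'   (relative to root depth).
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_ages <- function(tree, tol = 1e-8, check = TRUE) {
  depths <- node_depths(tree)
  tips <- seq_len(ape::Ntip(tree))
  h <- max(depths[tips])
  ages <- h - depths
  if (check) {
    if (any(abs(ages[tips]) > tol * max(h, 1))) {
      stop("tree is not ultrametric: tip depths differ beyond tolerance")
    }
    ages[tips] <- 0
  }
  ages
}

# Distance from the root to every node (root has depth 0).
node_depths <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  depths <- numeric(ntot)
  # edges in preorder: parents appear before children when traversing rows
  # ordered so that each parent's depth is known; reorder guarantees this.
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]
    c <- ord$edge[e, 2L]
    depths[c] <- depths[p] + ord$edge.length[e]
  }
  depths
}

#' Build a chronogram from a topology and node ages
#'
#' Sets branch lengths to the age difference of the endpoints (durations in
#' Ma). Validates the age order (parent strictly not younger than child) and
#' that tips are at age 0.
#'
#' @param tree rooted `phylo` topology.
#' @param ages numeric vector indexed by ape node id (tips first).
#' @return a `phylo` whose edge lengths are `ages[parent] - ages[child]`.
#' @export
set_node_ages <- function(tree, ages) {
  ntip <- ape::Ntip(tree)
  stopifnot(length(ages) == ntip + tree$Nnode)
  if (any(ages[seq_len(ntip)] != 0)) stop("tip ages must all be 0")
  len <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  if (any(len < 0)) stop("parent age older-than-child violated")
  tree$edge.length <- len
  tree
}

#' Read a taxon annotation table
#'
#' Tab-separated table with columns `tip_label`, `genus`, `order`, `class`,
#' `phylum`, `domain`. Missing ranks may be `NA` or empty (treated as
#' unknown).
#'
#' @param file path to a TSV file.
#' @return a data.frame with one row per tip.
#' @export
read_annotations <- function(file) {
  ann <- utils::read.delim(file, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("tip_label", "genus", "order", "class", "phylum", "domain")
  missing_cols <- setdiff("tip_label", names(ann))
  if (length(missing_cols)) stop("annotation table lacks column tip_label")
  for (r in setdiff(need, names(ann))) ann[[r]] <- NA_character_
  ann[need]
}

#' @rdname read_annotations
#' @param annotations data.frame as returned by [read_annotations()].
#' @export
write_annotations <- function(annotations, file) {
  utils::write.table(annotations, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Assert that every annotated tip exists in the tree.
check_annotations <- function(tree, annotations) {
  extra <- setdiff(annotations$tip_label, tree$tip.label)
  if (length(extra)) {
    stop("annotated tips absent from tree: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  invisible(TRUE)
}
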