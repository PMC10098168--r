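#' Maximal monophyletic clades at a taxonomic rank
#'
#' Scans a rooted tree for the maximal clades whose tips all carry the same
#' value at a chosen rank (genus, order, class, phylum or domain). Tips with
#' an unknown (NA) rank value never join a clade. Returned clades are
#' node-disjoint by maximality; single tips whose parent clade is mixed are
#' reported as singleton clades.
#'
#' @param tree rooted `phylo`.
#' @param annotations data.frame with columns `tip_label` and the rank.
#' @param rank one of `"genus"`, `"order"`, `"class"`, `"phylum"`, `"domain"`
#'   (any column of `annotations` other than `tip_label` is accepted).
#' @return data.frame with one row per clade: `node` (ape node id), `value`
#'   (shared rank value), `size`, and `tips` (list column of tip labels).
#' @export
find_monophyletic_clades <- function(tree, annotations, rank) {
  vals <- rank_values(tree, annotations, rank)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  node_val <- c(vals, rep(NA_character_, tree$Nnode))
  mono <- c(!is.na(vals), rep(FALSE, tree$Nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  children <- split(ord$edge[, 2L], ord$edge[, 1L])
  for (p in unique(ord$edge[, 1L])) {        # postorder: children first
    kids <- children[[as.character(p)]]
    kv <- node_val[kids]
    if (all(mono[kids]) && !anyNA(kv) && length(unique(kv)) == 1L) {
      mono[p] <- TRUE
      node_val[p] <- kv[1L]
    }
  }
  parent <- node_parents(tree)
  keep <- which(mono & (is.na(parent) | !mono[parent]))
  below <- tips_below(tree)
  res <- data.frame(node = keep, value = node_val[keep],
                    size = vapply(keep, function(v) sum(below[[v]]), 0L))
  res$tips <- lapply(keep, function(v) tree$tip.label[below[[v]]])
  res[order(res$node), , drop = FALSE]
}

#' Subsample tips within clades
#'
#' Keeps at most `k` representatives per clade; tips outside every clade are
#' always retained. For `k = 1` the representative is the tip with the
#' longest terminal branch; for `k = 2` the retained pair is the most
#' divergent pair (maximal path length within the clade); for larger `k`
#' additional tips are added greedily by farthest-point selection. All ties
#' break lexicographically by tip label, so the result is independent of
#' input order.
#'
#' @param tree `phylo` with branch lengths.
#' @param clades data.frame as returned by [find_monophyletic_clades()], or a
#'   list of character vectors of tip labels.
#' @param k number of representatives per clade (>= 1).
#' @return character vector of retained tip labels, in tree order.
#' @export
subsample_clades <- function(tree, clades, k) {
  stopifnot(k >= 1)
  tip_sets <- if (is.data.frame(clades)) clades$tips else clades
  d <- ape::cophenetic.phylo(tree)
  pend <- pendant_lengths(tree)
  keep <- rep(TRUE, ape::Ntip(tree))
  names(keep) <- tree$tip.label
  for (tips in tip_sets) {
    tips <- sort(tips)
    if (length(tips) <= k) next
    chosen <- if (k == 1L) {
      tips[order(-pend[tips], tips)][1L]
    } else {
      dd <- d[tips, tips, drop = FALSE]
      sel <- best_pair(dd)
      while (length(sel) < k) {
        rest <- setdiff(tips, sel)
        md <- apply(dd[rest, sel, drop = FALSE], 1L, min)
        sel <- c(sel, rest[order(-md, rest)][1L])
      }
      sel
    }
    keep[setdiff(tips, chosen)] <- FALSE
  }
  tree$tip.label[keep[tree$tip.label]]
}

# most divergent pair; ties broken by the lexicographically smallest
# (sorted) label pair
best_pair <- function(dd) {
  labs <- rownames(dd)
  idx <- which(upper.tri(dd), arr.ind = TRUE)
  dv <- dd[idx]
  cand <- idx[dv == max(dv), , drop = FALSE]
  pairs <- apply(cand, 1L, function(r) sort(labs[r]))
  key <- apply(pairs, 2L, paste, collapse = "\r")
  pairs[, order(key)[1L]]
}

pendant_lengths <- function(tree) {
  ntip <- ape::Ntip(tree)
  pend <- numeric(ntip)
  tip_edges <- tree$edge[, 2L] <= ntip
  pend[tree$edge[tip_edges, 2L]] <- tree$edge.length[tip_edges]
  names(pend) <- tree$tip.label
  pend
}

#' Clade composition coding
#'
#' Finds the maximal clades in which a single rank value's share of tips
#' strictly exceeds `threshold` (default 0.67, i.e. "over 67% representation
#' of a single group"). Tips with unknown rank count in the denominator but
#' can never be the majority value. By maximality, a returned clade's parent
#' never satisfies the rule, and returned clades are node-disjoint.
#'
#' @inheritParams find_monophyletic_clades
#' @param threshold majority fraction in (0, 1); the share must strictly
#'   exceed it.
#' @return data.frame with columns `node`, `label` (majority value), `share`
#'   (exact fraction), `size`, and list column `tips`.
#' @export
clade_composition <- function(tree, annotations, rank, threshold = 0.67) {
  stopifnot(threshold > 0, threshold < 1)
  vals <- rank_values(tree, annotations, rank)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  below <- tips_below(tree)
  lev <- sort(unique(vals[!is.na(vals)]))
  maj_lab <- rep(NA_character_, ntot)
  maj_share <- rep(NA_real_, ntot)
  ok <- logical(ntot)
  for (v in seq_len(ntot)) {
    tv <- vals[below[[v]]]
    if (!length(tv)) next
    counts <- table(factor(tv, levels = lev))
    if (!length(counts) || all(counts == 0)) next
    share <- as.numeric(counts) / length(tv)   # unknowns in denominator
    i <- which.max(share)
    maj_lab[v] <- lev[i]
    maj_share[v] <- share[i]
    ok[v] <- share[i] > threshold
  }
  parent <- node_parents(tree)
  keep <- which(ok & (is.na(parent) | !ok[parent]))
  res <- data.frame(node = keep, label = maj_lab[keep],
                    share = maj_share[keep],
                    size = vapply(keep, function(v) sum(below[[v]]), 0L))
  res$tips <- lapply(keep, function(v) tree$tip.label[below[[v]]])
  res[order(res$node), , drop = FALSE]
}

#' Write a clade report
#'
#' @param clades data.frame from [clade_composition()] or
#'   [find_monophyletic_clades()].
#' @param file output TSV path.
#' @export
write_clade_report <- function(clades, file) {
  out <- clades
  out$tips <- NULL
  out <- cbind(clade_id = seq_len(nrow(out)), out)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

rank_values <- function(tree, annotations, rank) {
  if (!rank %in% names(annotations)) {
    stop("rank '", rank, "' absent from annotations")
  }
  check_annotations(tree, annotations)
  vals <- annotations[[rank]][match(tree$tip.label, annotations$tip_label)]
  as.character(vals)
}

node_parents <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, ntot)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}
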