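#' Minimal ancestor deviation (MAD) rooting
#'
#' Roots an unrooted, branch-length-bearing gene tree at the point that
#' minimizes the root-mean-square relative deviation of tip pairs from the
#' molecular-clock expectation. For every candidate branch and every tip pair
#' (i, j) with putative ancestor `a` under that rooting, the pair deviation is
#'
#'   r_ij = | 2 d(a, i) / (d(a, i) + d(a, j)) - 1 |
#'
#' and the branch score is the RMS of r_ij over all pairs. For pairs spanning
#' the candidate branch (length t) the ancestor slides along the branch; with
#' d_i the distance from the branch's child endpoint to tip i and
#' D_ij = d_i + d_j + t, the minimizing position measured from the child
#' endpoint is
#'
#'   rho* = clamp( sum_ij (D_ij - 2 d_i) / D_ij^2 / (2 sum_ij 1 / D_ij^2), 0, t )
#'
#' Pairs on one side of the branch have a fixed ancestor (their own most
#' recent common ancestor), so their deviations do not depend on rho.
#'
#' Ties between branches with equal minimal score are broken in favour of the
#' branch encountered first in a deterministic postorder edge traversal.
#' Zero-length candidate branches are allowed; their rho is fixed at 0. A
#' rooted input is silently unrooted first (the artificial root is ignored).
#'
#' @param tree a `phylo` with branch lengths; at least 3 tips, at least one
#'   positive branch length.
#' @return a list of class `mad_root` with elements
#'   \describe{
#'     \item{tree}{the rooted `phylo`, with a new root node inserted on the
#'       winning branch at distance rho from its child endpoint.}
#'     \item{branch_tips}{tip labels on the child side of the winning branch
#'       (identifies the branch as a bipartition).}
#'     \item{rho}{distance of the root from the child endpoint, in branch
#'       units.}
#'     \item{branch_length}{length of the winning branch.}
#'     \item{mad}{the minimal RMS deviation.}
#'     \item{scores}{data.frame of per-branch scores (postorder), columns
#'       `child_tips`, `rho`, `mad`.}
#'   }
#' @export
mad_root <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (ape::Ntip(tree) < 3L) stop("MAD rooting needs at least 3 tips")
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  tr <- ape::unroot(tree)
  tr <- ape::reorder.phylo(tr, "postorder")
  if (all(tr$edge.length <= 0)) {
    stop("all branch lengths are zero: no metric information to root on")
  }
  ntip <- ape::Ntip(tr)
  dn <- ape::dist.nodes(tr)
  pairs <- which(upper.tri(matrix(0, ntip, ntip)), arr.ind = TRUE)
  pi <- pairs[, 1L]
  pj <- pairs[, 2L]
  dij <- dn[cbind(pi, pj)]
  npairs <- nrow(pairs)

  # tip sets below each node in the (arbitrary) stored orientation
  below <- tips_below(tr)

  nedge <- nrow(tr$edge)
  best <- list(mad = Inf, edge = NA_integer_, rho = NA_real_)
  scores <- data.frame(child_tips = character(nedge), rho = numeric(nedge),
                       mad = numeric(nedge), stringsAsFactors = FALSE)
  for (e in seq_len(nedge)) {
    u <- tr$edge[e, 1L]
    v <- tr$edge[e, 2L]
    t <- tr$edge.length[e]
    in_v <- below[[v]]                     # logical over tips
    side_i <- in_v[pi]
    side_j <- in_v[pj]
    r2 <- numeric(npairs)

    same <- side_i == side_j
    if (any(same)) {
      anchor <- ifelse(in_v[pi[same]], v, u)
      dai <- (dn[cbind(anchor, pi[same])] + dij[same] -
                dn[cbind(anchor, pj[same])]) / 2
      r <- ifelse(dij[same] > 0, abs(2 * dai / dij[same] - 1), 0)
      r2[same] <- r * r
    }
    span <- !same
    rho <- 0
    if (any(span)) {
      # orient so i is on the v (child) side
      si <- ifelse(side_i[span], pi[span], pj[span])
      sj <- ifelse(side_i[span], pj[span], pi[span])
      di <- dn[cbind(v, si)]
      dj <- dn[cbind(u, sj)]
      D <- di + dj + t
      ok <- D > 0
      if (any(ok)) {
        rho <- sum((D[ok] - 2 * di[ok]) / D[ok]^2) / (2 * sum(1 / D[ok]^2))
        rho <- min(max(rho, 0), t)
        r <- abs(2 * (di[ok] + rho) / D[ok] - 1)
        rsp <- numeric(sum(span))
        rsp[ok] <- r
        r2[span] <- rsp * rsp
      }
    }
    m <- sqrt(mean(r2))
    scores$child_tips[e] <- paste(sort(tr$tip.label[in_v]), collapse = "|")
    scores$rho[e] <- rho
    scores$mad[e] <- m
    if (m < best$mad) best <- list(mad = m, edge = e, rho = rho)
  }

  e <- best$edge
  rooted <- insert_root_on_edge(tr, e, best$rho)
  structure(list(
    tree = rooted,
    branch_tips = sort(tr$tip.label[below[[tr$edge[e, 2L]]]]),
    rho = best$rho,
    branch_length = tr$edge.length[e],
    mad = best$mad,
    scores = scores
  ), class = "mad_root")
}

#' @export
print.mad_root <- function(x, ...) {
  cat("MAD rooting\n")
  cat(sprintf("  minimal ancestor deviation: %.6g\n", x$mad))
  cat(sprintf("  root branch (child side): %s\n",
              paste(x$branch_tips, collapse = ", ")))
  cat(sprintf("  position rho = %.6g of branch length %.6g\n",
              x$rho, x$branch_length))
  invisible(x)
}

# logical tip membership below each node, postorder fill
tips_below <- function(tr) {
  ntip <- ape::Ntip(tr)
  ntot <- ntip + tr$Nnode
  below <- vector("list", ntot)
  for (i in seq_len(ntip)) {
    b <- logical(ntip)
    b[i] <- TRUE
    below[[i]] <- b
  }
  ord <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]
    c <- ord$edge[e, 2L]
    if (is.null(below[[p]])) below[[p]] <- logical(ntip)
    below[[p]] <- below[[p]] | below[[c]]
  }
  below
}

# Re-root an unrooted tree by inserting a new root node on edge `e`,
# at distance `rho` from the child endpoint. Built by DFS over the
# adjacency graph, emitting Newick (labels are quoted when needed).
insert_root_on_edge <- function(tr, e, rho) {
  ntip <- ape::Ntip(tr)
  ntot <- ntip + tr$Nnode
  u <- tr$edge[e, 1L]
  v <- tr$edge[e, 2L]
  t <- tr$edge.length[e]
  adj <- vector("list", ntot)
  for (k in seq_len(nrow(tr$edge))) {
    if (k == e) next
    a <- tr$edge[k, 1L]
    b <- tr$edge[k, 2L]
    w <- tr$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  lab <- function(node) {
    if (node <= ntip) return(quote_label(tr$tip.label[node]))
    if (!is.null(tr$node.label)) {
      l <- tr$node.label[node - ntip]
      if (!is.na(l) && nzchar(l)) return(quote_label(l))
    }
    ""
  }
  emit <- function(node, from) {
    nb <- adj[[node]]
    kids <- if (is.null(nb)) integer(0) else nb[nb[, 1L] != from, 1L]
    if (!length(kids)) return(lab(node))
    lens <- nb[nb[, 1L] != from, 2L]
    parts <- vapply(seq_along(kids), function(i) {
      paste0(emit(kids[i], node), ":", format(lens[i], digits = 15))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  left <- paste0(emit(v, u), ":", format(rho, digits = 15))
  right <- paste0(emit(u, v), ":", format(t - rho, digits = 15))
  read_newick(paste0("(", left, ",", right, ");"))
}

quote_label <- function(x) {
  if (grepl("[^A-Za-z0-9_.|-]", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}
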