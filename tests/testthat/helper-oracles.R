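# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the MAD oracle is a brute-force grid search over
# distances from a sliding root point, the Poisson oracle is a library-free
# pmf, and the CIR oracle is an Euler-Maruyama discretization of the SDE.

# Exhaustive MAD search: every branch x a rho grid; deviations from first
# principles via distances to the candidate root point.
mad_grid_oracle <- function(tree, step = 1e-4) {
  tr <- ape::unroot(tree)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- ape::Ntip(tr)
  dn <- ape::dist.nodes(tr)
  idx <- which(upper.tri(matrix(0, ntip, ntip)), arr.ind = TRUE)
  pi <- idx[, 1L]; pj <- idx[, 2L]
  dij <- dn[cbind(pi, pj)]
  # tip side of each edge by BFS over the adjacency graph minus that edge
  nn <- ntip + tr$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tr$edge))) {
    a <- tr$edge[k, 1L]; b <- tr$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  side_of <- function(v, u) {            # nodes reachable from v avoiding u
    seen <- logical(nn); seen[v] <- TRUE
    queue <- v
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      for (y in adj[[x]]) {
        if (y != u && !seen[y]) { seen[y] <- TRUE; queue <- c(queue, y) }
      }
    }
    seen
  }
  best <- list(mad = Inf, tips = NULL, rho = NA)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]; t <- tr$edge.length[e]
    inV <- side_of(v, u)[seq_len(ntip)]
    rho <- if (t > 0) seq(0, t, by = step * t) else 0
    droot <- matrix(0, ntip, length(rho))
    for (i in seq_len(ntip)) {
      droot[i, ] <- if (inV[i]) dn[v, i] + rho else dn[u, i] + (t - rho)
    }
    dai <- (droot[pi, , drop = FALSE] + dij - droot[pj, , drop = FALSE]) / 2
    r <- abs(2 * dai / dij - 1)
    r[dij == 0, ] <- 0
    mads <- sqrt(colMeans(r * r))
    g <- which.min(mads)
    if (mads[g] < best$mad) {
      best <- list(mad = mads[g], tips = sort(tr$tip.label[inV]),
                   rho = rho[g], branch_length = t)
    }
  }
  best
}

# library-free log Poisson pmf
log_pois_oracle <- function(k, lam) {
  lf <- if (k > 0) sum(log(seq_len(k))) else 0
  if (lam == 0) return(if (k == 0) 0 else -Inf)
  k * log(lam) - lam - lf
}

# Euler-Maruyama discretization of dr = theta (1 - r) dt + sigma sqrt(r) dW
cir_em_oracle <- function(n, r0, theta, sigma, t_total, dt = 1e-3) {
  r <- rep(r0, n)
  for (s in seq_len(round(t_total / dt))) {
    r <- r + theta * (1 - r) * dt +
      sigma * sqrt(pmax(r, 0)) * stats::rnorm(n) * sqrt(dt)
    r <- pmax(r, 1e-12)
  }
  r
}

# random non-clock tree: Yule topology with gamma-perturbed branch lengths
random_noisy_tree <- function(n_tips, crown = 1) {
  tr <- relclock::simulate_time_tree(n_tips, crown)
  tr$edge.length <- tr$edge.length *
    stats::rgamma(length(tr$edge.length), shape = 4, rate = 4)
  tr
}

# direct rejection sampler from the dating prior: truncated-normal root,
# internal ages as uniform order statistics given the root, calibrations
# enforced by rejection
prior_root_oracle <- function(tree, prior, calibrations = list(),
                              n = 20000L) {
  cal <- if (length(calibrations)) {
    do.call(rbind, lapply(calibrations, function(cl) {
      data.frame(node = ape::getMRCA(tree, c(cl$tip_a, cl$tip_b)),
                 min = cl$min_age, max = cl$max_age)
    }))
  } else NULL
  ntip <- ape::Ntip(tree)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  internal <- setdiff(seq_len(ntip + tree$Nnode), seq_len(ntip))
  free <- setdiff(internal, root)
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  ntot <- ntip + tree$Nnode
  out <- numeric(0)
  while (length(out) < n) {
    m <- 50000L
    roots <- stats::rnorm(m, prior$mean, prior$sd)
    roots <- roots[roots > 0]
    m <- length(roots)
    ages <- matrix(0, ntot, m)
    ages[root, ] <- roots
    for (v in free) ages[v, ] <- stats::runif(m, 0, roots)
    ok <- rep(TRUE, m)
    for (e in seq_len(nrow(tree$edge))) {
      ok <- ok & ages[tree$edge[e, 1L], ] >= ages[tree$edge[e, 2L], ]
    }
    if (!is.null(cal)) {
      for (i in seq_len(nrow(cal))) {
        a <- ages[cal$node[i], ]
        ok <- ok & a >= cal$min[i] & a <= cal$max[i]
      }
    }
    out <- c(out, roots[ok])
  }
  out[seq_len(n)]
}

# adaptive quadrature of a density over (0, 50], split at the mode so
# narrow peaks are not missed
quad_unit_mass <- function(f, mode) {
  stats::integrate(f, 0, mode, rel.tol = 1e-10,
                   subdivisions = 500L)$value +
    stats::integrate(f, mode, 50, rel.tol = 1e-10,
                     subdivisions = 500L)$value
}

# thin an MCMC draw down to approximately independent samples for KS use
thin_to_ess <- function(x) {
  ess <- relclock::effective_size(x)
  x[seq(1L, length(x), by = max(1L, ceiling(length(x) / ess)))]
}
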