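#' Fossil calibration on the MRCA of two tips
#'
#' A calibration constrains the age of the most recent common ancestor of
#' two named tips to a hard interval `[min_age, max_age]` (uniform within,
#' zero prior mass outside), matching the default behaviour of mainstream
#' dating software.
#'
#' @param name short identifier (used in reports and subset definitions).
#' @param tip_a,tip_b tip labels whose MRCA is constrained.
#' @param min_age,max_age bounds in Ma, `0 < min_age < max_age`.
#' @return object of class `calibration`.
#' @export
calibration <- function(name, tip_a, tip_b, min_age, max_age) {
  stopifnot(min_age > 0, min_age < max_age)
  structure(list(name = name, tip_a = tip_a, tip_b = tip_b,
                 min_age = min_age, max_age = max_age),
            class = "calibration")
}

#' Normally-distributed root prior from an age interval
#'
#' The interval `[young_bound, old_bound]` (Ma) is read as the central 95%
#' span of a normal distribution: mean `(old + young) / 2`, standard
#' deviation `(old - young) / 4` (bounds at mean +/- 2 sd). The prior is
#' truncated at 0.
#'
#' @param old_bound,young_bound interval in Ma, `old_bound > young_bound > 0`.
#' @return object of class `root_prior` with fields `mean` and `sd`.
#' @export
root_prior <- function(old_bound, young_bound) {
  stopifnot(old_bound > young_bound, young_bound > 0)
  structure(list(old_bound = old_bound, young_bound = young_bound,
                 mean = (old_bound + young_bound) / 2,
                 sd = (old_bound - young_bound) / 4),
            class = "root_prior")
}

#' Log density of the root prior
#'
#' Truncated-normal (at 0) log density of a root age.
#'
#' @param age root age in Ma.
#' @param prior a [root_prior()] object.
#' @export
root_prior_logpdf <- function(age, prior) {
  out <- rep(-Inf, length(age))
  pos <- age > 0
  out[pos] <- stats::dnorm(age[pos], prior$mean, prior$sd, log = TRUE) -
    stats::pnorm(0, prior$mean, prior$sd, lower.tail = FALSE, log.p = TRUE)
  out
}

#' MCMC configuration for divergence dating
#'
#' @param model rate model tag, `"UGAM"`, `"LN"` or `"CIR"`.
#' @param chain_length total MCMC sweeps per chain.
#' @param burnin_frac fraction of sweeps discarded (and used for step-size
#'   adaptation, which is frozen afterwards to preserve detailed balance).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param n_chains number of independent chains (convergence checks need 2).
#' @param seed integer seed; chain i uses `seed + i - 1`.
#' @param use_likelihood `FALSE` runs the sampler on the prior alone
#'   (prior-predictive / prior-recovery mode).
#' @param mu_init initial global rate (subst/site/Ma).
#' @param nu_init,sigma2_init,theta_init,sigma_init initial hyperparameters.
#' @param mu_prior_mean,hyper_prior_mean means of the diffuse exponential
#'   hyperpriors on `mu` and on the model hyperparameters.
#' @param sample_hyper if `FALSE`, hyperparameters stay at their initial
#'   values (fixed-parameter runs).
#' @return object of class `dating_config`.
#' @export
dating_config <- function(model = c("UGAM", "LN", "CIR"),
                          chain_length = 20000L, burnin_frac = 0.2,
                          thin = 10L, n_chains = 2L, seed = 1L,
                          use_likelihood = TRUE,
                          mu_init = 1e-3, nu_init = 0.3, sigma2_init = 5e-4,
                          theta_init = 0.01, sigma_init = 0.1,
                          mu_prior_mean = 10 * mu_init,
                          hyper_prior_mean = NULL,
                          sample_hyper = TRUE) {
  model <- match.arg(model)
  stopifnot(chain_length > 0, burnin_frac >= 0, burnin_frac < 1,
            thin >= 1, n_chains >= 1)
  if (is.null(hyper_prior_mean)) {
    # diffuse exponentials on a per-Ma scale: rate variation of order 1
    # across a ~1000 Ma tree, CIR reversion over ~50-100 Ma
    hyper_prior_mean <- switch(model, UGAM = 1, LN = 1e-3,
                               CIR = c(0.02, 0.1))
  }
  structure(list(model = model, chain_length = as.integer(chain_length),
                 burnin_frac = burnin_frac, thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 use_likelihood = use_likelihood,
                 mu_init = mu_init, nu_init = nu_init,
                 sigma2_init = sigma2_init, theta_init = theta_init,
                 sigma_init = sigma_init, mu_prior_mean = mu_prior_mean,
                 hyper_prior_mean = hyper_prior_mean,
                 sample_hyper = sample_hyper),
            class = "dating_config")
}

#' Per-branch substitution counts
#'
#' Desk-scale stand-in for a sequence alignment: each branch carries an
#' observed substitution count `k_b`, modelled as Poisson with mean
#' `r_bar_b * mu * dt_b * L` where `L` is the alignment length in sites.
#'
#' @param tree the rooted `phylo` the counts belong to.
#' @param counts non-negative integer vector, one per edge in `tree$edge`
#'   order.
#' @param L alignment length (sites, > 0).
#' @return data.frame of class `branch_data` with columns `parent`, `child`,
#'   `count`; attribute `L`.
#' @export
branch_data <- function(tree, counts, L) {
  stopifnot(length(counts) == nrow(tree$edge), all(counts >= 0), L > 0)
  out <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                    count = as.integer(round(counts)))
  attr(out, "L") <- L
  attr(out, "tree") <- tree
  class(out) <- c("branch_data", class(out))
  out
}

#' @rdname branch_data
#' @param file TSV path. Each branch is keyed by its child clade -- the tip
#'   label for terminal branches, `tipA|tipB` (two tips whose MRCA is the
#'   child node) for internal branches -- so counts survive Newick
#'   re-numbering. `L` is stored in a `#L=` header comment.
#' @export
write_branch_data <- function(data, file) {
  tree <- attr(data, "tree")
  if (is.null(tree)) stop("branch data lacks its tree; rebuild with branch_data()")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#L=%.10g", attr(data, "L")), con)
  out <- data.frame(branch = branch_keys(tree)[match(data$child,
                                                     tree$edge[, 2L])],
                    count = data$count)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname branch_data
#' @export
read_branch_data <- function(tree, file) {
  first <- readLines(file, n = 1L)
  if (!startsWith(first, "#L=")) stop("branch data file lacks #L= header")
  L <- as.numeric(sub("#L=", "", first))
  tab <- utils::read.delim(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  child <- vapply(strsplit(tab$branch, "|", fixed = TRUE), function(tp) {
    bad <- setdiff(tp, tree$tip.label)
    if (length(bad)) stop("branch key names unknown tip(s): ",
                          paste(bad, collapse = ", "))
    if (length(tp) == 1L) match(tp, tree$tip.label)
    else ape::getMRCA(tree, tp)
  }, 0L)
  m <- match(tree$edge[, 2L], child)
  if (anyNA(m)) stop("branch data rows do not match the tree's edges")
  branch_data(tree, tab$count[m], L)
}

# stable per-branch key: child tip label, or "tipA|tipB" spanning the child
branch_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  below <- tips_below(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  vapply(tree$edge[, 2L], function(c) {
    if (c <= ntip) return(tree$tip.label[c])
    kids <- children[[as.character(c)]]
    paste(tree$tip.label[which(below[[kids[1L]]])[1L]],
          tree$tip.label[which(below[[kids[2L]]])[1L]], sep = "|")
  }, "")
}

# Resolve calibrations to node ids; errors at configuration time.
resolve_calibrations <- function(tree, calibrations) {
  if (!length(calibrations)) {
    return(data.frame(name = character(), node = integer(),
                      min_age = numeric(), max_age = numeric()))
  }
  rows <- lapply(calibrations, function(cal) {
    missing <- setdiff(c(cal$tip_a, cal$tip_b), tree$tip.label)
    if (length(missing)) {
      stop("calibration '", cal$name, "': tip(s) not in tree: ",
           paste(missing, collapse = ", "))
    }
    node <- ape::getMRCA(tree, c(cal$tip_a, cal$tip_b))
    data.frame(name = cal$name, node = node,
               min_age = cal$min_age, max_age = cal$max_age)
  })
  out <- do.call(rbind, rows)
  # several calibrations on one node: intersect the bounds
  if (anyDuplicated(out$node)) {
    out <- do.call(rbind, lapply(split(out, out$node), function(g) {
      data.frame(name = paste(g$name, collapse = "+"), node = g$node[1L],
                 min_age = max(g$min_age), max_age = min(g$max_age))
    }))
    if (any(out$min_age >= out$max_age)) {
      bad <- out[out$min_age >= out$max_age, ]
      stop("contradictory calibrations on one node: ", bad$name[1L])
    }
  }
  rownames(out) <- NULL
  out
}

#' Joint log prior of a node-age configuration
#'
#' The prior is a truncated-normal density on the root age times a uniform
#' density over order-compatible internal ages given the root. The uniform
#' conditional is normalized: its support scales as `a_root^m` with
#' `m = (number of internal nodes) - 1`, contributing `-m * log(a_root)`.
#' (Normalizing the conditional makes the marginal prior of the root age
#' exactly the truncated normal, which is what the prior-recovery checks
#' sample directly.) Any parent-younger-than-child order violation or any
#' calibrated MRCA outside its hard bounds gives `-Inf`.
#'
#' @param tree rooted `phylo`.
#' @param ages numeric vector indexed by ape node id (tips must be 0).
#' @param prior a [root_prior()].
#' @param calibrations list of [calibration()] objects.
#' @return log prior density (up to a topology-dependent constant).
#' @export
log_prior <- function(tree, ages, prior, calibrations = list()) {
  ntip <- ape::Ntip(tree)
  if (any(ages[seq_len(ntip)] != 0)) return(-Inf)
  if (any(ages[tree$edge[, 1L]] < ages[tree$edge[, 2L]])) return(-Inf)
  cal <- resolve_calibrations(tree, calibrations)
  if (nrow(cal)) {
    a <- ages[cal$node]
    if (any(a < cal$min_age | a > cal$max_age)) return(-Inf)
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  m <- tree$Nnode - 1L
  root_prior_logpdf(ages[root], prior) - m * log(ages[root])
}

#' Poisson branch-count log likelihood
#'
#' `sum_b [ k_b log(e_b L) - e_b L - log(k_b!) ]` with
#' `e_b = r_bar_b * mu * dt_b` and the convention `0 * log 0 = 0`; a branch
#' with `e_b = 0` but `k_b > 0` gives `-Inf`.
#'
#' @param tree rooted `phylo`.
#' @param ages node ages (Ma) indexed by ape node id.
#' @param r_bar per-edge effective rate multipliers (tree edge order).
#' @param mu global rate (subst/site/Ma).
#' @param data a [branch_data()] object.
#' @return log likelihood.
#' @export
log_likelihood <- function(tree, ages, r_bar, mu, data) {
  dt <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  if (any(dt < 0)) return(-Inf)
  lam <- r_bar * mu * dt * attr(data, "L")
  k <- data$count
  if (any(lam == 0 & k > 0)) return(-Inf)
  term <- ifelse(k == 0, 0, k * log(lam))
  sum(term - lam - lgamma(k + 1))
}

#' Run the divergence-dating MCMC
#'
#' Metropolis-within-Gibbs sampler over internal node ages (uniform sliding
#' windows scaled to the local parent/child interval, reflected at the
#' bounds), branch rates (multiplicative log-normal proposals), the global
#' rate `mu`, the model hyperparameters, and a joint age/rate rescaling move
#' that decorrelates time scale from `mu`. Step sizes are tuned during
#' burn-in toward 20--50% acceptance and then frozen.
#'
#' @param tree rooted `phylo` (topology fixed).
#' @param data a [branch_data()] object (ignored when
#'   `config$use_likelihood` is `FALSE`, in which case it may be `NULL`).
#' @param config a [dating_config()].
#' @param calibrations list of [calibration()] objects.
#' @param prior a [root_prior()].
#' @return list of `chain_trace` matrices (one per chain): rows are retained
#'   samples; columns `age_<node>` for every internal node, `mu`, the model
#'   hyperparameters, and `logpost`. Attributes record the tree's internal
#'   node ids and the config.
#' @export
mcmc_run <- function(tree, data, config, calibrations = list(), prior) {
  stopifnot(inherits(config, "dating_config"), inherits(prior, "root_prior"))
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  cal <- resolve_calibrations(tree, calibrations)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  if (is.null(data)) {
    if (config$use_likelihood) stop("data required when use_likelihood=TRUE")
    data <- branch_data(tree, rep(0L, nrow(tree$edge)), 1)
  }
  bounds <- propagate_calibration_bounds(tree, cal)
  model_code <- match(config$model, c("UGAM", "LN", "CIR")) - 1L
  hyper_init <- switch(config$model,
    UGAM = config$nu_init, LN = config$sigma2_init,
    CIR = c(config$theta_init, config$sigma_init))
  hyper_names <- switch(config$model, UGAM = "nu", LN = "sigma2",
                        CIR = c("theta", "sigma"))
  cal_nodes <- if (nrow(cal)) cal$node else integer(0)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    ages0 <- initial_ages(tree, bounds, prior, root)
    res <- .Call(`_relclock_mcmc_counts`,
                 tree$edge - 1L, ntip, root - 1L,
                 as.numeric(data$count), as.numeric(attr(data, "L")),
                 model_code,
                 as.integer(cal_nodes - 1L),
                 as.numeric(if (nrow(cal)) cal$min_age else numeric(0)),
                 as.numeric(if (nrow(cal)) cal$max_age else numeric(0)),
                 as.numeric(prior$mean), as.numeric(prior$sd),
                 isTRUE(config$use_likelihood),
                 isTRUE(config$sample_hyper),
                 as.integer(config$chain_length),
                 as.integer(round(config$burnin_frac * config$chain_length)),
                 as.integer(config$thin),
                 ages0, as.numeric(config$mu_init), as.numeric(hyper_init),
                 as.numeric(config$mu_prior_mean),
                 as.numeric(config$hyper_prior_mean))
    samp <- res$samples
    internal <- sort(setdiff(seq_len(ntot), seq_len(ntip)))
    colnames(samp) <- c(paste0("age_", internal), "mu", hyper_names,
                        "logpost")
    attr(samp, "internal_nodes") <- internal
    attr(samp, "root_node") <- root
    attr(samp, "model") <- config$model
    attr(samp, "acceptance") <- res$acceptance
    class(samp) <- c("chain_trace", class(samp))
    chains[[ch]] <- samp
  }
  chains
}

# Hard-bound propagation: lb bottom-up, ub top-down. Errors name the
# offending calibrations when the system is infeasible.
propagate_calibration_bounds <- function(tree, cal) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  lb <- numeric(ntot)
  ub <- rep(Inf, ntot)
  lb_src <- rep(NA_character_, ntot)
  cmin <- rep(NA_real_, ntot); cmax <- rep(NA_real_, ntot)
  cname <- rep(NA_character_, ntot)
  if (nrow(cal)) {
    cmin[cal$node] <- cal$min_age
    cmax[cal$node] <- cal$max_age
    cname[cal$node] <- cal$name
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; c <- ord$edge[e, 2L]
    if (lb[c] > lb[p]) { lb[p] <- lb[c]; lb_src[p] <- lb_src[c] }
    if (!is.na(cmin[p]) && cmin[p] > lb[p]) {
      lb[p] <- cmin[p]; lb_src[p] <- cname[p]
    }
  }
  pre <- ape::reorder.phylo(tree, "cladewise")
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  if (!is.na(cmax[root])) ub[root] <- cmax[root]
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; c <- pre$edge[e, 2L]
    ub[c] <- min(ub[p], if (is.na(cmax[c])) Inf else cmax[c])
  }
  bad <- which(lb > ub)
  if (length(bad)) {
    v <- bad[1L]
    stop("contradictory calibrations: '", lb_src[v],
         "' forces a minimum age of ", lb[v], " Ma on a node capped at ",
         ub[v], " Ma by '", if (!is.na(cname[v])) cname[v] else "an ancestor",
         "'")
  }
  list(lb = lb, ub = ub)
}

# Valid, lightly randomized starting ages (top-down between propagated
# bounds; uses the chain's RNG stream).
initial_ages <- function(tree, bounds, prior, root) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  ages <- numeric(ntot)
  lb <- bounds$lb; ub <- bounds$ub
  target <- max(prior$mean, lb[root] * 1.2 + 1e-6)
  ages[root] <- if (is.finite(ub[root])) {
    lb[root] + stats::runif(1L, 0.4, 0.6) * (ub[root] - lb[root])
  } else max(target * stats::runif(1L, 0.8, 1.2), lb[root] * 1.05 + 1e-6)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; c <- pre$edge[e, 2L]
    if (c <= ntip) next
    hi <- min(ub[c], ages[p])
    ages[c] <- lb[c] + stats::runif(1L, 0.55, 0.9) * (hi - lb[c])
  }
  ages
}

#' Summarize posterior node ages
#'
#' Pools chains after discarding an optional extra burn-in fraction and
#' reports, per variable, the posterior mean and the 95% equal-tailed
#' interval (2.5 and 97.5 percentiles, linear interpolation).
#'
#' @param traces a `chain_trace` or list of them.
#' @param burn_in additional fraction of each chain to discard (the sampler
#'   has already dropped its configured burn-in).
#' @return data.frame with columns `variable`, `mean`, `lower`, `upper`.
#' @export
posterior_summary <- function(traces, burn_in = 0) {
  if (!is.list(traces)) traces <- list(traces)
  stopifnot(burn_in >= 0, burn_in < 1)
  pooled <- do.call(rbind, lapply(traces, function(tr) {
    tr <- unclass(tr)
    if (!nrow(tr)) return(tr)
    from <- floor(burn_in * nrow(tr)) + 1L
    tr[from:nrow(tr), , drop = FALSE]
  }))
  if (nrow(pooled) < 2L) stop("need at least 2 retained samples")
  qs <- apply(pooled, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  data.frame(variable = colnames(pooled), mean = colMeans(pooled),
             lower = qs[1L, ], upper = qs[2L, ], row.names = NULL)
}

#' Run the model-by-calibration-subset grid
#'
#' Runs one dating analysis per (rate model, calibration subset) cell and
#' reports posterior age summaries for a set of tracked clades. The default
#' subset enumeration follows the study design this pipeline emulates: with
#' calibrations organised into named groups (e.g. plant `P`, animal `A`,
#' fungal `F`), all `2^g` group subsets are run, from the empty set (root
#' prior only) through all groups combined.
#'
#' @param tree rooted `phylo`.
#' @param data a [branch_data()] object.
#' @param calibrations named list of [calibration()] objects.
#' @param groups named list mapping group name to calibration names;
#'   `NULL` puts every calibration in its own group.
#' @param models character vector of rate model tags.
#' @param config a [dating_config()] (its `model` field is overridden per
#'   cell; its `seed` seeds each cell deterministically).
#' @param prior a [root_prior()].
#' @param track named list of tip-label pairs whose MRCA ages are reported;
#'   defaults to every calibration's clade.
#' @return list with `summary` (data.frame: model, subset, clade, mean,
#'   lower, upper, plus per-cell convergence fields) and `failed`
#'   (data.frame of cells whose run errored, with the message).
#' @export
run_model_grid <- function(tree, data, calibrations, groups = NULL,
                           models = c("UGAM", "LN", "CIR"), config, prior,
                           track = NULL) {
  if (is.null(names(calibrations))) {
    names(calibrations) <- vapply(calibrations, `[[`, "", "name")
  }
  if (is.null(groups)) {
    groups <- as.list(stats::setNames(names(calibrations),
                                      names(calibrations)))
  }
  subsets <- enumerate_subsets(groups)
  if (is.null(track)) {
    track <- lapply(calibrations, function(cal) c(cal$tip_a, cal$tip_b))
  }
  track_nodes <- vapply(track, function(tp) ape::getMRCA(tree, tp), 0L)

  rows <- list(); failed <- list(); cell <- 0L
  for (model in models) {
    for (s in seq_along(subsets)) {
      cell <- cell + 1L
      cfg <- config
      cfg$model <- model
      cfg$seed <- config$seed + 1000L * cell
      cals <- calibrations[subsets[[s]]]
      res <- tryCatch({
        traces <- mcmc_run(tree, data, cfg, cals, prior)
        conv <- convergence_report(traces)
        summ <- posterior_summary(traces)
        lapply(seq_along(track_nodes), function(i) {
          v <- paste0("age_", track_nodes[i])
          r <- summ[summ$variable == v, ]
          data.frame(model = model, subset = names(subsets)[s],
                     clade = names(track)[i], node = track_nodes[i],
                     mean = r$mean, lower = r$lower, upper = r$upper,
                     converged = conv$pass, min_ess = min(conv$table$ess),
                     max_discrepancy = max(conv$table$discrepancy))
        })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed[[length(failed) + 1L]] <-
          data.frame(model = model, subset = names(subsets)[s],
                     message = conditionMessage(res))
      } else {
        rows <- c(rows, res)
      }
    }
  }
  list(summary = do.call(rbind, rows),
       failed = if (length(failed)) do.call(rbind, failed) else
         data.frame(model = character(), subset = character(),
                    message = character()),
       subsets = subsets)
}

# all subsets of the named groups; "none" for the empty set, group names
# concatenated otherwise ({} first, full set last)
enumerate_subsets <- function(groups) {
  g <- names(groups)
  idx <- expand.grid(rep(list(c(FALSE, TRUE)), length(g)))
  ord <- order(rowSums(idx))
  idx <- idx[ord, , drop = FALSE]
  subsets <- lapply(seq_len(nrow(idx)), function(i) {
    unlist(groups[g[unlist(idx[i, ])]], use.names = FALSE)
  })
  names(subsets) <- vapply(seq_len(nrow(idx)), function(i) {
    on <- g[unlist(idx[i, ])]
    if (!length(on)) "none" else paste(on, collapse = "+")
  }, "")
  subsets
}
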