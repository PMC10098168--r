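#' Simulation scenario
#'
#' The stated world for the synthetic generators: a Yule time-tree of
#' `n_tips` with the given crown age, branch rates from one of the three
#' rate models, Poisson substitution counts at global rate `mu` over an
#' alignment of `L` sites, and `n_calibrations` fossil calibrations whose
#' reported intervals bracket the true node ages (optionally shifted to
#' inject bias). Defaults mirror the parameter-recovery design used
#' throughout the test-suite: 20 tips, 2000 Ma crown age, UGAM with
#' nu = 0.3, mu = 1e-3 subst/site/Ma, L = 2000 sites, 3 accurate
#' calibrations spanning +/-10% of the true age.
#'
#' @param n_tips number of tips (>= 2).
#' @param crown_age root age in Ma (> 0).
#' @param model,nu,sigma2,theta,sigma,mu rate model and parameters, see
#'   [rate_model_params()].
#' @param L alignment length in sites.
#' @param n_calibrations how many internal nodes receive calibrations.
#' @param calibration_halfwidth half-width of the reported fossil interval
#'   as a fraction of the true age.
#' @param calibration_bias shift of the reported interval as a fraction of
#'   the true age (positive = biased old).
#' @param root_prior_bounds `c(old, young)` Ma for the root prior.
#' @param seed integer seed; every generated product is a deterministic
#'   function of (scenario, seed).
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_tips = 20L, crown_age = 2000,
                                model = "UGAM", nu = 0.3, sigma2 = 0.1,
                                theta = 1, sigma = 0.5, mu = 1e-3,
                                L = 2000, n_calibrations = 3L,
                                calibration_halfwidth = 0.1,
                                calibration_bias = 0,
                                root_prior_bounds = c(3800, 800),
                                seed = 1L) {
  stopifnot(n_tips >= 2L, crown_age > 0, L >= 0, n_calibrations >= 0)
  params <- rate_model_params(model, nu = nu, sigma2 = sigma2,
                              theta = theta, sigma = sigma, mu = mu)
  structure(list(n_tips = as.integer(n_tips), crown_age = crown_age,
                 params = params, L = L,
                 n_calibrations = as.integer(n_calibrations),
                 calibration_halfwidth = calibration_halfwidth,
                 calibration_bias = calibration_bias,
                 root_prior_bounds = root_prior_bounds,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Simulate an ultrametric Yule time-tree
#'
#' Pure-birth tree conditioned on the number of tips, with the root (crown)
#' age rescaled to `crown_age`; all tips sit at age 0. At every speciation
#' event a uniformly chosen extant lineage splits (Yule exchangeability), so
#' ranked topologies have the uniform Yule distribution.
#'
#' @param n_tips number of tips.
#' @param crown_age crown age in Ma.
#' @param seed optional integer seed.
#' @return rooted ultrametric `phylo`, tip labels `t1..tn`; edge lengths are
#'   durations in Ma.
#' @export
simulate_time_tree <- function(n_tips, crown_age, seed = NULL) {
  stopifnot(n_tips >= 2L, crown_age > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  # event j (j = 1..n-1) splits one of j extant lineages; after the last
  # event an Exp(n) stub runs to the present, then everything is rescaled
  waits <- stats::rexp(n - 1L, rate = seq(2L, n))   # after events 1..n-1
  times <- c(0, cumsum(waits))                      # event times, + present
  present <- times[n]
  scale <- crown_age / present
  edges <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  elen <- numeric(2L * n - 2L)
  nedge <- 0L
  # active lineages: parent node id and start time
  act_parent <- NA_integer_
  act_start <- 0
  for (j in seq_len(n - 1L)) {
    pick <- if (j == 1L) 1L else sample.int(length(act_parent), 1L)
    node <- n + j                                   # ape internal id
    if (!is.na(act_parent[pick])) {
      nedge <- nedge + 1L
      edges[nedge, ] <- c(act_parent[pick], node)
      elen[nedge] <- times[j] - act_start[pick]
    }
    act_parent <- c(act_parent[-pick], node, node)
    act_start <- c(act_start[-pick], times[j], times[j])
  }
  for (i in seq_len(n)) {                           # tips, in active order
    nedge <- nedge + 1L
    edges[nedge, ] <- c(act_parent[i], i)
    elen[nedge] <- present - act_start[i]
  }
  tr <- structure(list(edge = edges, edge.length = elen * scale,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate per-branch substitution counts
#'
#' Generative twin of the dating likelihood: independent
#' `k_b ~ Poisson(r_bar_b * mu * dt_b * L)` per branch.
#'
#' @param tree chronogram (`phylo`, durations in Ma).
#' @param rates a `rate_assignment` from [simulate_rates()] (edge order must
#'   match the tree).
#' @param mu global rate (subst/site/Ma).
#' @param L alignment length in sites (`L = 0` gives all-zero counts).
#' @param seed optional integer seed.
#' @return a [branch_data()] object.
#' @export
simulate_branch_counts <- function(tree, rates, mu, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(rates) == nrow(tree$edge))
  lam <- rates$r_bar * mu * tree$edge.length * L
  k <- stats::rpois(length(lam), lam)
  if (L > 0) {
    branch_data(tree, k, L)
  } else {
    out <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                      count = 0L)
    attr(out, "L") <- 0
    attr(out, "tree") <- tree
    class(out) <- c("branch_data", class(out))
    out
  }
}

#' Plant a taxonomy with monophyletic blocks and HGT nestings
#'
#' Assigns genus/order/class/phylum/domain labels to a tree's tips so that
#' requested blocks are monophyletic at the order (and phylum) level, and
#' optional HGT nestings place a labelled eukaryote sub-clade inside a
#' larger bacteria-labelled clade. Background tips get unique rank values.
#'
#' @param tree rooted `phylo`.
#' @param block_sizes integer vector: one planted monophyletic block per
#'   entry, of exactly that tip count. Blocks are chosen among the tree's
#'   clades, disjointly; an error is raised if no disjoint assignment
#'   exists.
#' @param hgt_nestings number of HGT nestings to plant (host clade labelled
#'   Bacteria with a nested sub-clade labelled Eukaryota, host at least
#'   3x+1 the nested size so the host keeps a >2/3 bacterial majority).
#' @param seed optional integer seed.
#' @return list with `annotations` (data.frame) and `truth` (planted block
#'   and nesting records: rank value, node id, tip labels).
#' @export
make_taxonomy_fixture <- function(tree, block_sizes = integer(0),
                                  hgt_nestings = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  below <- tips_below(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  clade_size <- vapply(internal, function(v) sum(below[[v]]), 0L)
  used <- logical(ntip)
  ann <- data.frame(tip_label = tree$tip.label,
                    genus = paste0("Genus_", seq_len(ntip)),
                    order = paste0("BgOrder_", seq_len(ntip)),
                    class = paste0("BgClass_", seq_len(ntip)),
                    phylum = paste0("BgPhylum_", seq_len(ntip)),
                    domain = "Bacteria",
                    stringsAsFactors = FALSE)
  blocks <- list()
  take_clade <- function(size_ok) {
    cand <- internal[size_ok(clade_size)]
    cand <- cand[vapply(cand, function(v) !any(used[below[[v]]]), TRUE)]
    if (!length(cand)) return(NA_integer_)
    if (length(cand) > 1L) sample(cand, 1L) else cand
  }
  for (i in seq_along(block_sizes)) {
    v <- take_clade(function(s) s == block_sizes[i])
    if (is.na(v)) {
      stop("infeasible placement: no free clade of size ", block_sizes[i])
    }
    tips <- which(below[[v]])
    used[tips] <- TRUE
    ann$order[tips] <- paste0("Order_", i)
    ann$phylum[tips] <- paste0("Phylum_", i)
    blocks[[i]] <- list(kind = "block", rank = "order",
                        value = paste0("Order_", i), node = v,
                        tips = tree$tip.label[tips])
  }
  nestings <- list()
  for (j in seq_len(hgt_nestings)) {
    placed <- FALSE
    hosts <- internal[vapply(internal, function(v) {
      !any(used[below[[v]]]) && sum(below[[v]]) >= 7L
    }, TRUE)]
    for (host in (if (length(hosts)) sample(hosts) else integer(0))) {
      htips <- which(below[[host]])
      hsize <- length(htips)
      # nested candidates: clades strictly inside the host, small enough
      subs <- internal[vapply(internal, function(u) {
        su <- below[[u]]
        sum(su) >= 2L && all(which(su) %in% htips) && sum(su) < hsize &&
          hsize >= 3L * sum(su) + 1L
      }, TRUE)]
      if (!length(subs)) next
      u <- if (length(subs) > 1L) sample(subs, 1L) else subs
      utips <- which(below[[u]])
      used[htips] <- TRUE
      ann$phylum[htips] <- paste0("HostPhylum_", j)
      ann$domain[htips] <- "Bacteria"
      ann$domain[utips] <- "Eukaryota"
      ann$phylum[utips] <- paste0("EukPhylum_", j)
      nestings[[j]] <- list(kind = "hgt", host_node = host, nested_node = u,
                            host_tips = tree$tip.label[htips],
                            nested_tips = tree$tip.label[utips])
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible placement: no host clade for HGT nesting")
  }
  list(annotations = ann, truth = list(blocks = blocks, hgt = nestings))
}

#' Alignment fixture with planted QC violations
#'
#' Background columns are drawn uniformly over the 20 amino acids; the
#' catalytic-triad columns are fixed to Glu/Lys/Cys except in planted
#' gap-violator sequences; planted insertion violators carry a private
#' residue run of the stated length where every other sequence is gapped.
#'
#' @param n_seqs number of sequences.
#' @param width alignment width before insertions are carved out.
#' @param triad_cols three distinct site columns (1-based).
#' @param n_triad_violators sequences given a gap at a triad column.
#' @param n_insertion_violators sequences given a private insertion.
#' @param insertion_len insertion length in residues.
#' @param seed optional integer seed.
#' @return list with `alignment` (an [alignment_matrix()]) and `truth`
#'   (`triad_violators`, `insertion_violators`).
#' @export
make_alignment_fixture <- function(n_seqs = 50L, width = 120L,
                                   triad_cols = c(20L, 60L, 100L),
                                   n_triad_violators = 0L,
                                   n_insertion_violators = 0L,
                                   insertion_len = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_triad_violators + n_insertion_violators <= n_seqs,
            all(triad_cols <= width), length(triad_cols) == 3L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  m <- matrix(sample(aa, n_seqs * width, replace = TRUE), nrow = n_seqs)
  rownames(m) <- sprintf("seq%03d", seq_len(n_seqs))
  m[, triad_cols[1L]] <- "E"
  m[, triad_cols[2L]] <- "K"
  m[, triad_cols[3L]] <- "C"
  viol <- sample.int(n_seqs, n_triad_violators + n_insertion_violators)
  triad_ids <- viol[seq_len(n_triad_violators)]
  ins_ids <- setdiff(viol, triad_ids)
  for (i in triad_ids) {
    m[i, sample(triad_cols, 1L)] <- "-"
  }
  # non-overlapping insertion windows, clear of the triad +/- 2 columns
  forbidden <- unique(as.integer(outer(triad_cols, -2:2, `+`)))
  free_start <- setdiff(seq_len(width - insertion_len + 1L),
                        unique(as.integer(outer(forbidden,
                                                0:(insertion_len - 1L),
                                                `-`))))
  starts <- integer(0)
  for (i in ins_ids) {
    ok <- free_start[vapply(free_start, function(s) {
      !any(abs(s - starts) < insertion_len + 2L)
    }, TRUE)]
    if (!length(ok)) stop("alignment too narrow for requested insertions")
    s <- if (length(ok) > 1L) sample(ok, 1L) else ok
    starts <- c(starts, s)
    cols <- s:(s + insertion_len - 1L)
    m[, cols] <- "-"
    m[i, cols] <- sample(aa, insertion_len, replace = TRUE)
  }
  list(alignment = alignment_matrix(m),
       truth = list(triad_violators = sort(rownames(m)[triad_ids]),
                    insertion_violators = sort(rownames(m)[ins_ids])))
}

#' Hit-table fixture straddling a filter profile
#'
#' Generates hits with known pass/fail labels: passing hits clear every
#' threshold by at least `margin` (in the unit of each rule), and each
#' failing hit violates exactly one rule by at most `margin`, so per-rule
#' rejection counts are unambiguous.
#'
#' @param n number of hits.
#' @param profile a [filter_profile()].
#' @param margin positive threshold offset (percent points for
#'   identity/coverage, residues for length, decades for the E-value).
#' @param seed optional integer seed.
#' @return list with `hits` (data.frame) and `truth` (`retained` ids,
#'   `rejections` named counts).
#' @export
make_hits_fixture <- function(n = 100L, profile, margin = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(margin > 0)
  modes <- c("pass", "identity", "coverage", "evalue", "length", "partial")
  if (profile$min_identity <= 0) modes <- setdiff(modes, "identity")
  if (profile$min_coverage <= 0) modes <- setdiff(modes, "coverage")
  lo <- profile$length_range[1L]; hi <- profile$length_range[2L]
  mid <- if (is.finite(hi)) (lo + hi) / 2 else lo + 100
  mode <- sample(modes, n, replace = TRUE)
  u <- stats::runif(n, 0.1, 1)
  id <- pmin(100, profile$min_identity + margin * u)
  cov <- pmin(100, profile$min_coverage + margin * u)
  ev <- profile$max_evalue * 10^(-1 - 3 * u)
  len <- round(mid + (u - 0.5) * (if (is.finite(hi)) (hi - lo) / 4 else 50))
  part <- rep(FALSE, n)
  fail_id <- mode == "identity"
  id[fail_id] <- profile$min_identity - margin * u[fail_id]
  fail_cov <- mode == "coverage"
  cov[fail_cov] <- profile$min_coverage - margin * u[fail_cov]
  fail_ev <- mode == "evalue"
  ev[fail_ev] <- profile$max_evalue * (1 + u[fail_ev])
  fail_len <- mode == "length"
  low_side <- stats::runif(n) < 0.5 | !is.finite(hi)
  len[fail_len & low_side] <- round(lo - 1 - margin * u[fail_len & low_side])
  if (is.finite(hi)) {
    len[fail_len & !low_side] <-
      round(hi + 1 + margin * u[fail_len & !low_side])
  }
  part[mode == "partial"] <- TRUE
  hits <- data.frame(
    query = "q1",
    subject = sprintf("hit%04d", seq_len(n)),
    identity = round(id, 2), coverage = round(cov, 2),
    evalue = signif(ev, 4), length = len,
    organism = sprintf("Genus%03d species", sample.int(max(2L, n %/% 3L),
                                                       n, replace = TRUE)),
    partial = part, stringsAsFactors = FALSE)
  rej <- vapply(c("identity", "coverage", "evalue", "length", "partial"),
                function(r) sum(mode == r), 0L)
  list(hits = hits,
       truth = list(retained = hits$subject[mode == "pass"],
                    n_retained = sum(mode == "pass"), rejections = rej))
}

#' Build a complete synthetic dataset on disk
#'
#' Composes the generators into one directory that the full pipeline
#' (qc, root, date, diagnose, cv) can consume: a true chronogram, an
#' unrooted gene tree with substitutions/site branch lengths
#' (`k_b / (L * dt)` smoothed through the true counts), per-branch counts,
#' taxon annotations, calibrations (accurate up to the scenario's stated
#' half-width and bias), and a machine-readable truth manifest.
#'
#' @param scenario a [simulation_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`tree`, `rates`,
#'   `counts`, `annotations`, `calibrations`, `prior`, `truth`) and `paths`.
#' @export
build_end_to_end_dataset <- function(scenario, dir) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(scenario$seed)
  tree <- simulate_time_tree(scenario$n_tips, scenario$crown_age)
  ages <- node_ages(tree)
  rates <- simulate_rates(tree, scenario$params)
  counts <- simulate_branch_counts(tree, rates, scenario$params$mu,
                                   scenario$L)
  # unrooted gene tree in subst/site for MAD rooting
  gene <- tree
  gene$edge.length <- (counts$count + 0.5) / max(scenario$L, 1)
  gene <- ape::unroot(gene)

  ntip <- ape::Ntip(tree)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  internal <- setdiff(seq_len(ntip + tree$Nnode), c(seq_len(ntip), root))
  cals <- list()
  if (scenario$n_calibrations > 0L && length(internal)) {
    ord <- internal[order(ages[internal])]
    pick <- unique(ord[round(seq(1L, length(ord),
                                 length.out = scenario$n_calibrations))])
    below <- tips_below(tree)
    children <- split(tree$edge[, 2L], tree$edge[, 1L])
    for (i in seq_along(pick)) {
      v <- pick[i]
      kids <- children[[as.character(v)]]
      ta <- tree$tip.label[which(below[[kids[1L]]])[1L]]
      tb <- tree$tip.label[which(below[[kids[2L]]])[1L]]
      true_age <- ages[v]
      centre <- true_age * (1 + scenario$calibration_bias)
      half <- scenario$calibration_halfwidth * true_age
      cals[[i]] <- calibration(paste0("cal", i), ta, tb,
                               min_age = centre - half,
                               max_age = centre + half)
    }
    names(cals) <- vapply(cals, `[[`, "", "name")
  }
  prior <- root_prior(scenario$root_prior_bounds[1L],
                      scenario$root_prior_bounds[2L])
  tax <- taxonomy_for_tree(tree)

  paths <- list(
    chronogram = file.path(dir, "chronogram.nwk"),
    gene_tree = file.path(dir, "gene_tree.nwk"),
    counts = file.path(dir, "counts.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    calibrations = file.path(dir, "calibrations.json"),
    truth = file.path(dir, "truth.json"))
  write_newick(tree, paths$chronogram)
  write_newick(gene, paths$gene_tree)
  write_branch_data(counts, paths$counts)
  write_annotations(tax$annotations, paths$annotations)
  write_calibrations(cals, paths$calibrations)
  truth <- list(
    root_age = ages[root],
    node_ages = as.list(stats::setNames(
      ages[c(root, internal)], paste0("age_", c(root, internal)))),
    mu = scenario$params$mu, model = scenario$params$model,
    L = scenario$L,
    calibration_true_ages = if (length(cals)) {
      stats::setNames(lapply(names(cals), function(nm) {
        ages[ape::getMRCA(tree, c(cals[[nm]]$tip_a, cals[[nm]]$tip_b))]
      }), names(cals))
    } else list(),
    root_prior = scenario$root_prior_bounds,
    seed = scenario$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, rates = rates, counts = counts,
                 annotations = tax$annotations, calibrations = cals,
                 prior = prior, truth = truth, paths = paths))
}

# adaptive taxonomy: plant blocks in up to two free clades of size 3..6
taxonomy_for_tree <- function(tree) {
  ntip <- ape::Ntip(tree)
  below <- tips_below(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  sizes <- vapply(internal, function(v) sum(below[[v]]), 0L)
  want <- sizes[sizes >= 3L & sizes <= 6L]
  bs <- utils::head(sort(want, decreasing = TRUE), 2L)
  out <- try(make_taxonomy_fixture(tree, block_sizes = bs), silent = TRUE)
  if (inherits(out, "try-error")) {
    out <- make_taxonomy_fixture(tree, block_sizes = integer(0))
  }
  out
}

#' Read / write calibrations as JSON
#'
#' @param calibrations named list of [calibration()] objects.
#' @param file JSON path.
#' @export
write_calibrations <- function(calibrations, file) {
  jsonlite::write_json(lapply(unname(calibrations), unclass), file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_calibrations
#' @export
read_calibrations <- function(file) {
  raw <- jsonlite::read_json(file)
  cals <- lapply(raw, function(x) {
    calibration(x$name, x$tip_a, x$tip_b, x$min_age, x$max_age)
  })
  names(cals) <- vapply(cals, `[[`, "", "name")
  cals
}
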