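make_fixture_tree <- function(n = 8, crown = 2000, seed = 5) {
  simulate_time_tree(n, crown, seed = seed)
}

test_that("root_prior derives mean and sd from the interval", {
  pr <- root_prior(3800, 800)
  expect_equal(pr$mean, 2300)
  expect_equal(pr$sd, 750)
  # at the mode the truncated-normal log-pdf is the normal log-pdf up to
  # the (tiny) truncation constant
  expect_equal(root_prior_logpdf(2300, pr), dnorm(2300, 2300, 750, log = TRUE),
               tolerance = 1e-2)
  expect_equal(root_prior_logpdf(-5, pr), -Inf)
  expect_error(root_prior(800, 3800))
})

test_that("log_prior enforces order and hard calibration bounds", {
  tr <- make_fixture_tree()
  ages <- node_ages(tr)
  pr <- root_prior(3800, 800)
  expect_true(is.finite(log_prior(tr, ages, pr)))

  # child older than parent
  bad <- ages
  child <- tr$edge[which(tr$edge[, 2] > ape::Ntip(tr))[1], 2]
  bad[child] <- ages[tr$edge[tr$edge[, 2] == child, 1]] + 10
  expect_equal(log_prior(tr, bad, pr), -Inf)

  # calibrated MRCA outside its bounds: plant-style 750-590 window
  cal <- calibration("plant", "t1", "t2", 590, 750)
  node <- ape::getMRCA(tr, c("t1", "t2"))
  a2 <- ages
  sc <- 800 / ages[node]
  a2[(ape::Ntip(tr) + 1):length(ages)] <-
    a2[(ape::Ntip(tr) + 1):length(ages)] * sc   # MRCA moved to 800 Ma
  expect_equal(log_prior(tr, a2, pr, list(cal)), -Inf)
  # inside bounds: finite
  a3 <- ages
  a3[(ape::Ntip(tr) + 1):length(ages)] <-
    a3[(ape::Ntip(tr) + 1):length(ages)] * (650 / ages[node])
  expect_true(is.finite(log_prior(tr, a3, pr, list(cal))))
  # missing tip fails at configuration time
  expect_error(log_prior(tr, ages, pr,
                         list(calibration("x", "t1", "zz", 1, 2))),
               "zz")
})

test_that("log_likelihood matches the Poisson pmf oracle", {
  tr <- make_fixture_tree()
  ages <- node_ages(tr)
  # zero counts with zero expectation contribute zero
  z <- branch_data(tr, rep(0, nrow(tr$edge)), L = 100)
  expect_equal(log_likelihood(tr, ages, rep(0, nrow(tr$edge)), 0, z), 0)
  # single-branch arithmetic: k = 3, e*L = 3
  expect_equal(log_pois_oracle(3, 3), 3 * log(3) - 3 - log(6))
  # random cases against the library-free oracle
  set.seed(10)
  for (i in 1:100) {
    rbar <- runif(nrow(tr$edge), 0.2, 3)
    mu <- runif(1, 1e-4, 5e-3)
    L <- sample(500:3000, 1)
    k <- rpois(nrow(tr$edge), 2)
    bd <- branch_data(tr, k, L)
    lam <- rbar * mu * (ages[tr$edge[, 1]] - ages[tr$edge[, 2]]) * L
    want <- sum(mapply(log_pois_oracle, k, lam))
    expect_equal(log_likelihood(tr, ages, rbar, mu, bd), want,
                 tolerance = 1e-10)
  }
  # positive count on a zero-length expectation is impossible
  k1 <- rep(0, nrow(tr$edge)); k1[1] <- 2
  expect_equal(log_likelihood(tr, ages, rep(1, nrow(tr$edge)), 0,
                              branch_data(tr, k1, 100)), -Inf)
})

test_that("posterior_summary quantile arithmetic", {
  tr <- matrix(rep(1000, 50), ncol = 1, dimnames = list(NULL, "age_9"))
  s <- posterior_summary(tr)
  expect_equal(s$mean, 1000)
  expect_equal(s$lower, 1000)
  expect_equal(s$upper, 1000)

  tr2 <- matrix(1:1000, ncol = 1, dimnames = list(NULL, "x"))
  s2 <- posterior_summary(tr2)
  expect_equal(s2$mean, 500.5)
  expect_equal(s2$lower, 25.975)
  expect_equal(s2$upper, 975.025)

  # pooling equals concatenation
  a <- matrix(1:100, ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(901:1000, ncol = 1, dimnames = list(NULL, "x"))
  s3 <- posterior_summary(list(a, b))
  s4 <- posterior_summary(matrix(c(1:100, 901:1000), ncol = 1,
                                 dimnames = list(NULL, "x")))
  expect_equal(s3, s4)
  expect_error(posterior_summary(a[0, , drop = FALSE]), "2 retained")
})

test_that("mcmc_run is deterministic under a fixed seed", {
  tr <- make_fixture_tree()
  scen <- simulation_scenario(n_tips = 8, seed = 5)
  b <- build_end_to_end_dataset(scen, tempfile())
  cfg <- dating_config("UGAM", chain_length = 1500, thin = 5,
                       n_chains = 2, seed = 42)
  t1 <- mcmc_run(b$tree, b$counts, cfg, b$calibrations, b$prior)
  t2 <- mcmc_run(b$tree, b$counts, cfg, b$calibrations, b$prior)
  expect_identical(t1, t2)
  expect_false(identical(unclass(t1[[1]]), unclass(t1[[2]])))
})

test_that("every retained sample is order-valid and within bounds", {
  scen <- simulation_scenario(n_tips = 10, seed = 9)
  b <- build_end_to_end_dataset(scen, tempfile())
  for (m in c("UGAM", "LN", "CIR")) {
    cfg <- dating_config(m, chain_length = 2000, thin = 4, n_chains = 1,
                         seed = 7)
    tr <- mcmc_run(b$tree, b$counts, cfg, b$calibrations, b$prior)[[1]]
    internal <- attr(tr, "internal_nodes")
    ages <- unclass(tr)[, paste0("age_", internal)]
    # parent >= child on every edge, every sample
    for (e in seq_len(nrow(b$tree$edge))) {
      p <- b$tree$edge[e, 1]; c <- b$tree$edge[e, 2]
      ap <- ages[, paste0("age_", p)]
      ac <- if (c <= ape::Ntip(b$tree)) 0 else ages[, paste0("age_", c)]
      expect_true(all(ap >= ac))
    }
    for (cl in b$calibrations) {
      node <- ape::getMRCA(b$tree, c(cl$tip_a, cl$tip_b))
      a <- ages[, paste0("age_", node)]
      expect_true(all(a >= cl$min_age & a <= cl$max_age))
    }
    expect_true(all(is.finite(unclass(tr)[, "logpost"])))
  }
})

test_that("contradictory calibrations error names the offenders", {
  tr <- make_fixture_tree(10, 2000, seed = 21)
  # nested nodes: force child min above ancestor max
  below <- relclock:::tips_below(tr)
  internal <- 11:19
  sizes <- sapply(internal, function(v) sum(below[[v]]))
  v <- internal[order(-sizes)][2]          # a deep non-root node
  parent <- relclock:::node_parents(tr)[v]
  ch <- split(tr$edge[, 2], tr$edge[, 1])
  span_pair <- function(node) {
    kids <- ch[[as.character(node)]]
    c(tr$tip.label[which(below[[kids[1]]])[1]],
      tr$tip.label[which(below[[kids[2]]])[1]])
  }
  vt <- span_pair(v)
  pt <- span_pair(parent)
  deep <- calibration("deep_min", vt[1], vt[2], 900, 1000)
  shallow <- calibration("anc_max", pt[1], pt[2], 100, 500)
  cfg <- dating_config("UGAM", chain_length = 100, n_chains = 1, seed = 1,
                       use_likelihood = FALSE)
  expect_error(
    mcmc_run(tr, NULL, cfg, list(deep, shallow), root_prior(3800, 800)),
    "deep_min.*anc_max")
})

test_that("run_model_grid enumerates 8 subsets x 3 models", {
  scen <- simulation_scenario(n_tips = 8, seed = 4)
  b <- build_end_to_end_dataset(scen, tempfile())
  groups <- list(P = "cal1", A = "cal2", F = "cal3")
  cfg <- dating_config(chain_length = 400, thin = 4, n_chains = 1,
                       seed = 11)
  g <- run_model_grid(b$tree, b$counts, b$calibrations, groups = groups,
                      config = cfg, prior = b$prior)
  expect_length(g$subsets, 8)
  expect_equal(names(g$subsets)[1], "none")
  expect_setequal(g$subsets[["P+A+F"]], c("cal1", "cal2", "cal3"))
  cells <- unique(g$summary[c("model", "subset")])
  expect_equal(nrow(cells), 24)
  expect_equal(nrow(g$failed), 0)

  # the empty subset equals a standalone run with the cell's derived seed
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1000L; cfg1$model <- "UGAM"
  solo <- mcmc_run(b$tree, b$counts, cfg1, list(), b$prior)
  ssolo <- posterior_summary(solo)
  cal1 <- b$calibrations[["cal1"]]
  node1 <- ape::getMRCA(b$tree, c(cal1$tip_a, cal1$tip_b))
  grow <- g$summary[g$summary$model == "UGAM" &
                      g$summary$subset == "none" &
                      g$summary$node == node1, ][1, ]
  srow <- ssolo[ssolo$variable == paste0("age_", node1), ]
  expect_equal(grow$mean, srow$mean)
  expect_equal(grow$lower, srow$lower)
})

test_that("a true-containing calibration narrows its node's interval (majority of seeds)", {
  narrower <- 0
  for (s in 1:10) {
    scen <- simulation_scenario(n_tips = 8, seed = 40 + s)
    b <- build_end_to_end_dataset(scen, tempfile())
    cal <- b$calibrations["cal1"]
    node <- ape::getMRCA(b$tree, c(cal[[1]]$tip_a, cal[[1]]$tip_b))
    widths <- sapply(list(list(), cal), function(cs) {
      cfg <- dating_config("UGAM", chain_length = 4000, thin = 5,
                           n_chains = 1, seed = 90 + s)
      tr <- mcmc_run(b$tree, b$counts, cfg, cs, b$prior)
      r <- posterior_summary(tr)
      r <- r[r$variable == paste0("age_", node), ]
      r$upper - r$lower
    })
    narrower <- narrower + (widths[2] <= widths[1])
  }
  expect_gt(narrower, 5)
})
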