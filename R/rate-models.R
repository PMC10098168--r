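#' Branch-rate model parameters
#'
#' Container for the three relaxed-clock rate processes compared by the
#' pipeline, all in a mean-1 multiplier convention with a separate global
#' rate `mu` (substitutions/site/Ma):
#'
#' * `UGAM` — uncorrelated gamma multipliers: each branch draws an
#'   independent Gamma(shape = 1/nu, scale = nu) multiplier (mean 1,
#'   variance `nu`).
#' * `LN` — autocorrelated lognormal (geometric Brownian motion): the log
#'   rate evolves by Brownian motion in time with variance `sigma2` per Ma
#'   and drift `-sigma2/2`, so the rate itself is a martingale
#'   (E\[r_child | r_parent\] = r_parent).
#' * `CIR` — mean-reverting square-root diffusion
#'   dr = theta (1 - r) dt + sigma sqrt(r) dW, with stationary mean 1 and
#'   variance sigma^2 / (2 theta). The Feller condition
#'   2 theta > sigma^2 is enforced so paths stay strictly positive.
#'
#' @param model one of `"UGAM"`, `"LN"`, `"CIR"`.
#' @param nu UGAM multiplier variance (> 0).
#' @param sigma2 LN Brownian variance per Ma (>= 0).
#' @param theta CIR reversion strength (> 0).
#' @param sigma CIR diffusion coefficient (> 0).
#' @param mu global rate in substitutions/site/Ma (> 0).
#' @return object of class `rate_model_params`.
#' @export
rate_model_params <- function(model = c("UGAM", "LN", "CIR"),
                              nu = 0.3, sigma2 = 5e-4,
                              theta = 0.01, sigma = 0.1, mu = 1e-3) {
  model <- match.arg(model)
  stopifnot(mu > 0)
  if (model == "UGAM" && nu <= 0) stop("UGAM requires nu > 0")
  if (model == "LN" && sigma2 < 0) stop("LN requires sigma2 >= 0")
  if (model == "CIR") {
    if (theta <= 0 || sigma <= 0) stop("CIR requires theta > 0 and sigma > 0")
    if (2 * theta <= sigma^2) {
      stop("CIR parameters violate the Feller condition 2*theta > sigma^2")
    }
  }
  structure(list(model = model, nu = nu, sigma2 = sigma2,
                 theta = theta, sigma = sigma, mu = mu),
            class = "rate_model_params")
}

#' Simulate branch rates on a chronogram
#'
#' Draws a rate assignment for every branch of an ultrametric time-tree.
#' For the autocorrelated models (LN, CIR) an instantaneous rate is attached
#' to every node (root rate fixed at 1 by convention) and the branch
#' effective rate is the arithmetic mean of its endpoint rates; for UGAM each
#' branch draws an independent multiplier which is itself the effective rate.
#'
#' @param tree rooted `phylo` whose edge lengths are durations in Ma.
#' @param params a [rate_model_params()] object.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame of class `rate_assignment` with one row per edge (in
#'   the tree's edge order): `parent`, `child`, `duration`, `r_parent`,
#'   `r_child`, `r_bar`. For UGAM `r_parent`/`r_child` are both the branch
#'   multiplier. Attribute `node_rates` carries the per-node rates
#'   (LN/CIR).
#' @export
simulate_rates <- function(tree, params, seed = NULL) {
  stopifnot(inherits(params, "rate_model_params"))
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  nedge <- nrow(tree$edge)
  dur <- tree$edge.length
  model <- params$model

  if (model == "UGAM") {
    r_b <- stats::rgamma(nedge, shape = 1 / params$nu, scale = params$nu)
    out <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                      duration = dur, r_parent = r_b, r_child = r_b,
                      r_bar = r_b)
    node_rates <- NULL
  } else {
    node_rates <- rep(NA_real_, ntot)
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
    node_rates[root] <- 1
    ord <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    for (e in seq_len(nedge)) {
      p <- ord$edge[e, 1L]
      c <- ord$edge[e, 2L]
      dt <- ord$edge.length[e]
      rp <- node_rates[p]
      node_rates[c] <- if (model == "LN") {
        if (params$sigma2 == 0 || dt == 0) rp else
          exp(stats::rnorm(1L, log(rp) - params$sigma2 * dt / 2,
                           sqrt(params$sigma2 * dt)))
      } else {                                     # CIR exact transition
        if (dt == 0) rp else cir_transition_draw(rp, params$theta,
                                                 params$sigma, dt)
      }
    }
    rp <- node_rates[tree$edge[, 1L]]
    rc <- node_rates[tree$edge[, 2L]]
    out <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                      duration = dur, r_parent = rp, r_child = rc,
                      r_bar = (rp + rc) / 2)
  }
  attr(out, "node_rates") <- node_rates
  attr(out, "params") <- params
  class(out) <- c("rate_assignment", class(out))
  out
}

# one exact CIR draw: scaled noncentral chi-square
cir_transition_draw <- function(r_parent, theta, sigma, dt) {
  c2 <- 2 * theta / (sigma^2 * (1 - exp(-theta * dt)))
  df <- 4 * theta / sigma^2
  ncp <- 2 * c2 * r_parent * exp(-theta * dt)
  stats::rchisq(length(r_parent), df = df, ncp = ncp) / (2 * c2)
}

#' Log transition / marginal density of a branch rate
#'
#' Returns the log density of the child rate given the parent rate over a
#' duration `dt` (LN, CIR), or the log marginal density of the branch
#' multiplier (UGAM, `dt` ignored). Densities are proper: each integrates to
#' 1 over the positive half-line. Non-positive rates yield `-Inf` rather
#' than an error.
#'
#' @param params a [rate_model_params()] object.
#' @param r_child child-node rate (LN/CIR) or branch multiplier (UGAM);
#'   vectorized.
#' @param r_parent parent-node rate; ignored for UGAM.
#' @param dt branch duration in Ma (> 0 for LN/CIR).
#' @return log-density, same length as `r_child`.
#' @export
branch_log_density <- function(params, r_child, r_parent = 1, dt = 1) {
  stopifnot(inherits(params, "rate_model_params"))
  model <- params$model
  n <- length(r_child)
  r_parent <- rep_len(r_parent, n)
  out <- rep(-Inf, n)
  pos <- r_child > 0 & (model == "UGAM" | r_parent > 0)
  if (!any(pos)) return(out)
  if (model == "UGAM") {
    out[pos] <- stats::dgamma(r_child[pos], shape = 1 / params$nu,
                              scale = params$nu, log = TRUE)
  } else if (model == "LN") {
    if (dt <= 0) stop("LN transition density requires dt > 0")
    if (params$sigma2 <= 0) stop("LN density is degenerate at sigma2 = 0")
    s <- sqrt(params$sigma2 * dt)
    m <- log(r_parent[pos]) - params$sigma2 * dt / 2
    out[pos] <- stats::dnorm(log(r_child[pos]), m, s, log = TRUE) -
      log(r_child[pos])
  } else {
    if (dt <= 0) stop("CIR transition density requires dt > 0")
    c2 <- 2 * params$theta / (params$sigma^2 * (1 - exp(-params$theta * dt)))
    df <- 4 * params$theta / params$sigma^2
    ncp <- 2 * c2 * r_parent[pos] * exp(-params$theta * dt)
    out[pos] <- stats::dchisq(2 * c2 * r_child[pos], df = df, ncp = ncp,
                              log = TRUE) + log(2 * c2)
  }
  out
}

#' Stationary mean and variance of a rate process
#'
#' @param params a [rate_model_params()] object.
#' @return list with `mean` and `variance`; the LN process is nonstationary
#'   (log-variance grows linearly in time), so its variance is `NA` and
#'   `stationary = FALSE`.
#' @export
stationary_moments <- function(params) {
  stopifnot(inherits(params, "rate_model_params"))
  switch(params$model,
    UGAM = list(mean = 1, variance = params$nu, stationary = TRUE),
    LN = list(mean = 1, variance = NA_real_, stationary = FALSE),
    CIR = list(mean = 1, variance = params$sigma^2 / (2 * params$theta),
               stationary = TRUE)
  )
}

#' Write a rate assignment as TSV
#'
#' @param rates a `rate_assignment` data.frame.
#' @param file output path.
#' @export
write_rates <- function(rates, file) {
  utils::write.table(as.data.frame(rates), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
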