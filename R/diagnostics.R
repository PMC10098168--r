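#' Effective sample size of an MCMC series
#'
#' `n / (1 + 2 * sum(rho_k))` with autocorrelations summed under Geyer's
#' initial positive sequence rule: successive pairs
#' `Gamma_m = rho_{2m} + rho_{2m+1}` are accumulated while they remain
#' positive. Autocovariances are computed by FFT. A constant series carries
#' no autocorrelation evidence and returns `n` by convention; the result is
#' always capped at `n`.
#'
#' @param x numeric series, length >= 10.
#' @return estimated effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short (need >= 10)")
  x <- x - mean(x)
  if (all(x == 0)) return(n)                      # constant series
  # FFT autocovariance (biased, standard for ESS)
  npad <- 2L^ceiling(log2(2L * n))
  f <- stats::fft(c(x, rep(0, npad - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / npad
  rho <- ac / ac[1L]
  nmax <- (n - 1L) %/% 2L
  tau <- -1
  for (m in 0:nmax) {
    g <- rho[2L * m + 1L] +
      (if (2L * m + 2L <= n) rho[2L * m + 2L] else 0)
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  min(n, n / max(tau, 1e-12))
}

#' Between-chain discrepancy of one variable
#'
#' `|mean1 - mean2| / pooled SD`, with the pooled SD the square root of the
#' average of the two chain variances (the tracecomp convention behind the
#' 0.30 convergence threshold). Two constant chains give 0 when their means
#' agree and `Inf` otherwise. Symmetric in its arguments and invariant to
#' affine rescaling.
#'
#' @param x,y numeric series from two chains.
#' @return non-negative discrepancy.
#' @export
chain_discrepancy <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  v1 <- if (length(x) > 1L) stats::var(x) else 0
  v2 <- if (length(y) > 1L) stats::var(y) else 0
  dm <- abs(mean(x) - mean(y))
  pooled <- sqrt((v1 + v2) / 2)
  if (pooled == 0) return(if (dm == 0) 0 else Inf)
  dm / pooled
}

#' Convergence report across chains
#'
#' Per-variable effective sizes (summed over chains) and pairwise maximum
#' between-chain discrepancies. The run passes when every variable reaches
#' `min_ess` and no discrepancy exceeds `max_discrepancy` (defaults: the
#' conventional thresholds ESS >= 50 and d <= 0.30).
#'
#' @param traces list of `chain_trace` matrices (or a single one).
#' @param min_ess,max_discrepancy pass thresholds.
#' @return list with `table` (data.frame: variable, ess, discrepancy) and
#'   logical `pass`.
#' @export
convergence_report <- function(traces, min_ess = 50, max_discrepancy = 0.30) {
  if (!is.list(traces)) traces <- list(traces)
  vars <- colnames(traces[[1L]])
  tab <- data.frame(variable = vars,
                    ess = NA_real_, discrepancy = NA_real_)
  for (j in seq_along(vars)) {
    series <- lapply(traces, function(tr) unclass(tr)[, j])
    tab$ess[j] <- sum(vapply(series, effective_size, 0))
    d <- 0
    if (length(series) >= 2L) {
      for (a in seq_len(length(series) - 1L)) {
        for (b in (a + 1L):length(series)) {
          d <- max(d, chain_discrepancy(series[[a]], series[[b]]))
        }
      }
    }
    tab$discrepancy[j] <- d
  }
  list(table = tab,
       pass = all(tab$ess >= min_ess) && all(tab$discrepancy <= max_discrepancy))
}

#' Detect posterior piling against the root-prior bounds
#'
#' Operationalizes the relax-the-bound procedure: if a substantial fraction
#' of post-burn-in root-age samples sit within `eps` of either bound of the
#' interval that defined the root prior, the bound is likely truncating the
#' posterior and should be relaxed before ages are trusted.
#'
#' @param root_ages numeric vector of sampled root ages, or a `chain_trace`
#'   (its root-age column is used).
#' @param prior a [root_prior()].
#' @param eps proximity threshold as a fraction of the prior span
#'   (default 1%).
#' @param flag_fraction flag when the boundary fraction exceeds this
#'   (default 5%).
#' @return list: `flag`, `fraction`, `fraction_old`, `fraction_young`.
#' @export
prior_boundary_check <- function(root_ages, prior, eps = 0.01,
                                 flag_fraction = 0.05) {
  if (inherits(root_ages, "chain_trace")) {
    col <- paste0("age_", attr(root_ages, "root_node"))
    root_ages <- unclass(root_ages)[, col]
  }
  stopifnot(length(root_ages) > 0)
  span <- prior$old_bound - prior$young_bound
  tol <- eps * span
  near_old <- abs(root_ages - prior$old_bound) <= tol |
    root_ages > prior$old_bound
  near_young <- abs(root_ages - prior$young_bound) <= tol |
    root_ages < prior$young_bound
  fo <- mean(near_old)
  fy <- mean(near_young)
  frac <- mean(near_old | near_young)
  list(flag = frac > flag_fraction, fraction = frac,
       fraction_old = fo, fraction_young = fy)
}

#' Calibration cross-validation
#'
#' Evaluates how well each calibration, when active, recovers the
#' fossil-constrained ages of the clades whose own calibrations are held
#' out. A clade is never evaluated in a subset where its own calibration is
#' active (self-exclusion). Per evaluated (model, subset, clade) the status
#' is `recovered` when the posterior mean falls inside the clade's fossil
#' interval, `overestimate` above it, `underestimate` below it.
#'
#' @param grid output of [run_model_grid()] (list with `summary` and
#'   `subsets`), or a compatible summary data.frame plus `subsets`.
#' @param fossil_intervals named list `clade -> c(min, max)` in Ma; defaults
#'   to the calibration bounds when `calibrations` is given instead.
#' @param calibrations optional named list of [calibration()] objects used
#'   to derive `fossil_intervals`.
#' @return list of class `cv_report`: `table` (per-evaluation rows),
#'   `informativeness` (per-calibration recovery rate when active), and
#'   `missing` (clades without grid rows).
#' @export
calibration_cross_validation <- function(grid, fossil_intervals = NULL,
                                         calibrations = NULL) {
  summary <- if (is.data.frame(grid)) grid else grid$summary
  subsets <- if (is.data.frame(grid)) attr(grid, "subsets") else grid$subsets
  if (is.null(subsets)) stop("grid lacks subset definitions")
  if (is.null(fossil_intervals)) {
    if (is.null(calibrations)) {
      stop("provide fossil_intervals or calibrations")
    }
    if (is.null(names(calibrations))) {
      names(calibrations) <- vapply(calibrations, `[[`, "", "name")
    }
    fossil_intervals <- lapply(calibrations, function(cal) {
      c(cal$min_age, cal$max_age)
    })
  }
  clades <- names(fossil_intervals)
  missing <- setdiff(clades, unique(summary$clade))
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    if (!r$clade %in% clades) next
    active <- subsets[[r$subset]]
    if (r$clade %in% active) next                  # self-exclusion
    fi <- fossil_intervals[[r$clade]]
    status <- if (r$mean > fi[2L]) "overestimate"
      else if (r$mean < fi[1L]) "underestimate" else "recovered"
    rows[[length(rows) + 1L]] <-
      data.frame(model = r$model, subset = r$subset, clade = r$clade,
                 mean = r$mean, lower = r$lower, upper = r$upper,
                 fossil_min = fi[1L], fossil_max = fi[2L], status = status)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), subset = character(),
               clade = character(), mean = numeric(), lower = numeric(),
               upper = numeric(), fossil_min = numeric(),
               fossil_max = numeric(), status = character())
  all_cals <- unique(unlist(subsets))
  info <- do.call(rbind, lapply(all_cals, function(cal) {
    act <- vapply(tab$subset, function(s) cal %in% subsets[[s]], TRUE)
    sub <- tab[act, , drop = FALSE]
    data.frame(calibration = cal, n_evaluated = nrow(sub),
               recovery_rate = if (nrow(sub)) mean(sub$status == "recovered")
                               else NA_real_)
  }))
  structure(list(table = tab, informativeness = info, missing = missing),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Calibration cross-validation:", nrow(x$table), "evaluations\n")
  print(table(x$table$status))
  cat("\nPer-calibration recovery rate when active:\n")
  print(x$informativeness, row.names = FALSE)
  if (length(x$missing)) {
    cat("missing clades:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variance of co-calibrated clade age estimates
#'
#' For clades sharing one duplicate calibration, computes the population
#' (divide-by-n) variance and standard deviation of their posterior mean
#' ages. A rate model that is internally consistent should date the
#' co-calibrated clades alike, so lower variance ranks the model better.
#'
#' @param means numeric vector of posterior mean ages (>= 2 clades).
#' @return list with `variance` and `sd`.
#' @export
duplicate_calibration_variance <- function(means) {
  if (length(means) < 2L) stop("need >= 2 co-calibrated clades")
  v <- mean((means - mean(means))^2)
  list(variance = v, sd = sqrt(v))
}
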