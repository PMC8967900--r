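#' Trimmed ("quantile") standard deviation of one feature
#'
#' Sample SD (n-1 denominator) after removing missing values and dropping
#' exactly one minimum and one maximum observation — the robustified per-gene
#' variability measure used for variable-feature selection. An alternative
#' percent-quantile trim is available via `trim_percent` (default off).
#'
#' @param values numeric vector of one feature across samples.
#' @param trim_percent if > 0, instead drop values outside the
#'   (`trim_percent`, 1 - `trim_percent`) quantiles.
#' @return non-negative scalar, or `NA` if fewer than 2 values remain.
#' @export
quantile_sd <- function(values, trim_percent = 0) {
  x <- sort(values[!is.na(values)])
  if (trim_percent > 0) {
    q <- stats::quantile(x, c(trim_percent, 1 - trim_percent), names = FALSE)
    x <- x[x >= q[1] & x <= q[2]]
  } else if (length(x) >= 2) {
    x <- x[-c(1L, length(x))]  # one min and one max, single occurrence each
  }
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Plain 1-D EM with `n_restarts` random initializations (2-means centers plus
#' jitter), kept to convergence in log-likelihood; components are ordered by
#' mean so component 2 is the high-variability one.
#'
#' @param sds numeric vector (>= 20 finite values).
#' @param seed RNG seed for the restarts.
#' @param n_restarts random restarts; best log-likelihood wins.
#' @param tol absolute log-likelihood change declaring convergence.
#' @param max_iter iteration cap per restart (non-convergence is flagged, not
#'   fatal).
#' @return object of class `mixture_fit`: `mu`, `sigma`, `lambda` (weights),
#'   `loglik`, `loglik_trace`, `n_iterations`, `converged`, `separation`
#'   (|mu2-mu1| / sqrt(sigma1*sigma2), a diagnostic for near-duplicate
#'   components).
#' @export
fit_two_component_mixture <- function(sds, seed = 1, n_restarts = 5,
                                      tol = 1e-8, max_iter = 1000) {
  x <- sds[is.finite(sds)]
  if (length(x) < 20) stop("need >= 20 finite values for the mixture fit")
  if (stats::sd(x) < 1e-10) stop("degenerate input: all values identical")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- stats::kmeans(x, centers = 2, nstart = 1)
    mu <- sort(km$centers[, 1]) + stats::rnorm(2, 0, stats::sd(x) / 10)
    sg <- rep(max(stats::sd(x) / 2, 1e-3), 2)
    lam <- c(0.5, 0.5)
    ll_old <- -Inf; trace <- numeric(0); converged <- FALSE; it <- 0
    while (it < max_iter) {
      it <- it + 1
      d1 <- lam[1] * stats::dnorm(x, mu[1], sg[1])
      d2 <- lam[2] * stats::dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      g2 <- d2 / tot
      g1 <- 1 - g2
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      n1 <- sum(g1); n2 <- sum(g2)
      lam <- c(n1, n2) / length(x)
      mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
      sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                   sum(g2 * (x - mu[2])^2) / n2))
      sg <- pmax(sg, 1e-8)
    }
    if (any(sg < 1e-6)) stop("near-degenerate mixture component (sigma < 1e-6)")
    fit <- list(mu = mu, sigma = sg, lambda = lam, loglik = ll,
                loglik_trace = trace, n_iterations = it, converged = converged)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (best$mu[1] > best$mu[2]) {  # order components by mean
    best$mu <- rev(best$mu); best$sigma <- rev(best$sigma)
    best$lambda <- rev(best$lambda)
  }
  best$separation <- abs(diff(best$mu)) / sqrt(prod(best$sigma))
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  class(best) <- "mixture_fit"
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> mu = (%.3f, %.3f), sigma = (%.3f, %.3f), pi = (%.3f, %.3f)\n",
    x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$lambda[1], x$lambda[2]))
  cat(sprintf("  loglik %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iterations, x$converged))
  invisible(x)
}

#' Posterior probability of the high-variability component
#' @param fit `mixture_fit`.
#' @param x values.
#' @return P(component 2 | x).
#' @export
posterior_hv <- function(fit, x) {
  d1 <- fit$lambda[1] * stats::dnorm(x, fit$mu[1], fit$sigma[1])
  d2 <- fit$lambda[2] * stats::dnorm(x, fit$mu[2], fit$sigma[2])
  tot <- d1 + d2
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  d2 / tot
}

#' Threshold optimizing "highly variable minus unmodulated" above the cut
#'
#' Over a candidate grid (all observed SDs plus midpoints between consecutive
#' sorted values), picks the threshold t maximizing
#' sum over x > t of [P(HV | x) - P(unmodulated | x)], i.e. the expected
#' number of highly variable minus unmodulated features selected. Ties break
#' to the smallest t. A `hard = TRUE` variant counts hard-classified features
#' instead of posterior masses.
#'
#' @param fit `mixture_fit`.
#' @param sds observed values.
#' @param hard use hard classification (posterior > 0.5) in the objective.
#' @return scalar threshold.
#' @export
optimal_threshold <- function(fit, sds, hard = FALSE) {
  x <- sort(sds[is.finite(sds)])
  if (!length(x)) stop("empty candidate grid")
  grid <- sort(unique(c(x, (x[-1] + x[-length(x)]) / 2)))
  post2 <- posterior_hv(fit, x)
  contrib <- if (hard) ifelse(post2 > 0.5, 1, -1) else post2 - (1 - post2)
  # objective(t) = sum of contrib over x > t; evaluate by suffix sums
  obj <- vapply(grid, function(t) sum(contrib[x > t]), numeric(1))
  grid[which.max(obj)]  # which.max takes the first (smallest t) on ties
}

#' Select highly variable features
#'
#' Computes the trimmed SD per feature, fits the two-component mixture
#' `n_runs` times under distinct sub-seeds, takes each run's optimal
#' threshold, and floors the mean of the run thresholds to the nearest 0.5
#' below (floor(mean * 2) / 2) for a reproducible final cut. The HV set is
#' every feature whose trimmed SD exceeds the final threshold.
#'
#' @param matrix [omics_matrix()] (features x samples).
#' @param n_runs number of independent EM runs (default 10).
#' @param seed master seed; run i uses a derived sub-seed.
#' @param trim_percent passed to [quantile_sd()].
#' @return object of class `hvf_result`: `sd` (named per-feature trimmed SD),
#'   `run_thresholds`, `threshold` (final, floored), `hv_genes`, `fits`.
#' @export
select_hvf <- function(matrix, n_runs = 10, seed = 7, trim_percent = 0) {
  qsd <- apply(matrix, 1L, quantile_sd, trim_percent = trim_percent)
  runs <- numeric(n_runs)
  fits <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    fits[[i]] <- fit_two_component_mixture(qsd, seed = sub_seed(seed, i))
    runs[i] <- optimal_threshold(fits[[i]], qsd)
  }
  thr <- floor(mean(runs) * 2) / 2
  res <- list(sd = qsd, run_thresholds = runs, threshold = thr,
              hv_genes = names(qsd)[!is.na(qsd) & qsd > thr], fits = fits)
  class(res) <- "hvf_result"
  res
}

#' @export
print.hvf_result <- function(x, ...) {
  cat(sprintf(
    "<hvf_result> %d features, final threshold %.1f (runs: %s), %d highly variable\n",
    length(x$sd), x$threshold,
    paste(sprintf("%.2f", x$run_thresholds), collapse = " "),
    length(x$hv_genes)))
  invisible(x)
}
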