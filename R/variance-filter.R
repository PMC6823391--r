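#' Per-group probe standard deviations
#'
#' Computes, for every probe, the sample standard deviation (denominator
#' n - 1) of its log2 signal separately within the target cells and within
#' the comparison cells. The two-column SD table is the substrate of the
#' mixture diagnosis and the dual-group variance filter.
#'
#' @param matrix An [expr_matrix()]; linear scales are transformed
#'   `log2(x + 1)` first.
#' @param groups Named character vector (`cell_id` to `"target"` /
#'   `"comparison"`) or an annotation data.frame covering all cells.
#' @return Data.frame with columns `probe_id`, `sd_target`, `sd_comparison`.
#' @export
per_group_sd <- function(matrix, groups) {
  stopifnot(is_expr_matrix(matrix))
  g <- group_vector(groups, colnames(matrix))
  x <- as_log2(matrix)
  out <- data.frame(probe_id = rownames(matrix), stringsAsFactors = FALSE)
  for (grp in c("target", "comparison")) {
    cells <- names(g)[g == grp]
    if (length(cells) < 2L) {
      stop(sprintf(
        "group '%s' has %d cell(s); need >= 2 to compute an SD",
        grp, length(cells)
      ), call. = FALSE)
    }
    xs <- x[, cells, drop = FALSE]
    mu <- rowMeans(xs)
    s <- sqrt(rowSums((xs - mu)^2) / (length(cells) - 1L))
    out[[paste0("sd_", grp)]] <- unname(s)
  }
  out
}

#' Fit a two-component normal mixture to an SD distribution
#'
#' Expectation-maximization fit of
#' \eqn{w_1 N(\mu_1, \sigma_1^2) + w_2 N(\mu_2, \sigma_2^2)} to a vector of
#' per-probe standard deviations. The low-mean component is interpreted as
#' measurement noise (probes not differentially expressed across cells), the
#' high-mean component as biologically informative variation; components are
#' always reported in increasing-mean order. Initialization splits the data
#' at its median and uses per-half moments (falling back to the extremes
#' with a pooled spread if a half is degenerate), so the fit is
#' deterministic. The log-likelihood trace is retained and is nondecreasing
#' by construction of EM.
#'
#' @param sds Numeric vector of SD values (>= 10 values with nonzero spread).
#' @param max_iter Iteration cap.
#' @param tol Relative log-likelihood change declaring convergence.
#' @return An `sd_mixture` object: `weights`, `means`, `sds`,
#'   `log_likelihood`, `ll_trace`, `n_iter`, `converged`, `n`.
#' @export
fit_sd_mixture <- function(sds, max_iter = 500L, tol = 1e-8) {
  sds <- as.numeric(sds)
  if (length(sds) < 10L) {
    stop("need at least 10 SD values to fit a mixture", call. = FALSE)
  }
  if (stats::sd(sds) == 0) stop("degenerate SD distribution", call. = FALSE)

  n <- length(sds)
  med <- stats::median(sds)
  lo <- sds[sds <= med]
  hi <- sds[sds > med]
  if (length(hi) < 2L || length(lo) < 2L ||
    stats::sd(lo) == 0 || stats::sd(hi) == 0) {
    mu <- c(min(sds), max(sds))
    sig <- rep(stats::sd(sds), 2L)
    w <- c(0.5, 0.5)
  } else {
    mu <- c(mean(lo), mean(hi))
    sig <- c(stats::sd(lo), stats::sd(hi))
    w <- c(length(lo), length(hi)) / n
  }
  sig_floor <- 1e-6 * stats::sd(sds)
  sig <- pmax(sig, sig_floor)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step in log space for numerical stability
    lp1 <- log(w[1]) + stats::dnorm(sds, mu[1], sig[1], log = TRUE)
    lp2 <- log(w[2]) + stats::dnorm(sds, mu[2], sig[2], log = TRUE)
    m <- pmax(lp1, lp2)
    lse <- m + log(exp(lp1 - m) + exp(lp2 - m))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r2 <- exp(lp2 - lse)
    r1 <- 1 - r2
    # M step
    w <- c(sum(r1), sum(r2)) / n
    w <- pmin(pmax(w, 1e-12), 1 - 1e-12)
    mu <- c(sum(r1 * sds) / sum(r1), sum(r2 * sds) / sum(r2))
    sig <- sqrt(c(
      sum(r1 * (sds - mu[1])^2) / sum(r1),
      sum(r2 * (sds - mu[2])^2) / sum(r2)
    ))
    sig <- pmax(sig, sig_floor)
  }
  if (mu[1] > mu[2]) { # report components in increasing-mean order
    mu <- rev(mu)
    sig <- rev(sig)
    w <- rev(w)
  }
  structure(
    list(
      weights = w, means = mu, sds = sig,
      log_likelihood = ll_trace[length(ll_trace)],
      ll_trace = ll_trace, n_iter = iter, converged = converged, n = n
    ),
    class = "sd_mixture"
  )
}

#' @export
print.sd_mixture <- function(x, ...) {
  cat("<sd_mixture> two-component normal fit to", x$n, "SD values\n")
  cat(sprintf(
    "  noise:       w = %.3f, mean = %.3f, sd = %.3f\n",
    x$weights[1], x$means[1], x$sds[1]
  ))
  cat(sprintf(
    "  informative: w = %.3f, mean = %.3f, sd = %.3f\n",
    x$weights[2], x$means[2], x$sds[2]
  ))
  cat(sprintf(
    "  logLik %.2f after %d iteration(s)%s\n",
    x$log_likelihood, x$n_iter,
    if (x$converged) ", converged" else " (not converged)"
  ))
  invisible(x)
}

#' @export
plot.sd_mixture <- function(x, sds = NULL, breaks = 60, ...) {
  if (!is.null(sds)) {
    graphics::hist(sds,
      breaks = breaks, freq = FALSE, main = "SD mixture fit",
      xlab = "per-probe SD (log2 signal)", ...
    )
    xs <- seq(min(sds), max(sds), length.out = 400)
  } else {
    xs <- seq(x$means[1] - 4 * x$sds[1], x$means[2] + 4 * x$sds[2], length.out = 400)
    graphics::plot(NA,
      xlim = range(xs), ylim = c(0, 1.1 * max(
        x$weights[1] * stats::dnorm(x$means[1], x$means[1], x$sds[1]),
        x$weights[2] * stats::dnorm(x$means[2], x$means[2], x$sds[2])
      )),
      main = "SD mixture fit", xlab = "per-probe SD (log2 signal)",
      ylab = "density", ...
    )
  }
  graphics::lines(xs, x$weights[1] * stats::dnorm(xs, x$means[1], x$sds[1]), col = 2)
  graphics::lines(xs, x$weights[2] * stats::dnorm(xs, x$means[2], x$sds[2]), col = 4)
  graphics::abline(v = suggest_threshold(x), lty = 2)
  invisible(x)
}

#' Suggest an SD cutoff from a fitted mixture
#'
#' Returns the point between the two component means where the weighted
#' component densities are equal — the decision boundary separating noise
#' probes from informative ones. If no crossing lies strictly between the
#' means (possible with very unequal weights and spreads), the midpoint is
#' returned. The fitted suggestion is advisory; the operative study cutoff
#' is the fixed `threshold` of [dual_sd_filter()].
#'
#' @param fit An `sd_mixture`.
#' @return Numeric threshold in log2-signal units.
#' @export
suggest_threshold <- function(fit) {
  stopifnot(inherits(fit, "sd_mixture"))
  w <- fit$weights
  mu <- fit$means
  sig <- fit$sds
  # w1 N(x; mu1, s1) = w2 N(x; mu2, s2)  <=>  a x^2 + b x + c = 0
  a <- 1 / sig[2]^2 - 1 / sig[1]^2
  b <- 2 * (mu[1] / sig[1]^2 - mu[2] / sig[2]^2)
  c0 <- mu[2]^2 / sig[2]^2 - mu[1]^2 / sig[1]^2 +
    2 * (log(w[1] / sig[1]) - log(w[2] / sig[2]))
  mid <- mean(mu)
  if (abs(a) < 1e-12) { # equal variances: linear equation
    if (abs(b) < 1e-12) {
      return(mid)
    }
    x <- -c0 / b
    return(if (x > mu[1] && x < mu[2]) x else mid)
  }
  disc <- b^2 - 4 * a * c0
  if (disc < 0) {
    return(mid)
  }
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) inside[1] else mid
}

#' Dual-group SD filter
#'
#' Retains probes whose standard deviation exceeds the threshold in *both*
#' the target and the comparison group, removing the low-variance noise
#' component before clustering. The study cutoff is 2.5 (log2-signal units);
#' `strict = TRUE` reads "above" as a strict inequality.
#'
#' @param sd_table Output of [per_group_sd()].
#' @param threshold SD cutoff (>= 0).
#' @param strict Use `>` (default) rather than `>=`.
#' @return A `filter_result`: `retained_probe_ids`, `n_input`, `n_retained`,
#'   `threshold`, `strict`, and the annotated `table`.
#' @export
dual_sd_filter <- function(sd_table, threshold = 2.5, strict = TRUE) {
  stopifnot(
    is.data.frame(sd_table),
    all(c("probe_id", "sd_target", "sd_comparison") %in% names(sd_table))
  )
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  keep <- if (strict) {
    sd_table$sd_target > threshold & sd_table$sd_comparison > threshold
  } else {
    sd_table$sd_target >= threshold & sd_table$sd_comparison >= threshold
  }
  tab <- sd_table
  tab$retained <- keep
  structure(
    list(
      retained_probe_ids = sd_table$probe_id[keep],
      n_input = nrow(sd_table),
      n_retained = sum(keep),
      threshold = threshold,
      strict = strict,
      table = tab
    ),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "<filter_result> %d of %d probes retained (SD %s %g in both groups)\n",
    x$n_retained, x$n_input, if (x$strict) ">" else ">=", x$threshold
  ))
  invisible(x)
}
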