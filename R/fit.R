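#' Fit the mRNA nonlinear degree beta from expression-versus-volume data
#'
#' Normalizes volumes and expression to the smallest-volume bin, then
#' least-squares fits the one-parameter scaling curve
#' \eqn{\tilde m = A\, \tilde V (1+\beta)/(1+\beta\tilde V)} over
#' \eqn{\beta \in [-0.99/\tilde V_{max},\ 10]}. The amplitude `A` is
#' co-fitted (profiled analytically: the model is linear in `A`) because
#' experimental normalization - e.g. RPKM-scale data - is arbitrary; this
#' also makes the estimate invariant under rescaling all expression values.
#' The lower bound keeps the curve's denominator positive on the data range;
#' estimates pinned at a bound are flagged, not errored.
#'
#' @param volumes strictly increasing positive volumes (>= 3 bins).
#' @param expression nonnegative expression values (copy number, or
#'   RPKM x volume), same length.
#' @param weights `"none"` (default, plain least squares) or `"inv_expr"`
#'   (Poisson-like `1/max(m, eps)` weights).
#' @return A one-row data.frame (`scaling_estimate`): `beta_hat`,
#'   `amplitude`, `residual_sse`, `converged`, `n_points`.
#' @examples
#' v <- c(1, 1.5, 2, 2.5, 3)
#' fit_beta(v, mrna_curve(0.5, v))$beta_hat   # 0.5
#' @export
fit_beta <- function(volumes, expression, weights = c("none", "inv_expr")) {
  weights <- match.arg(weights)
  if (length(volumes) != length(expression))
    stop("volumes and expression must have the same length")
  if (length(volumes) < 3) stop("need at least 3 volume bins")
  if (any(volumes <= 0) || any(diff(volumes) <= 0))
    stop("volumes must be positive and strictly increasing")
  if (any(expression < 0)) stop("expression must be nonnegative")
  if (all(expression == 0)) stop("all-zero expression: nothing to fit")
  if (expression[1] == 0)
    stop("expression at the smallest (reference) volume is zero")

  Vt <- volumes / volumes[1]
  mt <- expression / expression[1]
  w <- if (weights == "inv_expr") 1 / pmax(mt, 1e-12) else rep(1, length(mt))
  lower <- -0.99 / max(Vt)
  upper <- 10

  sse_of <- function(beta) {
    f <- Vt * (1 + beta) / (1 + beta * Vt)
    A <- sum(w * mt * f) / sum(w * f^2)
    sum(w * (mt - A * f)^2)
  }
  opt <- stats::optimize(sse_of, c(lower, upper), tol = 1e-10)
  beta_hat <- opt$minimum
  sse <- opt$objective
  ## optimize never lands exactly on a bound; pin when the bound does better
  converged <- TRUE
  for (b in c(lower, upper)) {
    if (sse_of(b) <= sse + 1e-15 ||
        abs(beta_hat - b) < 1e-4 * (upper - lower)) {
      if (sse_of(b) < sse) {
        beta_hat <- b
        sse <- sse_of(b)
      }
      converged <- FALSE
    }
  }
  f <- Vt * (1 + beta_hat) / (1 + beta_hat * Vt)
  A <- sum(w * mt * f) / sum(w * f^2)
  structure(data.frame(beta_hat = beta_hat, amplitude = A,
                       residual_sse = sse, converged = converged,
                       n_points = length(Vt)),
            class = c("scaling_estimate", "data.frame"))
}

#' Fit the protein nonlinear degree alpha (and amplitude C)
#'
#' Fits \eqn{\Delta\tilde p = C \ln(1 + \alpha\, \Delta\tilde V)} by
#' nonlinear least squares, with `C` profiled analytically and
#' \eqn{\alpha \in (-0.99/\Delta\tilde V_{max},\ 20]}. Protein levels and
#' volumes are normalized to the smallest-volume bin. Exactly linear data
#' sit on a flat likelihood ridge (\eqn{\alpha \to 0}, \eqn{C\alpha} fixed);
#' such fits are flagged via `ridge = TRUE` and report the limiting slope as
#' `C_alpha`.
#'
#' @param volumes strictly increasing positive volumes (>= 4 bins: two
#'   parameters).
#' @param protein_levels positive protein levels, same length.
#' @return A one-row data.frame (`scaling_estimate`): `alpha_hat`, `C_hat`,
#'   `C_alpha` (the product, finite on the ridge), `residual_sse`,
#'   `converged`, `ridge`, `n_points`.
#' @export
fit_alpha <- function(volumes, protein_levels) {
  if (length(volumes) != length(protein_levels))
    stop("volumes and protein_levels must have the same length")
  if (length(volumes) < 4) stop("need at least 4 volume bins (two parameters)")
  if (any(volumes <= 0) || any(diff(volumes) <= 0))
    stop("volumes must be positive and strictly increasing")
  if (any(protein_levels <= 0)) stop("protein levels must be positive")

  dV <- volumes / volumes[1] - 1
  dP <- protein_levels / protein_levels[1] - 1
  lower <- -0.99 / max(dV)
  upper <- 20

  sse_of <- function(alpha) {
    g <- log1p(alpha * dV)
    s2 <- sum(g^2)
    if (s2 == 0) {      # alpha = 0: the ridge; SSE of the best linear fit
      k <- sum(dP * dV) / sum(dV^2)
      return(sum((dP - k * dV)^2))
    }
    C <- sum(dP * g) / s2
    sum((dP - C * g)^2)
  }
  opt <- stats::optimize(sse_of, c(lower, upper), tol = 1e-10)
  alpha_hat <- opt$minimum
  sse <- opt$objective
  converged <- TRUE
  for (b in c(lower, upper)) {
    if (sse_of(b) < sse || abs(alpha_hat - b) < 1e-4 * (upper - lower)) {
      if (sse_of(b) < sse) {
        alpha_hat <- b
        sse <- sse_of(b)
      }
      converged <- FALSE
    }
  }
  ridge <- abs(alpha_hat) * max(dV) < 1e-4
  if (ridge) {
    C_alpha <- sum(dP * dV) / sum(dV^2)
    C_hat <- NA_real_
  } else {
    g <- log1p(alpha_hat * dV)
    C_hat <- sum(dP * g) / sum(g^2)
    C_alpha <- C_hat * alpha_hat
  }
  structure(data.frame(alpha_hat = alpha_hat, C_hat = C_hat,
                       C_alpha = C_alpha, residual_sse = sse,
                       converged = converged, ridge = ridge,
                       n_points = length(volumes)),
            class = c("scaling_estimate", "data.frame"))
}

#' Production-rate proxy from smallest-volume expression
#'
#' In quick mRNA equilibrium, \eqn{m = k_n \tau_m}; the mRNA amount at the
#' smallest volume divided by the lifetime therefore estimates the
#' production rate. Genes without a lifetime are skipped (NA) with a
#' message.
#'
#' @param expression_at_smallest_volume mRNA amounts (copy number, or
#'   RPKM x volume) at the smallest volume bin; optionally named by gene.
#' @param tau_m per-gene mRNA lifetimes, minutes.
#' @return per-gene rates, 1/min.
#' @export
production_rate_proxy <- function(expression_at_smallest_volume, tau_m) {
  if (length(tau_m) == 1) tau_m <- rep(tau_m, length(expression_at_smallest_volume))
  if (length(tau_m) != length(expression_at_smallest_volume))
    stop("tau_m must be length 1 or match the expression vector")
  if (any(tau_m <= 0, na.rm = TRUE)) stop("tau_m must be positive")
  skip <- is.na(tau_m)
  if (any(skip))
    message(sum(skip), " gene(s) skipped: missing mRNA lifetime")
  out <- expression_at_smallest_volume / tau_m
  out[skip] <- NA_real_
  out
}

#' Fit beta for every gene of a trajectory or expression table
#'
#' @param x a `volscale_trajectory` or the list returned by
#'   [as_expression_table()] / [read_expression_table()].
#' @param n_bins thin the trajectory's time grid to this many volume bins
#'   before fitting (keeps the estimator cost flat in trajectory length).
#' @param ... passed to [fit_beta()].
#' @return data.frame with one row per gene: `gene_id`, `beta_hat`,
#'   `amplitude`, `residual_sse`, `converged`, `n_points`.
#' @export
fit_trajectory_betas <- function(x, n_bins = 40, ...) {
  tab <- if (inherits(x, "volscale_trajectory"))
    as_expression_table(x, "mRNA", n_bins = n_bins) else x
  est <- lapply(rownames(tab$expression), function(id) {
    fit <- fit_beta(tab$volumes, tab$expression[id, ], ...)
    cbind(gene_id = id, fit)
  })
  do.call(rbind, est)
}

#' Fit alpha for every gene of a trajectory or protein expression table
#'
#' @inheritParams fit_trajectory_betas
#' @export
fit_trajectory_alphas <- function(x, n_bins = 40, ...) {
  tab <- if (inherits(x, "volscale_trajectory"))
    as_expression_table(x, "protein", n_bins = n_bins) else x
  est <- lapply(rownames(tab$expression), function(id) {
    fit <- fit_alpha(tab$volumes, tab$expression[id, ], ...)
    cbind(gene_id = id, fit)
  })
  do.call(rbind, est)
}

#' Summary of a beta distribution and its correlation with production rates
#'
#' Median and histogram of the converged estimates, Pearson and Spearman
#' correlations (two-sided tests) between the fitted nonlinear degrees and
#' the per-gene production-rate proxy, and binned medians. Non-converged
#' (bound-pinned) estimates are excluded; degenerate inputs (zero variance)
#' yield NA correlations with a flag rather than an error.
#'
#' @param estimates data.frame from [fit_trajectory_betas()] (columns
#'   `beta_hat`, `converged`; `gene_id` optional).
#' @param rates per-gene production-rate proxy aligned with `estimates`.
#' @param n_bins number of rate bins for the binned medians.
#' @return list: `n`, `median_beta`, `iqr_beta`, `histogram`, `pearson`,
#'   `spearman` (each `list(estimate, p_value)`), `binned` data.frame,
#'   `degenerate` flag.
#' @export
scaling_summary <- function(estimates, rates, n_bins = 10) {
  if (nrow(estimates) != length(rates))
    stop("rates must align with estimates (one per gene)")
  keep <- estimates$converged & !is.na(rates)
  beta <- estimates$beta_hat[keep]
  rate <- rates[keep]
  if (length(beta) < 10)
    stop("too few converged estimates (", length(beta), " < 10)")
  degenerate <- stats::sd(beta) == 0 || stats::sd(rate) == 0
  if (degenerate) {
    pear <- spear <- list(estimate = NA_real_, p_value = NA_real_)
  } else {
    pt <- stats::cor.test(beta, rate, method = "pearson",
                          alternative = "two.sided")
    st <- suppressWarnings(stats::cor.test(beta, rate, method = "spearman",
                                           alternative = "two.sided",
                                           exact = FALSE))
    pear <- list(estimate = unname(pt$estimate), p_value = pt$p.value)
    spear <- list(estimate = unname(st$estimate), p_value = st$p.value)
  }
  h <- graphics::hist(beta, breaks = "FD", plot = FALSE)
  brk <- unique(stats::quantile(rate, probs = seq(0, 1, length.out = n_bins + 1)))
  binned <- if (length(brk) >= 3) {
    bins <- cut(rate, brk, include.lowest = TRUE)
    data.frame(rate_median = as.numeric(tapply(rate, bins, stats::median)),
               beta_median = as.numeric(tapply(beta, bins, stats::median)))
  } else {  # near-constant rates: a single bin
    data.frame(rate_median = stats::median(rate),
               beta_median = stats::median(beta))
  }
  list(n = length(beta), median_beta = stats::median(beta),
       iqr_beta = stats::IQR(beta),
       histogram = list(breaks = h$breaks, counts = h$counts),
       pearson = pear, spearman = spear, binned = binned,
       degenerate = degenerate)
}
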