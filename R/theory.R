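#' Mass-fraction-weighted average Michaelis-Menten constant
#'
#' \eqn{\langle K_{n,i}\rangle = \sum_i \phi_i K_{n,i}} with \eqn{\phi_i} the
#' protein mass fractions (initial fractions by default; a time-averaged
#' variant works equally well, see [predict_scaling()]). This weighted
#' average is the pivot separating sublinear from superlinear genes; for a
#' lognormal ensemble it sits below the unweighted mean, with the median
#' slightly above it.
#'
#' @param genome `volscale_genome`.
#' @param phi per-gene mass fractions, nonnegative, summing to 1 (tolerance
#'   1e-9).
#' @return The weighted average, molecules/um^3.
#' @export
weighted_K <- function(genome, phi) {
  if (length(phi) != nrow(genome))
    stop("phi must have one weight per gene (", nrow(genome), ")")
  if (any(phi < 0)) stop("phi must be nonnegative")
  if (abs(sum(phi) - 1) > 1e-9) stop("phi must sum to 1 (got ", sum(phi), ")")
  sum(phi * genome$K_n)
}

#' Predicted mRNA nonlinear degree
#'
#' \eqn{\beta_i = -\Delta K_{n,i}\, n(0) / (K_{n,i}\, n_c)} with
#' \eqn{\Delta K_{n,i} = K_{n,i} - \langle K_{n,i}\rangle}. Genes at the
#' weighted average have \eqn{\beta = 0}; above it, \eqn{\beta < 0}
#' (superlinear); below it, \eqn{\beta > 0} (sublinear).
#'
#' @param K_i per-gene MM constant(s), molecules/um^3.
#' @param K_avg weighted-average MM constant (see [weighted_K()]).
#' @param n0_over_nc initial RNAP saturation \eqn{n(0)/n_c}, in (0, 1).
#' @return beta, dimensionless (vectorised over `K_i`).
#' @examples
#' predicted_beta(20 * 6e3, 6e3, 0.5)   # -0.475
#' predicted_beta(0.2 * 6e3, 6e3, 0.5)  # 2
#' @export
predicted_beta <- function(K_i, K_avg, n0_over_nc) {
  stopifnot(all(K_i > 0), K_avg > 0, n0_over_nc > 0, n0_over_nc < 1)
  -(K_i - K_avg) * n0_over_nc / K_i
}

#' Predicted nonlinear degree of nondegradable proteins
#'
#' \eqn{\alpha_i = -\Delta K_{n,i}\, n(0) /
#'   (K_{n,i}\, n_c - \Delta K_{n,i}\, n(0))}; `n_c` scales out when written
#' in terms of `n0_over_nc`. Same sign as \eqn{\beta_i}. The denominator
#' must stay positive (it fails only when a gene's production would saturate
#' before the volume range ends - outside the theory's validity).
#'
#' @inheritParams predicted_beta
#' @return alpha, dimensionless (vectorised over `K_i`).
#' @export
predicted_alpha <- function(K_i, K_avg, n0_over_nc) {
  stopifnot(all(K_i > 0), K_avg > 0, n0_over_nc > 0, n0_over_nc < 1)
  dK <- K_i - K_avg
  den <- K_i - dK * n0_over_nc
  if (any(den <= 0))
    stop("predicted_alpha outside validity: K_i*n_c - dK*n(0) <= 0 for ",
         sum(den <= 0), " gene(s)")
  -dK * n0_over_nc / den
}

#' Normalized mRNA scaling curve
#'
#' \eqn{\tilde m(\tilde V) = \tilde V (1+\beta) / (1+\beta \tilde V)}.
#' `beta = 0` gives the linear law \eqn{\tilde m = \tilde V}; the
#' \eqn{\beta \to \infty} limit is a volume-independent copy number.
#'
#' @param beta nonlinear degree.
#' @param V_rel normalized volume \eqn{\tilde V \ge 1} (vectorised).
#' @return \eqn{\tilde m}, same length as `V_rel`.
#' @export
mrna_curve <- function(beta, V_rel) {
  den <- 1 + beta * V_rel
  if (any(den <= 0))
    stop("mrna_curve pole crossed: 1 + beta*V_rel <= 0 (beta = ", beta, ")")
  V_rel * (1 + beta) / den
}

#' Normalized nondegradable-protein accumulation curve
#'
#' \eqn{\Delta\tilde p(\Delta\tilde V) = C \ln(1 + \alpha\, \Delta\tilde V)};
#' in the \eqn{\alpha \to 0} limit (with \eqn{C\alpha} fixed) it degenerates
#' to the linear law \eqn{C\alpha\, \Delta\tilde V}.
#'
#' @param C amplitude (all pre-logarithm constants over `p(0)`).
#' @param alpha nonlinear degree.
#' @param dV_rel \eqn{\Delta\tilde V = \tilde V - 1 \ge 0} (vectorised).
#' @return \eqn{\Delta\tilde p}, same length as `dV_rel`.
#' @export
protein_curve <- function(C, alpha, dV_rel) {
  arg <- 1 + alpha * dV_rel
  if (any(arg <= 0))
    stop("protein_curve log-domain violation: 1 + alpha*dV_rel <= 0")
  C * log(arg)
}

#' Production rate of one special gene in a homogeneous background
#'
#' \eqn{k_{n,i} = \Gamma_{n,i} g_i K_n n / (K_{n,i} n_c - (K_{n,i}-K_n) n)}:
#' the Phase-1 rate of a single gene whose MM constant `K_i` differs from the
#' shared background value `K_avg`. Reduces to the homogeneous law
#' \eqn{\Gamma g\, n / n_c} when `K_i = K_avg`.
#'
#' @param K_i special gene's MM constant.
#' @param K_avg background (or weighted-average) MM constant.
#' @param n,n_c RNAP number and critical RNAP number (`n < n_c`).
#' @param Gamma_g product \eqn{\Gamma_{n,i} g_i}, 1/min.
#' @return production rate, 1/min (vectorised over `n`).
#' @export
special_gene_rate <- function(K_i, K_avg, n, n_c, Gamma_g) {
  stopifnot(K_i > 0, K_avg > 0, n_c > 0, Gamma_g >= 0)
  if (any(n >= n_c)) stop("special_gene_rate requires n < n_c (Phase 1)")
  den <- K_i * n_c - (K_i - K_avg) * n
  if (any(den <= 0))
    stop("special_gene_rate breakdown: denominator <= 0 near saturation")
  Gamma_g * K_avg * n / den
}

#' Theory predictions for every gene of a simulated trajectory
#'
#' Evaluates [predicted_beta()] and [predicted_alpha()] for each gene using
#' the weighted-average MM constant and the RNAP saturation measured at the
#' trajectory's (post-burn-in) normalization origin - the theory is expressed
#' in the realized `n(0)`, not in attempted values.
#'
#' @param traj `volscale_trajectory` from [run_experiment()].
#' @param weights `"initial"` (mass fractions at the origin snapshot) or
#'   `"time_averaged"` (mean mass fractions over the post-origin snapshots).
#' @return data.frame: `gene_id`, `K_n`, `beta_pred`, `alpha_pred` (NA where
#'   outside the alpha validity window), plus attributes `K_avg` and
#'   `n0_over_nc`.
#' @export
predict_scaling <- function(traj, weights = c("initial", "time_averaged")) {
  weights <- match.arg(weights)
  genome <- traj$genome
  L <- genome$L
  if (weights == "initial") {
    phi <- traj$p[traj$origin, ] * L / sum(traj$p[traj$origin, ] * L)
  } else {
    idx <- seq(traj$origin, length(traj$time))
    phimat <- traj$p[idx, , drop = FALSE] * rep(L, each = length(idx))
    phimat <- phimat / rowSums(phimat)
    phi <- colMeans(phimat)
  }
  K_avg <- weighted_K(genome, phi)
  s <- traj$n[traj$origin] / traj$n_c
  beta <- predicted_beta(genome$K_n, K_avg, s)
  dK <- genome$K_n - K_avg
  den <- genome$K_n - dK * s
  alpha <- ifelse(den > 0, -dK * s / den, NA_real_)
  out <- data.frame(gene_id = genome$gene_id, K_n = genome$K_n,
                    beta_pred = beta, alpha_pred = alpha,
                    stringsAsFactors = FALSE)
  attr(out, "K_avg") <- K_avg
  attr(out, "n0_over_nc") <- s
  out
}
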