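#' Critical RNAP number of a genome
#'
#' \eqn{n_c = \sum_i g_i (1 + \Lambda_{n,i})} with
#' \eqn{\Lambda_{n,i} = \Gamma_{n,i} L_i / v_n}: the maximum number of RNAPs
#' the genome can hold, promoter-bound plus elongating.
#'
#' @param genome calibrated `volscale_genome`.
#' @param globals `volscale_globals`.
#' @return A positive number.
#' @export
nc_of <- function(genome, globals) {
  validate_genome(genome)
  globals <- as_globals(globals)
  if (all(is.na(genome$Gamma_n)))
    stop("genome is uncalibrated (Gamma_n is NA); run calibrate() first")
  sum(genome$g * (1 + genome$Gamma_n * genome$L / globals$v_n))
}

#' Calibrate initiation rates and initial conditions
#'
#' Runs the provisioning procedure that turns an uncalibrated genome plus the
#' cell-level constants into a simulatable initial state:
#' \enumerate{
#'   \item the attempted ribosome mass fraction \eqn{\phi_r = \mu_0 L_r / v_r}
#'     (all ribosomes assumed actively translating);
#'   \item the attempted RNAP mass fraction
#'     \eqn{\phi_n = 0.1 \phi_r L_n / L_r}, i.e. the RNAP copy number is
#'     provisioned at 10\% of the ribosome copy number;
#'   \item the initiation-rate ratios \eqn{y = \Gamma_{n,n}/\Gamma_{n,r}} and
#'     \eqn{x = \Gamma_{n,i}/\Gamma_{n,r}} (generic genes) that make the
#'     steady-state mRNA pools consistent with those mass fractions under the
#'     low-occupancy approximation \eqn{c_n F_n \ll K_{n,i}};
#'   \item the ribosome-gene transcription initiation rate
#'     \eqn{\Gamma_{n,r} = (n_c - \sum_i g_i) v_n /
#'       (g_r L_r + y\, g_n L_n + x \sum_{i>2} g_i L_i)},
#'     which pins the realized critical RNAP number
#'     \eqn{\sum_i g_i (1+\Lambda_{n,i})} to the attempted `n_c_target`
#'     exactly;
#'   \item initial mRNAs \eqn{m_i(0) = k_{n,i} \tau_{m,i}} from the full
#'     free-RNAP solve at the attempted RNAP count, initial protein mass
#'     fractions \eqn{\phi_i \propto m_i(0) L_i}, and a shifted initial mass
#'     `M0_actual` such that `phi_n(actual) * M0_actual = phi_n(attempted) * M_b`
#'     (the RNAP copy number is continuous at t = 0).
#' }
#'
#' For genomes generated with `gamma_cv > 0`, the per-gene `gamma_mult`
#' multipliers are applied to the generic initiation rates after step 4,
#' renormalised so that \eqn{\sum g_i \Gamma_{n,i} L_i} over generic genes -
#' and hence the realized `n_c` - is unchanged.
#'
#' Calibration is idempotent: it depends only on `K_n`, `tau_m`, `g`, `L`,
#' `gamma_mult` and the globals, never on the current `Gamma_n`.
#'
#' @param genome `volscale_genome` (calibrated or not).
#' @param globals `volscale_globals`.
#' @return A `volscale_calibration` list: the calibrated `genome`, `globals`,
#'   attempted mass fractions `phi_r`, `phi_n`, rates `Gamma_n_r`, ratios
#'   `x`, `y`, initial copy numbers `m0`, `p0`, shifted mass `M0_actual`,
#'   realized `n_c`, initial free fraction `F_n0`, and the initial
#'   [cell_state()] `state0`.
#' @examples
#' gl <- global_params()
#' cal <- calibrate(make_genome(20, K_cv = 0, lifetime_cv = 0, seed = 1), gl)
#' cal$phi_r                       # 0.1
#' cal$n_c - gl$n_c_target         # 0 to machine precision
#' @export
calibrate <- function(genome, globals) {
  validate_genome(genome)
  globals <- as_globals(globals)
  genome <- as.data.frame(genome)
  if (is.null(genome$gamma_mult)) genome$gamma_mult <- 1

  i_n <- which(genome$role == "rnap")
  i_r <- which(genome$role == "ribosome")
  gen <- which(genome$role == "generic")
  L <- genome$L; g <- genome$g; K <- genome$K_n; tau_m <- genome$tau_m

  phi_r <- globals$mu0 * L[i_r] / globals$v_r
  if (phi_r >= 1)
    stop("attempted ribosome mass fraction phi_r = ", signif(phi_r, 4),
         " >= 1: growth rate infeasible for the given v_r")
  phi_n <- 0.1 * phi_r * L[i_n] / L[i_r]

  ## Gamma-free steady-state mRNA-mass weights S_i = g_i tau_m,i L_i / K_n,i
  S <- g * tau_m * L / K
  y <- (phi_n / phi_r) * S[i_r] / S[i_n]
  x <- (S[i_r] * (1 - phi_r) / phi_r - y * S[i_n]) / sum(S[gen])
  if (!is.finite(x) || x <= 0)
    stop("calibration infeasible: generic initiation-rate ratio x = ",
         signif(x, 4), " is not positive")

  denom <- g[i_r] * L[i_r] + y * g[i_n] * L[i_n] + x * sum(g[gen] * L[gen])
  free_slots <- globals$n_c_target - sum(g)
  if (free_slots <= 0)
    stop("n_c_target must exceed the total gene copy number sum(g)")
  if (denom <= 0) stop("calibration infeasible: nonpositive length-weighted sum")
  Gamma_n_r <- free_slots * globals$v_n / denom

  Gamma_n <- numeric(nrow(genome))
  Gamma_n[i_r] <- Gamma_n_r
  Gamma_n[i_n] <- y * Gamma_n_r
  ## unit-sum renormalisation keeps sum(g Gamma L) over generic genes, and
  ## therefore the realized n_c, exactly at the attempted value
  mult <- genome$gamma_mult[gen]
  mult_norm <- mult * sum(g[gen] * L[gen]) / sum(g[gen] * L[gen] * mult)
  Gamma_n[gen] <- x * Gamma_n_r * mult_norm
  genome$Gamma_n <- Gamma_n
  genome <- validate_genome(genome)

  n_c <- sum(g * (1 + Gamma_n * L / globals$v_n))

  ## initial conditions from the attempted RNAP pool and the full free solve
  n0 <- phi_n * globals$M_b / L[i_n]
  V <- globals$M_b / globals$rho
  V_n <- V / globals$a
  c_n <- n0 / V_n
  slots <- g * (1 + Gamma_n * L / globals$v_n)
  F_n0 <- solve_free_fraction(n0, c_n, slots, K)
  P_b <- c_n * F_n0 / (c_n * F_n0 + K)
  k_n <- Gamma_n * g * P_b
  m0 <- k_n * tau_m

  phi <- m0 * L / sum(m0 * L)
  M0_actual <- phi_n * globals$M_b / phi[i_n]
  p0 <- phi * M0_actual / L

  structure(list(
    genome = genome, globals = globals,
    phi_r = phi_r, phi_n = phi_n,
    Gamma_n_r = Gamma_n_r, x = x, y = y,
    m0 = m0, p0 = p0, phi0 = phi,
    M0_actual = M0_actual, n_c = n_c, F_n0 = F_n0,
    state0 = cell_state(m0, p0, t = 0)
  ), class = "volscale_calibration")
}

#' @export
print.volscale_calibration <- function(x, ...) {
  cat("volscale calibration\n")
  cat(sprintf("  genes: %d   realized n_c = %.6g (target %.6g)\n",
              nrow(x$genome), x$n_c, x$globals$n_c_target))
  cat(sprintf("  phi_r = %.4g  phi_n = %.4g  (RNAP:ribosome copies = %.4g)\n",
              x$phi_r, x$phi_n,
              (x$phi_n / x$genome$L[x$genome$role == "rnap"]) /
                (x$phi_r / x$genome$L[x$genome$role == "ribosome"])))
  cat(sprintf("  Gamma_n_r = %.4g /min   y = %.4g   x = %.4g\n",
              x$Gamma_n_r, x$y, x$x))
  cat(sprintf("  M0_actual = %.6g aa   initial F_n = %.3g\n",
              x$M0_actual, x$F_n0))
  invisible(x)
}
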