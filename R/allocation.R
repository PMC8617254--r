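#' Instantaneous cell state
#'
#' Copy numbers of every mRNA and protein at one instant. All cell-level
#' quantities (total protein mass `M`, volume `V = M/rho`, nuclear volume
#' `V_n = V/a`, RNAP and ribosome counts) are derived from the state and the
#' genome; see [production_rates()].
#'
#' @param m,p numeric vectors of mRNA and protein copy numbers (one entry per
#'   gene, genome row order). Nonnegative reals; the model is mean-field, so
#'   copy numbers need not be integers.
#' @param t time, minutes.
#' @return A `volscale_state` list.
#' @export
cell_state <- function(m, p, t = 0) {
  if (length(m) != length(p)) stop("m and p must have the same length")
  if (any(!is.finite(m)) || any(!is.finite(p)))
    stop("state contains non-finite copy numbers")
  if (any(m < 0) || any(p < 0)) stop("negative copy numbers in cell state")
  structure(list(t = t, m = as.numeric(m), p = as.numeric(p)),
            class = "volscale_state")
}

## Cell-level quantities derived from a state
state_quantities <- function(state, genome, globals) {
  L <- genome$L
  M <- sum(state$p * L)
  if (M <= 0) stop("total protein mass must be positive")
  V <- M / globals$rho
  V_n <- V / globals$a
  V_c <- V - V_n
  n <- state$p[genome$role == "rnap"]
  r <- state$p[genome$role == "ribosome"]
  list(M = M, V = V, V_n = V_n, V_c = V_c, n = n, r = r,
       c_n = n / V_n, c_r = r / V_c)
}

#' Self-consistent free-fraction solve (shared by RNAP and ribosome pools)
#'
#' Root of  total*(1-F) = sum_i slots_i * conc*F / (conc*F + K_i)  on [0, 1].
#'
#' Uniqueness/monotonicity: the left side is strictly decreasing in F (from
#' `total` to 0) and the right side is strictly increasing (from 0), so h(F) =
#' LHS - RHS is strictly decreasing with h(0) = total > 0 and h(1) <= 0; a
#' bracketed root always exists and is unique. uniroot gets within ~1e-13 and
#' two Newton steps (analytic derivative) polish to machine precision, which
#' the bookkeeping-closure invariant (relative error < 1e-9) relies on.
#'
#' @noRd
solve_free_fraction <- function(total, conc, slots, K) {
  if (total <= 0) {
    warning("free-fraction solve with a nonexistent polymerase pool; ",
            "returning F = 0 by convention")
    return(0)
  }
  s_tot <- sum(slots)
  if (s_tot == 0) return(1)  # no binding targets: everything free
  h <- function(F) total * (1 - F) - sum(slots * conc * F / (conc * F + K))
  if (h(1) >= 0) return(1)
  root <- stats::uniroot(h, c(0, 1), f.lower = total, tol = 1e-13,
                         maxiter = 1000L)$root
  ## Newton polish to machine precision; extra iterations matter when the
  ## root sits far below uniroot's interval tolerance (K -> 0 regimes)
  for (i in 1:20) {
    hr <- h(root)
    if (abs(hr) <= 1e-13 * total) break
    hp <- -total - sum(slots * conc * K / (conc * root + K)^2)
    root <- min(max(root - hr / hp, 0), 1)
  }
  root
}

#' Free RNAP fraction and concentration
#'
#' Solves the self-consistency equation for the nuclear RNAP pool,
#' \eqn{n (1 - F_n) = \sum_i g_i (1 + \Lambda_{n,i})
#'   \frac{c_n F_n}{c_n F_n + K_{n,i}}}:
#' bound polymerases (promoter-bound plus elongating, the left-to-right
#' bookkeeping) balance the non-free part of the pool. With a common `K_n`
#' this is the classic single-K self-consistency relation; the per-gene sum
#' is its direct heterogeneous generalisation.
#'
#' @param state [cell_state()].
#' @param genome calibrated `volscale_genome`.
#' @param globals `volscale_globals`.
#' @return list with `F_n` (fraction of free RNAPs in (0, 1]) and `c_n_free`
#'   (free nuclear RNAP concentration, molecules/um^3).
#' @export
solve_free_rnap <- function(state, genome, globals) {
  globals <- as_globals(globals)
  q <- state_quantities(state, genome, globals)
  slots <- genome$g * (1 + genome$Gamma_n * genome$L / globals$v_n)
  if (q$n <= 0) {
    warning("no RNAPs in the cell; F_n undefined, returning 0")
    return(list(F_n = 0, c_n_free = 0))
  }
  F_n <- solve_free_fraction(q$n, q$c_n, slots, genome$K_n)
  list(F_n = F_n, c_n_free = q$c_n * F_n)
}

#' Free ribosome fraction and concentration
#'
#' Ribosome analog of [solve_free_rnap()]: mRNAs compete for ribosomes with
#' per-mRNA capacity \eqn{1 + \Lambda_{r,i}},
#' \eqn{\Lambda_{r,i} = \Gamma_{r,i} L_i / v_r}, in the cytoplasmic volume
#' \eqn{V_c = V - V_n}.
#'
#' @inheritParams solve_free_rnap
#' @return list with `F_r` and `c_r_free`.
#' @export
solve_free_ribosome <- function(state, genome, globals) {
  globals <- as_globals(globals)
  q <- state_quantities(state, genome, globals)
  slots <- state$m * (1 + genome$Gamma_r * genome$L / globals$v_r)
  if (q$r <= 0) {
    warning("no ribosomes in the cell; F_r undefined, returning 0")
    return(list(F_r = 0, c_r_free = 0))
  }
  F_r <- solve_free_fraction(q$r, q$c_r, slots, genome$K_r)
  list(F_r = F_r, c_r_free = q$c_r * F_r)
}

#' Per-gene production rates from the instantaneous allocation
#'
#' Runs both free-fraction solves and returns promoter occupancies and
#' production rates: \eqn{k_{n,i} = \Gamma_{n,i} g_i P_{b,i}} with
#' \eqn{P_{b,i} = c_{n,free} / (c_{n,free} + K_{n,i})}, and
#' \eqn{k_{r,i} = \Gamma_{r,i} m_i \, c_{r,free} / (c_{r,free} + K_{r,i})}.
#'
#' @inheritParams solve_free_rnap
#' @return A `volscale_allocation` list: `F_n`, `F_r`, `c_n_free`,
#'   `c_r_free`, per-gene `P_b`, `k_n`, `k_r`, and `phase1 = (n < n_c)`.
#' @export
production_rates <- function(state, genome, globals) {
  validate_genome(genome)
  globals <- as_globals(globals)
  if (all(is.na(genome$Gamma_n))) stop("genome is uncalibrated")
  rn <- solve_free_rnap(state, genome, globals)
  rb <- solve_free_ribosome(state, genome, globals)
  P_b <- rn$c_n_free / (rn$c_n_free + genome$K_n)
  k_n <- genome$Gamma_n * genome$g * P_b
  P_r <- rb$c_r_free / (rb$c_r_free + genome$K_r)
  k_r <- genome$Gamma_r * state$m * P_r
  q <- state_quantities(state, genome, globals)
  structure(list(F_n = rn$F_n, F_r = rb$F_r,
                 c_n_free = rn$c_n_free, c_r_free = rb$c_r_free,
                 P_b = P_b, P_r = P_r, k_n = k_n, k_r = k_r,
                 phase1 = q$n < nc_of(genome, globals)),
            class = "volscale_allocation")
}
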