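## Precompute per-gene constant vectors used by the ODE right-hand side and
## the per-snapshot allocation solves.
make_model_env <- function(genome, globals) {
  validate_genome(genome)
  globals <- as_globals(globals)
  if (all(is.na(genome$Gamma_n)))
    stop("genome is uncalibrated (Gamma_n is NA); run calibrate() first")
  G <- nrow(genome)
  list(
    G = G,
    L = genome$L,
    g = genome$g,
    K_n = genome$K_n,
    K_r = genome$K_r,
    Gamma_n = genome$Gamma_n,
    Gamma_r = genome$Gamma_r,
    inv_tau_m = 1 / genome$tau_m,
    inv_tau_p = ifelse(is.infinite(genome$tau_p), 0, 1 / genome$tau_p),
    slots_n = genome$g * (1 + genome$Gamma_n * genome$L / globals$v_n),
    cap_r = 1 + genome$Gamma_r * genome$L / globals$v_r,  # per-mRNA ribosome slots
    i_n = which(genome$role == "rnap"),
    i_r = which(genome$role == "ribosome"),
    rho = globals$rho, a = globals$a,
    n_c = sum(genome$g * (1 + genome$Gamma_n * genome$L / globals$v_n))
  )
}

## Allocation on raw copy-number vectors (fast path used inside the RHS).
alloc_raw <- function(m, p, me) {
  M <- sum(p * me$L)
  V <- M / me$rho
  V_n <- V / me$a
  V_c <- V - V_n
  n <- p[me$i_n]
  r <- p[me$i_r]
  c_n <- n / V_n
  c_r <- r / V_c
  F_n <- solve_free_fraction(n, c_n, me$slots_n, me$K_n)
  cf_n <- c_n * F_n
  F_r <- solve_free_fraction(r, c_r, m * me$cap_r, me$K_r)
  cf_r <- c_r * F_r
  list(M = M, V = V, n = n, r = r, F_n = F_n, F_r = F_r,
       c_n_free = cf_n, c_r_free = cf_r,
       k_n = me$Gamma_n * me$g * cf_n / (cf_n + me$K_n),
       k_r = me$Gamma_r * m * cf_r / (cf_r + me$K_r))
}

make_rhs <- function(me) {
  G <- me$G
  function(t, y) {
    m <- pmax(y[seq_len(G)], 0)
    p <- pmax(y[G + seq_len(G)], 0)
    al <- alloc_raw(m, p, me)
    c(al$k_n - m * me$inv_tau_m, al$k_r - p * me$inv_tau_p)
  }
}

## Assemble a trajectory object from grid output, recomputing the allocation
## diagnostics at every snapshot.
build_trajectory <- function(time, y, me, genome, globals, origin = 1L,
                             meta = list()) {
  G <- me$G
  Tn <- length(time)
  m <- y[, seq_len(G), drop = FALSE]
  p <- y[, G + seq_len(G), drop = FALSE]
  colnames(m) <- colnames(p) <- genome$gene_id
  M <- V <- n <- r <- F_n <- F_r <- numeric(Tn)
  k_n <- matrix(NA_real_, Tn, G, dimnames = list(NULL, genome$gene_id))
  for (i in seq_len(Tn)) {
    al <- alloc_raw(pmax(m[i, ], 0), pmax(p[i, ], 0), me)
    M[i] <- al$M; V[i] <- al$V; n[i] <- al$n; r[i] <- al$r
    F_n[i] <- al$F_n; F_r[i] <- al$F_r
    k_n[i, ] <- al$k_n
  }
  phase1 <- n < me$n_c
  if (any(!phase1))
    warning("RNAP number reached n_c at t = ", time[which(!phase1)[1]],
            " min: the cell left Phase 1", call. = FALSE)
  structure(list(time = time, m = m, p = p, M = M, V = V, n = n, r = r,
                 F_n = F_n, F_r = F_r, k_n = k_n, phase1 = phase1,
                 n_c = me$n_c, origin = origin, genome = genome,
                 globals = globals, meta = meta),
            class = "volscale_trajectory")
}

#' Integrate the coupled mRNA/protein dynamics
#'
#' Solves \eqn{dm_i/dt = k_{n,i} - m_i/\tau_{m,i}} and
#' \eqn{dp_i/dt = k_{r,i} - p_i/\tau_{p,i}} where the production rates are
#' recomputed from the two free-fraction solves at every right-hand-side
#' evaluation (see [production_rates()]). Nondegradable proteins use
#' \eqn{1/\tau_p = 0}. Output is sampled on a uniform grid; the integrator
#' lands on each grid time exactly.
#'
#' @param state0 initial [cell_state()].
#' @param genome calibrated `volscale_genome`.
#' @param globals `volscale_globals`.
#' @param t_end end time, minutes (must exceed `state0$t`).
#' @param dt_out output cadence, minutes.
#' @param rtol,atol integrator tolerances.
#' @param stop_mass if non-`NULL`, integration stops at the first grid point
#'   with total protein mass above this value.
#' @param meta named list stored in the trajectory (seed, config hash, ...).
#' @return A `volscale_trajectory`: time grid, `m`/`p`/`k_n` matrices
#'   (time x gene), per-time `M`, `V`, `n`, `r`, `F_n`, `F_r`, `phase1`
#'   flags, the genome and globals.
#' @export
integrate_cell <- function(state0, genome, globals, t_end, dt_out = 1,
                           rtol = 1e-8, atol = 1e-6, stop_mass = NULL,
                           meta = list()) {
  me <- make_model_env(genome, globals)
  if (t_end <= state0$t) stop("t_end must exceed the initial time")
  rhs <- make_rhs(me)
  y0 <- c(state0$m, state0$p)
  stop_fn <- NULL
  if (!is.null(stop_mass)) {
    L <- me$L; G <- me$G
    stop_fn <- function(t, y) sum(y[G + seq_len(G)] * L) > stop_mass
  }
  sol <- ode_solve_grid(rhs, y0, state0$t, t_end, dt_out, rtol, atol, stop_fn)
  neg <- min(sol$y)
  if (neg < -1e-9 * max(1, max(abs(sol$y))))
    stop("integration produced negative copy numbers (min = ", neg,
         "); the model state left its domain")
  sol$y[sol$y < 0] <- 0
  build_trajectory(sol$time, sol$y, me, genome, globals, meta = meta)
}

#' Run the volume-growth experiment protocol
#'
#' Calibrates the genome, integrates from the calibrated initial state,
#' removes the transient by re-basing the trajectory origin at `burn_in`
#' minutes (20 by default; use 100 when degradable proteins are under
#' study), and stops when the total protein mass exceeds
#' `stop_multiplier * M_b` or at `t_end`, whichever comes first. Normalized
#' series (\eqn{\tilde V}, \eqn{\tilde m_i}, \eqn{\tilde p_i}) are measured
#' relative to the re-based origin by the downstream fitting helpers.
#'
#' @param genome `volscale_genome` (calibrated or not; calibration is
#'   idempotent).
#' @param globals `volscale_globals`.
#' @param burn_in transient-removal time, minutes.
#' @param t_end maximum simulated time, minutes.
#' @param stop_multiplier stop when `M > stop_multiplier * M_b`.
#' @inheritParams integrate_cell
#' @return A `volscale_trajectory` with `origin` set to the burn-in snapshot.
#' @export
run_experiment <- function(genome, globals, burn_in = 20, t_end = 800,
                           stop_multiplier = 9, dt_out = 1, rtol = 1e-8,
                           atol = 1e-6, meta = list()) {
  globals <- as_globals(globals)
  if (burn_in < 0) stop("burn_in must be nonnegative")
  if (burn_in >= t_end)
    stop("burn_in (", burn_in, ") must be smaller than t_end (", t_end, ")")
  cal <- calibrate(genome, globals)
  traj <- integrate_cell(cal$state0, cal$genome, globals, t_end = t_end,
                         dt_out = dt_out, rtol = rtol, atol = atol,
                         stop_mass = stop_multiplier * globals$M_b,
                         meta = meta)
  origin <- which(traj$time >= burn_in)[1]
  if (is.na(origin) || origin >= length(traj$time))
    stop("trajectory ended at t = ", max(traj$time),
         " min, before or at the burn-in of ", burn_in, " min")
  traj$origin <- origin
  traj$calibration <- cal
  traj
}

#' @export
print.volscale_trajectory <- function(x, ...) {
  Tn <- length(x$time)
  cat("volscale trajectory:", ncol(x$m), "genes x", Tn, "snapshots\n")
  cat(sprintf("  t = [%g, %g] min (origin at t = %g)\n",
              x$time[1], x$time[Tn], x$time[x$origin]))
  cat(sprintf("  volume fold change from origin: %.3g\n",
              x$V[Tn] / x$V[x$origin]))
  cat(sprintf("  n/n_c: %.3g -> %.3g; max F_n = %.3g; phase 1 throughout: %s\n",
              x$n[1] / x$n_c, x$n[Tn] / x$n_c, max(x$F_n), all(x$phase1)))
  invisible(x)
}

#' Periodic cell cycle driven by a concentration-ratio division trigger
#'
#' Integrates the model and divides the cell (all mRNA and protein copy
#' numbers halved exactly; gene copy numbers are time-independent) whenever
#' the concentration ratio of a superlinear reporter protein to a sublinear
#' reporter protein crosses `ratio_threshold` from below. Halving every copy
#' number leaves all concentrations - including the trigger ratio - unchanged
#' at the instant of division, so a level trigger would re-fire immediately;
#' instead the trigger re-arms once the ratio has either fallen below the
#' threshold or passed a local minimum (the dip). It is the halved
#' RNAP-to-genome ratio `n/n_c` that pushes the superlinear reporter's
#' concentration down after birth and makes the ratio dip and recover,
#' exactly once per cycle on the periodic orbit; the local-minimum re-arm
#' only matters on the approach transient, where the post-division dip can
#' sit entirely above the threshold.
#'
#' @param genome `volscale_genome`.
#' @param globals `volscale_globals`.
#' @param reporter_super,reporter_sub gene ids of the reporters; the
#'   superlinear reporter must have `K_n` above the mass-fraction-weighted
#'   average, the sublinear one below.
#' @param ratio_threshold division trigger on
#'   (superlinear protein concentration) / (sublinear protein concentration).
#' @param n_cycles number of complete birth-to-division cycles to record
#'   after the first division.
#' @param dt_out,rtol,atol see [integrate_cell()].
#' @param max_cycle_time diagnostic abort if no division happens within this
#'   many minutes (default: five attempted doubling times).
#' @return A `volscale_cell_cycle` list: concatenated trajectory arrays, a
#'   `cycles` data.frame (birth/division times, length, maximum relative
#'   deviation of the division-to-birth fold change from 2), last-cycle fold
#'   changes `fold_m`/`fold_p`, `converged` and `degenerate` flags.
#' @export
run_cell_cycle <- function(genome, globals, reporter_super, reporter_sub,
                           ratio_threshold, n_cycles = 8, dt_out = 1,
                           rtol = 1e-8, atol = 1e-6, max_cycle_time = NULL) {
  globals <- as_globals(globals)
  cal <- calibrate(genome, globals)
  genome <- cal$genome
  me <- make_model_env(genome, globals)
  G <- me$G
  is_sup <- match(reporter_super, genome$gene_id)
  is_sub <- match(reporter_sub, genome$gene_id)
  if (is.na(is_sup) || is.na(is_sub)) stop("unknown reporter gene id")
  K_avg <- weighted_K(genome, cal$phi0)
  if (genome$K_n[is_sup] <= K_avg)
    stop("reporter_super must have K_n above the weighted average (superlinear)")
  if (genome$K_n[is_sub] >= K_avg)
    stop("reporter_sub must have K_n below the weighted average (sublinear)")
  if (ratio_threshold <= 0) stop("ratio_threshold must be positive")
  max_cycle_time <- max_cycle_time %||% (5 * log(2) / globals$mu0)

  rhs <- make_rhs(me)
  ratio_of <- function(y) y[G + is_sup] / y[G + is_sub]
  event_fn <- function(t, y) ratio_of(y) - ratio_threshold

  t <- 0
  y <- c(cal$m0, cal$p0)
  degenerate <- FALSE
  cycles <- list()
  birth_states <- list()
  division_states <- list()
  completed <- 0L
  t_birth <- NA_real_

  if (ratio_of(y) >= ratio_threshold) {
    ## degenerate trigger: threshold already met at t = 0
    degenerate <- TRUE
    division_states[[1]] <- y
    y <- y / 2
    birth_states[[1]] <- y
    cycles[[1]] <- data.frame(cycle = 0L, t_birth = 0, t_division = 0,
                              length = 0, max_fold_dev = NA_real_)
    t_birth <- 0
  }
  armed <- ratio_of(y) < ratio_threshold
  seen_decrease <- FALSE

  times <- t
  ys <- list(y)
  h <- NULL
  t_anchor <- t   # last division (or start); for the never-crossed diagnostic
  fold_m <- fold_p <- NULL

  while (completed < n_cycles) {
    t_next <- t + dt_out
    adv <- ode_advance(rhs, t, y, t_next, rtol, atol, h)
    h <- adv$h
    rat_prev <- ratio_of(y)
    y_prev <- y
    t_prev <- t
    y <- adv$y
    t <- t_next
    rat <- ratio_of(y)
    if (!armed) {
      if (rat < ratio_threshold * (1 - 1e-12)) {
        armed <- TRUE                      # dipped below the threshold
      } else if (seen_decrease && rat > rat_prev * (1 + 1e-12)) {
        armed <- TRUE                      # passed a local minimum above it
      } else if (rat < rat_prev * (1 - 1e-12)) {
        seen_decrease <- TRUE
      }
    }
    if (armed && rat >= ratio_threshold) {
      if (rat_prev < ratio_threshold) {
        ev <- ode_locate_event(rhs, t_prev, y_prev, t, event_fn, rtol, atol,
                               tol_t = 1e-5)
      } else {
        ev <- list(t = t, y = y)  # re-armed above threshold: divide here
      }
      y_div <- ev$y
      if (!is.na(t_birth)) {
        ## a full birth-to-division cycle just ended
        y_birth <- birth_states[[length(birth_states)]]
        fold <- y_div / y_birth
        fold_m <- fold[seq_len(G)]
        fold_p <- fold[G + seq_len(G)]
        completed <- completed + 1L
        cycles[[length(cycles) + 1L]] <- data.frame(
          cycle = completed, t_birth = t_birth, t_division = ev$t,
          length = ev$t - t_birth,
          max_fold_dev = max(abs(fold / 2 - 1)))
      }
      division_states[[length(division_states) + 1L]] <- y_div
      y <- y_div / 2
      t <- ev$t
      birth_states[[length(birth_states) + 1L]] <- y
      t_birth <- ev$t
      t_anchor <- ev$t
      armed <- FALSE
      seen_decrease <- FALSE
      h <- NULL
      times <- c(times, ev$t, ev$t)
      ys <- c(ys, list(y_div), list(y))
      next
    }
    times <- c(times, t)
    ys <- c(ys, list(y))
    if (t - t_anchor > max_cycle_time)
      stop("division threshold never crossed within ", max_cycle_time,
           " min (last ratio = ", signif(rat, 6), ", threshold = ",
           ratio_threshold, ")")
  }

  ymat <- do.call(rbind, ys)
  m <- ymat[, seq_len(G), drop = FALSE]
  p <- ymat[, G + seq_len(G), drop = FALSE]
  colnames(m) <- colnames(p) <- genome$gene_id
  M <- as.numeric(p %*% genome$L)
  cycdf <- do.call(rbind, cycles)
  nb <- length(birth_states)
  converged <- if (nb >= 2) {
    a <- birth_states[[nb - 1]]; b <- birth_states[[nb]]
    max(abs(b / a - 1)) < 1e-3
  } else FALSE
  structure(list(time = times, m = m, p = p, M = M, V = M / globals$rho,
                 n = p[, me$i_n], r = p[, me$i_r],
                 cycles = cycdf, fold_m = fold_m, fold_p = fold_p,
                 birth_states = birth_states,
                 division_states = division_states,
                 degenerate = degenerate, converged = converged,
                 threshold = ratio_threshold,
                 reporters = c(super = reporter_super, sub = reporter_sub),
                 genome = genome, globals = globals),
            class = "volscale_cell_cycle")
}

#' @export
print.volscale_cell_cycle <- function(x, ...) {
  cat("volscale cell-cycle run:", nrow(x$cycles %||% data.frame()),
      "recorded cycles\n")
  if (!is.null(x$cycles)) print(x$cycles)
  cat(sprintf("  converged: %s   degenerate trigger: %s\n",
              x$converged, x$degenerate))
  invisible(x)
}

#' Expression-versus-volume table from a trajectory
#'
#' Extracts the post-burn-in snapshots as a gene x volume-bin matrix plus
#' the per-bin volumes, the structure consumed by [fit_beta()] /
#' [fit_alpha()] and emitted by the expression-table writers.
#'
#' @param traj `volscale_trajectory`.
#' @param series `"mRNA"` or `"protein"`.
#' @param n_bins optionally thin the time grid to this many volume bins
#'   (evenly spaced in snapshot index, endpoints kept).
#' @return list with `expression` (genes x bins, rownames = gene ids),
#'   `volumes`, and `lifetimes` (named per-gene mRNA lifetimes).
#' @export
as_expression_table <- function(traj, series = c("mRNA", "protein"),
                                n_bins = NULL) {
  series <- match.arg(series)
  idx <- seq(traj$origin, length(traj$time))
  if (!is.null(n_bins) && n_bins < length(idx)) {
    if (n_bins < 3) stop("need at least 3 volume bins")
    idx <- idx[unique(round(seq(1, length(idx), length.out = n_bins)))]
  }
  mat <- if (series == "mRNA") traj$m[idx, , drop = FALSE] else traj$p[idx, , drop = FALSE]
  list(expression = t(mat), volumes = traj$V[idx],
       lifetimes = stats::setNames(traj$genome$tau_m, traj$genome$gene_id))
}
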