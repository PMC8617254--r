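test_that("mRNA relaxes on the closed-form curve when the proteome is frozen", {
  # Gamma_r = 0 freezes p, hence V and k_n; then
  # m(t) = k tau (1 - exp(-t/tau)) from m(0) = 0, and m -> k tau at t >> tau.
  gl <- global_params()
  genome <- custom_genome(L = c(5000, 10000, 500, 800), g = c(1, 5, 1, 1),
                          K_n = 6e3, K_r = 6e3,
                          Gamma_n = c(10, 40, 20, 15), Gamma_r = 0,
                          tau_m = 10)
  p0 <- c(500, 1e4, 2e5, 1.5e5)   # below this little genome's n_c (~870)
  st <- cell_state(m = rep(0, 4), p = p0)
  traj <- integrate_cell(st, genome, gl, t_end = 80, dt_out = 1)
  expect_equal(unname(traj$p[81, ]), p0, tolerance = 1e-12)  # frozen proteome
  k <- traj$k_n[1, ]
  for (ti in c(6, 21, 81)) {
    t <- traj$time[ti]
    expect_equal(unname(traj$m[ti, ]), unname(k * 10 * (1 - exp(-t / 10))),
                 tolerance = 1e-6)
  }
  expect_equal(unname(traj$m[81, ]), unname(k * 10), tolerance = 1e-3)
})

test_that("halving the integrator tolerance leaves the endpoint unchanged", {
  gl <- global_params()
  g <- make_genome(20, K_cv = 0.5, lifetime_cv = 0, seed = 31)
  cal <- calibrate(g, gl)
  t1 <- integrate_cell(cal$state0, cal$genome, gl, t_end = 60, rtol = 1e-8)
  t2 <- integrate_cell(cal$state0, cal$genome, gl, t_end = 60, rtol = 5e-9)
  last <- nrow(t1$m)
  expect_lt(max(abs(t1$m[last, ] / t2$m[last, ] - 1)), 1e-6)
  expect_lt(max(abs(t1$p[last, ] / t2$p[last, ] - 1)), 1e-6)
})

test_that("mass bookkeeping holds at every snapshot and runs are deterministic", {
  traj <- fx_homog()
  expect_lt(max(abs(traj$M - as.numeric(traj$p %*% traj$genome$L)) / traj$M),
            1e-8)
  expect_equal(traj$V * traj$globals$rho, traj$M, tolerance = 1e-12)
  gl <- global_params()
  g <- make_genome(15, seed = 32, lifetime_cv = 0)
  tr1 <- run_experiment(g, gl, t_end = 50)
  tr2 <- run_experiment(g, gl, t_end = 50)
  expect_identical(tr1$m, tr2$m)
  expect_identical(tr1$p, tr2$p)
})

test_that("homogeneous recruitment gives exponential volume growth and
           constant concentrations", {
  traj <- fx_homog()
  idx <- seq(traj$origin, length(traj$time))
  expect_gt(traj$V[max(idx)] / traj$V[traj$origin], 3)
  fit <- stats::lm(log(traj$V[idx]) ~ traj$time[idx])
  expect_gt(summary(fit)$r.squared, 0.9999)
  # every generic gene's mRNA concentration within 2% of its origin value
  conc <- traj$m[idx, -(1:2)] / traj$V[idx]
  drift <- sweep(conc, 2, conc[1, ], "/") - 1
  expect_lt(max(abs(drift)), 0.02)
})

test_that("short mRNA lifetimes slave the mRNA pool to the production rate", {
  gl <- global_params()
  g <- make_genome(20, K_cv = 0.5, lifetime_mean = 0.1, lifetime_cv = 0,
                   seed = 33)
  cal <- calibrate(g, gl)
  traj <- integrate_cell(cal$state0, cal$genome, gl, t_end = 10, dt_out = 0.5)
  late <- which(traj$time >= 1)
  rel <- abs(traj$m[late, ] / (0.1 * traj$k_n[late, ]) - 1)
  expect_lt(max(rel), 0.01)
})

test_that("degradable proteins track the quasi-steady production balance", {
  gl <- global_params()
  check_quasi_steady <- function(tau_p) {
    g <- make_genome(20, K_cv = 0, lifetime_mean = 1, lifetime_cv = 0,
                     n_degradable = 18, tau_p_deg = tau_p, seed = 34)
    cal <- calibrate(g, gl)
    traj <- run_experiment(g, gl, burn_in = 100, t_end = 200)
    i <- length(traj$time)
    st <- cell_state(m = traj$m[i, ], p = traj$p[i, ])
    al <- production_rates(st, cal$genome, gl)
    deg <- is.finite(cal$genome$tau_p)
    mu <- log(traj$M[i] / traj$M[i - 10]) / 10   # realized growth rate
    list(raw = max(abs(traj$p[i, deg] / (al$k_r[deg] * tau_p) - 1)),
         lagged = max(abs(traj$p[i, deg] * (1 + mu * tau_p) /
                            (al$k_r[deg] * tau_p) - 1)))
  }
  # tau_p short against the doubling time: quasi-steady form within 5%
  expect_lt(check_quasi_steady(5)$raw, 0.05)
  # at tau_p = 10 the systematic growth-dilution lag 1/(1 + mu tau_p) is
  # itself ~6%; the lag-corrected form holds to 1%
  expect_lt(check_quasi_steady(10)$lagged, 0.01)
})

test_that("protocol violations are rejected", {
  gl <- global_params()
  g <- make_genome(10, seed = 35)
  expect_error(run_experiment(g, gl, burn_in = 100, t_end = 50), "burn_in")
  cal <- calibrate(g, gl)
  expect_error(integrate_cell(cal$state0, cal$genome, gl, t_end = 0), "t_end")
})

test_that("the periodic cell cycle doubles every copy number at division", {
  cyc <- fx_cycle()
  expect_false(cyc$degenerate)
  expect_true(cyc$converged)
  # birth -> division fold change of 2 within 1% for every mRNA and protein
  expect_lt(max(abs(c(cyc$fold_m, cyc$fold_p) / 2 - 1)), 0.01)
  # the superlinear reporter's concentration dips after birth, then recovers
  tb <- cyc$cycles$t_birth[nrow(cyc$cycles)]
  td <- cyc$cycles$t_division[nrow(cyc$cycles)]
  sel <- cyc$time >= tb & cyc$time <= td
  conc <- cyc$p[sel, "gene_0001"] / cyc$V[sel]
  expect_lt(min(conc), conc[1] * (1 - 1e-3))
  expect_equal(conc[sum(sel)], conc[1], tolerance = 0.02)
  # cycle length settles at the mass doubling time
  len <- cyc$cycles$length[nrow(cyc$cycles)]
  expect_equal(len * cyc$globals$mu0 / log(2), 1, tolerance = 0.1)
})

test_that("degenerate and unreachable division triggers are flagged/errored", {
  gl <- global_params()
  g <- make_genome(30, K_cv = 0, lifetime_cv = 0, lifetime_mean = 1,
                   special_overrides = c(gene_0001 = 20, gene_0002 = 0.2),
                   seed = 36)
  cal <- calibrate(g, gl)
  r0 <- cal$p0[g$gene_id == "gene_0001"] / cal$p0[g$gene_id == "gene_0002"]
  # threshold at the current ratio: immediate division, zero-length cycle
  cyc <- run_cell_cycle(g, gl, "gene_0001", "gene_0002",
                        ratio_threshold = r0, n_cycles = 1)
  expect_true(cyc$degenerate)
  expect_true(any(cyc$cycles$length == 0))
  # threshold out of reach: diagnostic error
  expect_error(run_cell_cycle(g, gl, "gene_0001", "gene_0002",
                              ratio_threshold = 1e6, n_cycles = 1,
                              max_cycle_time = 60),
               "never crossed")
  # reporter on the wrong side of the pivot
  expect_error(run_cell_cycle(g, gl, "gene_0002", "gene_0001",
                              ratio_threshold = r0, n_cycles = 1),
               "weighted average")
})
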