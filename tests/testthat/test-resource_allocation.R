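# The spec example: homogeneous K, n = 50, a genome holding n_c = 100 RNAPs,
# total RNAP concentration c_n = 1000 K. The self-consistency equation
# reduces to a quadratic whose root is the oracle:
#   F = (-50050 + sqrt(50050^2 + 4 * 5e4 * 50)) / 1e5  ~ 9.98e-4.
# The crafted genome: slots = 1*(1+9) + 5*(1+9) + 1*(1+39) = 100, and the
# protein numbers are chosen so that M = rho V is consistent with c_n.
crafted_half_saturated <- function(K = 6e3) {
  gl <- global_params(v_n = 2400, rho = 3e11, a = 10)
  genome <- custom_genome(L = c(1000, 1000, 1000), g = c(1, 5, 1),
                          K_n = K, K_r = K,
                          Gamma_n = c(21.6, 21.6, 93.6),  # Lambda = 9, 9, 39
                          Gamma_r = 6)
  n <- 50
  V_n <- n / (1000 * K)              # c_n = 1000 K
  M <- gl$rho * gl$a * V_n
  p_rest <- (M - n * 1000) / 1000    # split over ribosome + generic
  state <- cell_state(m = c(10, 10, 10),
                      p = c(n, p_rest * 0.6, p_rest * 0.4))
  list(gl = gl, genome = genome, state = state, n = n, K = K)
}

test_that("numeric free-RNAP root matches the homogeneous quadratic oracle", {
  cs <- crafted_half_saturated()
  sol <- solve_free_rnap(cs$state, cs$genome, cs$gl)
  F_expected <- (-50050 + sqrt(50050^2 + 4 * 5e4 * 50)) / 1e5
  expect_equal(sol$F_n, F_expected, tolerance = 1e-10)
  expect_equal(sol$F_n, quad_free_fraction(50, 100, 1000 * cs$K, cs$K),
               tolerance = 1e-9)
  # P_b ~ n/n_c = 0.5 within 0.2%
  P_b <- sol$c_n_free / (sol$c_n_free + cs$K)
  expect_lt(abs(P_b / 0.5 - 1), 0.002)
})

test_that("solver equals the quadratic oracle on random homogeneous cases", {
  set.seed(20)
  for (i in 1:200) {
    K <- 10^runif(1, 2, 5)
    S <- 10^runif(1, 2, 5)                 # total slots
    n <- S * runif(1, 0.05, 0.95)          # stay in Phase 1
    conc <- K * 10^runif(1, 0.5, 4)
    slots <- rep(S / 10, 10)
    F_num <- volscale:::solve_free_fraction(n, conc, slots, rep(K, 10))
    expect_equal(F_num, quad_free_fraction(n, S, conc, K), tolerance = 1e-10)
  }
})

test_that("polymerase bookkeeping closes for random heterogeneous states", {
  set.seed(21)
  gl <- global_params()
  for (i in 1:25) {
    cal <- calibrate(make_genome(40, K_cv = 1, gamma_cv = 1, seed = i), gl)
    for (j in 1:8) {
      scale <- 10^runif(1, -0.5, 1)
      st <- cell_state(m = cal$m0 * stats::runif(40, 0.2, 5),
                       p = cal$p0 * scale)
      al <- production_rates(st, cal$genome, gl)
      q <- volscale:::state_quantities(st, cal$genome, gl)
      slots_n <- cal$genome$g * (1 + cal$genome$Gamma_n * cal$genome$L / gl$v_n)
      bound_n <- sum(slots_n * al$P_b)
      expect_lt(abs(q$n * al$F_n + bound_n - q$n) / q$n, 1e-9)
      slots_r <- st$m * (1 + cal$genome$Gamma_r * cal$genome$L / gl$v_r)
      bound_r <- sum(slots_r * al$P_r)
      expect_lt(abs(q$r * al$F_r + bound_r - q$r) / q$r, 1e-9)
    }
  }
})

test_that("F_n grows with the RNAP pool; occupancy tracks n/n_c when c_n >> K", {
  gl <- global_params()
  cal <- calibrate(make_genome(40, K_cv = 0.5, seed = 3), gl)
  fracs <- seq(0.05, 0.9, by = 0.05)
  F_prev <- -Inf
  for (f in fracs) {
    p <- cal$p0
    p[1] <- f * cal$n_c        # dial the RNAP copy number
    st <- cell_state(m = cal$m0, p = p)
    al <- production_rates(st, cal$genome, gl)
    expect_gt(al$F_n, F_prev)  # monotone in n
    F_prev <- al$F_n
  }
  # homogeneous-K limit: |P_b - n/n_c| / (n/n_c) <= K/c_n * n_c/(n_c - n)
  cal0 <- calibrate(make_genome(40, K_cv = 0, lifetime_cv = 0, seed = 3), gl)
  for (f in c(0.1, 0.5, 0.9)) {
    p <- cal0$p0
    p[1] <- f * cal0$n_c
    st <- cell_state(m = cal0$m0, p = p)
    al <- production_rates(st, cal0$genome, gl)
    q <- volscale:::state_quantities(st, cal0$genome, gl)
    bound <- (cal0$genome$K_n[1] / q$c_n) * 1 / (1 - f)
    expect_lt(abs(al$P_b[3] / f - 1), bound)
  }
})

test_that("degenerate pools behave by convention", {
  cs <- crafted_half_saturated()
  # no RNAPs at all
  st0 <- cs$state
  st0$p[1] <- 0
  expect_warning(sol <- solve_free_rnap(st0, cs$genome, cs$gl), "no RNAPs")
  expect_equal(sol$c_n_free, 0)
  # no mRNAs: every ribosome is free
  stm <- cell_state(m = c(0, 0, 0), p = cs$state$p)
  sol <- solve_free_ribosome(stm, cs$genome, cs$gl)
  expect_equal(sol$F_r, 1)
  # ribosomes far above the mRNA slot capacity: F_r -> 1 - slots/r
  gl <- cs$gl
  genome <- cs$genome
  genome$K_r <- rep(1e-8, 3)              # saturated binding sites
  st <- cell_state(m = c(2, 2, 2), p = cs$state$p)
  slots <- sum(st$m * (1 + genome$Gamma_r * genome$L / gl$v_r))
  r <- st$p[2]
  expect_gt(r, 10 * slots)
  sol <- solve_free_ribosome(st, genome, gl)
  expect_equal(sol$F_r, 1 - slots / r, tolerance = 1e-6)
  # vanishing K with n = n_c/2: every polymerase binds, F_n -> 0, P_b -> 1/2
  genome2 <- cs$genome
  genome2$K_n <- rep(1e-9, 3)
  sol2 <- solve_free_rnap(cs$state, genome2, cs$gl)
  expect_lt(sol2$F_n, 1e-6)
  P_b <- sol2$c_n_free / (sol2$c_n_free + genome2$K_n[1])
  expect_equal(P_b, 0.5, tolerance = 1e-6)
})

test_that("production rates follow the Phase-1 laws", {
  # homogeneous K at c_n = 1000 K: k_n,i = Gamma g n/n_c within 1%
  cs <- crafted_half_saturated()
  al <- production_rates(cs$state, cs$genome, cs$gl)
  expect_true(al$phase1)
  expect_equal(al$k_n, cs$genome$Gamma_n * cs$genome$g * 0.5, tolerance = 0.01)

  # one special gene at 20 K in a large homogeneous background, n/n_c = 0.5:
  # k = Gamma g K * 50/1050 (hand evaluation of the one-special-gene law)
  gl <- global_params()
  g <- make_genome(300, K_cv = 0, lifetime_cv = 0,
                   special_overrides = c(gene_0001 = 20), seed = 11)
  cal <- calibrate(g, gl)
  p <- cal$p0
  p[1] <- 0.5 * cal$n_c
  st <- cell_state(m = cal$m0, p = p)
  al <- production_rates(st, cal$genome, gl)
  i <- which(g$gene_id == "gene_0001")
  expect_equal(al$k_n[i],
               cal$genome$Gamma_n[i] * cal$genome$g[i] * 50 / 1050,
               tolerance = 0.01)

  # a silent gene produces nothing whatever the occupancy
  genome0 <- cs$genome
  genome0$Gamma_n[3] <- 0
  al0 <- production_rates(cs$state, genome0, cs$gl)
  expect_identical(al0$k_n[3], 0)
})
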