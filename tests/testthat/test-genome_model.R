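test_that("make_genome reproduces the requested statistics and structure", {
  g <- make_genome(2000, K_mean = 6e3, K_cv = 0.5, seed = 1)
  gen <- g[g$role == "generic", ]
  expect_lt(abs(mean(gen$K_n) / 6e3 - 1), 0.05)
  expect_lt(abs(sd(gen$K_n) / mean(gen$K_n) / 0.5 - 1), 0.10)
  expect_identical(g$g, c(1, 5, rep(1, 1998)))
  expect_identical(g$role[1:2], c("rnap", "ribosome"))

  # bit-reproducible under the seed; distinct across seeds
  expect_identical(g, make_genome(2000, K_mean = 6e3, K_cv = 0.5, seed = 1))
  expect_false(isTRUE(all.equal(
    g$K_n, make_genome(2000, K_mean = 6e3, K_cv = 0.5, seed = 2)$K_n)))

  # degenerate CV: every K exactly at the mean (machinery included)
  g0 <- make_genome(50, K_cv = 0, seed = 3)
  expect_true(all(g0$K_n == 6e3))

  # special overrides are exact multiples of K_mean, machinery untouched
  gs <- make_genome(50, K_cv = 0, seed = 3,
                    special_overrides = c(gene_0003 = 20, gene_0010 = 0.2))
  expect_equal(gs$K_n[gs$gene_id == "gene_0003"], 20 * 6e3)
  expect_equal(gs$K_n[gs$gene_id == "gene_0010"], 0.2 * 6e3)
  expect_equal(gs$K_n[1:2], c(6e3, 6e3))

  expect_error(make_genome(50, seed = 1, special_overrides = c(rnap = 2)),
               "model assumption")
  expect_error(make_genome(50, seed = 1, special_overrides = c(nope = 2)),
               "unknown gene_id")
  expect_error(make_genome(50, K_mean = -1, seed = 1))
  expect_error(make_genome(2, seed = 1), "at least 3")

  # degradable subset gets the finite lifetime, everyone else Inf
  gd <- make_genome(50, seed = 4, n_degradable = 10, tau_p_deg = 10)
  expect_equal(sum(is.finite(gd$tau_p)), 10)
  expect_true(all(gd$tau_p[is.finite(gd$tau_p)] == 10))
  expect_true(all(gd$role[is.finite(gd$tau_p)] == "generic"))
})

test_that("calibration evaluates the provisioning identities", {
  gl <- global_params()  # mu0 = 0.006/min, v_r = 600, L_r = 1e4, L_n = 5e3
  cal <- calibrate(make_genome(50, K_cv = 0, lifetime_cv = 0, seed = 1), gl)
  # phi_r = mu0 L_r / v_r = 0.006 * 1e4 / 600 ; phi_n = 0.1 phi_r L_n / L_r
  expect_equal(cal$phi_r, 0.1)
  expect_equal(cal$phi_n, 0.005)

  # mass-shift rule and initial-mass bookkeeping
  i_n <- which(cal$genome$role == "rnap")
  expect_equal(cal$phi0[i_n] * cal$M0_actual, cal$phi_n * gl$M_b)
  expect_equal(sum(cal$p0 * cal$genome$L), cal$M0_actual)
  # attempted RNAP copy number carried into the initial state
  expect_equal(cal$p0[i_n], cal$phi_n * gl$M_b / cal$genome$L[i_n])
})

test_that("realized n_c hits the attempted value to machine precision", {
  gl <- global_params()
  set.seed(10)
  for (i in 1:100) {
    g <- make_genome(sample(10:80, 1), K_cv = runif(1, 0, 1),
                     lifetime_cv = runif(1, 0, 1),
                     gamma_cv = sample(c(0, 1), 1), seed = i)
    cal <- calibrate(g, gl)
    expect_lt(abs(cal$n_c - gl$n_c_target) / gl$n_c_target, 1e-12)
    expect_lt(abs(nc_of(cal$genome, gl) - gl$n_c_target) / gl$n_c_target, 1e-12)
  }
})

test_that("attempted RNAP:ribosome copy ratio is 0.1 whatever the lengths", {
  set.seed(11)
  for (i in 1:20) {
    L_n <- runif(1, 1000, 9000)
    L_r <- runif(1, 5000, 20000)
    mu0 <- runif(1, 0.002, 0.01)
    gl <- global_params(mu0 = mu0)
    g <- make_genome(30, seed = i, L_rnap = L_n, L_ribosome = L_r)
    cal <- calibrate(g, gl)
    ratio <- (cal$phi_n / L_n) / (cal$phi_r / L_r)
    expect_equal(ratio, 0.1, tolerance = 1e-12)
  }
})

test_that("calibration is idempotent", {
  gl <- global_params()
  cal1 <- calibrate(make_genome(60, gamma_cv = 1, seed = 7), gl)
  cal2 <- calibrate(cal1$genome, gl)
  expect_equal(cal2$genome$Gamma_n, cal1$genome$Gamma_n, tolerance = 1e-14)
  expect_equal(cal2$m0, cal1$m0, tolerance = 1e-14)
})

test_that("calibration rejects infeasible worlds", {
  g <- make_genome(30, seed = 1)
  # phi_r >= 1: doubling faster than a ribosome can copy itself
  expect_error(calibrate(g, global_params(mu0 = 0.1)), "phi_r")
  # n_c_target below the bare gene copy count leaves no elongation slots
  expect_error(calibrate(g, global_params(n_c_target = 10)), "n_c_target")
})

test_that("nc_of sums promoter and elongation slots", {
  # three genes, each g = 1 with Gamma_n L / v_n = 9: n_c = 3 * 10
  g <- custom_genome(L = c(900, 900, 900), g = c(1, 1, 1), K_n = 1e3,
                     K_r = 1e3, Gamma_n = 24, Gamma_r = 6)
  expect_equal(nc_of(g, global_params(v_n = 2400)), 30)
  # no transcribing slots: n_c = sum(g)
  g2 <- custom_genome(L = c(900, 900, 900), g = c(1, 5, 2), K_n = 1e3,
                      K_r = 1e3, Gamma_n = 0, Gamma_r = 6)
  expect_equal(nc_of(g2, global_params()), 8)
  expect_error(nc_of(make_genome(10, seed = 1), global_params()),
               "uncalibrated")
  # the flagship calibrated genome holds exactly 1e4 RNAPs
  cal <- calibrate(make_genome(2000, seed = 1), global_params())
  expect_equal(nc_of(cal$genome, global_params()), 1e4)
})

test_that("gene-table TSV round trip is lossless at 12 significant digits", {
  gl <- global_params()
  cal <- calibrate(make_genome(200, gamma_cv = 1, n_degradable = 20, seed = 9), gl)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genome(cal$genome, path, meta = list(seed = 9, config_hash = "abc"))
  g2 <- read_genome(path)
  for (col in c("L", "g", "K_n", "K_r", "Gamma_n", "Gamma_r", "tau_m", "gamma_mult"))
    expect_equal(g2[[col]], cal$genome[[col]], tolerance = 1e-12)
  expect_identical(g2$gene_id, cal$genome$gene_id)
  expect_identical(is.infinite(g2$tau_p), is.infinite(cal$genome$tau_p))
  expect_equal(read_meta_header <- volscale:::read_meta(path)$seed, "9")

  # schema violations are hard errors naming the offender
  lines <- readLines(path)
  hdr <- grep("^gene_id", lines)
  lines[hdr] <- sub("\trole", "\tROLE", lines[hdr])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_genome(bad), "role")

  lines2 <- readLines(path)
  lines2[hdr + 3] <- "truncated\trow"
  writeLines(lines2, bad)
  expect_error(read_genome(bad), "line")
})
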