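test_that("atom percent excess subtracts the natural-abundance baseline", {
  expect_equal(atom_percent_excess(0.3663), 0)
  expect_equal(atom_percent_excess(10.3663), 10)
  expect_equal(atom_percent_excess(98, 0.3663), 97.6337)
  expect_error(atom_percent_excess(0.2), "negative excess")
})

test_that("two-point estimator reproduces the analytical solutions", {
  nat <- 0.3663
  # constant pool: p = (C0/dt) ln(A0/At)
  s <- tracer_series("a", "amino_acid", c(0, 720), c(10, 10),
                     c(8, 4) + nat)
  r <- gross_rates_kb(s)
  expect_equal(r$production, 10 / 0.5 * log(2), tolerance = 1e-10)
  expect_equal(r$consumption, r$production, tolerance = 1e-10)
  expect_length(r$flags, 0L)

  # changing pool: p = ((C0-Ct)/dt) ln(A0/At)/ln(C0/Ct)
  s2 <- tracer_series("a", "amino_acid", c(0, 1440), c(10, 14),
                      c(10, 5) + nat)
  r2 <- gross_rates_kb(s2)
  expect_equal(r2$production, -4 * log(2) / log(10 / 14), tolerance = 1e-10)
  expect_equal(r2$consumption, r2$production - 4, tolerance = 1e-10)
  expect_equal(round(r2$production, 4), 8.2402)
  expect_equal(round(r2$consumption, 4), 4.2402)

  # no dilution, no net change -> both rates zero, flagged
  s3 <- tracer_series("a", "ammonium", c(0, 1440), c(10, 10),
                      c(5, 5) + nat)
  r3 <- gross_rates_kb(s3)
  expect_equal(r3$production, 0)
  expect_equal(r3$consumption, 0)
  expect_true("no-dilution" %in% r3$flags)
})

test_that("estimator obeys mass balance and scale/baseline equivariance", {
  nat <- 0.3663
  set.seed(101)
  for (i in 1:25) {
    p <- runif(1, 0, 30); cns <- runif(1, 0, 30)
    C0 <- runif(1, 2, 20); A0 <- runif(1, 1, 30)
    tr <- closed_form_ipd(p, cns, C0, A0, 720)
    if (tr$C <= 0.2 * C0) next
    s <- tracer_series("a", "amino_acid", c(0, 720), c(C0, tr$C),
                       c(A0, tr$A) + nat)
    r <- gross_rates_kb(s)
    if (length(r$flags) == 0L) {
      # consumption - production = -(net pool change)/dt, exactly
      expect_equal(r$consumption - r$production, -(tr$C - C0) / 0.5,
                   tolerance = 1e-9)
    }
    # multiplying all concentrations by k multiplies both rates by k
    k <- 3.7
    sk <- tracer_series("a", "amino_acid", c(0, 720), k * c(C0, tr$C),
                        c(A0, tr$A) + nat)
    rk <- gross_rates_kb(sk)
    expect_equal(rk$production, k * r$production, tolerance = 1e-9)
    expect_equal(rk$consumption, k * r$consumption, tolerance = 1e-9)
    # shifting the natural-abundance baseline identically leaves rates alone
    sb <- tracer_series("a", "amino_acid", c(0, 720), c(C0, tr$C),
                        c(A0, tr$A) + 1.2, natural_abundance = 1.2)
    rb <- gross_rates_kb(sb)
    expect_equal(rb$production, r$production, tolerance = 1e-9)
  }
})

test_that("two-point formula is continuous at the constant-pool branch", {
  nat <- 0.3663
  p_limit <- gross_rates_kb(tracer_series("a", "amino_acid", c(0, 720),
                                          c(10, 10), c(8, 4) + nat))
  for (dC in c(1e-3, 1e-5)) {
    r <- gross_rates_kb(tracer_series("a", "amino_acid", c(0, 720),
                                      c(10, 10 + dC), c(8, 4) + nat))
    expect_equal(r$production, p_limit$production, tolerance = 1e-3)
  }
})

test_that("forward simulation matches closed forms", {
  nat <- 0.3663
  # p = c: pool conserved
  s <- simulate_ipd_forward(12, 12, 8, 20, c(5, 30, 120))
  expect_equal(s$concentrations, rep(8, 3), tolerance = 1e-8)
  expect_equal(s$atom_pcts - nat,
               closed_form_ipd(12, 12, 8, 20, c(5, 30, 120))$A,
               tolerance = 1e-7)
  # c = 0: dilution by production only, A = A0 C0 / C(t)
  s2 <- simulate_ipd_forward(10, 0, 5, 30, c(10, 60))
  C_t <- 5 + 10 * c(10, 60) / 1440
  expect_equal(s2$concentrations, C_t, tolerance = 1e-8)
  expect_equal(s2$atom_pcts - nat, 30 * 5 / C_t, tolerance = 1e-7)
  # consumption that exhausts the pool within the horizon errors out
  expect_error(simulate_ipd_forward(0, 40, 1, 10, c(60, 2880)), "horizon")
})

test_that("simulate -> estimate round trip recovers the rates", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(1, 0, 50); cns <- runif(1, 0, 50)
    C0 <- runif(1, 5, 50); A0 <- runif(1, 5, 40)
    s <- tryCatch(simulate_ipd_forward(p, cns, C0, A0, c(30, 720)),
                  error = function(e) NULL)
    if (is.null(s)) next
    r <- gross_rates_kb(s)
    if (p > 1e-3) expect_equal(r$production, p, tolerance = 1e-3)
    if (cns > 1e-3) expect_equal(r$consumption, cns, tolerance = 1e-3)
  }
})

test_that("all-pairs estimates agree on noiseless multi-point series", {
  s <- simulate_ipd_forward(6, 9, 12, 25, c(2, 10, 20))
  r <- gross_rates_kb(s, pair = "all")
  expect_equal(nrow(r$pairwise), 3L)
  expect_equal(r$production, 6, tolerance = 1e-6)
  expect_equal(r$consumption, 9, tolerance = 1e-6)
})

test_that("per-sample rate assembly maps pools to the right fluxes", {
  aa <- simulate_ipd_forward(4, 6, 10, 25, c(2, 10, 20),
                             sample_id = "s1", pool = "amino_acid")
  nh4 <- simulate_ipd_forward(2, 1.5, 8, 0.8, c(240, 1440),
                              sample_id = "s1", pool = "ammonium")
  no3 <- simulate_ipd_forward(0.5, 0.4, 4, 1.5, c(240, 1440),
                              sample_id = "s1", pool = "nitrate")
  rates <- pool_rates_for_sample(list(aa, nh4, no3))
  expect_equal(rates$U_N, 6, tolerance = 1e-4)
  expect_equal(rates$M_N, 2, tolerance = 1e-4)
  expect_equal(rates$gross_nitrification, 0.5, tolerance = 1e-4)
  expect_equal(rates$nh4_consumption, 1.5, tolerance = 1e-4)
  expect_equal(rates$no3_consumption, 0.4, tolerance = 1e-4)

  # no mineralization: ammonium shows no dilution, production 0
  nh4_0 <- simulate_ipd_forward(0, 0.2, 8, 0.8, c(240, 1440),
                                sample_id = "s1", pool = "ammonium")
  r0 <- pool_rates_for_sample(list(aa, nh4_0))
  expect_equal(r0$M_N, 0)
  expect_true(is.na(r0$gross_nitrification))

  expect_error(pool_rates_for_sample(list(aa)), "incomplete")
  aa2 <- simulate_ipd_forward(4, 6, 10, 25, c(2, 10), sample_id = "other")
  expect_error(pool_rates_for_sample(list(aa, aa2, nh4)),
               "more than one sample")
})
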