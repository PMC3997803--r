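test_that("NUE is the retained fraction of gross organic N uptake", {
  expect_equal(as.numeric(compute_nue(1, 0)), 1)
  expect_equal(as.numeric(compute_nue(1, 1)), 0)
  expect_equal(as.numeric(compute_nue(2, 0.34)), 0.83)
  expect_error(compute_nue(0, 1), "U_N")
  expect_error(compute_nue(1, -0.1), "M_N")

  # noise-induced M_N > U_N is clamped to 0, flagged, never an error
  clamped <- compute_nue(1, 1.2)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "flagged"))

  # strictly decreasing in M_N, invariant under joint rescaling
  u <- 5
  m <- seq(0, 5, by = 0.5)
  nue <- as.numeric(compute_nue(rep(u, length(m)), m))
  expect_true(all(diff(nue) < 0))
  expect_equal(as.numeric(compute_nue(7 * u, 7 * m)), nue)
})

test_that("inorganic-inclusive NUE extends the organic-only definition", {
  # all inorganic terms zero: reduces to compute_nue
  expect_equal(as.numeric(compute_nue_inorg(2, 0, 0, 0.34, 0)),
               as.numeric(compute_nue(2, 0.34)))
  expect_equal(as.numeric(compute_nue_inorg(8, 1, 0.5, 1, 0.5)),
               8 / 9.5)
  # everything released again: zero
  expect_equal(as.numeric(compute_nue_inorg(1, 0.5, 0, 1.2, 0.3)), 0)
  # the addition variant only subtracts mineralization
  expect_equal(as.numeric(compute_nue_inorg(8, 1, 0.5, 1, 0.5,
                                            variant = "addition")),
               8.5 / 9.5)
  expect_error(compute_nue_inorg(0, 0, 0, 0, 0), "total uptake")
})

test_that("imbalance is resource C:N normalized to biomass C:N", {
  expect_equal(imbalance(20, 5.4), 20 / 5.4)
  expect_equal(imbalance(10, 10), 1)
  expect_equal(imbalance(62, 9), 62 / 9)
  expect_true(is.na(imbalance(20, NA)))
  expect_error(imbalance(-1, 5), "must be > 0")
})

test_that("TER algebra reproduces the published mass-balance example", {
  # CUE implied at the threshold: NUE 0.83, biomass C:N 5.4, TER 20
  expect_equal(round(cue_at_ter(0.83, 5.4, 20), 4), 0.2241)
  # and forward again with the printed (rounded) CUE of 0.22
  t1 <- ter(0.83, 0.22, 5.4)
  expect_equal(round(t1$TER_CN, 2), 20.37)
  expect_equal(ter(0.4, 0.4, 7.7)$TER_CN, 7.7)  # NUE = CUE -> TER = B_CN
  expect_equal(ter(1.0, 0.5, 8)$TER_CN, 16)
  expect_equal(round(cue_at_ter(0.89, 9, 45), 3), 0.178)
  expect_error(cue_at_ter(0.8, 5, 0), "TER_CN")
})

test_that("ter and cue_at_ter invert each other to 1e-12", {
  set.seed(5)
  for (i in 1:50) {
    nue <- runif(1, 0.05, 1); cue <- runif(1, 0.05, 1)
    b <- runif(1, 3, 25)
    tt <- ter(nue, cue, b)
    expect_equal(cue_at_ter(nue, b, tt$TER_CN), cue, tolerance = 1e-12)
  }
})

test_that("the stoichiometric mass balance solves for any missing member", {
  expect_equal(unname(mass_balance_solve(R_CN = 20, CUE = 0.2241,
                                         NUE = 0.83)),
               5.4, tolerance = 1e-3)
  expect_equal(unname(mass_balance_solve(R_CN = 12, B_CN = 12, CUE = 0.3)),
               0.3)  # balanced resource: NUE = CUE
  expect_equal(unname(mass_balance_solve(B_CN = 8, NUE = 0.6, CUE = 0.3)),
               16)
  # round trips to 1e-12
  out <- mass_balance_solve(NUE = 0.7, B_CN = 6, R_CN = 30)
  expect_named(out, "CUE")
  expect_equal(unname(mass_balance_solve(CUE = unname(out), B_CN = 6,
                                         R_CN = 30)),
               0.7, tolerance = 1e-12)
  # an implied efficiency above 1 is returned but flagged
  flagged <- mass_balance_solve(CUE = 0.9, R_CN = 30, B_CN = 6)
  expect_true(attr(flagged, "flagged"))
  expect_error(mass_balance_solve(CUE = 0.5, NUE = 0.5), "arity")
  expect_error(mass_balance_solve(CUE = 0.5, NUE = 0.5, B_CN = 5,
                                  R_CN = 20), "arity")
})

test_that("homeostasis regression classifies regulation strength", {
  r <- c(10, 15, 20, 30, 45, 60)
  # constant biomass C:N: strict homeostasis, slope 0
  f0 <- suppressWarnings(fit_homeostasis(r, rep(8, 6)))
  expect_equal(f0$slope, 0, tolerance = 1e-10)
  expect_identical(f0$classification, "homeostatic")
  # biomass tracking the resource one-to-one: no regulation
  f1 <- suppressWarnings(fit_homeostasis(r, r))
  expect_equal(f1$slope, 1, tolerance = 1e-10)
  expect_identical(f1$classification, "non-homeostatic")
  expect_error(fit_homeostasis(c(10, 20), c(5, 6)), "insufficient")
  # samples without biomass are excluded, not imputed
  f2 <- suppressWarnings(fit_homeostasis(c(r, 25), c(rep(8, 6), NA)))
  expect_equal(f2$n, 6L)
})

test_that("homeostasis slope recovery stays within 2 standard errors", {
  hits <- vapply(1:40, function(s) {
    ds <- generate_dataset(fast_config(), seed = s, tracer = FALSE)
    tr <- ds$truth[ds$truth$biomass_measured, ]
    f <- fit_homeostasis(tr$R_CN, tr$B_CN)
    abs(f$slope - 0.14) <= 2 * f$slope_se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
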