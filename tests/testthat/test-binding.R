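test_that("simulate_itc honours degenerate limits", {
  sch <- titration_schedule()
  z <- simulate_itc(list(kd = 10, dh = 0, n = 1), sch, noise_sd = 0)
  expect_true(all(z$heat_ucal == 0))
  nb <- simulate_itc(list(kd = 1e9, dh = -8, n = 1), sch, noise_sd = 0)
  expect_true(all(abs(nb$heat_ucal) < 1e-3))
  # determinism under seed, and seed-locality of the RNG state
  a <- simulate_itc(list(kd = 10, dh = -8, n = 1), sch, 0.1, seed = 7)
  b <- simulate_itc(list(kd = 10, dh = -8, n = 1), sch, 0.1, seed = 7)
  expect_identical(a$heat_ucal, b$heat_ucal)
  d <- simulate_itc(list(kd = 10, dh = -8, n = 1), sch, 0.1, seed = 8)
  expect_false(identical(a$heat_ucal, d$heat_ucal))
})

test_that("integrated heat respects enthalpy conservation when saturating", {
  # rapid saturation at small cumulative volume keeps overflow losses < 1%
  sch <- titration_schedule(syringe_conc = 6600, injection_volume = 1,
                            n_injections = 15)
  q <- simulate_itc(list(kd = 1e-3, dh = -8, n = 1), sch, noise_sd = 0)
  expected <- -8 * 1 * 60 * 200 * 1e-12 * 1e9  # dh * n * M0 * V0, in ucal
  expect_equal(sum(q$heat_ucal), expected, tolerance = 0.01)
})

test_that("fit_one_site round-trips noise-free data exactly", {
  tt <- simulate_itc(list(kd = 10, dh = -8, n = 1), noise_sd = 0)
  f <- fit_one_site(tt)
  expect_equal(f$kd, 10, tolerance = 1e-4)
  expect_equal(f$dh, -8, tolerance = 1e-4)
  expect_equal(f$n, 1, tolerance = 1e-4)
  expect_true(f$converged)
  # the optional baseline variant round-trips too
  fb <- fit_one_site(tt, fit_baseline = TRUE)
  expect_equal(fb$kd, 10, tolerance = 1e-3)
  # flat data is flagged, not an error
  flat <- tt; flat$heat_ucal <- 0
  ff <- fit_one_site(flat)
  expect_false(ff$converged)
  expect_match(ff$flag, "unidentifiable")
})

test_that("noisy titrations recover Kd within 10% (median over seeds)", {
  kds <- vapply(1:20, function(r) {
    tt <- simulate_itc(list(kd = 15.7, dh = -7.4, n = 1), noise_sd = 0.1,
                       seed = r)
    fit_one_site(tt)$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 15.7) / 15.7, 0.10)
})

test_that("pool_kd implements inverse-variance pooling", {
  p <- pool_kd(c(4, 6), variances = c(1, 1))
  expect_equal(p$estimate, 5)
  expect_equal(p$sd, sqrt(0.5))
  # an (effectively) infinite-variance replicate is dropped with a warning
  expect_warning(p2 <- pool_kd(c(4, 6, 100), variances = c(1, 1, Inf)),
                 "dropped")
  expect_equal(p2$estimate, 5)
  expect_equal(p2$n_used, 2)
  # unequal variances weight toward the precise replicate
  p3 <- pool_kd(c(4, 6), variances = c(0.01, 1))
  expect_lt(abs(p3$estimate - 4), 0.1)
  expect_error(pool_kd(5, variances = 1), ">= 2")
})

test_that("simulate_displacement matches the 4PL definition", {
  tr <- list(ec50 = 363, top = 1.2, bottom = 0.05, hill = 1)
  doses <- displacement_doses_nm()
  expect_true(all(diff(doses) > 0))
  y <- simulate_displacement(tr, c(36.3, 363, 3630), noise_sd = 0)
  expect_equal(y$response[2], (1.2 + 0.05) / 2, tolerance = 1e-12)
  # steep-hill limit approaches a step
  st <- simulate_displacement(list(ec50 = 100, top = 1, bottom = 0, hill = 50),
                              c(50, 90, 110, 200), noise_sd = 0)
  expect_equal(st$response, c(1, 1, 0, 0), tolerance = 1e-2)
  expect_error(simulate_displacement(tr, c(1, 1, 2), noise_sd = 0),
               "strictly increasing")
})

test_that("fit_4pl round-trips and is equivariant", {
  tr <- list(ec50 = 363, top = 1.2, bottom = 0.05, hill = 1)
  cu <- simulate_displacement(tr, displacement_doses_nm(), noise_sd = 0)
  f <- fit_4pl(cu)
  expect_equal(f$ec50, 363, tolerance = 1e-3)
  expect_equal(f$hill, 1, tolerance = 1e-3)
  expect_gte(f$top, f$bottom)

  # dose rescaling scales EC50; affine response rescaling leaves it fixed
  cu10 <- cu; cu10$dose <- cu10$dose * 10
  expect_equal(fit_4pl(cu10)$ec50, 3630, tolerance = 1e-3)
  cuA <- cu; cuA$response <- 3 * cuA$response + 2
  expect_equal(fit_4pl(cuA)$ec50, 363, tolerance = 1e-3)

  # flat data flagged
  flat <- cu; flat$response <- 1
  expect_match(fit_4pl(flat)$flag, "flat")
  # doses far below the EC50 are unidentifiable
  low <- simulate_displacement(list(ec50 = 1e7, top = 1.2, bottom = 0.05,
                                    hill = 1),
                               displacement_doses_nm(), noise_sd = 0.002,
                               seed = 3)
  expect_match(fit_4pl(low)$flag, "unidentifiable")
})

test_that("relative_affinity follows the half-saturation definition", {
  doses <- displacement_doses_nm()
  ref <- simulate_displacement(list(ec50 = 300, top = 1, bottom = 0, hill = 1),
                               doses, noise_sd = 0)
  weak <- simulate_displacement(list(ec50 = 3000, top = 1, bottom = 0, hill = 1),
                                doses, noise_sd = 0)
  ra <- relative_affinity(list(ref = ref, weak = weak), "ref")
  expect_equal(unname(ra["ref"]), 1)
  expect_equal(unname(ra["weak"]), 0.1, tolerance = 1e-3)
  # invariant to common top/bottom rescaling
  weak2 <- weak; weak2$response <- 0.5 * weak2$response + 0.2
  ref2 <- ref; ref2$response <- 0.5 * ref2$response + 0.2
  ra2 <- relative_affinity(list(ref = ref2, weak = weak2), "ref")
  expect_equal(unname(ra2["weak"]), 0.1, tolerance = 1e-3)
  # unfittable curves are excluded with a warning
  flat <- ref; flat$response <- 1
  expect_warning(ra3 <- relative_affinity(list(ref = ref, bad = flat), "ref"),
                 "excluded")
  expect_false("bad" %in% names(ra3))
})

test_that("titration TSV round-trips through the reader", {
  tt <- simulate_itc(list(kd = 5.29, dh = -8.6, n = 1), noise_sd = 0.1,
                     seed = 12)
  f <- tempfile(fileext = ".tsv")
  write_curve_tsv(tt, f)
  back <- read_titration_tsv(f, schedule = titration_schedule())
  expect_equal(back$heat_ucal, tt$heat_ucal, tolerance = 1e-9)
  expect_s3_class(fit_one_site(back), "itc_fit")
})
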