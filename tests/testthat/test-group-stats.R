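test_that("paired_t matches the closed-form df=2 CDF", {
  res <- paired_t(c(1, 2, 3))
  expect_equal(res$t, sqrt(12), tolerance = 1e-9)       # 3.4641
  expect_equal(res$df, 2)
  # closed form for df = 2: P(T <= t) = 1/2 + t / (2*sqrt(2)*sqrt(1+t^2/2))
  t <- res$t
  p_oracle <- 1 - (0.5 + t / (2 * sqrt(2) * sqrt(1 + t^2 / 2)))
  expect_equal(res$p_one_tailed, p_oracle, tolerance = 1e-9)
  expect_equal(round(res$p_one_tailed, 4), 0.0371)
})

test_that("paired_t handles degenerate and mirrored inputs", {
  res0 <- paired_t(c(0, 0, 0, 0))
  expect_true(res0$degenerate)
  expect_equal(res0$p_one_tailed, 1)
  resc <- paired_t(c(2, 2, 2))
  expect_true(resc$degenerate)
  expect_equal(resc$p_one_tailed, 0)
  set.seed(4)
  d <- rnorm(10)
  a <- paired_t(d); b <- paired_t(-d)
  expect_equal(abs(a$t), abs(b$t))
  expect_equal(a$p_one_tailed + b$p_one_tailed, 1, tolerance = 1e-12)
  expect_error(paired_t(c(1, NA, 2)), "finite")
  expect_error(paired_t(3), "2 pairs")
})

test_that("paired_t agrees with the t.test oracle on random inputs", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_t(x - y)
    ref_g <- t.test(x, y, paired = TRUE, alternative = "greater")
    ref_2 <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref_g$statistic), tolerance = 1e-9)
    expect_equal(mine$p_one_tailed, ref_g$p.value, tolerance = 1e-9)
    expect_equal(mine$p_two_tailed, ref_2$p.value, tolerance = 1e-9)
  }
})

test_that("identical cohorts yield no significant bands", {
  specs <- lapply(1:5, function(i)
    manual_spectrum(runif(300, 1, 2), sprintf("s%d", i)))
  cmp <- per_frequency_tests(specs, specs)
  expect_equal(nrow(cmp$bands), 0)
  expect_equal(nrow(cmp$singletons), 0)
  expect_true(all(cmp$tests$p == 1))
})

test_that("per-frequency tests find an injected band with its direction", {
  set.seed(6)
  n <- 12
  ctrl <- lapply(1:n, function(i)
    manual_spectrum(runif(400, 1, 1.2), sprintf("p%d", i)))
  # elevate case power at bins 250:260 (periods ~18.6-19.4 um, i.e. <= 22)
  case <- lapply(1:n, function(i) {
    pw <- ctrl[[i]]$power + c(rep(0, 249), rep(0.5, 11), rep(0, 140))
    manual_spectrum(pw, sprintf("c%d", i))
  })
  cmp <- per_frequency_tests(case, ctrl)
  expect_equal(nrow(cmp$bands), 1)
  expect_equal(cmp$bands$k_lo, 250)
  expect_equal(cmp$bands$k_hi, 260)
  expect_equal(cmp$bands$direction, "case_gt_control")
  expect_equal(cmp$bands$period_um_hi, 800 * (200 / 33) / 250)
  expect_true(all(cmp$tests$p[250:260] < 0.05))
  # every bin inside a band is significant in its hypothesized direction
  expect_true(all(cmp$tests$significant[cmp$bands$k_lo:cmp$bands$k_hi]))
  # the same elevation at long periods tests the control>case direction
  case_lo <- lapply(1:n, function(i) {
    pw <- ctrl[[i]]$power + c(rep(0.5, 30), rep(0, 370))  # periods > 160 um
    manual_spectrum(pw, sprintf("c%d", i))
  })
  cmp2 <- per_frequency_tests(case_lo, ctrl)
  expect_true(all(cmp2$tests$direction[1:30] == "control_gt_case"))
  expect_equal(nrow(cmp2$bands), 0)    # elevation is in the wrong direction
})

test_that("pairing is validated and unpaired subjects are named", {
  specs <- lapply(1:4, function(i)
    manual_spectrum(runif(10), sprintf("s%d", i)))
  expect_error(
    per_frequency_tests(specs[1:3], specs[1:3],
                        case_pair_ids = c(1, 2, 3),
                        control_pair_ids = c(1, 2, 9)),
    "unpaired.*(3|9)")
  # reordered controls are re-aligned by pair id
  ctrl <- lapply(1:4, function(i)
    manual_spectrum(rep(i, 10), sprintf("k%d", i)))
  case <- lapply(1:4, function(i)
    manual_spectrum(rep(i, 10) + 0.001, sprintf("c%d", i)))
  cmp <- per_frequency_tests(case, ctrl[c(3, 1, 4, 2)],
                             case_pair_ids = 1:4,
                             control_pair_ids = c(3, 1, 4, 2))
  expect_true(all(abs(cmp$tests$mean_case - cmp$tests$mean_control - 0.001)
                  < 1e-12))
})

test_that("thickness comparisons match direct computation", {
  cs <- cohort_spec(20, case_perturbation = list(
    boundary_offset_px = c(ISOS = 2)), seed = 23)   # RPECH_ISOS 2 px thinner
  coh <- render_cohort(cs)
  th <- cohort_thickness(coh, label = "RPECH_ISOS", boundaries = "truth")
  tt <- thickness_tests(th$case_profiles, th$control_profiles)
  expect_equal(nrow(tt), 15)
  # significant two-tailed differences at most locations
  expect_gt(sum(tt$p < 0.05, na.rm = TRUE), 10)
  expect_true(all(tt$mean_case < tt$mean_control))
  # means match the long-format table
  tab <- thickness_table(th$case_profiles)
  j <- which(tt$location_deg == 0)
  expect_equal(tt$mean_case[j],
               mean(tab$thickness_um[tab$location_deg == 0]))
  # identical cohorts are degenerate with p = 1
  t0 <- thickness_tests(th$case_profiles, th$case_profiles)
  expect_true(all(t0$p == 1))
})

test_that("age regression recovers exact and degenerate fits", {
  ex <- age_regression(2 * (1:10) + 1, 1:10)
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_equal(ex$intercept, 1, tolerance = 1e-12)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)
  const <- age_regression(rep(5, 8), 1:8)
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$r_squared, 0)
  hand <- age_regression(c(300, 290, 286), c(50, 60, 70))
  expect_equal(hand$slope, -0.7, tolerance = 1e-9)
  expect_equal(hand$r_squared, 98 / 104, tolerance = 1e-9)  # 0.9423
  expect_error(age_regression(c(1, 2, 3), c(5, 5, 5)), "variance")
})
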