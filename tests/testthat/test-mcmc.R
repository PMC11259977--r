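test_that("HPD and ESS summaries behave on known samples", {
  expect_equal(hpd_interval(rep(2.5, 500)), c(2.5, 2.5))
  set.seed(1)
  u <- runif(1e5)
  h <- hpd_interval(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.01)
  x <- rnorm(2e4)
  expect_gt(ess(x), 0.9 * length(x)) # iid draws: ESS near n
  expect_lt(ess(x), 1.15 * length(x))
  # strongly autocorrelated draws: ESS well below n
  y <- as.numeric(stats::filter(rnorm(2e4), 0.95, method = "recursive"))
  expect_lt(ess(y), length(y) / 10)
})

test_that("posterior summaries demand enough draws and convert to Ma", {
  tt <- parse_newick("(A:1,B:1);")
  cal <- list("3" = calibration(2, 3))
  ps <- run_chain(tt, calibrations = cal, n_iter = 600, thin = 1, seed = 1)
  expect_error(summarize_posterior(
    structure(list(draws = ps$draws[1:50, , drop = FALSE]),
              class = "posterior_samples")), "100")
  sm <- summarize_posterior(ps)
  age <- sm[sm$param == "t_n3", ]
  expect_gt(age$mean, 200) # Ma scale
  expect_lt(age$mean, 300)
  expect_true(age$lower < age$mean && age$mean < age$upper)
  expect_gt(age$ess, 0)
})

test_that("a fixed seed reproduces the chain bit for bit", {
  set.seed(77)
  des <- small_design()
  tt <- simulate_chronogram(des, seed = 77)
  loci <- lapply(1:3, function(l)
    simulate_locus(tt, clock_config("ILN", mu_r = 0.05, sigma2 = 0.1),
                   300, mode = "brlen_approx", id = paste0("L", l)))
  cal <- attr(tt, "calibrations")
  a <- run_chain(timetree(tt$phy), loci, calibrations = cal,
                 n_iter = 400, seed = 123)
  b <- run_chain(timetree(tt$phy), loci, calibrations = cal,
                 n_iter = 400, seed = 123)
  expect_identical(a$draws, b$draws)
  c2 <- run_chain(timetree(tt$phy), loci, calibrations = cal,
                  n_iter = 400, seed = 124)
  expect_false(identical(a$draws, c2$draws))
})

test_that("prior-only sampling reproduces the analytic prior marginals", {
  # single calibrated node: marginal is exactly the calibration
  tt <- parse_newick("(A:1,B:1);")
  cal <- list("3" = calibration(2.26, 3.0))
  ps <- run_chain(tt, calibrations = cal, n_iter = 6e4, thin = 2, seed = 8)
  x <- ps$draws[, "t_n3"]
  ks <- suppressWarnings(stats::ks.test(x, function(q)
    calibration_cdf(q, cal[["3"]])))
  expect_lt(unname(ks$statistic), 0.02)

  # with loci but likelihood off: sigma2 marginal is its gamma prior
  set.seed(9)
  des <- small_design()
  ttc <- simulate_chronogram(des, seed = 9)
  loci <- list(simulate_locus(ttc, clock_config("ILN"), 300,
                              mode = "brlen_approx", id = "L1"))
  ps2 <- run_chain(timetree(ttc$phy), loci,
                   calibrations = attr(ttc, "calibrations"),
                   n_iter = 3e4, thin = 2, seed = 10,
                   use_likelihood = FALSE)
  s2 <- ps2$draws[, "sigma2_1"]
  ks2 <- suppressWarnings(stats::ks.test(s2, function(q)
    stats::pgamma(q, 1, rate = 10)))
  expect_lt(unname(ks2$statistic), 0.02)
})

test_that("convergence report flags discordant chains only", {
  tt <- parse_newick("(A:1,B:1);")
  cal <- list("3" = calibration(2.26, 3.0))
  a <- run_chain(tt, calibrations = cal, n_iter = 2e4, thin = 2, seed = 1)
  b <- run_chain(tt, calibrations = cal, n_iter = 2e4, thin = 2, seed = 2)
  rep_ab <- check_convergence(a, b)
  expect_true(all(rep_ab$rhat < 1.01))
  expect_false(any(rep_ab$flag))
  # identical sample sets: R-hat exactly 1
  rep_aa <- check_convergence(a, a)
  expect_equal(rep_aa$rhat, rep(1, nrow(rep_aa)))
  # incompatible parameter sets
  set.seed(3)
  des <- small_design()
  ttc <- simulate_chronogram(des, seed = 3)
  loci <- list(simulate_locus(ttc, clock_config("ILN"), 300,
                              mode = "brlen_approx", id = "L1"))
  c2 <- run_chain(timetree(ttc$phy), loci,
                  calibrations = attr(ttc, "calibrations"),
                  n_iter = 500, seed = 4)
  expect_error(check_convergence(a, c2), "parameter sets differ")
})

test_that("the sampler requires a calibrated root", {
  tt <- parse_newick("((A:1,B:1):1,C:2);")
  cal <- list("5" = calibration(0.5, 1.5)) # internal, not the root
  expect_error(run_chain(tt, calibrations = cal, n_iter = 100, seed = 1),
               "root must carry a calibration")
})

test_that("incremental likelihood state stays consistent over a long chain", {
  set.seed(12)
  des <- small_design()
  tt <- simulate_chronogram(des, seed = 12)
  loci <- lapply(1:4, function(l)
    simulate_locus(tt, clock_config("ILN", mu_r = 0.06, sigma2 = 0.08),
                   400, mode = "brlen_approx", id = paste0("L", l)))
  # run_chain audits its cache at exit and warns on drift beyond 1e-6
  for (clk in c("ILN", "GBM")) {
    expect_no_warning(
      run_chain(timetree(tt$phy), loci, clock = clock_config(clk),
                calibrations = attr(tt, "calibrations"),
                n_iter = 1500, seed = 13))
  }
})
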