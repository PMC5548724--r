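test_that("closed-form MLE solves the moment condition", {
  # human whole-repertoire totals
  th <- theta_mle(906 / 424)
  expect_equal(round(th, 2), 0.74)
  expect_equal(bdi_mean_size(th), 906 / 424, tolerance = 1e-10)
  # frozen from the bisection oracle on mean_size(theta) = 2
  oracle <- uniroot(function(t) bdi_mean_size(t) - 2,
                    c(1e-9, 1 - 1e-12), tol = 1e-14)$root
  expect_equal(theta_mle(2), oracle, tolerance = 1e-9)
  expect_equal(round(theta_mle(2), 3), 0.715)
  # degenerate limits
  expect_lt(theta_mle(1 + 1e-4), 0.01)
  expect_error(theta_mle(1), "degenerate")
  expect_error(theta_mle(0.9), "degenerate")
  expect_error(theta_mle(rep(1L, 10)), "degenerate")
})

test_that("closed-form MLE maximizes the log-likelihood", {
  set.seed(7)
  for (rep in 1:5) {
    th0 <- runif(1, 0.3, 0.9)
    sizes <- bdi_sample_sizes(300, th0, M = 3000)
    if (mean(sizes) <= 1) next
    th_hat <- theta_mle(sizes)
    opt <- optimize(function(t) bdi_loglik(t, sizes),
                    c(1e-6, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
    expect_equal(th_hat, opt$maximum, tolerance = 1e-6)
  }
})

test_that("finite and infinite truncation agree where the tail is empty", {
  set.seed(21)
  sizes <- bdi_sample_sizes(200, 0.8, M = 2000)
  expect_lt(abs(theta_mle(sizes) - theta_mle(sizes, M = sum(sizes))), 1e-3)
  # at a harsh truncation they must differ
  expect_gt(abs(theta_mle(2.3) - theta_mle(2.3, M = 6)), 1e-3)
  expect_error(theta_mle(5, M = 6), "not attainable")
})

test_that("KS distance follows its definition on the discrete support", {
  # all-singleton sample against the human-regime law
  expect_equal(ks_statistic(rep(1L, 50), 0.74), 1 - bdi_pmf(1, 0.74))
  # quantile-matched design sample stays within 1/F of its law
  F <- 500
  ds <- design_sample(0.6, F)
  expect_lte(ks_statistic(ds, 0.6), 1 / F)
  # brute-force sup over the support
  set.seed(4)
  sizes <- bdi_sample_sizes(80, 0.7, M = 1000)
  th <- 0.65
  sup <- max(vapply(seq_len(max(sizes)), function(i) {
    abs(mean(sizes <= i) - bdi_cdf(i, th))
  }, numeric(1)))
  expect_equal(ks_statistic(sizes, th), sup)
})

test_that("bootstrap GoF rejects planted structure but not null samples", {
  set.seed(9)
  null_sizes <- bdi_sample_sizes(400, 0.6, M = 4000)
  fit0 <- gof_pvalue(null_sizes, n_boot = 200, seed = 10)
  expect_gte(fit0$p_value, 0.05)
  expect_true(fit0$p_value >= 0 && fit0$p_value <= 1)
  # a size-60 family far beyond the support mass of theta = 0.6
  spiked <- c(null_sizes, 60L)
  fit1 <- gof_pvalue(spiked, n_boot = 200, seed = 10)
  expect_lt(fit1$p_value, 0.05)
  # the report carries its provenance
  expect_equal(fit1$n_boot, 200)
  expect_equal(fit1$seed, 10)
})

test_that("trim scan accepts untrimmed data matching the law", {
  # quantile-matched design sample: as close to the law as integers allow
  sizes <- design_sample(0.6, 300)
  ts <- trim_scan(sizes, T_grid = max(sizes) + 1, Ns_grid = 0,
                  n_boot = 100, seed = 14)
  expect_false(is.na(ts$T_star))
  expect_equal(ts$T_star, max(sizes) + 1)
  expect_equal(ts$Ns_accepted, c(0, 0))
})

test_that("trim scan drops infeasible singleton removals with a warning", {
  sizes <- c(rep(1L, 5), 2L, 3L)
  expect_warning(
    ts <- trim_scan(sizes, T_grid = 10, Ns_grid = c(0, 100),
                    n_boot = 20, seed = 1),
    "singletons")
  expect_true(all(ts$grid$Ns <= 5))
})

test_that("DBD classes are placed against the simulated neutral bands", {
  env <- fn_envelope(0.74, init_range = seq(20, 400, by = 20),
                     n_rep = 400, seed = 31)
  # neutral classes: simulate a few at the reference theta
  set.seed(32)
  rates <- bdi_rates_balanced(0.74)
  neutral <- do.call(rbind, lapply(1:8, function(k) {
    s <- bdi_simulate(rates, 150)
    if (s$extinct) return(NULL)
    data.frame(dbd_class = paste0("neutral_", k), N = s$N, F = s$F)
  }))
  # a frozen class (no innovation: one family) and a fast-diversifying one
  frozen <- data.frame(dbd_class = "frozen", N = 200L, F = 1L)
  set.seed(33)
  fast_sizes <- bdi_sample_sizes(170, 0.4, M = 400) # F/N ~ 0.77 >> 0.47
  fast <- data.frame(dbd_class = "fast", N = sum(fast_sizes),
                     F = length(fast_sizes))
  rep_tab <- per_dbd_split(rbind(neutral, frozen, fast), env)
  expect_true(all(abs(rep_tab$z[grepl("neutral", rep_tab$dbd_class)]) < 3.5))
  expect_equal(rep_tab$position[rep_tab$dbd_class == "frozen"],
               "outlier_low")
  expect_equal(rep_tab$position[rep_tab$dbd_class == "fast"],
               "outlier_high")
  expect_error(per_dbd_split(data.frame(dbd_class = "x", N = 2, F = 3),
                             env), "exceed")
})

test_that("theta scaling exponent is recovered exactly on exact data", {
  two <- fit_theta_scaling(data.frame(
    species = c("a", "b"), n_tf = c(100, 1000),
    theta = c(0.2, 0.2 * 10^0.85)))
  expect_equal(two$exponent, 0.85)
  # zero-noise power law over five species
  n <- c(200, 400, 700, 1000, 1500)
  five <- fit_theta_scaling(data.frame(
    species = letters[1:5], n_tf = n, theta = 0.01 * n^0.6))
  expect_equal(five$exponent, 0.6, tolerance = 1e-10)
  expect_lt(five$se, 1e-10)
  expect_warning(
    fit_theta_scaling(data.frame(species = c("a", "b", "c"),
                                 n_tf = c(1, 2, 3),
                                 theta = c(0.5, 0.6, -1))),
    "excluding")
})
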