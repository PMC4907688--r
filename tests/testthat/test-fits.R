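test_that("Hill fits recover exact parameters and flag flat data", {
  S <- 10^seq(-1.5, 1.5, length.out = 10)
  y <- hill_response(S, start = 1, end = 0, ic50 = 1.6, n = 1.5)
  cf <- coef(hill_fit(S, y))
  expect_equal(unname(cf["START"]), 1, tolerance = 1e-6)
  expect_equal(unname(cf["END"]), 0, tolerance = 1e-6)
  expect_equal(unname(cf["IC50"]), 1.6, tolerance = 1e-6)
  expect_equal(unname(cf["n"]), 1.5, tolerance = 1e-6)
  # flat responses carry no concentration information
  flat <- hill_fit(S, rep(0.7, 10) + rnorm(10, 0, 1e-3))
  expect_identical(flat$flag, "unidentifiable")
  expect_true(is.na(coef(flat)["IC50"]))
  # the response at S = IC50 is the plateau midpoint for any n
  for (n in c(0.5, 1, 3)) {
    expect_equal(hill_response(2.5, 0.2, 0.9, 2.5, n), (0.2 + 0.9) / 2)
  }
  expect_error(hill_fit(c(1, 2, 3), c(1, 0.5, 0)), "4 distinct")
  expect_error(hill_fit(c(1, 2, 3, 4), c(1, 0.8, 0.6, 0.4)), "decade")
})

test_that("Kv4.3 kinetic fits recover the generating constants", {
  t_act <- seq(0, 10, 0.01)
  i_act <- kv43_activation_curve(t_act, a = 218, b = 0, tau_act = 0.69)
  fa <- fit_kv43_activation(t_act, i_act)
  expect_equal(unname(coef(fa)["tau_act"]), 0.69, tolerance = 1e-6)
  expect_equal(unname(coef(fa)["a"]), 218, tolerance = 1e-6)

  t_in <- seq(0, 1500, 0.5)
  i_in <- kv43_inactivation_curve(t_in, a = 150, b = 60, c = 8,
                                  tau_fast = 51, tau_slow = 352)
  fi <- fit_kv43_inactivation(t_in, i_in)
  expect_identical(fi$flag, "ok")
  expect_equal(unname(coef(fi)["tau_fast"]), 51, tolerance = 0.01)
  expect_equal(unname(coef(fi)["tau_slow"]), 352, tolerance = 0.01)
  expect_lt(unname(coef(fi)["tau_fast"]), unname(coef(fi)["tau_slow"]))

  # single-exponential input degenerates and is flagged
  i_single <- 100 * exp(-t_in / 80) + 5
  fs <- fit_kv43_inactivation(t_in, i_single)
  expect_identical(fs$flag, "degenerate")
})

test_that("activation fit stays accurate on noisy currents", {
  set.seed(31)
  t <- seq(0, 10, 0.01)
  clean <- kv43_activation_curve(t, 218, 0, 0.69)
  taus <- replicate(20, {
    y <- clean + rnorm(length(t), 0, max(clean) / 50)   # SNR ~ 50
    unname(coef(fit_kv43_activation(t, y))["tau_act"])
  })
  expect_lt(abs(mean(taus) - 0.69) / 0.69, 0.02)
})

test_that("Z-prime matches the formula, symmetry and affine invariance", {
  expect_equal(zprime(c(1, 1, 1), c(0, 0, 0)), 1)
  # mu_p 1, mu_n 0, sd = 1/6 each gives exactly 0
  g <- c(-1, 0, 1) / (6 * sd(c(-1, 0, 1)))
  expect_equal(zprime(1 + g, 0 + g), 0, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    p <- rnorm(8, 2, 0.3); n <- rnorm(8, 0.5, 0.2)
    zp <- zprime(p, n)
    # independent two-pass computation
    ref <- 1 - 3 * (sd(p) + sd(n)) / abs(mean(p) - mean(n))
    expect_equal(zp, ref, tolerance = 1e-12)
    expect_equal(zprime(n, p), zp, tolerance = 1e-12)       # symmetry
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(zprime(a * p + b, a * n + b), zp, tolerance = 1e-10)
  }
  expect_error(zprime(1, c(0, 0)), ">= 2")
  expect_error(zprime(c(1, 1), c(1, 1)), "undefined")
})

test_that("hit calling applies the 5-SD rule to test wells only", {
  role <- c(rep("negative_control", 8), rep("positive_control", 8),
            rep("test", 10))
  set.seed(2)
  neg <- rnorm(8, 0.01, 0.002)
  thr <- mean(neg) + 5 * sd(neg)
  sigma <- c(neg, rnorm(8, 0.2, 0.02),
             rep(mean(neg), 8), mean(neg) + 6 * sd(neg),
             mean(neg) + 4 * sd(neg))
  hits <- call_hits(sigma, role)
  expect_false(any(hits[role != "test"]))   # controls never flagged
  expect_true(hits[25])                     # 6 SD above
  expect_false(hits[26])                    # 4 SD above
  expect_equal(sum(hits), 1)
  expect_equal(attr(hits, "threshold"), thr)
  expect_error(call_hits(sigma[1:3], role[c(1, 2, 3)]), "negative-control")
})

test_that("alternation score separates alternating from monotone patterns", {
  expect_equal(alternation_score(spike_train(rep(1, 8))), 0)
  expect_equal(alternation_score(spike_train(rep(c(1, 0), 4))), 1)
  expect_lte(alternation_score(spike_train(seq(1, 0.3, length.out = 8))), 0)
  expect_error(alternation_score(spike_train(c(1, 0.5))), "four")
})

test_that("Hill IC50 recovery stays tight under 5% noise", {
  set.seed(12)
  S <- 10^seq(-1.5, 1.5, length.out = 8)
  errs <- replicate(200, {
    truth <- 10^runif(1, -0.5, 0.5)
    y <- hill_response(S, 1, 0, truth, 1.5) + rnorm(8, 0, 0.05)
    f <- hill_fit(S, y)
    ic <- coef(f)["IC50"]
    # IC50 errors in decades (log10), the conventional dose-response scale
    if (is.na(ic)) NA else abs(log10(ic / truth))
  })
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})
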