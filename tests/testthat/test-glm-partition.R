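test_that("binomial GLM matches the 2x2-table closed forms", {
  # intercept-only, balanced response
  f0 <- fit_binomial_glm(rep(c(0, 1), each = 10),
                         data.frame(row.names = 1:20))
  expect_equal(f0$coefficients$estimate[1], 0, tolerance = 1e-8)
  expect_equal(f0$d2, 0, tolerance = 1e-12)
  expect_equal(f0$null_deviance, f0$residual_deviance)

  # binary predictor: slope = log OR, SE = sqrt(sum of 1/counts)
  y <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15))
  x <- rep(c(0, 1), each = 20)
  f <- fit_binomial_glm(y, data.frame(x = x))
  expect_equal(f$coefficients$estimate[2], log((5 / 15) / (10 / 10)),
               tolerance = 1e-6)
  expect_equal(f$coefficients$se[2],
               sqrt(1 / 5 + 1 / 15 + 1 / 10 + 1 / 10), tolerance = 1e-6)
  expect_equal(f$coefficients$z[2],
               f$coefficients$estimate[2] / f$coefficients$se[2],
               tolerance = 1e-10)
  # closed-form agreement over random 2x2 tables
  set.seed(60)
  for (rep in 1:20) {
    n <- c(a = sample(3:20, 1), b = sample(3:20, 1),
           c = sample(3:20, 1), d = sample(3:20, 1))
    yy <- c(rep(1, n["a"]), rep(0, n["b"]), rep(1, n["c"]), rep(0, n["d"]))
    xx <- c(rep(0, n["a"] + n["b"]), rep(1, n["c"] + n["d"]))
    ff <- fit_binomial_glm(yy, data.frame(x = xx))
    lor <- log((n[["c"]] / n[["d"]]) / (n[["a"]] / n[["b"]]))
    expect_equal(ff$coefficients$estimate[2], lor, tolerance = 1e-6)
    expect_equal(ff$coefficients$se[2], sqrt(sum(1 / n)), tolerance = 1e-6)
  }
})

test_that("separation and rank deficiency are reported", {
  y <- rep(c(0, 1), each = 10)
  x <- y  # perfect prediction
  expect_warning(f <- fit_binomial_glm(y, data.frame(x = x)), "separation")
  expect_true(f$separation)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  X$c <- X$a + X$b
  expect_error(suppressWarnings(fit_binomial_glm(y, X)), "c")
})

test_that("adjusted D2 penalizes added coefficients while D2 cannot decrease", {
  set.seed(61)
  n <- 80
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x1))
  noise <- data.frame(x1 = x1, replicate(6, rnorm(n)))
  d2 <- adj <- numeric(ncol(noise))
  for (k in seq_len(ncol(noise))) {
    f <- fit_binomial_glm(y, noise[, seq_len(k), drop = FALSE])
    d2[k] <- f$d2; adj[k] <- f$adj_d2
    expect_lte(f$adj_d2, f$d2)
    expect_lte(f$residual_deviance, f$null_deviance + 1e-8)
    expect_gte(f$d2, 0); expect_lte(f$d2, 1)
  }
  expect_true(all(diff(d2) >= -1e-12))   # nested D2 monotone
  expect_true(any(diff(adj) < 0))        # adjusted D2 is not
})

test_that("Bonferroni screen multiplies and caps p values", {
  set.seed(62)
  n <- 120
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X$signal))
  sc <- single_predictor_screen(y, X, family_size = 12)
  expect_equal(sc$p_adj, pmin(1, sc$p * 12))
  expect_true(sc$significant[sc$predictor == "signal"])
  expect_error(single_predictor_screen(y, X, family_size = 2),
               "family_size")
})

test_that("Bonferroni familywise error stays at or below nominal on null predictors", {
  set.seed(63)
  n <- 60; k <- 6
  fwer <- mean(replicate(400, {
    y <- rbinom(n, 1, 0.5)
    X <- as.data.frame(matrix(rnorm(n * k), n))
    any(single_predictor_screen(y, X, family_size = k)$significant)
  }))
  # nominal 0.05 plus Monte-Carlo tolerance (400 reps)
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("three-way partition satisfies its additivity identity on arbitrary data", {
  set.seed(64)
  for (rep in 1:5) {
    n <- 150
    XA <- matrix(rnorm(n * 3), n); XB <- matrix(rnorm(n * 2), n)
    XC <- matrix(rbinom(n * 2, 1, 0.4), n)
    y <- rbinom(n, 1, plogis(0.5 * XA[, 1] - 0.7 * XC[, 1]))
    vp <- varpart3(y, XA, XB, XC)
    expect_equal(sum(vp$fractions[1:7]), vp$adj_d2[["ABC"]],
                 tolerance = 1e-10)
    expect_equal(vp$fractions[["residual"]], 1 - vp$adj_d2[["ABC"]],
                 tolerance = 1e-12)
  }
})

test_that("partition assigns signal to the generating matrix and shares collinear signal", {
  set.seed(65)
  n <- 2000
  XA <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("a", 1:3)))
  XB <- matrix(rnorm(n * 2), n, dimnames = list(NULL, paste0("b", 1:2)))
  XC <- matrix(rnorm(n * 2), n, dimnames = list(NULL, paste0("c", 1:2)))
  y <- rbinom(n, 1, plogis(XA %*% c(1, -0.8, 0.5)))
  vp <- varpart3(y, XA, XB, XC)
  fr <- vp$fractions
  expect_lt(abs(fr[["b_unique_2"]]), 0.03)
  expect_lt(abs(fr[["c_unique_3"]]), 0.03)
  for (nm in c("d_joint_12", "e_joint_23", "f_joint_13", "g_joint_123"))
    expect_lt(abs(fr[[nm]]), 0.03)
  expect_equal(fr[["a_unique_1"]], vp$adj_d2[["ABC"]], tolerance = 0.05)

  # duplicating A as C moves the signal into the A&C joint fraction
  vp2 <- varpart3(y, XA, XB, XA)
  expect_lt(abs(vp2$fractions[["a_unique_1"]]), 0.01)
  expect_lt(abs(vp2$fractions[["c_unique_3"]]), 0.01)
  expect_gt(vp2$fractions[["f_joint_13"]], 0.1)

  # relabeling (A,B,C) -> (C,A,B) permutes the fractions correspondingly
  vp3 <- varpart3(y, XC, XA, XB)
  expect_equal(vp3$fractions[["b_unique_2"]], fr[["a_unique_1"]],
               tolerance = 1e-10)
  expect_equal(vp3$fractions[["e_joint_23"]], fr[["d_joint_12"]],
               tolerance = 1e-10)
})

test_that("cytotype cross-occurrence statistics are direction-symmetric", {
  set.seed(66)
  tab <- toy_pop_table(133, seed = 66)
  out <- apomict_cross_occurrence(tab)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adj >= out$p - 1e-12))
  expect_true(all(out$p_adj <= 1))
  # z symmetry is asserted internally; check D2 differs by direction
  expect_false(all(out$d2_fwd == out$d2_rev))
  # identical occurrence vectors -> separation flag
  tab2 <- toy_pop_table(40, seed = 67)
  tab2$present_7x <- tab2$present_5x
  tab2$present_8x <- pmax(tab2$present_8x,
                          1 - pmax(tab2$present_5x, tab2$present_7x))
  out2 <- suppressWarnings(apomict_cross_occurrence(tab2))
  expect_true(out2$separation[out2$cytotype_1 == "present_5x" &
                                out2$cytotype_2 == "present_7x"])
})

test_that("cross-occurrence null simulations keep adjusted significance near nominal", {
  # restricting to apomict-containing populations makes independently
  # drawn cytotypes negatively dependent, so a clean null needs the
  # restriction to be vacuous: one cytotype present everywhere, the
  # other two independent
  set.seed(68)
  hits <- replicate(300, {
    tab <- data.frame(present_5x = rbinom(133, 1, 0.4),
                      present_7x = rbinom(133, 1, 0.3),
                      present_8x = rep(1L, 133))
    out <- suppressWarnings(apomict_cross_occurrence(tab))
    pair <- out$cytotype_1 == "present_5x" & out$cytotype_2 == "present_7x"
    any(out$significant[pair])
  })
  # Bonferroni family of 3 puts the per-pair level at 0.05/3
  expect_lte(mean(hits),
             0.05 / 3 + 2 * sqrt(0.0167 * 0.9833 / 300) + 0.01)
})
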