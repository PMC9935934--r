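# Min-max relative instability scoring.

test_that("minmax_ratio interpolates linearly between the extremes", {
  expect_equal(unname(minmax_ratio(c(10, 20, 30))), c(0, 50, 100))
  expect_equal(unname(minmax_ratio(c(3, 1, 2, 1))), c(100, 0, 50, 0))
  expect_error(minmax_ratio(5), "at least 2")
  expect_error(minmax_ratio(c(1, NA)), "finite")
})

test_that("minmax_ratio ties give all zeros", {
  expect_equal(unname(minmax_ratio(rep(4.2, 5))), rep(0, 5))
})

test_that("minmax_ratio is invariant to positive affine transforms", {
  set.seed(11)
  for (k in 1:20) {
    v <- runif(8, 0, 100)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -50, 50)
    expect_equal(unname(minmax_ratio(a * v + b)), unname(minmax_ratio(v)),
                 tolerance = 1e-12)
  }
})

test_that("models attaining every column extreme get mean 0% and 100%", {
  set.seed(7)
  m <- matrix(runif(48, 10, 90), 8, 6,
              dimnames = list(fracture_variants(), paste0("ind", 1:6)))
  m["BASIC", ] <- 1   # strict minimum everywhere
  m["M", ] <- 100     # strict maximum everywhere
  res <- aggregate_instability(m)
  expect_identical(unname(res$mean_ratio["BASIC"]), 0)
  expect_identical(unname(res$mean_ratio["M"]), 100)
  expect_true(all(res$per_indicator_ratios >= 0 & res$per_indicator_ratios <= 100))
  expect_identical(res$ranking[1], "M")
  expect_identical(res$ranking[8], "BASIC")
})

test_that("single-indicator aggregation reduces to minmax_ratio", {
  m <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "i"))
  res <- aggregate_instability(m)
  expect_equal(unname(res$mean_ratio), c(0, 50, 100))
})

test_that("degenerate indicators are dropped from the mean", {
  m <- cbind(spread = c(0, 5, 10), flat = c(3, 3, 3))
  rownames(m) <- c("a", "b", "c")
  res <- aggregate_instability(m)
  expect_identical(res$dropped_indicators, "flat")
  expect_equal(unname(res$mean_ratio), c(0, 50, 100))
})

test_that("row permutation permutes the output identically", {
  set.seed(3)
  m <- matrix(runif(24), 8, 3, dimnames = list(fracture_variants(), NULL))
  perm <- sample(8)
  r1 <- aggregate_instability(m)
  r2 <- aggregate_instability(m[perm, ])
  expect_equal(r2$mean_ratio[rownames(m)], r1$mean_ratio[rownames(m)])
  expect_identical(r1$ranking, r2$ranking)
})

test_that("an all-intermediate model does not disturb existing extremes", {
  m <- matrix(c(1, 5, 9, 2, 6, 10), 3, 2,
              dimnames = list(c("lo", "mid", "hi"), NULL))
  r1 <- aggregate_instability(m)
  m2 <- rbind(m, new = c(4, 5))
  r2 <- aggregate_instability(m2)
  expect_equal(r2$mean_ratio["lo"], r1$mean_ratio["lo"])
  expect_equal(r2$mean_ratio["hi"], r1$mean_ratio["hi"])
})

test_that("ranking against the reference ordering reports concordance", {
  ratios <- c(BASIC = 0, PL = 8.8, AL = 15.8, PM = 21.3, L = 36.6,
              PML = 54.6, AM = 78.7, M = 100)
  m <- cbind(ind = ratios)
  res <- aggregate_instability(m)
  rk <- rank_models(res)
  expect_identical(unname(rk$ranking),
                   rev(reference_instability_order()))
  expect_true(rk$exact_match)
  expect_equal(rk$concordance, 1.0)
  # reversed values give zero concordance
  res_rev <- aggregate_instability(cbind(ind = 100 - ratios))
  expect_equal(rank_models(res_rev)$concordance, 0.0)
})
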