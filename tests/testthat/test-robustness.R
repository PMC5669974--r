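test_that("hypercube sampling is stratified, bounded and reproducible", {
  m <- one_node_model()
  sp <- parameter_space(m, span = 10)
  d1 <- sample_hypercube(sp, 10, seed = 4)
  d2 <- sample_hypercube(sp, 10, seed = 4)
  expect_identical(d1, d2)
  expect_false(identical(d1, sample_hypercube(sp, 10, seed = 5)))
  expect_true(all(d1 >= matrix(sp$lower, 10, 2, byrow = TRUE)))
  expect_true(all(d1 <= matrix(sp$upper, 10, 2, byrow = TRUE)))
  # each log-scale stratum hit exactly once
  for (j in 1:2) {
    u <- (log(d1[, j]) - log(sp$lower[j])) /
      (log(sp$upper[j]) - log(sp$lower[j]))
    expect_setequal(findInterval(u, seq(0, 1, 0.1), rightmost.closed = TRUE),
                    1:10)
  }
  expect_error(sample_hypercube(sp, 1), "at least 2")
})

test_that("marginals are log-uniform over the bounds", {
  m <- one_node_model()
  sp <- parameter_space(m, span = 100)
  d <- sample_hypercube(sp, 1e4, seed = 8)
  u <- (log(d[, 1]) - log(sp$lower[1])) / diff(log(c(sp$lower[1], sp$upper[1])))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("fixed parameters stay fixed and level bounds respect [0, 1]", {
  m <- build_default_model()
  sp <- parameter_space(m, fixed = c(k_MEK_ERK = 2))
  d <- sample_hypercube(sp, 50, seed = 2)
  expect_equal(unname(d[, "k_MEK_ERK"]), rep(2, 50))
  lvl <- grep("^level_", colnames(d))
  expect_true(all(d[, lvl] <= 1))
  expect_error(parameter_space(m, fixed = c(k_MEK_ERK = 1e9)), "outside bounds")
  sp_all <- sp
  sp_all$fixed <- TRUE
  sp_all$value <- sp_all$nominal
  expect_error(sample_hypercube(sp_all, 10), "degenerate")
})

test_that("joint tail conditioning returns alpha-tails and intersections", {
  set.seed(31)
  n <- 100
  draws <- matrix(stats::runif(n), ncol = 1, dimnames = list(NULL, "p"))
  auc <- matrix(stats::rnorm(n), ncol = 1, dimnames = list(NULL, "A"))
  s <- fake_samples(draws, auc)
  ts <- tail_spec(0.1, c(A = "upper"))
  tails <- select_joint_tail(s, ts, min_size = 5)
  expect_length(tails$sOS_like, 10)
  expect_length(tails$lOS_like, 10)
  expect_true(all(auc[tails$sOS_like, 1] >= max(auc[tails$lOS_like, 1])))

  # perfectly correlated same-direction proteins collapse to one tail
  auc2 <- cbind(A = auc[, 1], B = 2 * auc[, 1] + 1)
  s2 <- fake_samples(draws, auc2)
  t2 <- select_joint_tail(s2, tail_spec(0.1, c(A = "upper", B = "upper")),
                          min_size = 5)
  expect_setequal(t2$sOS_like, tails$sOS_like)
  expect_false(t2$fallback)
})

test_that("independent proteins give product-law intersection sizes", {
  set.seed(17)
  n <- 20000
  draws <- matrix(stats::runif(n), ncol = 1, dimnames = list(NULL, "p"))
  auc <- cbind(A = stats::rnorm(n), B = stats::rnorm(n))
  s <- fake_samples(draws, auc)
  t2 <- select_joint_tail(s, tail_spec(0.1, c(A = "upper", B = "upper")),
                          min_size = 5)
  expected <- 0.01 * n
  expect_false(t2$fallback)
  expect_lt(abs(length(t2$sOS_like) - expected),
            5 * sqrt(n * 0.01 * 0.99))
})

test_that("an empty intersection falls back to signed-score ranking", {
  set.seed(9)
  n <- 500
  draws <- matrix(stats::runif(n), ncol = 1, dimnames = list(NULL, "p"))
  # anti-correlated: upper tail of A is lower tail of B, intersection empty
  a <- stats::rnorm(n)
  s <- fake_samples(draws, cbind(A = a, B = -a))
  tails <- select_joint_tail(s, tail_spec(0.1, c(A = "upper", B = "upper")))
  expect_true(tails$fallback)
  expect_gte(length(tails$sOS_like), 20)
  expect_length(intersect(tails$sOS_like, tails$lOS_like), 0)
})

test_that("MIRI matches analytic total-variation values", {
  set.seed(42)
  x <- stats::rnorm(2000)
  idx <- seq_along(x)
  expect_lt(compute_miri(x, idx, idx), 0.03)

  disj <- c(stats::runif(500, 0, 1), stats::runif(500, 2, 3))
  expect_gt(compute_miri(disj, 1:500, 501:1000), 0.95)

  nn <- c(stats::rnorm(1e4, 0), stats::rnorm(1e4, 1))
  miri <- compute_miri(nn, 1:1e4, 1e4 + 1:1e4)
  expect_equal(miri, tv_normal(0, 1), tolerance = 0.03 / tv_normal(0, 1))
})

test_that("MIRI is symmetric, bounded and order-invariant", {
  set.seed(12)
  x <- c(stats::rnorm(400, 0), stats::rnorm(400, 0.7))
  a <- 1:400
  b <- 401:800
  m1 <- compute_miri(x, a, b)
  expect_equal(m1, compute_miri(x, b, a))
  expect_gte(m1, 0)
  expect_lte(m1, 1)
  expect_equal(compute_miri(x, sample(a), sample(b)), m1)
  expect_error(compute_miri(x, 1:5, b), "insufficient")
})

test_that("KDE and histogram MIRI estimators agree within 0.05", {
  set.seed(77)
  shifts <- c(0, 0.3, 1, 2.5)
  for (s in shifts) {
    x <- c(stats::rnorm(5000, 0), stats::rnorm(5000, s))
    kde <- compute_miri(x, 1:5000, 5001:10000)
    hist <- compute_miri_hist(x, 1:5000, 5001:10000)
    expect_lt(abs(kde - hist), 0.05)
  }
})

test_that("MIRI matrix: dominant planted rate ranks first, disconnected near zero", {
  m <- chain_model(with_disconnected = TRUE)
  sp <- parameter_space(m, span = 1.2)
  wide <- sp$name == "k_A_B"
  sp$lower[wide] <- sp$nominal[wide] / 100
  sp$upper[wide] <- sp$nominal[wide] * 100
  mm <- miri_matrix(m, sp, eval_nodes = "B", n = 1500, realizations = 3,
                    seed = 10)
  miri_b <- mm$mean["B", ]
  expect_equal(names(which.max(miri_b)), "k_A_B")
  for (p in c("kact_D", "kdec_D")) {
    expect_lt(miri_b[p], max(3 * mm$sd["B", p], 0.1))
  }
})

test_that("averaging over realizations shrinks the MIRI spread", {
  m <- chain_model()
  sp <- parameter_space(m, span = 100)
  mm <- miri_matrix(m, sp, eval_nodes = "B", n = 600, realizations = 4,
                    seed = 3)
  # realization sd of a strongly identified parameter stays modest
  expect_lt(mm$sd["B", "k_A_B"] / max(mm$mean["B", "k_A_B"], 1e-9), 0.5)
})
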