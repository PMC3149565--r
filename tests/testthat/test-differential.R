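test_that("set partition satisfies inclusion-exclusion on random sets", {
  set.seed(61)
  pool <- sprintf("acc%04d", 1:500)
  for (i in 1:50) {
    a <- sample(pool, sample(10:300, 1))
    b <- sample(pool, sample(10:300, 1))
    p <- partition_sets(a, b)
    s <- p$sizes
    expect_identical(unname(s["union"]),
                     unname(s["n_a"] + s["n_b"] - s["shared"]))
    expect_identical(unname(s["shared"] + s["exclusive_a"]), unname(s["n_a"]))
    expect_identical(unname(s["shared"] + s["exclusive_b"]), unname(s["n_b"]))
    expect_length(intersect(p$shared, p$exclusive_a), 0)
    expect_length(intersect(p$exclusive_a, p$exclusive_b), 0)
  }
  ident <- partition_sets(pool[1:5], pool[1:5])
  expect_identical(ident$shared, sort(pool[1:5]))
  expect_length(ident$exclusive_a, 0)
})

test_that("interval classifier reproduces hand-worked example", {
  pr2 <- c(4.9, 5.0, 5.1, 4.9, 5.0, 5.1)
  ref <- c(0.9, 1.0, 1.1, 0.9, 1.0, 1.1)
  res <- classify_protein(pr2, ref)
  # MEP 5, MSD sqrt(0.04/6); hand-computed interval ratio
  msd <- sqrt(0.04 / 6)
  expect_equal(res$ratio_up, (5 - msd) / (1 + msd), tolerance = 1e-10)
  expect_identical(res$call, "increased")
  # Welch p from the textbook formula, independently of t.test()
  welch_p <- function(x, y) {
    sx <- var(x) / length(x); sy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(sx + sy)
    df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
    2 * stats::pt(-abs(t), df)
  }
  expect_equal(res$p_value, welch_p(pr2, ref), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  # strain swap mirrors the call
  expect_identical(classify_protein(ref, pr2)$call, "decreased")
})

test_that("identical profiles and degenerate intervals give constant", {
  v <- c(1, 2, 3, 1, 2, 3)
  expect_identical(classify_protein(v, v)$call, "constant")
  # both strains at zero: ratios undefined, never a call
  z <- rep(0, 6)
  res <- classify_protein(z, z)
  expect_identical(res$call, "constant")
  expect_true(is.na(res$ratio_up))
  # reference absent, test present: ratio +Inf, increased
  res <- classify_protein(c(5, 5.1, 4.9, 5, 5.2, 4.8), z)
  expect_identical(res$ratio_up, Inf)
  expect_identical(res$call, "increased")
})

test_that("calls are exhaustive, exclusive, and monotone in thresholds", {
  set.seed(62)
  n <- 60
  sc <- matrix(rpois(n * 12, lambda = rep(runif(n, 2, 40), 12)), nrow = n)
  sc[1:10, 7:12] <- sc[1:10, 7:12] * 4     # some genuine signal
  toy <- toy_study(sc, op = rep(30, n))
  q <- quantify_strains(toy$counts, toy$design, toy$op_table)
  qr <- q[q$strain == "SP06081", ]; qt <- q[q$strain == "PR2", ]
  res <- call_table(qt, qr)
  expect_identical(nrow(res$calls), res$summary$shared)
  expect_true(all(res$calls$call %in% c("increased", "decreased", "constant")))
  expect_identical(res$summary$increased + res$summary$decreased +
                     res$summary$constant, res$summary$shared)
  # recount from the emitted table equals the summary
  expect_identical(sum(res$calls$call == "increased"), res$summary$increased)
  # monotonicity: larger alpha / smaller up threshold never loses calls
  n_inc <- function(alpha, up) {
    call_table(qt, qr, alpha = alpha, up = up)$summary$increased
  }
  expect_true(n_inc(0.10, 1.5) >= n_inc(0.05, 1.5))
  expect_true(n_inc(0.05, 1.2) >= n_inc(0.05, 1.5))
  expect_true(n_inc(0.05, 1.5) >= n_inc(0.01, 2.5))
})

test_that("call_table flags missing quantification records and empty input", {
  sc <- matrix(5, nrow = 2, ncol = 12)
  toy <- toy_study(sc, op = c(10, 10))
  q <- quantify_strains(toy$counts, toy$design, toy$op_table)
  qr <- q[q$strain == "SP06081", ]; qt <- q[q$strain == "PR2", ]
  fake <- partition_sets(c(toy$accessions, "ghost"),
                         c(toy$accessions, "ghost"))
  expect_error(call_table(qt, qr, fake), "ghost",
               class = "empaiq_missing_record")
  empty <- call_table(qt[0, ], qr[0, ])
  expect_identical(empty$summary$shared, 0L)
  expect_identical(nrow(empty$calls), 0L)
})

test_that("optional BH correction only removes calls", {
  set.seed(63)
  n <- 40
  sc <- matrix(rpois(n * 12, 10), nrow = n)
  sc[1:5, 7:12] <- sc[1:5, 7:12] * 5
  toy <- toy_study(sc, op = rep(25, n))
  q <- quantify_strains(toy$counts, toy$design, toy$op_table)
  qr <- q[q$strain == "SP06081", ]; qt <- q[q$strain == "PR2", ]
  raw <- call_table(qt, qr)
  bh <- call_table(qt, qr, p_adjust = "BH")
  expect_true(bh$summary$increased <= raw$summary$increased)
  expect_true(bh$summary$decreased <= raw$summary$decreased)
  expect_true(all(bh$calls$p_value >= raw$calls$p_value - 1e-12))
})
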