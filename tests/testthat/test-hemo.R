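test_that("AHR is the percent change in dP/dt_max", {
  expect_equal(ahr(1000, 1150), 15)
  expect_equal(ahr(875, 875), 0)
  expect_equal(ahr(c(800, 900), c(880, 810)), c(10, -10))
  expect_error(ahr(0, 100), "positive")
  expect_error(ahr(-5, 100), "positive")
})

test_that("responder classification honours the threshold operator", {
  expect_true(classify_responder(14.4))
  expect_false(classify_responder(6.9))
  expect_false(classify_responder(10))            # strict > by default
  expect_true(classify_responder(10, strict = FALSE))
  expect_true(classify_responder(c(8, 16)))       # mean of repeats = 12
  expect_error(classify_responder(numeric()), "no AHR")
})

test_that("the exact test reproduces the printed two-sided p-values", {
  responders <- matrix(c(10, 2, 3, 9), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(responders)$p, 3), 0.012)
  remodeling <- matrix(c(4, 4, 5, 2), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(remodeling)$p, 3), 0.608)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
})

test_that("the exact test equals brute-force enumeration exhaustively", {
  for (n in 2:30) {
    for (r1 in 1:(n - 1)) {
      r2 <- n - r1
      for (c1 in 1:(n - 1)) {
        a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
        a <- if (a_max > a_min) sample(a_min:a_max, 1) else a_min
        tab <- matrix(c(a, r1 - a, c1 - a, r2 - (c1 - a)), 2, byrow = TRUE)
        expect_equal(fisher_exact_2x2(tab)$p, fisher_bruteforce(tab),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the exact test agrees with the standard implementation", {
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "zero")
  expect_error(fisher_exact_2x2(matrix(c(3, 0, 5, 0), 2)), "margins")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("remodeling response applies the volumetric threshold", {
  expect_true(remodeling_response(200, 160))      # 20% reduction
  expect_false(remodeling_response(100, 86))      # 14%
  # the reported cohort means: 133.8 -> 103.5 ml is a 22.6% reduction
  expect_true(remodeling_response(133.8, 103.5))
  expect_equal(round(100 * (133.8 - 103.5) / 133.8, 1), 22.6)
  expect_false(remodeling_response(100, 85))      # exactly 15%, strict
  expect_true(remodeling_response(100, 85, strict = FALSE))
  expect_error(remodeling_response(0, 50), "positive")
})

test_that("AHR and remodeling classifications are scale invariant", {
  set.seed(8)
  b <- runif(20, 500, 1500); v <- b * runif(20, 0.9, 1.3)
  for (c_scale in c(0.5, 3.7)) {
    expect_equal(ahr(b, v), ahr(c_scale * b, c_scale * v))
    expect_equal(remodeling_response(b, v),
                 remodeling_response(c_scale * b, c_scale * v))
  }
})

test_that("paired tests flag degenerate inputs", {
  x <- c(10, 12, 9, 14)
  same <- paired_comparison(x, x)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  const <- paired_comparison(x + 5, x)
  expect_true(const$degenerate)
  expect_true(is.na(const$p))
  expect_error(paired_comparison(1:3, 1:4), "mismatch")
  w <- paired_comparison(c(14, 18, 12, 20, 16), c(7, 5, 9, 6, 8),
                         method = "wilcoxon")
  expect_false(w$degenerate)
  expect_lt(w$p, 0.07)
})

test_that("cohort summary reports group stats and the responder table", {
  co <- generate_hemo_cohort(12, seed = 4)
  s <- hemo_summary(co)
  expect_equal(s$groups$n, c(12, 12))
  expect_equal(sum(s$responders), 24)
  expect_equal(s$responders["target", "responder"],
               sum(co$ahr[co$is_target] > 10))
  # formatting contract: the printed proportions from the reported counts
  expect_equal(round(100 * 10 / 12, 1), 83.3)
  expect_equal(round(100 * 3 / 12, 1), 25.0)
})

test_that("paired target-vs-nontarget power is high at study parameters", {
  hits <- 0
  for (s in 1:200) {
    co <- generate_hemo_cohort(14, seed = s)
    p <- paired_comparison(co$ahr[co$is_target], co$ahr[!co$is_target])$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.8)
})
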