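test_that("discrimination groups trails closer than d and averages them", {
  res <- apply_discrimination(c(1.0, 0.98, 0.5, 0.1), d = 0.05)
  expect_equal(res$effective, c(0.99, 0.99, 0.5, 0.1))
  expect_equal(res$groups, list(c(1L, 2L), 3L, 4L))

  # d = 0: identity, all singleton groups
  c0 <- c(0.3, 0.1, 0.7, 0.7)
  res0 <- apply_discrimination(c0, d = 0)
  expect_equal(res0$effective, c0)
  expect_length(res0$groups, 4)

  # all equal within d: one group, unchanged values
  res1 <- apply_discrimination(c(1, 1, 1, 1), d = 0.5)
  expect_equal(res1$effective, c(1, 1, 1, 1))
  expect_equal(res1$groups, list(1:4))

  # chaining is single-linkage: pairwise gaps < d chain across a spread > d
  res2 <- apply_discrimination(c(0, 0.4, 0.8), d = 0.5)
  expect_equal(res2$groups, list(1:3))
  expect_equal(res2$effective, rep(0.4, 3))

  expect_error(apply_discrimination(c(1, 2), d = -1), "non-negative")
  expect_error(apply_discrimination(c(-1, 2), d = 0), "non-negative")
})

test_that("preference reproduces the worked examples of each rule", {
  expect_equal(preference(c(9, 1, 4, 2), choice_rule("random")),
               rep(0.25, 4))
  expect_equal(preference(c(3, 1, 0, 0), choice_rule("linear")),
               c(0.75, 0.25, 0, 0))
  expect_equal(preference(c(3, 1, 0, 0), choice_rule("sigmoidal", k = 0, x = 2)),
               c(0.9, 0.1, 0, 0))
  expect_equal(
    preference(c(0.2, 0, 0, 0), choice_rule("sigmoidal", k = 20, x = 2)),
    c(20.2^2, 400, 400, 400) / (20.2^2 + 3 * 400)
  )
  expect_equal(
    preference(c(2, 1, 1, 0), choice_rule("sigmoidal", k = 0, x = 1)),
    c(0.5, 0.25, 0.25, 0)
  )
  expect_error(preference(c(1, 2), "linear"), "choice_rule")
})

test_that("ranked rule assigns recursive masses, averaging over ties", {
  expect_equal(preference_ranked(c(4, 3, 2, 1), p_top = 0.75),
               c(0.75, 0.1875, 0.046875, 0.015625))
  expect_equal(preference_ranked(c(1, 1, 1, 1), p_top = 0.75),
               rep(0.25, 4))
  expect_equal(preference_ranked(c(1, 1, 0.5, 0.2), p_top = 0.75),
               c(0.46875, 0.46875, 0.046875, 0.015625))
  expect_equal(
    preference_ranked(c(4, 3, 2, 1), p_top = 0.75, error_mode = "uniform"),
    c(0.75, rep(0.25 / 3, 3))
  )
  # discrimination groups tie trails for the ranked rule
  expect_equal(
    preference(c(1.0, 0.98, 0.5, 0.2), choice_rule("ranked"), d = 0.05),
    c(0.46875, 0.46875, 0.046875, 0.015625)
  )
  expect_error(preference_ranked(numeric(0), 0.75), "length >= 2")
  expect_error(preference_ranked(c(1, 2), p_top = 0), "p_top")
})

test_that("recursive ranked probabilities equal exhaustive tree enumeration", {
  set.seed(101)
  for (i in 1:40) {
    s <- sample(2:4, 1)
    strengths <- round(stats::runif(s, 0, 3), 1) # coarse => frequent ties
    p_top <- sample(c(0.4, 0.6, 0.75, 0.9, 1), 1)
    expect_equal(preference_ranked(strengths, p_top),
                 ranked_oracle(strengths, p_top),
                 tolerance = 1e-12,
                 label = paste("strengths", paste(strengths, collapse = ",")))
  }
})

test_that("preference vectors are valid distributions for all rules", {
  set.seed(7)
  rules <- list(choice_rule("random"), choice_rule("linear"),
                choice_rule("sigmoidal", k = 0, x = 2),
                choice_rule("sigmoidal", k = 20, x = 3),
                choice_rule("ranked"),
                choice_rule("ranked", error_mode = "uniform"))
  for (i in 1:60) {
    s <- sample(2:6, 1)
    strengths <- stats::runif(s, 0, 1e6) *
      stats::rbinom(s, 1, 0.8) # zeros are common in practice
    d <- stats::runif(1, 0, 10)
    for (rule in rules) {
      p <- preference(strengths, rule, d = d)
      expect_length(p, s)
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("k = 0 sigmoidal preferences are scale invariant", {
  set.seed(8)
  rule <- choice_rule("sigmoidal", k = 0, x = 2)
  for (i in 1:25) {
    c0 <- stats::runif(4, 0, 10)
    alpha <- stats::runif(1, 1e-3, 1e3)
    expect_equal(preference(c0, rule), preference(alpha * c0, rule),
                 tolerance = 1e-9)
  }
})

test_that("more pheromone never lowers a trail's linear/sigmoidal preference", {
  set.seed(9)
  for (rule in list(choice_rule("linear"),
                    choice_rule("sigmoidal", k = 2, x = 3))) {
    for (i in 1:25) {
      c0 <- stats::runif(4, 0, 5)
      j <- sample(4, 1)
      c1 <- c0
      c1[j] <- c1[j] + stats::runif(1, 0, 5)
      expect_gte(preference(c1, rule)[j], preference(c0, rule)[j])
    }
  }
})

test_that("permuting trails permutes preferences identically", {
  set.seed(10)
  rules <- list(choice_rule("linear"), choice_rule("sigmoidal", k = 2, x = 2),
                choice_rule("ranked"))
  for (i in 1:20) {
    c0 <- stats::runif(4, 0, 2)
    perm <- sample(4)
    for (rule in rules) {
      expect_equal(preference(c0[perm], rule, d = 0.1),
                   preference(c0, rule, d = 0.1)[perm])
    }
  }
})

test_that("linear rule is exactly the k = 0, x = 1 sigmoidal rule", {
  set.seed(11)
  sig <- choice_rule("sigmoidal", k = 0, x = 1)
  lin <- choice_rule("linear")
  for (i in 1:1000) {
    c0 <- stats::runif(4, 0, 100) * stats::rbinom(4, 1, 0.9)
    expect_identical(preference(c0, lin), preference(c0, sig))
  }
})

test_that("all-zero trails fall back to the uniform choice", {
  z <- c(0, 0, 0, 0)
  expect_equal(preference(z, choice_rule("linear")), rep(0.25, 4))
  expect_equal(preference(z, choice_rule("sigmoidal", k = 0, x = 2)),
               rep(0.25, 4))
  expect_equal(preference(z, choice_rule("ranked")), rep(0.25, 4))
})

test_that("sample_trail matches its preference distribution", {
  expect_equal(unique(sample_trail(c(1, 0, 0, 0), n = 100)), 1L)

  set.seed(12)
  p <- c(0.75, 0.1875, 0.046875, 0.015625)
  n <- 1e5
  draws <- sample_trail(p, n = n)
  counts <- tabulate(draws, nbins = 4)
  # frequencies within 3-sigma binomial bands
  expect_true(all(abs(counts / n - p) <= 3 * sqrt(p * (1 - p) / n)))
  # chi-square goodness of fit not rejected at alpha = 0.001
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.001)

  expect_error(sample_trail(c(0.5, 0.4)), "summing to 1")
})

test_that("the engine's compiled preference agrees with the R reference", {
  set.seed(13)
  specs <- list(list(choice_rule("random"), 0),
                list(choice_rule("linear"), 0.3),
                list(choice_rule("sigmoidal", k = 2, x = 3), 0.5),
                list(choice_rule("ranked"), 0.2),
                list(choice_rule("ranked", error_mode = "uniform"), 0))
  for (i in 1:50) {
    c0 <- round(stats::runif(4, 0, 2), 1)
    for (sp in specs) {
      rule <- sp[[1]]
      d <- sp[[2]]
      expect_equal(
        antsym:::preference_engine(c0, antsym:::rule_code(rule), rule$k,
                                   rule$x, rule$p_top,
                                   as.integer(rule$error_mode == "uniform"),
                                   d),
        preference(c0, rule, d = d),
        tolerance = 1e-14
      )
    }
  }
})
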