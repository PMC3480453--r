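test_that("sweeps run every cell x replicate with distinct, stable seeds", {
  spec <- sweep_spec(
    tidyr::crossing(rule = "linear", colony_size = c(30, 60)),
    replicates = 3, base_seed = 9
  )
  tbl <- run_sweep(spec)
  expect_equal(nrow(tbl), 6)
  expect_equal(dplyr::n_distinct(tbl$seed), 6)
  expect_setequal(tbl$colony_size, c(30, 60))
  # determinism: same spec, same table
  expect_identical(run_sweep(spec), tbl)
})

test_that("sweep grids are validated", {
  expect_error(sweep_spec(tibble::tibble(rule = character(0))), "non-empty")
  expect_error(sweep_spec(tibble::tibble(colony_size = 5)), "`rule`")
  expect_error(sweep_spec(tibble::tibble(rule = "linear", banana = 1)),
               "banana")
  expect_error(
    run_sweep(sweep_spec(tibble::tibble(rule = "linear", decay = 2),
                         replicates = 1)),
    "cell 1"
  )
})

test_that("per-run seeds are deterministic and collision-free in a sweep", {
  seeds <- outer(1:50, 1:40,
                 function(cell, rep) seed_for_run(123, cell, rep))
  expect_equal(length(unique(as.vector(seeds))), 50 * 40)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_identical(seed_for_run(123, 7, 3), seed_for_run(123, 7, 3))
})

test_that("the null envelope is the per-size upper quantile", {
  tbl <- fake_table(c(100, 200), list(rep(0.4, 20), rep(0.1, 20)),
                    rule = "random")
  env <- null_envelope(tbl)
  expect_equal(env$q, c(0.4, 0.1))

  # documented convention: linear interpolation of order statistics
  tbl2 <- fake_table(100, list(seq(0, 1, by = 0.05)), reps = 21,
                     rule = "random")
  expect_equal(null_envelope(tbl2)$q,
               stats::quantile(seq(0, 1, by = 0.05), 0.95, names = FALSE))
  expect_equal(null_envelope(tbl2)$q, 0.95)

  expect_error(null_envelope(fake_table(5, list(0.1))), "random")
})

test_that("the null envelope shrinks with colony size under the null", {
  spec <- preset_sweep("null", replicates = 20,
                       colony_sizes = c(20, 200, 2000), base_seed = 2)
  env <- null_envelope(run_sweep(spec))
  expect_equal(order(env$q, decreasing = TRUE), 1:3)
})

test_that("rank-sum comparison against the null behaves sanely", {
  same <- fake_table(100, list(seq(0.1, 0.3, length.out = 10)), reps = 10)
  cmp <- compare_to_null(same, dplyr::mutate(same, rule = "random"))
  expect_gt(cmp$p_value, 0.9)

  apart <- compare_to_null(
    fake_table(100, list(rep(1, 10)), reps = 10),
    fake_table(100, list(rep(0, 10)), reps = 10, rule = "random")
  )
  expect_lt(apart$p_value, 0.001)

  expect_error(
    compare_to_null(fake_table(100, list(0.5), reps = 3),
                    fake_table(100, list(0.1), reps = 10)),
    ">= 5 runs"
  )
})

test_that("trend detection recovers planted slopes and flags flat data", {
  flat <- fake_table(c(50, 100, 200), list(0.4, 0.4, 0.4))
  tr <- asymmetry_trend(flat)
  expect_equal(tr$slope, 0)
  expect_equal(tr$direction, "none")

  set.seed(14)
  sizes <- seq(50, 500, by = 50)
  planted <- fake_table(sizes, lapply(sizes * 0.296, function(n) {
    pmin(1, pmax(0, 0.001 * n + stats::rnorm(20, 0, 0.02)))
  }))
  expect_equal(asymmetry_trend(planted)$direction, "increasing")
  expect_equal(
    asymmetry_trend(dplyr::mutate(planted, A = 1 - A))$direction,
    "decreasing"
  )

  expect_error(asymmetry_trend(fake_table(100, list(0.2))), "distinct")
})

test_that("threshold detection finds the first size that beats the null", {
  sizes <- c(50, 100, 150, 200)
  base <- lapply(sizes, function(s) seq(0.01, 0.2, length.out = 20))
  null_tbl <- fake_table(sizes, base, rule = "random")
  shifted <- lapply(seq_along(sizes), function(i) {
    if (sizes[i] > 100) base[[i]] + 0.3 else base[[i]]
  })
  treat <- fake_table(sizes, shifted)
  hit <- detect_threshold(treat, null_tbl)
  expect_equal(hit$colony_size, 150)
  expect_equal(hit$mean_active_foragers, 150 * 0.296)

  none <- detect_threshold(fake_table(sizes, base), null_tbl)
  expect_true(is.na(none$colony_size))

  expect_error(detect_threshold(fake_table(c(50, 99), base[1:2]), null_tbl),
               "grid")
})

test_that("capacity divergence recovers planted change points", {
  sizes <- c(50, 100, 200, 400)
  high <- lapply(sizes, function(s) seq(0.5, 0.7, length.out = 20))
  null_a <- lapply(sizes, function(s) seq(0.01, 0.1, length.out = 20))
  unlimited <- fake_table(sizes, high)
  null_tbl <- fake_table(sizes, null_a, rule = "random")

  # identical tables: no divergence, no convergence with the null
  same <- capacity_divergence(unlimited, unlimited, null_tbl)
  expect_true(is.na(same$divergence_size))

  # damped above 100: drops to null level from size 200 on
  damped <- fake_table(sizes, list(high[[1]], high[[2]], null_a[[3]],
                                   null_a[[4]]))
  out <- capacity_divergence(damped, unlimited, null_tbl)
  expect_equal(out$divergence_size, 200)
  expect_equal(out$convergence_size, 200)
})

test_that("presets encode the standard experiment designs", {
  r8 <- preset_sweep("rules8", replicates = 2)
  expect_equal(nrow(r8$grid), 8 * 25)
  expect_setequal(unique(r8$grid$rule), c("linear", "sigmoidal", "ranked"))
  expect_equal(sum(r8$grid$rule == "sigmoidal"), 6 * 25)

  xs <- preset_sweep("xsweep")
  expect_setequal(unique(xs$grid$x), 2:5)
  expect_true(all(xs$grid$k == 0))

  ks <- preset_sweep("ksweep")
  expect_setequal(unique(ks$grid$k), 0:6)

  disc <- preset_sweep("discrimination")
  expect_equal(disc$replicates, 500)
  expect_setequal(unique(disc$grid$discrimination), 0:5)
  sz <- unique(disc$grid$colony_size)
  expect_equal(length(sz), 20)
  expect_equal(range(sz), c(5, 200))

  cap <- preset_sweep("capacity")
  expect_setequal(unique(cap$grid$patch_capacity), c(15, Inf))

  rp <- preset_sweep("ranked_pref")
  expect_setequal(unique(rp$grid$p_top), c(0.4, 0.5, 0.6, 0.75, 0.9))

  expect_equal(length(colony_sizes_default()), 25)
  expect_equal(range(colony_sizes_default()), c(5, 2000))
  expect_error(preset_sweep("nope"), "unknown preset")
})

test_that("sweep summaries aggregate per rule cell", {
  tbl <- dplyr::bind_rows(
    dplyr::mutate(fake_table(c(50, 100, 200),
                             list(0.2, 0.5, 0.8)), rule_label = "up"),
    dplyr::mutate(fake_table(c(50, 100, 200),
                             list(0.4, 0.4, 0.4)), rule_label = "flat")
  )
  sm <- summarize_sweep(tbl)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$direction[sm$rule_label == "up"], "increasing")
  expect_equal(sm$direction[sm$rule_label == "flat"], "none")
  expect_equal(sm$median_A[sm$rule_label == "up"], 0.5)
})
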