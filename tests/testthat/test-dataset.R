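test_that("default ranges carry the documented bounds", {
  r <- parameter_ranges()
  expect_equal(r$E_bone, c(100, 3000))
  expect_equal(r$nu_bone, c(0.2, 0.3))
  expect_equal(r$t_skull, c(2, 4))
  expect_equal(r$w_ost, c(10, 20))
  expect_equal(r$l_ost, c(0, 40))
  expect_equal(r$l_skull, c(153, 170))
  expect_equal(r$w_skull, c(107, 120))
  expect_equal(r$x_spring, c(10, 40))
  expect_equal(r$n_spring, c(2L, 3L))
  expect_error(parameter_ranges(E_bone = c(5, 5)), "min < max")
})

test_that("sampling respects bounds, reproducibility and the cut constraint", {
  s <- sample_parameters(n = 212, seed = 3)
  expect_equal(nrow(s), 212)
  r <- parameter_ranges()
  for (nm in c("E_bone", "nu_bone", "t_skull", "w_ost", "l_ost",
               "l_skull", "w_skull", "x_spring")) {
    expect_true(all(s[[nm]] >= r[[nm]][1] & s[[nm]] <= r[[nm]][2]),
                info = nm)
  }
  expect_true(all(s$n_spring %in% c(2L, 3L)))
  expect_true(all(s$d_wire %in% spring_catalog()$d_wire))
  # springs always inside the cut
  expect_true(all(s$x_spring >= s$l_ost))
  # same seed, same draw; different seed, different draw
  expect_identical(s, sample_parameters(n = 212, seed = 3))
  expect_false(identical(s, sample_parameters(n = 212, seed = 4)))
})

test_that("large-sample statistics cover the ranges uniformly", {
  s <- sample_parameters(n = 10000, seed = 9)
  r <- parameter_ranges()
  for (nm in c("E_bone", "nu_bone", "t_skull", "w_ost", "x_spring")) {
    span <- r[[nm]][2] - r[[nm]][1]
    expect_lt(min(s[[nm]]) - r[[nm]][1], 0.01 * span)
    expect_lt(r[[nm]][2] - max(s[[nm]]), 0.01 * span)
  }
  # two/three springs about 50/50 (binomial 3 sigma)
  p2 <- mean(s$n_spring == 2L)
  expect_lt(abs(p2 - 0.5), 3 * sqrt(0.25 / nrow(s)))
  # uniform scaling keeps skull proportions fixed
  expect_equal(sd(s$w_skull / s$l_skull), 0, tolerance = 1e-12)
  s_ind <- sample_parameters(n = 500, seed = 9, scaling = "independent")
  expect_gt(sd(s_ind$w_skull / s_ind$l_skull), 0.01)
})

test_that("a small campaign produces complete records with expanded CI", {
  s <- sample_parameters(n = 5, seed = 21)
  rec <- run_campaign(s, campaign_config(resolution = 12))
  expect_equal(nrow(rec), 5)
  expect_true(all(rec$converged))
  # positive spring forces must not shrink the head
  expect_true(all(rec$post_op_ci >= rec$pre_op_ci))
  expect_true(all(rec$post_op_ci_pct == 100 * rec$post_op_ci))
  expect_true(all(rec$max_displacement > 0))
})

test_that("zero-force springs leave the cephalic index unchanged", {
  s <- sample_parameters(n = 2, seed = 22)
  cfg <- campaign_config(
    resolution = 12,
    characteristic = spring_characteristic(1.2, F0 = 1e-9, opening_max = 10)
  )
  rec <- run_campaign(s, cfg)
  expect_equal(rec$post_op_ci, rec$pre_op_ci, tolerance = 1e-6)
})

test_that("individual failures are flagged without aborting the campaign", {
  s <- sample_parameters(n = 3, seed = 23)
  s$t_skull[2] <- -1 # invalid: rejected by the geometry validator
  rec <- run_campaign(s, campaign_config(resolution = 12))
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$converged), 2)
  expect_match(rec$error[2], "t_skull")
  expect_true(is.na(rec$post_op_ci[2]))
})

test_that("campaign cache makes reruns resumable and identical", {
  cache <- withr::local_tempdir()
  s <- sample_parameters(n = 3, seed = 24)
  cfg <- campaign_config(resolution = 12, cache_dir = cache)
  r1 <- run_campaign(s, cfg)
  expect_length(list.files(cache, pattern = "record_"), 3)
  r2 <- run_campaign(s, cfg) # second pass reads the cache
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
})

test_that("records round-trip through CSV", {
  s <- sample_parameters(n = 2, seed = 25)
  rec <- run_campaign(s, campaign_config(resolution = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  back <- tibble::as_tibble(read.csv(path))
  num <- vapply(rec, is.numeric, TRUE)
  for (nm in names(rec)[num]) {
    expect_equal(back[[nm]], rec[[nm]], tolerance = 1e-12, info = nm)
  }
})

test_that("split sizes, disjointness and reproducibility hold", {
  rec <- tibble::tibble(
    id = 1:212, post_op_ci = runif(212, 0.70, 0.73), converged = TRUE
  )
  sp <- split_dataset(rec, seed = 5)
  expect_equal(nrow(sp$train), 170)
  expect_equal(nrow(sp$test), 42)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), rec$id)
  sp2 <- split_dataset(rec, seed = 5)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_dataset(rec[1:100, ], seed = 5), "need 212")
})
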