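test_that("tree simulation is deterministic and structurally valid", {
  a <- simulate_timetree(25, bd_params(5, 1, 1), seed = 801)
  b <- simulate_timetree(25, bd_params(5, 1, 1), seed = 801)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_false(identical(ape::write.tree(a),
                         ape::write.tree(simulate_timetree(
                           25, bd_params(5, 1, 1), seed = 802))))

  tr <- simulate_timetree(100, bd_params(5, 1, 1), seed = 803)
  expect_equal(length(tr$tip.label), 100L)
  expect_equal(tr$Nnode, 99L)
  expect_silent(validate_timetree(tr))
  expect_error(simulate_timetree(10, bd_params(5, 1, 1)), "seed")

  fixed <- simulate_timetree(50, bd_params(5, 1, 1), seed = 804,
                             root_age = 1)
  expect_equal(root_age(fixed), 1, tolerance = 1e-9)
})

test_that("simulated Yule node ages follow the truncated exponential", {
  lam <- 3
  set.seed(805)
  ages <- simulate_node_ages(5000, bd_params(lam, 0, 1), t1 = 1)
  expect_true(all(ages > 0 & ages < 1))
  cdf <- function(t) (1 - exp(-lam * t)) / (1 - exp(-lam))
  ks <- suppressWarnings(stats::ks.test(ages, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("the age sampler inverts the model CDF for general parameters", {
  p <- bd_params(4, 2, 0.3)
  set.seed(806)
  ages <- simulate_node_ages(5000, p, t1 = 2)
  cdf <- function(t) bd_v(t, p) / bd_v(2, p)
  ks <- suppressWarnings(stats::ks.test(ages, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("random community sampling behaves binomially", {
  tr <- simulate_timetree(236, bd_params(17, 6, 1), seed = 807)
  expect_setequal(sample_community_random(tr, 1), tr$tip.label)

  set.seed(808)
  sizes <- replicate(1000, length(sample_community_random(tr, 0.2)))
  se_mean <- sqrt(236 * 0.2 * 0.8) / sqrt(1000)
  expect_lt(abs(mean(sizes) - 47.2), 3 * se_mean)
  expect_identical(sample_community_random(tr, 0.3, seed = 809),
                   sample_community_random(tr, 0.3, seed = 809))
  expect_error(sample_community_random(tr, 0.001, min_size = 50,
                                       max_tries = 5), "could not reach")
})

test_that("clade-biased sampling concentrates membership as directed", {
  tr <- simulate_timetree(100, bd_params(8, 2, 1), seed = 810)
  nd <- pick_skew_clade(tr, 0.3)
  tips <- clade_tips(tr, nd)
  expect_gt(length(tips), 1L)

  m <- sample_community_clade_biased(tr, nd, p_in = 0.8, p_out = 0,
                                     seed = 811, min_size = 5)
  expect_true(all(m %in% tips))
  expect_error(sample_community_clade_biased(tr, 5000, 0.5, 0.1),
               "unknown clade")

  # p_in = p_out reduces to the uniform sampler
  set.seed(812)
  even <- replicate(200, length(
    sample_community_clade_biased(tr, nd, p_in = 0.2, p_out = 0.2)))
  expect_lt(abs(mean(even) - 20), 3 * sqrt(100 * 0.2 * 0.8 / 200))
})

test_that("grid generation is reproducible and carries a truth sidecar", {
  sc <- grid_scenario(n_species = 60, bd = bd_params(8, 2, 1), n_cells = 10,
                      base_rho0 = 0.35, seed = 813)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_grid(sc, dir = d1)
  g2 <- generate_grid(sc, dir = d2)
  expect_identical(readLines(file.path(d1, "occurrences.csv")),
                   readLines(file.path(d2, "occurrences.csv")))
  expect_match(readLines(file.path(d1, "occurrences.csv"), n = 1),
               "^# seed: 813$")
  occ <- utils::read.csv(file.path(d1, "occurrences.csv"),
                         comment.char = "#")
  expect_equal(occ, g1$occurrences, ignore_attr = TRUE)

  expect_equal(nrow(g1$truth), 10L)
  expect_setequal(unique(g1$truth$regime), c("tropical", "temperate"))
  expect_true(all(g1$truth$mode[g1$truth$regime == "temperate"] == "random"))
  expect_true(all(table(g1$occurrences$longitude) >= 11))

  flat <- grid_scenario(n_species = 60, bd = bd_params(8, 2, 1),
                        n_cells = 10, base_rho0 = 0.35, skew_strength = 0,
                        seed = 813)
  g0 <- generate_grid(flat)
  expect_true(all(g0$truth$mode == "random"))
})

test_that("the likelihood prefers generating over perturbed rates", {
  p <- bd_params(6, 2, 1)
  set.seed(814)
  wins <- replicate(100, {
    times <- c(1, sort(simulate_node_ages(60, p, t1 = 1), decreasing = TRUE))
    at_truth <- bd_loglik(times, p)
    at_truth > bd_loglik(times, bd_params(9, 2, 1)) &&
      at_truth > bd_loglik(times, bd_params(3, 2, 1))
  })
  expect_gte(mean(wins), 0.8)
})
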