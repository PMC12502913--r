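test_that("resampling reports are seed-reproducible and well-formed", {
  sim <- simulate_ms_cohort(n_families = 10, m_per_group = c(5, 5), seed = 81)
  a <- resample_robustness(sim$abundance, sim$index, sim$metadata,
                           n_per_group = 3, rounds = 4, seed = 99)
  b <- resample_robustness(sim$abundance, sim$index, sim$metadata,
                           n_per_group = 3, rounds = 4, seed = 99)
  expect_identical(a$t_matrix, b$t_matrix)
  expect_identical(a$correlations, b$correlations)
  expect_equal(dim(a$t_matrix), c(4, 10))
  expect_true(all(is.finite(a$t_matrix)))
  gl <- glance(a)
  expect_equal(gl$rounds, 4)
  expect_equal(nrow(tidy(a)), 10)
})

test_that("a full-size subsample reproduces the full-data t vector", {
  sim <- simulate_ms_cohort(n_families = 8, m_per_group = c(4, 4), seed = 82)
  rep <- resample_robustness(sim$abundance, sim$index, sim$metadata,
                             n_per_group = 4, rounds = 1, seed = 1)
  expect_equal(as.vector(rep$t_matrix[1, ]), unname(rep$t_full),
               tolerance = 1e-10)
  expect_equal(unname(rep$correlations[1]), 1, tolerance = 1e-10)

  expect_error(
    resample_robustness(sim$abundance, sim$index, sim$metadata,
                        n_per_group = 5, rounds = 1),
    "n_per_group"
  )
})

test_that("subsampled t-statistics stay positively correlated with full data", {
  sim <- simulate_ms_cohort(n_families = 15, m_per_group = c(6, 6),
                            fraction_dysregulated = 0.4, effect_size = 1,
                            sigma = 0.3, seed = 83)
  rep <- resample_robustness(sim$abundance, sim$index, sim$metadata,
                             n_per_group = 3, rounds = 10, seed = 7)
  expect_gt(mean(rep$correlations), 0)
})

test_that("t-statistic concordance detects identity, inversion and hits", {
  sim <- simulate_ms_cohort(n_families = 10, fraction_dysregulated = 0.5,
                            effect_size = 1.5, sigma = 0.2, seed = 91)
  res <- run_family_lm(sim$abundance, sim$index, sim$metadata)
  self <- tstat_concordance(res, res)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_setequal(self$common_hits, res$family_id[res$significant])

  neg <- res |> dplyr::mutate(t_stat = -t_stat,
                              direction = ifelse(direction == "up",
                                                 "down", "up"))
  opp <- tstat_concordance(res, neg)
  expect_equal(opp$r, -1, tolerance = 1e-12)
  expect_length(opp$common_hits, 0)

  expect_error(tstat_concordance(res[1:2, ], res), ">= 3")
})

test_that("two cohorts simulated from one truth share their hits", {
  sim1 <- simulate_ms_cohort(n_families = 20, fraction_dysregulated = 0.3,
                             effect_size = 1.5, sigma = 0.2, seed = 19)
  # same dysregulated families, new samples: reuse truth by regenerating with
  # the same seed for the layout but a different noise draw
  sim2 <- simulate_ms_cohort(n_families = 20, fraction_dysregulated = 0.3,
                             effect_size = 1.5, sigma = 0.2, seed = 19)
  set.seed(20)
  sim2$abundance <- sim2$abundance |>
    dplyr::mutate(rpm = rpm * 10^rnorm(dplyr::n(), sd = 0.05))
  r1 <- run_family_lm(sim1$abundance, sim1$index, sim1$metadata)
  r2 <- run_family_lm(sim2$abundance, sim2$index, sim2$metadata)
  conc <- tstat_concordance(r1, r2)
  expect_gt(conc$r, 0.5)
  truth_up <- sim1$truth$family_id[sim1$truth$gamma != 0]
  expect_true(length(intersect(conc$common_hits, truth_up)) >=
                length(truth_up) / 2)
})

test_that("coverage depth sums intervals and conserves mass", {
  ann <- tibble::tibble(
    species_id = c("a", "b"),
    parent_id = "tRNA-Gly-GCC",
    family_id = "GtsRNA-Gly-GCC",
    start = c(1, 5), end = c(10, 15)
  )
  ab <- tidyr::crossing(species_id = c("a", "b"), sample_id = "s1") |>
    dplyr::mutate(count = 1, library_size = 1e6, rpm = c(5, 7))
  d <- coverage_depth(ab, ann, "tRNA-Gly-GCC", 20)
  depth <- d$depth
  expect_equal(depth[3], 5)
  expect_equal(depth[7], 12)
  expect_equal(depth[12], 7)
  expect_equal(depth[16:20], rep(0, 5))
  expect_equal(sum(depth), 5 * 10 + 7 * 11)

  # identical samples give SEM 0 everywhere
  ab2 <- tidyr::crossing(species_id = c("a", "b"),
                         sample_id = c("s1", "s2")) |>
    dplyr::mutate(count = 1, library_size = 1e6, rpm = rep(c(5, 7), each = 2))
  prof <- coverage_profile(ab2, ann, "tRNA-Gly-GCC", 20)
  expect_equal(prof$sem, rep(0, 20))
  expect_equal(prof$mean_rpm[1:4], rep(5, 4))

  expect_error(coverage_depth(ab, ann, "tRNA-Gly-GCC", 12), "parent_length")
})

test_that("coverage mass conservation holds on random interval fixtures", {
  set.seed(131)
  for (i in 1:5) {
    n_sp <- sample(3:10, 1)
    L <- 100
    starts <- sample(1:80, n_sp, replace = TRUE)
    ends <- pmin(L, starts + sample(10:40, n_sp, replace = TRUE))
    ann <- tibble::tibble(species_id = sprintf("sp%d", 1:n_sp),
                          parent_id = "28S", family_id = "rsRNA-28S",
                          start = starts, end = ends)
    ab <- tidyr::crossing(species_id = ann$species_id,
                          sample_id = c("s1", "s2", "s3")) |>
      dplyr::mutate(count = 1, library_size = 1e6,
                    rpm = 10^runif(n_sp * 3, -1, 2))
    d <- coverage_depth(ab, ann, "28S", L)
    for (s in c("s1", "s2", "s3")) {
      got <- sum(d$depth[d$sample_id == s])
      span <- ends - starts + 1
      want <- sum(ab$rpm[ab$sample_id == s][match(ann$species_id,
                    ab$species_id[ab$sample_id == s])] * span)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("species without coordinates are excluded with a report", {
  ann <- tibble::tibble(species_id = c("a", "b"),
                        parent_id = "28S", family_id = "rsRNA-28S",
                        start = c(1, NA), end = c(10, NA))
  ab <- tidyr::crossing(species_id = c("a", "b"), sample_id = "s1") |>
    dplyr::mutate(count = 1, library_size = 1e6, rpm = 5)
  expect_message(d <- coverage_depth(ab, ann, "28S", 20), "lack coordinates")
  expect_equal(sum(d$depth), 50)
})

test_that("dysregulation proportions count pairs exactly", {
  res <- tibble::tibble(
    pair_id = rep(sprintf("p%d", 1:4), each = 2),
    family_id = rep(c("famA", "famB"), 4),
    p_adjusted = c(0.01, 1, 0.02, 1, 0.03, 1, 0.9, 1),
    direction = c("up", "up", "up", "tie", "down", "down", "up", "tie")
  )
  cs <- concordance_summary(res)
  a <- cs[cs$family_id == "famA", ]
  expect_equal(c(a$prop_up, a$prop_down, a$prop_ns), c(0.5, 0.25, 0.25))
  b <- cs[cs$family_id == "famB", ]
  expect_equal(c(b$prop_up, b$prop_down, b$prop_ns), c(0, 0, 1))
  expect_equal(cs$prop_up + cs$prop_down + cs$prop_ns, rep(1, 2))
})

test_that("paired cohorts from a shared truth agree in their up-proportions", {
  sim1 <- simulate_paired_cohort(n_families = 15, species_per_family = 12,
                                 n_pairs = 6, fraction_dysregulated = 0.4,
                                 effect_size = 1.2, sigma = 0.25, seed = 141)
  sim2 <- simulate_paired_cohort(n_families = 15, species_per_family = 12,
                                 n_pairs = 6, fraction_dysregulated = 0.4,
                                 effect_size = 1.2, sigma = 0.25, seed = 141)
  set.seed(142)
  sim2$abundance <- sim2$abundance |>
    dplyr::mutate(rpm = rpm * 10^rnorm(dplyr::n(), sd = 0.03))
  r1 <- run_signedrank_cohort(sim1$abundance, sim1$index, sim1$metadata)
  r2 <- run_signedrank_cohort(sim2$abundance, sim2$index, sim2$metadata)
  c1 <- concordance_summary(r1)
  c2 <- concordance_summary(r2)
  merged <- dplyr::inner_join(c1, c2, by = "family_id")
  expect_gt(cor(merged$prop_up.x, merged$prop_up.y), 0)
})
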