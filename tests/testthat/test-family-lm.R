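# metadata for a 2-group, 2x2-sample toy cohort
toy_meta <- function(samples, groups) {
  tibble::tibble(sample_id = samples, phenotype = groups)
}

test_that("log10_eps matches its definition at the documented anchors", {
  expect_equal(log10_eps(0, 0.01), -2)
  expect_equal(log10_eps(99.99, 0.01), 2)
  expect_equal(log10_eps(1, 1e-12), 0, tolerance = 1e-10)
  expect_error(log10_eps(-1), "non-negative")
  expect_error(log10_eps(1, 0), "positive")
})

test_that("build_family_design stacks species-major with 0/1 group coding", {
  data <- tidyr::crossing(species_id = c("hi", "lo"),
                          sample_id = c("x1", "x2", "x3")) |>
    dplyr::mutate(rpm = c(100, 110, 120, 1, 2, 3))
  md <- toy_meta(c("x1", "x2", "x3"), c("ctrl", "ctrl", "case"))
  d <- build_family_design(data, md)
  expect_s3_class(d, "ms_design")
  expect_length(d$E, 6)
  expect_equal(d$df, 3)
  # "case" sorts first so it is the reference -> ctrl coded 1
  expect_equal(d$G, rep(c(1, 1, 0), 2))
  d2 <- build_family_design(data, md, reference_group = "ctrl")
  expect_equal(d2$G, rep(c(0, 0, 1), 2))
  # reference species has the highest mean RPM
  expect_equal(d$reference_species, "hi")
  expect_equal(levels(d$species)[1], "hi")

  cont <- toy_meta(c("x1", "x2", "x3"), NA)
  cont$phenotype <- c(1.2, 3.4, 5.6)
  d3 <- build_family_design(data, cont)
  expect_equal(d3$G, rep(c(1.2, 3.4, 5.6), 2))

  const <- toy_meta(c("x1", "x2", "x3"), "same")
  expect_error(build_family_design(data, const),
               class = "sncfam_degenerate_design")
})

test_that("single-species model reduces to the pooled-variance t-test", {
  data <- tibble::tibble(species_id = "only",
                         sample_id = c("a1", "a2", "b1", "b2"),
                         rpm = c(1, 2, 3, 4))
  md <- toy_meta(c("a1", "a2", "b1", "b2"), c("g0", "g0", "g1", "g1"))
  # epsilon tiny so log10(rpm + eps) ~ log10(rpm); feed 10^values to make the
  # response equal (1, 2, 3, 4) on the log scale
  data$rpm <- 10^data$rpm
  d <- build_family_design(data, md, epsilon = 1e-12,
                           allow_single_species = TRUE)
  fit <- fit_family_model(d)
  expect_equal(fit$t_stat, 2.828427, tolerance = 1e-6)
  expect_equal(fit$df, 2)
  expect_equal(fit$p_value, 0.105573, tolerance = 1e-5)
  tt <- t.test(c(3, 4), c(1, 2), var.equal = TRUE)
  expect_equal(fit$t_stat, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("an additive species offset is absorbed by the species indicator", {
  md <- toy_meta(c("a1", "a2", "b1", "b2"), c("g0", "g0", "g1", "g1"))
  base <- c(1, 2, 3, 4)
  one <- tibble::tibble(species_id = "s1",
                        sample_id = c("a1", "a2", "b1", "b2"),
                        rpm = 10^base)
  two <- dplyr::bind_rows(one,
    tibble::tibble(species_id = "s2",
                   sample_id = c("a1", "a2", "b1", "b2"),
                   rpm = 10^(base + 1)))
  f1 <- fit_family_model(build_family_design(one, md, epsilon = 1e-12,
                                             allow_single_species = TRUE))
  f2 <- fit_family_model(build_family_design(two, md, epsilon = 1e-12))
  expect_equal(f2$df, 8 - 3)
  expect_equal(f2$beta1, f1$beta1, tolerance = 1e-9)
  # same signal with doubled observations: t grows, p-value structure from
  # the pooled fit; the specific invariant is that beta1 is unchanged and
  # residuals stay zero-mean per species
  expect_equal(f2$direction, "up")
})

test_that("flat families give a zero effect with p = 1", {
  md <- toy_meta(c("a1", "a2", "b1", "b2"), c("g0", "g0", "g1", "g1"))
  data <- tidyr::crossing(species_id = c("s1", "s2"),
                          sample_id = c("a1", "a2", "b1", "b2")) |>
    dplyr::mutate(rpm = rep(c(10, 50), each = 4))
  fit <- fit_family_model(build_family_design(data, md))
  expect_equal(fit$beta1, 0)
  expect_equal(fit$t_stat, 0)
  expect_equal(fit$p_value, 1)
})

test_that("fit matches the normal-equations oracle on random small designs", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(2:5, 1)
    m <- sample(4:8, 1)
    rpm <- matrix(10^runif(n * m, 0, 3), n, m,
                  dimnames = list(sprintf("sp%d", 1:n),
                                  sprintf("s%d", 1:m)))
    g <- sample(rep(c(0, 1), length.out = m))
    data <- tibble::tibble(
      species_id = rep(rownames(rpm), each = m),
      sample_id = rep(colnames(rpm), n),
      rpm = as.vector(t(rpm))
    )
    md <- tibble::tibble(sample_id = colnames(rpm), phenotype = g)
    fit <- fit_family_model(build_family_design(data, md))
    o <- oracle_design_matrix(rpm, g)
    ref <- oracle_ols(o$X, o$E, "G")
    expect_equal(fit$t_stat, ref$t, tolerance = 1e-8)
    expect_equal(fit$p_value, ref$p, tolerance = 1e-8)
    expect_equal(fit$df, ref$df)
  }
})

test_that("tidy and glance expose the phenotype coefficient", {
  md <- toy_meta(c("a1", "a2", "b1", "b2"), c("g0", "g0", "g1", "g1"))
  data <- tidyr::crossing(species_id = c("s1", "s2"),
                          sample_id = c("a1", "a2", "b1", "b2")) |>
    dplyr::mutate(rpm = c(1, 2, 9, 11, 2, 3, 11, 14))
  fit <- fit_family_model(build_family_design(data, md))
  td <- tidy(fit)
  expect_equal(td$term, "G")
  expect_equal(td$statistic, fit$t_stat)
  gl <- glance(fit)
  expect_equal(gl$df, fit$df)
  expect_equal(gl$n_species, 2)
})

test_that("run_family_lm orders results, adjusts p and isolates failures", {
  sim <- simulate_ms_cohort(n_families = 8, species_per_family = 3,
                            m_per_group = c(4, 4), fraction_dysregulated = 0.5,
                            effect_size = 1, sigma = 0.2, seed = 31)
  # inject a family that cannot be fit (single species)
  idx <- dplyr::bind_rows(
    sim$index,
    tibble::tibble(family_id = "broken", species_id = sim$index$species_id[1],
                   mean_rpm = 1, uniquely_annotated = TRUE)
  )
  res <- run_family_lm(sim$abundance, idx, sim$metadata)
  expect_equal(nrow(res), 9)
  broken <- res[res$family_id == "broken", ]
  expect_true(is.na(broken$p_value))
  expect_false(broken$status == "ok")
  expect_true(all(res$status[res$family_id != "broken"] == "ok"))
  # failures sort last; finite p ascending
  expect_equal(res$family_id[nrow(res)], "broken")
  okp <- res$p_value[res$status == "ok"]
  expect_true(all(diff(okp) >= 0))
  # multiplier counts all 9 attempted families
  expect_equal(res$p_adjusted, bonferroni_adjust(res$p_value, 9))
  # direction matches the sign of t
  expect_equal(res$direction[res$status == "ok"],
               ifelse(res$t_stat[res$status == "ok"] > 0, "up", "down"))
})

test_that("binary group coding direction follows the non-reference group", {
  sim <- simulate_ms_cohort(n_families = 6, fraction_dysregulated = 1,
                            effect_size = 1, sigma = 0.1, seed = 5)
  res <- run_family_lm(sim$abundance, sim$index, sim$metadata)
  expect_true(all(res$direction == "up"))   # shift applies to "patient"
  flipped <- run_family_lm(sim$abundance, sim$index, sim$metadata,
                           reference_group = "patient")
  expect_true(all(flipped$direction == "down"))
  expect_equal(abs(flipped$t_stat), abs(res$t_stat), tolerance = 1e-10)
})
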