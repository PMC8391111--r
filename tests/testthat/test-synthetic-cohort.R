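test_that("group covariance has the stated block values and perturbation rule", {
  spec <- cohort_spec(n_regions = 6, n_volumes = 50, n_cases = 2,
                      n_controls = 2, n_communities = 2,
                      within_cor = 0.5, between_cor = 0.1)
  s <- build_group_covariance(spec, "control")
  off <- s[upper.tri(s)]
  expect_setequal(round(unique(off), 10), c(0.5, 0.1))
  expect_true(isSymmetric(s))
  expect_equal(unname(diag(s)), rep(1, 6))

  # zero effect: case and control identical
  spec0 <- cohort_spec(n_regions = 10, n_volumes = 50, n_cases = 2,
                       n_controls = 2, perturbed_nodes = 1:3,
                       effect_size = 0)
  expect_identical(build_group_covariance(spec0, "case"),
                   build_group_covariance(spec0, "control"))

  # perturbation scales every incident entry by 1 - effect_size
  spec1 <- cohort_spec(n_regions = 10, n_volumes = 50, n_cases = 2,
                       n_controls = 2, n_communities = 2,
                       perturbed_nodes = 1L, effect_size = 0.4)
  ctrl <- build_group_covariance(spec1, "control")
  case <- build_group_covariance(spec1, "case")
  for (j in 2:10) {
    expect_equal(case[1, j], 0.6 * ctrl[1, j])
    expect_equal(case[j, 1], 0.6 * ctrl[j, 1])
  }
  expect_equal(case[2:10, 2:10], ctrl[2:10, 2:10])
  ev <- eigen(case, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("cohort sampling is deterministic and respects group sizes", {
  spec <- cohort_spec(n_regions = 8, n_volumes = 40, n_cases = 5,
                      n_controls = 7, n_communities = 2,
                      perturbed_nodes = 1L, effect_size = 0.3,
                      symptom_coupling = 0.4, seed = 42)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  expect_length(a$subjects, 12)
  expect_equal(sum(a$manifest$group == "case"), 5)
  expect_equal(sum(a$manifest$group == "control"), 7)
  for (s in a$subjects) {
    expect_true(all(is.finite(s$series)))
    expect_equal(dim(s$series), c(8, 40))
  }
  expect_true(all(a$manifest$symptom_score >= 0 &
                  a$manifest$symptom_score <= 136))
  # case scores sit in the CAPS-like case range, controls lower
  expect_gt(mean(a$manifest$symptom_score[a$manifest$group == "case"]),
            mean(a$manifest$symptom_score[a$manifest$group == "control"]))
})

test_that("full-scale default cohort spec gives 91 cases and 126 controls", {
  spec <- cohort_spec()
  expect_equal(spec$n_cases, 91L)
  expect_equal(spec$n_controls, 126L)
  expect_equal(spec$n_regions, 90L)
  expect_equal(spec$n_volumes, 190L)
  expect_equal(spec$tr_seconds, 2)
})

test_that("empirical correlations converge to the generating matrix", {
  spec <- cohort_spec(n_regions = 5, n_volumes = 10000, n_cases = 2,
                      n_controls = 2, n_communities = 2,
                      ar_coefficient = 0, noise_sd = 0, seed = 7)
  co <- sample_cohort(spec)
  target <- cov2cor(build_group_covariance(spec, "control"))
  s <- co$subjects[[which(co$manifest$group == "control")[1]]]
  emp <- cor(t(s$series))
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("case symptom scores track the designated nodal property", {
  spec <- cohort_spec(n_regions = 12, n_volumes = 190, n_cases = 95,
                      n_controls = 5, n_communities = 4,
                      perturbed_nodes = 1:3, effect_size = 0.5,
                      symptom_coupling = 0.6, seed = 9)
  co <- sample_cohort(spec)
  cases <- which(co$manifest$group == "case")
  proxy <- vapply(co$subjects[cases], function(s)
    symptom_proxy(s$series, 1, spec$tr_seconds), 0)
  r <- cor(proxy, co$manifest$symptom_score[cases])
  expect_lt(abs(r - 0.6), 0.15)
})

test_that("invalid cohort specs are rejected and rank warnings raised", {
  expect_error(cohort_spec(n_regions = 2), "n_regions")
  expect_error(cohort_spec(n_cases = 1), "at least 2")
  expect_error(cohort_spec(perturbed_nodes = 95), "perturbed_nodes")
  expect_error(cohort_spec(effect_size = 1.5), "effect_size")
  expect_error(cohort_spec(ar_coefficient = 1), "ar_coefficient")
  expect_warning(cohort_spec(n_regions = 40, n_volumes = 30, n_cases = 3,
                             n_controls = 3), "rank-deficient")
})

test_that("cohorts round-trip through the TSV/manifest disk format", {
  spec <- cohort_spec(n_regions = 6, n_volumes = 20, n_cases = 3,
                      n_controls = 3, n_communities = 2, seed = 5)
  co <- sample_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$manifest$subject_id, co$manifest$subject_id)
  expect_equal(back$subjects[[1]]$series, co$subjects[[1]]$series,
               tolerance = 1e-12)
  expect_equal(back$subjects[[4]]$group, co$subjects[[4]]$group)
})
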