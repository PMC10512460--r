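test_that("effect_plan validates planted sets", {
  expect_error(effect_plan(10, increased_edges = 0:4, decreased_edges = 4:8),
               "disjoint")
  expect_error(effect_plan(10, increased_edges = 45), "must lie in")
  p <- effect_plan(10, increased_edges = 0:4, decreased_edges = 40:44)
  expect_identical(p$n_edges, 45L)
})

test_that("cohort generation is bit-identical under the same seed", {
  plan <- effect_plan(n_nodes = 15, increased_edges = 0:4,
                      decreased_edges = 5:9, delta = 0.4)
  a <- generate_cohort(plan, 10, 12, seed = 61)
  b <- generate_cohort(plan, 10, 12, seed = 61)
  expect_identical(a$edges, b$edges)
  expect_identical(a$labels, b$labels)
  c2 <- generate_cohort(plan, 10, 12, seed = 62)
  expect_false(identical(a$edges, c2$edges))
  # labels: controls first then patients, patient = 1 coding
  expect_identical(a$labels, c(rep(0L, 10), rep(1L, 12)))
  expect_error(generate_cohort(plan, 1, 12, seed = 1), "at least 2")
})

test_that("planted shifts move the group means by +/- delta", {
  plan <- effect_plan(n_nodes = 15, increased_edges = 0:9,
                      decreased_edges = 10:19, delta = 0.5, noise_sd = 0.05)
  d <- generate_cohort(plan, 200, 200, seed = 63)
  diff <- colMeans(d$edges[d$labels == 1, ]) - colMeans(d$edges[d$labels == 0, ])
  expect_equal(mean(diff[1:10]), 0.5, tolerance = 0.01)
  expect_equal(mean(diff[11:20]), -0.5, tolerance = 0.01)
  expect_equal(mean(abs(diff[21:105])), 0, tolerance = 0.02)
})

test_that("null generation is calibrated: ~t of edges pass threshold t", {
  counts <- c("0.05" = 0, "0.01" = 0)
  n_total <- 0
  for (s in 1:20) {
    d <- null_cohort(seed = 600 + s, n_nodes = 20, n_per = 20)
    rp <- edgewise_label_correlation(d$edges, d$labels)
    counts["0.05"] <- counts["0.05"] + sum(rp$p < 0.05)
    counts["0.01"] <- counts["0.01"] + sum(rp$p < 0.01)
    n_total <- n_total + length(rp$p)
  }
  # 99.9% binomial bands around the nominal rates
  for (t in c(0.05, 0.01)) {
    lo <- qbinom(5e-4, n_total, t)
    hi <- qbinom(1 - 5e-4, n_total, t)
    expect_gte(counts[as.character(t)], lo)
    expect_lte(counts[as.character(t)], hi)
  }
})

test_that("strong effects are selected with near-certain power", {
  # delta = 10 * noise_sd: every planted edge selected at p < 0.001
  plan <- effect_plan(n_nodes = 15, increased_edges = 0:9, delta = 2,
                      noise_sd = 0.2)
  hits <- vapply(1:20, function(s) {
    d <- generate_cohort(plan, 15, 15, seed = 700 + s)
    rp <- edgewise_label_correlation(d$edges, d$labels)
    sel <- select_directional_features(rp$r, rp$p, 0.001)
    all(sel$increased[1:10])
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("two-site designs share decreased and control increased overlap", {
  plan <- effect_plan(n_nodes = 20, delta = 0.3)
  full <- generate_two_sites(site_design(overlap = 1,
                                         n_controls = c(10, 10),
                                         n_patients = c(10, 10)),
                             plan, seed = 64)
  expect_identical(full$truth$increased_edges_site1,
                   full$truth$increased_edges_site2)
  none <- generate_two_sites(site_design(overlap = 0,
                                         n_controls = c(10, 10),
                                         n_patients = c(10, 10)),
                             plan, seed = 64)
  expect_length(intersect(none$truth$increased_edges_site1,
                          none$truth$increased_edges_site2), 0)
  expect_identical(none$truth$decreased_edges, sort(none$truth$decreased_edges))
  half <- generate_two_sites(site_design(n_increased_per_site = 20,
                                         overlap = 0.5,
                                         n_controls = c(10, 10),
                                         n_patients = c(10, 10)),
                             plan, seed = 65)
  expect_length(intersect(half$truth$increased_edges_site1,
                          half$truth$increased_edges_site2), 10)
  # requesting more planted edges than exist fails
  tiny <- effect_plan(n_nodes = 4, delta = 0.3)
  expect_error(generate_two_sites(site_design(n_shared_decreased = 5,
                                              n_increased_per_site = 5,
                                              overlap = 0,
                                              n_controls = c(5, 5),
                                              n_patients = c(5, 5)),
                                  tiny, seed = 1),
               "only 6 edges exist")
})

test_that("sites are generated independently from their own seeds", {
  plan <- effect_plan(n_nodes = 15, delta = 0.3)
  sites <- generate_two_sites(site_design(n_controls = c(8, 8),
                                          n_patients = c(8, 8)),
                              plan, seed = 66)
  # regenerate site 1 from its recorded seed and planted map: bit-identical,
  # regardless of what happens to site 2
  plan1 <- effect_plan(n_nodes = 15,
                       increased_edges = sites$truth$increased_edges_site1,
                       decreased_edges = sites$truth$decreased_edges,
                       delta = 0.3)
  again <- generate_cohort(plan1, 8, 8, seed = sites$truth$site_seeds[1])
  expect_identical(again$edges, sites$site1$edges)
})

test_that("time-series cohorts recover planted connectivity differences", {
  # near-identity target: mean |z| shrinks with timepoints
  plan0 <- effect_plan(n_nodes = 6, baseline_mean = 0, baseline_sd = 0.01,
                       noise_sd = 0.01)
  ts <- generate_timeseries_cohort(plan0, 4, 4, n_timepoints = 3000, seed = 67)
  fc <- compute_fc(ts$panel)
  mean_abs_z <- mean(vapply(fc, function(m) mean(abs(vectorize_edges(m))),
                            numeric(1)))
  expect_lt(mean_abs_z, 0.05)

  # planted decreased edge: group z-difference near -delta
  plan1 <- effect_plan(n_nodes = 6, decreased_edges = 0L, delta = 0.3,
                       baseline_mean = 0.3, baseline_sd = 0.05,
                       noise_sd = 0.05)
  ts1 <- generate_timeseries_cohort(plan1, 12, 12, n_timepoints = 4000,
                                    seed = 68)
  z1 <- t(vapply(compute_fc(ts1$panel), vectorize_edges,
                 numeric(n_edges_for_nodes(6))))
  diff <- colMeans(z1[ts1$labels == 1, ]) - colMeans(z1[ts1$labels == 0, ])
  # Monte-Carlo se of the group difference is ~0.02 at these sizes
  expect_equal(diff[1], -0.3, tolerance = 0.25)
  expect_equal(mean(abs(diff[-1])), 0, tolerance = 0.05)

  # seeded determinism
  a <- generate_timeseries_cohort(plan1, 3, 3, n_timepoints = 100, seed = 69)
  b <- generate_timeseries_cohort(plan1, 3, 3, n_timepoints = 100, seed = 69)
  expect_identical(a$panel$data, b$panel$data)
})

test_that("correlation repair returns a valid correlation matrix", {
  set.seed(70)
  bad <- tanh(random_symmetric(12, seed = 71) * 0.8)
  diag(bad) <- 1
  fixed <- conncpm:::repair_correlation(bad)
  expect_equal(diag(fixed), rep(1, 12))
  expect_gte(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values),
             1e-7)
  expect_equal(fixed, t(fixed))
})

test_that("atlas construction validates sizes and covers defaults", {
  a <- make_atlas(10, network_sizes = rep(1, 10))
  expect_identical(levels(a$network), canonical_networks())
  expect_identical(nrow(make_atlas(268)), 268L)
  expect_error(make_atlas(10, network_sizes = rep(1, 9)), "sum to 9")
})
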