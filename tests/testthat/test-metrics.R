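make_set <- function(id, pts) {
  probe_set(pts, space = "mni", subject_id = id, modality = "mri")
}

grid_points <- function(offset = c(0, 0, 0)) {
  data.frame(label = c("D1", "D2", "S1", "S2"),
             x = c(0, 30, 0, 30) + offset[1],
             y = c(0, 0, 30, 30) + offset[2],
             z = c(100, 100, 100, 100) + offset[3])
}

test_that("euclidean distance matches hand computations", {
  expect_equal(euclidean(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(euclidean(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_error(euclidean(c(Inf, 0, 0), c(0, 0, 0)))
})

test_that("metric_report bookkeeping invariants hold", {
  d <- data.frame(label = c("D1", "D1", "S1"), group = c("a", "b", "a"),
                  distance = c(1, 3, 5))
  rep <- metric_report("accuracy", "landmark_free", d)
  expect_equal(rep$n_distances, sum(rep$per_label$n))
  expect_equal(rep$pooled_mean, mean(d$distance))
  expect_equal(rep$pooled_sd, sd(d$distance))
  expect_lte(rep$pooled_mean, max(rep$per_label$mean))
  expect_error(metric_report("accuracy", "landmark_free",
                             transform(d, distance = -distance)), ">= 0")
})

test_that("per-subject pooling averages the per-group means", {
  d <- data.frame(label = "D1", group = c("a", "a", "b"),
                  distance = c(1, 3, 8))
  rep <- metric_report("accuracy", "landmark_free", d,
                       pooling = "per_subject")
  expect_equal(rep$pooled_mean, mean(c(2, 8)))
  expect_equal(rep$pooled_sd, sd(c(2, 8)))
})

test_that("cap-fixation variability on trivial cohorts", {
  same <- lapply(c("s1", "s2", "s3"), make_set, pts = grid_points())
  rep <- cap_fixation_variability(same)
  expect_equal(rep$pooled_mean, 0)
  expect_equal(max(rep$per_label$max), 0)

  shifted <- list(make_set("s1", grid_points()),
                  make_set("s2", transform(grid_points(),
                                           z = z + c(10, 0, 0, 0))))
  rep2 <- cap_fixation_variability(shifted)
  d1 <- rep2$per_label[rep2$per_label$label == "D1", ]
  expect_equal(d1$mean, 10)
  expect_equal(d1$max, 10)

  expect_error(cap_fixation_variability(same[1]), ">= 2 subjects")
})

test_that("cap-fixation skips labels present in fewer than 2 subjects", {
  a <- make_set("s1", rbind(grid_points(),
                            data.frame(label = "D9", x = 1, y = 2, z = 3)))
  b <- make_set("s2", grid_points())
  expect_warning(rep <- cap_fixation_variability(list(a, b)), "D9")
  expect_false("D9" %in% rep$per_label$label)
})

test_that("cap-fixation matches the double-loop oracle exactly", {
  coh <- simulate_cohort(cohort_config(seed = 21))
  template <- load_montage("standard_1005")
  aligned <- lapply(coh$subjects, function(s) {
    align(s$mri, template, mode = "landmark_based")$probe_set
  })
  for (method in c("pairwise", "centroid")) {
    rep <- cap_fixation_variability(aligned, method = method)
    oracle <- oracle_cap_fixation(aligned, method = method)
    expect_equal(sort(report_distances(rep)), sort(oracle))
    expect_equal(rep$pooled_mean, mean(oracle))
  }
})

test_that("accuracy is zero for identical or rigidly moved scans", {
  set.seed(201)
  mri <- random_probe_set(n = 10)
  mri$space <- "mri"
  for (mode in c("landmark_based", "landmark_free")) {
    rep <- accuracy(list(mri), mri, mode = mode)
    expect_lt(rep$pooled_mean, 1e-9)
  }
  moved <- apply_transform(
    rigid_transform(random_rotation(), rnorm(3, 0, 20)), mri, "scanner")
  rep2 <- accuracy(list(moved), mri, mode = "landmark_free")
  expect_lt(rep2$pooled_mean, 1e-9)
})

test_that("accuracy and reproducibility match the loop oracles exactly", {
  coh <- simulate_cohort(cohort_config(seed = 22, n_subjects = 2))
  for (mode in c("landmark_based", "landmark_free")) {
    for (s in coh$subjects) {
      acc <- accuracy(s$scans, s$mri, mode = mode)
      expect_equal(sort(report_distances(acc)),
                   sort(oracle_accuracy(s$scans, s$mri, mode)))
      rep <- reproducibility(s$scans, mode = mode)
      expect_equal(sort(report_distances(rep)),
                   sort(oracle_reproducibility(s$scans, mode)))
    }
  }
  expect_error(reproducibility(list(coh$subjects[[1]]$scans[[1]])),
               ">= 2 scans")
})

test_that("reproducibility is zero for identical and rigidly moved scans", {
  set.seed(202)
  s1 <- random_probe_set(n = 8)
  s2 <- apply_transform(rigid_transform(random_rotation(), rnorm(3)),
                        s1, "scanner")
  rep <- reproducibility(list(s1, s1, s2), mode = "landmark_free")
  expect_lt(rep$pooled_mean, 1e-9)
})

test_that("inter-optode distances report chord lengths per channel", {
  ps <- probe_set(data.frame(label = c("S1", "D1"),
                             x = c(0, 30), y = 0, z = 0), space = "scanner")
  ch <- channel_table("S1", "D1")
  rep <- inter_optode_distances(ps, ch)
  expect_equal(rep$pooled_mean, 30)
  expect_equal(rep$per_label$label, "S1-D1")

  expect_error(inter_optode_distances(ps, channel_table("S1", "D9")),
               "D9")
})

test_that("inter-optode report is invariant under rigid motion", {
  set.seed(203)
  layout <- place_optodes(make_head(580), cohort_config())
  rep0 <- inter_optode_distances(layout$probe_set, layout$channels)
  moved <- apply_transform(
    rigid_transform(random_rotation(), rnorm(3, 0, 50)),
    layout$probe_set, "head")
  rep1 <- inter_optode_distances(moved, layout$channels)
  expect_equal(report_distances(rep1), report_distances(rep0),
               tolerance = 1e-9)
  oracle <- oracle_inter_optode(layout$probe_set, layout$channels)
  expect_equal(report_distances(rep0), oracle)
})

test_that("all four analyses are invariant under one common rigid motion", {
  set.seed(204)
  coh <- simulate_cohort(cohort_config(seed = 23, n_subjects = 3))
  t_common <- rigid_transform(random_rotation(), rnorm(3, 0, 40))
  moved <- coh
  moved$subjects <- lapply(coh$subjects, function(s) {
    s$mri <- apply_transform(t_common, s$mri, "mri")
    s$scans <- lapply(s$scans, apply_transform, transform = t_common,
                      new_space = "scanner")
    s
  })
  for (f in list(
    function(c) cohort_cap_fixation(c)$pooled_mean,
    function(c) cohort_accuracy(c, "landmark_based")$pooled_mean,
    function(c) cohort_reproducibility(c, "landmark_free")$pooled_mean,
    function(c) cohort_inter_optode(c, "all")$pooled_mean)) {
    expect_equal(f(moved), f(coh), tolerance = 1e-9)
  }
})

test_that("Welch comparison matches the textbook formula to 1e-12", {
  set.seed(205)
  for (i in 1:10) {
    a <- rnorm(17, 5, 2)
    b <- rnorm(23, 6, 3)
    got <- compare_distances(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    expect_equal(got$test_name, "welch_t")
  }
})

test_that("Welch comparison degenerate and separated cases", {
  x <- c(1, 2, 3, 4)
  same <- compare_distances(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  flat <- compare_distances(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_equal(flat$p_value, 1)

  sep <- compare_distances(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_lt(sep$p_value, 0.001)

  expect_error(compare_distances(1, c(1, 2)), ">= 2")
})
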