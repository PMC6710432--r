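test_that("phantom atlas partitions the mask deterministically", {
  a1 <- build_phantom_atlas(c(32, 32, 32), n_regions = 2, seed = 7)
  lab <- a1$labels[a1$mask != 0]
  expect_setequal(unique(lab), c(1L, 2L))
  expect_true(all(a1$labels[a1$mask == 0] == 0L))
  # every nonzero label appears in the table, regions nonempty
  expect_setequal(unique(lab), a1$label_table$region_id)
  expect_true(all(table(lab) > 0))

  a2 <- build_phantom_atlas(c(32, 32, 32), n_regions = 15, seed = 1)
  a3 <- build_phantom_atlas(c(32, 32, 32), n_regions = 15, seed = 1)
  expect_identical(a2$labels, a3$labels)
  expect_identical(a2$label_table, a3$label_table)
})

test_that("atlas construction rejects impossible requests", {
  expect_error(build_phantom_atlas(c(4, 4, 4), n_regions = 15),
               ">= 16")
  expect_error(build_phantom_atlas(c(16, 16, 16), n_regions = 1),
               "between 2 and 30")
})

test_that("ground-truth pattern assigns regional amplitudes", {
  atlas <- small_atlas()
  tr <- make_ground_truth_pattern(atlas, c("1" = 0.1, "2" = -0.1))
  expect_true(all(tr$map[atlas$labels == 1] == 0.1))
  expect_true(all(tr$map[atlas$labels == 2] == -0.1))
  expect_true(all(tr$map[atlas$labels > 2] == 0))
  expect_identical(tr$values, tr$map[which(atlas$mask != 0)])

  empty <- make_ground_truth_pattern(atlas, numeric(0))
  expect_true(all(empty$map == 0))

  expect_error(make_ground_truth_pattern(atlas, c("99" = 1)),
               "unknown region")
})

test_that("cohort generation is reproducible and validates inputs", {
  atlas <- small_atlas()
  truth <- make_ground_truth_pattern(atlas, small_effects())
  c1 <- generate_cohort(atlas, truth, seed = 5)
  c2 <- generate_cohort(atlas, truth, seed = 5)
  expect_identical(c1$images, c2$images)
  expect_identical(c1$meta, c2$meta)
  expect_equal(nrow(c1$meta), 18 * 5)
  expect_true(all(c1$meta$motor_score >= 0 & c1$meta$motor_score <= 100))

  expect_error(generate_cohort(atlas, truth, n_pd = 0), ">= 1")
  expect_error(generate_cohort(atlas, truth, voxel_noise_sd = -1),
               "positive")
  expect_error(generate_cohort(atlas, truth,
                               schedule = c(baseline = 0.5, w3 = 0.5,
                                            w4 = 0.6, w6 = 0.9, w9 = 1)),
               "start at 0")
  expect_error(generate_cohort(atlas, truth,
                               schedule = c(baseline = 0, w3 = 0.5,
                                            w4 = 0.4, w6 = 0.9, w9 = 1)),
               "non-decreasing")
})

test_that("planted signal direction shows in regional group means", {
  # Monte-Carlo check of the generative formula: at full effect and low
  # noise, PD mean uptake exceeds control mean in a +0.1 region and is
  # lower in a -0.1 region, for every seed tried
  atlas <- small_atlas()
  truth <- make_ground_truth_pattern(atlas, small_effects())
  pos_vox <- which(atlas$labels == 1)   # +0.1 region
  neg_vox <- which(atlas$labels == 4)   # -0.1 region
  for (seed in 1:8) {
    coh <- generate_cohort(atlas, truth, timepoints = "w9",
                           voxel_noise_sd = 1, seed = seed)
    pd <- coh$meta$group == "PD"
    # uptake normalized per scan by its mask mean (removes subject scale)
    reg_mean <- function(keys, vox) {
      vapply(keys, function(k) {
        img <- coh$images[[k]]
        mean(img[vox]) / mean(img[coh$mask != 0])
      }, numeric(1))
    }
    expect_gt(mean(reg_mean(coh$meta$image[pd], pos_vox)),
              mean(reg_mean(coh$meta$image[!pd], pos_vox)))
    expect_lt(mean(reg_mean(coh$meta$image[pd], neg_vox)),
              mean(reg_mean(coh$meta$image[!pd], neg_vox)))
  }
})

test_that("zero-amplitude cohorts carry no group signal in a region mean", {
  atlas <- small_atlas()
  null_truth <- make_ground_truth_pattern(atlas, numeric(0))
  pvals <- vapply(1:60, function(seed) {
    coh <- generate_cohort(atlas, null_truth, timepoints = "w9",
                           seed = seed)
    pd <- coh$meta$group == "PD"
    vox <- which(atlas$labels == 2)
    vals <- vapply(coh$meta$image, function(k) {
      img <- coh$images[[k]]
      mean(img[vox]) / mean(img[coh$mask != 0])
    }, numeric(1))
    stats::t.test(vals[pd], vals[!pd])$p.value
  }, numeric(1))
  # nominal-rate check with a tolerant binomial band for 60 draws
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.35)   # roughly uniform p-values
  expect_lt(mean(pvals), 0.65)
})

test_that("cohort round-trips through NIfTI + tables on disk", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$meta$subject_id, coh$meta$subject_id)
  expect_equal(back$meta$motor_score, coh$meta$motor_score,
               tolerance = 1e-6)
  key <- coh$meta$image[1]
  expect_equal(back$images[[key]], coh$images[[key]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$atlas$label_table$region_name,
               coh$atlas$label_table$region_name)
})
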