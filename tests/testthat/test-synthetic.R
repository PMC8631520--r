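test_that("lesion generation is bit-reproducible from its spec", {
  sp <- lesion_spec(class_label = "malignant", cyst = "irregular", seed = 77)
  l1 <- generate_lesion(sp)
  l2 <- generate_lesion(sp)
  expect_identical(l1$volume$voxels, l2$volume$voxels)
  expect_identical(l1$volume$mask, l2$volume$mask)
  l3 <- generate_lesion(lesion_spec(class_label = "malignant",
                                    cyst = "irregular", seed = 78))
  expect_false(identical(l1$volume$voxels, l3$volume$voxels))
})

test_that("lesion specs validate geometry", {
  expect_error(lesion_spec(semi_axes = c(1, 8, 6)), "semi-axes")
  expect_error(lesion_spec(corr_length = 0), "correlation length")
  expect_error(lesion_spec(cyst = "regular", cyst_radius_frac = 0.9), "cyst")
})

test_that("cyst voxels lie strictly inside the lesion and are dark", {
  for (kind in c("regular", "irregular")) {
    l <- generate_lesion(lesion_spec(cyst = kind, cyst_radius_frac = 0.5,
                                     seed = 5))
    vm <- l$volume
    expect_gt(l$truth$cyst_voxels, 0)
    # zero-enhancement: the darkest voxels sit far below the tissue level
    expect_lt(sort(vm$voxels[vm$mask])[l$truth$cyst_voxels %/% 2],
              l$truth$base_mean / 2)
  }
})

test_that("default cohort mirrors the study composition", {
  coh <- generate_cohort(cohort_spec(seed = 1))
  expect_length(coh$lesions, 47)
  expect_equal(sum(coh$labels == 0), 26)
  expect_equal(sum(coh$labels == 1), 21)
  # findings wall column agrees with the generated cyst geometry
  truth_wall <- vapply(coh$truth, function(t)
    if (t$cyst == "none") "none"
    else if (t$wall_irregular) "irregular" else "regular", character(1))
  expect_identical(coh$findings$cyst_wall, unname(truth_wall))
})

test_that("cohorts are reproducible from the master seed and differ across seeds", {
  c1 <- generate_cohort(cohort_spec(n_benign = 3, n_malignant = 3, seed = 9))
  c2 <- generate_cohort(cohort_spec(n_benign = 3, n_malignant = 3, seed = 9))
  c3 <- generate_cohort(cohort_spec(n_benign = 3, n_malignant = 3, seed = 10))
  expect_identical(c1$lesions[[1]]$volume$voxels, c2$lesions[[1]]$volume$voxels)
  expect_identical(c1$findings, c2$findings)
  expect_false(identical(c1$lesions[[1]]$volume$voxels,
                         c3$lesions[[1]]$volume$voxels))
})

test_that("cohort export writes volumes, labels, findings and truth", {
  td <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n_benign = 2, n_malignant = 2, seed = 4),
                         out_dir = td)
  expect_length(list.files(td, pattern = "_vol\\.nii\\.gz$"), 4)
  labs <- read.csv(file.path(td, "labels.csv"))
  expect_equal(labs$label, coh$labels)
  back <- load_volume_mask(file.path(td, "lesion_001_vol.nii.gz"),
                           file.path(td, "lesion_001_mask.nii.gz"))
  expect_identical(back$mask, coh$lesions[[1]]$volume$mask)
})

test_that("class contrasts point the planted directions", {
  coh <- generate_cohort(cohort_spec(n_benign = 20, n_malignant = 20, seed = 11))
  tab <- extract_cohort(lapply(coh$lesions, `[[`, "volume"), coh$labels)
  p_greater <- function(nm, hi_class) {
    hi <- tab[[nm]][tab$label == hi_class]
    lo <- tab[[nm]][tab$label != hi_class]
    wilcox.test(hi, lo, alternative = "greater", exact = FALSE)$p.value
  }
  # benign-like lesions have the higher mean level, spread and upper tail
  expect_lt(p_greater("Mean", 0), 0.05)
  expect_lt(p_greater("Variance", 0), 0.05)
  expect_lt(p_greater("Perc.90%", 0), 0.05)
  # malignant-like lesions have the higher run-length non-uniformity
  expect_lt(p_greater("Z_GLevNonU", 1), 0.05)
  expect_lt(p_greater("45dgr_GLevNonU", 1), 0.05)
})
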