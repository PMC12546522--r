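test_that("discretization covers both policies and the constant case", {
  vox <- array(c(0, 1, 2, 3, 0, 1, 2, 3), c(2, 2, 2))
  img <- image_volume(vox, masks = list(roi = array(TRUE, c(2, 2, 2))))
  d <- discretize(img, n_bins = 2)
  expect_equal(sort(unique(d$levels[!is.na(d$levels)])), c(1L, 2L))
  expect_equal(as.integer(d$levels[1:4]), c(1L, 1L, 2L, 2L))

  const <- image_volume(array(7, c(2, 2, 1)),
                        masks = list(roi = array(TRUE, c(2, 2, 1))))
  dc <- discretize(const)
  expect_equal(dc$ng_effective, 1L)
  expect_true(all(dc$levels == 1L))

  dw <- discretize(img, policy = "fixed_bin_width", bin_width = 1)
  expect_equal(max(dw$levels, na.rm = TRUE), 4L)
  expect_error(discretize(img, policy = "fixed_bin_width", bin_width = 0),
               "positive")

  # roughly uniform histogram for uniform input
  set.seed(1)
  big <- image_volume(array(runif(4000), c(20, 20, 10)),
                      masks = list(roi = array(TRUE, c(20, 20, 10))))
  db <- discretize(big, n_bins = 32)
  h <- tabulate(db$levels[!is.na(db$levels)], 32)
  expect_gt(stats::chisq.test(h)$p.value, 1e-4)
})

test_that("first-order features match closed forms and Total Energy relation", {
  img <- image_volume(array(5, c(2, 2, 2)), spacing = c(1, 1, 2),
                      masks = list(roi = array(TRUE, c(2, 2, 2))))
  fo <- first_order(img)
  expect_equal(fo[c("Mean", "Minimum", "RMS", "Energy")],
               list(Mean = 5, Minimum = 5, RMS = 5, Energy = 200))
  expect_equal(fo$`Total Energy`, 2 * fo$Energy)

  pm <- image_volume(array(c(-1, 1), c(2, 1, 1)),
                     masks = list(roi = array(TRUE, c(2, 1, 1))))
  fpm <- first_order(pm)
  expect_equal(fpm$Mean, 0)
  expect_equal(fpm$RMS, 1)
  expect_equal(fpm$Energy, 2)

  # shift c enters before squaring
  expect_equal(first_order(pm, shift = 1)$Energy, 4)

  # random ROI: equals direct recomputation
  set.seed(3)
  vox <- array(rnorm(60), c(5, 4, 3))
  mask <- array(runif(60) < 0.7, c(5, 4, 3)); mask[1] <- TRUE
  ri <- image_volume(vox, spacing = c(0.5, 0.5, 2), masks = list(roi = mask))
  fr <- first_order(ri)
  x <- vox[mask]
  expect_equal(fr$Energy, sum(x^2))
  expect_equal(fr$`Total Energy`, 0.5 * sum(x^2))
  expect_equal(fr$RMS, sqrt(mean(x^2)))
})

test_that("texture families match brute-force oracles on random ROIs", {
  for (seed in 1:3) {
    shape <- list(c(4, 4, 2), c(6, 5, 3), c(10, 10, 5))[[seed]]
    ng <- c(4, 3, 5)[seed]
    d <- random_test_roi(shape, ng, seed)
    glcm <- glcm_features(d)
    oc <- oracle_glcm(d$levels, d$ng)
    for (nm in names(oc)) expect_equal(glcm[[nm]], oc[[nm]], tolerance = 1e-10)

    expect_equal(glrlm_features(d), oracle_glrlm(d$levels), tolerance = 1e-10)
    expect_equal(glszm_features(d), oracle_glszm(d$levels), tolerance = 1e-10)
    expect_equal(gldm_features(d), oracle_gldm(d$levels), tolerance = 1e-10)
    expect_equal(ngtdm_features(d), oracle_ngtdm(d$levels, d$ng),
                 tolerance = 1e-10)
  }
  # nonzero GLDM alpha
  d <- random_test_roi(c(6, 6, 3), 5, 9)
  expect_equal(gldm_features(d, alpha = 1), oracle_gldm(d$levels, alpha = 1),
               tolerance = 1e-10)
})

test_that("degenerate ROIs take the documented sentinel values", {
  const <- image_volume(array(4, c(3, 3, 3)),
                        masks = list(roi = array(TRUE, c(3, 3, 3))))
  d <- discretize(const)
  glcm <- glcm_features(d)
  expect_equal(glcm[c("Contrast", "DifferenceAverage", "DifferenceVariance",
                      "ClusterShade", "ClusterProminence")],
               list(Contrast = 0, DifferenceAverage = 0,
                    DifferenceVariance = 0, ClusterShade = 0,
                    ClusterProminence = 0))
  szm <- glszm_features(d)
  expect_equal(szm[c("SZN", "GLN", "GLV")], list(SZN = 1, GLN = 1, GLV = 0))
  ng <- ngtdm_features(d)
  expect_equal(ng, list(Coarseness = 1e6, Complexity = 0, Strength = 0))

  # single-voxel ROI: no pairs -> GLCM zero & flagged; GLDM j = 1
  single <- image_volume(array(1:27 * 1.0, c(3, 3, 3)),
                         masks = list(roi = array(c(TRUE, rep(FALSE, 26)),
                                                  c(3, 3, 3))))
  ds <- discretize(single, n_bins = 4)
  gs <- glcm_features(ds)
  expect_true(gs$flagged)
  expect_equal(gs$Contrast, 0)
  gd <- gldm_features(ds)
  expect_equal(gd[c("DN", "DNN")], list(DN = 1, DNN = 1))
  expect_equal(gd$HGLE, 1)    # its level is 1
})

test_that("hand-enumerated examples hold", {
  # 1-D row [1, 1, 2]: runs {(1,2),(2,1)} along the row axis
  img <- image_volume(array(c(1, 1, 2), c(3, 1, 1)),
                      masks = list(roi = array(TRUE, c(3, 1, 1))))
  d <- discretize(img, policy = "fixed_bin_width", bin_width = 1)
  runs <- aneuhemo:::enumerate_runs(d$levels, c(1L, 0L, 0L))
  expect_equal(runs[order(runs[, 1]), ], cbind(c(1L, 2L), c(2L, 1L)),
               ignore_attr = TRUE)
  nr <- 2
  expect_equal(sum(c(1, 1)^2) / nr, 1)                    # GLN along that axis
  expect_equal((1^2 * 1 + 2^2 * 1) / nr, 2.5)             # HGLRE along axis

  # constant 1-D row of length L: single run, RLN = 1, LRHGLE = L^2 (per axis)
  L <- 6
  rowc <- image_volume(array(2, c(L, 1, 1)),
                       masks = list(roi = array(TRUE, c(L, 1, 1))))
  dc <- discretize(rowc)
  runsc <- aneuhemo:::enumerate_runs(dc$levels, c(1L, 0L, 0L))
  expect_equal(nrow(runsc), 1)
  expect_equal(unname(runsc[1, 2]), L)

  # two disjoint single-voxel zones of levels 1 and 3 -> GLV = 1
  vox <- array(0, c(3, 1, 1)); vox[1] <- 1; vox[3] <- 3
  mask <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
  zi <- image_volume(vox, masks = list(roi = mask))
  dz <- discretize(zi, policy = "fixed_bin_width", bin_width = 1)
  expect_equal(sort(unique(dz$levels[mask])), c(1L, 3L))
  expect_equal(glszm_features(dz)$GLV, 1)

  # strict 2-level checkerboard: per-axis GLCM Contrast 1, DA 1, DV 0
  ck <- make_texture_image(c(4, 4, 4), "checkerboard")$image
  dk <- discretize(ck, n_bins = 2)
  for (ax in list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))) {
    pr <- aneuhemo:::offset_pairs(dk$levels, ax)
    expect_true(all(abs(pr$a - pr$b) == 1))
  }
  expect_equal(ngtdm_features(dk), oracle_ngtdm(dk$levels, dk$ng),
               tolerance = 1e-10)
})

test_that("feature vectors are complete, deterministic and order-invariant", {
  g <- make_texture_image(c(8, 8, 6), "gaussian_random_field", seed = 21,
                          masks = list(
                            wall_free_of_IST = array(c(TRUE, FALSE), c(8, 8, 6)),
                            wall_next_to_IST = array(c(FALSE, TRUE), c(8, 8, 6))))
  fv <- extract_feature_vector(g$image, n_bins = 8)
  expect_setequal(names(fv), c("wall_free_of_IST", "wall_next_to_IST", "meta"))
  expect_equal(names(fv$wall_free_of_IST), names(fv$wall_next_to_IST))
  expect_length(fv$wall_free_of_IST, 28)
  expect_true(all(is.finite(fv$wall_free_of_IST)))

  # identical ROIs give identical vectors
  g2 <- make_texture_image(c(6, 6, 4), "gaussian_random_field", seed = 4,
                           masks = list(wall_free_of_IST = array(TRUE, c(6, 6, 4)),
                                        wall_next_to_IST = array(TRUE, c(6, 6, 4))))
  fv2 <- extract_feature_vector(g2$image, n_bins = 8)
  expect_equal(fv2$wall_free_of_IST, fv2$wall_next_to_IST)

  expect_error(extract_feature_vector(g2$image, rois = "nope"), "missing ROI")

  # axis permutation of the volume leaves every texture feature unchanged
  img <- g2$image
  perm <- image_volume(aperm(img$voxels, c(3, 1, 2)),
                       img$spacing[c(3, 1, 2)],
                       list(wall_free_of_IST = aperm(img$masks[[1]], c(3, 1, 2)),
                            wall_next_to_IST = aperm(img$masks[[2]], c(3, 1, 2))))
  fvp <- extract_feature_vector(perm, n_bins = 8)
  expect_equal(fvp$wall_free_of_IST, fv2$wall_free_of_IST, tolerance = 1e-12)
})
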