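test_that("marker point rules and boundaries are exact", {
  pts <- marker_points(make_results())
  expect_equal(unname(pts[c("CD5", "CD23", "FMC7", "CD79b", "sIgM", "CD200")]),
               rep(1L, 6))
  # 30% boundary: inclusive for CD5/CD23/CD200, strict for FMC7/CD79b
  pts_b <- marker_points(make_results(cd5 = 30, cd23 = 30, cd200 = 30,
                                      fmc7 = 30, cd79b = 30))
  expect_equal(unname(pts_b[c("CD5", "CD23", "CD200")]), rep(1L, 3))
  expect_equal(unname(pts_b[c("FMC7", "CD79b")]), rep(0L, 2))
  expect_equal(unname(pts_b[c("FMC7", "CD79b")]),
               unname(marker_points(make_results(fmc7 = 29.99, cd79b = 29.99))[c("FMC7", "CD79b")] - 1L))
  # sIgM scores on the pattern class, not the percent
  expect_equal(unname(marker_points(make_results(sigm_pattern = "moderate"))["sIgM"]), 0L)
  expect_error(marker_points(make_results()[-1, ]), "CD5")
})

test_that("CD200 can be scored by MFIR in the optional mode", {
  res <- make_results(cd200 = 10, cd200_mfir = 25)
  expect_equal(unname(marker_points(res)["CD200"]), 0L)
  expect_equal(unname(marker_points(res, cd200_mode = "mfir")["CD200"]), 1L)
  # MFIR threshold of 18 is inclusive
  expect_equal(unname(marker_points(make_results(cd200_mfir = 18),
                                    cd200_mode = "mfir")["CD200"]), 1L)
})

test_that("the three scores sum their point sets", {
  pts <- c(CD5 = 1L, CD23 = 1L, FMC7 = 0L, CD79b = 0L, sIgM = 1L, CD200 = 1L)
  expect_equal(classical_score(pts), 3L)          # the atypical-CLL pattern
  expect_equal(cd200_augmented_score(pts), 4L)
  expect_equal(four_marker_score(pts), 4L)
  all1 <- setNames(rep(1L, 6), names(pts))
  expect_equal(classical_score(all1), 5L)
  expect_equal(cd200_augmented_score(all1), 6L)
  all0 <- setNames(rep(0L, 6), names(pts))
  expect_equal(classical_score(all0), 0L)
  expect_equal(cd200_augmented_score(setNames(c(1L,1L,0L,0L,0L,0L), names(pts))), 2L)
  expect_error(classical_score(pts[-1]), "missing")
})

test_that("classification thresholds and ranges are enforced", {
  expect_equal(classify_sample(c(6, 4, 3, 2, 0), "augmented"),
               c("typical-CLL", "typical-CLL", "atypical-CLL", "non-CLL", "non-CLL"))
  expect_equal(classify_sample(4, "four_marker"), "typical-CLL")
  expect_error(classify_sample(6, "classical"), "out of range")
  expect_error(classify_sample(-1, "augmented"), "out of range")
})

test_that("adding the CD200 point is monotone and bounded", {
  set.seed(99)
  for (i in 1:200) {
    pts <- setNames(as.integer(rbinom(6, 1, 0.5)),
                    c("CD5", "CD23", "FMC7", "CD79b", "sIgM", "CD200"))
    cs <- classical_score(pts)
    as <- cd200_augmented_score(pts)
    expect_true((as - cs) %in% c(0L, 1L))
    expect_gte(as, cs)
    # a CLL call under the classical screen is never lost by augmentation
    if (cs >= 4) expect_gte(as, 4L)
  }
})

test_that("score_cohort reproduces the designed cohort histograms", {
  # moderate-size designed cohort covering every card
  d <- cohort_design()
  reps <- d[!duplicated(d$card_id), ]
  res <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
    sim <- simulate_sample(reps[i, ], master_seed = 5,
                           n_events = 4000, n_isotype = 1500)
    suppressWarnings(analyze_sample(sim$events, sim$isotype,
                                    sample_id = reps$sample_id[i]))
  })
  sc <- score_cohort(res)
  sc <- dplyr::left_join(sc, reps[, c("sample_id", "card_id", "pt_CD5", "pt_CD23",
                                      "pt_FMC7", "pt_CD79b", "pt_sIgM", "pt_CD200")],
                         by = "sample_id")
  # every measured point equals the card's designed point
  expect_equal(sc$pt_CD5.x, sc$pt_CD5.y)
  expect_equal(sc$pt_CD23.x, sc$pt_CD23.y)
  expect_equal(sc$pt_FMC7.x, sc$pt_FMC7.y)
  expect_equal(sc$pt_CD79b.x, sc$pt_CD79b.y)
  expect_equal(sc$pt_sIgM.x, sc$pt_sIgM.y)
  expect_equal(sc$pt_CD200.x, sc$pt_CD200.y)
  expect_equal(sc$augmented_score - sc$classical_score, sc$pt_CD200.y)
})
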