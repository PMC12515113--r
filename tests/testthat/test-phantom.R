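test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(cl3_reduction_mm = 5, cl5_reduction_mm = 4),
               "cl5_reduction_mm > cl3_reduction_mm")
  expect_error(phantom_spec(ridge_height_mm = 6, cl5_reduction_mm = 8),
               "ridge_height_mm")
  sp <- phantom_spec(dentition_status = "edentulous", tooth_count = 10L)
  expect_equal(sp$tooth_count, 0L)
})

test_that("same seed gives bit-identical phantoms", {
  a <- make_phantom(phantom_spec(seed = 77, dentition_status = "partial"))
  b <- make_phantom(phantom_spec(seed = 77, dentition_status = "partial"))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$gt_original$data, b$gt_original$data)
  expect_identical(a$gt_cl3$data, b$gt_cl3$data)
  expect_identical(a$present_teeth, b$present_teeth)
})

test_that("atrophy variants are nested and differ only in the ridge band", {
  for (ph in list(phantom_full(), phantom_partial())) {
    o <- ph$gt_original$data; c3 <- ph$gt_cl3$data; c5 <- ph$gt_cl5$data
    expect_true(all(c5 <= c3))
    expect_true(all(c3 <= o))
    expect_lt(sum(c5), sum(c3))       # monotone atrophy, strictly
    expect_lt(sum(c3), sum(o))
    # identical outside the alveolar band: everything at or below the
    # basal body top is untouched (caudolateral region immutability)
    zs <- ph$gt_original$origin[3] +
      (seq_len(dim(o)[3]) - 1) * ph$gt_original$spacing[3]
    low <- zs <= ph$spec$body_height_mm / 2
    expect_identical(o[, , low], c5[, , low])
    expect_identical(o[, , low], c3[, , low])
  }
})

test_that("edentulous originals change only marginally toward Class III", {
  ph <- phantom_edentulous()
  diff_frac <- sum(xor(ph$gt_original$data == 1, ph$gt_cl3$data == 1)) /
    sum(ph$gt_original$data)
  expect_lt(diff_frac, 0.02)
})

test_that("removed ridge volume matches the analytic slab within 10%", {
  ph <- phantom_edentulous()  # no teeth, so the O-to-Cl.V difference is pure
  spec <- ph$spec             # ridge slab
  removed_vox <- (sum(ph$gt_original$data) - sum(ph$gt_cl5$data)) *
    prod(spec$spacing_mm)
  # analytic: ridge band cross-section (half-width ar) lowered from
  # (crest - 0.8 cl3) to (crest - cl5) along the banded part of the arch
  g <- mandseg:::phantom_geom(spec)
  al <- mandseg:::arch_arclen(spec)
  band_len <- diff(stats::approx(al$t, al$s, xout = g$ridge_t)$y)
  depth <- spec$cl5_reduction_mm - 0.8 * spec$cl3_reduction_mm
  # the removed column height is constant across the band (crest rounding
  # cancels between the two variants), so the slab is a simple prism
  analytic <- band_len * 2 * g$ar * depth
  expect_lt(abs(removed_vox - analytic) / analytic, 0.10)
})

test_that("cohort status counts follow the rounding rule and are reproducible", {
  co <- make_cohort(10, status_fractions = c(0.2, 0.6, 0.2), seed = 9,
                    include_distractors = FALSE)
  expect_equal(as.integer(table(co$metadata$status)[c("full", "partial",
                                                      "edentulous")]),
               c(2L, 6L, 2L))
  co2 <- make_cohort(10, status_fractions = c(0.2, 0.6, 0.2), seed = 9,
                     include_distractors = FALSE)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$cases[[1]]$image$data, co2$cases[[1]]$image$data)
  expect_error(make_cohort(2, status_fractions = c(0.34, 0.33, 0.33)),
               "too small")
})

test_that("cohort spec ranges are honored", {
  rng <- list(cl5_reduction_mm = c(7.5, 8.0), arch_width_mm = c(90, 91))
  co <- make_cohort(6, spec_ranges = rng, seed = 4,
                    include_distractors = FALSE)
  expect_true(all(co$metadata$cl5_reduction_mm >= 7.5 &
                    co$metadata$cl5_reduction_mm <= 8.0))
  expect_true(all(co$metadata$arch_width_mm >= 90 &
                    co$metadata$arch_width_mm <= 91))
})

test_that("analytic curves expose the expected dental gap", {
  ph <- phantom_full()
  ac <- ph$analytic_curves
  expect_s3_class(ac$caudolateral, "CurvePolyline")
  expect_s3_class(ac$dental_original, "CurvePolyline")
  # the O dental curve rides on tooth cusps, the Cl.V curve on the reduced
  # crest: the mean gap must exceed the crest reduction and stay below
  # reduction + tooth height
  expect_gt(ac$dental_gap_o_cl5_mm, ph$spec$cl5_reduction_mm)
  expect_lt(ac$dental_gap_o_cl5_mm,
            ph$spec$cl5_reduction_mm + ph$spec$tooth_height_mm)
  expect_gt(ac$dental_gap_o_cl5_mm, ac$dental_gap_o_cl3_mm)
})
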