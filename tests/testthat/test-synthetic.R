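test_that("prototype presets plant the documented copy-number geometry", {
  expect_length(core_prototypes(), 6)

  non <- generate_point_set(core_spec("NON_DELETION", seed = 1,
                                      signal_loss_prob = 0,
                                      colocalization_prob = 0))
  expect_equal(non$expected_global_ratio, 1)
  realized <- non$regions$realized_ratio[1]
  n_ch <- non$regions$cep_count[1]
  expect_lt(abs(realized - 1), 3 * sqrt(2 / n_ch))   # within 3 SE

  hemi <- generate_point_set(core_spec("HEMIZYGOUS_DELETION", seed = 2))
  expect_equal(hemi$expected_global_ratio, 0.5)

  ith <- generate_point_set(core_spec("INTRATUMOUR_HET", seed = 3))
  expect_equal(nrow(ith$regions), 2)
  expect_gt(ith$regions$realized_ratio[1], 0.8)   # left: two copies
  expect_lt(ith$regions$realized_ratio[2], 0.1)   # right: zero copies

  homo <- generate_point_set(core_spec("HOMOZYGOUS_DELETION", seed = 4))
  expect_lt(homo$expected_global_ratio, 0.6)
  expect_gt(homo$regions$realized_ratio[2], 0.7)  # benign rim retains signal
})

test_that("expected ratio is independent of equal-channel loss", {
  # analytic: the ratio conditional on cell placement has no loss term;
  # simulation: realized ratios at different loss levels agree in expectation
  for (loss in c(0, 0.15, 0.3)) {
    tr <- generate_point_set(core_spec("HEMIZYGOUS_DELETION", seed = 10,
                                       signal_loss_prob = loss))
    expect_equal(tr$expected_global_ratio, 0.5)
  }
  ratios <- vapply(1:8, function(s) {
    tr <- generate_point_set(core_spec("HEMIZYGOUS_DELETION", seed = 50 + s,
                                       signal_loss_prob = 0.3,
                                       colocalization_prob = 0))
    tr$regions$realized_ratio[1]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.04)
})

test_that("generation is deterministic and densities sit in the expected band", {
  a <- generate_point_set(core_spec("INTRATUMOUR_HET", seed = 9))
  b <- generate_point_set(core_spec("INTRATUMOUR_HET", seed = 9))
  expect_identical(a, b)

  for (proto in core_prototypes()) {
    n <- nrow(generate_point_set(core_spec(proto, seed = 77))$points)
    expect_gte(n, 1000)
    expect_lte(n, 5000)
  }

  expect_error(generate_point_set(core_spec("NON_DELETION", image_size = 256,
                                            n_cells = 5000)),
               class = "dq_data_error")   # infeasible packing
  expect_error(core_spec("NON_DELETION", signal_loss_prob = 1.2),
               class = "dq_param_error")
})

test_that("rendering is pixel-deterministic and draws the planted palette", {
  spec <- core_spec("NON_DELETION", image_size = 512, seed = 31)
  truth <- generate_point_set(spec)
  img1 <- render_core(truth, spec)
  img2 <- render_core(truth, spec)
  expect_identical(img1$pixels, img2$pixels)

  # planted colours: gene dots dark, CEP dots red-dominant at their centres
  px <- as_numeric_array(img1)
  genes <- truth$points[truth$points$true_label == "GENE", ]
  ceps <- truth$points[truth$points$true_label == "CEP", ]
  gl <- px[cbind(round(genes$y) + 1, round(genes$x) + 1, 1)]
  expect_lt(mean(gl), 0.3)
  cr <- px[cbind(round(ceps$y) + 1, round(ceps$x) + 1, 1)]
  cg <- px[cbind(round(ceps$y) + 1, round(ceps$x) + 1, 2)]
  expect_gt(mean(cr - cg), 0.3)

  # a zero-signal spec renders background only: detection stays near-silent
  empty_spec <- core_spec("NON_DELETION", image_size = 512, n_cells = 10,
                          noise_density = 0, stain_density = 0, seed = 5,
                          signal_loss_prob = 1)
  etruth <- generate_point_set(empty_spec)
  expect_equal(nrow(etruth$points), 0)
  eimg <- render_core(etruth, empty_spec)
  expect_lte(nrow(detect_signals(eimg, etruth$mask)), 5)
})

test_that("slides stitch cores with globally consistent truth", {
  specs <- lapply(1:4, function(i) {
    core_spec("NON_DELETION", image_size = 512, seed = 60 + i)
  })
  slide <- generate_slide(specs)
  expect_equal(dim(slide$image$pixels)[1:2], c(1024, 1024))
  expect_equal(nrow(slide$cores), 4)

  # single-region slide equals the core rendered at the origin
  one <- generate_slide(specs[1], grid_dim = c(1, 1))
  tr <- generate_point_set(specs[[1]])
  expect_identical(one$image$pixels, render_core(tr, specs[[1]])$pixels)
  expect_equal(one$points$x, tr$points$x)

  # per-core truth offsets: all points of core 4 live in its quadrant
  p4 <- slide$points[slide$points$core_id == 4, ]
  expect_true(all(p4$x >= 512 & p4$y >= 512))
})

test_that("training sets are balanced with labels matching rendered colours", {
  ts <- generate_training_set(crops_per_class = 12, seed = 3, specs = list(
    core_spec("NON_DELETION", image_size = 2048, n_cells = 220,
              colocalization_prob = 0.45, stain_density = 6e-5, seed = 91),
    core_spec("NON_DELETION", image_size = 2048, n_cells = 220,
              colocalization_prob = 0.45, stain_density = 6e-5, seed = 92)))
  expect_s3_class(ts, "ish_training_set")
  expect_equal(as.integer(table(ts$annotations$label)), rep(12L, 5))

  # crop pixels agree with the annotated class for gene vs CEP
  ann <- ts$annotations
  img <- ts$images[[1]]
  px <- as_numeric_array(img)
  pick <- function(lab) {
    r <- ann[ann$label == lab & ann$image == "core1", ]
    cbind(round(r$y) + 1, round(r$x) + 1)
  }
  g <- pick("GENE"); c_ <- pick("CEP")
  expect_lt(mean(px[cbind(g, 1)]), 0.35)                      # dark
  expect_gt(mean(px[cbind(c_, 1)] - px[cbind(c_, 2)]), 0.25)  # red excess

  expect_error(generate_training_set(crops_per_class = 5),
               class = "dq_param_error")
  expect_error(
    generate_training_set(crops_per_class = 500, seed = 1, specs = list(
      core_spec("NON_DELETION", image_size = 512, seed = 1))),
    class = "dq_data_error")   # classes unreachable at this size
})

test_that("cohort specs mix prototypes with per-core variation", {
  ch <- cohort_specs(2, seed = 5)
  expect_length(ch$specs, 12)
  expect_equal(nrow(ch$info), 12)
  expect_setequal(unique(ch$info$prototype), core_prototypes())
  # deterministic
  ch2 <- cohort_specs(2, seed = 5)
  expect_identical(ch$info, ch2$info)
  expect_identical(ch$specs[[7]], ch2$specs[[7]])
})
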