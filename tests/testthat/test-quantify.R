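test_that("degenerate nuclear channels yield no nuclei", {
  expect_warning(seg <- segment_nuclei(matrix(0, 64, 64)), "all-constant")
  expect_equal(nrow(seg), 0)
  expect_warning(seg2 <- segment_nuclei(matrix(777, 64, 64)), "all-constant")
  expect_equal(nrow(seg2), 0)
})

test_that("planted nuclei are recovered with accurate centroids", {
  cfg <- sim_config(seed = 2, image_size = c(200, 200), noise_sd = 0)
  set.seed(7)
  x <- c(30, 80, 130, 170, 30, 80, 130, 170, 55, 105) + runif(10, -0.3, 0.3)
  y <- rep(c(50, 150), each = 4)[c(1:8, 1, 2)] + c(rep(0, 8), 50, 50) +
    runif(10, -0.3, 0.3)
  truth <- make_truth(x, y, n_droplets = rep(0L, 10))
  img <- render_well_image(truth, cfg)
  seg <- segment_nuclei(img$channels$nuclear)
  expect_equal(nrow(seg), 10)
  # match each planted cell to its nearest recovered centroid
  d <- sqrt(outer(y, seg$centroid_row, "-")^2 +
              outer(x, seg$centroid_col, "-")^2)
  expect_true(all(apply(d, 1, min) < 2))
  # area filter removes everything when min_area exceeds the spot size
  seg_big <- segment_nuclei(img$channels$nuclear, min_area = 10000)
  expect_equal(nrow(seg_big), 0)
})

test_that("fixed thresholding and 8-connectivity behave as documented", {
  img <- matrix(0, 20, 20)
  img[5:8, 5:8] <- 100          # blob A
  img[9:12, 9:12] <- 100        # blob B, touching A only diagonally
  seg <- segment_nuclei(img, sigma = 0, threshold_method = "fixed",
                        threshold_value = 50, min_area = 1)
  expect_equal(nrow(seg), 1)    # 8-connected: one object
  expect_equal(seg$area_px, 32)
  expect_error(segment_nuclei(img, threshold_method = "fixed"),
               "threshold_value")
})

test_that("positivity threshold calibration follows median + k * MAD", {
  expect_equal(calibrate_positivity_threshold(c(90, 95, 100, 105, 110),
                                              k = 3, min_cells = 5), 115)
  expect_warning(
    tau <- calibrate_positivity_threshold(rep(100, 60), k = 3),
    "MAD.*0")
  expect_equal(tau, 100)
  expect_equal(
    calibrate_positivity_threshold(c(1, 2, 3, 4, 100), k = 0, min_cells = 5),
    3)
  expect_error(calibrate_positivity_threshold(1:10), "10")
})

test_that("a noise-free well quantifies to its planted composition", {
  cfg <- sim_config(seed = 3, image_size = c(200, 200), noise_sd = 0)
  set.seed(13)
  x <- c(30, 80, 130, 170, 30, 80, 130, 170, 55, 105) + runif(10, -0.3, 0.3)
  y <- c(rep(50, 4), rep(150, 4), 100, 100) + runif(10, -0.3, 0.3)
  truth <- make_truth(x, y, n_droplets = c(rep(3L, 4), rep(0L, 6)))
  img <- render_well_image(truth, cfg)
  q <- quantify_well(img, tau = cfg$background_level, role = "compound",
                     compound_id = "CX")
  expect_equal(q$total_cells, 10)
  expect_equal(q$positive_cells, 4)
  expect_equal(q$percent_positive, 40)
  expect_false(q$low_cell_flag)

  # threshold dominance: a saturating threshold suppresses every positive
  q_inf <- quantify_well(img, tau = 65535)
  expect_equal(q_inf$positive_cells, 0)

  # raising tau never increases the positive count
  taus <- c(0, 500, 600, 1000, 5000, 65535)
  pos <- vapply(taus, function(t) quantify_well(img, t)$positive_cells,
                integer(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("an empty image reports zero cells with the low-cell flag", {
  cfg <- sim_config(seed = 4, image_size = c(96, 96), noise_sd = 30)
  img <- render_well_image(make_truth(numeric(0), numeric(0), integer(0)),
                           cfg)
  expect_warning(q <- quantify_well(img, tau = 1000), "signal-free")
  expect_equal(q$total_cells, 0)
  expect_equal(q$positive_cells, 0)
  expect_equal(q$percent_positive, 0)
  expect_true(q$low_cell_flag)
})

test_that("channel shape mismatches are rejected", {
  img <- structure(list(well = "A01", plate_id = "P", bit_depth = 16L,
                        channels = list(nuclear = matrix(0, 10, 10),
                                        lipid = matrix(0, 10, 12))),
                   class = "well_image")
  expect_error(quantify_well(img, tau = 1), "shape mismatch")
})

test_that("noise-free image quantification is exact across random truths", {
  # conditions: generator defaults scaled to 40 cells on 256 px frames
  lay <- generate_plate_layout(21, 4, n_rows = 5, n_cols = 6, seed = 8)
  cfg <- sim_config(seed = 21, cells_per_well = 40,
                    image_size = c(256, 256), noise_sd = 0,
                    baseline_percent_positive = 20)
  n_checked <- 0
  for (seed in c(21, 22, 23, 24)) {
    cfg$seed <- seed
    truth <- simulate_well_truth(lay, cfg)
    wells <- lay$well[lay$role != "empty"]
    imgs <- lapply(truth[wells], render_well_image, config = cfg)
    qp <- suppressWarnings(quantify_plate(imgs, lay))
    truth_n <- vapply(truth[qp$well], function(t) nrow(t$cells), integer(1))
    truth_pos <- vapply(truth[qp$well],
                        function(t) sum(t$cells$n_droplets > 0), integer(1))
    expect_equal(qp$total_cells, unname(truth_n))
    expect_equal(qp$positive_cells, unname(truth_pos))
    n_checked <- n_checked + nrow(qp)
  }
  expect_gte(n_checked, 100)
})

test_that("cell counts stay within 5% under 5% nuclear-channel noise", {
  lay <- generate_plate_layout(21, 4, n_rows = 5, n_cols = 6, seed = 9)
  rel_err <- c()
  for (seed in c(31, 32, 33, 34)) {
    cfg <- sim_config(seed = seed, cells_per_well = 40,
                      image_size = c(256, 256), noise_sd = 1000)  # 5% of peak
    truth <- simulate_well_truth(lay, cfg)
    wells <- lay$well[lay$role != "empty"]
    for (w in wells) {
      img <- render_well_image(truth[[w]], cfg)
      seg <- segment_nuclei(img$channels$nuclear)
      rel_err <- c(rel_err,
                   abs(nrow(seg) - nrow(truth[[w]]$cells)) /
                     nrow(truth[[w]]$cells))
    }
  }
  expect_gte(length(rel_err), 100)
  expect_true(all(rel_err <= 0.05))
})
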