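small_layout <- function(seed = 1, n_compounds = 8, controls = 4) {
  generate_plate_layout(n_compounds, controls, n_rows = 4, n_cols = 6,
                        seed = seed)
}

test_that("planted hits and death shape the ground truth as configured", {
  lay <- small_layout()
  cfg <- sim_config(seed = 3, cells_per_well = 300,
                    baseline_percent_positive = 5, hit_effect = 0.5,
                    planted_hits = "C002",
                    death_by_compound = c(C007 = 0.8))
  truth <- simulate_well_truth(lay, cfg)
  w_hit <- lay$well[!is.na(lay$compound_id) & lay$compound_id == "C002"]
  expect_equal(truth[[w_hit]]$responder_fraction, 0.55)
  w_dead <- lay$well[!is.na(lay$compound_id) & lay$compound_id == "C007"]
  expect_equal(truth[[w_dead]]$death_fraction, 0.8)
  expect_equal(nrow(truth[[w_dead]]$cells), 60)  # 300 * (1 - 0.8)
  w_neg <- lay$well[lay$role == "negative_control"][1]
  expect_equal(truth[[w_neg]]$responder_fraction, 0.05)
  w_pos <- lay$well[lay$role == "positive_control"][1]
  expect_equal(truth[[w_pos]]$responder_fraction, 0.6)
})

test_that("truth simulation is deterministic and keeps cells separated", {
  lay <- small_layout()
  cfg <- sim_config(seed = 11, cells_per_well = 120,
                    image_size = c(256, 256))
  t1 <- simulate_well_truth(lay, cfg)
  t2 <- simulate_well_truth(lay, cfg)
  expect_identical(t1, t2)
  for (w in names(t1)[1:6]) {
    cells <- t1[[w]]$cells
    if (nrow(cells) < 2) next
    d <- as.matrix(dist(cells[, c("x", "y")]))
    diag(d) <- Inf
    expect_gte(min(d), 2 * cfg$nucleus_radius_px)
  }
})

test_that("impossible cell density errors with advice", {
  lay <- small_layout()
  cfg <- sim_config(seed = 1, cells_per_well = 500, image_size = c(64, 64))
  expect_error(simulate_well_truth(lay, cfg), "lower")
})

test_that("summary plate obeys degenerate binomial cases and conservation", {
  lay <- small_layout(seed = 5)
  cfg <- sim_config(seed = 5, cells_per_well = 250,
                    baseline_percent_positive = 0,
                    positive_control_fraction = 1)
  q <- simulate_summary_plate(lay, cfg)
  expect_true(all(q$percent_positive[q$role == "positive_control"] == 100))
  neg <- q[q$role == "negative_control", ]
  expect_true(all(neg$percent_positive == 0))
  expect_true(all(neg$total_cells == 250))
  expect_true(all(q$positive_cells <= q$total_cells))
  expect_true(all(q$total_cells <= cfg$cells_per_well))
  expect_true(all(q$percent_positive >= 0 & q$percent_positive <= 100))
  expect_identical(q, simulate_summary_plate(lay, cfg))
})

test_that("summary draws follow the binomial law across replicate wells", {
  # >= 1000 compound wells at p_true = 0.05, n = 300 cells
  n_cells <- 300; p <- 0.05
  lay <- generate_plate_layout(320, 16, seed = 2)
  qs <- lapply(1:4, function(r) {
    l <- generate_plate_layout(320, 16, replicate_id = r, seed = r)
    cfg <- sim_config(seed = 100 + r, cells_per_well = n_cells,
                      baseline_percent_positive = 100 * p)
    simulate_summary_plate(l, cfg)
  })
  k <- unlist(lapply(qs, function(q) q$positive_cells[q$role == "compound"]))
  pct <- unlist(lapply(qs,
                       function(q) q$percent_positive[q$role == "compound"]))
  m <- length(k)
  expect_gte(m, 1000)
  se_mean <- 100 * sqrt(p * (1 - p) / n_cells) / sqrt(m)
  expect_lt(abs(mean(pct) - 100 * p), 3 * se_mean)
  binom_var <- n_cells * p * (1 - p)
  se_var <- binom_var * sqrt(2 / (m - 1))
  expect_lt(abs(var(k) - binom_var), 4 * se_var)
})

test_that("rendering: empty well is flat, spots are countable, and reruns are identical", {
  cfg <- sim_config(seed = 1, image_size = c(128, 128), noise_sd = 0)
  empty <- make_truth(numeric(0), numeric(0), integer(0))
  img <- render_well_image(empty, cfg)
  expect_true(all(img$channels$nuclear == cfg$background_level))
  expect_true(all(img$channels$lipid == cfg$background_level))

  set.seed(41)
  gx <- rep(seq(20, 100, by = 20), 2)[1:10] + runif(10, -0.4, 0.4)
  gy <- rep(c(30, 80), each = 5) + runif(10, -0.4, 0.4)
  truth <- make_truth(gx, gy, n_droplets = rep(2L, 10))
  img2 <- render_well_image(truth, cfg)
  expect_equal(count_local_maxima(img2$channels$nuclear,
                                  above = cfg$background_level + 1), 10)
  img3 <- render_well_image(truth, cfg)
  expect_identical(img2$channels, img3$channels)
  expect_true(max(img2$channels$nuclear) <= 65535)
})

test_that("out-of-bounds truth positions are rejected", {
  cfg <- sim_config(seed = 1, image_size = c(64, 64), noise_sd = 0)
  truth <- make_truth(x = 90, y = 10, n_droplets = 0L)
  expect_error(render_well_image(truth, cfg), "bounds")
})
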