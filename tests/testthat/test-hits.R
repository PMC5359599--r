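test_that("cell death is read off the negative-control reference", {
  negs <- c(500, 480, 520)
  expect_equal(estimate_cell_death(500, negs, min_controls = 3), 0)
  expect_equal(estimate_cell_death(200, negs, min_controls = 3), 0.6)
  expect_equal(estimate_cell_death(700, negs, min_controls = 3), 0)  # clamped
  expect_equal(estimate_cell_death(0, negs, min_controls = 3), 1)
  expect_error(estimate_cell_death(100, c(0, 0, NA)), "0 usable")
  expect_error(estimate_cell_death(100, c(500, 480)), "2 usable")
})

test_that("the replicate-consensus hit rule is applied exactly", {
  z <- rbind(A = c(6, 7), B = c(6, 4), C = c(8, 9), D = c(5, 5))
  death <- rbind(A = c(0.1, 0.1), B = c(0.1, 0.1), C = c(0.7, 0.1),
                 D = c(0, 0))
  res <- call_hits(make_scored(z, death))$results
  res <- res[order(res$compound_id), ]
  expect_equal(res$is_hit, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$is_excluded, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$avg_z, c(6.5, 5, 8.5, 5))   # avg_z reported for everyone
  expect_equal(res$max_death_fraction, c(0.1, 0.1, 0.7, 0))
  # a hit is never simultaneously excluded
  expect_true(all(!(res$is_hit & res$is_excluded)))
})

test_that("under-replicated compounds are flagged and never hits", {
  z <- rbind(A = c(6, 7), B = c(20, NA))
  sc <- make_scored(z)
  sc <- sc[!(sc$compound_id == "B" & sc$replicate_id == 2), ]
  res <- call_hits(sc)$results
  b <- res[res$compound_id == "B", ]
  expect_true(b$insufficient_replicates)
  expect_false(b$is_hit)
  expect_true(res$is_hit[res$compound_id == "A"])
})

test_that("hits are ranked by decreasing average z with a lexicographic tie-break", {
  z <- rbind(Chloroquine = c(5.4, 5.4), Merbromin = c(58.8, 58.8),
             Nortriptyline = c(12.7, 12.7))
  rep_tbl <- hit_report(call_hits(z_threshold = 5, make_scored(z)))
  expect_equal(rep_tbl$hits$compound_id,
               c("Merbromin", "Nortriptyline", "Chloroquine"))
  expect_equal(rep_tbl$hits$avg_z, c(58.8, 12.7, 5.4))
  expect_equal(rep_tbl$hits$rank, 1:3)

  z2 <- rbind(Zeta = c(7, 7), Alpha = c(7, 7), Mid = c(8, 8))
  r2 <- hit_report(call_hits(make_scored(z2)))
  expect_equal(r2$hits$compound_id, c("Mid", "Alpha", "Zeta"))

  # zero hits: empty hit table, full companion table
  z3 <- rbind(A = c(1, 2), B = c(0, 3))
  r3 <- hit_report(call_hits(make_scored(z3)))
  expect_equal(nrow(r3$hits), 0)
  expect_equal(nrow(r3$all_compounds), 2)
})

test_that("annotations join the hit report by compound id", {
  z <- rbind(A = c(6, 7), B = c(9, 9))
  r <- hit_report(call_hits(make_scored(z)),
                  annotations = c(A = "TCA", B = "antiseptic"))
  expect_equal(r$hits$annotation, c("antiseptic", "TCA"))
})

test_that("hit calling is monotone in z and in death", {
  set.seed(555)
  for (i in 1:25) {
    z <- matrix(rnorm(12, mean = 4, sd = 2), 6, 2,
                dimnames = list(LETTERS[1:6], NULL))
    death <- matrix(runif(12, 0, 0.9), 6, 2,
                    dimnames = list(LETTERS[1:6], NULL))
    base <- call_hits(make_scored(z, death))$results
    # raising one z never turns a hit into a non-hit
    j <- sample(6, 1)
    z_up <- z; z_up[j, ] <- z_up[j, ] + runif(1, 0, 5)
    up <- call_hits(make_scored(z_up, death))$results
    was_hit <- base$compound_id[base$is_hit]
    expect_true(all(was_hit %in% up$compound_id[up$is_hit]))
    # raising death never creates a hit
    d_up <- death; d_up[j, ] <- pmin(d_up[j, ] + runif(1, 0, 0.5), 1)
    dres <- call_hits(make_scored(z, d_up))$results
    new_hits <- setdiff(dres$compound_id[dres$is_hit],
                        base$compound_id[base$is_hit])
    expect_equal(new_hits, character(0))
  }
})

test_that("death fractions are computed per replicate plate when absent", {
  lay1 <- generate_plate_layout(20, 6, replicate_id = 1, seed = 1)
  lay2 <- generate_plate_layout(20, 6, plate_id = "P2", replicate_id = 2,
                                seed = 2)
  cfg <- sim_config(seed = 10, planted_hits = c("C003", "C011"),
                    hit_effect = 0.4,
                    death_by_compound = c(C003 = 0.8))
  scored <- rbind(score_plate(simulate_summary_plate(lay1, cfg)),
                  score_plate(simulate_summary_plate(lay2, cfg)))
  h <- call_hits(scored)
  res <- h$results
  dead <- res[res$compound_id == "C003", ]
  expect_true(dead$is_excluded)     # planted 80% death > 60% cutoff
  expect_false(dead$is_hit)
  expect_gt(dead$max_death_fraction, 0.6)
  live <- res[res$compound_id == "C011", ]
  expect_true(live$is_hit)
  expect_equal(res$compound_id[res$is_hit], "C011")
})
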