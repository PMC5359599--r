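# Shared fixtures and independent oracles.

# Brute-force order-statistic oracles, independent of the implementation
# under test: median as the midpoint of the central order statistics of the
# explicitly sorted vector, MAD by direct application of the definition.
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
brute_mad <- function(x) brute_median(abs(x - brute_median(x)))
brute_z <- function(x, values) (x - brute_median(values)) /
  (brute_mad(values) * 1.4826)

# Hand-built well-quantification rows with given percent-positive values
# (counts chosen consistently: percent = 100 * positive / total).
make_quants <- function(percent, role = "compound", plate_id = "P1",
                        replicate_id = 1L, total = 1000L) {
  n <- length(percent)
  if (length(role) == 1L) role <- rep(role, n)
  pos <- as.integer(round(percent / 100 * total))
  data.frame(
    plate_id = plate_id, replicate_id = replicate_id,
    well = sprintf("A%02d", seq_len(n)), role = role,
    compound_id = ifelse(role == "compound", sprintf("C%03d", seq_len(n)),
                         NA_character_),
    total_cells = total, positive_cells = pos,
    percent_positive = percent, low_cell_flag = FALSE,
    stringsAsFactors = FALSE)
}

# Hand-built scored table for hit calling: one row per compound x replicate
# with prescribed z and death values.
make_scored <- function(z_by_rep, death_by_rep = NULL) {
  ids <- rownames(z_by_rep)
  if (is.null(death_by_rep)) {
    death_by_rep <- matrix(0, nrow(z_by_rep), ncol(z_by_rep))
  }
  do.call(rbind, lapply(seq_len(ncol(z_by_rep)), function(r) {
    data.frame(plate_id = paste0("P", r), replicate_id = r, well = ids,
               role = "compound", compound_id = ids,
               z = z_by_rep[, r], death_fraction = death_by_rep[, r],
               stringsAsFactors = FALSE)
  }))
}

# A hand-assembled well truth (bypassing simulate_well_truth) for rendering
# tests where exact cell geometry matters.
make_truth <- function(x, y, n_droplets, is_responder = n_droplets > 0,
                       well = "A01", plate_id = "T", seed = 99L) {
  structure(list(
    well = well, role = "compound", compound_id = "CX",
    plate_id = plate_id, replicate_id = 1L,
    n_cells_seeded = length(x), death_fraction = 0,
    responder_fraction = mean(is_responder),
    cells = data.frame(x = x, y = y, is_responder = is_responder,
                       n_droplets = as.integer(n_droplets)),
    render_seed = seed), class = "well_truth")
}

# Count strict 8-neighbourhood local maxima above background: the oracle for
# "how many distinct bright spots does this noise-free image contain".
count_local_maxima <- function(img, above) {
  nr <- nrow(img); nc <- ncol(img)
  n <- 0L
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      v <- img[i, j]
      if (v <= above) next
      nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
      nb[2, 2] <- -Inf
      if (v > max(nb)) n <- n + 1L
    }
  }
  n
}
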