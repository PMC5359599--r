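#' Simulate per-well ground truth for a plate
#'
#' Draws the latent state every downstream check can be compared against: how
#' many cells survive in each well, where they sit, which are responders
#' (droplet-accumulating), and how many droplets each carries. Controls and
#' planted hits get their responder fractions from the config; compound-induced
#' death removes cells before placement. Cell centres are placed by rejection
#' sampling with a minimum separation of twice the nucleus radius (capped at
#' 50 x n attempts), so rendered nuclei never merge.
#'
#' The truth for a compound (responder fraction, death fraction) is a
#' deterministic function of the layout roles and the config, so replicate
#' plates built from the same config share truth parameters while drawing
#' independent well noise.
#'
#' @param layout a [generate_plate_layout()] result (validated here).
#' @param config a [sim_config()].
#' @return Named list (by well label) of `well_truth` objects: lists with
#'   `well`, `role`, `compound_id`, `n_cells_seeded`, `death_fraction`,
#'   `responder_fraction`, and `cells`, a data.frame with columns `x`, `y`
#'   (0-based pixel coordinates, x = column, y = row), `is_responder`,
#'   `n_droplets`. The surviving-cell count is `nrow(cells)` =
#'   `round(n_cells_seeded * (1 - death_fraction))`.
#' @export
simulate_well_truth <- function(layout, config) {
  validate_plate_layout(layout)
  validate_sim_config(config)
  rep_id <- attr(layout, "replicate_id") %||% 1L
  out <- vector("list", nrow(layout))
  names(out) <- layout$well
  for (i in seq_len(nrow(layout))) {
    role <- layout$role[i]
    cid <- layout$compound_id[i]
    pars <- well_truth_params(role, cid, config)
    n_seed <- if (role == "empty") 0L else config$cells_per_well
    ws <- derive_seed(config$seed, rep_id, i)
    out[[i]] <- with_seed(ws, {
      n_surv <- as.integer(round(n_seed * (1 - pars[["d_true"]])))
      pos <- place_cells(n_surv, config)
      is_resp <- if (n_surv > 0) {
        runif(n_surv) < pars[["p_true"]]
      } else logical(0)
      lam <- ifelse(is_resp, config$droplet_count_responder,
                    config$droplet_count_background)
      n_drop <- if (n_surv > 0) rpois(n_surv, lam) else integer(0)
      structure(list(
        well = layout$well[i], role = role, compound_id = cid,
        plate_id = attr(layout, "plate_id"), replicate_id = rep_id,
        n_cells_seeded = n_seed,
        death_fraction = unname(pars[["d_true"]]),
        responder_fraction = unname(pars[["p_true"]]),
        cells = data.frame(x = pos$x, y = pos$y, is_responder = is_resp,
                           n_droplets = as.integer(n_drop)),
        render_seed = derive_seed(ws, 2L, 1L)
      ), class = "well_truth")
    })
  }
  out
}

# Uniform placement with a hard minimum separation of 2 x nucleus radius;
# rejection sampling, erroring after 50 x n attempts. Margin keeps nuclei and
# their droplets fully inside the frame.
place_cells <- function(n, cfg) {
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  margin <- cfg$nucleus_radius_px + cfg$droplet_offset_max_px +
    cfg$droplet_radius_px + 1
  if (2 * margin >= H || 2 * margin >= W) {
    stop("image too small for the configured radii")
  }
  min_d2 <- (2 * cfg$nucleus_radius_px)^2
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 50L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " cells without overlap after ",
           max_attempts, " attempts; lower cells_per_well or the nucleus ",
           "radius, or enlarge image_size", call. = FALSE)
    }
    x <- runif(1, margin, W - 1 - margin)
    y <- runif(1, margin, H - 1 - margin)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < min_d2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  list(x = xs, y = ys)
}

#' @export
print.well_truth <- function(x, ...) {
  cat(sprintf("Well %s (%s%s): %d/%d cells surviving, %d responders\n",
              x$well, x$role,
              if (!is.na(x$compound_id)) paste0(", ", x$compound_id) else "",
              nrow(x$cells), x$n_cells_seeded, sum(x$cells$is_responder)))
  invisible(x)
}

#' Simulate the per-well readout of a plate without rendering images
#'
#' The fast path: draws each well's quantified counts directly from the
#' generative model the imaging pipeline estimates. Surviving cells are
#' binomial in the seeded count with survival `1 - d_true`; positives are
#' binomial in the survivors with the well's responder fraction; percent
#' positive is `100 k / n` (0 with `low_cell_flag` when no cells survive).
#' Useful for statistical validation at screen scale where rendering and
#' re-segmenting every well would add nothing.
#'
#' @inheritParams simulate_well_truth
#' @return A well-quantification data.frame (one row per non-empty well):
#'   `plate_id`, `replicate_id`, `well`, `role`, `compound_id`,
#'   `total_cells`, `positive_cells`, `percent_positive`, `low_cell_flag`.
#' @export
#' @examples
#' lay <- generate_plate_layout(40, controls_per_role = 8, seed = 2)
#' q <- simulate_summary_plate(lay, sim_config(seed = 2))
#' head(q)
simulate_summary_plate <- function(layout, config) {
  validate_plate_layout(layout)
  validate_sim_config(config)
  rep_id <- attr(layout, "replicate_id") %||% 1L
  keep <- layout$role != "empty"
  lay <- layout[keep, , drop = FALSE]
  idx <- which(keep)
  n <- nrow(lay)
  total <- integer(n); pos <- integer(n)
  for (i in seq_len(n)) {
    pars <- well_truth_params(lay$role[i], lay$compound_id[i], config)
    ws <- derive_seed(config$seed, rep_id, idx[i])
    draws <- with_seed(ws, {
      nt <- rbinom(1L, config$cells_per_well, 1 - pars[["d_true"]])
      c(nt, rbinom(1L, nt, pars[["p_true"]]))
    })
    total[i] <- draws[1]; pos[i] <- draws[2]
  }
  quant_table(plate_id = attr(layout, "plate_id"), replicate_id = rep_id,
              well = lay$well, role = lay$role,
              compound_id = lay$compound_id,
              total_cells = total, positive_cells = pos)
}

# Canonical constructor for the well-quantification table; enforces the
# percent-positive and low-cell invariants in one place.
quant_table <- function(plate_id, replicate_id, well, role, compound_id,
                        total_cells, positive_cells) {
  stopifnot(all(positive_cells <= total_cells), all(total_cells >= 0))
  low <- total_cells == 0L
  pct <- ifelse(low, 0, 100 * positive_cells / pmax(total_cells, 1L))
  data.frame(plate_id = plate_id, replicate_id = as.integer(replicate_id),
             well = well, role = role, compound_id = compound_id,
             total_cells = as.integer(total_cells),
             positive_cells = as.integer(positive_cells),
             percent_positive = pct, low_cell_flag = low,
             stringsAsFactors = FALSE, row.names = NULL)
}
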