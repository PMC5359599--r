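#' Simulation configuration
#'
#' Collects every knob of the synthetic screen generator. Defaults are
#' desk-scale: 300 cells per well on 512 x 512 px images, which preserves the
#' statistical structure of a 1500-cells-per-well 384-well screen while
#' keeping full-plate image runs to minutes (use [sim_config_screen_scale()]
#' for the full-scale preset).
#'
#' Intensity units are arbitrary detector counts on the unsigned 16-bit
#' scale (0..65535). Geometry is in pixels.
#'
#' @param seed integer; fully determines every stochastic draw.
#' @param cells_per_well nominal cells seeded per well.
#' @param image_size `(height, width)` in pixels.
#' @param nucleus_radius_px nuclear spot radius.
#' @param nucleus_intensity peak nuclear-channel intensity of a cell.
#' @param droplet_count_responder mean droplet count (Poisson) for responder
#'   cells — cells that have re-acquired lipid droplets.
#' @param droplet_count_background mean droplet count for non-responders
#'   (default 0: quiescent-marker-negative cells carry no droplet signal).
#' @param droplet_intensity peak lipid-channel intensity of one droplet.
#' @param droplet_radius_px droplet spot radius.
#' @param droplet_offset_max_px maximum distance of a droplet centre from its
#'   cell centre; default `max(1, nucleus_radius_px - 3)`. Droplets are
#'   perinuclear: the default keeps every droplet's signal inside the zone
#'   the quantifier measures for its own cell (nucleus mask dilated by 3 px)
#'   and outside any neighbouring cell's zone given the placement guarantee
#'   of 2 nucleus radii between cell centres, so noise-free image
#'   quantification can recover droplet-bearing cells exactly.
#' @param background_level constant background intensity, both channels.
#' @param noise_sd SD of additive zero-mean Gaussian noise, both channels.
#' @param baseline_percent_positive percent of cells that are responders in
#'   negative-control and untreated compound wells (default 5).
#' @param positive_control_fraction responder fraction in positive-control
#'   wells (default 0.6 — strong droplet induction, as in reference-matrix
#'   culture).
#' @param hit_effect additive shift in responder *fraction* for planted hit
#'   compounds (default 0.15, i.e. baseline 5\% -> 20\%).
#' @param planted_hits character vector of compound ids that respond.
#' @param death_by_compound named numeric vector, compound id -> death
#'   fraction in `[0,1]`; compounds absent from it have no induced death.
#' @param illumination_gradient logical; add a linear left-to-right
#'   multiplicative illumination gradient (off by default).
#' @param gradient_strength relative amplitude of the gradient when enabled.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, planted_hits = c("C010", "C042"))
#' cfg$cells_per_well
sim_config <- function(seed = 1L,
                       cells_per_well = 300L,
                       image_size = c(512L, 512L),
                       nucleus_radius_px = 5,
                       nucleus_intensity = 20000,
                       droplet_count_responder = 8,
                       droplet_count_background = 0,
                       droplet_intensity = 12000,
                       droplet_radius_px = 1,
                       droplet_offset_max_px = NULL,
                       background_level = 500,
                       noise_sd = 200,
                       baseline_percent_positive = 5,
                       positive_control_fraction = 0.6,
                       hit_effect = 0.15,
                       planted_hits = character(),
                       death_by_compound = numeric(),
                       illumination_gradient = FALSE,
                       gradient_strength = 0.1) {
  if (is.null(droplet_offset_max_px)) {
    droplet_offset_max_px <- max(1, nucleus_radius_px - 3)
  }
  cfg <- list(
    seed = as.integer(seed),
    cells_per_well = as.integer(cells_per_well),
    image_size = as.integer(image_size),
    nucleus_radius_px = nucleus_radius_px,
    nucleus_intensity = nucleus_intensity,
    droplet_count_responder = droplet_count_responder,
    droplet_count_background = droplet_count_background,
    droplet_intensity = droplet_intensity,
    droplet_radius_px = droplet_radius_px,
    droplet_offset_max_px = droplet_offset_max_px,
    background_level = background_level,
    noise_sd = noise_sd,
    baseline_percent_positive = baseline_percent_positive,
    positive_control_fraction = positive_control_fraction,
    hit_effect = hit_effect,
    planted_hits = as.character(planted_hits),
    death_by_compound = death_by_compound,
    illumination_gradient = isTRUE(illumination_gradient),
    gradient_strength = gradient_strength
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
sim_config_screen_scale <- function(seed = 1L, ...) {
  sim_config(seed = seed, cells_per_well = 1500L,
             image_size = c(1024L, 1024L), ...)
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$image_size) == 2L)
  if (cfg$cells_per_well < 0L) stop("cells_per_well must be >= 0")
  for (f in c("nucleus_intensity", "droplet_intensity", "background_level",
              "noise_sd", "droplet_count_responder",
              "droplet_count_background")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  for (f in c("nucleus_radius_px", "droplet_radius_px",
              "droplet_offset_max_px")) {
    if (cfg[[f]] <= 0) stop(f, " must be > 0")
  }
  frac <- c(baseline = cfg$baseline_percent_positive / 100,
            positive_control = cfg$positive_control_fraction,
            hit_shift = cfg$hit_effect)
  if (any(frac < 0 | frac > 1)) {
    stop("responder fractions must lie in [0, 1]; got ",
         paste(sprintf("%s=%.3g", names(frac), frac), collapse = ", "))
  }
  if (length(cfg$death_by_compound)) {
    if (is.null(names(cfg$death_by_compound)) ||
        any(!nzchar(names(cfg$death_by_compound)))) {
      stop("death_by_compound must be a named vector (compound_id -> fraction)")
    }
    if (any(cfg$death_by_compound < 0 | cfg$death_by_compound > 1)) {
      stop("death fractions must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:",
      sprintf("%d cells/well, %dx%d px, seed %d",
              x$cells_per_well, x$image_size[1], x$image_size[2], x$seed),
      "\n")
  cat(sprintf("  baseline %.1f%% positive, positive controls %.0f%%, hit effect +%.0f points\n",
              x$baseline_percent_positive, 100 * x$positive_control_fraction,
              100 * x$hit_effect))
  if (length(x$planted_hits)) {
    cat("  planted hits:", paste(x$planted_hits, collapse = ", "), "\n")
  }
  if (length(x$death_by_compound)) {
    cat("  induced death:", length(x$death_by_compound), "compound(s)\n")
  }
  invisible(x)
}

# True responder fraction and death fraction for one well, from its role and
# compound id. This is the deterministic part of the generative model shared
# by the image and summary paths (and across replicate plates).
well_truth_params <- function(role, compound_id, cfg) {
  p <- switch(role,
    negative_control = cfg$baseline_percent_positive / 100,
    positive_control = cfg$positive_control_fraction,
    compound = {
      base <- cfg$baseline_percent_positive / 100
      if (!is.na(compound_id) && compound_id %in% cfg$planted_hits) {
        min(1, base + cfg$hit_effect)
      } else base
    },
    empty = 0
  )
  d <- 0
  if (role == "compound" && !is.na(compound_id) &&
      compound_id %in% names(cfg$death_by_compound)) {
    d <- unname(cfg$death_by_compound[[compound_id]])
  }
  c(p_true = p, d_true = d)
}
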