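#' Render a two-channel well image from simulated ground truth
#'
#' Produces the raster pair the quantifier consumes: a nuclear channel with
#' one radially symmetric bright spot per surviving cell, and a lipid channel
#' with each cell's droplets as smaller puncta near the nucleus. Both
#' channels sit on a constant background with additive zero-mean Gaussian
#' noise, optionally modulated by a linear illumination gradient, and are
#' clipped and rounded to the unsigned 16-bit range. Spots use a quadratic
#' radial profile, `peak * (1 - (r/R)^2)` for `r < R`, which is strictly
#' decreasing from the centre and exactly zero at the spot radius, so
#' noise-free nuclei of well-separated cells are countable as distinct
#' bright regions.
#'
#' Rendering is a pure function of `(truth, config)`: the noise and droplet
#' placements are drawn under a seed stored in the truth object, so repeated
#' calls give identical pixel arrays.
#'
#' @param truth a `well_truth` from [simulate_well_truth()].
#' @param config the same [sim_config()] used to simulate the truth.
#' @return A `well_image`: list with `well`, `plate_id`, `bit_depth = 16`,
#'   and `channels`, a list of two numeric matrices `nuclear` and `lipid`
#'   (rows = image rows).
#' @export
render_well_image <- function(truth, config) {
  validate_sim_config(config)
  H <- config$image_size[1]; W <- config$image_size[2]
  cells <- truth$cells
  if (nrow(cells) > 0) {
    r_max <- config$nucleus_radius_px
    if (any(cells$x < 0 | cells$x > W - 1 | cells$y < 0 | cells$y > H - 1)) {
      stop("cell positions outside image bounds")
    }
  }
  nuc <- matrix(0, H, W)
  lip <- matrix(0, H, W)
  seed <- truth$render_seed %||% derive_seed(config$seed, 3L, 1L)
  with_seed(seed, {
    for (i in seq_len(nrow(cells))) {
      nuc <- add_spot(nuc, cells$y[i], cells$x[i],
                       config$nucleus_radius_px, config$nucleus_intensity)
      nd <- cells$n_droplets[i]
      if (nd > 0) {
        # droplets perinuclear: uniform in a disc around the cell centre
        rr <- config$droplet_offset_max_px * sqrt(runif(nd))
        th <- runif(nd, 0, 2 * pi)
        for (j in seq_len(nd)) {
          lip <- add_spot(lip, cells$y[i] + rr[j] * sin(th[j]),
                           cells$x[i] + rr[j] * cos(th[j]),
                           config$droplet_radius_px, config$droplet_intensity)
        }
      }
    }
    gain <- 1
    if (config$illumination_gradient) {
      gain <- matrix(rep(1 + config$gradient_strength *
                           (seq_len(W) - 1) / max(W - 1, 1) -
                           config$gradient_strength / 2,
                         each = H), H, W)
    }
    for (ch in c("nuclear", "lipid")) {
      base <- if (ch == "nuclear") nuc else lip
      img <- (base + config$background_level) * gain
      if (config$noise_sd > 0) {
        img <- img + rnorm(H * W, 0, config$noise_sd)
      }
      img <- round(pmin(pmax(img, 0), 65535))
      if (ch == "nuclear") nuc <- img else lip <- img
    }
  })
  structure(list(well = truth$well, plate_id = truth$plate_id,
                 bit_depth = 16L,
                 channels = list(nuclear = nuc, lipid = lip)),
            class = "well_image")
}

# Add one radial spot (quadratic cap profile) into matrix `img` at 0-based
# centre (row0, col0); summed into existing signal, touching only its
# bounding box.
add_spot <- function(img, row0, col0, radius, peak) {
  H <- nrow(img); W <- ncol(img)
  r1 <- max(1L, floor(row0 - radius) + 1L)
  r2 <- min(H, ceiling(row0 + radius) + 1L)
  c1 <- max(1L, floor(col0 - radius) + 1L)
  c2 <- min(W, ceiling(col0 + radius) + 1L)
  if (r1 > r2 || c1 > c2) return(img)
  dr <- (r1:r2) - 1 - row0
  dc <- (c1:c2) - 1 - col0
  d2 <- outer(dr^2, dc^2, "+")
  spot <- peak * pmax(0, 1 - d2 / radius^2)
  img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] + spot
  img
}

#' @export
print.well_image <- function(x, ...) {
  cat(sprintf("Well image %s/%s: %d x %d px, %d-bit, channels %s\n",
              x$plate_id %||% "?", x$well %||% "?",
              nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$bit_depth,
              paste(names(x$channels), collapse = "+")))
  invisible(x)
}

validate_well_image <- function(image) {
  ch <- image$channels
  if (!all(c("nuclear", "lipid") %in% names(ch))) {
    stop("well_image must have 'nuclear' and 'lipid' channels")
  }
  if (!identical(dim(ch$nuclear), dim(ch$lipid))) {
    stop("channel shape mismatch: nuclear ",
         paste(dim(ch$nuclear), collapse = "x"), " vs lipid ",
         paste(dim(ch$lipid), collapse = "x"))
  }
  maxv <- 2^(image$bit_depth %||% 16L) - 1
  if (min(ch$nuclear) < 0 || min(ch$lipid) < 0 ||
      max(ch$nuclear) > maxv || max(ch$lipid) > maxv) {
    stop("channel values outside [0, ", maxv, "]")
  }
  invisible(image)
}
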