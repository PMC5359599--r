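#' Segment nuclei in the nuclear-stain channel
#'
#' Deterministic pipeline: Gaussian smoothing, a global threshold (Otsu by
#' default, or a fixed value), 8-connected component labelling, and an area
#' filter. One nucleus per surviving component, with its 0-based `(row, col)`
#' centroid and pixel area. Touching nuclei are not split; on data from the
#' bundled generator cell placement guarantees separation, and for real
#' images a watershed step would slot in before the area filter.
#'
#' @param nuclear_channel numeric matrix of nuclear-stain intensities.
#' @param sigma Gaussian smoothing SD in px (0 disables smoothing).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value threshold intensity when `threshold_method="fixed"`.
#' @param min_area,max_area inclusive component-area bounds in px.
#' @param min_snr foreground guard for Otsu thresholding: the threshold must
#'   exceed the robust background (median of the smoothed image) by at least
#'   `min_snr` robust SDs (`1.4826 * MAD`), otherwise the image is treated
#'   as signal-free (no nuclei, with a warning). Protects empty wells, where
#'   Otsu would otherwise split the noise itself.
#' @return data.frame with one row per nucleus: `label` (1..n), `centroid_row`,
#'   `centroid_col`, `area_px`; the relabelled component matrix (0 =
#'   background) is attached as attribute `"label_matrix"`. An all-constant
#'   image under Otsu yields zero rows with a warning.
#' @export
segment_nuclei <- function(nuclear_channel, sigma = 1,
                           threshold_method = c("otsu", "fixed"),
                           threshold_value = NULL,
                           min_area = 10L, max_area = 5000L,
                           min_snr = 5) {
  threshold_method <- match.arg(threshold_method)
  img <- as.matrix(nuclear_channel)
  if (length(img) == 0L) stop("empty nuclear channel")
  sm <- if (sigma > 0) {
    EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  } else img

  empty <- data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0))
  attr(empty, "label_matrix") <- matrix(0L, nrow(img), ncol(img))

  if (threshold_method == "otsu") {
    rng <- range(sm)
    if (diff(rng) == 0) {
      warning("all-constant nuclear channel: Otsu threshold undefined, ",
              "returning no nuclei")
      return(empty)
    }
    scaled <- (sm - rng[1]) / diff(rng)
    thr_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                                levels = 256)
    thr <- rng[1] + thr_scaled * diff(rng)
    bg <- median(sm)
    if (thr <= bg + min_snr * MAD_SCALE * mad_raw(as.vector(sm))) {
      warning("Otsu threshold does not clear the background by ", min_snr,
              " robust SDs: treating the image as signal-free")
      return(empty)
    }
  } else {
    if (is.null(threshold_value)) {
      stop("threshold_value required for threshold_method='fixed'")
    }
    thr <- threshold_value
  }
  binary <- sm > thr
  if (!any(binary)) return(empty)

  lab <- label_components_8(binary)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0L) return(empty)

  # relabel kept components 1..n in raster order of first occurrence
  map <- integer(nlab)
  map[keep] <- seq_along(keep)
  newlab <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  newlab[nz] <- map[lab[nz]]

  pix <- which(newlab > 0L, arr.ind = TRUE)
  l <- newlab[newlab > 0L]
  area <- tabulate(l, nbins = length(keep))
  cr <- rowsum(as.numeric(pix[, 1] - 1L), l)[, 1] / area
  cc <- rowsum(as.numeric(pix[, 2] - 1L), l)[, 1] / area
  out <- data.frame(label = seq_along(keep), centroid_row = unname(cr),
                    centroid_col = unname(cc), area_px = as.integer(area))
  attr(out, "label_matrix") <- newlab
  out
}

# 8-connected component labelling of a logical matrix. EBImage's flood-fill
# labelling is 4-connected; labels that meet only diagonally are merged with
# a union-find pass over the (few) diagonal label adjacencies.
label_components_8 <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary * 1)))
  lab <- matrix(as.integer(round(lab)), nrow(binary), ncol(binary))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  compact <- match(root, sort(unique(root)))
  nz <- lab > 0L
  lab[nz] <- compact[lab[nz]]
  lab
}

#' Calibrate the lipid-positivity threshold from negative-control cells
#'
#' A cell counts as lipid-positive when its mean lipid-channel intensity
#' exceeds `tau = median + k * MAD` of the pooled per-cell intensities from
#' negative-control (vehicle) wells. MAD here is the raw median absolute
#' deviation ([mad_raw()]). With idealized noise-free data the MAD can be 0;
#' the threshold then degrades to the median and a warning is issued.
#'
#' @param intensities numeric vector of per-cell mean lipid intensities
#'   pooled over negative-control wells.
#' @param k multiplier on the MAD (default 3).
#' @param min_cells minimum pooled control cells required (default 50).
#' @return threshold `tau`, a single number.
#' @export
#' @examples
#' calibrate_positivity_threshold(c(90, 95, 100, 105, 110), k = 3) # 115
calibrate_positivity_threshold <- function(intensities, k = 3,
                                           min_cells = 50L) {
  intensities <- intensities[!is.na(intensities)]
  if (length(intensities) < min_cells) {
    stop("only ", length(intensities), " negative-control cells pooled; ",
         "need at least ", min_cells, " to calibrate the positivity ",
         "threshold", call. = FALSE)
  }
  m <- median(intensities)
  s <- mad_raw(intensities)
  if (s == 0) {
    warning("MAD of negative-control intensities is 0; ",
            "positivity threshold degrades to the control median")
  }
  m + k * s
}

#' Per-nucleus mean lipid intensity over the perinuclear region
#'
#' For each segmented nucleus the lipid channel is averaged over the nucleus
#' mask dilated by `dilation_radius_px` (Euclidean disc), a stand-in for the
#' cell body: droplets are cytoplasmic and sit adjacent to the nucleus.
#' Dilated masks of different nuclei may overlap; each nucleus is measured
#' over its own dilation independently.
#'
#' @param nuclei a [segment_nuclei()] result (with its label matrix).
#' @param lipid_channel numeric matrix, same shape as the segmented channel.
#' @param dilation_radius_px dilation radius in px (default 3).
#' @return `nuclei` with an added `mean_lipid_intensity` column.
#' @export
measure_lipid_intensity <- function(nuclei, lipid_channel,
                                    dilation_radius_px = 3L) {
  lab <- attr(nuclei, "label_matrix")
  if (is.null(lab)) stop("nuclei must carry a label_matrix attribute")
  if (!identical(dim(lab), dim(lipid_channel))) {
    stop("channel shape mismatch: labels ", paste(dim(lab), collapse = "x"),
         " vs lipid ", paste(dim(lipid_channel), collapse = "x"))
  }
  d <- dilation_radius_px
  nr <- nrow(lab); nc <- ncol(lab)
  means <- numeric(nrow(nuclei))
  if (nrow(nuclei) > 0) {
    pix <- which(lab > 0L, arr.ind = TRUE)
    lv <- lab[lab > 0L]
    ord <- order(lv)
    pix <- pix[ord, , drop = FALSE]
    lv <- lv[ord]
    starts <- c(1L, which(diff(lv) > 0L) + 1L, length(lv) + 1L)
    for (i in seq_len(nrow(nuclei))) {
      rows <- pix[starts[i]:(starts[i + 1L] - 1L), , drop = FALSE]
      r1 <- max(1L, min(rows[, 1]) - d); r2 <- min(nr, max(rows[, 1]) + d)
      c1 <- max(1L, min(rows[, 2]) - d); c2 <- min(nc, max(rows[, 2]) + d)
      gr <- r1:r2; gc <- c1:c2
      # candidate pixel is in the dilated mask iff within d of a mask pixel
      dr2 <- outer(gr, rows[, 1], "-")^2
      dc2 <- outer(gc, rows[, 2], "-")^2
      inmask <- matrix(FALSE, length(gr), length(gc))
      for (j in seq_len(nrow(rows))) {
        inmask <- inmask | outer(dr2[, j], dc2[, j], "+") <= d^2
      }
      means[i] <- mean(lipid_channel[gr, gc][inmask])
    }
  }
  nuclei$mean_lipid_intensity <- means
  nuclei
}

#' Quantify one well image
#'
#' The per-well readout of the screen: total cell count (nuclear-stain
#' positive), positive cell count (lipid- and nuclear-stain positive, i.e.
#' segmented nuclei whose perinuclear mean lipid intensity strictly exceeds
#' `tau`), and the percent positive. Wells with no detected cells report
#' 0 percent with `low_cell_flag` set.
#'
#' @param image a `well_image` (see [render_well_image()] / [read_well_image()]).
#' @param tau lipid-positivity threshold, typically from
#'   [calibrate_positivity_threshold()]; must be non-negative.
#' @param role,compound_id,replicate_id well metadata carried into the row.
#' @param sigma,threshold_method,threshold_value,min_area,max_area
#'   segmentation parameters, see [segment_nuclei()].
#' @param dilation_radius_px see [measure_lipid_intensity()].
#' @return one-row well-quantification data.frame (the same schema as
#'   [simulate_summary_plate()]), with the per-nucleus table attached as
#'   attribute `"nuclei"`.
#' @export
quantify_well <- function(image, tau, role = NA_character_,
                          compound_id = NA_character_, replicate_id = 1L,
                          sigma = 1, threshold_method = "otsu",
                          threshold_value = NULL,
                          min_area = 10L, max_area = 5000L,
                          dilation_radius_px = 3L) {
  validate_well_image(image)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("tau must be a single non-negative number")
  }
  nuc <- segment_nuclei(image$channels$nuclear, sigma = sigma,
                        threshold_method = threshold_method,
                        threshold_value = threshold_value,
                        min_area = min_area, max_area = max_area)
  nuc <- measure_lipid_intensity(nuc, image$channels$lipid,
                                 dilation_radius_px = dilation_radius_px)
  nuc$is_positive <- nuc$mean_lipid_intensity > tau
  out <- quant_table(plate_id = image$plate_id %||% NA_character_,
                     replicate_id = replicate_id,
                     well = image$well %||% NA_character_,
                     role = role, compound_id = compound_id,
                     total_cells = nrow(nuc),
                     positive_cells = sum(nuc$is_positive))
  attr(out, "nuclei") <- nuc
  out
}

#' Quantify all wells of one plate, calibrating the threshold from controls
#'
#' Two passes: segment and measure every well once, pool per-cell lipid
#' intensities of negative-control wells to calibrate `tau`
#' ([calibrate_positivity_threshold()]), then classify each cell against
#' `tau` and assemble the quantification table.
#'
#' @param images named list of `well_image` objects keyed by well label
#'   (every non-empty layout well must be present).
#' @param layout the plate's [generate_plate_layout()] / [read_plate_map()]
#'   layout.
#' @param k MAD multiplier for calibration.
#' @param tau optional fixed threshold; skips calibration when supplied.
#' @param ... segmentation/measurement parameters passed to [quantify_well()]
#'   internals ([segment_nuclei()], [measure_lipid_intensity()]).
#' @return well-quantification data.frame with one row per non-empty well;
#'   the calibrated threshold is attached as attribute `"tau"`.
#' @export
quantify_plate <- function(images, layout, k = 3, tau = NULL,
                           sigma = 1, threshold_method = "otsu",
                           threshold_value = NULL, min_area = 10L,
                           max_area = 5000L, dilation_radius_px = 3L) {
  validate_plate_layout(layout)
  lay <- layout[layout$role != "empty", , drop = FALSE]
  missing_wells <- setdiff(lay$well, names(images))
  if (length(missing_wells)) {
    stop("missing images for wells: ",
         paste(head(missing_wells, 5), collapse = ", "),
         if (length(missing_wells) > 5) " ...")
  }
  measured <- lapply(lay$well, function(w) {
    img <- images[[w]]
    validate_well_image(img)
    nuc <- segment_nuclei(img$channels$nuclear, sigma = sigma,
                          threshold_method = threshold_method,
                          threshold_value = threshold_value,
                          min_area = min_area, max_area = max_area)
    measure_lipid_intensity(nuc, img$channels$lipid,
                            dilation_radius_px = dilation_radius_px)
  })
  names(measured) <- lay$well
  if (is.null(tau)) {
    neg <- lay$well[lay$role == "negative_control"]
    pooled <- unlist(lapply(measured[neg],
                            function(m) m$mean_lipid_intensity))
    tau <- calibrate_positivity_threshold(pooled, k = k)
  }
  total <- vapply(measured, nrow, integer(1))
  pos <- vapply(measured, function(m) sum(m$mean_lipid_intensity > tau),
                integer(1))
  out <- quant_table(plate_id = attr(layout, "plate_id"),
                     replicate_id = attr(layout, "replicate_id") %||% 1L,
                     well = lay$well, role = lay$role,
                     compound_id = lay$compound_id,
                     total_cells = unname(total),
                     positive_cells = unname(pos))
  attr(out, "tau") <- tau
  out
}
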