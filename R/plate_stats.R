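#' Raw median absolute deviation
#'
#' `median(|x - median(x)|)` with no consistency scaling: the robust spread
#' estimate the plate Z score is built on. The scaling to the normal SD is
#' applied separately via [MAD_SCALE] in [robust_z()], keeping the two pieces
#' of the formula auditable. The median of an even-length vector is the
#' midpoint of the two central order statistics.
#'
#' @param values non-empty numeric vector (NAs removed; all-NA errors).
#' @return a single non-negative number.
#' @export
#' @examples
#' mad_raw(c(1, 2, 3, 4, 100)) # 1
mad_raw <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("mad_raw: empty input")
  median(abs(values - median(values)))
}

#' Per-plate summary statistics of percent positive
#'
#' Computes the per-plate mean, sample standard deviation, median and raw MAD
#' of percent-positive over the plate's scoring wells. The scoring scope is
#' `"compound_only"` by default: control wells are excluded from the centre
#' and spread so that strong positive controls cannot inflate the MAD (they
#' are still scored later). `"all_non_empty"` includes controls. Wells with
#' `low_cell_flag` are never scoring wells.
#'
#' @param quants well-quantification data.frame for one `(plate_id,
#'   replicate_id)` (see [simulate_summary_plate()] / [quantify_plate()]).
#' @param scope `"compound_only"` or `"all_non_empty"`.
#' @param min_wells minimum scoring wells required (default 8).
#' @return a `plate_stats` object: list with `plate_id`, `replicate_id`,
#'   `n_scoring_wells`, `mean`, `sd`, `median`, `mad`, `scoring_scope`.
#' @export
#' @examples
#' q <- simulate_summary_plate(generate_plate_layout(40, 8, seed = 3),
#'                             sim_config(seed = 3))
#' compute_plate_stats(q)
compute_plate_stats <- function(quants,
                                scope = c("compound_only", "all_non_empty"),
                                min_wells = 8L) {
  scope <- match.arg(scope)
  if (length(unique(quants$plate_id)) > 1L ||
      length(unique(quants$replicate_id)) > 1L) {
    stop("quants must come from a single (plate_id, replicate_id)")
  }
  keep <- !quants$low_cell_flag & quants$role != "empty"
  if (scope == "compound_only") keep <- keep & quants$role == "compound"
  x <- quants$percent_positive[keep]
  if (length(x) < min_wells) {
    stop("only ", length(x), " scoring wells under scope '", scope,
         "'; need at least ", min_wells, call. = FALSE)
  }
  structure(list(plate_id = quants$plate_id[1],
                 replicate_id = quants$replicate_id[1],
                 n_scoring_wells = length(x),
                 mean = mean(x), sd = sd(x),
                 median = median(x), mad = mad_raw(x),
                 scoring_scope = scope),
            class = "plate_stats")
}

#' @export
print.plate_stats <- function(x, ...) {
  cat(sprintf(
    "Plate %s rep %d: %d scoring wells (%s)\n  mean %.4g  sd %.4g  median %.4g  MAD %.4g\n",
    x$plate_id, x$replicate_id, x$n_scoring_wells, x$scoring_scope,
    x$mean, x$sd, x$median, x$mad))
  invisible(x)
}

#' MAD-based Z score
#'
#' `z = (x - median) / (MAD * 1.4826)`, with the plate median and raw MAD
#' from [compute_plate_stats()]. The 1.4826 factor ([MAD_SCALE]) makes the
#' denominator a consistent estimate of the SD under normality, so z reads
#' on the usual z-score scale while staying insensitive to the strong
#' responders a successful screen hopes to contain.
#'
#' A degenerate plate (MAD = 0) has no robust scale; by default this errors.
#' `mad_zero = "sd_fallback"` instead scores `(x - mean) / sd` with a
#' warning.
#'
#' @param x percent-positive value(s); vectorized.
#' @param stats a `plate_stats` object.
#' @param mad_zero `"error"` (default) or `"sd_fallback"`.
#' @return numeric vector of Z scores.
#' @export
#' @examples
#' s <- structure(list(median = 11, mad = 1, mean = 18.6, sd = 17.6),
#'                class = "plate_stats")
#' robust_z(50, s) # (50 - 11) / 1.4826
robust_z <- function(x, stats, mad_zero = c("error", "sd_fallback")) {
  mad_zero <- match.arg(mad_zero)
  if (stats$mad > 0) {
    return((x - stats$median) / (stats$mad * MAD_SCALE))
  }
  if (mad_zero == "error") {
    stop("plate ", stats$plate_id %||% "?", " is degenerate: MAD = 0, ",
         "robust Z undefined (set mad_zero='sd_fallback' to score ",
         "against mean/sd)", call. = FALSE)
  }
  if (is.null(stats$sd) || is.na(stats$sd) || stats$sd <= 0) {
    stop("MAD = 0 and sd fallback unavailable (sd = ", stats$sd, ")")
  }
  warning("plate MAD = 0: falling back to (x - mean)/sd")
  (x - stats$mean) / stats$sd
}

#' Score every well of a plate
#'
#' Attaches the MAD-based Z score to every non-empty well, controls
#' included (controls are scored for QC but are never hit-eligible;
#' [call_hits()] restricts candidacy to compound wells).
#'
#' @param quants well-quantification data.frame for one plate.
#' @param stats the plate's [compute_plate_stats()]; computed here when
#'   omitted.
#' @param scope,min_wells passed to [compute_plate_stats()] when `stats` is
#'   computed here.
#' @param mad_zero passed to [robust_z()].
#' @return `quants` restricted to non-empty wells, with a `z` column.
#' @export
score_plate <- function(quants, stats = NULL,
                        scope = c("compound_only", "all_non_empty"),
                        min_wells = 8L, mad_zero = c("error", "sd_fallback")) {
  if (is.null(stats)) {
    stats <- compute_plate_stats(quants, scope = scope, min_wells = min_wells)
  }
  out <- quants[quants$role != "empty", , drop = FALSE]
  out$z <- robust_z(out$percent_positive, stats, mad_zero = mad_zero)
  rownames(out) <- NULL
  attr(out, "plate_stats") <- stats
  out
}
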