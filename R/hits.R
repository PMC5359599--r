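#' Estimate compound-associated cell death from cell counts
#'
#' Death is read from the loss of nuclear-stain-positive cells relative to
#' the same plate's vehicle wells: `d = clamp(1 - total / median(negative
#' control totals), 0, 1)`. Wells richer than the reference clamp to 0.
#'
#' @param total_cells well cell count(s); vectorized.
#' @param negative_control_totals cell counts of the plate's
#'   negative-control wells; zeros are dropped as unusable.
#' @param min_controls minimum usable control wells (default 4).
#' @return death fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' estimate_cell_death(200, c(500, 480, 520), min_controls = 3) # 0.6
estimate_cell_death <- function(total_cells, negative_control_totals,
                                min_controls = 4L) {
  usable <- negative_control_totals[!is.na(negative_control_totals) &
                                      negative_control_totals > 0]
  if (length(usable) < min_controls) {
    stop("only ", length(usable), " usable negative-control wells ",
         "(total_cells > 0); need at least ", min_controls, call. = FALSE)
  }
  ref <- median(usable)
  pmin(pmax(1 - total_cells / ref, 0), 1)
}

#' Call screen hits by replicate consensus with a cell-death exclusion
#'
#' The screen's decision rule: a compound is a hit when its MAD-based Z score
#' strictly exceeds `z_threshold` in at least `min_replicates` replicate
#' plates, unless it is excluded for toxicity — death fraction strictly above
#' `death_cutoff` in any replicate (each replicate's death is measured
#' against that plate's own negative controls). The average Z over all
#' replicates (sub-threshold ones included) is always computed and ranks the
#' hits, ties broken by compound id.
#'
#' @param scored data.frame of scored wells across replicate plates (rows
#'   from [score_plate()], row-bound over replicates). Needs columns
#'   `compound_id`, `replicate_id`, `role`, `z`, and either `death_fraction`
#'   or (`total_cells` + negative-control rows per plate, from which death is
#'   estimated via [estimate_cell_death()]).
#' @param z_threshold Z cutoff, strict (default 5).
#' @param min_replicates replicates that must pass (default 2).
#' @param death_cutoff death-fraction exclusion cutoff, strict (default 0.60).
#' @return a `screen_hits` object: list with `results` (one row per compound:
#'   `compound_id`, per-replicate `z_rep*` and `death_rep*` columns, `avg_z`,
#'   `max_death_fraction`, `n_replicates`, `n_above_threshold`, `is_hit`,
#'   `is_excluded`, `insufficient_replicates`, `rank` — NA unless a hit) and
#'   `params`. Compounds seen in fewer than `min_replicates` replicates are
#'   flagged, reported, and never hits.
#' @export
#' @examples
#' lay <- lapply(1:2, function(r)
#'   generate_plate_layout(40, 8, plate_id = paste0("P", r),
#'                         replicate_id = r, seed = r))
#' cfg <- sim_config(seed = 9, planted_hits = "C005", hit_effect = 0.4)
#' scored <- do.call(rbind, lapply(lay, function(l)
#'   score_plate(simulate_summary_plate(l, cfg))))
#' call_hits(scored)
call_hits <- function(scored, z_threshold = 5, min_replicates = 2L,
                      death_cutoff = 0.60) {
  need <- c("compound_id", "replicate_id", "role", "z")
  miss <- setdiff(need, names(scored))
  if (length(miss)) stop("scored is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"death_fraction" %in% names(scored)) {
    scored <- add_death_fractions(scored)
  }
  cand <- scored[scored$role == "compound" & !is.na(scored$compound_id), ,
                 drop = FALSE]
  if (nrow(cand) == 0L) stop("no compound wells in scored input")
  reps <- sort(unique(cand$replicate_id))
  ids <- sort(unique(cand$compound_id))

  zmat <- matrix(NA_real_, length(ids), length(reps),
                 dimnames = list(ids, paste0("rep", reps)))
  dmat <- zmat
  ri <- match(cand$replicate_id, reps)
  ci <- match(cand$compound_id, ids)
  dup <- duplicated(cbind(ci, ri))
  if (any(dup)) {
    stop("compound(s) scored more than once in a replicate: ",
         paste(unique(cand$compound_id[dup]), collapse = ", "))
  }
  zmat[cbind(ci, ri)] <- cand$z
  dmat[cbind(ci, ri)] <- cand$death_fraction

  n_reps <- rowSums(!is.na(zmat))
  avg_z <- rowMeans(zmat, na.rm = TRUE)
  n_above <- rowSums(zmat > z_threshold, na.rm = TRUE)
  max_death <- apply(dmat, 1L, function(d) {
    d <- d[!is.na(d)]
    if (length(d)) max(d) else NA_real_
  })
  insufficient <- n_reps < min_replicates
  excluded <- !is.na(max_death) & max_death > death_cutoff
  hit <- n_above >= min_replicates & !excluded & !insufficient

  res <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(reps)) {
    res[[paste0("z_rep", reps[j])]] <- zmat[, j]
    res[[paste0("death_rep", reps[j])]] <- dmat[, j]
  }
  res$avg_z <- avg_z
  res$max_death_fraction <- max_death
  res$n_replicates <- n_reps
  res$n_above_threshold <- n_above
  res$is_hit <- hit
  res$is_excluded <- excluded
  res$insufficient_replicates <- insufficient

  res <- res[order(-res$avg_z, res$compound_id), , drop = FALSE]
  rownames(res) <- NULL
  res$rank <- NA_integer_
  res$rank[res$is_hit] <- seq_len(sum(res$is_hit))

  structure(list(results = res,
                 params = list(z_threshold = z_threshold,
                               min_replicates = as.integer(min_replicates),
                               death_cutoff = death_cutoff),
                 replicates = reps),
            class = "screen_hits")
}

# Death fraction for every scored well, per replicate plate, against that
# plate's own negative controls.
add_death_fractions <- function(scored) {
  if (!"total_cells" %in% names(scored)) {
    stop("scored needs either a death_fraction or a total_cells column")
  }
  scored$death_fraction <- NA_real_
  key <- interaction(scored$plate_id, scored$replicate_id, drop = TRUE)
  for (k in levels(key)) {
    sel <- key == k
    negs <- scored$total_cells[sel & scored$role == "negative_control"]
    scored$death_fraction[sel] <-
      estimate_cell_death(scored$total_cells[sel], negs)
  }
  scored
}

#' Ranked hit report
#'
#' The screen's headline table: hits only, ranked by decreasing average
#' MAD-based Z score, with an optional free-text annotation per compound.
#' The full per-compound table (non-hits, excluded and under-replicated
#' compounds included) is returned alongside.
#'
#' @param results a [call_hits()] object.
#' @param annotations optional named character vector or two-column
#'   data.frame (`compound_id`, `annotation`).
#' @return list of class `hit_report` with `hits` (columns `rank`,
#'   `compound_id`, `avg_z`, `annotation`) and `all_compounds`.
#' @export
hit_report <- function(results, annotations = NULL) {
  stopifnot(inherits(results, "screen_hits"))
  res <- results$results
  hits <- res[res$is_hit, c("rank", "compound_id", "avg_z"), drop = FALSE]
  hits <- hits[order(hits$rank), , drop = FALSE]
  rownames(hits) <- NULL
  ann <- rep(NA_character_, nrow(hits))
  if (!is.null(annotations)) {
    if (is.data.frame(annotations)) {
      annotations <- setNames(as.character(annotations[[2]]),
                              annotations[[1]])
    }
    ann <- unname(annotations[hits$compound_id])
  }
  hits$annotation <- ann
  structure(list(hits = hits, all_compounds = res), class = "hit_report")
}

#' @export
print.hit_report <- function(x, ...) {
  if (nrow(x$hits) == 0L) {
    cat("No hits.\n")
  } else {
    cat(nrow(x$hits), "hit(s), ranked by average MAD-based Z score:\n")
    print.data.frame(x$hits, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.screen_hits <- function(x, ...) {
  res <- x$results
  cat(sprintf(
    "Screen hit calling: %d compounds, %d replicate(s)\n", nrow(res),
    length(x$replicates)))
  cat(sprintf("  rule: Z > %g in >= %d replicates, excluded if death > %g%%\n",
              x$params$z_threshold, x$params$min_replicates,
              100 * x$params$death_cutoff))
  cat(sprintf("  %d hit(s), %d excluded for cell death, %d under-replicated\n",
              sum(res$is_hit), sum(res$is_excluded),
              sum(res$insufficient_replicates)))
  if (any(res$is_hit)) {
    cat("Top hits:\n")
    top <- res[res$is_hit, c("rank", "compound_id", "avg_z",
                             "max_death_fraction")]
    print.data.frame(head(top[order(top$rank), ], 10), digits = 3,
                     row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.screen_hits <- function(object, ...) {
  res <- object$results
  out <- list(n_compounds = nrow(res), n_hits = sum(res$is_hit),
              n_excluded = sum(res$is_excluded),
              n_insufficient = sum(res$insufficient_replicates),
              avg_z_range = range(res$avg_z), params = object$params)
  class(out) <- "summary.screen_hits"
  out
}

#' @export
print.summary.screen_hits <- function(x, ...) {
  cat(sprintf("%d compounds: %d hits, %d excluded, %d under-replicated\n",
              x$n_compounds, x$n_hits, x$n_excluded, x$n_insufficient))
  cat(sprintf("average Z range: %.3g .. %.3g\n",
              x$avg_z_range[1], x$avg_z_range[2]))
  invisible(x)
}

#' @export
as.data.frame.screen_hits <- function(x, ...) x$results

#' Plot per-compound Z scores
#'
#' Scatter of per-replicate (or average) MAD-based Z score by compound
#' index, with the hit threshold drawn as a horizontal line — the standard
#' at-a-glance picture of a screen's separation between the compound bulk
#' and its outliers.
#'
#' @param x a `screen_hits` object.
#' @param which `"avg"` for average Z, or a replicate id.
#' @param ... passed to [plot()].
#' @export
plot.screen_hits <- function(x, which = "avg", ...) {
  res <- x$results
  z <- if (identical(which, "avg")) res$avg_z else res[[paste0("z_rep", which)]]
  if (is.null(z)) stop("no replicate '", which, "' in results")
  col <- ifelse(res$is_hit, "firebrick",
                ifelse(res$is_excluded, "orange", "grey40"))
  plot(seq_along(z), z, pch = 16, cex = 0.6, col = col,
       xlab = "compound (ranked by average Z)",
       ylab = if (identical(which, "avg")) "average MAD-based Z score"
              else paste0("MAD-based Z score (replicate ", which, ")"),
       ...)
  abline(h = x$params$z_threshold, lwd = 1.5)
  legend("topright", pch = 16, col = c("firebrick", "orange", "grey40"),
         legend = c("hit", "excluded (death)", "other"), bty = "n")
  invisible(x)
}
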