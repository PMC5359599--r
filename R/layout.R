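#' Well-label helpers
#'
#' Wells are addressed row-letter + zero-padded column number ("A01" ...
#' "P24" on a 384-well plate). `normalize_well_label()` accepts unpadded
#' labels ("A1") and upper/lower case; malformed labels error.
#'
#' @param labels character vector of well labels.
#' @param n_cols number of plate columns, used to decide zero-padding width.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_well_label(c("A1", "a01", "P24"))
normalize_well_label <- function(labels, n_cols = 24L) {
  labels <- toupper(trimws(as.character(labels)))
  ok <- grepl("^[A-Z][0-9]{1,2}$", labels)
  if (any(!ok)) {
    stop("malformed well label(s): ", paste(labels[!ok], collapse = ", "),
         call. = FALSE)
  }
  row <- substr(labels, 1L, 1L)
  col <- as.integer(substr(labels, 2L, nchar(labels)))
  width <- max(2L, nchar(as.character(n_cols)))
  sprintf("%s%0*d", row, width, col)
}

well_labels_grid <- function(n_rows, n_cols) {
  if (n_rows > 26L) stop("plates with more than 26 rows are not supported")
  rows <- LETTERS[seq_len(n_rows)]
  width <- max(2L, nchar(as.character(n_cols)))
  as.vector(t(outer(rows, seq_len(n_cols),
                    function(r, c) sprintf("%s%0*d", r, width, c))))
}

WELL_ROLES <- c("negative_control", "positive_control", "compound", "empty")

#' Generate a plate layout by seeded random placement
#'
#' Assigns compound and control wells to random positions on an
#' `n_rows x n_cols` plate (default 384-well, 16 x 24). Placement is a seeded
#' shuffle, so a fixed seed gives a byte-identical layout; replicate plates
#' are meant to be generated independently (same compounds, different seed),
#' mirroring how replicate assay plates are stamped from one compound
#' collection.
#'
#' @param n_compounds number of compound wells.
#' @param controls_per_role wells per control role (negative = vehicle,
#'   positive = droplet-inducing reference); minimum 4 of each, needed
#'   downstream as the cell-death reference and positivity calibration pool.
#' @param plate_id plate identifier string.
#' @param replicate_id positive integer replicate index.
#' @param n_rows,n_cols plate geometry.
#' @param compound_ids optional character vector of length `n_compounds`;
#'   default `"C001"`, `"C002"`, ... Each compound appears once per plate.
#' @param seed integer seed controlling placement.
#' @return A `plate_layout`: data.frame with columns `well`, `role`,
#'   `compound_id` (NA outside compound wells) and attributes `plate_id`,
#'   `replicate_id`, `n_rows`, `n_cols`.
#' @export
#' @examples
#' lay <- generate_plate_layout(320, controls_per_role = 16, seed = 7)
#' table(lay$role)
generate_plate_layout <- function(n_compounds, controls_per_role = 16L,
                                  plate_id = "P1", replicate_id = 1L,
                                  n_rows = 16L, n_cols = 24L,
                                  compound_ids = NULL, seed = 1L) {
  n_compounds <- as.integer(n_compounds)
  controls_per_role <- as.integer(controls_per_role)
  if (controls_per_role < 4L) {
    stop("controls_per_role must be at least 4 per role (got ",
         controls_per_role, "): control wells anchor the cell-death ",
         "reference and positivity calibration", call. = FALSE)
  }
  n_wells <- n_rows * n_cols
  n_used <- n_compounds + 2L * controls_per_role
  if (n_used > n_wells) {
    stop("capacity exceeded: ", n_compounds, " compounds + 2x",
         controls_per_role, " controls = ", n_used, " wells > ",
         n_wells, " available (", n_rows, "x", n_cols, ")", call. = FALSE)
  }
  if (is.null(compound_ids)) {
    compound_ids <- sprintf("C%03d", seq_len(n_compounds))
  }
  compound_ids <- as.character(compound_ids)
  if (length(compound_ids) != n_compounds) {
    stop("compound_ids must have length n_compounds")
  }
  if (anyDuplicated(compound_ids)) {
    stop("compound_ids must be unique within a plate")
  }

  wells <- well_labels_grid(n_rows, n_cols)
  shuffled <- with_seed(seed, sample(wells, n_wells, replace = FALSE))
  role <- rep("empty", n_wells)
  cid <- rep(NA_character_, n_wells)
  idx <- seq_len(n_compounds)
  role[idx] <- "compound"
  cid[idx] <- compound_ids
  role[n_compounds + seq_len(controls_per_role)] <- "negative_control"
  role[n_compounds + controls_per_role + seq_len(controls_per_role)] <-
    "positive_control"

  out <- data.frame(well = shuffled, role = role, compound_id = cid,
                    stringsAsFactors = FALSE)
  out <- out[order(out$well), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            plate_id = as.character(plate_id),
            replicate_id = as.integer(replicate_id),
            n_rows = n_rows, n_cols = n_cols,
            class = c("plate_layout", "data.frame"))
}

#' Validate a plate layout
#'
#' Checks the structural invariants every downstream stage assumes: a full
#' grid of unique wells, known roles, a compound id on (exactly) compound
#' wells, each compound at most once per plate, and at least 4 wells of each
#' control role.
#'
#' @param layout a `plate_layout` (or equivalent data.frame with attributes).
#' @return `layout`, invisibly; errors describe the first violation found.
#' @export
validate_plate_layout <- function(layout) {
  need <- c("well", "role", "compound_id")
  if (!all(need %in% names(layout))) {
    stop("layout must have columns ", paste(need, collapse = ", "))
  }
  n_rows <- attr(layout, "n_rows") %||% 16L
  n_cols <- attr(layout, "n_cols") %||% 24L
  if (nrow(layout) != n_rows * n_cols) {
    stop("layout has ", nrow(layout), " wells; expected ", n_rows * n_cols)
  }
  if (anyDuplicated(layout$well)) {
    stop("duplicate well label(s): ",
         paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(layout$role), WELL_ROLES)
  if (length(bad_role)) {
    stop("unknown role(s) ", paste(bad_role, collapse = ", "),
         "; allowed: ", paste(WELL_ROLES, collapse = ", "))
  }
  is_cmp <- layout$role == "compound"
  if (any(is_cmp & is.na(layout$compound_id))) {
    stop("compound wells without compound_id: ",
         paste(layout$well[is_cmp & is.na(layout$compound_id)], collapse = ", "))
  }
  cids <- layout$compound_id[is_cmp]
  if (anyDuplicated(cids)) {
    stop("compound_id appears more than once per plate: ",
         paste(unique(cids[duplicated(cids)]), collapse = ", "))
  }
  for (r in c("negative_control", "positive_control")) {
    if (sum(layout$role == r) < 4L) {
      stop("fewer than 4 ", r, " wells (", sum(layout$role == r), ")")
    }
  }
  invisible(layout)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("Plate layout '%s' replicate %d (%d x %d)\n",
              attr(x, "plate_id"), attr(x, "replicate_id"),
              attr(x, "n_rows"), attr(x, "n_cols")))
  tab <- table(factor(x$role, levels = WELL_ROLES))
  cat(paste(sprintf("  %-17s %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
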