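# Tabular interchange is CSV throughout; images are single-channel 16-bit
# grayscale TIFFs; configs are YAML. Floating-point CSV output is written at
# 6 significant digits so that fixed-seed reruns are byte-identical.

#' Read a plate map CSV
#'
#' Expects the header `plate_id,replicate_id,well,role,compound_id`; one row
#' per assigned well, one or more plates per file. Well labels are
#' normalized (`A1` and `A01` are the same well), the role vocabulary is
#' enforced, and wells absent from the file become `empty`. Errors cite the
#' offending file row.
#'
#' @param path CSV file path.
#' @param n_rows,n_cols plate geometry assumed for every plate in the file.
#' @return named list of `plate_layout` objects, keyed
#'   `"<plate_id>:<replicate_id>"`.
#' @export
read_plate_map <- function(path, n_rows = 16L, n_cols = 24L) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("plate_id", "replicate_id", "well", "role", "compound_id")
  if (!all(need %in% names(raw))) {
    stop("plate map must have columns ", paste(need, collapse = ","),
         "; got ", paste(names(raw), collapse = ","))
  }
  rowno <- seq_len(nrow(raw)) + 1L   # +1 for the header line
  bad_role <- !(raw$role %in% WELL_ROLES)
  if (any(bad_role)) {
    stop("row ", rowno[which(bad_role)[1]], ": unknown role '",
         raw$role[which(bad_role)[1]], "'; allowed: ",
         paste(WELL_ROLES, collapse = ", "), call. = FALSE)
  }
  well <- tryCatch(normalize_well_label(raw$well, n_cols),
                   error = function(e) {
                     stop("malformed well label in plate map: ",
                          conditionMessage(e), call. = FALSE)
                   })
  raw$well <- well
  raw$compound_id[!nzchar(trimws(raw$compound_id))] <- NA_character_
  key <- paste(raw$plate_id, raw$replicate_id, sep = ":")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    d <- duplicated(raw$well[sel])
    if (any(d)) {
      stop("row ", rowno[sel][which(d)[1]], ": duplicate well ",
           raw$well[sel][which(d)[1]], " in plate ", k,
           " (labels are normalized, e.g. A1 = A01)", call. = FALSE)
    }
    grid <- well_labels_grid(n_rows, n_cols)
    unknown <- setdiff(raw$well[sel], grid)
    if (length(unknown)) {
      stop("well(s) outside the ", n_rows, "x", n_cols, " plate: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    lay <- data.frame(well = grid, role = "empty",
                      compound_id = NA_character_, stringsAsFactors = FALSE)
    idx <- match(raw$well[sel], grid)
    lay$role[idx] <- raw$role[sel]
    lay$compound_id[idx] <- raw$compound_id[sel]
    lay <- structure(lay,
                     plate_id = raw$plate_id[sel][1],
                     replicate_id = as.integer(raw$replicate_id[sel][1]),
                     n_rows = n_rows, n_cols = n_cols,
                     class = c("plate_layout", "data.frame"))
    validate_plate_layout(lay)
    out[[k]] <- lay
  }
  out
}

#' Write plate layouts to a plate map CSV
#'
#' Inverse of [read_plate_map()]: writes every assigned (non-empty) well.
#'
#' @param layouts a `plate_layout` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layouts, path) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  rows <- lapply(layouts, function(l) {
    keep <- l$role != "empty"
    data.frame(plate_id = attr(l, "plate_id"),
               replicate_id = attr(l, "replicate_id"),
               well = l$well[keep], role = l$role[keep],
               compound_id = ifelse(is.na(l$compound_id[keep]), "",
                                    l$compound_id[keep]),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# CSV writer with numeric columns at 6 significant digits (documented output
# precision; makes fixed-seed byte-identity well-defined).
write_csv6 <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write well-quantification tables
#'
#' The quant CSV schema:
#' `plate_id,replicate_id,well,role,compound_id,total_cells,positive_cells,`
#' `percent_positive,low_cell_flag`. [read_quants()] restores column types;
#' extra columns (e.g. `z` on scored tables) pass through.
#'
#' @param quants quantification data.frame.
#' @param path CSV path.
#' @return [read_quants()]: the data.frame; [write_quants()]: `path`,
#'   invisibly.
#' @export
write_quants <- function(quants, path) {
  q <- quants
  q$compound_id[is.na(q$compound_id)] <- ""
  write_csv6(q, path)
}

#' @rdname write_quants
#' @export
read_quants <- function(path) {
  q <- read.csv(path, stringsAsFactors = FALSE)
  q$compound_id <- as.character(q$compound_id)
  q$compound_id[!nzchar(trimws(q$compound_id)) | is.na(q$compound_id)] <-
    NA_character_
  q$low_cell_flag <- as.logical(q$low_cell_flag)
  q
}

# filename convention shared by writer, reader and the CLI
CHANNEL_FILE_NAMES <- c(nuclear = "hoechst", lipid = "bodipy")

#' Write / read a well image as two 16-bit grayscale TIFFs
#'
#' Files are named `<plate_id>_<well>_<channel>.tiff` with channel `hoechst`
#' (nuclear) or `bodipy` (lipid), the stains they record.
#'
#' @param image a `well_image`.
#' @param dir directory for the TIFF pair.
#' @param plate_id,well identify the image pair to read.
#' @return [write_well_image()]: the two paths, invisibly;
#'   [read_well_image()]: a `well_image`.
#' @export
write_well_image <- function(image, dir) {
  validate_well_image(image)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(2)
  for (i in seq_along(CHANNEL_FILE_NAMES)) {
    ch <- names(CHANNEL_FILE_NAMES)[i]
    paths[i] <- file.path(dir, sprintf("%s_%s_%s.tiff", image$plate_id,
                                       image$well, CHANNEL_FILE_NAMES[[ch]]))
    tiff::writeTIFF(image$channels[[ch]] / 65535, paths[i],
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(paths)
}

#' @rdname write_well_image
#' @export
read_well_image <- function(dir, plate_id, well) {
  channels <- list()
  for (ch in names(CHANNEL_FILE_NAMES)) {
    p <- file.path(dir, sprintf("%s_%s_%s.tiff", plate_id, well,
                                CHANNEL_FILE_NAMES[[ch]]))
    if (!file.exists(p)) stop("missing image file: ", p)
    channels[[ch]] <- round(tiff::readTIFF(p) * 65535)
  }
  structure(list(well = well, plate_id = plate_id, bit_depth = 16L,
                 channels = channels),
            class = "well_image")
}

# --- minimal leveled run log ------------------------------------------------

LOG_LEVELS <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

log_line <- function(state, level, ...) {
  if (is.null(state)) return(invisible(NULL))
  if (LOG_LEVELS[[level]] < LOG_LEVELS[[state$level]]) return(invisible(NULL))
  msg <- sprintf("[%s] %s %s", toupper(level),
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"), paste0(...))
  cat(msg, "\n", file = state$path, append = TRUE, sep = "")
  if (isTRUE(state$echo)) message(msg)
  invisible(NULL)
}

open_log <- function(path, level = "info", echo = FALSE) {
  cat("", file = path)  # truncate
  list(path = path, level = level, echo = echo)
}
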