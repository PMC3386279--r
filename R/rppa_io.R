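# Canonical spot-table columns, in canonical order.
SPOT_COLUMNS <- c("array_id", "block", "row", "col",
                  "sample_id", "dilution_step", "replicate_id", "intensity")

#' Validate a spot-level RPPA table
#'
#' Checks the structural invariants of a spot table: required columns,
#' unique `(array_id, block, row, col)` coordinates, contiguous dilution
#' steps within each series, and nonnegative finite intensities
#' (missing intensities are allowed and mark flagged spots).
#'
#' @param spots A data frame with the canonical spot columns.
#' @return The validated data frame (invisibly unchanged), with columns
#'   coerced to their canonical types.
#' @export
validate_spot_table <- function(spots) {
  stopifnot(is.data.frame(spots))
  missing_cols <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing_cols)) {
    stop("spot table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  spots <- as.data.frame(spots)[SPOT_COLUMNS]
  for (col in c("block", "row", "col", "dilution_step", "replicate_id")) {
    spots[[col]] <- as.integer(spots[[col]])
    if (anyNA(spots[[col]]) || any(spots[[col]] < 1L)) {
      stop("column '", col, "' must contain positive integers", call. = FALSE)
    }
  }
  spots$array_id <- as.character(spots$array_id)
  spots$sample_id <- as.character(spots$sample_id)
  spots$intensity <- as.numeric(spots$intensity)
  ok <- is.na(spots$intensity) | (is.finite(spots$intensity) & spots$intensity >= 0)
  if (!all(ok)) {
    stop("negative or non-finite intensity at row(s): ",
         paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(spots$array_id, spots$block, spots$row, spots$col, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- spots[duplicated(key) | duplicated(key, fromLast = TRUE), , drop = FALSE]
    stop("duplicate spot coordinates (array_id, block, row, col): ",
         paste(unique(paste0("(", dup$array_id, ",", dup$block, ",",
                             dup$row, ",", dup$col, ")")), collapse = " "),
         call. = FALSE)
  }
  # dilution steps within a series must be a contiguous run 1..D
  series <- paste(spots$array_id, spots$sample_id, spots$replicate_id, sep = "\r")
  bad <- tapply(spots$dilution_step, series, function(d) {
    d <- sort(unique(d))
    !identical(d, seq_len(max(d)))
  })
  if (any(bad)) {
    stop("non-contiguous dilution steps in series: ",
         paste(utils::head(gsub("\r", "/", names(bad)[bad]), 3L), collapse = ", "),
         call. = FALSE)
  }
  spots
}

#' Read a spot-level RPPA table
#'
#' Reads a delimited export of spot intensities with array layout
#' (block, row, column), sample identity, dilution step and replicate
#' index. Column names may be remapped through `column_map` to accept
#' arbitrary scanner-export dialects.
#'
#' @param path Path to a comma- or tab-delimited text file with a header.
#' @param format_hint `"tab"` or `"csv"`; the delimiter of the file.
#' @param column_map Named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(sample_id = "Sample", intensity = "Mean.Net")`. Unmapped
#'   canonical names are looked up verbatim.
#' @return A validated spot table (data frame) with the canonical columns
#'   `array_id, block, row, col, sample_id, dilution_step, replicate_id,
#'   intensity`.
#' @seealso [write_spot_table()] for the inverse operation.
#' @export
read_spot_table <- function(path, format_hint = c("tab", "csv"),
                            column_map = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format_hint == "tab") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- stats::setNames(SPOT_COLUMNS, SPOT_COLUMNS)
  if (!is.null(column_map)) wanted[names(column_map)] <- column_map
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols)) {
    stop("input file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[unname(wanted)]
  names(out) <- SPOT_COLUMNS
  validate_spot_table(out)
}

#' Write a spot table in the canonical dialect
#'
#' Writes a tab-delimited file with the canonical column names; reading
#' it back with [read_spot_table()] reproduces the input exactly.
#'
#' @param spots A validated spot table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  spots <- validate_spot_table(spots)
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Describe a serial-dilution design
#'
#' A dilution design records the dilution factors of the printed steps
#' (step 1 = undiluted), the starting concentration and the dilution
#' fold. Factors default to `fold^-(k-1)`.
#'
#' @param n_dilutions Number of dilution steps.
#' @param fold Dilution fold between consecutive steps (default 2).
#' @param starting_concentration Concentration of step 1 in mg/ml.
#' @param dilution_factors Optional explicit factors in (0, 1], strictly
#'   decreasing from 1; overrides `n_dilutions`/`fold` generation.
#' @return An object of class `dilution_design`.
#' @export
dilution_design <- function(n_dilutions = 15L, fold = 2,
                            starting_concentration = 1,
                            dilution_factors = NULL) {
  if (is.null(dilution_factors)) {
    stopifnot(n_dilutions >= 1L, fold > 1)
    dilution_factors <- fold^(-(seq_len(n_dilutions) - 1L))
  }
  if (any(dilution_factors <= 0) || any(dilution_factors > 1)) {
    stop("dilution factors must lie in (0, 1]", call. = FALSE)
  }
  if (length(dilution_factors) > 1L && any(diff(dilution_factors) >= 0)) {
    stop("dilution factors must be strictly decreasing", call. = FALSE)
  }
  stopifnot(starting_concentration > 0)
  structure(
    list(dilution_factors = dilution_factors,
         starting_concentration = starting_concentration,
         fold = fold),
    class = "dilution_design")
}

#' @export
print.dilution_design <- function(x, ...) {
  cat(sprintf("Dilution design: %d steps, %.3g-fold, starting at %g mg/ml\n",
              length(x$dilution_factors), x$fold, x$starting_concentration))
  invisible(x)
}

#' Centered log-scale dilution covariates
#'
#' Maps dilution factors to the log scale (base = the dilution fold) and
#' centers them on their median, so that for a 2-fold series the
#' covariates are consecutive integers and the most concentrated step
#' carries the largest value: factors `{1, 1/2, 1/4, 1/8, 1/16}` map to
#' `{2, 1, 0, -1, -2}`.
#'
#' @param design A [dilution_design()].
#' @return Numeric vector of centered covariates, one per dilution step
#'   (step 1 first).
#' @export
center_dilution_covariates <- function(design) {
  stopifnot(inherits(design, "dilution_design"))
  f <- design$dilution_factors
  if (any(f <= 0)) stop("non-positive dilution factor", call. = FALSE)
  d <- log(f, base = design$fold)
  d - stats::median(d)
}

#' Assemble an antibody array with aligned control channels
#'
#' Attaches, spot-for-spot, the intensities of an optional negative
#' control array (no primary antibody; `ctrl`) and an optional
#' total-protein-stain array (`sypro`) to the antibody spot table, by
#' matching the `(block, row, col)` layout coordinates.
#'
#' @param antibody Spot table of the antibody-stained array.
#' @param ctrl,sypro Optional spot tables of the paired control arrays,
#'   sharing the antibody array's layout. `NULL` when the channel was
#'   not measured.
#' @return An object of class `array_set`: a list with the antibody spot
#'   table and numeric vectors `ctrl` and `sypro` aligned to its rows
#'   (or `NULL` for absent channels).
#' @export
align_array_set <- function(antibody, ctrl = NULL, sypro = NULL) {
  antibody <- validate_spot_table(antibody)
  key <- function(df) paste(df$block, df$row, df$col, sep = "\r")
  pull_channel <- function(channel, name) {
    if (is.null(channel)) return(NULL)
    channel <- validate_spot_table(channel)
    idx <- match(key(antibody), key(channel))
    if (anyNA(idx)) {
      miss <- antibody[is.na(idx), , drop = FALSE][1L, ]
      stop(sprintf("channel '%s' lacks intensity at coordinate (%d,%d,%d)",
                   name, miss$block, miss$row, miss$col), call. = FALSE)
    }
    channel$intensity[idx]
  }
  structure(
    list(antibody = antibody,
         ctrl = pull_channel(ctrl, "ctrl"),
         sypro = pull_channel(sypro, "sypro")),
    class = "array_set")
}

#' @export
print.array_set <- function(x, ...) {
  cat(sprintf("RPPA array set: %d antibody spots; ctrl: %s; sypro: %s\n",
              nrow(x$antibody),
              if (is.null(x$ctrl)) "absent" else "aligned",
              if (is.null(x$sypro)) "absent" else "aligned"))
  invisible(x)
}

# Internal: series identifier (a sample with all its dilution steps of
# one replicate deposit) for each spot of an array set.
series_ids <- function(spots) {
  paste(spots$sample_id, spots$replicate_id, sep = ".r")
}
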