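#' Read cell outlines
#'
#' Reads manually traced 2D cell outlines (closed polygons, pixel
#' coordinates) from either a plain CSV vertex table or an ImageJ ROI-zip
#' archive, and validates each polygon. Malformed records (fewer than three
#' vertices, self-intersecting, zero area) are rejected individually with a
#' logged reason; valid records are returned as a tibble with one row per
#' cell.
#'
#' The CSV dialect has one row per vertex with columns
#' `cell_id, embryo_id, plane, structure, domain, x, y` (plus an optional
#' `somite_index`), UTF-8, header required. Coordinates are 0-based pixels
#' with y increasing downward. The ROI-zip dialect stores only polygons and
#' names (ImageJ polygon ROIs); contextual fields are filled from the
#' `plane`, `embryo_id` and `structure` arguments.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"roi_zip"`.
#' @param plane,embryo_id,structure Context applied to ROI-zip records,
#'   which carry no metadata of their own. Ignored for CSV input.
#' @return A tibble with columns `cell_id`, `embryo_id`, `plane`,
#'   `structure`, `domain`, `somite_index` and a `vertices` list-column of
#'   two-column coordinate matrices. Rejected records are attached as the
#'   `"rejected"` attribute (a tibble of `cell_id`, `reason`).
#' @seealso [write_outlines()], [read_timelapse()]
#' @export
read_outlines <- function(path, dialect = c("csv", "roi_zip"),
                          plane = "sagittal", embryo_id = "unknown",
                          structure = "psm") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    needed <- c("cell_id", "embryo_id", "plane", "structure", "domain", "x", "y")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols)) {
      abort(sprintf("Outline CSV is missing columns: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    if (!"somite_index" %in% names(df)) df$somite_index <- NA_integer_
    recs <- split(df, factor(df$cell_id, levels = unique(df$cell_id)))
    raw <- lapply(recs, function(d) {
      list(cell_id = d$cell_id[1], embryo_id = d$embryo_id[1],
           plane = d$plane[1], structure = d$structure[1],
           domain = d$domain[1],
           somite_index = suppressWarnings(as.integer(d$somite_index[1])),
           vertices = cbind(x = as.double(d$x), y = as.double(d$y)))
    })
  } else {
    exdir <- tempfile("roizip")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    files <- unzip(path, exdir = exdir)
    files <- files[grepl("\\.roi$", files)]
    raw <- lapply(files, function(f) {
      list(cell_id = sub("\\.roi$", "", basename(f)), embryo_id = embryo_id,
           plane = plane, structure = structure, domain = "unassigned",
           somite_index = NA_integer_,
           vertices = decode_imagej_roi(readBin(f, "raw", file.size(f))))
    })
  }
  build_outlines(raw)
}

# Validate raw outline records and assemble the outline tibble; rejected
# records are reported (message per record) and attached as an attribute.
build_outlines <- function(raw) {
  reasons <- character(0); bad_ids <- character(0)
  keep <- logical(length(raw))
  for (i in seq_along(raw)) {
    r <- raw[[i]]
    v <- close_polygon(r$vertices)
    reason <- NULL
    if (anyNA(v)) {
      reason <- "non-numeric or missing coordinates"
    } else if (nrow(v) < 3) {
      reason <- sprintf("only %d vertices (need >= 3)", nrow(v))
    } else if (!is_simple_polygon(v)) {
      reason <- "self-intersecting polygon"
    } else if (polygon_area(v) <= 0) {
      reason <- "zero-area polygon"
    } else if (identical(r$structure, "somite") && is.na(r$somite_index)) {
      reason <- "somite cell without somite_index"
    } else if (!identical(r$structure, "somite") && !is.na(r$somite_index)) {
      reason <- "somite_index on a non-somite cell"
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      bad_ids <- c(bad_ids, r$cell_id)
      reasons <- c(reasons, reason)
      inform(sprintf("Rejected outline '%s': %s", r$cell_id, reason))
    }
  }
  ok <- unname(raw[keep])
  ids <- vapply(ok, `[[`, "", "cell_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate cell_id in file: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble(
    cell_id = ids,
    embryo_id = vapply(ok, `[[`, "", "embryo_id"),
    plane = vapply(ok, `[[`, "", "plane"),
    structure = vapply(ok, `[[`, "", "structure"),
    domain = vapply(ok, `[[`, "", "domain"),
    somite_index = vapply(ok, function(r) as.integer(r$somite_index), 1L),
    vertices = lapply(ok, function(r) close_polygon(r$vertices))
  )
  attr(out, "rejected") <- tibble(cell_id = bad_ids, reason = reasons)
  out
}

#' Write cell outlines
#'
#' Writes an outline tibble (as returned by [read_outlines()] or
#' [generate_outline_field()]) to the CSV vertex dialect or to an ImageJ
#' ROI-zip archive. CSV preserves coordinates at full double precision; the
#' ImageJ ROI format stores 16-bit integer pixel coordinates, so non-integer
#' vertices are rounded (with a warning).
#'
#' @param outlines Outline tibble with a `vertices` list-column.
#' @param path Output file path.
#' @param dialect `"csv"` or `"roi_zip"`.
#' @return `path`, invisibly.
#' @export
write_outlines <- function(outlines, path, dialect = c("csv", "roi_zip")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    rows <- purrr::pmap(outlines, function(cell_id, embryo_id, plane, structure,
                                           domain, somite_index, vertices, ...) {
      data.frame(cell_id = cell_id, embryo_id = embryo_id, plane = plane,
                 structure = structure, domain = domain,
                 somite_index = somite_index,
                 x = sprintf("%.17g", vertices[, 1]),
                 y = sprintf("%.17g", vertices[, 2]))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  } else {
    entries <- lapply(outlines$vertices, encode_imagej_roi)
    names(entries) <- paste0(outlines$cell_id, ".roi")
    zip_write_stored(path, entries)
  }
  invisible(path)
}

#' Read a time-lapse distance table
#'
#' Reads per-timepoint measurements from a DiI time-lapse experiment: total
#' segmented-mesoderm length, distance from the DiI front to the last somite
#' border, PSM length, and cumulative somite count. Records are returned
#' sorted by time; a decreasing somite count is a hard error naming the
#' offending row, since somites never un-form.
#'
#' @param path CSV file with columns `t_minutes`, `segmented_length_um`,
#'   `dii_front_to_border_um`, `psm_length_um`, `somite_count`.
#' @return A tibble of timepoint records sorted by `t_minutes`.
#' @seealso [fit_position_time()], [somite_interval()]
#' @export
read_timelapse <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t_minutes", "segmented_length_um", "dii_front_to_border_um",
              "psm_length_um", "somite_count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Time-lapse table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- df[order(df$t_minutes), needed]
  validate_timelapse(as_tibble(df))
}

validate_timelapse <- function(df) {
  if (any(diff(df$t_minutes) <= 0)) {
    abort("t_minutes must be strictly increasing.")
  }
  dec <- which(diff(df$somite_count) < 0)
  if (length(dec)) {
    abort(sprintf("somite_count decreases at row %d (t = %g min).",
                  dec[1] + 1L, df$t_minutes[dec[1] + 1L]))
  }
  if (any(df$t_minutes < 0) || any(df$psm_length_um <= 0) ||
      any(df$dii_front_to_border_um < 0) || any(df$segmented_length_um < 0)) {
    abort("Time-lapse distances must be non-negative and PSM length positive.")
  }
  df
}

#' Write a time-lapse distance table
#'
#' @param track Timepoint tibble (see [read_timelapse()] for columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(track, path) {
  out <- as.data.frame(track)
  for (col in c("t_minutes", "segmented_length_um", "dii_front_to_border_um",
                "psm_length_um")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Assembles the pipeline's run configuration, optionally layered over a
#' YAML file. Recognised settings: `pixel_size_um` (physical calibration,
#' default 1), `ar_method` (`"ellipse"` for the second-moment fitted-ellipse
#' aspect ratio, `"feret"` for the max/min caliper ratio), `log_ar` (fit
#' profiles on log AR), `band_depth_px` (surface band depth; `NULL` means
#' the median cell minor-axis length), `dorsal_up`, `medial_side`,
#' `anterior_side` (anatomical orientation of the section in image
#' coordinates), and `intensity_stat` (`"mean"` or `"sum"` for apical/basal
#' summaries).
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @param ... Named settings overriding both defaults and file entries.
#' @return A named list of settings.
#' @export
psm_config <- function(path = NULL, ...) {
  cfg <- list(pixel_size_um = 1, ar_method = "ellipse", log_ar = FALSE,
              band_depth_px = NULL, dorsal_up = TRUE, medial_side = "left",
              anterior_side = "right", intensity_stat = "mean")
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}
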