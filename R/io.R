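#' Write regional TACs to a CSV table
#'
#' Format: UTF-8 CSV with header
#' `region,frame_start_min,frame_duration_min,activity_kbq_per_ml`, one
#' row per region x frame. Values are written to full double precision.
#'
#' @param tacs A list of [region_tac()] objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path) {
  if (inherits(tacs, "region_tac")) tacs <- list(tacs)
  rows <- lapply(tacs, function(tac) {
    data.frame(
      region = tac$region,
      frame_start_min = tac$schedule$start,
      frame_duration_min = tac$schedule$duration,
      activity_kbq_per_ml = tac$frame_means
    )
  })
  df <- do.call(rbind, rows)
  write_csv_full(df, path)
  invisible(path)
}

# CSV writer preserving full double precision (15 significant digits).
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read regional TACs from a CSV table
#'
#' Inverse of [write_tac_table()]. Frame rows of each region must form a
#' valid contiguous schedule; a gap or overlap raises a schema error
#' naming the region, and non-numeric cells raise a parse error with the
#' offending row number. Region names outside [roi_names()] are accepted
#' with a warning.
#'
#' @param path CSV file path.
#' @return Named list of [region_tac()] objects, in file order.
#' @export
read_tac_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("region", "frame_start_min", "frame_duration_min",
            "activity_kbq_per_ml")
  if (!identical(names(df), need)) {
    stop("TAC table header must be exactly: ", paste(need, collapse = ","))
  }
  for (col in need[-1L]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   col, bad[1L]))
    }
    df[[col]] <- v
  }
  regions <- unique(df$region)
  unknown <- setdiff(regions, roi_names())
  if (length(unknown)) {
    warning("unknown region name(s): ", paste(unknown, collapse = ", "))
  }
  out <- list()
  for (r in regions) {
    sub <- df[df$region == r, , drop = FALSE]
    sched <- tryCatch(
      frame_schedule(sub$frame_start_min, sub$frame_duration_min),
      error = function(e) {
        stop(sprintf("schema error in region '%s': %s", r, conditionMessage(e)),
             call. = FALSE)
      }
    )
    out[[r]] <- region_tac(r, sched, sub$activity_kbq_per_ml)
  }
  out
}

#' Write blood data to a sectioned CSV
#'
#' Single CSV with columns `kind,time_min,value`; `kind` is one of
#' `plasma` (kBq/mL), `whole_blood` (kBq/mL), `parent_fraction`
#' (fraction) or `fp_replicate` (fraction, `time_min` empty).
#'
#' @param blood A [blood_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blood_table <- function(blood, path) {
  stopifnot(inherits(blood, "blood_data"))
  parts <- list(
    data.frame(kind = "plasma", time_min = blood$plasma$times,
               value = blood$plasma$values)
  )
  if (!is.null(blood$whole_blood)) {
    parts <- c(parts, list(
      data.frame(kind = "whole_blood", time_min = blood$whole_blood$times,
                 value = blood$whole_blood$values)))
  }
  parts <- c(parts, list(
    data.frame(kind = "parent_fraction",
               time_min = blood$parent_samples$time_min,
               value = blood$parent_samples$parent_fraction),
    data.frame(kind = "fp_replicate", time_min = NA_real_,
               value = blood$fp_triplicate)
  ))
  write_csv_full(do.call(rbind, parts), path)
  invisible(path)
}

#' Read blood data from a sectioned CSV
#'
#' Inverse of [write_blood_table()].
#'
#' @param path CSV file path.
#' @return A [blood_data()].
#' @export
read_blood_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("kind", "time_min", "value"))) {
    stop("blood table header must be exactly: kind,time_min,value")
  }
  pick <- function(kind) df[df$kind == kind, , drop = FALSE]
  pl <- pick("plasma")
  if (nrow(pl) < 2L) stop("blood table must contain at least 2 plasma rows")
  wb <- pick("whole_blood")
  pf <- pick("parent_fraction")
  fp <- pick("fp_replicate")
  blood_data(
    plasma = sampled_curve(pl$time_min, pl$value, label = "plasma"),
    whole_blood = if (nrow(wb)) {
      sampled_curve(wb$time_min, wb$value, label = "whole blood")
    },
    parent_samples = data.frame(time_min = pf$time_min,
                                parent_fraction = pf$value),
    fp_triplicate = fp$value
  )
}

#' Read a regional V_T table with free-fraction metadata
#'
#' The V_T table is a CSV with a `region` column and one column per scan
#' condition; missing cells are encoded `n.d.`. The companion metadata
#' CSV has columns `condition`, `fp` and `fp_note` carrying each
#' condition's plasma free fraction (empty `fp` with an explanatory note
#' when only a range is known).
#'
#' @param path V_T table CSV path.
#' @param fp_path Free-fraction metadata CSV path (optional).
#' @return List of class `regional_vt_table` with `vt` (data frame, NA
#'   for missing cells), `conditions` and `fp` (metadata data frame or
#'   NULL).
#' @export
read_vt_table <- function(path, fp_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "region") stop("first column must be 'region'")
  for (j in seq(2L, ncol(df))) {
    v <- df[[j]]
    v[v %in% c("n.d.", "nd", "NA", "")] <- NA
    df[[j]] <- suppressWarnings(as.numeric(v))
  }
  fp <- NULL
  if (!is.null(fp_path)) {
    fp <- utils::read.csv(fp_path, stringsAsFactors = FALSE)
    if (!all(c("condition", "fp") %in% names(fp))) {
      stop("fp metadata must have columns 'condition' and 'fp'")
    }
  }
  structure(list(vt = df, conditions = names(df)[-1L], fp = fp),
            class = "regional_vt_table")
}

#' Extract one condition column as a named V_T vector
#'
#' @param table A `regional_vt_table` (see [read_vt_table()]).
#' @param condition Condition column name.
#' @return Named numeric vector of V_T, NA for missing cells.
#' @export
vt_column <- function(table, condition) {
  stopifnot(inherits(table, "regional_vt_table"))
  if (!condition %in% table$conditions) {
    stop("unknown condition: ", condition)
  }
  stats::setNames(table$vt[[condition]], table$vt$region)
}

#' The packaged published V_T table fixture
#'
#' Regional V_T values (mL/cm^3) for the two GSK-3 radiotracers in rhesus
#' macaques, transcribed from the published table: 13 regions x 8 scan
#' conditions (two C-11 baselines, three C-11 blocking doses, one F-18
#' baseline, two F-18 blocking scans), with exactly one missing cell
#' (amygdala, 0.1 mg/kg, animal 2). C-11 values come from 2T fits to the
#' first 60 min of data; F-18 values from 1T fits to the full 120 min.
#' The companion metadata carries the printed per-condition plasma free
#' fractions; the C-11 blocking f_P is known only as the range 0.07-0.10
#' and is left empty with a note.
#'
#' @return A `regional_vt_table` (see [read_vt_table()]).
#' @export
load_table2_fixture <- function() {
  read_vt_table(
    system.file("extdata", "table2_vt.csv", package = "petkin",
                mustWork = TRUE),
    system.file("extdata", "table2_fp.csv", package = "petkin",
                mustWork = TRUE)
  )
}
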