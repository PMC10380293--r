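# CSV dialects and report writers. Units at the boundaries are uM, degrees
# Celsius, M urea and kcal/mol; Kelvin is used internally. Delimiter is ","
# with "." as decimal separator; no locale handling.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_invalid(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_schema(paste0(basename(path), " is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  df
}

check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad) > 0)
      fs_stop(sprintf("%s: non-numeric value '%s' in column %s at row %d",
                      basename(path), v[bad[1L]], col, bad[1L]),
              "fretstab_parse_error")
    df[[col]] <- vn
  }
  df
}

#' Read a long-format plate CSV
#'
#' Expected header:
#' `sample_id,well,replicate,donor_conc_uM,acceptor_conc_uM,inhibitor_conc_uM,channel,intensity`
#' with channel values `DD`, `AA` or `DA`. Unknown extra columns are
#' preserved.
#'
#' @param path Path to the CSV file.
#' @return Validated plate data frame.
#' @export
read_plate_csv <- function(path) {
  df <- read_csv_checked(path, PLATE_COLUMNS)
  for (col in c("replicate", "donor_conc_uM", "acceptor_conc_uM",
                "inhibitor_conc_uM", "intensity"))
    df <- check_numeric_col(df, col, path)
  bad <- which(!(df$channel %in% CHANNELS))
  if (length(bad) > 0)
    fs_stop(sprintf("%s: unknown channel value '%s' at row %d",
                    basename(path), df$channel[bad[1L]], bad[1L]),
            "fretstab_parse_error")
  validate_plate(df)
  df
}

#' Write a plate data frame to CSV
#'
#' @param readings Plate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(readings, path) {
  validate_plate(readings)
  utils::write.csv(readings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read DSF melt curves from CSV
#'
#' Expected header: `sample_id,replicate,temperature_C,intensity`.
#' Temperatures are converted to Kelvin on ingest and must be strictly
#' increasing within each (sample, replicate) series.
#'
#' @param path Path to the CSV file.
#' @return Named list of [melt_curve()] objects
#'   (`"<sample_id>.<replicate>"`).
#' @export
read_melt_csv <- function(path) {
  df <- read_csv_checked(path,
                         c("sample_id", "replicate", "temperature_C",
                           "intensity"))
  for (col in c("replicate", "temperature_C", "intensity"))
    df <- check_numeric_col(df, col, path)
  key <- interaction(df$sample_id, df$replicate, drop = TRUE)
  lapply(split(df, key), function(p) {
    if (any(diff(p$temperature_C) <= 0))
      stop_invalid(sprintf(
        "temperatures not strictly increasing for sample %s replicate %d",
        p$sample_id[1L], p$replicate[1L]))
    melt_curve(p$temperature_C, p$intensity, p$sample_id[1L],
               p$replicate[1L], celsius = TRUE)
  })
}

#' Write melt curves to CSV
#'
#' @param curves A `melt_curve` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, replicate = cv$replicate,
               temperature_C = kelvin_to_celsius(cv$temperature),
               intensity = cv$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read chemical-denaturation curves from CSV
#'
#' Expected header: `sample_id,replicate,urea_M,intensity`.
#'
#' @param path Path to the CSV file.
#' @return Named list of [denaturation_curve()] objects.
#' @export
read_urea_csv <- function(path) {
  df <- read_csv_checked(path,
                         c("sample_id", "replicate", "urea_M", "intensity"))
  for (col in c("replicate", "urea_M", "intensity"))
    df <- check_numeric_col(df, col, path)
  key <- interaction(df$sample_id, df$replicate, drop = TRUE)
  lapply(split(df, key), function(p) {
    denaturation_curve(p$urea_M, p$intensity, p$sample_id[1L],
                       p$replicate[1L])
  })
}

#' Write denaturation curves to CSV
#'
#' @param curves A `denaturation_curve` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_urea_csv <- function(curves, path) {
  if (inherits(curves, "denaturation_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, replicate = cv$replicate,
               urea_M = cv$urea, intensity = cv$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a work-value table from CSV
#'
#' Expected header: `direction,work_kcal_mol` with direction `forward` or
#' `reverse`.
#'
#' @param path Path to the CSV file.
#' @param temperature Temperature of the transitions, K.
#' @param edge_label Label; defaults to the file name.
#' @return A [work_set()]. A file with only forward rows is valid input for
#'   [jarzynski()] but will be rejected by [bar()] and
#'   [crooks_gaussian_intersection()].
#' @export
read_work_csv <- function(path, temperature = 300, edge_label = NULL) {
  df <- read_csv_checked(path, c("direction", "work_kcal_mol"))
  df <- check_numeric_col(df, "work_kcal_mol", path)
  bad <- setdiff(unique(df$direction), c("forward", "reverse"))
  if (length(bad) > 0)
    fs_stop(sprintf("%s: unknown direction '%s'", basename(path), bad[1L]),
            "fretstab_parse_error")
  work_set(df$work_kcal_mol[df$direction == "forward"],
           df$work_kcal_mol[df$direction == "reverse"],
           temperature,
           edge_label %||% sub("\\.csv$", "", basename(path)))
}

#' Write a work set to CSV
#'
#' @param workset A [work_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_work_csv <- function(workset, path) {
  df <- data.frame(
    direction = c(rep("forward", length(workset$forward)),
                  rep("reverse", length(workset$reverse))),
    work_kcal_mol = c(workset$forward, workset$reverse))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit report
#'
#' Writes a TSV summary (full precision plus display-rounded columns; the
#' rounded columns never feed back into computation) and a JSON sidecar of
#' the full structured result.
#'
#' @param results A named list of fit objects or a data frame.
#' @param path Output stem; `<path>.tsv` and `<path>.json` are written.
#' @return Character vector of the written paths, invisibly.
#' @export
report <- function(results, path) {
  df <- if (is.data.frame(results)) results else {
    do.call(rbind, lapply(names(results), function(nm) {
      x <- results[[nm]]
      flat <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1,
                       logical(1))]
      cbind(data.frame(id = nm, stringsAsFactors = FALSE),
            as.data.frame(flat))
    }))
  }
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  strip <- function(x) {
    if (is.list(x) && !is.data.frame(x))
      lapply(x[!vapply(x, inherits, logical(1), what = "nls")], strip)
    else x
  }
  jsonlite::write_json(strip(results), json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(tsv, json))
}
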