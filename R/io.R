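#' Readers and writers
#'
#' All tabular inputs are comma-separated UTF-8 with '.' decimals; reports
#' are written as tab-separated tables (spreadsheet-safe) plus a JSON
#' document carrying full provenance. Row-level problems are collected with
#' line numbers rather than aborting the read.
#'
#' @name io
NULL

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("no data: ", path, " (",
                                           conditionMessage(e), ")"))
  if (nrow(tab) == 0) stop("no data: ", path, " is empty")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  tab
}

#' Read a plate table
#'
#' Required header: sample_id, construct, competitor, conc_nm,
#' competitor_conc_nm, f_para, f_perp, replicate (an optional `blocked`
#' logical column marks 30 uM-inhibitor control wells). Rows with
#' non-numeric or negative concentrations are rejected and reported in the
#' `rejected` attribute (line numbers refer to data rows), the remainder
#' is kept.
#'
#' @param path CSV file path
#' @return plate data.frame; `attr(, "rejected")` lists dropped rows
#' @export
read_plate <- function(path) {
  tab <- read_checked_csv(path, required_plate_cols)
  if (!"blocked" %in% names(tab)) tab$blocked <- FALSE
  num_cols <- c("conc_nm", "competitor_conc_nm", "f_para", "f_perp")
  for (cc in num_cols) tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
  bad <- !stats::complete.cases(tab[num_cols]) |
    tab$conc_nm < 0 | tab$competitor_conc_nm < 0
  rejected <- data.frame(line = which(bad),
                         reason = rep("non-numeric or negative value",
                                      sum(bad)))
  out <- tab[!bad, , drop = FALSE]
  if (nrow(out) == 0) stop("no data: every row of ", path, " was rejected")
  attr(out, "rejected") <- rejected
  out
}

#' Read a melting series (CSV: temperature_c, peak_height)
#' @param path CSV file path
#' @param condition condition label attached to the series
#' @return data.frame with temperature_c, peak_height, condition
#' @export
read_melt <- function(path, condition = "apo") {
  tab <- read_checked_csv(path, c("temperature_c", "peak_height"))
  tab$temperature_c <- suppressWarnings(as.numeric(tab$temperature_c))
  tab$peak_height <- suppressWarnings(as.numeric(tab$peak_height))
  bad <- !stats::complete.cases(tab[c("temperature_c", "peak_height")])
  tab <- tab[!bad, , drop = FALSE]
  if (nrow(tab) == 0) stop("no data in ", path)
  tab$condition <- condition
  tab
}

#' Read a transport trace and its event schedule
#' @param path CSV with columns time_s, fluorescence_au
#' @param events_path JSON array of objects with fields event, time_s and,
#'   for the cocl2 event, conc_um
#' @return list with `trace` and `events` data.frames
#' @export
read_trace <- function(path, events_path) {
  trace <- read_checked_csv(path, c("time_s", "fluorescence_au"))
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("trace time must be strictly increasing")
  if (!file.exists(events_path)) stop("file not found: ", events_path)
  events <- as.data.frame(jsonlite::fromJSON(events_path))
  if (!all(c("event", "time_s") %in% names(events)))
    stop("event schedule needs fields: event, time_s")
  list(trace = trace, events = events)
}

#' Read SPR sensorgrams (long CSV: time_s, response_ru, conc_nm, phase)
#' @param path CSV file path
#' @return data.frame
#' @export
read_spr <- function(path) {
  tab <- read_checked_csv(path, c("time_s", "response_ru", "conc_nm", "phase"))
  if (length(unique(tab$conc_nm)) < 2)
    stop("need sensorgrams at >= 2 analyte concentrations")
  tab
}

#' Write a plate table (the format [read_plate()] consumes)
#' @param plate plate data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(plate[required_plate_cols_out(plate)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

required_plate_cols_out <- function(plate)
  intersect(c(required_plate_cols, "blocked"), names(plate))

fmt_pm <- function(value, se, digits = 3) {
  ifelse(is.na(value), "n.d.",
         paste0(signif(value, digits), "±", signif(se, 2)))
}

#' Write a pipeline report as TSV and JSON
#'
#' The TSV mirrors the per-construct binding table (tracer KD column, then
#' one KD column per competitor) with `n.d.` for cells not determined; the
#' JSON carries the full numeric table plus provenance (seed, well counts,
#' package version).
#'
#' @param report an `fpn_report` from [run_pipeline()]
#' @param path output path stem; `.tsv` and `.json` are appended
#' @param format subset of `c("tsv", "json")`
#' @return named character vector of files written
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "fpn_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  tab <- report$table
  comp_cols <- grep("^k_d_(?!tracer)[^_]+$", names(tab), perl = TRUE,
                    value = TRUE)
  out <- data.frame(construct = tab$construct, stringsAsFactors = FALSE)
  out[["K_D tracer (nM)"]] <- fmt_pm(tab$k_d_tracer, tab$k_d_tracer_se)
  for (cc in comp_cols) {
    comp <- sub("^k_d_", "", cc)
    out[[paste0("K_D ", comp, " (nM)")]] <-
      fmt_pm(tab[[cc]], tab[[paste0(cc, "_se")]])
  }
  files <- character()
  if ("tsv" %in% format) {
    f <- paste0(path, ".tsv")
    utils::write.table(out, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files["tsv"] <- f
  }
  if ("json" %in% format) {
    f <- paste0(path, ".json")
    jsonlite::write_json(list(table = report$table, wells = report$wells,
                              errors = report$errors,
                              provenance = report$provenance),
                         f, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    files["json"] <- f
  }
  files
}
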