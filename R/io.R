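# Stable file contracts: events/outcomes tables (CSV or JSONL), structured
# run configuration (YAML/JSON), run manifests.  Dates are ISO-8601 only.

EVENT_COLUMNS <- c("patient_id", "date", "modality", "code", "value",
                   "birth_date")

#' Read an events file (CSV or JSONL)
#'
#' Columns: `patient_id`, `date` (ISO-8601), `modality`, `code`, `value`,
#' `birth_date`.  Rows are validated (known modality; exactly one of
#' code/value, with values only on the value-bearing modalities) and
#' returned stably sorted by patient and date.
#'
#' @param path file path; `.jsonl`/`.ndjson` parses as JSON lines,
#'   anything else as CSV
#' @return data.frame of events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- read_table_file(path)
  miss <- setdiff(setdiff(EVENT_COLUMNS, c("code", "value")), names(ev))
  if (length(miss))
    stop("events file missing columns: ", paste(miss, collapse = ", "))
  if (is.null(ev$code)) ev$code <- NA_character_
  if (is.null(ev$value)) ev$value <- NA_real_
  ev$code[!is.na(ev$code) & ev$code == ""] <- NA_character_
  bad_mod <- which(!(ev$modality %in% MODALITIES))
  if (length(bad_mod))
    stop("unknown modality '", ev$modality[bad_mod[1]], "' at row ",
         bad_mod[1])
  ev$date <- parse_iso_date(ev$date, "date")
  ev$birth_date <- parse_iso_date(ev$birth_date, "birth_date")
  ev$value <- suppressWarnings(as.numeric(ev$value))
  is_val <- ev$modality %in% VALUE_MODALITIES
  bad <- which((is_val & (!is.finite(ev$value) | !is.na(ev$code))) |
                 (!is_val & (is.na(ev$code) | !is.na(ev$value))))
  if (length(bad))
    stop("row ", bad[1], ": exactly one of code/value must be present ",
         "(values only for ", paste(VALUE_MODALITIES, collapse = "/"), ")")
  ev <- ev[order(ev$patient_id, ev$date), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Read an outcomes file (`patient_id`, `disease`, `incident_date`)
#' @param path file path (CSV or JSONL)
#' @return data.frame of outcomes
#' @export
read_outcomes <- function(path) {
  oc <- read_table_file(path)
  miss <- setdiff(c("patient_id", "disease", "incident_date"), names(oc))
  if (length(miss))
    stop("outcomes file missing columns: ", paste(miss, collapse = ", "))
  oc$incident_date <- parse_iso_date(oc$incident_date, "incident_date")
  oc
}

read_table_file <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- lapply(seq_along(lines), function(i) {
      tryCatch(as.data.frame(jsonlite::fromJSON(lines[i]),
                             stringsAsFactors = FALSE),
               error = function(e) stop("malformed JSON at line ", i))
    })
    as.data.frame(data.table::rbindlist(rows, fill = TRUE))
  } else {
    as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  }
}

parse_iso_date <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad))
    stop("malformed ", what, " '", x[bad[1]], "' at row ", bad[1])
  d
}

#' Write events to CSV (ISO-8601 dates)
#' @param events events data.frame
#' @param path output path
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
}

## ---- run configuration ---------------------------------------------------

RUN_CONFIG_KEYS <- c("events", "outcomes", "out_dir", "cohort", "model",
                     "augmentation", "schedule", "synthetic", "seed")

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown top-level keys are rejected with a message naming the key.
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @return named list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key: ", unknown[1])
  cfg
}

#' Write a run manifest next to an output artifact
#' @param out_dir directory to write `manifest.json` into
#' @param config the run configuration (list)
#' @param seed the seed used
#' @param inputs named character vector of input file paths (hashed)
#' @export
write_manifest <- function(out_dir, config, seed, inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  jsonlite::write_json(
    list(package = "hierehr",
         version = as.character(utils::packageVersion("hierehr")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = config, input_md5 = hashes),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(file.path(out_dir, "manifest.json"))
}

#' Stratified train/tune/validation split by label
#' @param labels 0/1 vector
#' @param fractions length-3 vector summing to 1 (default 60/10/30)
#' @param seed integer seed
#' @return list of index vectors `train`, `tune`, `val`
#' @export
stratified_split <- function(labels, fractions = c(0.6, 0.1, 0.3),
                             seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  idx <- list(train = integer(), tune = integer(), val = integer())
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    n <- length(i)
    n1 <- round(fractions[1] * n)
    n2 <- round(fractions[2] * n)
    idx$train <- c(idx$train, i[seq_len(n1)])
    idx$tune <- c(idx$tune, i[seq_len(n2) + n1])
    if (n1 + n2 < n) idx$val <- c(idx$val, i[seq.int(n1 + n2 + 1L, n)])
  }
  lapply(idx, sort)
}
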