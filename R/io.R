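# Trial-log file formats: one CSV per task table with a '#'-prefixed
# metadata header (schema version, units, seed), plus a plain-text
# manifest. Fixed dialect: comma delimiter, '.' decimal, UTF-8, 0-based
# trial indices, cm and s as the only units.

LOG_SCHEMA_VERSION <- "1"

write_annotated_csv <- function(df, path, meta) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  # %.17g keeps doubles bit-faithful across a write/read round trip
  fmt <- vapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1,
                                    dimnames = list(NULL, names(df)))
  writeLines(paste(colnames(fmt), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  invisible(path)
}

read_annotated_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]+: ?", "", kv)
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  attr(df, "meta") <- meta
  df
}

#' Write or read a cohort's trial logs
#'
#' `write_trial_logs()` writes one annotated CSV per table
#' (`participants`, `reproduction`, `discrimination`, `pointing`,
#' `rhythm`) plus a `manifest.txt` recording the seed, package version,
#' row counts and a content checksum. `read_trial_logs()` inverts it
#' losslessly and verifies the manifest row counts.
#'
#' @param cohort a `cohort_data`.
#' @param dir output directory (created if needed).
#' @return `write_trial_logs()` returns `dir` invisibly;
#'   `read_trial_logs()` returns a `cohort_data`.
#' @export
write_trial_logs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("participants", "reproduction", "discrimination", "pointing",
              "rhythm")
  meta <- list(schema_version = LOG_SCHEMA_VERSION, seed = cohort$seed,
               units = "cm (space), s (time)")
  for (tb in tables) {
    write_annotated_csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                        c(meta, table = tb))
  }
  sizes <- vapply(tables, function(tb) {
    file.size(file.path(dir, paste0(tb, ".csv")))
  }, numeric(1))
  manifest <- c(
    sprintf("schema_version: %s", LOG_SCHEMA_VERSION),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("contextdep"))),
    sprintf("seed: %d", cohort$seed),
    sprintf("n_sets: %d", cohort$design$n_sets),
    sprintf("rhythm_interval: %.17g", cohort$design$rhythm_interval),
    sprintf("rows_%s: %d", tables,
            vapply(tables, function(tb) nrow(cohort[[tb]]), integer(1))),
    sprintf("checksum_bytes: %.0f", sum(sizes))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(dir) {
  manifest_path <- file.path(dir, "manifest.txt")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no manifest.txt in '%s'", dir), call. = FALSE)
  }
  manifest <- readLines(manifest_path)
  get_field <- function(name) {
    m <- grep(sprintf("^%s:", name), manifest, value = TRUE)
    if (length(m) != 1L) stop(sprintf("manifest field '%s' missing", name),
                              call. = FALSE)
    sub("^[^:]+: ?", "", m)
  }
  tables <- c("participants", "reproduction", "discrimination", "pointing",
              "rhythm")
  out <- lapply(tables, function(tb) {
    df <- read_annotated_csv(file.path(dir, paste0(tb, ".csv")))
    expected <- as.integer(get_field(sprintf("rows_%s", tb)))
    if (nrow(df) != expected) {
      stop(sprintf("table '%s': %d rows on disk, manifest says %d",
                   tb, nrow(df), expected), call. = FALSE)
    }
    attr(df, "meta") <- NULL
    df
  })
  names(out) <- tables
  out$discrimination$comparison_judged_longer <-
    as.logical(out$discrimination$comparison_judged_longer)
  structure(
    c(out, list(seed = as.integer(get_field("seed")),
                design = list(
                  n_sets = as.integer(get_field("n_sets")),
                  rhythm_interval = as.numeric(get_field("rhythm_interval"))))),
    class = "cohort_data"
  )
}

#' Write the analysis outputs as CSV files
#'
#' One CSV per `cohort_analysis` table: psychometric fit summaries,
#' central-tendency summaries, control metrics, the long-format metric
#' table (ready for external mixed-model tools), and the group-test
#' report.
#'
#' @param analysis a `cohort_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("fits", "central_tendency", "controls", "metrics_long",
               "group_tests")) {
    utils::write.csv(analysis[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
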