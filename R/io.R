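# Table readers/writers with schema validation, reference data, run
# manifests and the umbrella command-line dispatcher. All tables are plain
# comma-separated text with a mandatory header row, UTF-8, decimal point.

tableSchemas <- list(
  trials = list(
    required = c("female_id", "day_id", "line_id", "generation", "n_larvae",
                 "flies_emerged", "flies_encapsulated", "wasp_offspring"),
    integer = c("generation", "n_larvae", "flies_emerged",
                "flies_encapsulated", "wasp_offspring")),
  controls = list(
    required = c("day_id", "vial_id", "n_larvae", "n_emerged"),
    integer = c("n_larvae", "n_emerged")),
  pedigree = list(required = c("id", "sex", "dam", "sire"), integer = character()),
  means = list(required = c("line", "generation", "mean_all", "mean_selected"),
               integer = c("generation")))

#' Read a validated table
#'
#' Reads one of the package's comma-separated table formats and enforces
#' its schema: required columns, integer-valued count columns, and the
#' count invariants (encapsulated <= emerged <= larvae, offspring within
#' the killed count). Violations are reported with row numbers.
#'
#' @param path file path.
#' @param schema one of `"trials"`, `"controls"`, `"pedigree"`, `"means"`.
#' @return validated data.frame.
#' @export
readTable <- function(path, schema = names(tableSchemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- tableSchemas[[schema]]
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8"),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  missing <- setdiff(sc$required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, " (is the header present?): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in sc$integer) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != round(v)) ||
        any(v < 0)) {
      bad <- which(!is.numeric(v) | !is.finite(v) | v != round(v) | v < 0)[1]
      stop("column '", col, "' must hold non-negative integers (row ",
           bad, " of ", path, ")", call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  if (schema == "trials") {
    bad <- which(df$flies_encapsulated > df$flies_emerged)
    if (length(bad)) {
      stop("flies_encapsulated > flies_emerged in row(s) ",
           paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
    }
    bad <- which(df$flies_emerged > df$n_larvae)
    if (length(bad)) {
      stop("flies_emerged > n_larvae in row(s) ",
           paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
    }
    bad <- which(df$wasp_offspring > df$n_larvae - df$flies_emerged)
    if (length(bad)) {
      stop("wasp_offspring exceeds killed hosts in row(s) ",
           paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
    }
  }
  if (schema == "controls" && any(df$n_emerged > df$n_larvae)) {
    stop("n_emerged > n_larvae in ", path, call. = FALSE)
  }
  df
}

#' @rdname readTable
#' @export
readTrialsTable <- function(path) readTable(path, "trials")

#' @rdname readTable
#' @export
readControlsTable <- function(path) readTable(path, "controls")

#' @rdname readTable
#' @export
readPedigreeTable <- function(path) readTable(path, "pedigree")

#' @rdname readTable
#' @export
readMeansTable <- function(path) readTable(path, "means")

#' Write a table in the package's CSV convention
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTableCsv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference variance-component estimates
#'
#' Posterior-mode variance components and heritabilities reported for the
#' eight half-sib trait models (four indices, unstandardized and
#' day-standardized), shipped as plain text. Used for internal-consistency
#' checks of the heritability formula and as simulator defaults for the day
#' and mother components.
#'
#' @return data.frame with columns `trait`, `standardized`, `va`, `vday`,
#'   `vmother`, `vr`, `h2_mode`.
#' @export
referenceVarianceModes <- function() {
  read.csv(system.file("extdata", "halfsib_variance_modes.csv",
                       package = "parasitoidQG"), stringsAsFactors = FALSE)
}

#' Express a count as a percentage
#'
#' @param x count of events.
#' @param n total.
#' @param digits rounding (default 2).
#' @return 100 x / n, rounded.
#' @examples
#' asPercent(5, 2070) # 0.24
#' @export
asPercent <- function(x, n, digits = 2) {
  stopifnot(all(n > 0))
  round(100 * x / n, digits)
}

#' Write a run manifest
#'
#' Every command-line run records its command, configuration, seed, package
#' version, timestamp and input/output file digests so the outputs can be
#' regenerated from config + seed alone.
#'
#' @param path manifest path (JSON).
#' @param command command name.
#' @param seed integer seed used.
#' @param config named list of settings.
#' @param inputs,outputs character vectors of file paths (digested if they
#'   exist).
#' @return the manifest list, invisibly.
#' @export
writeRunManifest <- function(path, command, seed = NA_integer_,
                             config = list(), inputs = character(),
                             outputs = character()) {
  digest <- function(paths) {
    vapply(paths, function(p) {
      if (file.exists(p)) {
        as.character(tools::md5sum(p))
      } else NA_character_
    }, character(1))
  }
  man <- list(command = command,
              package_version = as.character(utils::packageVersion("parasitoidQG")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config,
              inputs = as.list(digest(inputs)),
              outputs = as.list(digest(outputs)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(man)
}
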