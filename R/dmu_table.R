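#' Construct and validate a DMU table
#'
#' A DMU table holds one row per decision-making unit (a producer's broiler
#' batch) with the five inputs and one output used throughout the package:
#' \describe{
#'   \item{housing}{number of birds housed (count)}
#'   \item{age}{age at slaughter (days)}
#'   \item{feed}{feed mass consumed (same mass unit as \code{total_weight})}
#'   \item{mortality}{fraction of housed birds lost, in (0, 1)}
#'   \item{cost}{unit production cost (currency per kg produced)}
#'   \item{total_weight}{total available weight of the batch}
#' }
#' Mortality is stored as a fraction; reporting functions render it as a
#' percentage. Feed and total weight must share a mass unit so that the feed
#' conversion ratio feed/total_weight is dimensionless; values outside the
#' plausible band (0.5, 5) trigger a validation warning.
#'
#' @param data a data.frame with column \code{dmu} (unique positive integer
#'   ids) plus the six columns above. Mortality may be given as a fraction
#'   or as a percent (values > 1 are interpreted as percent and divided by
#'   100 with a message suppressed).
#' @param input_names,output_names which columns play input / output roles
#'   in the DEA runs. Defaults to the study's choice: all five resource
#'   columns as inputs, total weight as the single output.
#' @return an object of class \code{dmu_table}: the validated data.frame with
#'   attributes \code{inputs} and \code{outputs}.
#' @seealso [read_dmu_table()], [broiler_batches()]
#' @export
dmu_table <- function(data,
                      input_names = c("housing", "age", "feed", "mortality", "cost"),
                      output_names = "total_weight") {
  stopifnot(is.data.frame(data))
  needed <- c("dmu", union(input_names, output_names))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) < 2)
    stop("a DMU table needs at least 2 units (got ", nrow(data), ")",
         call. = FALSE)
  if (anyDuplicated(data$dmu))
    stop("duplicated DMU ids: ",
         paste(unique(data$dmu[duplicated(data$dmu)]), collapse = ", "),
         call. = FALSE)

  data <- as.data.frame(data)[, needed, drop = FALSE]
  if ("mortality" %in% names(data) && any(data$mortality > 1, na.rm = TRUE))
    data$mortality <- data$mortality / 100

  num_cols <- setdiff(needed, "dmu")
  for (col in num_cols) {
    v <- data[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' is not numeric", call. = FALSE)
    if (anyNA(v) || any(v <= 0))
      stop("non-positive or missing '", col, "' for DMU ",
           paste(data$dmu[is.na(v) | v <= 0], collapse = ", "), call. = FALSE)
  }
  if ("mortality" %in% num_cols && any(data$mortality >= 1))
    stop("mortality must lie strictly below 1 (100%) for DMU ",
         paste(data$dmu[data$mortality >= 1], collapse = ", "), call. = FALSE)
  if (all(c("feed", "total_weight") %in% names(data))) {
    fcr <- data$feed / data$total_weight
    off <- fcr <= 0.5 | fcr >= 5
    if (any(off))
      warning("feed conversion outside (0.5, 5) for DMU ",
              paste(data$dmu[off], collapse = ", "),
              " - check feed / weight units", call. = FALSE)
  }

  structure(data,
            inputs = input_names,
            outputs = output_names,
            class = c("dmu_table", "data.frame"))
}

#' @rdname dmu_table
#' @param x object to test or print
#' @export
is.dmu_table <- function(x) inherits(x, "dmu_table")

#' @export
print.dmu_table <- function(x, ...) {
  cat("DMU table:", nrow(x), "units |",
      length(attr(x, "inputs")), "input(s):",
      paste(attr(x, "inputs"), collapse = ", "), "|",
      length(attr(x, "outputs")), "output(s):",
      paste(attr(x, "outputs"), collapse = ", "), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

# numeric matrices (units x variables) for the LP layer
input_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, attr(table, "inputs"), drop = FALSE])
}
output_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, attr(table, "outputs"), drop = FALSE])
}

#' Read / write DMU tables as delimited text
#'
#' `read_dmu_table()` reads a comma- or tab-delimited file with a header row,
#' strips thousands separators and `%` suffixes, converts percent mortality
#' to a fraction, and validates the result via [dmu_table()].
#' `write_dmu_table()` writes the table back as CSV with mortality rendered
#' as percent (2 decimals, `%` suffix) so files round-trip through
#' `read_dmu_table()`.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping file column
#'   names to canonical ones, e.g. `c(lodging = "housing")` renames the file
#'   column `lodging` to `housing`.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param ... passed on to [dmu_table()] (e.g. `input_names`).
#' @return `read_dmu_table()`: a [dmu_table()]; `write_dmu_table()`: the path,
#'   invisibly.
#' @export
read_dmu_table <- function(path, column_map = NULL, sep = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", strip.white = TRUE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(raw))
    if (anyNA(idx))
      stop("column_map names absent from file: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "), call. = FALSE)
    names(raw)[idx] <- unname(column_map)
  }
  pct <- vapply(raw, function(v) any(grepl("%$", v)), logical(1))
  parsed <- lapply(raw, function(v) {
    v <- gsub(",", "", v, fixed = TRUE)
    as.numeric(sub("%$", "", v))
  })
  bad <- vapply(parsed, anyNA, logical(1)) & !vapply(raw, anyNA, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(names(raw)[bad], collapse = ", "), call. = FALSE)
  out <- as.data.frame(parsed, check.names = FALSE)
  for (col in names(out)[pct]) out[[col]] <- out[[col]] / 100
  dmu_table(out, ...)
}

#' @rdname read_dmu_table
#' @param table a [dmu_table()].
#' @export
write_dmu_table <- function(table, path) {
  stopifnot(is.dmu_table(table))
  out <- as.data.frame(table)
  if ("mortality" %in% names(out))
    out$mortality <- sprintf("%.2f%%", 100 * out$mortality)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 31-batch reference dataset
#'
#' Production records of 31 broiler batches from integrated producers in a
#' Brazilian production system (closed lots, January 2021 to October 2022):
#' birds housed, age at slaughter (days), feed consumed, mortality, unit
#' cost (BRL/kg) and total available weight. Feed and total weight share one
#' mass unit (tonnes), which is the only reading under which the dataset's
#' feed conversion ratios (~1.5) are coherent. This is the universe against
#' which all worked examples and acceptance checks in the package run.
#'
#' @return a [dmu_table()] with 31 rows.
#' @export
#' @examples
#' tab <- broiler_batches()
#' nrow(tab)
broiler_batches <- function() {
  path <- system.file("extdata", "broiler_batches_31.csv",
                      package = "broilerDEA", mustWork = TRUE)
  read_dmu_table(path)
}

#' Descriptive statistics of a DMU table
#'
#' Per-column mean, median, standard deviation, coefficient of variation
#' (sd/mean, %), maximum and minimum. Mortality is reported on the percent
#' scale. The population (divisor n) standard deviation is the default
#' because batch-level summaries in the integration industry treat the
#' closed-lot universe as complete, not as a sample; set
#' `sd_method = "sample"` for the n-1 convention (the CV is affected, the
#' other rows are not).
#'
#' @param table a [dmu_table()].
#' @param sd_method `"population"` (divisor n, default) or `"sample"` (n-1).
#' @return a data.frame with rows mean, median, sd, cv, max, min and one
#'   column per variable.
#' @export
descriptive_stats <- function(table, sd_method = c("population", "sample")) {
  stopifnot(is.dmu_table(table))
  sd_method <- match.arg(sd_method)
  vars <- setdiff(names(table), "dmu")
  dat <- as.data.frame(table)[, vars, drop = FALSE]
  if ("mortality" %in% vars) dat$mortality <- 100 * dat$mortality
  n <- nrow(dat)
  res <- vapply(dat, function(v) {
    s <- if (n < 2) {
      warning("single record: sd reported as 0", call. = FALSE)
      0
    } else {
      s2 <- sd(v)
      if (sd_method == "population") s2 * sqrt((n - 1) / n) else s2
    }
    m <- mean(v)
    c(mean = m, median = median(v), sd = s,
      cv = if (m == 0) 0 else 100 * s / m,
      max = max(v), min = min(v))
  }, numeric(6))
  as.data.frame(res)
}

#' Pearson correlation matrix of a DMU table
#'
#' Correlations across all numeric columns (inputs and outputs alike). In
#' the reference dataset feed, housing and total weight are nearly
#' collinear (r = 1.00 at 2 decimals) while cost correlates weakly
#' negatively with weight.
#'
#' @param table a [dmu_table()] with at least 3 units.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  stopifnot(is.dmu_table(table))
  vars <- setdiff(names(table), "dmu")
  dat <- as.matrix(as.data.frame(table)[, vars, drop = FALSE])
  if (nrow(dat) < 3)
    stop("need at least 3 units for correlations", call. = FALSE)
  sds <- apply(dat, 2, sd)
  if (any(sds == 0))
    stop("constant column(s), correlation undefined: ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  cor(dat)
}
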