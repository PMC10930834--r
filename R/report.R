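#' Run the full benchmarking pipeline and write its report tables
#'
#' End-to-end driver mirroring a desktop DEA workflow: load (or simulate)
#' a DMU table, compute descriptive statistics and correlations, solve the
#' selected DEA runs, the inverted-frontier composite ranking and the
#' zootechnical panel with benchmark gaps, and write everything as
#' delimited tables plus a machine-readable JSON summary.
#'
#' @param input path to a delimited DMU table, or `"fixture"` for the
#'   packaged 31-batch reference dataset ([broiler_batches()]).
#' @param out_dir output directory (created if absent).
#' @param rts,orientation which DEA runs to solve: each may be a subset of
#'   its two values; all four combinations of the defaults reproduce the
#'   classical four-run analysis.
#' @param composite,zootech,stats logical switches for the inverted/composite
#'   ranking, the indicator panel and the descriptive/correlation tables.
#' @param benchmark_id benchmark unit for the gap report; default: the
#'   top-ranked unit of the composite analysis (or of the first DEA run if
#'   `composite = FALSE`).
#' @param digits rounding for written score tables (the JSON summary keeps
#'   full precision).
#' @param seed used only when `input` is `"simulate:<n>"`, which generates
#'   `n` farms via [simulate_farms()].
#' @param verbose print stage progress to standard error.
#' @return (invisibly) a list with every computed object plus the paths of
#'   the written files.
#' @export
run_report <- function(input = "fixture", out_dir = tempfile("dea_report_"),
                       rts = c("crs", "vrs"),
                       orientation = c("input", "output"),
                       composite = TRUE, zootech = TRUE, stats = TRUE,
                       benchmark_id = NULL, digits = 6, seed = 1,
                       verbose = FALSE) {
  if (!length(rts) || !length(orientation))
    stop("select at least one DEA run", call. = FALSE)
  rts <- match.arg(rts, c("crs", "vrs"), several.ok = TRUE)
  orientation <- match.arg(orientation, c("input", "output"),
                           several.ok = TRUE)
  say <- function(...) if (verbose) message("[broilerDEA] ", ...)

  say("loading input: ", input)
  table <- if (identical(input, "fixture")) {
    broiler_batches()
  } else if (grepl("^simulate:", input)) {
    simulate_farms(as.integer(sub("^simulate:", "", input)), seed = seed)
  } else {
    read_dmu_table(input)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }

  out <- list(table = table)
  if (stats) {
    say("descriptive statistics and correlations")
    out$stats <- descriptive_stats(table)
    out$correlations <- correlation_matrix(table)
    emit(cbind(statistic = rownames(out$stats), round(out$stats, 2)), "stats")
    emit(cbind(variable = rownames(out$correlations),
               round(as.data.frame(out$correlations), 2)), "correlations")
  }

  say("DEA runs: ", paste(outer(rts, orientation, paste, sep = "/"),
                          collapse = ", "))
  runs <- list()
  scores <- data.frame(dmu = table$dmu)
  for (r in rts) for (o in orientation) {
    key <- paste(r, o, sep = "_")
    runs[[key]] <- dea(table, dea_model(r, o))
    scores[[key]] <- round(unname(runs[[key]]$scores), digits)
  }
  out$runs <- runs
  out$scores <- cbind(as.data.frame(table), scores[-1])
  emit(out$scores, "scores")
  out$efficient_counts <- vapply(runs, function(x)
    length(efficient_dmus(x)), integer(1))

  if (composite) {
    say("inverted frontier and composite ranking")
    out$composite <- composite_efficiency(table)
    emit(within(as.data.frame(out$composite), {
      standard <- round(standard, digits)
      inverted <- round(inverted, digits)
      composed <- round(composed, digits)
      composed_star <- round(composed_star, digits)
    }), "composite")
  }

  if (zootech && all(c("housing", "age", "feed", "mortality", "cost",
                       "total_weight") %in% names(table))) {
    say("zootechnical indicators and benchmark gaps")
    out$indicators <- zootech_indicators(table)
    eff <- if (!is.null(out$composite)) out$composite
           else setNames(runs[[1]]$scores, table$dmu)
    if (is.null(benchmark_id)) {
      # best-ranked unit that also lies on the standard frontier
      frontier <- efficient_dmus(runs[[1]])
      benchmark_id <- if (!is.null(out$composite))
        out$composite$dmu[out$composite$dmu %in% frontier][1]
      else frontier[which.max(runs[[1]]$scores[as.character(frontier)])]
      if (is.na(benchmark_id)) benchmark_id <- frontier[1]
    }
    out$gaps <- gap_report(out$indicators, eff, benchmark_id,
                           check_efficiency = runs[[1]])
    emit(within(as.data.frame(out$gaps), {
      viability <- round(viability, 2)
      dwg <- round(dwg, 2)
      feed_conversion <- round(feed_conversion, 3)
      pef <- round(pef, 0)
    }), "indicators")
  }

  summary <- list(
    n_dmus = nrow(table),
    runs = names(runs),
    efficient = lapply(runs, function(x) efficient_dmus(x)),
    benchmark_id = benchmark_id,
    files = as.list(paths)
  )
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["summary"]] <- p
  out$paths <- paths
  say("done: ", out_dir)
  invisible(out)
}
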