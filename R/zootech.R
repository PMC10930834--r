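#' Zootechnical indicator panel
#'
#' Derives the standard broiler batch indicators from a DMU table:
#' \describe{
#'   \item{viability}{percent of housed birds surviving to slaughter,
#'     `100 (1 - mortality)`}
#'   \item{dwg}{daily weight gain in g/bird/day: mean final weight per
#'     surviving bird divided by the cycle length,
#'     `total_weight * scale / (housing (1 - mortality)) / age`}
#'   \item{feed_conversion}{feed mass per unit live weight,
#'     `feed / total_weight` (lower is better)}
#'   \item{pef}{the European production efficiency factor,
#'     `viability * dwg / (10 * feed_conversion)`}
#' }
#' The surviving-bird denominator for DWG is the integration-industry
#' convention: mortality removes birds from the weighed batch, so dividing
#' by housed birds would understate individual growth.
#'
#' @param table a [dmu_table()].
#' @param mass_unit_to_grams factor converting the `total_weight` unit to
#'   grams; the default 1e6 means weights are recorded in tonnes, as in the
#'   reference dataset.
#' @return data.frame with columns `dmu`, `viability`, `dwg`,
#'   `feed_conversion`, `pef`.
#' @export
#' @examples
#' head(zootech_indicators(broiler_batches()))
zootech_indicators <- function(table, mass_unit_to_grams = 1e6) {
  stopifnot(is.dmu_table(table))
  stopifnot(is.numeric(mass_unit_to_grams), mass_unit_to_grams > 0)
  d <- as.data.frame(table)
  surv <- 1 - d$mortality
  if (any(surv <= 0))
    stop("no surviving birds for DMU ",
         paste(d$dmu[surv <= 0], collapse = ", "), call. = FALSE)
  viability <- 100 * surv
  dwg <- d$total_weight * mass_unit_to_grams / (d$housing * surv) / d$age
  fcr <- d$feed / d$total_weight
  pef <- viability * dwg / (10 * fcr)
  data.frame(dmu = d$dmu, viability = viability, dwg = dwg,
             feed_conversion = fcr, pef = pef)
}

#' Benchmark gap report
#'
#' Signed, direction-aware gaps of every unit's indicators to a benchmark
#' unit: for viability, DWG and PEF the gap is `indicator - benchmark`
#' (higher is better, negative gaps mark shortfalls); for feed conversion
#' it is `benchmark - indicator` (lower is better), so for every metric a
#' negative gap means the unit is worse than the benchmark and is flagged.
#' Rows are ordered by the supplied efficiency scores, descending, so the
#' improvement agenda reads top-down from best to worst practice.
#'
#' @param indicators output of [zootech_indicators()].
#' @param efficiency named numeric vector of efficiency scores (names = DMU
#'   ids), e.g. `dea(...)$scores` or `composite_efficiency(...)` rows; a
#'   `composite_result` is accepted directly and contributes its
#'   `composed_star` column.
#' @param benchmark_id id of the reference unit; must be efficient
#'   (score >= 1 - 1e-6) under a standard [dea()] run supplied via
#'   `check_efficiency`, or simply hold the top efficiency in `efficiency`.
#' @param check_efficiency optional [dea()] result used to verify the
#'   benchmark lies on the frontier.
#' @return data.frame of class `gap_report`: indicators, their gaps
#'   (`gap_*`) and logical flags (`worse_*`), ordered by efficiency.
#' @export
#' @examples
#' tab <- broiler_batches()
#' ind <- zootech_indicators(tab)
#' eff <- composite_efficiency(tab)
#' head(gap_report(ind, eff, benchmark_id = 4))
gap_report <- function(indicators, efficiency, benchmark_id,
                       check_efficiency = NULL) {
  stopifnot(is.data.frame(indicators))
  if (inherits(efficiency, "composite_result"))
    efficiency <- setNames(efficiency$composed_star, efficiency$dmu)
  if (is.null(names(efficiency)))
    stop("efficiency must be a named vector or composite_result",
         call. = FALSE)
  if (!is.null(check_efficiency)) {
    sc <- check_efficiency$scores[as.character(benchmark_id)]
    if (is.na(sc) || sc < 1 - 1e-6)
      stop("benchmark DMU ", benchmark_id, " is not efficient (score ",
           round(sc, 4), ")", call. = FALSE)
  }
  if (!benchmark_id %in% indicators$dmu)
    stop("benchmark DMU ", benchmark_id, " not in indicator table",
         call. = FALSE)
  bench <- indicators[indicators$dmu == benchmark_id, ]
  out <- indicators
  out$efficiency <- unname(efficiency[as.character(out$dmu)])
  out$gap_viability <- out$viability - bench$viability
  out$gap_dwg <- out$dwg - bench$dwg
  out$gap_feed_conversion <- bench$feed_conversion - out$feed_conversion
  out$gap_pef <- out$pef - bench$pef
  for (v in c("viability", "dwg", "feed_conversion", "pef"))
    out[[paste0("worse_", v)]] <- out[[paste0("gap_", v)]] < 0
  out <- out[order(-out$efficiency, out$dmu), ]
  rownames(out) <- NULL
  class(out) <- c("gap_report", "data.frame")
  out
}
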