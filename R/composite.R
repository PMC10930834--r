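#' Swap input and output roles of a DMU table
#'
#' Produces the table used by the inverted-frontier run: the original output
#' columns become inputs and vice versa, ids and data unchanged. Applying it
#' twice returns the original role assignment.
#'
#' @param table a [dmu_table()].
#' @return a [dmu_table()] with roles exchanged.
#' @export
invert_dmu_table <- function(table) {
  stopifnot(is.dmu_table(table))
  dmu_table(as.data.frame(table),
            input_names = attr(table, "outputs"),
            output_names = attr(table, "inputs"))
}

#' Composite (double-frontier) efficiency ranking
#'
#' Combines the standard frontier with the inverted one, on which a score of
#' 1 marks worst observed practice. For each DMU:
#' \deqn{composed = (standard + (1 - inverted)) / 2}
#' and `composed_star` is composed divided by its maximum, so the best unit
#' scores exactly 1. Units are ranked by `composed_star` descending, ties
#' broken by ascending id. A unit lying on both frontiers (standard =
#' inverted = 1) gets composed 0.5 and is flagged `ambiguous`: it is
#' simultaneously best- and worst-practice in different variable directions,
#' so the composite ranking cannot discriminate it.
#'
#' @param table a [dmu_table()].
#' @param model model family for both runs; default CCR input-oriented,
#'   matching the classical double-frontier convention. The inverted run
#'   reuses the same family and orientation.
#' @return a data.frame of class `composite_result` with columns `dmu`,
#'   `standard`, `inverted`, `composed`, `composed_star`, `rank`,
#'   `ambiguous`, ordered by rank.
#' @export
#' @examples
#' comp <- composite_efficiency(broiler_batches())
#' head(comp)
composite_efficiency <- function(table, model = dea_model("crs", "input")) {
  stopifnot(is.dmu_table(table), inherits(model, "dea_model"))
  std <- dea(table, model)$scores
  inv_model <- dea_model(model$rts, model$orientation, frontier = "inverted",
                         epsilon = model$epsilon,
                         eps_value = model$eps_value)
  inv <- dea(table, inv_model)$scores
  composed <- (std + (1 - inv)) / 2
  cstar <- composed / max(composed)
  ord <- order(-cstar, table$dmu)
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  out <- data.frame(dmu = table$dmu, standard = unname(std),
                    inverted = unname(inv), composed = unname(composed),
                    composed_star = unname(cstar), rank = rank,
                    ambiguous = unname(std >= 1 - 1e-6 & inv >= 1 - 1e-6))
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("composite_result", "data.frame")
  out
}
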