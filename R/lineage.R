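#' Lineage inheritance
#'
#' A daughter cell always carries its parent's lineage identifier; class
#' changes (mutation, CSC conversion, dedifferentiation, TAC maturation)
#' never change it.
#'
#' @param parent,child [CellState-class] objects; the parent must be
#'   non-empty.
#' @return the child with the parent's lineage id.
#' @export
inheritLineage <- function(parent, child) {
  if (parent@cls == 6L) stop("state-error: empty cells have no lineage")
  child@lineage <- parent@lineage
  child
}

#' Per-lineage summary table
#'
#' One row per founding lineage: current size, size among mutated classes,
#' size among cancer classes (CSC + TC), and the extinction step when the
#' lineage has died out. Every initial non-empty cell founds a lineage at
#' step 0 and no lineages are founded later, so the number of living
#' lineages is non-increasing.
#'
#' @param x a [SimResult-class] or [LatticeState-class].
#' @param ... unused.
#' @return data.frame with columns lineage, founder, foundingStep, size,
#'   mutatedSize, cancerSize, extinctStep.
#' @export
setMethod("lineageTable", "SimResult", function(x, ...) x@lineages)

#' @rdname lineageTable
#' @export
setMethod("lineageTable", "LatticeState", function(x, ...) {
  .lineageSummary(x, NULL, rep(-1L, x@nLineages + 1L))
})

#' Largest lineages
#'
#' The k largest lineages by current size, ties broken by smaller founder
#' id, so \code{topLineages(tab, k)} is always a prefix of
#' \code{topLineages(tab, k + 1)}.
#'
#' @param table a lineage table (see [lineageTable()]).
#' @param k number of lineages.
#' @return integer vector of lineage ids, largest first.
#' @export
topLineages <- function(table, k = 20L) {
  stopifnot(k >= 1)
  ord <- order(-table$size, table$founder)
  table$lineage[ord][seq_len(min(k, nrow(table)))]
}

#' Clonality of the cancer population
#'
#' \code{"none"} when no cancer-class (CSC or TC) cells exist,
#' \code{"monoclonal"} when exactly one lineage holds cancer-class cells,
#' \code{"polyclonal"} otherwise. Set \code{tumorCellsOnly = TRUE} to count
#' lineages via TC alone.
#'
#' @param x a lineage table, [SimResult-class] or [LatticeState-class].
#' @param tumorCellsOnly count only TC (not CSC) occupancy.
#' @param ... unused.
#' @return one of "none", "monoclonal", "polyclonal".
#' @export
setMethod("classifyClonality", "data.frame", function(x,
                                                      tumorCellsOnly = FALSE,
                                                      ...) {
  n <- sum(x$cancerSize > 0)
  if (tumorCellsOnly) {
    if (!"tumorSize" %in% names(x))
      stop("tumorCellsOnly requires a tumorSize column")
    n <- sum(x$tumorSize > 0)
  }
  if (n == 0) "none" else if (n == 1) "monoclonal" else "polyclonal"
})

#' @rdname classifyClonality
#' @export
setMethod("classifyClonality", "SimResult", function(x, ...) {
  classifyClonality(x@lineages, ...)
})

#' @rdname classifyClonality
#' @export
setMethod("classifyClonality", "LatticeState", function(x, ...) {
  classifyClonality(lineageTable(x), ...)
})

#' Top-k lineage map
#'
#' A categorical layer for plotting: entry 1..k for cells of the k largest
#' lineages (rank order), 0 for occupied cells outside the top k, NA for
#' empty sites.
#'
#' @param state a [LatticeState-class].
#' @param k number of lineages to color.
#' @return N x N integer matrix.
#' @export
lineageMap <- function(state, k = 20L) {
  tab <- lineageTable(state)
  top <- topLineages(tab, k)
  m <- matrix(match(as.vector(state@lineage), top, nomatch = 0L),
              state@N, state@N)
  m[state@cls == 6L] <- NA_integer_
  m
}
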