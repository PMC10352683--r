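#' One time-series row from a lattice state
#'
#' Class fractions, fraction of mutated cells (MNTC + MNSC + CSC + TC), mean
#' expression per gene over occupied sites, the fraction of genes whose
#' population-mean expression is positively mutated, and the number of
#' lineages holding cancer-class cells. Means over an all-empty grid are
#' reported as \code{NA}.
#'
#' @param state a [LatticeState-class].
#' @param panel a [GenePanel-class] (for gene types).
#' @return one-row data.frame.
#' @export
recordStep <- function(state, panel = hnsccPanel()) {
  cls <- as.vector(state@cls)
  occ <- cls != 6L
  N2 <- state@N^2
  fr <- as.list(classCounts(state) / N2)
  names(fr) <- paste0("frac", .CLASS_NAMES)
  meanE <- if (any(occ)) colMeans(state@E[occ, , drop = FALSE])
           else rep(NA_real_, ncol(state@E))
  pos <- if (any(occ))
    mean(positivelyMutated(meanE, panel@geneType, panel@MBar))
  else NA_real_
  lin <- unique(as.vector(state@lineage)[cls %in% c(4L, 5L)])
  out <- data.frame(step = state@t)
  out <- cbind(out, as.data.frame(fr),
               fracMutated = sum(cls %in% c(1L, 3L, 4L, 5L)) / N2)
  em <- as.data.frame(as.list(meanE))
  names(em) <- paste0("meanExpr_", state@geneNames)
  cbind(out, em, fracGenesPositive = pos, cancerLineages = length(lin))
}

#' Fraction of genes positively mutated at the population level
#'
#' Two aggregations: \code{"population-mean"} classifies each gene by its
#' mean expression over occupied sites; \code{"per-cell"} averages the
#' per-cell fraction of positively mutated genes.
#'
#' @param state a [LatticeState-class].
#' @param panel a [GenePanel-class].
#' @param method aggregation method.
#' @return numeric in [0, 1] (NA for an empty grid).
#' @export
fractionGenesPositive <- function(state, panel = hnsccPanel(),
                                  method = c("population-mean", "per-cell")) {
  method <- match.arg(method)
  occ <- as.vector(state@cls) != 6L
  if (!any(occ)) return(NA_real_)
  E <- state@E[occ, , drop = FALSE]
  if (method == "population-mean") {
    mean(positivelyMutated(colMeans(E), panel@geneType, panel@MBar))
  } else {
    mean(vapply(seq_len(nrow(E)), function(i)
      mean(positivelyMutated(E[i, ], panel@geneType, panel@MBar)),
      numeric(1)))
  }
}

#' Detect event times from a recorded time series
#'
#' First step at which each mutated / cancer class appears, with missing
#' events encoded as \code{NA}. Event steps are exact when the series was
#' recorded with stride 1. For a [SimResult-class] the engine's exact event
#' record is returned directly.
#'
#' @param x a time-series data.frame (from [timeSeries()]) or a
#'   [SimResult-class].
#' @return named list: firstMutated, firstCSC, firstTC.
#' @export
detectEvents <- function(x) {
  if (is(x, "SimResult")) return(x@events)
  firstAt <- function(col) {
    i <- which(x[[col]] > 0)
    if (length(i)) as.integer(x$step[min(i)]) else NA_integer_
  }
  list(firstMutated = firstAt("fracMutated"),
       firstCSC = firstAt("fracCSC"),
       firstTC = firstAt("fracTC"))
}

#' Summarize replicate runs
#'
#' Medians and quartiles of event times and final clonality counts per
#' condition, with the seeds logged.
#'
#' @param results named list of conditions, each a list of
#'   [SimResult-class] replicates.
#' @return data.frame, one row per condition.
#' @export
replicateSummary <- function(results) {
  one <- function(name, reps) {
    ev <- lapply(reps, eventRecord)
    q <- function(field) {
      v <- vapply(ev, function(e) as.numeric(e[[field]] %||% NA), numeric(1))
      stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    }
    fm <- q("firstMutated"); fc <- q("firstCSC"); ft <- q("firstTC")
    clon <- vapply(ev, function(e) e$finalClonality, character(1))
    seeds <- vapply(reps, function(r)
      as.numeric(r@metadata$seed %||% NA), numeric(1))
    data.frame(condition = name, nReps = length(reps),
               firstMutatedQ1 = fm[1], firstMutatedMedian = fm[2],
               firstMutatedQ3 = fm[3], firstCSCMedian = fc[2],
               firstTCMedian = ft[2],
               nNone = sum(clon == "none"),
               nMonoclonal = sum(clon == "monoclonal"),
               nPolyclonal = sum(clon == "polyclonal"),
               seeds = paste(seeds, collapse = ";"))
  }
  do.call(rbind, Map(one, names(results), results))
}

#' Time-series CSV round trip
#'
#' @param series a time-series data.frame.
#' @param file path.
#' @export
writeTimeSeries <- function(series, file) {
  utils::write.csv(series, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(file) {
  utils::read.csv(file)
}

#' Run metadata JSON round trip
#'
#' The metadata echoes the full configuration, the RNG seed and the
#' calibration factors, so a run can be reproduced from its metadata file.
#'
#' @param metadata metadata list (from a [SimResult-class]).
#' @param file path.
#' @export
writeRunMetadata <- function(metadata, file) {
  jsonlite::write_json(metadata, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}

#' @rdname writeRunMetadata
#' @export
readRunMetadata <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Class color map
#'
#' NTC brown, MNTC green, NSC blue, MNSC yellow, CSC purple, TC red, empty
#' white.
#'
#' @return named character vector of 7 colors in class order 0..6.
#' @export
classColors <- function() {
  c(NTC = "#8B4513", MNTC = "#228B22", NSC = "#1E64C8", MNSC = "#FFD700",
    CSC = "#800080", TC = "#FF0000", empty = "#FFFFFF")
}

#' Write a class snapshot as a PNG image
#'
#' One pixel per lattice site, colored by the class map of [classColors()].
#'
#' @param cls N x N integer class matrix (a snapshot or \code{state@cls}).
#' @param file output path.
#' @export
writeSnapshotPNG <- function(cls, file) {
  cols <- grDevices::col2rgb(classColors()) / 255
  arr <- array(0, c(nrow(cls), ncol(cls), 3))
  for (ch in 1:3)
    arr[, , ch] <- matrix(cols[ch, as.vector(cls) + 1L], nrow(cls))
  png::writePNG(arr, file)
  invisible(file)
}

#' Plot class fractions over time
#'
#' @param result a [SimResult-class].
#' @param months use months instead of steps on the x axis.
#' @export
plotClassFractions <- function(result, months = FALSE) {
  s <- timeSeries(result)
  xv <- if (months) s$months else s$step
  cols <- classColors()
  cols["empty"] <- "#BBBBBB"
  graphics::matplot(xv, as.matrix(s[, paste0("frac", .CLASS_NAMES)]),
                    type = "l", lty = 1, col = cols,
                    xlab = if (months) "months" else "time-step",
                    ylab = "fraction of sites")
  graphics::legend("topright", legend = .CLASS_NAMES, col = cols, lty = 1,
                   cex = 0.8)
  invisible(result)
}
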