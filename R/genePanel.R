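.ACTIONS <- c("proliferation", "quiescence", "apoptosis", "differentiation")

#' Construct a gene panel from per-gene annotations
#'
#' Builds every gene-level parameter matrix of the simulator from a list of
#' declarative per-gene annotations: the type vector \code{T}, the carcinogen
#' sign matrix (the carcinogen columns of the input weight matrix), the output
#' weight matrix \code{WY}, the relationship matrix \code{R}, and the
#' phenotype increment matrices \code{Uinc}/\code{Dinc}.
#'
#' \code{WY} is generated from a construction rule: every diagonal entry
#' starts at \code{wyDefault} and gains \code{wyPerCall} for each gene the
#' gene calls (a gene flagged \code{relatedToAll} counts all other genes);
#' off-diagonal entry \code{WY[i, j]} is \code{+wyOffDiag} when gene j
#' upregulates gene i and \code{-wyOffDiag} when it downregulates it.
#' \code{R[i, j] = 1} when gene i calls gene j (either direction of
#' regulation), and a \code{relatedToAll} gene relates to every other gene.
#'
#' @param annotations list of per-gene lists with elements \code{name},
#'   \code{type} ("suppressor" or "oncogene"), \code{carcinogenSigns}
#'   (integer vector in \{-1,0,1\}, one per carcinogen),
#'   \code{phenotypeEffects} (named character vector, e.g.
#'   \code{c(proliferation = "up", apoptosis = "down")}, applying in the
#'   gene's positive-mutation direction), \code{activates} (named character
#'   vector of regulated genes, values "up"/"down") and optional logical
#'   \code{relatedToAll}.
#' @param carcinogenNames labels of the carcinogen columns, in matrix order.
#' @param MBar positive mutation threshold on gene expression.
#' @param Upsilon minimum count of positively mutated genes for a mutated cell.
#' @param incrementMagnitude magnitude of one phenotype increment.
#' @param ageWeight magnitude of the age weight of the gene network input.
#' @param wyDefault,wyPerCall,wyOffDiag constants of the \code{WY}
#'   construction rule.
#' @return A [GenePanel-class].
#' @examples
#' panel <- hnsccPanel()
#' geneNames(panel)
#' @export
genePanel <- function(annotations, carcinogenNames,
                      MBar = 0.1, Upsilon = 4L,
                      incrementMagnitude = 1e-6, ageWeight = 1e-7,
                      wyDefault = 0.1, wyPerCall = 0.1, wyOffDiag = 0.01) {
  G <- length(annotations)
  C <- length(carcinogenNames)
  nms <- vapply(annotations, function(a) a$name, character(1))
  type <- vapply(annotations, function(a) {
    if (!a$type %in% c("suppressor", "oncogene"))
      stop("panel-error: unknown gene type '", a$type, "'")
    if (a$type == "oncogene") 1L else 0L
  }, integer(1))

  WXsigns <- matrix(0, G, C, dimnames = list(nms, carcinogenNames))
  for (g in seq_len(G)) {
    s <- annotations[[g]]$carcinogenSigns
    if (length(s) != C)
      stop("panel-error: carcinogenSigns of ", nms[g], " must have length ", C)
    if (!all(s %in% c(-1, 0, 1)))
      stop("panel-error: carcinogenSigns must be in {-1,0,+1}")
    WXsigns[g, ] <- s
  }

  R <- matrix(0, G, G, dimnames = list(nms, nms))
  WY <- matrix(0, G, G, dimnames = list(nms, nms))
  for (g in seq_len(G)) {
    a <- annotations[[g]]
    act <- a$activates
    if (length(act) && is.null(names(act)))
      stop("panel-error: activates must be a named vector for ", nms[g])
    targets <- match(names(act), nms)
    if (anyNA(targets))
      stop("panel-error: unknown gene in activates of ", nms[g])
    relAll <- isTRUE(a$relatedToAll)
    calls <- if (relAll) G - 1L else length(act)
    WY[g, g] <- wyDefault + wyPerCall * calls
    if (length(act))
      WY[cbind(targets, g)] <- ifelse(act == "up", wyOffDiag, -wyOffDiag)
    if (relAll) R[g, -g] <- 1 else R[g, targets] <- 1
  }

  inc <- buildIncrementMatrices(annotations, incrementMagnitude)

  new("GenePanel",
      geneNames = nms, geneType = type, carcinogenNames = carcinogenNames,
      WXsigns = WXsigns, WY = WY, R = R,
      Uinc = inc$Uinc, Dinc = inc$Dinc,
      MBar = MBar, Upsilon = as.integer(Upsilon),
      incrementMagnitude = incrementMagnitude, ageWeight = ageWeight,
      annotations = annotations)
}

#' Phenotype increment matrices from gene annotations
#'
#' For each gene, the signed phenotype effects listed in its annotation
#' (which apply in the gene's positive-mutation direction) are written into
#' the increment matrix of that direction: the \code{Dinc} column for a tumor
#' suppressor (whose positive mutation is downregulation) and the \code{Uinc}
#' column for an oncogene; the other matrix is the negation, so
#' \code{Uinc == -Dinc} always.
#'
#' @inheritParams genePanel
#' @param incrementMagnitude magnitude of each nonzero increment.
#' @return list with 4 x G matrices \code{Uinc} and \code{Dinc} (rows:
#'   proliferation, quiescence, apoptosis, differentiation).
#' @export
buildIncrementMatrices <- function(annotations, incrementMagnitude = 1e-6) {
  G <- length(annotations)
  nms <- vapply(annotations, function(a) a$name, character(1))
  Uinc <- matrix(0, 4, G, dimnames = list(.ACTIONS, nms))
  for (g in seq_len(G)) {
    a <- annotations[[g]]
    eff <- a$phenotypeEffects
    if (length(eff)) {
      if (!all(names(eff) %in% .ACTIONS))
        stop("panel-error: unknown action label in phenotypeEffects of ",
             nms[g])
      col <- ifelse(eff == "up", incrementMagnitude, -incrementMagnitude)
      positive <- numeric(4)
      positive[match(names(eff), .ACTIONS)] <- col
      # positive-mutation direction: Dinc for suppressors, Uinc for oncogenes
      Uinc[, g] <- if (a$type == "oncogene") positive else -positive
    }
  }
  list(Uinc = Uinc, Dinc = -Uinc)
}

#' The default 10-gene head-and-neck squamous cell carcinoma panel
#'
#' Ten genes commonly implicated in HNSCC: five tumor suppressors (TP53,
#' TP73, RB, TP21, TP16) and five oncogenes (EGFR, CCDN1, MYC, PIK3CA, RAS),
#' with two carcinogen columns (alcohol-type and smoking-type exposure), a
#' mutation threshold of 0.1 and a four-gene mutated-cell criterion. TP53 is
#' taken to be related to all other genes.
#'
#' @return A [GenePanel-class] with \code{G = 10} genes and \code{C = 2}
#'   carcinogens.
#' @examples
#' panel <- hnsccPanel()
#' panel@WXsigns["TP53", ]   # alcohol up, smoking down
#' @export
hnsccPanel <- function() {
  file <- system.file("extdata", "hnscc_panel.yaml", package = "fieldCA",
                      mustWork = TRUE)
  readGenePanel(file)
}

#' Read and write declarative gene-panel files
#'
#' Panels are stored as YAML mirroring the annotation fields, so non-default
#' panels can be defined without code changes. The packaged default is the
#' HNSCC panel at \code{system.file("extdata", "hnscc_panel.yaml", package =
#' "fieldCA")}.
#'
#' @param file path to a panel YAML file.
#' @return \code{readGenePanel} returns a [GenePanel-class].
#' @export
readGenePanel <- function(file) {
  y <- yaml::read_yaml(file)
  anns <- lapply(y$genes, function(g) {
    list(name = g$name,
         type = g$type,
         carcinogenSigns = as.integer(unlist(g$carcinogenSigns %||% rep(0, length(y$carcinogens)))),
         phenotypeEffects = unlist(g$phenotypeEffects) %||% character(0),
         activates = unlist(g$activates) %||% character(0),
         relatedToAll = isTRUE(g$relatedToAll))
  })
  genePanel(anns,
            carcinogenNames = as.character(unlist(y$carcinogens)),
            MBar = y$mutationThreshold %||% 0.1,
            Upsilon = y$upsilon %||% 4L,
            incrementMagnitude = y$incrementMagnitude %||% 1e-6,
            ageWeight = y$ageWeight %||% 1e-7)
}

#' @rdname readGenePanel
#' @param panel a [GenePanel-class] to serialize.
#' @export
writeGenePanel <- function(panel, file) {
  y <- list(
    carcinogens = as.list(panel@carcinogenNames),
    mutationThreshold = panel@MBar,
    upsilon = panel@Upsilon,
    incrementMagnitude = panel@incrementMagnitude,
    ageWeight = panel@ageWeight,
    genes = lapply(panel@annotations, function(a) {
      out <- list(name = a$name, type = a$type,
                  carcinogenSigns = as.list(as.integer(a$carcinogenSigns)))
      if (length(a$phenotypeEffects))
        out$phenotypeEffects <- as.list(a$phenotypeEffects)
      if (length(a$activates)) out$activates <- as.list(a$activates)
      if (isTRUE(a$relatedToAll)) out$relatedToAll <- TRUE
      out
    })
  )
  yaml::write_yaml(y, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the full input weight matrix
#'
#' The input weight matrix has one carcinogen column per carcinogen (signs
#' from the panel) and a final age column whose entries are
#' \code{ageSigns * ageWeight}; the signs are redrawn every time-step by the
#' network (see [drawAgeSigns()]).
#'
#' @param panel a [GenePanel-class].
#' @param ageSigns vector of +1/-1, one per gene.
#' @return G x (C+1) matrix.
#' @examples
#' p <- hnsccPanel()
#' buildWX(p, rep(1, nGenes(p)))[, 3]   # all +1e-7
#' @export
buildWX <- function(panel, ageSigns) {
  G <- nGenes(panel)
  if (length(ageSigns) != G)
    stop("panel-error: ageSigns must have length G = ", G)
  if (!all(ageSigns %in% c(-1, 1)))
    stop("panel-error: ageSigns entries must be -1 or +1")
  cbind(panel@WXsigns, age = ageSigns * panel@ageWeight)
}

#' @rdname genePanel
#' @param x a [GenePanel-class].
#' @export
setMethod("geneNames", "GenePanel", function(x) x@geneNames)

#' @rdname genePanel
#' @export
setMethod("nGenes", "GenePanel", function(x) length(x@geneNames))

#' @rdname genePanel
#' @export
setMethod("nCarcinogens", "GenePanel", function(x) length(x@carcinogenNames))

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel with", nGenes(object), "genes,",
      nCarcinogens(object), "carcinogens\n")
  cat("  genes:", paste(object@geneNames, collapse = ", "), "\n")
  cat("  tumor suppressors:",
      paste(object@geneNames[object@geneType == 0L], collapse = ", "), "\n")
  cat("  oncogenes:",
      paste(object@geneNames[object@geneType == 1L], collapse = ", "), "\n")
  cat("  MBar =", object@MBar, " Upsilon =", object@Upsilon, "\n")
})
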