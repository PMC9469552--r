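#' @rdname accessors
#' @aliases nodeIds,SimilarityMatrix-method
setMethod("nodeIds", "SimilarityMatrix", function(x) x@ids)

#' @rdname accessors
setMethod("nodeIds", "DrugRegistry", function(x) x@ids)

#' @rdname accessors
setMethod("nodeIds", "DiseaseRegistry", function(x) x@ids)

#' @rdname accessors
setMethod("nodeIds", "DiseaseDAG", function(x) x@nodes)

#' @rdname accessors
setMethod("matrixValues", "SimilarityMatrix", function(x) x@values)

#' @rdname accessors
setMethod("matrixValues", "AssociationMatrix", function(x) x@values)

#' @rdname accessors
setMethod("viewTag", "SimilarityMatrix", function(x) x@view)

#' @rdname accessors
setMethod("drugIds", "AssociationMatrix", function(x) x@drugIds)

#' @rdname accessors
setMethod("diseaseIds", "AssociationMatrix", function(x) x@diseaseIds)

#' @rdname accessors
setMethod("drugIds", "HeterogeneousNetwork", function(x) x@GC@ids)

#' @rdname accessors
setMethod("diseaseIds", "HeterogeneousNetwork", function(x) x@GM@ids)

#' @rdname accessors
setMethod("targetSets", "DrugRegistry", function(x) x@targets)

#' @rdname accessors
setMethod("targetSets", "DiseaseRegistry", function(x) x@targets)

#' Fingerprint matrix of a drug registry
#' @param x a \linkS4class{DrugRegistry}.
#' @return integer matrix (drugs x bits).
#' @export
fingerprints <- function(x) {
  stopifnot(is(x, "DrugRegistry"))
  x@fingerprints
}

#' Extract one similarity view from a heterogeneous network
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param view one of "C", "T", "M", "A".
#' @return the requested \linkS4class{SimilarityMatrix}.
#' @export
similarityView <- function(net, view = c("C", "T", "M", "A")) {
  view <- match.arg(view)
  slot(net, paste0("G", view))
}

#' Known association matrix of a network
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @return the \linkS4class{AssociationMatrix}.
#' @export
knownAssociations <- function(net) net@assoc

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix view=%s over %d nodes\n",
              object@view, length(object@ids)))
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix %d drugs x %d diseases, %d known pairs\n",
              length(object@drugIds), length(object@diseaseIds),
              sum(object@values)))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG with %d terms, %d roots\n",
              length(object@nodes), length(object@roots)))
})

setMethod("show", "DrugRegistry", function(object) {
  cat(sprintf("DrugRegistry of %d drugs, fingerprint length %d\n",
              length(object@ids), ncol(object@fingerprints)))
})

setMethod("show", "DiseaseRegistry", function(object) {
  cat(sprintf("DiseaseRegistry of %d diseases\n", length(object@ids)))
})

setMethod("show", "HeterogeneousNetwork", function(object) {
  cat(sprintf(paste0("HeterogeneousNetwork: %d drugs (views C,T), ",
                     "%d diseases (views M,A), %d known associations\n"),
              length(drugIds(object)), length(diseaseIds(object)),
              sum(object@assoc@values)))
})

setMethod("show", "GcmmModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("GcmmModel (%s): %d GCN layers, embedding %d, ",
                     "%d output channels\n"),
              cfg$variant, cfg$nLayers, cfg$embedDim, cfg$outChannels))
})

setMethod("show", "CvPlan", function(object) {
  cat(sprintf("CvPlan: %d folds, %s regime, %d pairs (%d positive)\n",
              object@k, object@regime, nrow(object@pairs),
              sum(object@pairs[, "label"] == 1L)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d folds\n", nrow(object@perFold)))
  m <- object@means
  cat(sprintf("  mean AUC %.4f  AUPR %.4f  F1 %.4f  ACC %.4f\n",
              m["AUC"], m["AUPR"], m["F1"], m["ACC"]))
})

#' Per-fold metric table of an evaluation report
#' @param x an \linkS4class{EvalReport}.
#' @return data.frame of per-fold metrics and confusion counts.
#' @export
foldMetrics <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@perFold
}

#' Mean metrics of an evaluation report
#' @param x an \linkS4class{EvalReport}.
#' @return named numeric vector.
#' @export
meanMetrics <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@means
}
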