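#' Accessor generics
#'
#' Small accessor set used across the package's containers: node identifiers,
#' the numeric payload of matrix-like objects, and the view tag of a
#' similarity matrix.
#'
#' @param x an object.
#' @return \code{nodeIds}: character vector; \code{matrixValues}: numeric
#'   matrix; \code{viewTag}: length-1 character; \code{drugIds} /
#'   \code{diseaseIds}: character vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' @rdname accessors
#' @export
setGeneric("viewTag", function(x) standardGeneric("viewTag"))

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("targetSets", function(x) standardGeneric("targetSets"))

#' Ancestor closure of an ontology term
#'
#' Returns N(s): the term itself plus all ancestors reachable through
#' parent links up to the roots.
#'
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param term a term token present in the DAG.
#' @return character vector of term tokens (s first, then ancestors in
#'   breadth-first discovery order).
#' @export
setGeneric("ancestorClosure", function(dag, term)
  standardGeneric("ancestorClosure"))
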