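#' @import methods
NULL

## Central S4 containers for the heterogeneous drug-disease network.

#' DrugRegistry: drugs with fingerprints and target sets
#'
#' Ordered registry of drugs. Each drug carries a fixed-length binary
#' substructure fingerprint (MACCS-style) and a (possibly empty) set of
#' protein target identifiers.
#'
#' @slot ids character vector of unique drug identifiers, in file order.
#' @slot fingerprints integer matrix (drugs x bits), entries in \{0,1\},
#'   rownames = ids.
#' @slot targets named list of character vectors of target ids per drug.
#' @export
setClass("DrugRegistry",
  representation(ids = "character", fingerprints = "matrix",
                 targets = "list"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@ids))
      msg <- c(msg, "duplicate drug ids")
    if (nrow(object@fingerprints) != length(object@ids))
      msg <- c(msg, "fingerprint rows must match ids")
    if (length(object@targets) != length(object@ids))
      msg <- c(msg, "targets list must match ids")
    if (length(object@fingerprints) &&
        !all(object@fingerprints %in% c(0L, 1L)))
      msg <- c(msg, "fingerprint entries must be 0/1")
    if (is.null(msg)) TRUE else msg
  })

#' DiseaseRegistry: diseases with ontology terms and target sets
#'
#' @slot ids character vector of unique disease identifiers.
#' @slot dagNodes character vector: ontology term of each disease.
#' @slot targets named list of character vectors of target ids per disease.
#' @export
setClass("DiseaseRegistry",
  representation(ids = "character", dagNodes = "character",
                 targets = "list"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@ids))
      msg <- c(msg, "duplicate disease ids")
    if (length(object@dagNodes) != length(object@ids))
      msg <- c(msg, "dagNodes must match ids")
    if (length(object@targets) != length(object@ids))
      msg <- c(msg, "targets list must match ids")
    if (is.null(msg)) TRUE else msg
  })

#' DiseaseDAG: rooted ontology of disease terms
#'
#' Directed acyclic graph of ontology terms with parent-to-child edges.
#' Supports ancestor-closure queries: the closure N(s) of a term s contains
#' s itself plus all its ancestors up to the roots.
#'
#' @slot nodes character vector of term tokens.
#' @slot parents named list: for each node, its parent tokens (empty for
#'   roots).
#' @slot roots character vector of nodes with no parent.
#' @export
setClass("DiseaseDAG",
  representation(nodes = "character", parents = "list", roots = "character"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate DAG nodes")
    if (!all(names(object@parents) == object@nodes))
      msg <- c(msg, "parents list must be keyed by nodes")
    if (length(object@nodes) && length(object@roots) == 0L)
      msg <- c(msg, "a non-empty DAG must have at least one root")
    if (is.null(msg)) TRUE else msg
  })

#' SimilarityMatrix: one similarity view over one node family
#'
#' Square symmetric matrix with entries in [0,1] over a single node family
#' (drugs or diseases), tagged with its view: \code{"C"} chemical, \code{"T"}
#' therapeutic (drug side), \code{"M"} semantic, \code{"A"} target-based
#' (disease side).
#'
#' @slot view one of "C", "T", "M", "A".
#' @slot ids ordered node tokens labelling rows and columns.
#' @slot values square numeric matrix.
#' @export
setClass("SimilarityMatrix",
  representation(view = "character", ids = "character", values = "matrix"),
  validity = function(object) {
    msg <- NULL
    v <- object@values
    if (!object@view %in% c("C", "T", "M", "A"))
      msg <- c(msg, "view must be one of C, T, M, A")
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (nrow(v) != length(object@ids))
      msg <- c(msg, "ids must label the matrix")
    if (length(v)) {
      if (max(abs(v - t(v))) > 1e-9)
        msg <- c(msg, "values must be symmetric within 1e-9")
      if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
        msg <- c(msg, "entries must lie in [0,1]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' AssociationMatrix: binary drug-disease label matrix
#'
#' @slot drugIds ordered drug tokens (rows).
#' @slot diseaseIds ordered disease tokens (columns).
#' @slot values binary matrix, 1 = experimentally verified association.
#' @export
setClass("AssociationMatrix",
  representation(drugIds = "character", diseaseIds = "character",
                 values = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@values) != length(object@drugIds))
      msg <- c(msg, "rows must match drugIds")
    if (ncol(object@values) != length(object@diseaseIds))
      msg <- c(msg, "columns must match diseaseIds")
    if (length(object@values) && !all(object@values %in% c(0, 1)))
      msg <- c(msg, "entries must be 0/1")
    if (is.null(msg)) TRUE else msg
  })

#' HeterogeneousNetwork: the assembled multi-view network
#'
#' Bundles the two drug similarity views (chemical \code{GC}, therapeutic
#' \code{GT}), the two disease views (semantic \code{GM}, target-based
#' \code{GA}) and the known association matrix, with aligned id orders.
#'
#' @slot GC,GT drug-side \linkS4class{SimilarityMatrix} objects.
#' @slot GM,GA disease-side \linkS4class{SimilarityMatrix} objects.
#' @slot assoc \linkS4class{AssociationMatrix}.
#' @export
setClass("HeterogeneousNetwork",
  representation(GC = "SimilarityMatrix", GT = "SimilarityMatrix",
                 GM = "SimilarityMatrix", GA = "SimilarityMatrix",
                 assoc = "AssociationMatrix"),
  validity = function(object) {
    msg <- NULL
    if (!identical(object@GC@ids, object@GT@ids))
      msg <- c(msg, "drug-side views must share one id order")
    if (!identical(object@GM@ids, object@GA@ids))
      msg <- c(msg, "disease-side views must share one id order")
    if (!identical(object@assoc@drugIds, object@GC@ids))
      msg <- c(msg, "association rows must match drug view ids")
    if (!identical(object@assoc@diseaseIds, object@GM@ids))
      msg <- c(msg, "association columns must match disease view ids")
    if (is.null(msg)) TRUE else msg
  })

#' GcmmModel: parameter bundle for the multi-view GCN model
#'
#' Holds the per-view GCN weight stacks, the per-family attention weights,
#' the per-family fully connected extractor weights, and the fixed random
#' initial feature matrices.
#'
#' @slot config named list: nLayers, embedDim, outChannels, attReduction,
#'   variant ("full", "no_att" or "no_lin"), drugViews, diseaseViews, seed.
#' @slot params named list of numeric arrays (all trainable weights).
#' @slot X0 initial drug feature matrix (N_g x embedDim), fixed.
#' @slot Y0 initial disease feature matrix (N_s x embedDim), fixed.
#' @export
setClass("GcmmModel",
  representation(config = "list", params = "list", X0 = "matrix",
                 Y0 = "matrix"))

#' CvPlan: cross-validation fold plan over association pairs
#'
#' @slot k fold count.
#' @slot pairs integer matrix with columns drug, disease, label and fold;
#'   positive pairs partition the observed associations, negatives are
#'   sampled from zero cells (balanced regime) or enumerate them (all-pairs
#'   regime).
#' @slot regime "balanced" or "all_pairs".
#' @slot seed integer seed the plan was drawn with.
#' @export
setClass("CvPlan",
  representation(k = "integer", pairs = "matrix", regime = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("drug", "disease", "label", "fold")
    if (!identical(colnames(object@pairs), need))
      msg <- c(msg, "pairs must have columns drug, disease, label, fold")
    if (length(object@pairs) && !all(object@pairs[, "fold"] %in%
                                     seq_len(object@k)))
      msg <- c(msg, "fold indices out of range")
    if (is.null(msg)) TRUE else msg
  })

#' EvalReport: per-fold and mean cross-validation metrics
#'
#' @slot perFold data.frame, one row per fold, columns fold, AUC, AUPR, F1,
#'   ACC, Recall, Precision, Specificity, TP, TN, FP, FN, threshold.
#' @slot means named numeric vector of the metric means over folds.
#' @export
setClass("EvalReport",
  representation(perFold = "data.frame", means = "numeric"),
  validity = function(object) {
    metr <- c("AUC", "AUPR", "F1", "ACC", "Recall", "Precision",
              "Specificity")
    msg <- NULL
    if (!all(metr %in% colnames(object@perFold)))
      msg <- c(msg, "perFold must contain the seven metrics")
    if (!all(metr %in% names(object@means)))
      msg <- c(msg, "means must contain the seven metrics")
    if (is.null(msg)) TRUE else msg
  })
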