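## The four similarity measures feeding the heterogeneous network:
##   C  chemical   — Tanimoto on MACCS-style fingerprint bits
##   T  therapeutic — mean normalized Smith-Waterman over target pairs
##   M  semantic   — shared ontology-DAG ancestry (Wang-style values)
##   A  target     — Jaccard on disease target sets

#' AlignmentParams: scoring scheme for local protein alignment
#'
#' @slot matrixName name of the substitution matrix (a Biostrings data set,
#'   e.g. "BLOSUM62").
#' @slot substitutionMatrix the resolved square substitution matrix.
#' @slot gapOpening non-negative gap opening penalty (score units).
#' @slot gapExtension non-negative per-residue gap extension penalty.
#' @export
setClass("AlignmentParams",
  representation(matrixName = "character", substitutionMatrix = "matrix",
                 gapOpening = "numeric", gapExtension = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@gapOpening < 0 || object@gapExtension < 0)
      msg <- c(msg, "gap penalties must be non-negative")
    m <- object@substitutionMatrix
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "substitution matrix must be square over one alphabet")
    if (is.null(msg)) TRUE else msg
  })

#' Construct local-alignment scoring parameters
#'
#' Defaults are the community-standard protein settings: BLOSUM62 with gap
#' opening 10 and gap extension 1.
#'
#' @param matrixName substitution matrix name shipped with Biostrings.
#' @param gapOpening,gapExtension non-negative penalties.
#' @param substitutionMatrix optional explicit matrix overriding
#'   \code{matrixName}.
#' @return an \linkS4class{AlignmentParams}.
#' @export
alignmentParams <- function(matrixName = "BLOSUM62", gapOpening = 10,
                            gapExtension = 1, substitutionMatrix = NULL) {
  if (is.null(substitutionMatrix)) {
    e <- new.env()
    utils::data(list = matrixName, package = "Biostrings", envir = e)
    substitutionMatrix <- get(matrixName, envir = e)
  }
  new("AlignmentParams", matrixName = matrixName,
      substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension)
}

#' Tanimoto chemical similarity of two fingerprints
#'
#' With a and b bits set in the two fingerprints and c bits set in both,
#' returns c / (a + b - c). Two all-zero fingerprints count as identical
#' (similarity 1); a zero against a non-zero fingerprint scores 0.
#'
#' @param fpI,fpJ equal-length 0/1 integer vectors.
#' @return similarity in [0,1].
#' @examples
#' chemicalSimilarity(c(1,0,1,1,0), c(0,1,1,1,0))  # 2/(3+3-2) = 0.5
#' @export
chemicalSimilarity <- function(fpI, fpJ) {
  if (length(fpI) != length(fpJ))
    stop("fingerprint length mismatch: ", length(fpI), " vs ", length(fpJ))
  a <- popcount(fpI); b <- popcount(fpJ)
  c_ <- sum(fpI != 0 & fpJ != 0)
  if (a + b - c_ == 0) return(1)
  c_ / (a + b - c_)
}

# raw Smith-Waterman local-alignment optimum; empty local alignment -> 0
swRawScore <- function(seq1, seq2, params) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "local", substitutionMatrix = params@substitutionMatrix,
    gapOpening = params@gapOpening, gapExtension = params@gapExtension,
    scoreOnly = TRUE)
  max(0, sc)
}

checkResidues <- function(seq, params) {
  ok <- rownames(params@substitutionMatrix)
  bad <- setdiff(strsplit(seq, "")[[1]], ok)
  if (length(bad))
    stop("illegal residue character(s): ", paste(unique(bad), collapse = ""))
}

#' Normalized Smith-Waterman similarity of two protein sequences
#'
#' Computes the optimal local-alignment score SW(s1, s2) and normalizes by
#' the geometric mean of the self-alignment scores,
#' SW(s1, s2) / sqrt(SW(s1, s1) * SW(s2, s2)), which maps self-similarity
#' to 1 and keeps the value in [0,1].
#'
#' @param seq1,seq2 non-empty amino-acid strings.
#' @param params an \linkS4class{AlignmentParams}.
#' @return similarity in [0,1].
#' @export
smithWatermanSimilarity <- function(seq1, seq2,
                                    params = alignmentParams()) {
  if (!nzchar(seq1) || !nzchar(seq2))
    stop("sequences must be non-empty")
  checkResidues(seq1, params); checkResidues(seq2, params)
  s11 <- swRawScore(seq1, seq1, params)
  s22 <- swRawScore(seq2, seq2, params)
  if (s11 <= 0 || s22 <= 0) return(0)
  min(1, swRawScore(seq1, seq2, params) / sqrt(s11 * s22))
}

# normalized SW similarity for every target pair, computed once
targetSimilarityCache <- function(seqs, params = alignmentParams()) {
  ids <- names(seqs)
  n <- length(ids)
  self <- vapply(seqs, function(s) swRawScore(s, s, params), 0)
  m <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (self[i] <= 0 || self[j] <= 0) { m[i, j] <- m[j, i] <- 0; next }
      v <- min(1, swRawScore(seqs[[i]], seqs[[j]], params) /
                 sqrt(self[i] * self[j]))
      m[i, j] <- m[j, i] <- v
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Therapeutic similarity of two drugs from their target sets
#'
#' Mean normalized Smith-Waterman similarity over all cross pairs
#' (e1, e2), e1 in E1, e2 in E2, skipping pairs where e1 and e2 are the
#' same target token. Returns 0 when no pair survives the exclusion
#' (including empty target sets).
#'
#' @param targetsI,targetsJ character vectors of target ids.
#' @param sequences named character vector mapping target ids to amino-acid
#'   sequences.
#' @param params an \linkS4class{AlignmentParams}.
#' @param cache optional precomputed matrix from internal pairwise scores;
#'   used by \code{\link{buildSimilarityMatrix}} to avoid re-alignment.
#' @return similarity in [0,1].
#' @export
therapeuticSimilarity <- function(targetsI, targetsJ, sequences,
                                  params = alignmentParams(),
                                  cache = NULL) {
  targetsI <- unique(as.character(targetsI))
  targetsJ <- unique(as.character(targetsJ))
  if (is.null(cache)) {
    missing <- setdiff(union(targetsI, targetsJ), names(sequences))
    if (length(missing))
      stop("no sequence for target(s): ", paste(missing, collapse = ", "))
  }
  total <- 0; nPairs <- 0L
  for (e1 in targetsI) for (e2 in targetsJ) {
    if (e1 == e2) next
    v <- if (!is.null(cache)) cache[e1, e2] else
      smithWatermanSimilarity(sequences[[e1]], sequences[[e2]], params)
    total <- total + v
    nPairs <- nPairs + 1L
  }
  if (nPairs == 0L) 0 else total / nPairs
}

#' Semantic value of an ontology term
#'
#' Computes the per-ancestor contributions F_s(n) over the closure N(s):
#' F_s(s) = 1 and F_s(n) = delta * max of F_s over n's children inside the
#' closure. With \code{delta = 1} (the default) every ancestor contributes
#' 1. The semantic value DV(s) is the sum of the contributions.
#'
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param term a term in the DAG.
#' @param delta per-edge decay factor in (0,1]; 1 means no decay, 0.5 is
#'   the common convention of the ontology-similarity literature.
#' @return list with elements \code{F} (named numeric over N(s)) and
#'   \code{DV} (their sum).
#' @export
semanticValue <- function(dag, term, delta = 1) {
  closure <- ancestorClosure(dag, term)
  kids <- childrenWithin(dag, closure)
  F <- stats::setNames(rep(NA_real_, length(closure)), closure)
  evalF <- function(n) {
    if (!is.na(F[[n]])) return(F[[n]])
    v <- if (n == term) 1 else
      delta * max(vapply(kids[[n]], evalF, 0))
    F[[n]] <<- v
    v
  }
  for (n in closure) evalF(n)
  list(F = F, DV = sum(F))
}

#' Semantic similarity of two ontology terms
#'
#' Sum over shared ancestors n of F_si(n) + F_sj(n), divided by
#' DV(si) + DV(sj). Terms with disjoint closures score 0; a term against
#' itself scores 1.
#'
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param termI,termJ terms in the DAG.
#' @param delta decay factor, see \code{\link{semanticValue}}.
#' @return similarity in [0,1].
#' @export
semanticSimilarity <- function(dag, termI, termJ, delta = 1) {
  svI <- semanticValue(dag, termI, delta)
  svJ <- semanticValue(dag, termJ, delta)
  shared <- intersect(names(svI$F), names(svJ$F))
  if (!length(shared)) return(0)
  sum(svI$F[shared] + svJ$F[shared]) / (svI$DV + svJ$DV)
}

#' Jaccard similarity of two target sets
#'
#' |intersection| / |union|. Two empty sets count as identical
#' (similarity 1); an empty set against a non-empty one scores 0.
#'
#' @param eI,eJ character vectors of target ids.
#' @return similarity in [0,1].
#' @export
targetJaccard <- function(eI, eJ) {
  eI <- unique(as.character(eI)); eJ <- unique(as.character(eJ))
  u <- length(union(eI, eJ))
  if (u == 0L) return(1)
  length(intersect(eI, eJ)) / u
}

#' Build one similarity view over a registry
#'
#' Applies the chosen measure to every pair; the upper triangle is computed
#' and mirrored so the result is exactly symmetric. Diagonals follow each
#' measure's convention: 1 for chemical, semantic and target views;
#' computed under the e1 != e2 exclusion for the therapeutic view.
#'
#' @param registry a \linkS4class{DrugRegistry} (measures "chemical",
#'   "therapeutic") or \linkS4class{DiseaseRegistry} ("semantic", "target").
#' @param measure which similarity to compute.
#' @param dag \linkS4class{DiseaseDAG}, required for "semantic".
#' @param sequences named target sequences, required for "therapeutic".
#' @param params \linkS4class{AlignmentParams} for "therapeutic".
#' @param delta semantic decay factor.
#' @return a \linkS4class{SimilarityMatrix} tagged C, T, M or A.
#' @export
buildSimilarityMatrix <- function(registry,
                                  measure = c("chemical", "therapeutic",
                                              "semantic", "target"),
                                  dag = NULL, sequences = NULL,
                                  params = alignmentParams(), delta = 1) {
  measure <- match.arg(measure)
  ids <- nodeIds(registry)
  n <- length(ids)
  stopIfNot(n >= 2, "need at least 2 records to build a similarity matrix")
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  if (measure == "chemical") {
    stopifnot(is(registry, "DrugRegistry"))
    fp <- registry@fingerprints
    elem <- function(i, j) chemicalSimilarity(fp[i, ], fp[j, ])
    diagv <- rep(1, n); view <- "C"
  } else if (measure == "therapeutic") {
    stopifnot(is(registry, "DrugRegistry"))
    if (is.null(sequences)) stop("therapeutic measure needs sequences")
    tg <- registry@targets
    allT <- unique(unlist(tg, use.names = FALSE))
    missing <- setdiff(allT, names(sequences))
    if (length(missing))
      stop("no sequence for target(s): ", paste(missing, collapse = ", "))
    cache <- targetSimilarityCache(sequences[allT], params)
    elem <- function(i, j)
      therapeuticSimilarity(tg[[i]], tg[[j]], sequences, params, cache)
    diagv <- vapply(seq_len(n), function(i) elem(i, i), 0); view <- "T"
  } else if (measure == "semantic") {
    stopifnot(is(registry, "DiseaseRegistry"))
    if (is.null(dag)) stop("semantic measure needs a DAG")
    sv <- lapply(registry@dagNodes, function(s) semanticValue(dag, s, delta))
    elem <- function(i, j) {
      shared <- intersect(names(sv[[i]]$F), names(sv[[j]]$F))
      if (!length(shared)) return(0)
      sum(sv[[i]]$F[shared] + sv[[j]]$F[shared]) / (sv[[i]]$DV + sv[[j]]$DV)
    }
    diagv <- rep(1, n); view <- "M"
  } else {
    stopifnot(is(registry, "DiseaseRegistry"))
    tg <- registry@targets
    elem <- function(i, j) targetJaccard(tg[[i]], tg[[j]])
    diagv <- rep(1, n); view <- "A"
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- elem(i, j)
    vals[i, j] <- v
    vals[j, i] <- v
  }
  diag(vals) <- diagv
  new("SimilarityMatrix", view = view, ids = ids, values = vals)
}

#' Assemble the heterogeneous network from its five components
#'
#' Validates id alignment across all drug-side and disease-side matrices
#' (joins are by token, so inputs whose ids are ordered differently are
#' rejected rather than silently reindexed).
#'
#' @param GC,GT drug-side similarity views (chemical, therapeutic).
#' @param GM,GA disease-side similarity views (semantic, target).
#' @param assoc the known \linkS4class{AssociationMatrix}.
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @export
HeterogeneousNetwork <- function(GC, GT, GM, GA, assoc) {
  stopifnot(viewTag(GC) == "C", viewTag(GT) == "T",
            viewTag(GM) == "M", viewTag(GA) == "A")
  new("HeterogeneousNetwork", GC = GC, GT = GT, GM = GM, GA = GA,
      assoc = assoc)
}

#' Build the full heterogeneous network from registries
#'
#' Convenience wrapper computing all four similarity views and bundling
#' them with the association matrix.
#'
#' @param drugs a \linkS4class{DrugRegistry}.
#' @param diseases a \linkS4class{DiseaseRegistry}.
#' @param dag the disease ontology \linkS4class{DiseaseDAG}.
#' @param sequences named character vector of target protein sequences.
#' @param assoc the known \linkS4class{AssociationMatrix}.
#' @param params \linkS4class{AlignmentParams} for the therapeutic view.
#' @param delta semantic decay factor.
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @export
buildHetNet <- function(drugs, diseases, dag, sequences, assoc,
                        params = alignmentParams(), delta = 1) {
  HeterogeneousNetwork(
    GC = buildSimilarityMatrix(drugs, "chemical"),
    GT = buildSimilarityMatrix(drugs, "therapeutic", sequences = sequences,
                               params = params),
    GM = buildSimilarityMatrix(diseases, "semantic", dag = dag,
                               delta = delta),
    GA = buildSimilarityMatrix(diseases, "target"),
    assoc = assoc)
}
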