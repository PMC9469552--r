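## Synthetic fixture generator: fully offline inputs with planted cluster
## structure, so that every stage of the pipeline — similarity views, the
## encoder, training, evaluation — is testable without external databases.

#' Specification of a synthetic benchmark instance
#'
#' Drugs and diseases are grouped into matched clusters. Drugs in one
#' cluster share a prototype fingerprint (perturbed at the bit-flip rate)
#' and draw targets from the cluster's target pool; diseases in the
#' corresponding cluster attach to the same ontology branch and overlapping
#' target sets; associations are cluster-diagonal (drug cluster i with
#' disease cluster i) with a noise rate flipping cells. Target protein
#' sequences are random peptides; within-cluster targets are point
#' mutations of a cluster prototype, so local-alignment similarity is
#' higher within clusters.
#'
#' @param nDrugs,nDiseases,nTargets family sizes.
#' @param nClusters planted cluster count (<= min(nDrugs, nDiseases)).
#' @param fpLength fingerprint bit length (MACCS-like default, 166).
#' @param flipRate within-cluster fingerprint bit-flip probability.
#' @param dagDepth,dagBranching shape of the ontology branch under each
#'   cluster's anchor node.
#' @param noiseRate probability of flipping an association cell (< 0.5).
#' @param peptideLength target sequence length.
#' @param mutationRate within-cluster residue mutation probability.
#' @param targetsPerDrug,targetsPerDisease targets drawn per entity.
#' @param seed integer seed.
#' @return named list (the validated spec).
#' @export
syntheticSpec <- function(nDrugs = 100L, nDiseases = 60L, nTargets = 40L,
                          nClusters = 5L, fpLength = 166L, flipRate = 0.1,
                          dagDepth = 3L, dagBranching = 2L,
                          noiseRate = 0.05, peptideLength = 80L,
                          mutationRate = 0.05, targetsPerDrug = 3L,
                          targetsPerDisease = 3L, seed = 0L) {
  spec <- list(nDrugs = as.integer(nDrugs),
               nDiseases = as.integer(nDiseases),
               nTargets = as.integer(nTargets),
               nClusters = as.integer(nClusters),
               fpLength = as.integer(fpLength), flipRate = flipRate,
               dagDepth = as.integer(dagDepth),
               dagBranching = as.integer(dagBranching),
               noiseRate = noiseRate,
               peptideLength = as.integer(peptideLength),
               mutationRate = mutationRate,
               targetsPerDrug = as.integer(targetsPerDrug),
               targetsPerDisease = as.integer(targetsPerDisease),
               seed = as.integer(seed))
  if (spec$nClusters > min(spec$nDrugs, spec$nDiseases))
    stop("nClusters must not exceed min(nDrugs, nDiseases)")
  if (spec$noiseRate >= 0.5) stop("noiseRate must be < 0.5")
  if (spec$flipRate < 0 || spec$flipRate > 1)
    stop("flipRate must be in [0,1]")
  if (spec$nTargets < spec$nClusters)
    stop("need at least one target per cluster")
  spec
}

aminoAlphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

mutatePeptide <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(aminoAlphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic heterogeneous-network bundle
#'
#' Produces the five raw inputs (drug registry with fingerprints and
#' targets, disease registry, ontology DAG, target sequences, association
#' matrix) plus the planted cluster labels. Byte-identical for a given
#' spec (including its seed).
#'
#' @param spec list from \code{\link{syntheticSpec}}.
#' @return named list: \code{drugs}, \code{diseases}, \code{dag},
#'   \code{sequences}, \code{assoc}, \code{drugClusters},
#'   \code{diseaseClusters}, \code{spec}.
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  withSeed(spec$seed, {
    K <- spec$nClusters
    drugCl <- rep(seq_len(K), length.out = spec$nDrugs)
    disCl <- rep(seq_len(K), length.out = spec$nDiseases)
    targetCl <- rep(seq_len(K), length.out = spec$nTargets)
    drugIds <- sprintf("drug%03d", seq_len(spec$nDrugs))
    disIds <- sprintf("dis%03d", seq_len(spec$nDiseases))
    tgtIds <- sprintf("tgt%03d", seq_len(spec$nTargets))

    # fingerprints: cluster prototypes perturbed by the flip rate
    protos <- matrix(as.integer(stats::runif(K * spec$fpLength) < 0.5),
                     K, spec$fpLength)
    fp <- protos[drugCl, , drop = FALSE]
    flips <- matrix(stats::runif(length(fp)) < spec$flipRate, nrow(fp))
    fp[flips] <- 1L - fp[flips]

    # target sequences: one prototype peptide per cluster, point-mutated
    protoPep <- vapply(seq_len(K), function(i)
      paste(sample(aminoAlphabet, spec$peptideLength, replace = TRUE),
            collapse = ""), "")
    seqs <- vapply(seq_len(spec$nTargets), function(t)
      mutatePeptide(protoPep[targetCl[t]], spec$mutationRate), "")
    names(seqs) <- tgtIds

    # drug and disease target sets drawn from the own-cluster pool
    drawTargets <- function(cl, nPer) {
      pool <- tgtIds[targetCl == cl]
      sample(pool, min(nPer, length(pool)))
    }
    drugTg <- stats::setNames(lapply(drugCl, drawTargets,
                                     spec$targetsPerDrug), drugIds)
    disTg <- stats::setNames(lapply(disCl, drawTargets,
                                    spec$targetsPerDisease), disIds)

    # ontology: one branch per cluster under a shared root; each branch is
    # a (depth x branching) tree and diseases attach to its leaves
    edges <- NULL
    branchLeaves <- vector("list", K)
    for (cl in seq_len(K)) {
      anchor <- sprintf("term_c%d", cl)
      edges <- rbind(edges, c("root", anchor))
      level <- anchor
      for (d in seq_len(spec$dagDepth)) {
        nxt <- character()
        for (p in level) {
          kids <- sprintf("%s_%d_%s", p, d, letters[seq_len(spec$dagBranching)])
          edges <- rbind(edges, cbind(p, kids))
          nxt <- c(nxt, kids)
        }
        level <- nxt
      }
      branchLeaves[[cl]] <- level
    }
    dag <- DiseaseDAG(edges)
    disNodes <- vapply(disCl, function(cl)
      sample(branchLeaves[[cl]], 1L), "")

    drugs <- DrugRegistry(drugIds, fp, drugTg)
    diseases <- DiseaseRegistry(disIds, disNodes, dag, disTg)

    # cluster-diagonal associations with noise flips
    vals <- matrix(0, spec$nDrugs, spec$nDiseases,
                   dimnames = list(drugIds, disIds))
    vals[outer(drugCl, disCl, `==`)] <- 1
    noise <- matrix(stats::runif(length(vals)) < spec$noiseRate,
                    nrow(vals))
    vals[noise] <- 1 - vals[noise]
    assoc <- new("AssociationMatrix", drugIds = drugIds,
                 diseaseIds = disIds, values = vals)

    list(drugs = drugs, diseases = diseases, dag = dag, sequences = seqs,
         assoc = assoc, drugClusters = drugCl, diseaseClusters = disCl,
         spec = spec)
  })
}

#' Write a synthetic bundle as plain-text fixtures
#'
#' Emits the fingerprint TSV, DAG edge TSV, target FASTA, drug-to-target
#' and disease-to-target TSVs, disease-to-term TSV and the association pair
#' TSV, all in the package's file dialects, re-loadable into an equivalent
#' bundle with \code{\link{readFixture}}.
#'
#' @param bundle list from \code{\link{generateSynthetic}}.
#' @param dir writable directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeFixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeFingerprints(bundle$drugs, p("fingerprints.tsv"))
  writeDag(bundle$dag, p("dag.tsv"))
  writeTargetSequences(bundle$sequences, p("targets.fasta"))
  writeTargetMap(targetSets(bundle$drugs), p("drug_targets.tsv"),
                 "drug_id", "target_id")
  writeTargetMap(targetSets(bundle$diseases), p("disease_targets.tsv"),
                 "disease_id", "target_id")
  utils::write.table(
    data.frame(disease_id = nodeIds(bundle$diseases),
               term = bundle$diseases@dagNodes),
    p("disease_terms.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  writeAssociations(bundle$assoc, p("associations.tsv"))
  invisible(dir)
}

#' Read a fixture directory back into a bundle
#'
#' Inverse of \code{\link{writeFixture}} (cluster labels are not part of
#' the file dialect and are not recovered).
#'
#' @param dir directory written by \code{\link{writeFixture}}.
#' @return named list with \code{drugs}, \code{diseases}, \code{dag},
#'   \code{sequences}, \code{assoc}.
#' @export
readFixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  drugs <- readFingerprints(p("fingerprints.tsv"))
  drugTg <- readTargetMap(p("drug_targets.tsv"), nodeIds(drugs))
  drugs <- DrugRegistry(nodeIds(drugs), fingerprints(drugs), drugTg)
  dag <- readDag(p("dag.tsv"))
  terms <- utils::read.delim(p("disease_terms.tsv"),
                             colClasses = "character")
  disTg <- readTargetMap(p("disease_targets.tsv"), terms$disease_id)
  diseases <- DiseaseRegistry(terms$disease_id, terms$term, dag, disTg)
  seqs <- readTargetSequences(p("targets.fasta"))
  assoc <- readAssociations(p("associations.tsv"), nodeIds(drugs),
                            nodeIds(diseases))
  list(drugs = drugs, diseases = diseases, dag = dag, sequences = seqs,
       assoc = assoc)
}
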