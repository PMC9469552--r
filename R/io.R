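## Readers and writers for the package's file dialect: UTF-8 TSV with a
## header row; matrix files carry ids in the first row and column, and
## similarity matrices carry their view tag in a leading comment line.
## Joins are always by id token, never by position.

#' Construct a drug registry
#'
#' @param ids character vector of unique drug ids.
#' @param fingerprints integer 0/1 matrix (drugs x bits) or a character
#'   vector of equal-length bitstrings.
#' @param targets named list of character vectors (target ids per drug);
#'   defaults to empty sets.
#' @return a \linkS4class{DrugRegistry}.
#' @export
DrugRegistry <- function(ids, fingerprints, targets = NULL) {
  ids <- as.character(ids)
  if (is.character(fingerprints)) {
    lens <- nchar(fingerprints)
    if (length(unique(lens)) > 1L)
      stop("ragged fingerprint bitstrings: all drugs must share one length")
    if (length(fingerprints) && grepl("[^01]", paste(fingerprints,
                                                     collapse = "")))
      stop("fingerprint bitstrings may contain only 0/1 characters")
    fingerprints <- do.call(rbind, lapply(strsplit(fingerprints, ""),
                                          as.integer))
    if (is.null(fingerprints))
      fingerprints <- matrix(integer(), 0, 0)
  }
  storage.mode(fingerprints) <- "integer"
  rownames(fingerprints) <- ids
  if (is.null(targets))
    targets <- stats::setNames(rep(list(character()), length(ids)), ids)
  targets <- targets[ids]
  names(targets) <- ids
  targets <- lapply(targets, function(x) unique(as.character(x)))
  new("DrugRegistry", ids = ids, fingerprints = fingerprints,
      targets = targets)
}

#' Construct a disease registry
#'
#' Every disease must name an ontology term present in \code{dag}; records
#' pointing at unknown terms are rejected (not dropped) so the disease count
#' is never silently skewed.
#'
#' @param ids character vector of unique disease ids.
#' @param dagNodes character vector of ontology terms, one per disease.
#' @param dag the \linkS4class{DiseaseDAG} the terms must live in.
#' @param targets named list of character vectors (target ids per disease).
#' @return a \linkS4class{DiseaseRegistry}.
#' @export
DiseaseRegistry <- function(ids, dagNodes, dag, targets = NULL) {
  ids <- as.character(ids)
  dagNodes <- as.character(dagNodes)
  missing <- setdiff(dagNodes, nodeIds(dag))
  if (length(missing))
    stop("disease terms absent from the DAG: ",
         paste(missing, collapse = ", "))
  if (is.null(targets))
    targets <- stats::setNames(rep(list(character()), length(ids)), ids)
  targets <- targets[ids]
  names(targets) <- ids
  targets <- lapply(targets, function(x) unique(as.character(x)))
  new("DiseaseRegistry", ids = ids, dagNodes = dagNodes, targets = targets)
}

#' Read drug fingerprints from a TSV table
#'
#' Expects a header and either a \code{fingerprint} column of uniform-length
#' 0/1 bitstrings, or a \code{smiles} column together with a
#' \code{fingerprinter} callback that maps one SMILES string to an integer
#' 0/1 vector (for example an Open Babel backed function). Precomputed bit
#' tables are the primary path; SMILES is the optional one.
#'
#' @param path file path.
#' @param fingerprinter optional function(smiles) -> integer 0/1 vector.
#' @return a \linkS4class{DrugRegistry} in file order.
#' @export
readFingerprints <- function(path, fingerprinter = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  idCol <- colnames(df)[1]
  ids <- df[[idCol]]
  if (anyDuplicated(ids))
    stop("duplicate drug ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if ("fingerprint" %in% colnames(df)) {
    DrugRegistry(ids, df$fingerprint)
  } else if ("smiles" %in% colnames(df)) {
    if (is.null(fingerprinter))
      stop("SMILES input requires a fingerprinter backend; ",
           "supply precomputed bitstrings or a fingerprinter function")
    bits <- lapply(df$smiles, fingerprinter)
    lens <- lengths(bits)
    if (length(unique(lens)) > 1L)
      stop("fingerprinter returned vectors of differing lengths")
    DrugRegistry(ids, do.call(rbind, bits))
  } else stop("expected a 'fingerprint' or 'smiles' column")
}

#' Write drug fingerprints as a TSV bit table
#' @param registry a \linkS4class{DrugRegistry}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeFingerprints <- function(registry, path) {
  df <- data.frame(
    drug_id = registry@ids,
    fingerprint = apply(registry@fingerprints, 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an entity-to-target mapping
#'
#' Two-column TSV (entity id, target id) with header; returns a named list
#' of target id sets keyed by entity, covering \code{ids} (entities without
#' rows get empty sets).
#'
#' @param path file path.
#' @param ids entity ids the map should cover.
#' @return named list of character vectors.
#' @export
readTargetMap <- function(path, ids) {
  df <- utils::read.delim(path, colClasses = "character")
  unknown <- setdiff(df[[1]], ids)
  if (length(unknown))
    stop("target map names unknown entities: ",
         paste(unique(unknown), collapse = ", "))
  out <- stats::setNames(rep(list(character()), length(ids)), ids)
  if (nrow(df))
    for (i in seq_len(nrow(df)))
      out[[df[i, 1]]] <- unique(c(out[[df[i, 1]]], df[i, 2]))
  out
}

#' Write an entity-to-target mapping as TSV
#' @param targets named list of character vectors.
#' @param path file path.
#' @param entityCol,targetCol column names for the header.
#' @return invisibly, the path.
#' @export
writeTargetMap <- function(targets, path, entityCol = "entity_id",
                           targetCol = "target_id") {
  rows <- do.call(rbind, lapply(names(targets), function(e) {
    if (length(targets[[e]])) cbind(e, targets[[e]]) else NULL
  }))
  if (is.null(rows)) rows <- matrix(character(), 0, 2)
  df <- stats::setNames(as.data.frame(rows, stringsAsFactors = FALSE),
                        c(entityCol, targetCol))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read known drug-disease associations
#'
#' Two-column TSV (drug id, disease id) with header. Pairs are resolved
#' against the supplied id orders; repeated pairs collapse to a single 1.
#'
#' @param path file path.
#' @param drugIds,diseaseIds ordered id vectors defining the matrix axes.
#' @return an \linkS4class{AssociationMatrix}.
#' @export
readAssociations <- function(path, drugIds, diseaseIds) {
  df <- utils::read.delim(path, colClasses = "character")
  vals <- matrix(0, length(drugIds), length(diseaseIds),
                 dimnames = list(drugIds, diseaseIds))
  if (nrow(df)) {
    badD <- setdiff(df[[1]], drugIds)
    badS <- setdiff(df[[2]], diseaseIds)
    if (length(badD) || length(badS))
      stop("associations name unknown ids: ",
           paste(unique(c(badD, badS)), collapse = ", "))
    vals[cbind(df[[1]], df[[2]])] <- 1
  }
  new("AssociationMatrix", drugIds = drugIds, diseaseIds = diseaseIds,
      values = vals)
}

#' Write associations as a TSV pair list
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeAssociations <- function(assoc, path) {
  idx <- which(assoc@values == 1, arr.ind = TRUE)
  df <- data.frame(drug_id = assoc@drugIds[idx[, 1]],
                   disease_id = assoc@diseaseIds[idx[, 2]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$drug_id, df$disease_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a similarity or association matrix with its ids
#'
#' Matrix dialect: an optional leading \code{# view: X} comment (similarity
#' matrices only), then a TSV whose first row holds column ids and whose
#' first column holds row ids. Values are written in full double precision.
#'
#' @param m a \linkS4class{SimilarityMatrix} or
#'   \linkS4class{AssociationMatrix}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeMatrix <- function(m, path) {
  if (is(m, "SimilarityMatrix")) {
    rows <- m@ids; cols <- m@ids
    header <- sprintf("# view: %s", m@view)
  } else if (is(m, "AssociationMatrix")) {
    rows <- m@drugIds; cols <- m@diseaseIds
    header <- NULL
  } else stop("writeMatrix expects a SimilarityMatrix or AssociationMatrix")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(c("id", cols), collapse = "\t"), con)
  vals <- m@values
  for (i in seq_along(rows))
    writeLines(paste(c(rows[i], sprintf("%.17g", vals[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a similarity matrix written by \code{writeMatrix}
#' @param path file path.
#' @return a \linkS4class{SimilarityMatrix} (validated: square, symmetric,
#'   entries in [0,1]).
#' @export
readSimilarityMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# view: [CTMA]$", first))
    stop("missing '# view:' tag: not a similarity matrix file")
  view <- sub("^# view: ", "", first)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (nrow(vals) != ncol(vals))
    stop("similarity matrix payload must be square")
  if (!identical(colnames(vals), ids))
    stop("row and column ids disagree")
  dimnames(vals) <- list(ids, ids)
  new("SimilarityMatrix", view = view, ids = ids, values = vals)
}

#' Read an association matrix written by \code{writeMatrix}
#' @param path file path.
#' @return an \linkS4class{AssociationMatrix}.
#' @export
readAssociationMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  dIds <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  sIds <- colnames(vals)
  dimnames(vals) <- list(dIds, sIds)
  new("AssociationMatrix", drugIds = dIds, diseaseIds = sIds, values = vals)
}

#' Read target protein sequences from FASTA
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences keyed by target
#'   id (first whitespace-delimited token of each header).
#' @export
readTargetSequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write target protein sequences as FASTA
#' @param seqs named character vector of amino-acid sequences.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeTargetSequences <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
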