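#' Build a disease ontology DAG from parent-child edges
#'
#' Constructs a rooted directed acyclic graph of ontology terms from a
#' two-column edge list (parent, child). Acyclicity is verified; roots are
#' the nodes without parents. Isolated terms may be supplied through
#' \code{nodes}.
#'
#' @param edges two-column character matrix or data.frame (parent, child);
#'   may have zero rows.
#' @param nodes optional character vector of additional (possibly isolated)
#'   term tokens.
#' @return a \linkS4class{DiseaseDAG}.
#' @examples
#' dag <- DiseaseDAG(data.frame(parent = c("r", "a"), child = c("a", "s")))
#' ancestorClosure(dag, "s")
#' @export
DiseaseDAG <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    edges <- matrix(character(), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L)
      stop("edges must have exactly two columns (parent, child)")
    storage.mode(edges) <- "character"
  }
  allNodes <- unique(c(as.vector(t(edges)), nodes))
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("cycle detected: the ontology edge list is not acyclic")
  }
  parents <- stats::setNames(vector("list", length(allNodes)), allNodes)
  for (nm in allNodes) parents[[nm]] <- character()
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ch <- edges[i, 2]
      parents[[ch]] <- unique(c(parents[[ch]], edges[i, 1]))
    }
  }
  roots <- allNodes[vapply(parents, length, 1L) == 0L]
  new("DiseaseDAG", nodes = allNodes, parents = parents, roots = roots)
}

#' @rdname ancestorClosure
setMethod("ancestorClosure", "DiseaseDAG", function(dag, term) {
  if (!term %in% dag@nodes)
    stop(sprintf("term '%s' not found in the DAG", term))
  seen <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(dag@parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
})

# children map restricted to a node subset, derived from parent links
childrenWithin <- function(dag, subset) {
  kids <- stats::setNames(vector("list", length(subset)), subset)
  for (nm in subset) kids[[nm]] <- character()
  for (nm in subset) {
    for (p in intersect(dag@parents[[nm]], subset))
      kids[[p]] <- c(kids[[p]], nm)
  }
  kids
}

#' Read a disease ontology DAG from a TSV edge list
#'
#' The file is a UTF-8 TSV with a header row and two columns
#' (\code{parent}, \code{child}). An optional \code{nodes} argument adds
#' isolated terms not mentioned in any edge.
#'
#' @param path file path.
#' @param nodes optional character vector of extra term tokens.
#' @return a \linkS4class{DiseaseDAG}.
#' @export
readDag <- function(path, nodes = character()) {
  df <- utils::read.delim(path, colClasses = "character")
  if (nrow(df) == 0L)
    return(DiseaseDAG(NULL, nodes = nodes))
  DiseaseDAG(df[, 1:2], nodes = nodes)
}

#' Write a DAG edge list as TSV
#' @param dag a \linkS4class{DiseaseDAG}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeDag <- function(dag, path) {
  rows <- do.call(rbind, lapply(dag@nodes, function(ch) {
    ps <- dag@parents[[ch]]
    if (length(ps)) cbind(parent = ps, child = ch) else NULL
  }))
  if (is.null(rows)) rows <- matrix(character(), 0, 2,
                                    dimnames = list(NULL, c("parent", "child")))
  utils::write.table(as.data.frame(rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
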