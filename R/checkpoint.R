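## Model checkpointing as a plain-text key -> array archive.
## Format: "#config<TAB>name<TAB>value" lines, then per array a header
## "@<key><TAB>nrow<TAB>ncol" followed by nrow tab-separated rows written
## in full double precision. Keys are slash-separated parameter paths
## (e.g. gcn/C/1, att/drug/W1, ext/disease/b, X0, Y0).

flattenParams <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm
    val <- params[[nm]]
    if (is.list(val)) {
      nms <- names(val)
      if (is.null(nms)) names(val) <- seq_along(val)
      out <- c(out, flattenParams(val, key))
    } else out[[key]] <- val
  }
  out
}

#' Save a model checkpoint
#'
#' Writes every weight array, the fixed initial features and the model
#' configuration to one self-describing text archive.
#'
#' @param model a \linkS4class{GcmmModel}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
saveGcmmModel <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  cfg <- model@config
  for (nm in names(cfg))
    writeLines(sprintf("#config\t%s\t%s", nm,
                       paste(cfg[[nm]], collapse = ",")), con)
  arrays <- c(flattenParams(model@params),
              list(X0 = model@X0, Y0 = model@Y0))
  for (key in names(arrays)) {
    a <- arrays[[key]]
    if (!is.matrix(a)) a <- matrix(a, nrow = 1)
    writeLines(sprintf("@%s\t%d\t%d", key, nrow(a), ncol(a)), con)
    for (i in seq_len(nrow(a)))
      writeLines(paste(sprintf("%.17g", a[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by \code{\link{saveGcmmModel}}.
#' @return a \linkS4class{GcmmModel} equal (within text round-trip
#'   precision, which for %.17g is exact for doubles) to the saved one.
#' @export
loadGcmmModel <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  cfg <- list()
  arrays <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#config")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      val <- strsplit(f[3], ",", fixed = TRUE)[[1]]
      suppressWarnings(num <- as.numeric(val))
      cfg[[f[2]]] <- if (anyNA(num)) val else
        if (all(num == as.integer(num))) as.integer(num) else num
      i <- i + 1L
    } else if (startsWith(ln, "@")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      nr <- as.integer(f[2]); nc <- as.integer(f[3])
      block <- lines[(i + 1):(i + nr)]
      vals <- as.numeric(unlist(strsplit(block, "\t", fixed = TRUE)))
      arrays[[substring(f[1], 2)]] <- matrix(vals, nr, nc, byrow = TRUE)
      i <- i + 1L + nr
    } else i <- i + 1L
  }
  params <- list(gcn = list(), att = list(), ext = list())
  X0 <- arrays$X0; Y0 <- arrays$Y0
  for (key in setdiff(names(arrays), c("X0", "Y0"))) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    a <- arrays[[key]]
    if (parts[1] == "gcn") {
      params$gcn[[parts[2]]][[as.integer(parts[3])]] <- a
    } else if (parts[1] == "ext" && parts[3] == "b") {
      params$ext[[parts[2]]][[parts[3]]] <- as.vector(a)
    } else {
      params[[parts[1]]][[parts[2]]][[parts[3]]] <- a
    }
  }
  new("GcmmModel", config = cfg, params = params, X0 = X0, Y0 = Y0)
}
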