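# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Smith-Waterman with affine gaps (Gotoh 3-matrix DP): gap of length L
# costs open + L * extend. Returns the best local score (>= 0).
oracleSmithWaterman <- function(s1, s2, submat, open, extend) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch
  E <- matrix(-Inf, n + 1, m + 1) # gap in s2 (deletion from s1)
  F <- matrix(-Inf, n + 1, m + 1) # gap in s1
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - open - extend,
                             E[i, j + 1] - extend)
      F[i + 1, j + 1] <- max(H[i + 1, j] - open - extend,
                             F[i + 1, j] - extend)
      sc <- submat[a[i], b[j]]
      H[i + 1, j + 1] <- max(0, H[i, j] + sc,
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# triple-loop sigma(L X W) with ReLU
oracleGcnLayer <- function(L, X, W) {
  n <- nrow(L); fin <- ncol(X); fout <- ncol(W)
  LX <- matrix(0, n, fin)
  for (i in seq_len(n)) for (j in seq_len(fin))
    for (k in seq_len(n)) LX[i, j] <- LX[i, j] + L[i, k] * X[k, j]
  Z <- matrix(0, n, fout)
  for (i in seq_len(n)) for (j in seq_len(fout))
    for (k in seq_len(fin)) Z[i, j] <- Z[i, j] + LX[i, k] * W[k, j]
  pmax(Z, 0)
}

# double loop of dot products for U = t(Xp) %*% Yp
oracleDecode <- function(Xp, Yp) {
  U <- matrix(0, ncol(Xp), ncol(Yp))
  for (i in seq_len(ncol(Xp))) for (j in seq_len(ncol(Yp)))
    U[i, j] <- sum(Xp[, i] * Yp[, j])
  U
}

# AUC as the fraction of (positive, negative) pairs ranked correctly,
# ties counting one half
oracleAuc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# step-integrated precision-recall area from first principles
oracleAupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prevR <- 0; area <- 0
  for (th in ths) {
    sel <- scores >= th
    r <- sum(labels[sel] == 1) / n1
    p <- sum(labels[sel] == 1) / sum(sel)
    area <- area + (r - prevR) * p
    prevR <- r
  }
  area
}

# random rooted DAG over n nodes: node i>1 gets 1-2 parents among 1..i-1
randomDag <- function(n) {
  nodes <- paste0("t", seq_len(n))
  edges <- NULL
  for (i in 2:n) {
    nPar <- sample(1:min(2, i - 1), 1)
    pars <- sample(seq_len(i - 1), nPar)
    edges <- rbind(edges, cbind(nodes[pars], nodes[i]))
  }
  DiseaseDAG(edges)
}

blosum <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

randomPeptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# set a value at a nested list path (for finite-difference perturbation)
modifyIn <- function(lst, path, value) {
  if (length(path) == 1) {
    lst[[path[[1]]]] <- value
    return(lst)
  }
  lst[[path[[1]]]] <- modifyIn(lst[[path[[1]]]], path[-1], value)
  lst
}
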