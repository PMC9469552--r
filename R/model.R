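## The multi-view GCN encoder / channel-attention / extractor / decoder
## model, written in plain dense linear algebra. Gradients are derived by
## hand (reverse-mode through each block) since the whole network is a
## short composition of matrix products and elementwise nonlinearities.

#' Symmetric normalized adjacency operator of a similarity graph
#'
#' Uses the similarity values directly as a weighted adjacency A, adds
#' self-loops (Atilde = I + A), and returns
#' L = Dtilde^(-1/2) Atilde Dtilde^(-1/2) where Dtilde is the diagonal
#' degree matrix of Atilde. L is symmetric; its rows need not sum to 1.
#'
#' @param G a \linkS4class{SimilarityMatrix} or square non-negative matrix.
#' @param topK optional integer: keep only the k largest off-diagonal
#'   entries per row (then re-symmetrize by maximum) before normalizing,
#'   for sparsified variants of large graphs.
#' @return square numeric matrix.
#' @examples
#' normalizedAdjacency(matrix(c(1, 1, 1, 1), 2))  # [[2/3,1/3],[1/3,2/3]]
#' @export
normalizedAdjacency <- function(G, topK = NULL) {
  A <- if (is(G, "SimilarityMatrix")) G@values else G
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (min(A) < 0) stop("adjacency must be non-negative")
  if (!is.null(topK)) {
    n <- nrow(A)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      off <- A[i, ]; off[i] <- -Inf
      ord <- order(off, decreasing = TRUE)[seq_len(min(topK, n - 1))]
      keep[i, ord] <- TRUE
    }
    keep <- keep | t(keep)
    A <- A * keep
  }
  Atilde <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Atilde))
  L <- Atilde * outer(dinv, dinv)
  (L + t(L)) / 2
}

#' One graph convolution layer
#'
#' Computes sigma(L X W): propagate features through the normalized
#' adjacency, mix with the layer weight, apply the activation (ReLU on all
#' layers; the only nonlinearities in the model are ReLU and the sigmoid of
#' the attention output).
#'
#' @param L normalized adjacency (n x n).
#' @param X input features (n x Fin).
#' @param W layer weight (Fin x Fout).
#' @param activation "relu" or "identity".
#' @return feature matrix (n x Fout).
#' @export
gcnLayer <- function(L, X, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(L) != nrow(X)) stop("L and X dimensions do not match")
  if (ncol(X) != nrow(W)) stop("X and W dimensions do not match")
  Z <- L %*% X %*% W
  if (activation == "relu") relu(Z) else Z
}

#' Global-average-pooling channel statistic
#'
#' Collapses a view embedding to one scalar: the mean over all its
#' nodes-by-features entries.
#'
#' @param X numeric matrix (nodes x features).
#' @return single numeric.
#' @export
channelStatistic <- function(X) {
  if (!length(X)) stop("cannot pool an empty embedding")
  mean(X)
}

#' Channel attention weights
#'
#' Squeeze-and-excitation style gating on the vector of channel statistics:
#' sigmoid(W2 %*% relu(W1 %*% z)). Every component is strictly in (0,1).
#'
#' @param zg numeric vector of channel statistics (one per view).
#' @param W1 weight (reduced x channels).
#' @param W2 weight (channels x reduced).
#' @return numeric vector of per-channel weights in (0,1).
#' @export
attentionWeights <- function(zg, W1, W2) {
  if (ncol(W1) != length(zg)) stop("W1 does not match channel count")
  if (ncol(W2) != nrow(W1)) stop("W1/W2 shapes do not compose")
  as.vector(sigmoid(W2 %*% relu(W1 %*% zg)))
}

#' Scale view embeddings by their attention weights
#'
#' Each view's embedding is multiplied by its scalar attention weight; the
#' reweighted channels are returned side by side (recoverable per channel).
#'
#' @param views named list of view embeddings (nodes x features each).
#' @param zatt numeric vector, one weight per view.
#' @return list with \code{scaled} (list of reweighted embeddings) and
#'   \code{stacked} (nodes x channels*features column-bound matrix).
#' @export
applyAttention <- function(views, zatt) {
  if (length(views) != length(zatt))
    stop("one attention weight per view channel required")
  scaled <- Map(function(X, z) X * z, views, as.list(zatt))
  list(scaled = scaled, stacked = do.call(cbind, unname(scaled)))
}

#' Fully connected feature extractor
#'
#' Each of the F_out output channels applies an independent linear unit to
#' a node's stacked multi-channel feature vector and a ReLU:
#' X' = relu(W %*% t(stacked) + b), giving the final (F_out x nodes)
#' features.
#'
#' @param stacked nodes x (channels*features) matrix from
#'   \code{\link{applyAttention}}.
#' @param W extractor weight (F_out x channels*features).
#' @param b bias vector of length F_out.
#' @return matrix (F_out x nodes).
#' @export
extractFeatures <- function(stacked, W, b) {
  if (ncol(W) != ncol(stacked)) stop("extractor weight does not match input")
  if (length(b) != nrow(W)) stop("bias length must equal output channels")
  relu(W %*% t(stacked) + b)
}

#' Inner-product matrix-completion decoder
#'
#' U[i, j] = <drug i feature, disease j feature>: the predicted degree of
#' association between drug i and disease j.
#'
#' @param Xp drug features (F x N_g).
#' @param Yp disease features (F x N_s).
#' @return score matrix (N_g x N_s).
#' @export
decodeScores <- function(Xp, Yp) {
  if (nrow(Xp) != nrow(Yp))
    stop("drug and disease feature dimensions must match")
  t(Xp) %*% Yp
}

#' Masked squared-Frobenius reconstruction loss
#'
#' ||U - U'||_F^2, restricted to a subset of cells when a mask is given
#' (the training-fold pairs); the full matrix otherwise.
#'
#' @param U predicted score matrix.
#' @param Uprime binary label matrix (same shape).
#' @param mask optional 2-column integer matrix of (row, col) indices.
#' @return non-negative numeric.
#' @export
gcmmLoss <- function(U, Uprime, mask = NULL) {
  if (!all(dim(U) == dim(Uprime))) stop("U and U' shapes differ")
  D <- U - Uprime
  if (is.null(mask)) sum(D^2) else sum(D[mask]^2)
}

defaultConfig <- function() {
  list(nLayers = 2L, embedDim = 256L, outChannels = 128L,
       attReduction = 1L, variant = "full",
       drugViews = c("C", "T"), diseaseViews = c("M", "A"),
       adjTopK = NA_integer_)
}

#' Model configuration
#'
#' Defaults follow the settings the hyper-parameter analysis selects:
#' 2 GCN layers, embedding size 256, 128 output channels.
#'
#' @param nLayers number of GCN layers per view (0 returns the initial
#'   features unchanged).
#' @param embedDim GCN embedding width F.
#' @param outChannels extractor output channels F_out.
#' @param attReduction attention bottleneck reduction factor r (the hidden
#'   width is max(1, channels / r)).
#' @param variant "full", "no_att" (attention replaced by unit weights) or
#'   "no_lin" (extractor bypassed; channels averaged).
#' @param drugViews subset of c("C","T") to use.
#' @param diseaseViews subset of c("M","A") to use.
#' @param adjTopK optional neighbourhood size: sparsify each similarity
#'   graph to its top-k strongest neighbours per node before
#'   normalization (NA keeps the dense weighted graphs). Dense similarity
#'   graphs are near-complete, so two propagation hops can average the
#'   whole graph; top-k keeps local structure on small dense instances.
#' @return named list.
#' @export
gcmmConfig <- function(nLayers = 2L, embedDim = 256L, outChannels = 128L,
                       attReduction = 1L, variant = c("full", "no_att",
                                                      "no_lin"),
                       drugViews = c("C", "T"),
                       diseaseViews = c("M", "A"),
                       adjTopK = NA_integer_) {
  variant <- match.arg(variant)
  if (!length(drugViews) || !length(diseaseViews))
    stop("at least one view per node family is required")
  drugViews <- match.arg(drugViews, c("C", "T"), several.ok = TRUE)
  diseaseViews <- match.arg(diseaseViews, c("M", "A"), several.ok = TRUE)
  list(nLayers = as.integer(nLayers), embedDim = as.integer(embedDim),
       outChannels = as.integer(outChannels),
       attReduction = as.integer(attReduction), variant = variant,
       drugViews = drugViews, diseaseViews = diseaseViews,
       adjTopK = as.integer(adjTopK))
}

#' Initialize a model
#'
#' Initial feature matrices X0/Y0 are drawn uniform in [0,1) and treated as
#' fixed inputs; all weights are Glorot-uniform. Everything is drawn from a
#' single seeded stream, so a given (sizes, config, seed) triple always
#' yields the same model.
#'
#' @param nDrugs,nDiseases node family sizes.
#' @param config list from \code{\link{gcmmConfig}}.
#' @param seed integer seed.
#' @return a \linkS4class{GcmmModel}.
#' @export
initGcmmModel <- function(nDrugs, nDiseases, config = gcmmConfig(),
                          seed = 1L) {
  cfg <- utils::modifyList(defaultConfig(), config)
  cfg$seed <- as.integer(seed)
  F <- cfg$embedDim
  withSeed(seed, {
    X0 <- matrix(stats::runif(nDrugs * F), nDrugs, F)
    Y0 <- matrix(stats::runif(nDiseases * F), nDiseases, F)
    params <- list(gcn = list(), att = list(), ext = list())
    for (v in c(cfg$drugViews, cfg$diseaseViews))
      params$gcn[[v]] <- lapply(seq_len(cfg$nLayers),
                                function(l) glorot(F, F))
    for (fam in c("drug", "disease")) {
      ch <- length(if (fam == "drug") cfg$drugViews else cfg$diseaseViews)
      red <- max(1L, ch %/% cfg$attReduction)
      if (cfg$variant != "no_att")
        params$att[[fam]] <- list(W1 = glorot(red, ch),
                                  W2 = glorot(ch, red))
      if (cfg$variant != "no_lin")
        params$ext[[fam]] <- list(W = glorot(cfg$outChannels, ch * F),
                                  b = rep(0, cfg$outChannels))
    }
    new("GcmmModel", config = cfg, params = params, X0 = X0, Y0 = Y0)
  })
}

#' Per-view GCN encodings of a network
#'
#' Runs each view's GCN stack on that view's normalized adjacency, starting
#' from the family's shared initial features. A 0-layer stack returns the
#' initial features unchanged.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param model a \linkS4class{GcmmModel}.
#' @return named list of embeddings, one per active view tag.
#' @export
encodeViews <- function(net, model) {
  Ls <- networkOperators(net, model@config)
  lapply(stats::setNames(nm = names(Ls)), function(v) {
    X <- if (v %in% c("C", "T")) model@X0 else model@Y0
    for (W in model@params$gcn[[v]]) X <- gcnLayer(Ls[[v]], X, W)
    X
  })
}

# normalized adjacency per active view, computed once per network
networkOperators <- function(net, config) {
  views <- c(config$drugViews, config$diseaseViews)
  topK <- config$adjTopK
  if (is.null(topK) || is.na(topK)) topK <- NULL
  stats::setNames(lapply(views, function(v)
    normalizedAdjacency(slot(net, paste0("G", v)), topK = topK)), views)
}

# Full forward pass over precomputed operators. Returns the score matrix
# plus every intermediate the backward pass needs.
gcmmForward <- function(model, Ls) {
  cfg <- model@config
  cache <- list()
  fams <- list(drug = cfg$drugViews, disease = cfg$diseaseViews)
  feats <- list()
  for (fam in names(fams)) {
    views <- fams[[fam]]
    X0 <- if (fam == "drug") model@X0 else model@Y0
    emb <- list(); pre <- list()
    for (v in views) {
      X <- X0
      pre[[v]] <- list()
      for (l in seq_along(model@params$gcn[[v]])) {
        Z <- Ls[[v]] %*% X %*% model@params$gcn[[v]][[l]]
        pre[[v]][[l]] <- list(input = X, Z = Z)
        X <- relu(Z)
      }
      emb[[v]] <- X
    }
    nF <- ncol(X0)
    if (cfg$variant == "no_att") {
      zatt <- rep(1, length(views))
      attCache <- NULL
    } else {
      zg <- unname(vapply(emb, channelStatistic, 0))
      W1 <- model@params$att[[fam]]$W1
      W2 <- model@params$att[[fam]]$W2
      a <- as.vector(W1 %*% zg)
      h <- relu(a)
      s <- as.vector(W2 %*% h)
      zatt <- sigmoid(s)
      attCache <- list(zg = zg, a = a, h = h, zatt = zatt)
    }
    att <- applyAttention(emb, zatt)
    if (cfg$variant == "no_lin") {
      Fp <- t(Reduce(`+`, att$scaled) / length(views))
      extCache <- NULL
    } else {
      W <- model@params$ext[[fam]]$W
      b <- model@params$ext[[fam]]$b
      Zext <- W %*% t(att$stacked) + b
      Fp <- relu(Zext)
      extCache <- list(Zext = Zext)
    }
    feats[[fam]] <- Fp
    cache[[fam]] <- list(views = views, emb = emb, pre = pre,
                         att = attCache, zatt = zatt,
                         scaled = att$scaled, stacked = att$stacked,
                         ext = extCache, Fp = Fp)
  }
  U <- decodeScores(feats$drug, feats$disease)
  list(U = U, cache = cache)
}

# Reverse-mode gradients of the masked loss w.r.t. every trainable weight.
# dU is dLoss/dU (same shape as U).
gcmmBackward <- function(model, Ls, fw, dU) {
  cfg <- model@config
  cache <- fw$cache
  grads <- list(gcn = list(), att = list(), ext = list())
  dFp <- list(drug = cache$disease$Fp %*% t(dU),
              disease = cache$drug$Fp %*% dU)
  for (fam in c("drug", "disease")) {
    cc <- cache[[fam]]
    views <- cc$views
    nF <- ncol(cc$emb[[views[1]]])
    if (cfg$variant == "no_lin") {
      # Fp = t(sum(scaled)/ch): spread gradient equally across channels
      dStackedPer <- t(dFp[[fam]]) / length(views)
      dScaled <- stats::setNames(rep(list(dStackedPer), length(views)),
                                 views)
    } else {
      dZext <- dFp[[fam]] * (cc$ext$Zext > 0)
      grads$ext[[fam]] <- list(W = dZext %*% cc$stacked,
                               b = rowSums(dZext))
      dStacked <- t(t(model@params$ext[[fam]]$W) %*% dZext)
      dScaled <- lapply(seq_along(views), function(k)
        dStacked[, ((k - 1) * nF + 1):(k * nF), drop = FALSE])
      names(dScaled) <- views
    }
    # through the per-channel scalar scaling (and attention MLP if present)
    dEmb <- list()
    dzatt <- numeric(length(views))
    for (k in seq_along(views)) {
      v <- views[k]
      dEmb[[v]] <- dScaled[[v]] * cc$zatt[k]
      dzatt[k] <- sum(dScaled[[v]] * cc$emb[[v]])
    }
    if (cfg$variant != "no_att") {
      at <- cc$att
      ds <- dzatt * at$zatt * (1 - at$zatt)
      W2 <- model@params$att[[fam]]$W2
      W1 <- model@params$att[[fam]]$W1
      grads$att[[fam]] <- list(
        W1 = (as.matrix(t(W2) %*% ds) * (at$a > 0)) %*% t(at$zg),
        W2 = as.matrix(ds) %*% t(at$h))
      dzg <- as.vector(t(W1) %*% ((t(W2) %*% ds) * (at$a > 0)))
      # zg_k = mean(emb_k): distribute back through the pooling
      for (k in seq_along(views)) {
        v <- views[k]
        dEmb[[v]] <- dEmb[[v]] + dzg[k] / length(cc$emb[[v]])
      }
    }
    # through the GCN stacks (L symmetric, so t(L) = L)
    for (v in views) {
      layers <- model@params$gcn[[v]]
      dX <- dEmb[[v]]
      grads$gcn[[v]] <- vector("list", length(layers))
      for (l in rev(seq_along(layers))) {
        pc <- cc$pre[[v]][[l]]
        dZ <- dX * (pc$Z > 0)
        LX <- Ls[[v]] %*% pc$input
        grads$gcn[[v]][[l]] <- t(LX) %*% dZ
        if (l > 1) dX <- Ls[[v]] %*% (dZ %*% t(layers[[l]]))
      }
    }
  }
  grads
}
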