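## Training: Adam optimization of the masked Frobenius loss over the
## model's nested parameter lists.

# apply f leafwise over parallel nested lists (keyed alignment by name)
nestedMap <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    nms <- names(args[[1]])
    out <- lapply(seq_along(args[[1]]), function(i)
      do.call(nestedMap, c(list(f), lapply(args, function(a)
        if (!is.null(nms)) a[[nms[i]]] else a[[i]]))))
    names(out) <- nms
    out
  } else do.call(f, args)
}

#' Training configuration
#'
#' Defaults follow the reported protocol: Adam, 1000 epochs, learning rate
#' 0.001.
#'
#' @param epochs number of full-batch epochs (>= 1).
#' @param lr learning rate (> 0; 0 is allowed and performs no update, which
#'   is occasionally useful as a null control).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed integer seed controlling initialization.
#' @return named list.
#' @export
trainConfig <- function(epochs = 1000L, lr = 0.001, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, seed = 1L) {
  stopifnot(epochs >= 1, lr >= 0)
  list(epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, seed = as.integer(seed))
}

#' Train the model on one cross-validation fold
#'
#' Optimizes all trainable weights (per-view GCN stacks, attention MLPs,
#' extractor layers) against the squared-Frobenius loss restricted to the
#' fold's training pairs, using full-batch Adam. The initial features X0/Y0
#' stay fixed. Deterministic given the seed.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param modelConfig list from \code{\link{gcmmConfig}}.
#' @param plan a \linkS4class{CvPlan}.
#' @param foldIndex validation fold held out of the mask; 0 trains on every
#'   pair in the plan (no holdout).
#' @param config list from \code{\link{trainConfig}}.
#' @return list: \code{model} (trained \linkS4class{GcmmModel}),
#'   \code{lossTrajectory} (numeric, one loss per epoch, evaluated before
#'   each update), \code{U} (final score matrix).
#' @export
trainFold <- function(net, modelConfig, plan, foldIndex, config) {
  if (foldIndex < 0 || foldIndex > plan@k)
    stop("invalid fold index ", foldIndex)
  pairs <- plan@pairs
  trainPairs <- pairs[pairs[, "fold"] != foldIndex, , drop = FALSE]
  mask <- trainPairs[, c("drug", "disease"), drop = FALSE]
  Uprime <- matrixValues(knownAssociations(net))
  model <- initGcmmModel(nrow(Uprime), ncol(Uprime), modelConfig,
                         seed = config$seed + foldIndex)
  Ls <- networkOperators(net, model@config)
  params <- model@params
  m <- nestedMap(function(x) x * 0, params)
  v <- m
  traj <- numeric(config$epochs)
  dUtmpl <- Uprime * 0
  for (epoch in seq_len(config$epochs)) {
    model@params <- params
    fw <- gcmmForward(model, Ls)
    loss <- gcmmLoss(fw$U, Uprime, mask)
    if (!is.finite(loss))
      stop("training diverged to a non-finite loss at epoch ", epoch)
    traj[epoch] <- loss
    dU <- dUtmpl
    dU[mask] <- 2 * (fw$U[mask] - Uprime[mask])
    g <- gcmmBackward(model, Ls, fw, dU)
    m <- nestedMap(function(mm, gg) config$beta1 * mm +
                     (1 - config$beta1) * gg, m, g)
    v <- nestedMap(function(vv, gg) config$beta2 * vv +
                     (1 - config$beta2) * gg^2, v, g)
    bc1 <- 1 - config$beta1^epoch
    bc2 <- 1 - config$beta2^epoch
    params <- nestedMap(function(pp, mm, vv)
      pp - config$lr * (mm / bc1) / (sqrt(vv / bc2) + config$eps),
      params, m, v)
  }
  model@params <- params
  fw <- gcmmForward(model, Ls)
  list(model = model, lossTrajectory = traj, U = fw$U,
       finalLoss = gcmmLoss(fw$U, Uprime, mask))
}

#' Train a model on all known data
#'
#' Builds a single-fold balanced plan over all positives (plus sampled
#' negatives) and trains with no holdout; the result is what
#' \code{\link{predictTopK}} consumes for prospective ranking.
#'
#' @inheritParams trainFold
#' @param regime negative-sampling regime, see \code{\link{makeCvPlan}}.
#' @return as \code{\link{trainFold}}.
#' @export
trainGcmm <- function(net, modelConfig = gcmmConfig(),
                      config = trainConfig(),
                      regime = c("balanced", "all_pairs")) {
  regime <- match.arg(regime)
  plan <- makeCvPlan(knownAssociations(net), k = 1L, regime = regime,
                     seed = config$seed)
  trainFold(net, modelConfig, plan, foldIndex = 0L, config = config)
}
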