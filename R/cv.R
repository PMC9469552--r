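## Cross-validation machinery: fold plans with negative sampling, the
## k-fold evaluation loop, ablations, hyper-parameter sweeps and top-k
## prospective prediction.

#' Build a cross-validation plan over association pairs
#'
#' Known associations are the positives. In the \code{balanced} regime an
#' equal number of negatives is sampled uniformly without replacement from
#' the zero cells; in the \code{all_pairs} regime every cell is folded.
#' Positives (and negatives) are partitioned into k folds. Deterministic
#' given the seed.
#'
#' @param assoc an \linkS4class{AssociationMatrix}.
#' @param k fold count (default 5).
#' @param regime "balanced" or "all_pairs".
#' @param seed integer seed.
#' @return a \linkS4class{CvPlan}.
#' @export
makeCvPlan <- function(assoc, k = 5L, regime = c("balanced", "all_pairs"),
                       seed = 1L) {
  regime <- match.arg(regime)
  k <- as.integer(k)
  vals <- matrixValues(assoc)
  pos <- which(vals == 1, arr.ind = TRUE)
  neg <- which(vals == 0, arr.ind = TRUE)
  if (nrow(pos) < k)
    stop("need at least k positive pairs (", nrow(pos), " < ", k, ")")
  withSeed(seed, {
    pos <- pos[sample.int(nrow(pos)), , drop = FALSE]
    posFold <- rep(seq_len(k), length.out = nrow(pos))
    if (regime == "balanced") {
      if (nrow(neg) < nrow(pos))
        stop("not enough zero cells to sample balanced negatives")
      neg <- neg[sample.int(nrow(neg), nrow(pos)), , drop = FALSE]
    } else {
      neg <- neg[sample.int(nrow(neg)), , drop = FALSE]
    }
    negFold <- rep(seq_len(k), length.out = nrow(neg))
    pairs <- rbind(
      cbind(drug = pos[, 1], disease = pos[, 2], label = 1L,
            fold = posFold),
      cbind(drug = neg[, 1], disease = neg[, 2], label = 0L,
            fold = negFold))
    rownames(pairs) <- NULL
    new("CvPlan", k = k, pairs = pairs, regime = regime,
        seed = as.integer(seed))
  })
}

evalReport <- function(perFold) {
  metr <- c("AUC", "AUPR", "F1", "ACC", "Recall", "Precision",
            "Specificity")
  means <- colMeans(perFold[, metr, drop = FALSE])
  new("EvalReport", perFold = perFold, means = means)
}

#' Run k-fold cross-validation
#'
#' Trains one model per fold on the fold's training pairs and scores the
#' held-out validation pairs; reports per-fold and mean metrics.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param modelConfig list from \code{\link{gcmmConfig}}.
#' @param plan a \linkS4class{CvPlan}.
#' @param config list from \code{\link{trainConfig}}.
#' @param thresholdRule passed to \code{\link{scoreMetrics}}.
#' @param keepModels also return the k trained models and loss
#'   trajectories.
#' @return an \linkS4class{EvalReport}; with \code{keepModels = TRUE} a
#'   list with elements \code{report}, \code{folds}.
#' @export
runCV <- function(net, modelConfig = gcmmConfig(), plan,
                  config = trainConfig(), thresholdRule = "fixed",
                  keepModels = FALSE) {
  rows <- vector("list", plan@k)
  folds <- if (keepModels) vector("list", plan@k) else NULL
  for (f in seq_len(plan@k)) {
    fit <- trainFold(net, modelConfig, plan, f, config)
    val <- plan@pairs[plan@pairs[, "fold"] == f, , drop = FALSE]
    scores <- fit$U[val[, c("drug", "disease"), drop = FALSE]]
    sm <- scoreMetrics(scores, val[, "label"],
                       thresholdRule = thresholdRule)
    rows[[f]] <- data.frame(fold = f, t(sm$metrics),
                            TP = unname(sm$counts["TP"]),
                            TN = unname(sm$counts["TN"]),
                            FP = unname(sm$counts["FP"]),
                            FN = unname(sm$counts["FN"]),
                            threshold = unname(sm$counts["threshold"]),
                            row.names = NULL)
    if (keepModels) folds[[f]] <- fit
  }
  report <- evalReport(do.call(rbind, rows))
  if (keepModels) list(report = report, folds = folds) else report
}

#' Repeat cross-validation with distinct seeds
#'
#' Re-draws the fold plan and re-initializes the model with a different
#' seed per repeat and reports the mean and standard deviation of the mean
#' metrics across repeats.
#'
#' @inheritParams runCV
#' @param k fold count per repeat.
#' @param regime negative-sampling regime.
#' @param repeats number of repeats (default 1).
#' @param baseSeed seed of the first repeat; repeat r uses baseSeed + r - 1.
#' @return list: \code{perRepeat} (data.frame of mean metrics per repeat),
#'   \code{mean}, \code{sd} (named numeric vectors).
#' @export
repeatCV <- function(net, modelConfig = gcmmConfig(), k = 5L,
                     regime = "balanced", config = trainConfig(),
                     repeats = 1L, baseSeed = 1L) {
  rows <- lapply(seq_len(repeats), function(r) {
    seed <- baseSeed + r - 1L
    plan <- makeCvPlan(knownAssociations(net), k = k, regime = regime,
                       seed = seed)
    cfg <- config; cfg$seed <- seed
    as.data.frame(t(meanMetrics(runCV(net, modelConfig, plan, cfg))))
  })
  perRepeat <- do.call(rbind, rows)
  list(perRepeat = perRepeat,
       mean = colMeans(perRepeat),
       sd = apply(perRepeat, 2, stats::sd))
}

#' Run an ablated variant of the model through cross-validation
#'
#' \code{full} is identical to \code{\link{runCV}}; \code{no_att} replaces
#' the attention weights with unit weights; \code{no_lin} bypasses the
#' extractor and averages the channels into the final features. View
#' subsets drop the excluded similarity matrices and shrink the attention
#' channel count accordingly.
#'
#' @inheritParams runCV
#' @param variant "full", "no_att" or "no_lin".
#' @param drugViews subset of c("C", "T") (at least one).
#' @param diseaseViews subset of c("M", "A") (at least one).
#' @return an \linkS4class{EvalReport}.
#' @export
runAblation <- function(net, plan, config = trainConfig(),
                        variant = c("full", "no_att", "no_lin"),
                        drugViews = c("C", "T"),
                        diseaseViews = c("M", "A"),
                        modelConfig = gcmmConfig()) {
  variant <- match.arg(variant)
  modelConfig$variant <- variant
  modelConfig$drugViews <- drugViews
  modelConfig$diseaseViews <- diseaseViews
  modelConfig <- do.call(gcmmConfig, modelConfig[names(modelConfig) %in%
                                                 names(formals(gcmmConfig))])
  runCV(net, modelConfig, plan, config)
}

#' Sweep one hyper-parameter across a value grid
#'
#' Runs one cross-validation per value with everything else (including the
#' seed) fixed and tabulates the mean metrics.
#'
#' @inheritParams runCV
#' @param param one of "layers", "embedding", "channels", "lr".
#' @param values numeric vector (length >= 2) of settings to try.
#' @return data.frame: one row per value with the mean metrics and the
#'   final-epoch mean training loss.
#' @export
sweepHyperParams <- function(net, plan, param = c("layers", "embedding",
                                                  "channels", "lr"),
                             values, modelConfig = gcmmConfig(),
                             config = trainConfig()) {
  param <- match.arg(param)
  if (length(values) < 2) stop("sweep needs at least 2 values")
  rows <- lapply(values, function(val) {
    mc <- modelConfig; tc <- config
    switch(param,
           layers = { mc$nLayers <- as.integer(val) },
           embedding = { mc$embedDim <- as.integer(val) },
           channels = { mc$outChannels <- as.integer(val) },
           lr = { tc$lr <- val })
    rep <- runCV(net, mc, plan, tc)
    data.frame(param = param, value = val, t(meanMetrics(rep)))
  })
  do.call(rbind, rows)
}

#' Rank the top-k candidate drugs for a disease
#'
#' Scores every drug against the disease with the trained model (or the
#' mean score over a list of models), removes drugs already known to be
#' associated, and returns the k best. Ties are broken by drug id order.
#'
#' @param model a trained \linkS4class{GcmmModel}, a list of them, or a
#'   fit object returned by \code{\link{trainGcmm}}/\code{\link{trainFold}}.
#' @param net the \linkS4class{HeterogeneousNetwork} to score.
#' @param diseaseId disease token present in the network.
#' @param k list length (trimmed to the number of unknown pairs).
#' @return data.frame with columns drug_id, score, rank.
#' @export
predictTopK <- function(model, net, diseaseId, k = 5L) {
  sIds <- diseaseIds(net)
  if (!diseaseId %in% sIds)
    stop("unknown disease id: ", diseaseId)
  models <- if (is(model, "GcmmModel")) list(model)
    else if (is.list(model) && !is.null(model$model)) list(model$model)
    else lapply(model, function(m) if (is(m, "GcmmModel")) m else m$model)
  Us <- lapply(models, function(m)
    gcmmForward(m, networkOperators(net, m@config))$U)
  U <- Reduce(`+`, Us) / length(Us)
  j <- match(diseaseId, sIds)
  known <- matrixValues(knownAssociations(net))[, j] == 1
  dIds <- drugIds(net)
  cand <- which(!known)
  scores <- U[cand, j]
  ord <- order(-scores, cand)
  take <- utils::head(ord, k)
  data.frame(drug_id = dIds[cand[take]], score = scores[take],
             rank = seq_along(take), row.names = NULL)
}
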