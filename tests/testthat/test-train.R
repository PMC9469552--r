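smallAssoc <- function() {
  vals <- matrix(0, 5, 4, dimnames = list(paste0("d", 1:5),
                                          paste0("s", 1:4)))
  vals[cbind(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
             c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2))] <- 1
  new("AssociationMatrix", drugIds = rownames(vals),
      diseaseIds = colnames(vals), values = vals)
}

test_that("balanced fold plans partition positives and sample matched negatives", {
  am <- smallAssoc()  # 10 positives in a 5x4 grid
  plan <- makeCvPlan(am, k = 5, regime = "balanced", seed = 3L)
  pairs <- plan@pairs
  pos <- pairs[pairs[, "label"] == 1, , drop = FALSE]
  neg <- pairs[pairs[, "label"] == 0, , drop = FALSE]
  expect_identical(nrow(pos), 10L)
  expect_identical(nrow(neg), 10L)
  for (f in 1:5) {
    expect_identical(sum(pos[, "fold"] == f), 2L)
    expect_identical(sum(neg[, "fold"] == f), 2L)
  }
  # positives exactly cover the observed cells, once each
  vals <- matrixValues(am)
  obs <- which(vals == 1, arr.ind = TRUE)
  expect_identical(sort(pos[, "drug"] * 100 + pos[, "disease"]),
                   sort(unname(obs[, 1] * 100 + obs[, 2])))
  # negatives come from zero cells, no duplicates
  expect_true(all(vals[neg[, c("drug", "disease")]] == 0))
  expect_identical(anyDuplicated(neg[, c("drug", "disease")]), 0L)
})

test_that("fold plans are deterministic in the seed and cover all cells in all_pairs", {
  am <- smallAssoc()
  p1 <- makeCvPlan(am, k = 5, seed = 9L)
  p2 <- makeCvPlan(am, k = 5, seed = 9L)
  expect_identical(p1@pairs, p2@pairs)
  ap <- makeCvPlan(am, k = 4, regime = "all_pairs", seed = 2L)
  expect_identical(nrow(ap@pairs), 20L)
  expect_error(makeCvPlan(am, k = 11, seed = 1L), "at least k")
})

test_that("zero learning rate leaves parameters and loss untouched", {
  net <- tinyNet()
  plan <- makeCvPlan(knownAssociations(net), k = 3, seed = 1L)
  tc <- trainConfig(epochs = 5L, lr = 0, seed = 1L)
  fit <- trainFold(net, tinyModelConfig(), plan, 1L, tc)
  expect_identical(length(unique(fit$lossTrajectory)), 1L)
  init <- initGcmmModel(6, 4, tinyModelConfig(), seed = 1L + 1L)
  expect_equal(fit$model@params, init@params, tolerance = 0)
})

test_that("training descends and is bit-reproducible under a fixed seed", {
  net <- tinyNet()
  plan <- makeCvPlan(knownAssociations(net), k = 3, seed = 4L)
  tc <- trainConfig(epochs = 60L, seed = 4L)
  fit1 <- trainFold(net, tinyModelConfig(adjTopK = 3L), plan, 1L, tc)
  fit2 <- trainFold(net, tinyModelConfig(adjTopK = 3L), plan, 1L, tc)
  expect_lt(fit1$finalLoss, fit1$lossTrajectory[1])
  expect_identical(fit1$lossTrajectory, fit2$lossTrajectory)
  expect_identical(fit1$U, fit2$U)
})

test_that("threshold metrics reproduce the hand-computed confusion table", {
  # 8 TP + 2 FP scored high, 7 TN + 3 FN scored low
  scores <- c(rep(0.9, 10), rep(0.1, 10))
  labels <- c(rep(1, 8), rep(0, 2), rep(0, 7), rep(1, 3))
  sm <- scoreMetrics(scores, labels)
  expect_identical(unname(sm$counts[c("TP", "TN", "FP", "FN")]),
                   c(8, 7, 2, 3))
  expect_equal(unname(sm$metrics["Precision"]), 0.8)
  expect_equal(unname(sm$metrics["Recall"]), 8 / 11)
  expect_equal(unname(sm$metrics["ACC"]), 0.75)
  expect_equal(unname(sm$metrics["Specificity"]), 7 / 9)
  expect_equal(unname(sm$metrics["F1"]),
               2 * (0.8 * 8 / 11) / (0.8 + 8 / 11), tolerance = 1e-12)
})

test_that("ranking metrics match brute-force oracles and edge behaviour", {
  sep <- scoreMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(unname(sep$metrics["AUC"]), 1)
  expect_identical(unname(sep$metrics["AUPR"]), 1)

  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(20:200, 1)
      scores <- round(rnorm(n), 1)  # coarse grid forces ties
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) == 0 || sum(labels) == n) next
      sm <- scoreMetrics(scores, labels)
      expect_equal(unname(sm$metrics["AUC"]), oracleAuc(scores, labels),
                   tolerance = 1e-10)
      expect_equal(unname(sm$metrics["AUPR"]), oracleAupr(scores, labels),
                   tolerance = 1e-10)
    }
    # label-independent scores give chance-level AUC at large n
    n <- 4000
    scores <- rnorm(n); labels <- rbinom(n, 1, 0.5)
    expect_lt(abs(scoreMetrics(scores, labels)$metrics["AUC"] - 0.5), 0.05)
  })
  expect_error(scoreMetrics(c(1, 2), c(1, 1)), "both classes")
})

test_that("the F1-maximizing threshold rule never underperforms the fixed rule", {
  withr::with_seed(23, {
    scores <- rnorm(100)
    labels <- rbinom(100, 1, 0.5)
    fixed <- scoreMetrics(scores, labels)
    best <- scoreMetrics(scores, labels, thresholdRule = "f1max")
    expect_gte(best$metrics["F1"], fixed$metrics["F1"])
  })
})

test_that("cross-validation reports one row per fold and exact fold means", {
  net <- tinyNet()
  plan <- makeCvPlan(knownAssociations(net), k = 3, seed = 7L)
  rep1 <- runCV(net, tinyModelConfig(adjTopK = 3L), plan,
                trainConfig(epochs = 40L, seed = 7L))
  pf <- foldMetrics(rep1)
  expect_identical(nrow(pf), 3L)
  for (m in names(meanMetrics(rep1)))
    expect_equal(unname(meanMetrics(rep1)[m]), mean(pf[[m]]),
                 tolerance = 1e-12)
  rep2 <- runCV(net, tinyModelConfig(adjTopK = 3L), plan,
                trainConfig(epochs = 40L, seed = 7L))
  expect_identical(pf, foldMetrics(rep2))
})

test_that("ablation variants rewire the architecture as advertised", {
  net <- tinyNet()
  plan <- makeCvPlan(knownAssociations(net), k = 3, seed = 5L)
  tc <- trainConfig(epochs = 25L, seed = 5L)
  mc <- tinyModelConfig(adjTopK = 3L)
  full1 <- runAblation(net, plan, tc, variant = "full", modelConfig = mc)
  full2 <- runCV(net, do.call(gcmmConfig,
                              mc[names(mc) %in% names(formals(gcmmConfig))]),
                 plan, tc)
  expect_identical(foldMetrics(full1), foldMetrics(full2))
  # view subsets shrink the channel count
  oneview <- runAblation(net, plan, tc, drugViews = "C",
                         diseaseViews = "M", modelConfig = mc)
  expect_s4_class(oneview, "EvalReport")
  expect_error(gcmmConfig(drugViews = character()), "at least one view")
})

test_that("hyper-parameter sweeps tabulate one deterministic row per value", {
  net <- tinyNet()
  plan <- makeCvPlan(knownAssociations(net), k = 3, seed = 2L)
  tc <- trainConfig(epochs = 15L, seed = 2L)
  tab <- sweepHyperParams(net, plan, "layers", c(1L, 2L, 3L),
                          modelConfig = tinyModelConfig(adjTopK = 3L),
                          config = tc)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$value, c(1, 2, 3))
  tab2 <- sweepHyperParams(net, plan, "layers", c(1L, 2L, 3L),
                           modelConfig = tinyModelConfig(adjTopK = 3L),
                           config = tc)
  expect_identical(tab, tab2)
  expect_error(sweepHyperParams(net, plan, "lr", 0.1,
                                modelConfig = tinyModelConfig()),
               "at least 2")
})

test_that("top-k prediction excludes known pairs and breaks ties by drug order", {
  net <- tinyNet()
  model <- initGcmmModel(6, 4, tinyModelConfig(), seed = 8L)
  top <- predictTopK(model, net, "s1", k = 10)
  known <- drugIds(net)[matrixValues(knownAssociations(net))[, 1] == 1]
  expect_true(!any(top$drug_id %in% known))
  expect_identical(nrow(top), 3L)  # only 3 unknown drugs for s1
  expect_error(predictTopK(model, net, "nosuch", 5), "unknown disease")

  # force exact ties: zero weights make all scores equal
  m0 <- model
  m0@params$ext$drug$W[] <- 0; m0@params$ext$drug$b[] <- 0
  tie <- predictTopK(m0, net, "s1", k = 2)
  expect_identical(tie$drug_id, c("d4", "d5"))
})

test_that("repeat harness reports per-repeat means with their spread", {
  net <- tinyNet()
  out <- repeatCV(net, tinyModelConfig(adjTopK = 3L), k = 2,
                  config = trainConfig(epochs = 10L), repeats = 2,
                  baseSeed = 1L)
  expect_identical(nrow(out$perRepeat), 2L)
  expect_equal(unname(out$mean["AUC"]), mean(out$perRepeat$AUC))
  expect_identical(length(out$sd), ncol(out$perRepeat))
})
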