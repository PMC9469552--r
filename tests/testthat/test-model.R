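test_that("normalized adjacency matches hand-worked cases and stays symmetric", {
  expect_equal(normalizedAdjacency(matrix(1, 1, 1)), matrix(1, 1, 1),
               tolerance = 1e-12)
  L <- normalizedAdjacency(matrix(c(1, 1, 1, 1), 2))
  expect_equal(L, matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-15)
  withr::with_seed(4, {
    A <- matrix(runif(49), 7); A <- (A + t(A)) / 2
    Ln <- normalizedAdjacency(A)
    expect_lt(max(abs(Ln - t(Ln))), 1e-12)
    # equivariance: permuting the graph permutes the operator
    p <- sample(7)
    expect_equal(normalizedAdjacency(A[p, p]), Ln[p, p], tolerance = 1e-12)
  })
  expect_error(normalizedAdjacency(matrix(1, 2, 3)), "square")
})

test_that("a GCN layer is sigma(L X W) against a triple-loop oracle", {
  X <- matrix(c(1, 2, -3, 4), 2)
  expect_identical(gcnLayer(diag(2), pmax(X, 0), diag(2)), pmax(X, 0))
  expect_identical(gcnLayer(matrix(1), matrix(2), matrix(-3)), matrix(0))
  withr::with_seed(8, {
    for (i in 1:100) {
      n <- sample(2:5, 1); fin <- sample(2:4, 1); fout <- sample(2:4, 1)
      L <- matrix(rnorm(n * n), n)
      X <- matrix(rnorm(n * fin), n)
      W <- matrix(rnorm(fin * fout), fin)
      expect_equal(gcnLayer(L, X, W), oracleGcnLayer(L, X, W),
                   tolerance = 1e-10)
    }
  })
  expect_error(gcnLayer(diag(2), matrix(1, 3, 2), diag(2)), "dimension")
})

test_that("view encodings honour layer count, shape and node symmetry", {
  net <- tinyNet()
  m0 <- initGcmmModel(6, 4, tinyModelConfig(nLayers = 0L), seed = 2L)
  enc0 <- encodeViews(net, m0)
  expect_identical(enc0$C, m0@X0)
  expect_identical(enc0$M, m0@Y0)

  m2 <- initGcmmModel(6, 4, tinyModelConfig(), seed = 2L)
  enc <- encodeViews(net, m2)
  expect_identical(dim(enc$T), c(6L, 8L))
  expect_identical(dim(enc$A), c(4L, 8L))

  # identical drugs on a complete graph with identical start rows give
  # identical embedding rows (permutation equivariance)
  fp <- matrix(rep(c(1, 0, 1), 3), 3, byrow = TRUE)
  reg <- DrugRegistry(c("a", "b", "c"), fp)
  GC <- buildSimilarityMatrix(reg, "chemical")
  L <- normalizedAdjacency(GC)
  X0 <- matrix(1, 3, 5)
  W <- withr::with_seed(1, matrix(rnorm(25), 5))
  out <- gcnLayer(L, X0, W[, 1:5])
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-12)
})

test_that("channel statistics are global averages", {
  expect_identical(channelStatistic(matrix(7, 3, 5)), 7)
  expect_identical(channelStatistic(matrix(c(1, 3, 2, 4), 2)), 2.5)
  expect_identical(channelStatistic(matrix(0, 2, 2)), 0)
  expect_error(channelStatistic(matrix(numeric(), 0, 0)), "empty")
})

test_that("attention weights are sigmoid-bounded and zero-parameter neutral", {
  expect_identical(attentionWeights(c(3, -2), matrix(0, 2, 2),
                                    matrix(0, 2, 2)), c(0.5, 0.5))
  withr::with_seed(14, {
    for (i in 1:20) {
      z <- rnorm(2, sd = 5)
      W1 <- matrix(rnorm(4), 2); W2 <- matrix(rnorm(4), 2)
      w <- attentionWeights(z, W1, W2)
      expect_true(all(w > 0 & w < 1))
      # hand-composed arithmetic
      expect_equal(w, as.vector(1 / (1 + exp(-(W2 %*% pmax(W1 %*% z, 0))))))
    }
  })
  expect_error(attentionWeights(c(1, 2, 3), matrix(0, 2, 2),
                                matrix(0, 2, 2)), "channel")
})

test_that("attention scaling is per-channel and recoverable", {
  a <- matrix(2, 3, 2); b <- matrix(4, 3, 2)
  out <- applyAttention(list(C = a, T = b), c(1, 0.5))
  expect_identical(out$scaled$C, a)
  expect_identical(out$scaled$T, matrix(2, 3, 2))
  expect_identical(out$stacked[, 1:2], out$scaled$C)
  expect_identical(out$stacked[, 3:4], out$scaled$T)
  expect_error(applyAttention(list(a, b), 1), "per view")
})

test_that("the extractor is an independent linear unit per output channel", {
  stacked <- matrix(c(1, 2, 3, 4), 2)
  expect_identical(extractFeatures(stacked, matrix(0, 3, 2), rep(0, 3)),
                   matrix(0, 3, 2))
  # one node, one channel pair, one output: sigma(b + x.w)
  x <- matrix(c(2, -1), 1)
  W <- matrix(c(0.5, 1), 1)
  expect_identical(extractFeatures(x, W, 0.25), matrix(0.25, 1, 1))
  expect_identical(dim(extractFeatures(matrix(1, 5, 4),
                                       matrix(1, 3, 4), rep(0, 3))),
                   c(3L, 5L))
})

test_that("the decoder matches a brute-force inner-product oracle", {
  expect_identical(decodeScores(matrix(c(1, 0), 2), matrix(c(0, 1), 2)),
                   matrix(0, 1, 1))
  expect_identical(decodeScores(matrix(c(1, 0), 2), matrix(c(1, 0), 2)),
                   matrix(1, 1, 1))
  withr::with_seed(10, {
    for (i in 1:100) {
      f <- sample(2:4, 1)
      Xp <- matrix(rnorm(f * 3), f)
      Yp <- matrix(rnorm(f * 5), f)
      expect_equal(decodeScores(Xp, Yp), oracleDecode(Xp, Yp),
                   tolerance = 1e-12)
    }
  })
  expect_error(decodeScores(matrix(1, 2, 2), matrix(1, 3, 2)), "match")
})

test_that("the reconstruction loss is the masked squared Frobenius norm", {
  U <- matrix(c(1, 0, 0.5, 1), 2)
  expect_identical(gcmmLoss(U, U), 0)
  Up <- U; Up[1, 2] <- U[1, 2] - 2
  expect_identical(gcmmLoss(U, Up), 4)
  mask <- rbind(c(1, 1), c(2, 2), c(1, 2))
  D <- matrix(c(.1, .2, .3, .4), 2)
  expect_equal(gcmmLoss(U + D, U, mask), D[1, 1]^2 + D[2, 2]^2 + D[1, 2]^2)
  expect_error(gcmmLoss(matrix(0, 2, 2), matrix(0, 3, 2)), "shapes")
})

test_that("zero attention parameters reduce to the half-scaled no-attention model", {
  net <- tinyNet()
  full <- initGcmmModel(6, 4, tinyModelConfig(), seed = 6L)
  full@params$att$drug$W1[] <- 0; full@params$att$drug$W2[] <- 0
  full@params$att$disease$W1[] <- 0; full@params$att$disease$W2[] <- 0
  noatt <- initGcmmModel(6, 4, tinyModelConfig(variant = "no_att"),
                         seed = 6L)
  # align the shared weights (init order differs between variants)
  noatt@params$gcn <- full@params$gcn
  noatt@params$ext <- full@params$ext
  noatt@X0 <- full@X0; noatt@Y0 <- full@Y0
  ops <- gcmm:::networkOperators(net, full@config)
  fwFull <- gcmm:::gcmmForward(full, ops)
  fwNo <- gcmm:::gcmmForward(noatt, ops)
  expect_equal(fwFull$cache$drug$zatt, c(0.5, 0.5))
  # with zero biases the extractor is positively homogeneous, so halving
  # each channel quarters the decoded scores
  expect_equal(fwFull$U, fwNo$U * 0.25, tolerance = 1e-12)
})

test_that("the full forward pass is deterministic under a fixed seed", {
  net <- tinyNet()
  m1 <- initGcmmModel(6, 4, tinyModelConfig(), seed = 42L)
  m2 <- initGcmmModel(6, 4, tinyModelConfig(), seed = 42L)
  ops <- gcmm:::networkOperators(net, m1@config)
  expect_identical(gcmm:::gcmmForward(m1, ops)$U,
                   gcmm:::gcmmForward(m2, ops)$U)
})

test_that("analytic gradients agree with finite differences", {
  net <- tinyNet()
  Uprime <- matrixValues(knownAssociations(net))
  mask <- rbind(c(1, 1), c(2, 3), c(5, 2), c(6, 4), c(3, 1))
  for (variant in c("full", "no_att", "no_lin")) {
    model <- initGcmmModel(6, 4, gcmmConfig(embedDim = 3L,
                                            outChannels = 2L,
                                            variant = variant), seed = 9L)
    ops <- gcmm:::networkOperators(net, model@config)
    fw <- gcmm:::gcmmForward(model, ops)
    dU <- Uprime * 0
    dU[mask] <- 2 * (fw$U[mask] - Uprime[mask])
    g <- gcmm:::gcmmBackward(model, ops, fw, dU)
    flat <- gcmm:::flattenParams(g)
    for (key in names(flat)) {
      ga <- flat[[key]]
      idx <- if (is.matrix(ga))
        which(abs(ga) == max(abs(ga)), arr.ind = TRUE)[1, ]
      else which.max(abs(ga))
      eps <- 1e-6
      path <- lapply(strsplit(key, "/")[[1]], function(p)
        if (grepl("^[0-9]+$", p)) as.integer(p) else p)
      perturb <- function(h) {
        m2 <- model
        ref <- Reduce(function(acc, k) acc[[k]], path, m2@params)
        if (is.matrix(ref)) ref[idx[1], idx[2]] <- ref[idx[1], idx[2]] + h
        else ref[idx] <- ref[idx] + h
        m2@params <- modifyIn(m2@params, path, ref)
        gcmmLoss(gcmm:::gcmmForward(m2, ops)$U, Uprime, mask)
      }
      fd <- (perturb(eps) - perturb(-eps)) / (2 * eps)
      an <- if (is.matrix(ga)) ga[idx[1], idx[2]] else ga[idx]
      expect_equal(unname(an), fd, tolerance = 1e-5)
    }
  }
})
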