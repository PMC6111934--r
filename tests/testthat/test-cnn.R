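test_that("sliding-window bookkeeping follows floor((T - length)/shift) + 1", {
    expect_length(slidingWindows(matrix(0, 1800, 4))$starts, 59L)
    expect_length(slidingWindows(matrix(0, 60, 4))$starts, 1L)
    expect_length(slidingWindows(matrix(0, 89, 4))$starts, 1L)
    expect_length(slidingWindows(matrix(0, 90, 4))$starts, 2L)
    expect_error(slidingWindows(matrix(0, 59, 4)), "at least")
    sw <- slidingWindows(matrix(seq_len(300), 150, 2), length = 60,
                         shift = 30)
    # windows are half-open [start, start + 60)
    expect_equal(sw$starts, c(0L, 30L, 60L, 90L))
    expect_equal(sw$windows[, 1, 2], 31:90)
})

test_that("estimator specs mirror the schema layout", {
    sch <- defaultAttributeSchema()
    specs <- estimatorSpecs(sch)
    expect_length(specs, 14L)
    expect_equal(specs[["Ha(L)"]]$kernel, c(3L, 10L))
    expect_equal(specs[["He"]]$kernel, c(3L, 3L))
    expect_equal(specs[["He"]]$nOut, 5L)
    expect_equal(specs[["K(L)"]]$kind, "regression")
    expect_equal(specs[["Ha(R)"]]$M, 80L)
    # kernel wider than the channel count is refused
    toy <- toySchema("A,classification,x;y,s1")
    expect_error(estimatorSpec(toy, "A", kernel = c(3L, 11L)), "kernel")
})

test_that("untrained heads already honour the output constraints", {
    sch <- smallSchema()
    set.seed(2)
    x <- array(rnorm(60 * 10 * 7), c(60, 10, 7))
    cls <- buildEstimator(sch, "J1", seed = 1)
    p <- predictEstimator(cls, x)
    expect_equal(dim(p), c(3L, 7L))
    expect_equal(colSums(p), rep(1, 7))
    expect_true(all(p >= 0))
    reg <- buildEstimator(sch, "J2", seed = 1)
    x2 <- array(rnorm(60 * 20 * 7), c(60, 20, 7))
    p2 <- predictEstimator(reg, x2)
    expect_true(all(p2 >= 0 & p2 <= 1))
})

test_that("backpropagated gradients match finite differences", {
    sch <- smallSchema()
    spec <- estimatorSpec(sch, "J1", convChannels = c(3L, 2L), fcNodes = 6L,
                          dropout = 0, windowLength = 12L)
    est <- buildEstimator(sch, "J1", spec = spec, seed = 2)
    set.seed(3)
    N <- 4
    x <- array(rnorm(12 * 10 * N), c(12, 10, N))
    y <- c(1L, 2L, 3L, 2L)
    xb <- x; dim(xb) <- c(12, 10, 1, N)
    loss <- function(pp) {
        fw <- zslpose:::.cnnForward(pp, est@spec, xb, training = TRUE)
        zslpose:::.cnnLossGrad(fw$out, y, est@kind)$loss
    }
    pp <- est@params
    fw <- zslpose:::.cnnForward(pp, est@spec, xb, training = TRUE)
    g <- zslpose:::.cnnBackward(pp, est@spec, fw,
        zslpose:::.cnnLossGrad(fw$out, y, est@kind)$dz)
    eps <- 1e-5
    check <- function(get, set, ana, k = 4) {
        p0 <- get(pp)
        for (i in sample(length(p0), min(k, length(p0)))) {
            pa <- p0; pa[i] <- pa[i] + eps
            pb <- p0; pb[i] <- pb[i] - eps
            num <- (loss(set(pp, pa)) - loss(set(pp, pb))) / (2 * eps)
            expect_equal(ana[i], num, tolerance = 1e-4)
        }
    }
    check(function(p) p$conv[[1]]$w,
          function(p, v) { p$conv[[1]]$w <- v; p }, g$conv[[1]]$dw)
    check(function(p) p$conv[[2]]$w,
          function(p, v) { p$conv[[2]]$w <- v; p }, g$conv[[2]]$dw)
    check(function(p) p$conv[[1]]$gamma,
          function(p, v) { p$conv[[1]]$gamma <- v; p }, g$conv[[1]]$dgamma)
    check(function(p) p$conv[[2]]$beta,
          function(p, v) { p$conv[[2]]$beta <- v; p }, g$conv[[2]]$dbeta)
    check(function(p) p$fc1$w,
          function(p, v) { p$fc1$w <- v; p }, g$fc1$dw)
    check(function(p) p$head$w,
          function(p, v) { p$head$w <- v; p }, g$head$dw)
})

test_that("training recovers separable channel signatures", {
    sch <- smallSchema()
    set.seed(10)
    N <- 120
    y <- sample(1:3, N, replace = TRUE)
    # category k shifts every channel by k - 2: linearly separable by level
    x <- array(rnorm(60 * 10 * N, mean = rep(y - 2, each = 600)),
               c(60, 10, N))
    yt <- sample(1:3, 60, replace = TRUE)
    xt <- array(rnorm(60 * 10 * 60, mean = rep(yt - 2, each = 600)),
                c(60, 10, 60))
    est <- trainEstimator(buildEstimator(sch, "J1", seed = 1), x, y,
                          epochs = 8L, batch = 32L, lr = 0.02, seed = 1)
    p <- predictEstimator(est, xt)
    expect_gt(mean(apply(p, 2, which.max) == yt), 0.9)
    expect_equal(colSums(p), rep(1, 60))
    # smoothed (3-epoch window) training loss is non-increasing up to the
    # jitter that balanced resampling introduces near convergence
    sm <- stats::filter(est@lossHistory, rep(1 / 3, 3), sides = 1)
    sm <- sm[!is.na(sm)]
    expect_true(all(diff(sm) <= 0.02))
    expect_lt(sm[length(sm)], sm[1])

    # regression: the target is the common channel offset
    yr <- runif(N)
    xr <- array(rnorm(60 * 20 * N, mean = rep(2 * yr - 1, each = 1200),
                      sd = 0.5), c(60, 20, N))
    yrt <- runif(60)
    xrt <- array(rnorm(60 * 20 * 60, mean = rep(2 * yrt - 1, each = 1200),
                       sd = 0.5), c(60, 20, 60))
    estr <- trainEstimator(buildEstimator(sch, "J2", seed = 1), xr, yr,
                           epochs = 10L, batch = 32L, lr = 0.02, seed = 1)
    pr <- predictEstimator(estr, xrt)
    expect_lt(mean(abs(pr - yrt)), 0.1)
    expect_true(all(pr >= 0 & pr <= 1))
})

test_that("training is reproducible and rejects degenerate inputs", {
    sch <- smallSchema()
    set.seed(4)
    N <- 30
    y <- rep(1:3, 10)
    x <- array(rnorm(60 * 10 * N, mean = rep(y, each = 600)), c(60, 10, N))
    e1 <- trainEstimator(buildEstimator(sch, "J1", seed = 1), x, y,
                         epochs = 2L, seed = 7)
    e2 <- trainEstimator(buildEstimator(sch, "J1", seed = 1), x, y,
                         epochs = 2L, seed = 7)
    expect_identical(e1@lossHistory, e2@lossHistory)
    expect_identical(e1@params$fc1$w, e2@params$fc1$w)
    expect_error(trainEstimator(buildEstimator(sch, "J1", seed = 1), x,
                                rep(1L, N)), "single category")
    # J2 consumes 20 channels; a 10-channel array is refused
    expect_error(trainEstimator(buildEstimator(sch, "J2", seed = 1), x,
                                rep(0.5, N)), "matching the estimator")
    # zero-epoch training still yields valid outputs
    e0 <- trainEstimator(buildEstimator(sch, "J1", seed = 1), x, y,
                         epochs = 0L)
    p0 <- predictEstimator(e0, x)
    expect_equal(colSums(p0), rep(1, N))
})

test_that("attribute estimation concatenates per-joint outputs in schema order", {
    tabs <- defaultTables()
    sch <- tabs$schema
    # train on a deliberately tiny corpus: structure is what is under test
    recs <- generateImuCorpus(tabs$defs, sch, tabs$var,
                              classes = c("Standing", "Squatting", "Boxing",
                                          "Waist bending",
                                          "Waist twisting (L)"),
                              nPerClass = 1L, duration = 2, seed = 3,
                              variationDraw = "cycle")
    ests <- trainJointEstimators(recs, sch, epochs = 1L,
                                 wideKernelEpochs = 1L, batch = 16L,
                                 lr = 0.01, seed = 1)
    rec <- generateImuRecording("Standing", tabs$defs, sch, duration = 2.5,
                                seed = 99)
    aset <- estimateAttributes(ests, rec, sch)
    expect_s4_class(aset, "AttributeSet")
    expect_equal(nrow(aset), 33L)
    expect_equal(ncol(aset), length(slidingWindows(rec)$starts))
    expect_silent(checkAttributeVectors(attrValues(aset), sch))
    expect_equal(unique(poseLabels(aset)), "Standing")
    # channel-layout mismatch is caught
    bad <- Recording(rec@samples[, 1:300], pose = "Standing",
                     sensors = rec@sensors[1:30], states = rec@states)
    expect_error(estimateAttributes(ests, bad, sch), "lacks sensors")
})
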