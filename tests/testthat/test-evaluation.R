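test_that("F-measures follow the precision/recall arithmetic", {
    m <- matrix(c(5, 0, 0, 0, 5, 0, 0, 0, 5), 3,
                dimnames = list(letters[1:3], letters[1:3]))
    r <- fMeasures(m)
    expect_equal(perClassF(r)$f, rep(1, 3))
    expect_equal(averageF(r), 1)

    m2 <- matrix(c(8, 3, 2, 7), 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
    r2 <- fMeasures(m2)
    px <- 8 / 11; rx <- 8 / 10
    expect_equal(perClassF(r2)$f[1], 2 * px * rx / (px + rx),
                 tolerance = 1e-12)
    expect_equal(perClassF(r2)$f[1], 0.7619, tolerance = 1e-4)

    m3 <- matrix(c(0, 4, 6, 0), 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
    expect_equal(perClassF(fMeasures(m3))$f, c(0, 0))
    expect_error(fMeasures(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("noise-free definitional samples give perfect zero-shot recovery", {
    tabs <- defaultTables()
    samp <- generateAttributeSamples(tabs$defs, tabs$schema, NULL,
                                     nPerClass = 4L, seed = 1, noiseSd = 0)
    res <- locoZslEvaluate(samp, tabs$defs, tabs$schema,
                           importance = tabs$imp, metric = "weighted")
    expect_equal(perClassF(res)$f, rep(1, 22))
    # aggregation conservation: every test sample lands in the confusion
    expect_equal(sum(confusionMatrix(res)), 22 * 4)
    # degenerate single-class corpus is refused
    one <- generateAttributeSamples(tabs$defs["Boxing", , drop = FALSE],
                                    tabs$schema, NULL, nPerClass = 4L,
                                    seed = 1)
    expect_error(locoZslEvaluate(one, tabs$defs["Boxing", , drop = FALSE],
                                 tabs$schema, importance = tabs$imp),
                 "at least 2 classes")
    expect_error(locoZslEvaluate(samp, tabs$defs, tabs$schema,
                                 metric = "weighted"),
                 "needs an importance table")
})

test_that("uniform importance reproduces the naive confusion exactly", {
    tabs <- defaultTables()
    ones <- tabs$imp
    ones[] <- 1
    samp <- generateAttributeSamples(tabs$defs, tabs$schema, tabs$var,
                                     nPerClass = 25L, seed = 6)
    ru <- locoZslEvaluate(samp, tabs$defs, tabs$schema, importance = ones,
                          metric = "weighted")
    rn <- locoZslEvaluate(samp, tabs$defs, tabs$schema, metric = "naive")
    expect_identical(confusionMatrix(ru), confusionMatrix(rn))
})

test_that("the k-shot protocol folds and aggregates as specified", {
    tabs <- defaultTables()
    nc <- 12L
    samp <- generateAttributeSamples(tabs$defs, tabs$schema, tabs$var,
                                     nPerClass = nc, seed = 2)
    # k = Nc - 1: one fold, one test sample per class
    r1 <- kshotEvaluate(samp, tabs$defs, tabs$schema, importance = tabs$imp,
                        k = nc - 1L, seed = 1)
    expect_equal(unname(rowSums(confusionMatrix(r1))), rep(1, 22))
    # general k: each fold tests Nc - k samples; fold-averaged counts per
    # class still sum to Nc - k
    r3 <- kshotEvaluate(samp, tabs$defs, tabs$schema, importance = tabs$imp,
                        k = 5L, seed = 1)
    expect_equal(unname(rowSums(confusionMatrix(r3))), rep(nc - 5, 22))
    expect_error(kshotEvaluate(samp, tabs$defs, tabs$schema,
                               importance = tabs$imp, k = nc, seed = 1),
                 "need more than")
    # same seed, same result
    r3b <- kshotEvaluate(samp, tabs$defs, tabs$schema, importance = tabs$imp,
                         k = 5L, seed = 1)
    expect_identical(confusionMatrix(r3), confusionMatrix(r3b))
})

test_that("the random-importance baseline is seeded and summarised per class", {
    tabs <- defaultTables()
    samp <- generateAttributeSamples(tabs$defs, tabs$schema, tabs$var,
                                     nPerClass = 10L, seed = 3)
    b1 <- randomImportanceBaseline(samp, tabs$defs, tabs$schema, R = 3L,
                                   seed = 9)
    b2 <- randomImportanceBaseline(samp, tabs$defs, tabs$schema, R = 3L,
                                   seed = 9)
    expect_identical(b1, b2)
    expect_length(b1$reps, 3L)
    expect_equal(nrow(b1$perClass), 22L)
    expect_equal(b1$averageF, mean(b1$perClass$f))
    expect_true(all(b1$perClass$f >= 0 & b1$perClass$f <= 1))
})

test_that("confined noise-free variation separates the two metrics", {
    # variation only on zero-importance joints, no attribute noise: the
    # weighted metric is blind to the variation and recovers every class,
    # while the baseline metric is dragged below 1 by variant samples
    tabs <- defaultTables()
    cvar <- confinedVariationSpec(tabs$var, tabs$imp)
    cvar@noiseSd <- 0
    samp <- generateAttributeSamples(tabs$defs, tabs$schema, cvar,
                                     nPerClass = 40L, seed = 4)
    rw <- locoZslEvaluate(samp, tabs$defs, tabs$schema,
                          importance = tabs$imp, metric = "weighted")
    rn <- locoZslEvaluate(samp, tabs$defs, tabs$schema, metric = "naive")
    expect_equal(averageF(rw), 1)
    expect_lt(averageF(rn), 1)
})
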