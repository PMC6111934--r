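test_that("the packaged variation spec encodes the observed alternatives", {
    tabs <- defaultTables()
    v <- tabs$var
    sq <- variationAlternatives(v, "Squatting")
    expect_setequal(as.numeric(sq[["E(L)"]]), c(0, 1))
    expect_setequal(sq[["Ha(L)"]], c("normal", "grasp"))
    expect_length(variationAlternatives(v, "Standing"), 0L)
    expect_length(variationAlternatives(v, "Waist bending"), 0L)
    expect_setequal(variationAlternatives(v, "Stretching calf (L)")[["He"]],
                    c("front", "down"))
    expect_error(readVariationSpec(
        { f <- tempfile(); writeLines(c("pose,joint,alternatives",
                                        "Standing,He,sideways"), f); f },
        tabs$schema), "invalid alternative")
})

test_that("noise-free sampling without variation reproduces the definitions", {
    tabs <- defaultTables()
    sch <- tabs$schema
    samp <- generateAttributeSamples(tabs$defs, sch, NULL, nPerClass = 3L,
                                     seed = 1, noiseSd = 0)
    V <- expandDefinitionTable(tabs$defs, sch)
    for (cl in rownames(tabs$defs)) {
        cols <- which(poseLabels(samp) == cl)
        expect_length(cols, 3L)
        for (j in cols)
            expect_equal(unname(attrValues(samp)[, j]), unname(V[, cl]))
    }
})

test_that("sampled vectors stay valid and variation is confined to free joints", {
    tabs <- defaultTables()
    sch <- tabs$schema
    samp <- generateAttributeSamples(
        tabs$defs["Squatting", , drop = FALSE], sch, tabs$var,
        nPerClass = 1000L, seed = 2)
    X <- attrValues(samp)
    expect_silent(checkAttributeVectors(X, sch))
    # elbows (free) are bimodal near 0 and 1...
    el <- X[jointSlice(sch, "E(L)"), ]
    expect_gt(mean(el < 0.25), 0.3)
    expect_gt(mean(el > 0.75), 0.3)
    expect_lt(mean(el >= 0.25 & el <= 0.75), 0.05)
    # ...while the diagnostic hips/knees stay near the definitional 1
    # (truncated noise; the 3-sigma bound holds with the usual probability)
    for (jn in c("HJ(L)", "HJ(R)", "K(L)", "K(R)"))
        expect_gt(mean(X[jointSlice(sch, jn), ] > 1 - 3 * tabs$var@noiseSd),
                  0.99)
    # dimensions of importance-1 joints deviate from the definition only by
    # noise; free joints may move to an alternative state
    V <- expandDefinitionTable(tabs$defs, sch)
    kinds <- jointKinds(sch)
    for (jn in jointNames(sch)) {
        if (as.numeric(tabs$imp["Squatting", jn]) == 0) next
        dev <- abs(X[jointSlice(sch, jn), , drop = FALSE] -
                   V[jointSlice(sch, jn), "Squatting"])
        if (kinds[[jn]] == "regression")
            expect_gt(mean(dev <= 3 * tabs$var@noiseSd), 0.99)
        else expect_true(all(dev <= 0.5))
    }
})

test_that("restricting variation to non-diagnostic joints drops only those", {
    tabs <- defaultTables()
    cv <- confinedVariationSpec(tabs$var, tabs$imp)
    # waist twisting varies the head, which is diagnostic for it: dropped
    expect_false("He" %in% names(variationAlternatives(cv, "Waist twisting (L)")))
    # squatting's elbow/hand variation is non-diagnostic: kept
    expect_setequal(names(variationAlternatives(cv, "Squatting")),
                    c("E(L)", "E(R)", "Ha(L)", "Ha(R)"))
})

test_that("synthetic recordings have the documented geometry and injectivity", {
    tabs <- defaultTables()
    sch <- tabs$schema
    rec <- generateImuRecording("Standing", tabs$defs, sch, duration = 30,
                                seed = 1)
    expect_equal(nrow(rec@samples), 1800L)
    expect_equal(ncol(rec@samples), 10L * 31L)
    expect_length(rec@sensors, 31L)
    expect_equal(rec@states[["He"]], "front")
    expect_error(generateImuRecording("Moonwalk", tabs$defs, sch),
                 "unknown class")

    # zero noise, same seed: two classes differing in one joint produce
    # identical channels except on sensors driven by that joint
    r1 <- generateImuRecording("Standing", tabs$defs, sch, duration = 1.5,
                               seed = 7, signalNoiseSd = 0)
    r2 <- generateImuRecording("Raising arm (L)", tabs$defs, sch,
                               duration = 1.5, seed = 7, signalNoiseSd = 0)
    drivers <- zslpose:::.sensorDrivers(sch)
    diffSensors <- names(drivers)[vapply(names(drivers), function(s) {
        ch <- zslpose:::.sensorChannels(r1, s)
        any(r1@samples[, ch] != r2@samples[, ch])
    }, logical(1))]
    expect_setequal(diffSensors,
                    names(drivers)[drivers == "S(L)"])
})

test_that("recordings round-trip through the CSV writer", {
    tabs <- defaultTables()
    rec <- generateImuRecording("Boxing", tabs$defs, tabs$schema,
                                tabs$var, duration = 1, seed = 4)
    f <- tempfile(fileext = ".csv")
    writeRecording(rec, f)
    back <- readRecording(f)
    expect_equal(back@samples, rec@samples, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(back@pose, rec@pose)
    expect_equal(back@sensors, rec@sensors)
    expect_equal(back@states[["Ha(L)"]], as.character(rec@states[["Ha(L)"]]))
})

test_that("attribute sets round-trip through CSV", {
    tabs <- defaultTables()
    samp <- generateAttributeSamples(tabs$defs, tabs$schema, tabs$var,
                                     nPerClass = 2L, seed = 3)
    f <- tempfile(fileext = ".csv")
    writeAttributeSet(samp, f)
    back <- readAttributeSet(f, schema = tabs$schema)
    expect_equal(attrValues(back), attrValues(samp), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(poseLabels(back), poseLabels(samp))
})
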