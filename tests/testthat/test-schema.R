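test_that("the packaged schema has 14 joints spanning 33 dimensions", {
    sch <- defaultAttributeSchema()
    expect_equal(schemaDim(sch), 33L)
    expect_length(jointNames(sch), 14L)
    # per-joint contribution: head 5, shoulders 2x5, elbows/wrists/hips/knees
    # 1 each, hands 2x3, waist 4
    dims <- setNames(sch@joints$dim, sch@joints$name)
    expect_equal(unname(dims[c("He", "S(L)", "Ha(L)", "Wa", "E(L)", "K(R)")]),
                 c(5L, 5L, 3L, 4L, 1L, 1L))
    # slices are contiguous, disjoint and cover 1..33
    all_idx <- unlist(lapply(jointNames(sch), jointSlice, schema = sch))
    expect_equal(sort(all_idx), 1:33)
})

test_that("schema reading validates its inputs", {
    expect_equal(schemaDim(toySchema("Z,regression,,s9")), 1L)
    expect_error(toySchema(c("A,regression,,s1", "A,regression,,s2")),
                 "duplicate")
    expect_error(toySchema("A,ordination,,s1"), "unknown joint kind")
    expect_error(toySchema("A,classification,solo,s1"), "fewer than 2")
})

test_that("symbolic rows expand to one-hot / scalar attribute vectors", {
    tabs <- defaultTables()
    sch <- tabs$schema
    v <- expandPoseDefinition(tabs$defs["Standing", ], sch)
    # head one-hot on "front" (5th category), shoulders on "down" (2nd)
    expect_equal(v[jointSlice(sch, "He")], c(0, 0, 0, 0, 1))
    expect_equal(v[jointSlice(sch, "S(L)")], c(0, 1, 0, 0, 0))
    expect_equal(v[jointSlice(sch, "Wr(L)")], 0.5)
    expect_equal(v[jointSlice(sch, "Ha(R)")], c(1, 0, 0))
    expect_equal(v[jointSlice(sch, "Wa")], c(1, 0, 0, 0))
    expect_equal(v[jointSlice(sch, "K(R)")], 0)

    toy <- toySchema(c("A,regression,,s1", "B,regression,,s2"))
    expect_equal(expandPoseDefinition(list(A = 0, B = 1), toy), c(0, 1))

    # every packaged definition row satisfies the vector invariants
    V <- expandDefinitionTable(tabs$defs, sch)
    expect_equal(dim(V), c(33L, 22L))
    expect_silent(checkAttributeVectors(V, sch))

    expect_error(expandPoseDefinition(list(A = 0, B = 1.2), toy), "\\[0, 1\\]")
    bad <- tabs$defs["Standing", ]; bad[["He"]] <- "sideways"
    expect_error(expandPoseDefinition(bad, sch), "not in categories")
})

test_that("expansion and symbolic read-back round-trip every definition", {
    tabs <- defaultTables()
    sch <- tabs$schema
    for (cl in rownames(tabs$defs)) {
        v <- expandPoseDefinition(tabs$defs[cl, ], sch)
        back <- collapseAttributeVector(v, sch)
        for (jn in jointNames(sch)) {
            if (jointKinds(sch)[[jn]] == "classification")
                expect_identical(back[[jn]], tabs$defs[cl, jn])
            else expect_equal(back[[jn]], as.numeric(tabs$defs[cl, jn]))
        }
    }
})

test_that("importance rows expand per-dimension with per-joint normaliser", {
    tabs <- defaultTables()
    sch <- tabs$schema
    st <- expandImportance(tabs$imp["Standing", ], sch)
    expect_equal(st$Wai, 14)
    expect_equal(unname(st$wai), rep(1, 33))
    sq <- expandImportance(tabs$imp["Squatting", ], sch)
    # the printed squatting row has eight ones (head, shoulders, waist,
    # hip joints, knees)
    expect_equal(sq$Wai, 8)
    expect_equal(sum(sq$wai), 5 + 5 + 5 + 4 + 4)  # per-dimension copies
    expect_equal(unique(sq$wai[jointSlice(sch, "E(L)")]), 0)

    toy <- toySchema("A,regression,,s1")
    expect_error(expandImportance(list(A = 0), toy), "all-zero")
})

test_that("range-compensation weights are 0.5 for classification dims", {
    sch <- defaultAttributeSchema()
    w <- wrcWeights(sch)
    expect_equal(unique(w[jointSlice(sch, "He")]), 0.5)
    expect_equal(w[jointSlice(sch, "E(L)")], 1)
    toy <- toySchema(c("A,regression,,s1", "B,regression,,s2"))
    expect_equal(wrcWeights(toy), c(1, 1))
})

test_that("per-joint wrc-scaled L1 distance is at most 1 between valid vectors", {
    sch <- defaultAttributeSchema()
    set.seed(11)
    X <- cbind(randomAttributeVectors(50, sch),
               expandDefinitionTable(defaultPoseDefinitions(sch), sch))
    w <- wrcWeights(sch)
    for (jn in jointNames(sch)) {
        sl <- jointSlice(sch, jn)
        i <- sample(ncol(X), 30, replace = TRUE)
        j <- sample(ncol(X), 30, replace = TRUE)
        raw <- colSums(abs(X[sl, i, drop = FALSE] - X[sl, j, drop = FALSE]))
        scaled <- colSums(w[sl] * abs(X[sl, i, drop = FALSE] -
                                      X[sl, j, drop = FALSE]))
        lim <- if (jointKinds(sch)[[jn]] == "classification") 2 else 1
        expect_true(all(raw <= lim + 1e-9))
        expect_true(all(scaled <= 1 + 1e-9))
    }
})
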