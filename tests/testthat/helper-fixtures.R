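# Shared fixtures: tiny schemas written to disk on the fly, and random
# valid attribute vectors (uniform regression values, Dirichlet(1) simplex
# slices for classification joints).

writeToySchema <- function(lines) {
    f <- tempfile(fileext = ".csv")
    writeLines(c("joint,kind,categories,sensor_ids", lines), f)
    f
}

toySchema <- function(lines) readAttributeSchema(writeToySchema(lines))

# a 2-joint toy: one 3-category classification joint, one regression joint
smallSchema <- function() {
    toySchema(c("J1,classification,a;b;c,s1",
                "J2,regression,,s1;s2"))
}

randomAttributeVectors <- function(n, schema) {
    D <- schemaDim(schema)
    out <- matrix(NA_real_, D, n)
    for (jn in jointNames(schema)) {
        sl <- jointSlice(schema, jn)
        if (jointKinds(schema)[[jn]] == "classification") {
            g <- matrix(rgamma(length(sl) * n, 1), length(sl), n)
            out[sl, ] <- sweep(g, 2L, colSums(g), `/`)
        } else {
            out[sl, ] <- runif(n)
        }
    }
    out
}

defaultTables <- function() {
    sch <- defaultAttributeSchema()
    list(schema = sch,
         defs = defaultPoseDefinitions(sch),
         imp = defaultImportanceTable(sch),
         var = defaultVariationSpec(sch))
}
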