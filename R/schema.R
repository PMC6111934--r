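#' Read an attribute schema from a CSV table
#'
#' The table needs columns \code{joint}, \code{kind} (\code{classification}
#' or \code{regression}), \code{categories} (semicolon-separated, in one-hot
#' order; empty for regression joints) and \code{sensor_ids}
#' (semicolon-separated IMU identifiers).  Joint order in the file fixes the
#' layout of the attribute vector: each joint occupies a contiguous slice,
#' classification joints one dimension per category, regression joints one.
#'
#' @param file path to the schema CSV.
#' @return an \code{\link{AttributeSchema}}.
#' @examples
#' sch <- defaultAttributeSchema()
#' schemaDim(sch)   # 33
#' jointNames(sch)  # 14 joints
#' @export
readAttributeSchema <- function(file) {
    tab <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("joint", "kind", "categories", "sensor_ids")
    if (!all(need %in% names(tab)))
        stop("schema table must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$joint))
        stop("duplicate joint name in schema: ",
             paste(unique(tab$joint[duplicated(tab$joint)]), collapse = ", "))
    bad <- setdiff(tab$kind, c("classification", "regression"))
    if (length(bad))
        stop("unknown joint kind: ", paste(bad, collapse = ", "))
    split1 <- function(s) {
        s <- trimws(s)
        if (is.na(s) || !nzchar(s)) character(0)
        else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    }
    cats <- lapply(tab$categories, split1)
    sens <- lapply(tab$sensor_ids, split1)
    names(cats) <- names(sens) <- tab$joint
    dims <- ifelse(tab$kind == "regression", 1L, lengths(cats))
    short <- tab$kind == "classification" & lengths(cats) < 2L
    if (any(short))
        stop("classification joint with fewer than 2 categories: ",
             paste(tab$joint[short], collapse = ", "))
    joints <- data.frame(
        name = tab$joint, kind = tab$kind, dim = as.integer(dims),
        offset = as.integer(cumsum(c(1L, dims[-length(dims)]))),
        stringsAsFactors = FALSE)
    new("AttributeSchema", joints = joints, categories = cats, sensors = sens)
}

#' The packaged 14-joint, 33-dimension schema
#'
#' Head, two shoulders, two elbows, two wrists, two hands, waist, two hip
#' joints and two knees.  Head/shoulders (5 categories), hands (3) and waist
#' (4) are classification joints; elbows, wrists, hip joints and knees are
#' regression joints, giving 5 + 5 + 5 + 1 + 1 + 1 + 1 + 3 + 3 + 4 + 1 + 1 +
#' 1 + 1 = 33 dimensions.
#'
#' @return an \code{\link{AttributeSchema}}.
#' @export
defaultAttributeSchema <- function() {
    readAttributeSchema(system.file("extdata", "table2_schema.csv",
                                    package = "zslpose", mustWork = TRUE))
}

#' @rdname AttributeSchema-class
#' @aliases schemaDim jointNames jointKinds wrcWeights
#' @export
setMethod("schemaDim", "AttributeSchema", function(x) sum(x@joints$dim))

#' @rdname AttributeSchema-class
#' @export
setMethod("jointNames", "AttributeSchema", function(x) x@joints$name)

#' @rdname AttributeSchema-class
#' @export
setMethod("jointKinds", "AttributeSchema",
    function(x) setNames(x@joints$kind, x@joints$name))

#' Indices of a joint's slice of the attribute vector
#'
#' @param schema an \code{\link{AttributeSchema}}.
#' @param joint joint name.
#' @return integer vector of attribute-dimension indices (1-based).
#' @export
jointSlice <- function(schema, joint) {
    i <- match(joint, schema@joints$name)
    if (is.na(i)) stop("unknown joint: ", joint)
    seq.int(schema@joints$offset[i], length.out = schema@joints$dim[i])
}

#' Joint categories in one-hot order
#' @inheritParams jointSlice
#' @return character vector (empty for regression joints).
#' @export
jointCategories <- function(schema, joint) {
    if (!joint %in% schema@joints$name) stop("unknown joint: ", joint)
    schema@categories[[joint]]
}

#' Sensors feeding a joint's estimator
#' @inheritParams jointSlice
#' @return character vector of sensor identifiers.
#' @export
jointSensors <- function(schema, joint) {
    if (!joint %in% schema@joints$name) stop("unknown joint: ", joint)
    schema@sensors[[joint]]
}

#' Parent joint of every attribute dimension
#' @param schema an \code{\link{AttributeSchema}}.
#' @return character vector of length \code{schemaDim(schema)}.
#' @export
dimJoints <- function(schema) {
    rep(schema@joints$name, schema@joints$dim)
}

#' Range-compensation weights
#'
#' Per attribute dimension: 1 if the dimension is estimated by regression,
#' 0.5 if it belongs to a classification joint.  The factor equalises the
#' attainable per-joint L1 distance: a classification joint's slice can
#' differ by up to 2 between two one-hot vectors, a regression dimension by
#' at most 1.
#'
#' @param x an \code{\link{AttributeSchema}}.
#' @return numeric vector of length \code{schemaDim(x)}.
#' @export
setMethod("wrcWeights", "AttributeSchema", function(x) {
    rep(ifelse(x@joints$kind == "regression", 1, 0.5), x@joints$dim)
})

setMethod("show", "AttributeSchema", function(object) {
    j <- object@joints
    cat(sprintf("AttributeSchema: %d joints, %d attribute dimensions\n",
                nrow(j), sum(j$dim)))
    for (i in seq_len(nrow(j)))
        cat(sprintf("  %-6s %-14s dims %d..%d  sensors: %s\n", j$name[i],
                    j$kind[i], j$offset[i], j$offset[i] + j$dim[i] - 1L,
                    paste(object@sensors[[j$name[i]]], collapse = ",")))
    invisible(NULL)
})

.checkTableAgainstSchema <- function(tab, schema, what) {
    miss <- setdiff(jointNames(schema), colnames(tab))
    if (length(miss))
        stop(what, " table is missing joint columns: ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(rownames(tab)))
        stop("duplicate class names in ", what, " table")
    invisible(TRUE)
}

#' Read a symbolic pose-definition table
#'
#' One row per pose class, one column per joint; classification joints hold
#' a category label, regression joints a value in \code{[0, 1]}.  The first
#' column \code{pose} holds class names.  Class order in the file is the
#' canonical class order (used e.g. for deterministic tie-breaking).
#'
#' @param file CSV path.
#' @param schema an \code{\link{AttributeSchema}} used for validation.
#' @return data.frame with class names as row names and joints as columns.
#' @export
readPoseDefinitions <- function(file, schema = defaultAttributeSchema()) {
    tab <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "pose") stop("first column must be 'pose'")
    rownames(tab) <- tab$pose
    tab$pose <- NULL
    .checkTableAgainstSchema(tab, schema, "definition")
    tab <- tab[, jointNames(schema), drop = FALSE]
    for (cl in rownames(tab))    # fails early on bad labels/values
        expandPoseDefinition(tab[cl, , drop = FALSE], schema)
    tab
}

#' The packaged 22-pose definition table
#' @return data.frame (22 classes x 14 joints).
#' @export
defaultPoseDefinitions <- function(schema = defaultAttributeSchema()) {
    readPoseDefinitions(system.file("extdata", "table3_definitions.csv",
                                    package = "zslpose", mustWork = TRUE),
                        schema)
}

#' Read a per-class joint-importance table
#'
#' One row per class, one column per joint, values in \code{[0, 1]} (binary
#' in the packaged default).  A weight of 0 marks a joint whose state is not
#' diagnostic for the class and is ignored by the weighted distance.
#'
#' @inheritParams readPoseDefinitions
#' @return numeric data.frame with class names as row names.
#' @export
readImportanceTable <- function(file, schema = defaultAttributeSchema()) {
    tab <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "pose") stop("first column must be 'pose'")
    rownames(tab) <- tab$pose
    tab$pose <- NULL
    .checkTableAgainstSchema(tab, schema, "importance")
    tab <- tab[, jointNames(schema), drop = FALSE]
    m <- as.matrix(tab)
    if (!is.numeric(m) || any(m < 0 | m > 1))
        stop("importance weights must be numeric in [0, 1]")
    if (any(rowSums(m) == 0))
        stop("class with all-zero importance row: ",
             paste(rownames(tab)[rowSums(m) == 0], collapse = ", "))
    tab
}

#' The packaged 22-pose importance table
#' @inheritParams defaultPoseDefinitions
#' @return numeric data.frame (22 classes x 14 joints, binary).
#' @export
defaultImportanceTable <- function(schema = defaultAttributeSchema()) {
    readImportanceTable(system.file("extdata", "table4_importance.csv",
                                    package = "zslpose", mustWork = TRUE),
                        schema)
}

#' Expand a symbolic per-joint row into a numeric attribute vector
#'
#' Classification joints become one-hot vectors in the joint's category
#' order; regression joints keep their stated scalar.  The result satisfies
#' the attribute-vector invariants: all elements in \code{[0, 1]} and each
#' classification slice summing to 1.
#'
#' @param row a one-row data.frame (or named list/vector) with one entry per
#'   joint of \code{schema}.
#' @param schema an \code{\link{AttributeSchema}}.
#' @return numeric vector of length \code{schemaDim(schema)}.
#' @examples
#' sch <- defaultAttributeSchema()
#' defs <- defaultPoseDefinitions(sch)
#' v <- expandPoseDefinition(defs["Standing", ], sch)
#' sum(v[jointSlice(sch, "He")])  # 1: one-hot head slice
#' @export
expandPoseDefinition <- function(row, schema) {
    row <- as.list(row)
    out <- numeric(schemaDim(schema))
    for (jn in jointNames(schema)) {
        if (is.null(row[[jn]])) stop("row is missing joint: ", jn)
        sl <- jointSlice(schema, jn)
        if (jointKinds(schema)[[jn]] == "classification") {
            cats <- jointCategories(schema, jn)
            k <- match(as.character(row[[jn]]), cats)
            if (is.na(k))
                stop(sprintf("joint '%s': label '%s' not in categories (%s)",
                             jn, row[[jn]], paste(cats, collapse = ", ")))
            out[sl[k]] <- 1
        } else {
            val <- suppressWarnings(as.numeric(row[[jn]]))
            if (is.na(val) || val < 0 || val > 1)
                stop(sprintf("joint '%s': regression value must be in [0, 1], got '%s'",
                             jn, row[[jn]]))
            out[sl] <- val
        }
    }
    out
}

#' Expand a whole definition table into a matrix of attribute vectors
#'
#' @param defs data.frame from \code{\link{readPoseDefinitions}}.
#' @inheritParams expandPoseDefinition
#' @return D x nClasses numeric matrix with class names as column names.
#' @export
expandDefinitionTable <- function(defs, schema) {
    vapply(rownames(defs),
           function(cl) expandPoseDefinition(defs[cl, , drop = FALSE], schema),
           numeric(schemaDim(schema)))
}

#' Read back the symbolic row from an attribute vector
#'
#' Inverse of \code{\link{expandPoseDefinition}} for valid vectors: argmax
#' label for classification joints, raw value for regression joints.
#'
#' @param v numeric attribute vector.
#' @inheritParams expandPoseDefinition
#' @return named list, one entry per joint.
#' @export
collapseAttributeVector <- function(v, schema) {
    stopifnot(length(v) == schemaDim(schema))
    out <- vector("list", length(jointNames(schema)))
    names(out) <- jointNames(schema)
    for (jn in jointNames(schema)) {
        sl <- jointSlice(schema, jn)
        out[[jn]] <- if (jointKinds(schema)[[jn]] == "classification")
            jointCategories(schema, jn)[which.max(v[sl])]
        else v[sl]
    }
    out
}

#' Expand a per-joint importance row to per-dimension weights
#'
#' Every attribute dimension inherits the weight of its parent joint.  The
#' normaliser \code{Wai} is the sum of the per-joint (not per-dimension)
#' weights and can be read as the number of joints the class definition
#' treats as diagnostic.
#'
#' @param row one row of an importance table (named numeric values per joint).
#' @inheritParams expandPoseDefinition
#' @return list with \code{wai} (numeric, length D) and \code{Wai} (scalar).
#' @examples
#' sch <- defaultAttributeSchema()
#' imp <- defaultImportanceTable(sch)
#' expandImportance(imp["Squatting", ], sch)$Wai  # 9
#' @export
expandImportance <- function(row, schema) {
    row <- as.list(row)
    perJoint <- vapply(jointNames(schema), function(jn) {
        if (is.null(row[[jn]])) stop("importance row is missing joint: ", jn)
        w <- as.numeric(row[[jn]])
        if (is.na(w) || w < 0 || w > 1)
            stop(sprintf("joint '%s': importance must be in [0, 1]", jn))
        w
    }, numeric(1))
    Wai <- sum(perJoint)
    if (Wai == 0)
        stop("all-zero importance row: the weighted distance is undefined")
    list(wai = rep(perJoint, schema@joints$dim), Wai = Wai)
}

#' Check the attribute-vector invariants
#'
#' @param v numeric vector (or D x N matrix of column vectors).
#' @inheritParams expandPoseDefinition
#' @param tol tolerance on classification-slice sums.
#' @return \code{TRUE} invisibly; stops otherwise.
#' @export
checkAttributeVectors <- function(v, schema, tol = 1e-6) {
    m <- if (is.matrix(v)) v else matrix(v, ncol = 1)
    if (nrow(m) != schemaDim(schema))
        stop("attribute vectors must have length ", schemaDim(schema))
    if (any(m < -tol | m > 1 + tol))
        stop("attribute values outside [0, 1]")
    for (jn in jointNames(schema)) {
        if (jointKinds(schema)[[jn]] != "classification") next
        s <- colSums(m[jointSlice(schema, jn), , drop = FALSE])
        if (any(abs(s - 1) > tol))
            stop("classification slice of joint '", jn, "' does not sum to 1")
    }
    invisible(TRUE)
}
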