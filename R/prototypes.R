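#' Class prototypes as per-class mean vectors
#'
#' One prototype per class present in the sample set, the element-wise mean
#' of that class's attribute vectors.  Mean vectors are used instead of the
#' raw training vectors to cope with class imbalance; classification slices
#' of averaged softmax outputs still sum to 1, so no re-normalisation is
#' applied.
#'
#' @param x an \code{\link{AttributeSet}}, or a D x N numeric matrix
#'   accompanied by \code{labels}.
#' @param labels pose label per column (ignored when \code{x} is an
#'   \code{AttributeSet}).
#' @param classOrder optional character vector fixing the prototype order
#'   (e.g. definition-table order, which then governs tie-breaking in
#'   \code{\link{classifyPose}}); defaults to order of first appearance.
#' @return a \code{\link{PrototypeSet}} with \code{source = "data_mean"}.
#' @export
computePrototypes <- function(x, labels = NULL, classOrder = NULL) {
    if (is(x, "AttributeSet")) {
        labels <- poseLabels(x)
        x <- attrValues(x)
    }
    stopifnot(is.matrix(x), length(labels) == ncol(x))
    classes <- if (is.null(classOrder)) unique(labels)
               else intersect(classOrder, labels)
    if (!all(labels %in% classes))
        stop("labels outside classOrder: ",
             paste(setdiff(labels, classes), collapse = ", "))
    V <- vapply(classes, function(cl) {
        idx <- which(labels == cl)
        if (!length(idx)) stop("empty class: ", cl)
        rowMeans(x[, idx, drop = FALSE])
    }, numeric(nrow(x)))
    new("PrototypeSet", vectors = V, labels = classes,
        source = rep("data_mean", length(classes)))
}

#' Prototypes expanded from a symbolic definition table
#'
#' @param defs data.frame from \code{\link{readPoseDefinitions}}.
#' @param schema an \code{\link{AttributeSchema}}.
#' @param classes subset of classes to expand (default all, in table order).
#' @return a \code{\link{PrototypeSet}} with \code{source = "definition"}.
#' @export
definitionPrototypes <- function(defs, schema, classes = rownames(defs)) {
    V <- expandDefinitionTable(defs[classes, , drop = FALSE], schema)
    new("PrototypeSet", vectors = V, labels = classes,
        source = rep("definition", length(classes)))
}

#' Combine prototype sets
#'
#' Used by the leave-one-class-out protocol to join the held-out class's
#' definition prototype with the seen classes' data means.  \code{order}
#' fixes the final label order (and hence tie-breaking).
#'
#' @param ... \code{\link{PrototypeSet}} objects with disjoint labels.
#' @param order optional character vector of labels.
#' @return a \code{\link{PrototypeSet}}.
#' @export
combinePrototypes <- function(..., order = NULL) {
    sets <- list(...)
    labs <- unlist(lapply(sets, protoLabels))
    if (anyDuplicated(labs)) stop("duplicate prototype labels")
    V <- do.call(cbind, lapply(sets, protoVectors))
    src <- unlist(lapply(sets, function(s) s@source))
    colnames(V) <- labs
    if (!is.null(order)) {
        stopifnot(setequal(order, labs))
        V <- V[, order, drop = FALSE]
        src <- src[match(order, labs)]
        labs <- order
    }
    new("PrototypeSet", vectors = V, labels = labs, source = src)
}

#' @rdname PrototypeSet-class
#' @aliases protoLabels protoVectors
#' @export
setMethod("protoLabels", "PrototypeSet", function(x) x@labels)

#' @rdname PrototypeSet-class
#' @export
setMethod("protoVectors", "PrototypeSet", function(x) {
    V <- x@vectors
    colnames(V) <- x@labels
    V
})

setMethod("show", "PrototypeSet", function(object) {
    cat(sprintf("PrototypeSet: %d prototypes of dimension %d (%s)\n",
                length(object@labels), nrow(object@vectors),
                paste(sprintf("%d %s", table(object@source),
                              names(table(object@source))), collapse = ", ")))
    invisible(NULL)
})

#' Write prototypes to CSV (label, source, then one column per dimension)
#' @param x a \code{\link{PrototypeSet}}.
#' @param file CSV path.
#' @export
writePrototypes <- function(x, file) {
    df <- data.frame(label = protoLabels(x), source = x@source,
                     t(protoVectors(x)), check.names = FALSE)
    write.csv(df, file, row.names = FALSE)
    invisible(file)
}
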