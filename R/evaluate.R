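#' Per-class precision, recall and F-measure from a confusion matrix
#'
#' Rows are true classes, columns predicted classes.  For class \eqn{c}:
#' \eqn{P = TP/(TP+FP)}, \eqn{R = TP/(TP+FN)}, \eqn{F = 2PR/(P+R)}, with
#' \eqn{F = 0} when \eqn{P + R = 0} (and \eqn{P} or \eqn{R} taken as 0 when
#' their denominator is empty).  The summary \code{averageF} is the
#' unweighted mean over classes.
#'
#' @param confusion square numeric matrix with identical row/column names;
#'   counts may be fractional (fold-averaged).
#' @return an \code{\link{EvalResult}}.
#' @examples
#' m <- matrix(c(8, 3, 2, 7), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' perClassF(fMeasures(m))
#' @export
fMeasures <- function(confusion) {
    confusion <- as.matrix(confusion)
    if (!nrow(confusion) || is.null(rownames(confusion)))
        stop("confusion matrix must be non-empty with class names")
    stopifnot(identical(rownames(confusion), colnames(confusion)),
              all(confusion >= 0))
    tp <- diag(confusion)
    pred <- colSums(confusion)
    act <- rowSums(confusion)
    prec <- ifelse(pred > 0, tp / pred, 0)
    rec <- ifelse(act > 0, tp / act, 0)
    f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    pc <- data.frame(class = rownames(confusion), precision = prec,
                     recall = rec, f = f, row.names = NULL,
                     stringsAsFactors = FALSE)
    new("EvalResult", perClass = pc, averageF = mean(f),
        confusion = confusion)
}

#' @rdname EvalResult-class
#' @aliases perClassF averageF confusionMatrix
#' @export
setMethod("perClassF", "EvalResult", function(x) x@perClass)

#' @rdname EvalResult-class
#' @export
setMethod("averageF", "EvalResult", function(x) x@averageF)

#' @rdname EvalResult-class
#' @export
setMethod("confusionMatrix", "EvalResult", function(x) x@confusion)

setMethod("show", "EvalResult", function(object) {
    cat(sprintf("EvalResult: %d classes, average F = %.4f\n",
                nrow(object@perClass), object@averageF))
    print(head(object@perClass, 5L))
    if (nrow(object@perClass) > 5L) cat("  ...\n")
    invisible(NULL)
})

#' Write per-class metrics as CSV
#' @param x an \code{\link{EvalResult}}.
#' @param file CSV path.
#' @export
writeEvalResult <- function(x, file) {
    write.csv(perClassF(x), file, row.names = FALSE)
    invisible(file)
}

.checkEvalInputs <- function(samples, defs, importance, metric) {
    labs <- poseLabels(samples)
    classes <- rownames(defs)
    if (!all(labs %in% classes))
        stop("sample classes missing from the definition table: ",
             paste(setdiff(labs, classes), collapse = ", "))
    present <- intersect(classes, unique(labs))
    if (length(present) < 2L)
        stop("need samples from at least 2 classes")
    if (metric == "weighted") {
        if (is.null(importance))
            stop("the weighted metric needs an importance table")
        miss <- setdiff(classes, rownames(importance))
        if (length(miss))
            stop("importance table lacks classes: ",
                 paste(miss, collapse = ", "))
    }
    present
}

#' Leave-one-class-out zero-shot evaluation
#'
#' For each class \eqn{c} in turn, the evaluation treats \eqn{c} as unseen:
#' the prototype set consists of the data-mean prototypes of all other
#' classes plus the expanded symbolic definition of \eqn{c}, and every
#' sample of \eqn{c} is classified over the full label space.  Predictions
#' from all folds are aggregated into one confusion matrix (each fold
#' contributes its test class's row), from which per-class precision,
#' recall and F-measure are computed.
#'
#' @param samples an \code{\link{AttributeSet}}.
#' @param defs pose-definition table.
#' @param schema an \code{\link{AttributeSchema}}.
#' @param importance importance table (required for the weighted metric).
#' @param params a \code{\link{DistanceParams}}.
#' @param metric \code{"weighted"} (importance-weighted distance, including
#'   for the seen-class prototypes) or \code{"naive"} (range-compensated
#'   distance only).
#' @param verbose log fold progress via \code{message()}.
#' @return an \code{\link{EvalResult}}.
#' @export
locoZslEvaluate <- function(samples, defs, schema, importance = NULL,
                            params = distanceParams(),
                            metric = c("weighted", "naive"),
                            verbose = FALSE) {
    metric <- match.arg(metric)
    present <- .checkEvalInputs(samples, defs, importance, metric)
    classes <- rownames(defs)
    imp <- if (metric == "weighted") importance else NULL
    X <- attrValues(samples)
    labs <- poseLabels(samples)
    confusion <- matrix(0, length(classes), length(classes),
                        dimnames = list(classes, classes))
    for (cl in present) {
        if (verbose)
            message(sprintf("[zsl] fold %d/%d: held-out class '%s'",
                            match(cl, present), length(present), cl))
        seen <- computePrototypes(X[, labs != cl, drop = FALSE],
                                  labs[labs != cl],
                                  classOrder = classes)
        unseen <- definitionPrototypes(defs, schema, classes = cl)
        pro <- combinePrototypes(seen, unseen,
                                 order = intersect(classes, c(protoLabels(seen), cl)))
        pred <- classifyPose(X[, labs == cl, drop = FALSE], pro, schema,
                             params, importance = imp)
        tab <- table(factor(pred, levels = classes))
        confusion[cl, ] <- confusion[cl, ] + as.numeric(tab)
    }
    fMeasures(confusion)
}

#' k-shot evaluation
#'
#' Like the zero-shot protocol, but instead of the symbolic definition the
#' held-out class \eqn{c} is represented by the mean of \eqn{k} of its own
#' samples.  Per class, the samples are randomly permuted (seeded) and
#' split into \eqn{\lfloor N_c/k \rfloor} consecutive groups of \eqn{k};
#' fold \eqn{l} trains on group \eqn{l} and tests on the remaining
#' \eqn{N_c - k} samples.  Fold prediction counts are averaged per class
#' before the cross-class aggregation, so classes with different fold
#' counts contribute equally.
#'
#' @inheritParams locoZslEvaluate
#' @param k shots (every class must have more than \code{k} samples).
#' @param seed seed for the per-class permutations.
#' @return an \code{\link{EvalResult}} (confusion counts are fold-averaged,
#'   hence fractional).
#' @export
kshotEvaluate <- function(samples, defs, schema, importance = NULL, k = 1L,
                          params = distanceParams(),
                          metric = c("weighted", "naive"), seed = 1L,
                          verbose = FALSE) {
    metric <- match.arg(metric)
    stopifnot(k >= 1L)
    present <- .checkEvalInputs(samples, defs, importance, metric)
    classes <- rownames(defs)
    imp <- if (metric == "weighted") importance else NULL
    X <- attrValues(samples)
    labs <- poseLabels(samples)
    confusion <- matrix(0, length(classes), length(classes),
                        dimnames = list(classes, classes))
    set.seed(seed)
    for (cl in present) {
        if (verbose)
            message(sprintf("[%d-shot] class '%s'", k, cl))
        idx <- which(labs == cl)
        Nc <- length(idx)
        if (Nc <= k)
            stop(sprintf("class '%s' has %d samples, need more than k = %d",
                         cl, Nc, k))
        seen <- computePrototypes(X[, labs != cl, drop = FALSE],
                                  labs[labs != cl], classOrder = classes)
        seenOrder <- intersect(classes, c(protoLabels(seen), cl))
        # distances to the fixed seen prototypes are fold-invariant
        dFixedAll <- attributeDistances(X[, idx, drop = FALSE], seen, schema,
                                        params, importance = imp)
        cPos <- match(cl, seenOrder)
        full <- matrix(NA_real_, Nc, length(seenOrder))
        full[, -cPos] <- dFixedAll[, match(setdiff(seenOrder, cl),
                                           protoLabels(seen)), drop = FALSE]
        perm <- sample.int(Nc)
        nFolds <- Nc %/% k
        acc <- numeric(length(classes))
        wrc <- wrcWeights(schema)
        exImp <- if (!is.null(imp))
            expandImportance(imp[cl, , drop = FALSE], schema)
        for (l in seq_len(nFolds)) {
            tr <- perm[((l - 1L) * k + 1L):(l * k)]
            te <- setdiff(seq_len(Nc), tr)
            proto <- rowMeans(X[, idx[tr], drop = FALSE])
            ad <- abs(X[, idx[te], drop = FALSE] - proto)^params@p
            dC <- if (is.null(imp)) colSums(wrc * ad)^(1 / params@p)
                  else colSums(exImp$wai * wrc * ad)^(1 / params@p) /
                      exImp$Wai + params@lambda / exImp$Wai
            Dte <- full[te, , drop = FALSE]
            Dte[, cPos] <- dC
            pred <- seenOrder[max.col(-Dte, ties.method = "first")]
            acc <- acc + as.numeric(table(factor(pred, levels = classes)))
        }
        confusion[cl, ] <- acc / nFolds
    }
    fMeasures(confusion)
}

#' Random-importance baseline
#'
#' Re-runs the leave-one-class-out zero-shot evaluation \code{R} times with
#' importance weights drawn as independent fair coins per (class, joint)
#' pair (all-zero rows are redrawn, as the weighted metric is undefined for
#' them), and averages the per-class F-measures.  A designed importance
#' table should beat this baseline; if it does not, the importance
#' assignments carry no usable information.
#'
#' @inheritParams locoZslEvaluate
#' @param R repetitions (the reference protocol uses 1000; 100 gives a
#'   usable estimate in a fraction of the time).
#' @param seed RNG seed; results are reproducible.
#' @return list with \code{perClass} (data.frame of mean per-class F),
#'   \code{averageF} (mean over classes of the mean F), and \code{reps}
#'   (vector of per-repetition average F).
#' @export
randomImportanceBaseline <- function(samples, defs, schema, R = 1000L,
                                     params = distanceParams(), seed = 1L) {
    stopifnot(R >= 1L)
    classes <- rownames(defs)
    joints <- jointNames(schema)
    set.seed(seed)
    fSum <- numeric(length(classes))
    repAvg <- numeric(R)
    for (r in seq_len(R)) {
        w <- matrix(rbinom(length(classes) * length(joints), 1L, 0.5),
                    length(classes), length(joints),
                    dimnames = list(classes, joints))
        while (any(rowSums(w) == 0)) {
            z <- which(rowSums(w) == 0)
            w[z, ] <- rbinom(length(z) * length(joints), 1L, 0.5)
        }
        wdf <- as.data.frame(w)
        names(wdf) <- joints   # keep non-syntactic joint names intact
        res <- locoZslEvaluate(samples, defs, schema, importance = wdf,
                               params = params, metric = "weighted")
        fSum <- fSum + perClassF(res)$f
        repAvg[r] <- averageF(res)
    }
    list(perClass = data.frame(class = classes, f = fSum / R,
                               stringsAsFactors = FALSE),
         averageF = mean(fSum / R), reps = repAvg)
}
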