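#' Distance parameters
#'
#' @param p order of the distance; 1 (the default) gives a weighted L1
#'   metric.
#' @param lambda penalty coefficient discouraging classes that declare very
#'   few joints important; default 0.1.
#' @return a \code{\link{DistanceParams}} object.
#' @export
distanceParams <- function(p = 1, lambda = 0.1) {
    new("DistanceParams", p = p, lambda = lambda)
}

setMethod("show", "DistanceParams", function(object) {
    cat(sprintf("DistanceParams: p = %g, lambda = %g\n",
                object@p, object@lambda))
    invisible(NULL)
})

#' Range-compensated nearest-neighbour distance
#'
#' The baseline metric between two attribute vectors:
#' \deqn{d(a, v) = \left(\sum_d w_{rc}(d)\, |a_d - v_d|^p\right)^{1/p}}
#' where \eqn{w_{rc}(d)} is 1 for regression dimensions and 0.5 for
#' classification dimensions (see \code{\link{wrcWeights}}).  Symmetric,
#' non-negative, zero iff the vectors are equal.  No importance weighting
#' and no penalty term.
#'
#' @param a,v numeric attribute vectors of length \code{schemaDim(schema)}.
#' @param schema an \code{\link{AttributeSchema}}.
#' @param params a \code{\link{DistanceParams}}.
#' @return non-negative scalar.
#' @examples
#' sch <- defaultAttributeSchema()
#' defs <- defaultPoseDefinitions(sch)
#' V <- expandDefinitionTable(defs, sch)
#' naiveDistance(V[, "Standing"], V[, "Sitting"], sch)  # 2
#' @export
naiveDistance <- function(a, v, schema, params = distanceParams()) {
    if (length(a) != schemaDim(schema) || length(v) != schemaDim(schema))
        stop("attribute vectors must have length ", schemaDim(schema))
    w <- wrcWeights(schema)
    sum(w * abs(a - v)^params@p)^(1 / params@p)
}

#' Importance-weighted prototype distance
#'
#' The core metric of the package:
#' \deqn{d(a, v^{(i)}) = \frac{1}{W_{ai}(i)}
#'   \left(\sum_d w_{ai}(d,i)\, w_{rc}(d)\, |a_d - v_d^{(i)}|^p\right)^{1/p}
#'   + \frac{\lambda}{W_{ai}(i)}}
#' where \eqn{w_{ai}(d,i)} copies the importance of the parent joint of
#' dimension \eqn{d} for the prototype's class, and \eqn{W_{ai}(i)} is the
#' sum of the per-joint importances.  With binary importance and \eqn{p = 1}
#' the first term is the average range-compensated deviation over the
#' class's diagnostic joints; the \eqn{\lambda/W_{ai}} term penalises
#' classes defined through few joints.  Dimensions with zero importance
#' cannot change the distance, which is how legitimate intra-class variation
#' on non-diagnostic joints is ignored.
#'
#' @param a numeric attribute vector.
#' @param v the prototype vector for class \eqn{i}.
#' @param importanceRow that class's row of the importance table (named
#'   per-joint weights).
#' @inheritParams naiveDistance
#' @return non-negative scalar.
#' @examples
#' sch <- defaultAttributeSchema()
#' defs <- defaultPoseDefinitions(sch)
#' imp <- defaultImportanceTable(sch)
#' V <- expandDefinitionTable(defs, sch)
#' # a vector matching the definition on all important joints: lambda / Wai
#' weightedDistance(V[, "Squatting"], V[, "Squatting"],
#'                  imp["Squatting", ], sch)  # 0.1 / 9
#' @export
weightedDistance <- function(a, v, importanceRow, schema,
                             params = distanceParams()) {
    if (length(a) != schemaDim(schema) || length(v) != schemaDim(schema))
        stop("attribute vectors must have length ", schemaDim(schema))
    ex <- expandImportance(importanceRow, schema)
    w <- ex$wai * wrcWeights(schema)
    sum(w * abs(a - v)^params@p)^(1 / params@p) / ex$Wai +
        params@lambda / ex$Wai
}

#' Distances from attribute vectors to a set of prototypes
#'
#' Vectorised workhorse behind \code{\link{classifyPose}}: returns the full
#' N x K matrix of distances between N attribute vectors and K class
#' prototypes, under either metric.
#'
#' @param x numeric matrix D x N (or a single length-D vector).
#' @param prototypes a \code{\link{PrototypeSet}}.
#' @param schema an \code{\link{AttributeSchema}}.
#' @param params a \code{\link{DistanceParams}}.
#' @param importance \code{NULL} for the range-compensated baseline metric,
#'   or an importance table (data.frame, classes x joints) covering every
#'   prototype class for the weighted metric.
#' @return numeric matrix, one row per input vector, one column per
#'   prototype (columns named by prototype label).
#' @export
attributeDistances <- function(x, prototypes, schema,
                               params = distanceParams(),
                               importance = NULL) {
    if (!is.matrix(x)) x <- matrix(x, ncol = 1)
    stopifnot(nrow(x) == schemaDim(schema))
    labs <- protoLabels(prototypes)
    V <- protoVectors(prototypes)
    wrc <- wrcWeights(schema)
    out <- matrix(NA_real_, ncol(x), length(labs),
                  dimnames = list(NULL, labs))
    for (k in seq_along(labs)) {
        ad <- abs(x - V[, k])^params@p
        if (is.null(importance)) {
            out[, k] <- colSums(wrc * ad)^(1 / params@p)
        } else {
            if (!labs[k] %in% rownames(importance))
                stop("importance table has no row for class: ", labs[k])
            ex <- expandImportance(importance[labs[k], , drop = FALSE], schema)
            out[, k] <- colSums(ex$wai * wrc * ad)^(1 / params@p) / ex$Wai +
                params@lambda / ex$Wai
        }
    }
    out
}

#' Nearest-prototype pose classification
#'
#' Assigns each attribute vector the label of its minimum-distance
#' prototype, using the importance-weighted metric when an importance table
#' is supplied and the range-compensated baseline otherwise.  Ties are
#' broken deterministically in favour of the prototype whose class comes
#' first in the prototype set's label order (definition-table order when the
#' prototypes were built from one).
#'
#' @inheritParams attributeDistances
#' @return character vector of class labels, one per input vector.
#' @examples
#' sch <- defaultAttributeSchema()
#' defs <- defaultPoseDefinitions(sch)
#' pro <- definitionPrototypes(defs, sch)
#' V <- expandDefinitionTable(defs, sch)
#' classifyPose(V[, "Boxing"], pro, sch,
#'              importance = defaultImportanceTable(sch))  # "Boxing"
#' @export
classifyPose <- function(x, prototypes, schema, params = distanceParams(),
                         importance = NULL) {
    d <- attributeDistances(x, prototypes, schema, params, importance)
    protoLabels(prototypes)[apply(d, 1L, which.min)]
}
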