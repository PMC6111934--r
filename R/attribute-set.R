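#' Construct an AttributeSet
#'
#' @param values D x N numeric matrix of attribute vectors (columns are
#'   windows).
#' @param pose character vector of pose labels, length N.
#' @param subject character vector of subject identifiers, length N
#'   (recycled if length 1).
#' @param schema optional \code{\link{AttributeSchema}}; when supplied the
#'   vectors are checked against it and the schema is kept in
#'   \code{metadata()}.
#' @return an \code{\link{AttributeSet}}.
#' @export
AttributeSet <- function(values, pose, subject = "s1", schema = NULL) {
    values <- as.matrix(values)
    if (length(subject) == 1L) subject <- rep(subject, ncol(values))
    stopifnot(length(pose) == ncol(values),
              length(subject) == ncol(values))
    meta <- list()
    if (!is.null(schema)) {
        checkAttributeVectors(values, schema)
        rownames(values) <- paste(dimJoints(schema),
                                  sequence(schema@joints$dim), sep = ".")
        meta$schema <- schema
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(attributes = values),
        colData = S4Vectors::DataFrame(pose = as.character(pose),
                                       subject = as.character(subject)),
        metadata = meta)
    new("AttributeSet", se)
}

#' @rdname AttributeSet-class
#' @aliases attrValues poseLabels subjectIds
#' @export
setMethod("attrValues", "AttributeSet",
    function(x) SummarizedExperiment::assay(x, "attributes"))

#' @rdname AttributeSet-class
#' @export
setMethod("poseLabels", "AttributeSet",
    function(x) SummarizedExperiment::colData(x)$pose)

#' @rdname AttributeSet-class
#' @export
setMethod("subjectIds", "AttributeSet",
    function(x) SummarizedExperiment::colData(x)$subject)

setMethod("show", "AttributeSet", function(object) {
    cat(sprintf("AttributeSet: %d attribute dimensions x %d windows\n",
                nrow(object), ncol(object)))
    tab <- table(poseLabels(object))
    cat(sprintf("  %d pose classes, %d subjects\n", length(tab),
                length(unique(subjectIds(object)))))
    invisible(NULL)
})

#' Write / read attribute vectors as CSV
#'
#' One row per window: the attribute dimensions followed by \code{pose} and
#' \code{subject} columns.
#'
#' @param x an \code{\link{AttributeSet}}.
#' @param file CSV path.
#' @export
writeAttributeSet <- function(x, file) {
    df <- as.data.frame(t(attrValues(x)))
    df$pose <- poseLabels(x)
    df$subject <- subjectIds(x)
    write.csv(df, file, row.names = FALSE)
    invisible(file)
}

#' @rdname writeAttributeSet
#' @param schema optional \code{\link{AttributeSchema}} for validation.
#' @export
readAttributeSet <- function(file, schema = NULL) {
    df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot(all(c("pose", "subject") %in% names(df)))
    keep <- setdiff(names(df), c("pose", "subject"))
    AttributeSet(t(as.matrix(df[, keep, drop = FALSE])),
                 pose = df$pose, subject = df$subject, schema = schema)
}
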