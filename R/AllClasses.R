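#' @import methods
#' @useDynLib zslpose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma rbinom pnorm qnorm sd setNames
#' @importFrom utils read.csv write.csv head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' AttributeSchema: the joint/attribute layout
#'
#' An \code{AttributeSchema} describes how body joints map onto a fixed-length
#' attribute vector.  Each joint is estimated either by multiclass
#' classification (it contributes one dimension per category, holding a
#' softmax probability) or by regression (one dimension holding a scalar state
#' in \code{[0, 1]}).  The default schema packaged with \pkg{zslpose} has 14
#' joints (head, shoulders, elbows, wrists, hands, waist, hip joints, knees;
#' left and right listed separately) contributing 33 dimensions in total.
#'
#' @slot joints data.frame with one row per joint: \code{name}, \code{kind}
#'   (\code{"classification"} or \code{"regression"}), \code{dim} (dimensions
#'   contributed) and \code{offset} (1-based start of the joint's slice).
#' @slot categories named list; per classification joint, the ordered
#'   category labels (one-hot order is fixed by this ordering).
#' @slot sensors named list; per joint, the identifiers of the IMU sensors
#'   feeding that joint's estimator.
#'
#' @seealso \code{\link{readAttributeSchema}}, \code{\link{defaultAttributeSchema}}
#' @exportClass AttributeSchema
setClass("AttributeSchema",
    slots = c(joints = "data.frame", categories = "list", sensors = "list"))

setValidity("AttributeSchema", function(object) {
    j <- object@joints
    need <- c("name", "kind", "dim", "offset")
    if (!all(need %in% names(j)))
        return(sprintf("joints must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(j$name))
        return("duplicate joint names")
    if (!all(j$kind %in% c("classification", "regression")))
        return("joint kind must be 'classification' or 'regression'")
    for (i in seq_len(nrow(j))) {
        nm <- j$name[i]
        if (j$kind[i] == "regression") {
            if (j$dim[i] != 1L) return(sprintf("regression joint '%s' must have dim 1", nm))
            if (length(object@categories[[nm]]) != 0L)
                return(sprintf("regression joint '%s' must have no categories", nm))
        } else {
            k <- length(object@categories[[nm]])
            if (k < 2L) return(sprintf("classification joint '%s' needs >= 2 categories", nm))
            if (j$dim[i] != k)
                return(sprintf("joint '%s': dim != number of categories", nm))
        }
    }
    # slices must be contiguous, disjoint, and cover 1..D
    expected <- cumsum(c(1L, j$dim[-nrow(j)]))
    if (!all(j$offset == expected))
        return("joint slices must be contiguous in joint order")
    TRUE
})

#' AttributeSet: attribute vectors with pose and subject annotation
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} whose single
#' assay \code{"attributes"} is a D x N matrix of per-window attribute
#' vectors (D = 33 for the default schema), with \code{colData} columns
#' \code{pose} and \code{subject}.  Rows are attribute dimensions, columns are
#' sliding windows.
#'
#' @exportClass AttributeSet
setClass("AttributeSet", contains = "SummarizedExperiment")

setValidity("AttributeSet", function(object) {
    if (!"attributes" %in% SummarizedExperiment::assayNames(object))
        return("assay 'attributes' is required")
    v <- SummarizedExperiment::assay(object, "attributes")
    if (any(v < -1e-9 | v > 1 + 1e-9))
        return("attribute values must lie in [0, 1]")
    if (!all(c("pose", "subject") %in% names(SummarizedExperiment::colData(object))))
        return("colData must have 'pose' and 'subject'")
    TRUE
})

#' Recording: a multichannel IMU time series
#'
#' One continuous recording of a subject holding a pose, sampled from a set
#' of body-worn IMUs.  Each sensor contributes 10 channels: 3 accelerometer,
#' 3 gyroscope and 4 quaternion.  Channel columns are ordered sensor by
#' sensor.
#'
#' @slot samples T x C numeric matrix (C = 10 x number of sensors).
#' @slot rate sampling rate in Hz (default 60).
#' @slot pose pose class label.
#' @slot subject subject identifier.
#' @slot sensors character vector of sensor identifiers, in channel order.
#' @slot states named list giving the true per-joint state realised in this
#'   recording (category label or scalar); filled by the synthetic generator
#'   and used as ground truth when training estimators.
#'
#' @exportClass Recording
setClass("Recording",
    slots = c(samples = "matrix", rate = "numeric", pose = "character",
              subject = "character", sensors = "character", states = "list"))

setValidity("Recording", function(object) {
    if (ncol(object@samples) != 10L * length(object@sensors))
        return("ncol(samples) must equal 10 * number of sensors")
    if (length(object@rate) != 1L || object@rate <= 0)
        return("rate must be a positive scalar")
    TRUE
})

#' VariationSpec: admissible intra-class variation
#'
#' Describes, per pose class, which joints a subject may legitimately hold in
#' a state different from the definitional one, and the set of admissible
#' alternative states.  Also carries the noise parameters used by the
#' synthetic generator: \code{noiseSd}, the standard deviation of truncated
#' Gaussian noise added to regression attributes, and \code{concentration},
#' the Dirichlet sharpness of noisy simplex samples around one-hot targets
#' (the default 35 puts roughly 0.9 of the mass on the modal category).
#'
#' @slot alternatives named list (by class) of named lists (by joint) of
#'   admissible values.
#' @slot noiseSd non-negative numeric.
#' @slot concentration positive numeric.
#'
#' @exportClass VariationSpec
setClass("VariationSpec",
    slots = c(alternatives = "list", noiseSd = "numeric",
              concentration = "numeric"))

setValidity("VariationSpec", function(object) {
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@concentration <= 0) return("concentration must be > 0")
    TRUE
})

#' PrototypeSet: one representative attribute vector per class
#'
#' @slot vectors D x n numeric matrix, one column per prototype.
#' @slot labels class label of each prototype.
#' @slot source per prototype, \code{"definition"} (expanded from the symbolic
#'   pose-definition table) or \code{"data_mean"} (element-wise mean of that
#'   class's attribute vectors).
#'
#' @exportClass PrototypeSet
setClass("PrototypeSet",
    slots = c(vectors = "matrix", labels = "character", source = "character"))

setValidity("PrototypeSet", function(object) {
    if (ncol(object@vectors) != length(object@labels))
        return("one label per prototype column required")
    if (length(object@source) != length(object@labels))
        return("one source per prototype required")
    if (!all(object@source %in% c("definition", "data_mean")))
        return("source must be 'definition' or 'data_mean'")
    if (anyDuplicated(object@labels))
        return("duplicate prototype labels")
    if (any(object@vectors < -1e-9 | object@vectors > 1 + 1e-9))
        return("prototype values must lie in [0, 1]")
    TRUE
})

#' DistanceParams: parameters of the prototype distance
#'
#' @slot p order of the distance (>= 1); the study default is 1.
#' @slot lambda penalty coefficient on classes defined through few important
#'   joints (>= 0); the study default is 0.1.
#'
#' @exportClass DistanceParams
setClass("DistanceParams", slots = c(p = "numeric", lambda = "numeric"))

setValidity("DistanceParams", function(object) {
    if (length(object@p) != 1L || object@p < 1) return("p must be >= 1")
    if (length(object@lambda) != 1L || object@lambda < 0)
        return("lambda must be >= 0")
    TRUE
})

#' PoseCnn: a per-joint time-series convolutional estimator
#'
#' A small convolutional network mapping a 60 x M window of IMU channels to
#' either a probability vector over the joint's categories (softmax head,
#' cross-entropy loss) or a scalar state in \code{[0, 1]} (sigmoid head, mean
#' absolute error loss).  Four valid 2-D convolutions (25, 20, 15, 10 output
#' channels; kernels 3x10 for hands, 3x3 otherwise) mix the time and channel
#' axes jointly, each followed by batch normalisation and leaky ReLU; a
#' 100-node fully connected layer with dropout precedes the head.  Training
#' uses momentum SGD (momentum 0.9).
#'
#' @slot joint joint name.
#' @slot kind \code{"classification"} or \code{"regression"}.
#' @slot M number of input channels (10 per sensor).
#' @slot nOut output dimension (number of categories, or 1).
#' @slot spec architecture hyperparameters (conv channels, kernel, fc nodes,
#'   dropout rate, leaky-ReLU slope, batch-norm momentum).
#' @slot params list of weight matrices/arrays and batch-norm parameters.
#' @slot norm per-channel standardisation statistics from the training set.
#' @slot trained logical.
#' @slot lossHistory mean training loss per epoch.
#'
#' @exportClass PoseCnn
setClass("PoseCnn",
    slots = c(joint = "character", kind = "character", M = "integer",
              nOut = "integer", spec = "list", params = "list", norm = "list",
              trained = "logical", lossHistory = "numeric"))

#' EvalResult: per-class precision/recall/F and aggregate confusion
#'
#' @slot perClass data.frame with columns \code{class}, \code{precision},
#'   \code{recall}, \code{f}.
#' @slot averageF unweighted mean F-measure over classes.
#' @slot confusion square contingency matrix, rows = true class, columns =
#'   predicted class (counts may be fractional after per-class fold
#'   averaging in the k-shot protocol).
#'
#' @exportClass EvalResult
setClass("EvalResult",
    slots = c(perClass = "data.frame", averageF = "numeric",
              confusion = "matrix"))

setValidity("EvalResult", function(object) {
    pc <- object@perClass
    if (!all(c("class", "precision", "recall", "f") %in% names(pc)))
        return("perClass needs columns class, precision, recall, f")
    m <- as.matrix(pc[, c("precision", "recall", "f")])
    if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE))
        return("metrics must lie in [0, 1]")
    TRUE
})
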