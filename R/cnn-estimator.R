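#' Architecture specification for one joint's estimator
#'
#' Four valid 2-D convolutions with 25, 20, 15 and 10 output channels mix the
#' time axis and the sensor-channel axis jointly, integrating modalities from
#' the first layer on.  The kernel is 3x3, widened to 3x10 for joints fed by
#' many sensors (the hands, which use the hand IMU plus seven finger IMUs).
#' A 100-node fully connected layer with dropout precedes a softmax head
#' (classification joints, cross-entropy loss) or a single sigmoid unit
#' (regression joints, mean absolute error).  Training uses momentum SGD
#' with momentum 0.9.  Batch normalisation follows every convolution.
#'
#' @param schema an \code{\link{AttributeSchema}}.
#' @param joint joint name.
#' @param convChannels integer vector of convolution output channels.
#' @param kernel \code{c(kTime, kChannel)}; default 3x10 when the joint uses
#'   more than 3 sensors, 3x3 otherwise.
#' @param fcNodes,dropout,lreluSlope,bnMomentum,eps,momentum further
#'   hyperparameters (see details).
#' @param windowLength sliding-window length in samples (60 = 1 s at 60 Hz).
#' @return a list describing the architecture.
#' @export
estimatorSpec <- function(schema, joint, convChannels = c(25L, 20L, 15L, 10L),
                          kernel = NULL, fcNodes = 100L, dropout = 0.5,
                          lreluSlope = 0.01, bnMomentum = 0.9, eps = 1e-5,
                          momentum = 0.9, windowLength = 60L) {
    kind <- jointKinds(schema)[[joint]]
    sens <- jointSensors(schema, joint)
    M <- 10L * length(sens)
    if (is.null(kernel))
        kernel <- if (length(sens) > 3L) c(3L, 10L) else c(3L, 3L)
    if (M < kernel[2])
        stop(sprintf("joint '%s': %d channels but kernel spans %d",
                     joint, M, kernel[2]))
    nOut <- if (kind == "classification")
        length(jointCategories(schema, joint)) else 1L
    list(joint = joint, kind = kind, M = M, nOut = nOut,
         sensors = sens, convChannels = as.integer(convChannels),
         kernel = as.integer(kernel), fcNodes = as.integer(fcNodes),
         dropout = dropout, lreluSlope = lreluSlope,
         bnMomentum = bnMomentum, eps = eps, momentum = momentum,
         windowLength = as.integer(windowLength))
}

#' Specifications for every joint of a schema
#'
#' @inheritParams estimatorSpec
#' @param ... passed on to \code{\link{estimatorSpec}}.
#' @return named list of specs, one per joint (14 for the default schema).
#' @export
estimatorSpecs <- function(schema, ...) {
    out <- lapply(jointNames(schema), function(j) estimatorSpec(schema, j, ...))
    names(out) <- jointNames(schema)
    out
}

.convOutDims <- function(H, W, spec) {
    for (ch in spec$convChannels) {
        H <- H - spec$kernel[1] + 1L
        W <- W - spec$kernel[2] + 1L
        if (H < 1L || W < 1L)
            stop("window too small for the convolution stack")
    }
    c(H, W, spec$convChannels[length(spec$convChannels)])
}

#' Build an untrained per-joint estimator
#'
#' Weights are He-initialised from the given seed; batch-norm scale/shift
#' start at 1/0 and running statistics at 0/1.  The untrained network
#' already honours the output constraints (simplex / \code{[0, 1]}).
#'
#' @inheritParams estimatorSpec
#' @param spec a spec from \code{\link{estimatorSpec}} (built from
#'   \code{schema}/\code{joint} if omitted).
#' @param seed integer RNG seed for the initialisation.
#' @return an untrained \code{\link{PoseCnn}}.
#' @export
buildEstimator <- function(schema, joint, spec = NULL, seed = 1L, ...) {
    if (is.null(spec)) spec <- estimatorSpec(schema, joint, ...)
    set.seed(seed)
    kh <- spec$kernel[1]; kw <- spec$kernel[2]
    H <- spec$windowLength; W <- spec$M
    cin <- 1L
    conv <- vector("list", length(spec$convChannels))
    for (l in seq_along(spec$convChannels)) {
        cout <- spec$convChannels[l]
        fanIn <- kh * kw * cin
        w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fanIn)),
                   dim = c(kh, kw, cin, cout))
        conv[[l]] <- list(w = w, b = numeric(cout),
                          gamma = rep(1, cout), beta = numeric(cout),
                          rm = numeric(cout), rv = rep(1, cout))
        H <- H - kh + 1L; W <- W - kw + 1L
        if (H < 1L || W < 1L) stop("window too small for convolution stack")
        cin <- cout
    }
    flat <- H * W * cin
    fc1 <- list(w = matrix(rnorm(flat * spec$fcNodes, sd = sqrt(2 / flat)),
                           flat, spec$fcNodes),
                b = numeric(spec$fcNodes))
    head <- list(w = matrix(rnorm(spec$fcNodes * spec$nOut,
                                  sd = sqrt(2 / spec$fcNodes)),
                            spec$fcNodes, spec$nOut),
                 b = numeric(spec$nOut))
    new("PoseCnn", joint = spec$joint, kind = spec$kind,
        M = as.integer(spec$M), nOut = as.integer(spec$nOut), spec = spec,
        params = list(conv = conv, fc1 = fc1, head = head),
        norm = list(mean = numeric(spec$M), sd = rep(1, spec$M)),
        trained = FALSE, lossHistory = numeric(0))
}

setMethod("show", "PoseCnn", function(object) {
    cat(sprintf("PoseCnn '%s' (%s): %d x %d window -> %d output%s; %s\n",
                object@joint, object@kind, object@spec$windowLength,
                object@M, object@nOut, if (object@nOut > 1) "s" else "",
                if (object@trained)
                    sprintf("trained (%d epochs)", length(object@lossHistory))
                else "untrained"))
    invisible(NULL)
})

.standardizeWindows <- function(x, norm) {
    # x: (time, M, N); centre/scale each of the M channels
    d <- dim(x)
    sweep(sweep(x, 2L, norm$mean, `-`), 2L, norm$sd, `/`)
}

#' Train a per-joint estimator
#'
#' Minimises cross-entropy (classification) or mean absolute error
#' (regression) by momentum SGD over shuffled mini-batches.  Input channels
#' are standardised with per-channel z-scores computed from this training
#' set and stored in the estimator (raw accelerometer, gyroscope and
#' quaternion channels differ by orders of magnitude in scale).
#'
#' @param est an untrained (or previously trained) \code{\link{PoseCnn}}.
#' @param x numeric array (windowLength, M, N) of training windows.
#' @param y targets: integer category indices (1-based) for classification,
#'   numeric values in \code{[0, 1]} for regression.
#' @param epochs,batch,lr training hyperparameters.
#' @param clip global L2 gradient-norm clipping threshold (stabilises
#'   momentum SGD on the large hand networks); \code{Inf} disables.
#' @param balance for classification joints, draw each epoch's windows with
#'   probabilities inversely proportional to category frequency
#'   (with replacement), so rare joint states are not drowned out by the
#'   dominant one; ignored for regression.
#' @param seed RNG seed controlling shuffling and dropout; training is
#'   reproducible given the seed.
#' @param verbose print per-epoch loss.
#' @return the trained \code{\link{PoseCnn}} with \code{lossHistory} filled.
#' @export
trainEstimator <- function(est, x, y, epochs = 20L, batch = 32L, lr = 0.01,
                           clip = 5, balance = TRUE, seed = 1L,
                           verbose = FALSE) {
    stopifnot(is(est, "PoseCnn"))
    d <- dim(x)
    if (length(d) != 3L || d[1] != est@spec$windowLength || d[2] != est@M)
        stop("x must be a (windowLength, M, N) array matching the estimator")
    N <- d[3]
    if (N < 1L) stop("empty training set")
    if (est@kind == "classification") {
        y <- as.integer(y)
        if (any(y < 1L | y > est@nOut)) stop("category index out of range")
        if (length(unique(y)) < 2L)
            stop("degenerate training set: a single category present")
    } else {
        y <- as.numeric(y)
        if (any(y < 0 | y > 1)) stop("regression targets must be in [0, 1]")
    }
    if (length(y) != N) stop("one target per window required")

    mu <- apply(x, 2L, mean)
    sdv <- apply(x, 2L, sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    est@norm <- list(mean = mu, sd = sdv)
    xs <- .standardizeWindows(x, est@norm)

    set.seed(seed)
    pp <- est@params
    mom <- est@spec$momentum
    vel <- rapply(pp, function(p) p * 0, how = "replace")
    sampProb <- NULL
    if (balance && est@kind == "classification") {
        freq <- tabulate(y, est@nOut)
        sampProb <- 1 / freq[y]
    }
    lossHist <- numeric(epochs)
    if (epochs >= 1L) for (ep in seq_len(epochs)) {
        ord <- if (is.null(sampProb)) sample.int(N)
               else sample.int(N, N, replace = TRUE, prob = sampProb)
        losses <- c()
        for (b0 in seq(1L, N, by = batch)) {
            idx <- ord[b0:min(b0 + batch - 1L, N)]
            xb <- xs[, , idx, drop = FALSE]
            dim(xb) <- c(d[1], d[2], 1L, length(idx))
            fw <- .cnnForward(pp, est@spec, xb, training = TRUE)
            pp <- fw$pp   # batch-norm running stats advanced
            lg <- .cnnLossGrad(fw$out, y[idx], est@kind)
            g <- .cnnBackward(pp, est@spec, fw, lg$dz)
            if (is.finite(clip)) {
                gn <- sqrt(sum(unlist(rapply(
                    g, function(x) sum(x^2), how = "unlist"))))
                if (gn > clip) g <- rapply(g, function(x) x * clip / gn,
                                           how = "replace")
            }
            upd <- function(p, v, gr) {
                v2 <- mom * v - lr * gr
                list(p = p + v2, v = v2)
            }
            for (l in seq_along(pp$conv)) {
                for (nm in c("w", "b", "gamma", "beta")) {
                    gr <- switch(nm, w = g$conv[[l]]$dw, b = g$conv[[l]]$db,
                                 gamma = g$conv[[l]]$dgamma,
                                 beta = g$conv[[l]]$dbeta)
                    u <- upd(pp$conv[[l]][[nm]], vel$conv[[l]][[nm]], gr)
                    pp$conv[[l]][[nm]] <- u$p
                    vel$conv[[l]][[nm]] <- u$v
                }
            }
            for (nm in c("fc1", "head")) {
                u <- upd(pp[[nm]]$w, vel[[nm]]$w, g[[nm]]$dw)
                pp[[nm]]$w <- u$p; vel[[nm]]$w <- u$v
                u <- upd(pp[[nm]]$b, vel[[nm]]$b, g[[nm]]$db)
                pp[[nm]]$b <- u$p; vel[[nm]]$b <- u$v
            }
            losses <- c(losses, lg$loss)
        }
        lossHist[ep] <- mean(losses)
        if (verbose)
            message(sprintf("[%s] epoch %d/%d loss %.4f", est@joint, ep,
                            epochs, lossHist[ep]))
    }
    est@params <- pp
    est@trained <- TRUE
    est@lossHistory <- c(est@lossHistory, lossHist)
    est
}

#' Apply a per-joint estimator to windows
#'
#' @param est a \code{\link{PoseCnn}}.
#' @param x numeric array (windowLength, M, N).
#' @return matrix (nOut x N): softmax probabilities (columns sum to 1) or
#'   sigmoid-squashed scalars in \code{[0, 1]}.
#' @export
predictEstimator <- function(est, x) {
    d <- dim(x)
    if (length(d) == 2L) { x <- array(x, c(d, 1L)); d <- dim(x) }
    if (d[1] != est@spec$windowLength || d[2] != est@M)
        stop("window shape does not match the estimator")
    xs <- .standardizeWindows(x, est@norm)
    dim(xs) <- c(d[1], d[2], 1L, d[3])
    .cnnForward(est@params, est@spec, xs, training = FALSE)$out
}

#' Sliding windows over a recording
#'
#' Half-open windows \code{[start, start + length)} starting at 0, shift,
#' 2 shift, ...; their count is \code{floor((T - length) / shift) + 1}.
#' The defaults (length 60, shift 30) correspond to 1 s windows shifted by
#' 0.5 s at 60 Hz, giving 59 windows for a 30 s recording.
#'
#' @param rec a \code{\link{Recording}} (or a T x C matrix).
#' @param length window length in samples.
#' @param shift window shift in samples.
#' @return list with \code{windows}, an array (length, C, nWindows), and
#'   \code{starts}, the 0-based window start indices.
#' @export
slidingWindows <- function(rec, length = 60L, shift = 30L) {
    m <- if (is(rec, "Recording")) rec@samples else rec
    T_ <- nrow(m)
    if (T_ < length)
        stop(sprintf("recording has %d samples, need at least %d", T_, length))
    starts <- seq.int(0L, T_ - length, by = shift)
    w <- vapply(starts, function(s) m[(s + 1L):(s + length), , drop = FALSE],
                matrix(0, length, ncol(m)))
    list(windows = array(w, c(length, ncol(m), base::length(starts))),
         starts = starts)
}

.sensorChannels <- function(rec, sensors) {
    pos <- match(sensors, rec@sensors)
    if (anyNA(pos))
        stop("recording lacks sensors: ",
             paste(sensors[is.na(pos)], collapse = ", "))
    as.vector(vapply(pos, function(p) (p - 1L) * 10L + 1:10, integer(10)))
}

#' Estimate attribute vectors for a recording
#'
#' Slides a window over the recording, feeds each joint's sensor channels to
#' its trained estimator, and concatenates the per-joint outputs in schema
#' order into one attribute vector per window.
#'
#' @param estimators named list of trained \code{\link{PoseCnn}} objects,
#'   one per joint of \code{schema}.
#' @param rec a \code{\link{Recording}}.
#' @param schema an \code{\link{AttributeSchema}}.
#' @param length,shift windowing parameters.
#' @return an \code{\link{AttributeSet}} (one column per window).
#' @export
estimateAttributes <- function(estimators, rec, schema,
                               length = 60L, shift = 30L) {
    miss <- setdiff(jointNames(schema), names(estimators))
    if (base::length(miss))
        stop("missing estimators for: ", paste(miss, collapse = ", "))
    sw <- slidingWindows(rec, length, shift)
    nWin <- dim(sw$windows)[3]
    vals <- matrix(NA_real_, schemaDim(schema), nWin)
    for (jn in jointNames(schema)) {
        est <- estimators[[jn]]
        if (!est@trained) stop("estimator for '", jn, "' is not trained")
        ch <- .sensorChannels(rec, jointSensors(schema, jn))
        if (base::length(ch) != est@M)
            stop("channel-layout mismatch for joint '", jn, "'")
        vals[jointSlice(schema, jn), ] <-
            predictEstimator(est, sw$windows[, ch, , drop = FALSE])
    }
    AttributeSet(vals, pose = rep(rec@pose, nWin),
                 subject = rep(rec@subject, nWin), schema = schema)
}

#' Train estimators for every joint from a labelled corpus
#'
#' Windows every recording, looks up each joint's true state in the
#' recordings' \code{states} metadata, and trains one estimator per joint.
#'
#' @param recordings list of \code{\link{Recording}} objects whose
#'   \code{states} slot is filled (as produced by
#'   \code{\link{generateImuRecording}}).
#' @inheritParams estimateAttributes
#' @inheritParams trainEstimator
#' @param wideKernelEpochs epoch budget for joints using the wide 3x10
#'   kernel (the hand networks).  These are an order of magnitude more
#'   expensive per epoch than the other estimators and converge in far
#'   fewer epochs on their strongly separable inputs; \code{NULL} uses
#'   \code{epochs} for them too.
#' @param ... passed to \code{\link{estimatorSpec}}.
#' @return named list of trained \code{\link{PoseCnn}} objects.
#' @export
trainJointEstimators <- function(recordings, schema, epochs = 24L,
                                 wideKernelEpochs = 8L,
                                 batch = 32L, lr = 0.02, seed = 1L,
                                 length = 60L, shift = 30L,
                                 verbose = FALSE, ...) {
    sw <- lapply(recordings, slidingWindows, length = length, shift = shift)
    out <- list()
    for (jn in jointNames(schema)) {
        kind <- jointKinds(schema)[[jn]]
        cats <- jointCategories(schema, jn)
        xs <- list(); ys <- list()
        for (i in seq_along(recordings)) {
            rec <- recordings[[i]]
            st <- rec@states[[jn]]
            if (is.null(st)) stop("recording ", i, " lacks state for ", jn)
            ch <- .sensorChannels(rec, jointSensors(schema, jn))
            w <- sw[[i]]$windows[, ch, , drop = FALSE]
            n <- dim(w)[3]
            xs[[i]] <- w
            ys[[i]] <- if (kind == "classification")
                rep(match(as.character(st), cats), n)
            else rep(as.numeric(st), n)
        }
        x <- array(unlist(xs), c(length, base::length(.sensorChannels(
            recordings[[1]], jointSensors(schema, jn))),
            sum(vapply(xs, function(a) dim(a)[3], 0))))
        y <- unlist(ys)
        est <- buildEstimator(schema, jn, seed = seed, ...)
        ep <- if (!is.null(wideKernelEpochs) && est@spec$kernel[2] > 3L)
            wideKernelEpochs else epochs
        out[[jn]] <- trainEstimator(est, x, y, epochs = ep, batch = batch,
                                    lr = lr, seed = seed + match(jn, jointNames(schema)),
                                    verbose = verbose)
    }
    out
}
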