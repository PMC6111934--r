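# Internal layer math for the per-joint time-series CNN.
# Arrays flow through as (time, channel, featureMaps, batch); the valid 2-D
# convolutions, the per-channel batch-norm broadcasts/reductions and the
# leaky ReLU are compiled (src/conv.cpp), the fully connected pieces are
# plain BLAS.  Backward passes are verified against finite differences in
# the test suite.

.bnFwd <- function(z, bn, momentum, eps, training) {
    d <- dim(z)
    m <- d[1] * d[2] * d[4]
    if (training) {
        mu <- cpp_chan_sums(z) / m
        va <- cpp_chan_dot(z, z) / m - mu^2
        va <- pmax(va, 0)
        bn$rm <- momentum * bn$rm + (1 - momentum) * mu
        bn$rv <- momentum * bn$rv + (1 - momentum) * va
    } else {
        mu <- bn$rm
        va <- bn$rv
    }
    sdv <- sqrt(va + eps)
    xhat <- cpp_chan_affine(z, 1 / sdv, -mu / sdv)
    y <- cpp_chan_affine(xhat, bn$gamma, bn$beta)
    list(y = y, xhat = xhat, sd = sdv, m = m, bn = bn)
}

.bnBwd <- function(dy, cache, gamma) {
    dgamma <- cpp_chan_dot(dy, cache$xhat)
    dbeta <- cpp_chan_sums(dy)
    # dx = (gamma/sd) * (dy - mean(dy) - xhat * mean(dy * xhat)), means per
    # channel over positions and batch (batch statistics were used forward)
    t1 <- cpp_chan_affine(cache$xhat, dgamma / cache$m, dbeta / cache$m)
    dx <- cpp_chan_affine(dy - t1, gamma / cache$sd, numeric(length(gamma)))
    list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.softmaxCols <- function(z) {
    z <- sweep(z, 2L, apply(z, 2L, max), `-`)
    e <- exp(z)
    sweep(e, 2L, colSums(e), `/`)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Full forward pass.  x4: (60, M, 1, N).  Returns network output plus the
# caches needed for backprop when training = TRUE.
.cnnForward <- function(pp, spec, x4, training = FALSE, dropMask = NULL) {
    caches <- vector("list", length(pp$conv))
    a <- x4
    for (l in seq_along(pp$conv)) {
        cv <- pp$conv[[l]]
        z <- cpp_conv2d_fwd(a, cv$w, cv$b)
        bnr <- .bnFwd(z, cv, spec$bnMomentum, spec$eps, training)
        r <- cpp_lrelu(bnr$y, spec$lreluSlope)
        caches[[l]] <- list(x = a, bnCache = bnr, m = r$m)
        pp$conv[[l]]$rm <- bnr$bn$rm
        pp$conv[[l]]$rv <- bnr$bn$rv
        a <- r$y
    }
    d <- dim(a)
    N <- d[4]
    flat <- prod(d[1:3])
    dim(a) <- c(flat, N)
    z1 <- crossprod(pp$fc1$w, a) + pp$fc1$b
    r1 <- cpp_lrelu(z1, spec$lreluSlope)
    h <- r1$y
    if (training && spec$dropout > 0) {
        if (is.null(dropMask))
            dropMask <- matrix(
                (runif(length(h)) >= spec$dropout) / (1 - spec$dropout),
                nrow(h), ncol(h))
        h <- h * dropMask
    }
    z2 <- crossprod(pp$head$w, h) + pp$head$b
    out <- if (spec$kind == "classification") .softmaxCols(z2) else .sigmoid(z2)
    list(out = out, pp = pp,
         cache = list(caches = caches, aflat = a, m1 = r1$m,
                      dropMask = dropMask, h = h, flatDims = d))
}

# Backward pass from the gradient at the pre-head linear output (dz2).
.cnnBackward <- function(pp, spec, fw, dz2) {
    g <- list(conv = vector("list", length(pp$conv)))
    cache <- fw$cache
    g$head <- list(dw = cache$h %*% t(dz2), db = rowSums(dz2))
    dh <- pp$head$w %*% dz2
    if (!is.null(cache$dropMask)) dh <- dh * cache$dropMask
    dz1 <- dh * cache$m1
    g$fc1 <- list(dw = cache$aflat %*% t(dz1), db = rowSums(dz1))
    da <- pp$fc1$w %*% dz1
    dim(da) <- cache$flatDims
    for (l in rev(seq_along(pp$conv))) {
        cl <- cache$caches[[l]]
        dy <- da * cl$m
        bb <- .bnBwd(dy, cl$bnCache, pp$conv[[l]]$gamma)
        cb <- cpp_conv2d_bwd(cl$x, pp$conv[[l]]$w, bb$dx, need_dx = l > 1L)
        g$conv[[l]] <- list(dw = cb$dw, db = cb$db,
                            dgamma = bb$dgamma, dbeta = bb$dbeta)
        da <- cb$dx
    }
    g
}

# Loss value and head gradient for a batch.
.cnnLossGrad <- function(out, targets, kind) {
    N <- ncol(out)
    if (kind == "classification") {
        idx <- cbind(targets, seq_len(N))
        loss <- -mean(log(pmax(out[idx], 1e-12)))
        Y <- matrix(0, nrow(out), N)
        Y[idx] <- 1
        dz <- (out - Y) / N
    } else {
        err <- out - matrix(targets, 1L, N)
        loss <- mean(abs(err))
        dz <- sign(err) * out * (1 - out) / N
    }
    list(loss = loss, dz = dz)
}
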