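# Reference two-level U-Net with hand-written forward/backward passes.
# Feature maps are (H*W) x C matrices; 3x3 convolutions use a
# shift-and-matmul scheme (9 gathers + 9 matrix products), which keeps the
# whole net in BLAS calls. Shift index maps are cached per image size.

.shiftCache <- new.env(parent = emptyenv())

# index map for kernel offset (dx, dy): out pixel p takes input pixel
# idx[p], 0 when out of bounds (zero padding)
.shiftIndex <- function(H, W, dx, dy) {
    key <- paste(H, W, dx, dy, sep = "_")
    got <- .shiftCache[[key]]
    if (!is.null(got)) return(got)
    i <- rep(seq_len(H), times = W) + dx
    j <- rep(seq_len(W), each = H) + dy
    ok <- i >= 1L & i <= H & j >= 1L & j <= W
    idx <- integer(H * W)
    idx[ok] <- (j[ok] - 1L) * H + i[ok]
    .shiftCache[[key]] <- idx
    idx
}

# X: (H*W) x Cin; W3: list of 9 matrices Cin x Cout (offsets row-major
# over dy, dx in -1..1); returns (H*W) x Cout
.conv3Forward <- function(X, H, W, kern, bias) {
    Cout <- ncol(kern[[1]])
    Y <- matrix(rep(bias, each = H * W), H * W, Cout)
    k <- 0L
    for (dy in -1:1) for (dx in -1:1) {
        k <- k + 1L
        idx <- .shiftIndex(H, W, dx, dy)
        ok <- idx > 0L
        Xs <- matrix(0, H * W, nrow(kern[[k]]))
        Xs[ok, ] <- X[idx[ok], , drop = FALSE]
        Y <- Y + Xs %*% kern[[k]]
    }
    Y
}

# returns list(dX, dKern, dBias)
.conv3Backward <- function(X, H, W, kern, dY) {
    Cin <- ncol(X)
    dX <- matrix(0, H * W, Cin)
    dKern <- vector("list", 9L)
    k <- 0L
    for (dy in -1:1) for (dx in -1:1) {
        k <- k + 1L
        idx <- .shiftIndex(H, W, dx, dy)
        ok <- idx > 0L
        Xs <- matrix(0, H * W, Cin)
        Xs[ok, ] <- X[idx[ok], , drop = FALSE]
        dKern[[k]] <- crossprod(Xs, dY)
        dXs <- dY %*% t(kern[[k]])
        # scatter back: for fixed offset the map out-pixel -> in-pixel is
        # injective, so plain indexed addition is safe
        dX[idx[ok], ] <- dX[idx[ok], , drop = FALSE] + dXs[ok, , drop = FALSE]
    }
    list(dX = dX, dKern = dKern, dBias = colSums(dY))
}

# 2x2 max pool on (H*W) x C (H, W even); returns pooled matrix plus the
# argmax selector for the backward pass
.pool2Forward <- function(X, H, W) {
    C <- ncol(X)
    dim(X) <- c(H, W, C)
    a <- X[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
    b <- X[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
    cc <- X[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
    d <- X[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
    P <- pmax(a, b, cc, d)
    which4 <- (P == a) * 1L
    which4[which4 == 0L & P == b] <- 2L
    which4[which4 == 0L & P == cc] <- 3L
    which4[which4 == 0L & P == d] <- 4L
    list(P = matrix(P, (H / 2) * (W / 2), C), which = which4)
}

.pool2Backward <- function(dP, which4, H, W) {
    C <- ncol(dP)
    h2 <- H / 2; w2 <- W / 2
    dim(dP) <- c(h2, w2, C)
    dX <- array(0, c(H, W, C))
    sel <- function(q) (which4 == q) * dP
    dX[seq(1, H, 2), seq(1, W, 2), ] <- sel(1L)
    dX[seq(2, H, 2), seq(1, W, 2), ] <- sel(2L)
    dX[seq(1, H, 2), seq(2, W, 2), ] <- sel(3L)
    dX[seq(2, H, 2), seq(2, W, 2), ] <- sel(4L)
    matrix(dX, H * W, C)
}

.upsample2 <- function(P, H, W) {
    # P on (H/2, W/2) grid -> nearest-neighbour (H, W)
    C <- ncol(P)
    h2 <- H / 2; w2 <- W / 2
    dim(P) <- c(h2, w2, C)
    U <- P[rep(seq_len(h2), each = 2), rep(seq_len(w2), each = 2), ,
           drop = FALSE]
    matrix(U, H * W, C)
}

.upsample2Backward <- function(dU, H, W) {
    C <- ncol(dU)
    dim(dU) <- c(H, W, C)
    dP <- dU[seq(1, H, 2), , , drop = FALSE] + dU[seq(2, H, 2), , , drop = FALSE]
    dP <- dP[, seq(1, W, 2), , drop = FALSE] + dP[, seq(2, W, 2), , drop = FALSE]
    matrix(dP, (H / 2) * (W / 2), C)
}

.initKern <- function(cin, cout) {
    lapply(seq_len(9L), function(k)
        matrix(stats::rnorm(cin * cout, sd = sqrt(2 / (9 * cin))), cin, cout))
}

#' Initialise a UNetSegmenter with random weights
#'
#' He-normal initialisation, deterministic given the seed.
#'
#' @param model a \linkS4class{UNetSegmenter} (channel count taken from it).
#' @param seed RNG seed.
#' @return the initialised model.
#' @export
initUNet <- function(model, seed = 1L) {
    stopifnot(is(model, "UNetSegmenter"))
    set.seed(seed)
    C <- model@channels
    model@params <- list(
        k1 = .initKern(1L, C),       b1 = numeric(C),
        k2 = .initKern(C, 2L * C),   b2 = numeric(2L * C),
        k3 = .initKern(3L * C, C),   b3 = numeric(C),
        w4 = matrix(stats::rnorm(C, sd = sqrt(2 / C)), C, 1L),
        b4 = 0
    )
    model
}

# full forward pass; keepCache=TRUE retains intermediates for backward
.unetForward <- function(params, x, H, W, keepCache = FALSE) {
    X <- matrix(as.numeric(x), H * W, 1L)
    z1 <- .conv3Forward(X, H, W, params$k1, params$b1)
    h1 <- pmax(z1, 0)
    pl <- .pool2Forward(h1, H, W)
    h2c <- .conv3Forward(pl$P, H / 2, W / 2, params$k2, params$b2)
    h2 <- pmax(h2c, 0)
    u <- .upsample2(h2, H, W)
    cat3 <- cbind(h1, u)
    z3 <- .conv3Forward(cat3, H, W, params$k3, params$b3)
    h3 <- pmax(z3, 0)
    logits <- h3 %*% params$w4 + params$b4
    probs <- 1 / (1 + exp(-logits))
    if (!keepCache) return(probs)
    list(probs = probs, X = X, z1 = z1, h1 = h1, pool = pl, h2c = h2c,
         h2 = h2, cat3 = cat3, z3 = z3, h3 = h3)
}

# gradient of focal Tversky loss w.r.t. probabilities
.ftlGradProbs <- function(p, g, params, smooth = 1e-7) {
    tp <- sum(p * g)
    fn <- sum((1 - p) * g)
    fp <- sum(p * (1 - g))
    num <- tp + smooth
    den <- tp + params$alpha * fn + params$beta * fp + smooth
    ti <- num / den
    # d num / d p_i = g_i ; d den / d p_i = g_i - alpha*g_i + beta*(1-g_i)
    dden <- g * (1 - params$alpha) + params$beta * (1 - g)
    dti <- (g * den - num * dden) / den^2
    loss <- (1 - ti)^(1 / params$gamma)
    dloss <- -(1 / params$gamma) * (1 - ti)^(1 / params$gamma - 1)
    list(loss = loss, grad = dloss * dti)
}

# backward pass: returns gradient list matching params layout
.unetBackward <- function(params, cache, dProbs, H, W) {
    p <- cache$probs
    dLogits <- dProbs * p * (1 - p)
    dW4 <- crossprod(cache$h3, dLogits)
    dB4 <- sum(dLogits)
    dH3 <- dLogits %*% t(params$w4)
    dZ3 <- dH3 * (cache$z3 > 0)
    bw3 <- .conv3Backward(cache$cat3, H, W, params$k3, dZ3)
    C <- length(params$b1)
    dH1a <- bw3$dX[, seq_len(C), drop = FALSE]
    dU <- bw3$dX[, C + seq_len(2L * C), drop = FALSE]
    dH2 <- .upsample2Backward(dU, H, W)
    dZ2 <- dH2 * (cache$h2c > 0)
    bw2 <- .conv3Backward(cache$pool$P, H / 2, W / 2, params$k2, dZ2)
    dH1 <- dH1a + .pool2Backward(bw2$dX, cache$pool$which, H, W)
    dZ1 <- dH1 * (cache$z1 > 0)
    bw1 <- .conv3Backward(cache$X, H, W, params$k1, dZ1)
    list(k1 = bw1$dKern, b1 = bw1$dBias,
         k2 = bw2$dKern, b2 = bw2$dBias,
         k3 = bw3$dKern, b3 = bw3$dBias,
         w4 = dW4, b4 = dB4)
}

#' @describeIn predictProbs reference U-Net; tile sides must be even.
#' @export
setMethod("predictProbs", "UNetSegmenter", function(model, tile) {
    if (length(model@params) == 0L)
        stop("segmenter is not initialised; call initUNet() or fitToySegmenter()",
             call. = FALSE)
    H <- nrow(tile); W <- ncol(tile)
    if (H %% 2L || W %% 2L)
        stop("tile sides must be even for the two-level U-Net", call. = FALSE)
    matrix(.unetForward(model@params, tile, H, W), H, W)
})

# flatten/unflatten param list for the Adam update
.paramVec <- function(p) {
    unlist(list(unlist(p$k1), p$b1, unlist(p$k2), p$b2, unlist(p$k3), p$b3,
                as.numeric(p$w4), p$b4), use.names = FALSE)
}

.paramUnvec <- function(v, template) {
    out <- template
    pos <- 0L
    take <- function(n) {
        val <- v[pos + seq_len(n)]
        pos <<- pos + n
        val
    }
    for (nm in c("k1", "k2", "k3")) {
        kern <- template[[nm]]
        for (k in seq_along(kern)) {
            n <- length(kern[[k]])
            out[[nm]][[k]] <- matrix(take(n), nrow(kern[[k]]), ncol(kern[[k]]))
        }
        bn <- sub("k", "b", nm)
        out[[bn]] <- take(length(template[[bn]]))
    }
    out$w4 <- matrix(take(length(template$w4)), nrow(template$w4), 1L)
    out$b4 <- take(1L)
    out
}

#' Train the reference U-Net segmenter on phantom slices
#'
#' Adam on the focal Tversky loss over mini-batches; optional horizontal
#' flip augmentation. With zero epochs the model state is returned
#' unchanged (after deterministic initialisation if it was empty). A
#' non-finite loss aborts with an error.
#'
#' @param model a \linkS4class{UNetSegmenter}.
#' @param slices list of 2D numeric matrices (training images).
#' @param masks list of 0/1 matrices (matching truth).
#' @param config list: \code{epochs} (30), \code{batch_size} (4),
#'   \code{lr} (5e-3), \code{seed} (1), \code{flip} (TRUE), and the
#'   Tversky \code{alpha}/\code{beta}/\code{gamma}.
#' @return the trained model; per-step losses in \code{@lossTrace}.
#' @export
fitToySegmenter <- function(model, slices, masks, config = list()) {
    stopifnot(is(model, "UNetSegmenter"), length(slices) == length(masks))
    if (length(slices) < 8L && !identical(config$epochs, 0L))
        stop("need >= 8 training pairs", call. = FALSE)
    cfg <- utils::modifyList(
        list(epochs = 30L, batch_size = 4L, lr = 5e-3, seed = 1L,
             flip = TRUE, alpha = 0.7, beta = 0.3, gamma = 4 / 3), config)
    if (length(model@params) == 0L) model <- initUNet(model, cfg$seed)
    if (cfg$epochs == 0L) return(model)
    set.seed(cfg$seed)
    if (isTRUE(cfg$flip)) {
        nx <- length(slices)
        for (i in seq_len(nx)) {
            slices[[nx + i]] <- slices[[i]][rev(seq_len(nrow(slices[[i]]))), ]
            masks[[nx + i]] <- masks[[i]][rev(seq_len(nrow(masks[[i]]))), ]
        }
    }
    tpar <- list(alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma)
    params <- model@params
    v0 <- .paramVec(params)
    mAd <- numeric(length(v0)); vAd <- numeric(length(v0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    n <- length(slices)
    losses <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = cfg$batch_size)) {
            idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
            gAcc <- NULL
            lossB <- 0
            for (i in idx) {
                x <- slices[[i]]; g <- masks[[i]]
                H <- nrow(x); W <- ncol(x)
                cache <- .unetForward(params, x, H, W, keepCache = TRUE)
                fg <- .ftlGradProbs(cache$probs, as.numeric(g), tpar)
                lossB <- lossB + fg$loss
                gr <- .unetBackward(params, cache, matrix(fg$grad), H, W)
                gv <- .paramVec(gr)
                gAcc <- if (is.null(gAcc)) gv else gAcc + gv
            }
            lossB <- lossB / length(idx)
            if (!is.finite(lossB))
                stop("U-Net training diverged (non-finite loss)", call. = FALSE)
            losses <- c(losses, lossB)
            gAcc <- gAcc / length(idx)
            t <- t + 1L
            mAd <- b1 * mAd + (1 - b1) * gAcc
            vAd <- b2 * vAd + (1 - b2) * gAcc^2
            v0 <- v0 - cfg$lr * (mAd / (1 - b1^t)) / (sqrt(vAd / (1 - b2^t)) + eps)
            params <- .paramUnvec(v0, params)
        }
    }
    model@params <- params
    model@lossTrace <- losses
    model
}
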