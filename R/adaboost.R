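# Discrete AdaBoost (AdaBoost.M1) for binary voxel classification.
#
# The default base learner is an exhaustively optimised decision stump
# (depth 1), fitted on presorted feature columns so each boosting round costs
# O(features x voxels); depth > 1 delegates the base learner to rpart with
# case weights. Training is fully deterministic (ties broken toward the
# lowest feature index, then the lowest threshold).

# Best weighted stump for labels y in {-1,+1} and weights w (sum 1), given
# presorted column orders. Returns list(feature, threshold, polarity, err).
bestStump <- function(x, y, w, ord) {
    n <- nrow(x)
    best <- list(err = Inf)
    for (j in seq_len(ncol(x))) {
        o <- ord[, j]
        xs <- x[o, j]
        wy <- (w * y)[o]
        S <- cumsum(wy)
        tot <- S[n]
        # stump "+1 if x <= cut, -1 otherwise" at cut after position i has
        # weighted margin M_i = 2 S_i - tot; i = 0 gives the constant -1 rule
        M <- c(-tot, 2 * S - tot)
        valid <- c(TRUE, xs[-n] < xs[-1], TRUE)  # cuts between distinct values
        M[!valid] <- 0
        i <- which.max(abs(M)) # first maximum: lowest threshold wins ties
        m <- M[i]
        err <- (1 - abs(m)) / 2
        if (err < best$err - 1e-15) {
            thr <- if (i == 1L) -Inf
                   else if (i == n + 1L) Inf
                   else (xs[i - 1L] + xs[i]) / 2
            best <- list(feature = j, threshold = thr,
                         polarity = if (m >= 0) 1 else -1, err = err)
        }
    }
    best
}

stumpPredict <- function(stump, x) {
    stump$polarity * ifelse(x[, stump$feature] <= stump$threshold, 1, -1)
}

adaboostFit <- function(x, y01, rounds = 100L, learningRate = 1, depth = 1L) {
    y <- ifelse(y01 == 1L, 1, -1)
    n <- length(y)
    w <- rep(1 / n, n)
    learners <- vector("list", rounds)
    alphas <- numeric(rounds)
    ord <- if (depth == 1L) apply(x, 2, order) else NULL
    used <- 0L
    for (m in seq_len(rounds)) {
        if (depth == 1L) {
            st <- bestStump(x, y, w, ord)
            h <- stumpPredict(st, x)
        } else {
            df <- data.frame(y = factor(y, levels = c(-1, 1)), x)
            st <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                control = rpart::rpart.control(maxdepth = depth, cp = 0,
                    minsplit = 2, xval = 0, maxsurrogate = 0, maxcompete = 0))
            h <- as.numeric(as.character(predict(st, df, type = "class")))
        }
        err <- sum(w[h != y])
        err <- min(max(err, 1e-10), 1 - 1e-10)
        alpha <- learningRate * 0.5 * log((1 - err) / err)
        used <- m
        learners[[m]] <- st
        alphas[m] <- alpha
        if (err >= 0.5 - 1e-12) break      # no better than chance: stop
        w <- w * exp(-alpha * y * h)
        w <- w / sum(w)
        if (err <= 1e-9) break             # perfect base learner
    }
    structure(list(learners = learners[seq_len(used)],
                   alphas = alphas[seq_len(used)], depth = depth),
              class = "adaboostModel")
}

adaboostScore <- function(model, x) {
    s <- numeric(nrow(x))
    if (model$depth == 1L) {
        for (m in seq_along(model$learners))
            s <- s + model$alphas[m] * stumpPredict(model$learners[[m]], x)
    } else {
        df <- data.frame(x)
        for (m in seq_along(model$learners)) {
            h <- as.numeric(as.character(
                predict(model$learners[[m]], df, type = "class")))
            s <- s + model$alphas[m] * h
        }
    }
    s
}
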