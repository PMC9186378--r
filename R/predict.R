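.sigmoid <- function(x) stats::plogis(x)

#' Assemble the 7-feature table for ICB response prediction
#'
#' Four single-gene chemokine ssGSEA grades (CXCL9, CXCL10, CXCL11, CCL5)
#' plus three immune-cell fractions (M1 macrophages, CD8 T cells, activated
#' memory CD4 T cells), z-scored per feature; the response is coded 1 for
#' CR/PR, 0 for SD/PD.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param fractions a \linkS4class{CellFractions} over the same samples.
#' @param labels named 0/1 response vector.
#' @param chemokineGenes the four chemokine gene ids.
#' @param effectorTypes the three fraction columns to use.
#' @return A \code{FeatureTable} list: \code{features} (z-scored samples x 7
#'   matrix), \code{response}, \code{featureNames}, \code{center},
#'   \code{scale}.
#' @export
buildFeatures <- function(expr, fractions, labels,
                          chemokineGenes = c("CXCL9", "CXCL10", "CXCL11",
                                             "CCL5"),
                          effectorTypes = c("Macrophages.M1", "T.cells.CD8",
                              "T.cells.CD4.memory.activated")) {
    stopifnot(is(expr, "ExpressionMatrix"), is(fractions, "CellFractions"))
    samples <- sampleIds(expr)
    missF <- setdiff(samples, sampleIds(fractions))
    stopIf(length(missF) > 0, "samples missing from fractions: %s",
           paste(utils::head(missF, 5), collapse = ", "))
    missL <- setdiff(samples, names(labels))
    stopIf(length(missL) > 0, "samples missing from labels: %s",
           paste(utils::head(missL, 5), collapse = ", "))
    F <- fractionValues(fractions)
    missT <- setdiff(effectorTypes, colnames(F))
    stopIf(length(missT) > 0, "missing cell-type column(s): %s",
           paste(missT, collapse = ", "))
    sets <- stats::setNames(as.list(chemokineGenes), chemokineGenes)
    grades <- ssgsea(expr, sets, normalize = FALSE)
    feat <- cbind(grades[samples, , drop = FALSE],
                  F[samples, effectorTypes, drop = FALSE])
    ctr <- colMeans(feat)
    scl <- apply(feat, 2, stats::sd)
    const <- names(scl)[scl == 0]
    stopIf(length(const) > 0,
           "constant feature(s): %s; drop them or add variation before z-scoring",
           paste(const, collapse = ", "))
    z <- scale(feat, center = ctr, scale = scl)
    structure(list(features = z[, , drop = FALSE],
                   response = labels[samples],
                   featureNames = colnames(feat), center = ctr, scale = scl),
              class = "FeatureTable")
}

# forward pass; returns activations per layer (list) given input matrix
# X: n x p (samples x features). Weights are out x in.
.mlpForward <- function(weights, biases, X, masks = NULL) {
    a <- t(X)
    acts <- list(a)
    L <- length(weights)
    for (l in seq_len(L)) {
        a <- .sigmoid(weights[[l]] %*% a + biases[[l]])
        if (!is.null(masks) && l < L) a <- a * masks[[l]]
        acts[[l + 1]] <- a
    }
    acts
}

#' Mean binary cross-entropy loss and its analytic gradients
#'
#' Forward/backward pass of the sigmoid MLP with dropout disabled (or with
#' given inverted-dropout masks), returning the loss and the gradients with
#' respect to every weight matrix and bias. Used by training and by the
#' finite-difference gradient check.
#'
#' @param weights,biases lists of layer weight matrices (out x in) and bias
#'   vectors.
#' @param X samples x features matrix.
#' @param y 0/1 response vector.
#' @param masks optional list of inverted-dropout masks for the hidden
#'   layers.
#' @return List with \code{loss}, \code{gradWeights}, \code{gradBiases},
#'   \code{prob}.
#' @export
mlpLossGrad <- function(weights, biases, X, y, masks = NULL) {
    n <- nrow(X)
    acts <- .mlpForward(weights, biases, X, masks)
    L <- length(weights)
    p <- as.vector(acts[[L + 1]])
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    gW <- vector("list", L); gB <- vector("list", L)
    # output layer: d(loss)/d(z_L) = (p - y)/n for sigmoid + BCE
    delta <- matrix((p - y) / n, nrow = 1)
    for (l in seq(L, 1)) {
        gW[[l]] <- delta %*% t(acts[[l]])
        gB[[l]] <- rowSums(delta)
        if (l > 1) {
            a <- acts[[l]]
            back <- t(weights[[l]]) %*% delta
            if (!is.null(masks)) back <- back * masks[[l - 1]]
            delta <- back * a * (1 - a)
        }
    }
    list(loss = loss, gradWeights = gW, gradBiases = gB, prob = p)
}

#' Train the ICB-response MLP
#'
#' A 7-20-5-1 feed-forward network with logistic sigmoid at every layer,
#' trained by full-batch gradient descent on mean binary cross-entropy, with
#' inverted dropout on the hidden activations during training only. Weights
#' are initialized uniform(-0.5, 0.5) under the seed; training is
#' deterministic for a fixed seed.
#'
#' @param ft a \code{FeatureTable} from \code{\link{buildFeatures}} (>= 20
#'   samples, both classes present).
#' @param lr learning rate (default 0.01).
#' @param epochs full-batch epochs (default 2000).
#' @param dropoutRate hidden-layer dropout rate (default 0.2; 0 disables).
#' @param hidden hidden-layer sizes (default c(20, 5)).
#' @param seed integer seed.
#' @return An \linkS4class{MlpModel}; the training loss trace is in
#'   \code{@training$lossTrace}.
#' @export
trainMlp <- function(ft, lr = 0.01, epochs = 2000, dropoutRate = 0.2,
                     hidden = c(20, 5), seed = 1L) {
    stopifnot(inherits(ft, "FeatureTable"))
    X <- ft$features
    y <- as.numeric(ft$response)
    stopIf(length(unique(y)) < 2, "both response classes must be present")
    stopIf(nrow(X) < 20, "need >= 20 samples, got %d", nrow(X))
    sizes <- as.integer(c(ncol(X), hidden, 1))
    L <- length(sizes) - 1
    withSeed(seed, {
        weights <- lapply(seq_len(L), function(l)
            matrix(stats::runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                   sizes[l + 1], sizes[l]))
        biases <- lapply(seq_len(L), function(l)
            stats::runif(sizes[l + 1], -0.5, 0.5))
        trace <- numeric(epochs)
        for (e in seq_len(epochs)) {
            masks <- NULL
            if (dropoutRate > 0)
                masks <- lapply(seq_len(L - 1), function(l)
                    matrix(stats::rbinom(sizes[l + 1] * nrow(X), 1,
                                         1 - dropoutRate) / (1 - dropoutRate),
                           sizes[l + 1], nrow(X)))
            g <- mlpLossGrad(weights, biases, X, y, masks)
            stopIf(!is.finite(g$loss),
                   "non-finite loss at epoch %d (lr = %g); lower the learning rate",
                   e, lr)
            trace[e] <- g$loss
            for (l in seq_len(L)) {
                weights[[l]] <- weights[[l]] - lr * g$gradWeights[[l]]
                biases[[l]] <- biases[[l]] - lr * g$gradBiases[[l]]
            }
        }
        new("MlpModel", layerSizes = sizes,
            weights = lapply(weights, unname),
            biases = lapply(biases, unname), dropoutRate = dropoutRate,
            featureNames = ft$featureNames,
            featureCenter = as.numeric(ft$center),
            featureScale = as.numeric(ft$scale),
            training = list(lr = lr, epochs = epochs, seed = seed,
                            lossTrace = trace))
    })
}

#' Predict response probabilities
#'
#' Forward pass with dropout disabled. Accepts a \code{FeatureTable} (whose
#' schema must match the training schema) or a raw samples x features matrix
#' on the original scale, to which the model's stored z-scoring is applied.
#'
#' @param model an \linkS4class{MlpModel}.
#' @param newdata a \code{FeatureTable} or numeric matrix.
#' @return Named per-sample probabilities in (0, 1).
#' @export
predictMlp <- function(model, newdata) {
    if (inherits(newdata, "FeatureTable")) {
        stopIf(!identical(newdata$featureNames, model@featureNames),
               "feature schema mismatch: model has [%s], data has [%s]",
               paste(model@featureNames, collapse = ", "),
               paste(newdata$featureNames, collapse = ", "))
        X <- newdata$features
    } else {
        stopIf(!all(model@featureNames %in% colnames(newdata)),
               "feature schema mismatch: missing [%s]",
               paste(setdiff(model@featureNames, colnames(newdata)),
                     collapse = ", "))
        X <- scale(newdata[, model@featureNames, drop = FALSE],
                   center = model@featureCenter, scale = model@featureScale)
    }
    acts <- .mlpForward(model@weights, model@biases, X)
    stats::setNames(as.vector(acts[[length(acts)]]), rownames(X))
}

#' @describeIn predictMlp S4 predict method.
#' @param object an \linkS4class{MlpModel}.
#' @export
setMethod("predict", "MlpModel", function(object, newdata)
    predictMlp(object, newdata))

#' ROC curve, AUC and confusion matrix
#'
#' ROC over the sorted unique probability thresholds; AUC by the trapezoid
#' rule (equal to the tie-corrected Mann-Whitney statistic); confusion
#' matrix at the 0.5 threshold (probability > 0.5 predicts a responder).
#'
#' @param probabilities named numeric predictions in [0, 1].
#' @param labels 0/1 truth (both classes present).
#' @return List with \code{thresholds}, \code{tpr}, \code{fpr}, \code{auc},
#'   \code{confusion} (2 x 2 table, truth x prediction).
#' @export
evaluateRoc <- function(probabilities, labels) {
    y <- as.numeric(labels)
    stopIf(length(unique(y)) < 2, "both classes must be present")
    p <- as.numeric(probabilities)
    th <- c(Inf, sort(unique(p), decreasing = TRUE))
    nPos <- sum(y == 1); nNeg <- sum(y == 0)
    tpr <- vapply(th, function(t) sum(p >= t & y == 1) / nPos, numeric(1))
    fpr <- vapply(th, function(t) sum(p >= t & y == 0) / nNeg, numeric(1))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    pred <- factor(as.integer(p > 0.5), levels = c(0, 1))
    confusion <- table(truth = factor(y, levels = c(0, 1)),
                       prediction = pred)
    list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
         confusion = confusion)
}

#' Save / load an MlpModel as JSON
#'
#' Architecture, weights, dropout and normalization constants are written at
#' full double precision so that a reloaded model reproduces predictions
#' bit-exactly.
#'
#' @param model an \linkS4class{MlpModel}.
#' @param path JSON file path.
#' @return \code{saveMlpModel}: the path, invisibly. \code{loadMlpModel}:
#'   the restored \linkS4class{MlpModel}.
#' @export
saveMlpModel <- function(model, path) {
    obj <- list(layerSizes = model@layerSizes,
                weights = lapply(model@weights, function(w)
                    list(dim = dim(w), data = as.vector(w))),
                biases = model@biases,
                dropoutRate = model@dropoutRate,
                featureNames = model@featureNames,
                featureCenter = model@featureCenter,
                featureScale = model@featureScale,
                training = model@training[c("lr", "epochs", "seed")])
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname saveMlpModel
#' @export
loadMlpModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    num <- function(x) vapply(x, function(v) as.numeric(v), numeric(1))
    chr <- function(x) vapply(x, as.character, character(1))
    ws <- lapply(obj$weights, function(w) {
        d <- num(w$dim)
        matrix(num(w$data), d[1], d[2])
    })
    new("MlpModel", layerSizes = as.integer(num(obj$layerSizes)),
        weights = ws, biases = lapply(obj$biases, num),
        dropoutRate = as.numeric(obj$dropoutRate),
        featureNames = chr(obj$featureNames),
        featureCenter = num(obj$featureCenter),
        featureScale = num(obj$featureScale),
        training = list(lr = as.numeric(obj$training$lr),
                        epochs = as.numeric(obj$training$epochs),
                        seed = as.numeric(obj$training$seed)))
}
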