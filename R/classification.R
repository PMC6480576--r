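#' Predictor variable groups for stage classification
#'
#' The five modelled predictor sets built from the key features: the single
#' features SK and KUR, FAV (the activity-volume feature DTAV), FAD (the two
#' activity-distribution features SK and KUR) and FADV (all three).
#'
#' @param name one of "SK", "KUR", "FAV", "FAD", "FADV".
#' @return Character vector of feature names.
#' @export
variableGroup <- function(name = c("SK", "KUR", "FAV", "FAD", "FADV")) {
    name <- match.arg(name)
    switch(name,
           SK = "SK", KUR = "KUR", FAV = "DTAV",
           FAD = c("SK", "KUR"), FADV = c("SK", "KUR", "DTAV"))
}

#' 50/50 percentage split
#'
#' Randomly allocates the subjects into a training half (ceiling(n/2)) and a
#' test half (floor(n/2)). With `stratified = TRUE` (default) per-stage
#' proportions are preserved up to rounding; classes with fewer than 2
#' members trigger a warning because they may be absent from one side.
#' Deterministic for a fixed seed.
#'
#' @param features feature data.frame with a `stage` column.
#' @param seed integer seed.
#' @param stratified preserve class proportions (default TRUE).
#' @return list(train, test) of data.frames; the chosen training row
#'   indices are attached as `attr(, "trainIndex")`.
#' @export
splitHalf <- function(features, seed = 1L, stratified = TRUE) {
    n <- nrow(features)
    if (n < 2L) stop("need at least 2 subjects to split", call. = FALSE)
    nTrain <- as.integer(ceiling(n / 2))
    trainIdx <- withSeed(seed, {
        if (!stratified) {
            sample.int(n)[seq_len(nTrain)]
        } else {
            cls <- split(seq_len(n), factor(features$stage), drop = TRUE)
            small <- names(cls)[vapply(cls, length, 0L) < 2L]
            if (length(small))
                warning("class(es) with < 2 members may be absent from one side of the split: ",
                        paste(small, collapse = ", "))
            shuffled <- lapply(cls, function(ix) ix[sample.int(length(ix))])
            take <- vapply(shuffled, function(ix) length(ix) %/% 2L, 0L)
            extra <- nTrain - sum(take)
            odd <- names(shuffled)[vapply(shuffled, length, 0L) %% 2L == 1L]
            if (extra > 0L) {
                pick <- if (length(odd) > 1L) sample(odd, extra) else odd
                take[pick] <- take[pick] + 1L
            }
            sort(unlist(mapply(function(ix, k) ix[seq_len(k)], shuffled,
                               take, SIMPLIFY = FALSE), use.names = FALSE))
        }
    })
    out <- list(train = features[trainIdx, , drop = FALSE],
                test = features[setdiff(seq_len(n), trainIdx), , drop = FALSE])
    attr(out, "trainIndex") <- trainIdx
    out
}

#' Fit a multinomial logistic stage classifier
#'
#' Multinomial logistic regression (the softmax generalization of the
#' two-class model P(X) = exp(f(x)) / (1 + exp(f(x))) with linear predictor
#' f(x) = b0 + b1 x1 + ... + bk xk), fitted on the unstandardized features
#' with an intercept. When the fit shows signs of complete separation
#' (unbounded coefficients), it is refitted with a small ridge penalty and a
#' note is logged.
#'
#' @param train training feature data.frame (needs `stage` plus the
#'   predictor columns).
#' @param vars predictor names or a [variableGroup()] name.
#' @return A fitted model object of class `stageLR`.
#' @export
fitLogistic <- function(train, vars = "FADV") {
    if (length(vars) == 1L && vars %in% c("SK", "KUR", "FAV", "FAD", "FADV"))
        vars <- variableGroup(vars)
    stopifnot(all(vars %in% names(train)))
    stage <- factor(train$stage)
    if (nlevels(droplevels(stage)) < 2L)
        stop("training set must contain at least two classes", call. = FALSE)
    sds <- vapply(train[vars], sd, 0)
    if (any(is.na(sds) | sds == 0))
        stop("degenerate constant feature(s): ",
             paste(vars[is.na(sds) | sds == 0], collapse = ", "),
             call. = FALSE)
    dat <- data.frame(stage = droplevels(stage), train[vars])
    f <- stats::as.formula(paste("stage ~", paste(vars, collapse = " + ")))
    fit <- nnet::multinom(f, data = dat, trace = FALSE, maxit = 500)
    scaledCoef <- coef(fit)
    if (max(abs(scaledCoef)) > 1e3) {
        message("near-complete separation detected; refitting with a ridge penalty")
        fit <- nnet::multinom(f, data = dat, trace = FALSE, maxit = 500,
                              decay = 1e-2)
    }
    structure(list(fit = fit, vars = vars,
                   levels = levels(dat$stage), method = "LR"),
              class = "stageLR")
}

#' Fit an RBF-kernel SVM stage classifier
#'
#' One-vs-one multiclass support vector machine with a radial basis
#' function kernel. Features are standardized with the training mean and SD;
#' on that scale the default kernel width is gamma = 1/d (equivalently
#' 1/(d * feature variance)). Class scores for AUC are aggregated pairwise
#' decision values, which keeps prediction fully deterministic.
#'
#' @param train training feature data.frame.
#' @param vars predictor names or a [variableGroup()] name.
#' @param C soft-margin cost (default 1).
#' @param gamma RBF width; `NULL` (default) uses 1/d on standardized
#'   features.
#' @return A fitted model object of class `stageSVM`.
#' @export
fitSvmRbf <- function(train, vars = "FADV", C = 1, gamma = NULL) {
    if (length(vars) == 1L && vars %in% c("SK", "KUR", "FAV", "FAD", "FADV"))
        vars <- variableGroup(vars)
    stopifnot(all(vars %in% names(train)))
    stage <- droplevels(factor(train$stage))
    if (nlevels(stage) < 2L)
        stop("training set must contain at least two classes", call. = FALSE)
    x <- as.matrix(train[vars])
    mu <- colMeans(x)
    sds <- apply(x, 2, sd)
    if (any(is.na(sds) | sds == 0))
        stop("degenerate constant feature(s): ",
             paste(vars[is.na(sds) | sds == 0], collapse = ", "),
             call. = FALSE)
    xs <- scale(x, center = mu, scale = sds)
    if (is.null(gamma)) gamma <- 1 / length(vars)
    fit <- e1071::svm(xs, stage, kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    structure(list(fit = fit, vars = vars, mu = mu, sds = sds,
                   levels = levels(stage), method = "SVM"),
              class = "stageSVM")
}

#' Predict stage labels and per-class scores
#'
#' `predictClass` returns the predicted stage factor; `predictScores`
#' returns an n x k matrix of per-class scores (class probabilities for the
#' logistic model, aggregated pairwise decision values for the SVM) used for
#' one-vs-rest AUC.
#'
#' @param model a fitted `stageLR` or `stageSVM`.
#' @param newdata feature data.frame.
#' @return A factor, or a numeric matrix with one column per class.
#' @name stagePredict
NULL

#' @rdname stagePredict
#' @export
predictClass <- function(model, newdata) UseMethod("predictClass")

#' @rdname stagePredict
#' @export
predictScores <- function(model, newdata) UseMethod("predictScores")

#' @export
predictClass.stageLR <- function(model, newdata) {
    factor(as.character(predict(model$fit, newdata = newdata[model$vars])),
           levels = .STAGES)
}

#' @export
predictScores.stageLR <- function(model, newdata) {
    p <- predict(model$fit, newdata = newdata[model$vars], type = "probs")
    if (is.null(dim(p))) {  # two-class fit returns P(second level)
        p <- cbind(1 - p, p)
        colnames(p) <- model$levels
    }
    as.matrix(p)
}

.svmScale <- function(model, newdata) {
    scale(as.matrix(newdata[model$vars]), center = model$mu,
          scale = model$sds)
}

#' @export
predictClass.stageSVM <- function(model, newdata) {
    factor(as.character(predict(model$fit, .svmScale(model, newdata))),
           levels = .STAGES)
}

#' @export
predictScores.stageSVM <- function(model, newdata) {
    pr <- predict(model$fit, .svmScale(model, newdata),
                  decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    lev <- model$levels
    scores <- matrix(0, nrow(dv), length(lev), dimnames = list(NULL, lev))
    for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
        scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
    }
    scores
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e), with the expected
#' agreement p_e computed from the row and column marginals. A degenerate
#' table concentrated in a single cell (p_e = 1) returns 0 with a warning.
#'
#' @param cm square numeric matrix, rows = truth, columns = prediction.
#' @return Kappa in [-1, 1].
#' @examples
#' cohenKappa(matrix(c(40, 20, 10, 30), 2))
#' @export
cohenKappa <- function(cm) {
    cm <- as.matrix(cm)
    if (nrow(cm) != ncol(cm) || any(cm < 0))
        stop("confusion matrix must be square and non-negative",
             call. = FALSE)
    n <- sum(cm)
    if (n <= 0) stop("confusion matrix is empty", call. = FALSE)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    if (pe >= 1 - 1e-12) {
        warning("degenerate confusion matrix (expected agreement 1); kappa defined as 0")
        return(0)
    }
    (po - pe) / (1 - pe)
}

.rankAUC <- function(score, positive) {
    n1 <- sum(positive)
    n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L)
        stop("AUC needs at least one positive and one negative",
             call. = FALSE)
    r <- rank(score)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUC via the rank (Mann-Whitney) formulation
#'
#' For a score matrix (one column per class) the AUC of each class is
#' computed one-vs-rest from the ranks of its column, and the macro average
#' over classes is returned as the headline value with the per-class values
#' attached as an attribute. A plain numeric score vector is treated as a
#' binary problem with `labels` coercible to logical (TRUE/1 = positive).
#'
#' @param scores numeric matrix (n x k, named columns) or vector.
#' @param labels true labels: a factor matching the column names, or a
#'   logical/0-1 vector in the binary case.
#' @return Macro-averaged AUC with attribute `perClass`.
#' @examples
#' aucScore(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
aucScore <- function(scores, labels) {
    if (is.matrix(scores)) {
        labels <- factor(labels, levels = colnames(scores))
        if (nlevels(droplevels(labels)) < 2L)
            stop("labels contain a single class", call. = FALSE)
        present <- levels(droplevels(labels))
        per <- vapply(present, function(cl)
            .rankAUC(scores[, cl], labels == cl), 0)
        structure(mean(per), perClass = per)
    } else {
        pos <- as.logical(labels)
        if (all(pos) || !any(pos))
            stop("labels contain a single class", call. = FALSE)
        structure(.rankAUC(as.numeric(scores), pos),
                  perClass = c(positive = .rankAUC(as.numeric(scores), pos)))
    }
}

#' Evaluate a fitted stage classifier on a test set
#'
#' Builds the truth-by-prediction confusion matrix and the full validity
#' panel: per-class one-vs-rest sensitivity, specificity, PPV and NPV with
#' their prevalence-weighted averages, overall accuracy, macro one-vs-rest
#' AUC, and Cohen's kappa. Classes absent from the test set get NA one-vs-
#' rest metrics and are excluded from the averages.
#'
#' @param model a fitted `stageLR` or `stageSVM`.
#' @param test test feature data.frame.
#' @param varGroup optional predictor-set name recorded in the report.
#' @return A \linkS4class{ValidityReport}.
#' @export
evaluateModel <- function(model, test, varGroup = NA_character_) {
    if (!nrow(test)) stop("test set is empty", call. = FALSE)
    truth <- factor(test$stage, levels = .STAGES)
    pred <- predictClass(model, test)
    cm <- table(truth = truth, prediction = pred)
    per <- do.call(rbind, lapply(.STAGES, function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        fp <- sum(truth != cl & pred == cl)
        tn <- sum(truth != cl & pred != cl)
        if (tp + fn == 0L)
            return(data.frame(class = cl, n = 0L, sensitivity = NA_real_,
                              specificity = NA_real_, ppv = NA_real_,
                              npv = NA_real_))
        data.frame(class = cl, n = tp + fn,
                   sensitivity = tp / (tp + fn),
                   specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
    }))
    absent <- per$class[per$n == 0L]
    if (length(absent))
        warning("class(es) absent from the test set, excluded from averages: ",
                paste(absent, collapse = ", "))
    w <- per$n / sum(per$n)
    wmean <- function(v) {
        ok <- !is.na(v) & per$n > 0L
        sum(v[ok] * w[ok]) / sum(w[ok])
    }
    scores <- predictScores(model, test)
    cols <- intersect(.STAGES, colnames(scores))
    keep <- truth %in% cols
    auc <- aucScore(scores[keep, cols, drop = FALSE],
                    factor(truth[keep], levels = cols))
    new("ValidityReport",
        method = model$method,
        varGroup = as.character(varGroup),
        confusion = unclass(cm),
        perClass = per,
        sensitivity = wmean(per$sensitivity),
        specificity = wmean(per$specificity),
        ppv = wmean(per$ppv),
        npv = wmean(per$npv),
        accuracy = sum(diag(cm)) / sum(cm),
        auc = as.numeric(auc),
        kappa = cohenKappa(cm))
}

#' Run the full model grid
#'
#' Fits both classification methods (LR and SVM) on each of the five
#' predictor groups (SK, KUR, FAV, FAD, FADV) over one shared stratified
#' 50/50 split, and evaluates each of the ten fits on the common test half.
#'
#' @param features feature data.frame from [featureFrame()].
#' @param seed split seed.
#' @param C,gamma SVM hyperparameters, see [fitSvmRbf()].
#' @param stratified stratify the split (default TRUE).
#' @return Named list of ten \linkS4class{ValidityReport}s ("LR.SK", ...,
#'   "SVM.FADV"); see [validitySummary()] for a flat table.
#' @export
runModelGrid <- function(features, seed = 1L, C = 1, gamma = NULL,
                         stratified = TRUE) {
    need <- unique(unlist(lapply(c("SK", "KUR", "FAV", "FAD", "FADV"),
                                 variableGroup)))
    stopifnot(all(need %in% names(features)))
    halves <- splitHalf(features, seed = seed, stratified = stratified)
    groups <- c("SK", "KUR", "FAV", "FAD", "FADV")
    out <- list()
    for (method in c("LR", "SVM")) {
        for (g in groups) {
            model <- if (method == "LR")
                fitLogistic(halves$train, g)
            else fitSvmRbf(halves$train, g, C = C, gamma = gamma)
            out[[paste(method, g, sep = ".")]] <-
                evaluateModel(model, halves$test, varGroup = g)
        }
    }
    out
}

#' Flatten a list of validity reports into a table
#'
#' @param reports list of \linkS4class{ValidityReport}s, e.g. from
#'   [runModelGrid()].
#' @return data.frame with one row per report.
#' @export
validitySummary <- function(reports) {
    do.call(rbind, lapply(reports, function(r)
        data.frame(method = r@method, varGroup = r@varGroup,
                   sensitivity = r@sensitivity, specificity = r@specificity,
                   ppv = r@ppv, npv = r@npv, accuracy = r@accuracy,
                   auc = r@auc, kappa = r@kappa, row.names = NULL)))
}
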