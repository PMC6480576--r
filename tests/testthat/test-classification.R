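fakeTable <- function(n = c(6, 102, 94), seed = 1) {
    withr::with_seed(seed, {
        stage <- rep(c("healthy", "mild", "severe"), times = n)
        mu <- rep(c(3, 0, -3), times = n)
        data.frame(subject_id = sprintf("s%03d", seq_len(sum(n))),
                   stage = factor(stage,
                                  levels = c("healthy", "mild", "severe")),
                   SK = mu + rnorm(sum(n)),
                   KUR = mu / 2 + rnorm(sum(n)),
                   DTAV = 15 + 4 * mu + rnorm(sum(n)))
    })
}

test_that("the percentage split halves the cohort deterministically", {
    ft <- fakeTable()           # 202 subjects as in a full staging cohort
    sp <- suppressWarnings(splitHalf(ft, seed = 3))
    expect_equal(nrow(sp$train), 101L)
    expect_equal(nrow(sp$test), 101L)
    again <- suppressWarnings(splitHalf(ft, seed = 3))
    expect_identical(attr(sp, "trainIndex"), attr(again, "trainIndex"))
    other <- suppressWarnings(splitHalf(ft, seed = 4))
    expect_false(identical(attr(sp, "trainIndex"), attr(other, "trainIndex")))

    tiny <- fakeTable(c(2, 2, 1))
    expect_warning(splitHalf(tiny, seed = 1), "< 2 members")
    sp5 <- suppressWarnings(splitHalf(tiny, seed = 1))
    expect_equal(nrow(sp5$train), 3L)
    expect_equal(nrow(sp5$test), 2L)

    # stratification keeps per-class proportions up to rounding
    strat <- suppressWarnings(splitHalf(ft, seed = 9))
    tr <- table(strat$train$stage)
    expect_true(all(abs(tr - c(3, 51, 47)) <= 1))
})

test_that("logistic fits recover the direction of separation and chance behaves like chance", {
    ft <- fakeTable(c(0, 60, 60), seed = 5)
    ft$stage <- droplevels(ft$stage)
    fit <- fitLogistic(ft, vars = "SK")
    # multinom parameterizes log odds of 'severe' vs 'mild'; SK is lower in
    # severe, so the slope must be negative
    expect_lt(coef(fit$fit)[["SK"]], 0)
    acc <- mean(predictClass(fit, ft) == as.character(ft$stage))
    expect_gt(acc, 0.9)

    # labels independent of features: accuracy near the majority rate
    withr::with_seed(8, {
        null <- fakeTable(c(30, 30, 30))
        null$SK <- rnorm(90); null$KUR <- rnorm(90); null$DTAV <- rnorm(90)
    })
    nf <- fitLogistic(null, vars = "FADV")
    accNull <- mean(predictClass(nf, null) == as.character(null$stage))
    expect_lt(abs(accNull - 1 / 3), 0.2)
    probs <- predictScores(nf, null)
    expect_equal(rowSums(probs), rep(1, 90), tolerance = 1e-9,
                 ignore_attr = TRUE)

    const <- fakeTable(c(0, 30, 30))
    const$SK <- 1
    expect_error(fitLogistic(const, vars = "SK"), "constant")
})

test_that("the RBF SVM separates a separable toy exactly and deterministically", {
    ft <- fakeTable(seed = 2)
    m1 <- fitSvmRbf(ft, vars = "FADV")
    expect_equal(mean(predictClass(m1, ft) == as.character(ft$stage)), 1)
    m2 <- fitSvmRbf(ft, vars = "FADV")
    expect_identical(predictClass(m2, ft), predictClass(m1, ft))
    expect_identical(predictScores(m2, ft), predictScores(m1, ft))
    one <- fakeTable(c(0, 40, 0))
    one$stage <- droplevels(one$stage)
    expect_error(fitSvmRbf(one, vars = "FADV"), "two classes")
})

test_that("Cohen's kappa matches its closed forms", {
    expect_equal(cohenKappa(diag(c(10, 20, 30))), 1)
    expect_equal(cohenKappa(matrix(25, 2, 2)), 0)
    expect_equal(cohenKappa(matrix(c(40, 20, 10, 30), 2)), 0.4,
                 tolerance = 1e-12)
    expect_warning(k <- cohenKappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
    expect_equal(k, 0)
    expect_error(cohenKappa(matrix(1, 2, 3)), "square")
})

test_that("rank AUC equals the concordant-pair fraction", {
    expect_equal(as.numeric(aucScore(c(0.9, 0.4, 0.5, 0.1),
                                     c(TRUE, TRUE, FALSE, FALSE))), 0.75)
    expect_equal(as.numeric(aucScore(c(5, 4, 3, 2), c(1, 1, 0, 0))), 1)
    set.seed(91)
    for (i in 1:50) {
        n <- sample(4:20, 1)
        s <- round(runif(n), 1)          # ties on purpose
        lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (all(lab) || !any(lab)) next
        expect_equal(as.numeric(aucScore(s, lab)), bruteAUC(s, lab),
                     tolerance = 1e-12)
    }
    scores <- withr::with_seed(17, runif(2000))
    labs <- withr::with_seed(18, sample(c(TRUE, FALSE), 2000, TRUE))
    expect_lt(abs(as.numeric(aucScore(scores, labs)) - 0.5), 0.05)
    expect_error(aucScore(1:4, c(TRUE, TRUE, TRUE, TRUE)), "single class")
})

test_that("the validity panel matches hand computation on a fixed confusion matrix", {
    # truth: 3 healthy, 4 mild, 3 severe; fixed predictions giving
    # confusion rows (truth) [[2,1,0],[0,3,1],[1,0,2]]
    truth <- rep(c("healthy", "mild", "severe"), c(3, 4, 3))
    pred <- c("healthy", "healthy", "mild",
              "mild", "mild", "mild", "severe",
              "healthy", "severe", "severe")
    scores <- matrix(0, 10, 3,
                     dimnames = list(NULL, c("healthy", "mild", "severe")))
    scores[cbind(seq_len(10), match(pred, colnames(scores)))] <- 1
    mock <- structure(list(method = "LR"), class = "mockStage",
                      pred = pred, scores = scores)
    registerS3method("predictClass", "mockStage",
                     function(model, newdata)
                         factor(attr(model, "pred"),
                                levels = c("healthy", "mild", "severe")))
    registerS3method("predictScores", "mockStage",
                     function(model, newdata) attr(model, "scores"))
    rep <- evaluateModel(mock, data.frame(stage = truth))
    expect_equal(rep@accuracy, 0.7)
    # hand-evaluated one-vs-rest panels:
    # healthy: tp2 fn1 fp1 tn6; mild: tp3 fn1 fp1 tn5; severe: tp2 fn1 fp1 tn6
    expect_equal(rep@perClass$sensitivity, c(2 / 3, 3 / 4, 2 / 3),
                 tolerance = 1e-12)
    expect_equal(rep@perClass$specificity, c(6 / 7, 5 / 6, 6 / 7),
                 tolerance = 1e-12)
    expect_equal(rep@perClass$ppv, c(2 / 3, 3 / 4, 2 / 3), tolerance = 1e-12)
    expect_equal(rep@perClass$npv, c(6 / 7, 5 / 6, 6 / 7), tolerance = 1e-12)
    expect_equal(rep@sensitivity,
                 0.3 * (2 / 3) + 0.4 * (3 / 4) + 0.3 * (2 / 3),
                 tolerance = 1e-12)
    po <- 0.7
    cmRow <- c(3, 4, 3)   # truth marginals
    cmCol <- c(3, 4, 3)   # prediction marginals
    pe <- sum(cmRow * cmCol) / 100
    expect_equal(rep@kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
})

test_that("perfect and single-class predictions bound the panel", {
    ft <- fakeTable(c(10, 10, 10), seed = 3)
    model <- fitSvmRbf(ft, "FADV")
    rep <- evaluateModel(model, ft)
    expect_equal(rep@accuracy, 1)
    expect_equal(rep@kappa, 1)
    expect_equal(rep@auc, 1)
    expect_equal(rep@sensitivity, 1)

    # constant predictions carry no information: kappa 0
    allMild <- matrix(c(0, 10, 0, 0, 10, 0, 0, 10, 0), 3, byrow = TRUE)
    expect_equal(cohenKappa(allMild), 0)
})

test_that("kappa is centred at zero under label permutation", {
    withr::with_seed(23, {
        pred <- sample(1:3, 60, replace = TRUE)
        truth <- sample(1:3, 60, replace = TRUE)
        ks <- replicate(1000, {
            cm <- table(factor(sample(truth), levels = 1:3),
                        factor(pred, levels = 1:3))
            cohenKappa(cm)
        })
    })
    expect_lt(abs(mean(ks)), 0.05)
    expect_true(all(ks <= 1))
})

test_that("the model grid runs ten cells over one shared split", {
    ft <- fakeTable(c(12, 12, 12), seed = 6)
    grid <- runModelGrid(ft, seed = 11)
    expect_length(grid, 10L)
    expect_named(grid, c("LR.SK", "LR.KUR", "LR.FAV", "LR.FAD", "LR.FADV",
                         "SVM.SK", "SVM.KUR", "SVM.FAV", "SVM.FAD",
                         "SVM.FADV"))
    again <- runModelGrid(ft, seed = 11)
    expect_equal(validitySummary(grid), validitySummary(again))
    s <- validitySummary(grid)
    expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
    expect_true(all(s$kappa >= -1 & s$kappa <= 1))
})
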