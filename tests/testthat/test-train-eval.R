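# Splitting, training and evaluation: subject exclusivity, K-fold
# balance, confusion-count metric identities, ROC properties, table
# arithmetic, descent on easy data.

test_that("train/test split is subject-exclusive, deterministic and
           near the target fraction", {
    m <- fakeManifest(5, 5)
    plan <- splitTrainTest(m, 0.7, seed = 1)
    expect_length(intersect(plan$trainSubjects, plan$testSubjects), 0L)
    expect_setequal(c(plan$trainSubjects, plan$testSubjects),
                    unique(m$subject_id))
    frac <- sum(m$subject_id %in% plan$trainSubjects) / nrow(m)
    expect_lt(abs(frac - 0.7), 0.05 + 1e-9)
    # all clips of a train subject are in train
    expect_identical(plan, splitTrainTest(m, 0.7, seed = 1))
    expect_false(identical(plan, splitTrainTest(m, 0.7, seed = 2)))
})

test_that("a class with a single subject cannot be split", {
    m <- fakeManifest(1, 3)
    expect_error(splitTrainTest(m, 0.7, seed = 1), "single subject")
})

test_that("fourfold split of 51 + 25 subjects balances classes to
           within one subject per fold", {
    m <- fakeManifest(51, 25, clipsPerSubject = 2L)
    folds <- kfoldSplit(m, K = 4, seed = 3)
    expect_length(folds, 4L)
    tab <- subset(unique(m[, c("subject_id", "label")]), TRUE)
    murCounts <- vapply(folds, function(f)
        sum(tab$label[tab$subject_id %in% f] == "murmur"), numeric(1))
    norCounts <- vapply(folds, function(f)
        sum(tab$label[tab$subject_id %in% f] == "normal"), numeric(1))
    expect_true(all(murCounts %in% c(12, 13)))
    expect_true(all(norCounts %in% c(6, 7)))
    expect_equal(sum(murCounts), 51)
    expect_equal(sum(norCounts), 25)
    all_s <- unlist(folds)
    expect_false(anyDuplicated(all_s) > 0)
    expect_setequal(all_s, unique(m$subject_id))
    expect_error(kfoldSplit(m, K = 1, seed = 1), "at least 2")
    expect_error(kfoldSplit(fakeManifest(3, 8), K = 4), "fewer than K")
})

test_that("metric identities hold against a brute-force recount on 100
           random prediction vectors", {
    set.seed(10)
    for (i in 1:100) {
        n <- sample(5:40, 1)
        truth <- sample(c("murmur", "normal"), n, replace = TRUE)
        pred <- sample(c("murmur", "normal"), n, replace = TRUE)
        cc <- confusionCounts(truth, pred)
        oc <- oracleCounts(truth, pred)
        expect_equal(cc[order(names(cc))], oc[order(names(oc))],
                     ignore_attr = TRUE)
        m <- metricReport(cc)
        with(cc, {
            expect_equal(m[["accuracy"]] * n / 100, Tp + Tn)
            if (Tp + Fn > 0)
                expect_equal(m[["sensitivity"]], 100 * Tp / (Tp + Fn))
            if (Tn + Fp > 0)
                expect_equal(m[["specificity"]], 100 * Tn / (Tn + Fp))
        })
    }
})

test_that("published split-task confusion counts reproduce the printed
           rates", {
    m <- metricReport(list(Tp = 172, Fn = 6, Tn = 59, Fp = 1))
    expect_equal(round(m[["sensitivity"]], 1), 96.6)
    expect_equal(round(m[["specificity"]], 1), 98.3)
    expect_equal(round(m[["accuracy"]], 1), 97.1)
    expect_equal(round(m[["ppv"]], 1), 99.4)
    perfect <- metricReport(list(Tp = 10, Tn = 10, Fp = 0, Fn = 0))
    expect_true(all(perfect == 100))
    # undefined denominators are reported absent, not zero
    onlyPos <- metricReport(list(Tp = 5, Fn = 0, Tn = 0, Fp = 0))
    expect_true(is.na(onlyPos[["specificity"]]))
    expect_true(is.na(onlyPos[["npv"]]))
})

test_that("fold-average arithmetic matches the published average row", {
    sens <- c(99.2, 96.2, 99.3, 94.0)
    spec <- c(96.7, 98.3, 90.0, 82.9)
    # half-up at two decimals: printed 97.18 and 91.98
    expect_lt(abs(mean(sens) - 97.18), 0.005 + 1e-9)
    expect_lt(abs(mean(spec) - 91.98), 0.005 + 1e-9)
})

test_that("ROC is monotone, perfect separation gives AUC 1, constant
           scores give 0.5, and AUC matches pROC", {
    r <- rocCurve(c("murmur", "murmur", "normal", "normal"),
                  c(0.9, 0.8, 0.1, 0.2))
    expect_equal(r$auc, 1.0)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    rc <- rocCurve(rep(c("murmur", "normal"), 5), rep(0.5, 10))
    expect_equal(rc$auc, 0.5)
    set.seed(11)
    truth <- sample(c("murmur", "normal"), 40, replace = TRUE,
                    prob = c(0.6, 0.4))
    scores <- runif(40)
    mine <- rocCurve(truth, scores)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
        response = truth, predictor = scores, levels = c("normal",
        "murmur"), direction = "<")))
    expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
    expect_true(mine >= 0 && mine <= 1)
})

test_that("training reduces the loss monotonically on linearly
           separable toy features and is seed-reproducible", {
    set.seed(20)
    nclip <- 12
    feats <- lapply(seq_len(nclip), function(i) {
        shift <- if (i <= nclip / 2) 1.5 else -1.5
        matrix(rnorm(8 * 6, mean = shift, sd = 0.3), 8, 6)
    })
    labels <- rep(c("murmur", "normal"), each = nclip / 2)
    cfg <- tinyTapConfig()
    fit <- trainModel(feats, labels, cfg, epochs = 5,
                      batchSize = nclip, lr = 0.02, seed = 5,
                      validationFraction = 0)
    expect_true(all(diff(fit$log$loss) < 0))
    fit2 <- trainModel(feats, labels, cfg, epochs = 1,
                       batchSize = nclip, lr = 0.02, seed = 5,
                       validationFraction = 0)
    expect_equal(fit2$log$loss[1], fit$log$loss[1])
    expect_error(trainModel(feats, rep("murmur", nclip), cfg),
                 "both classes")
    expect_error(evaluateModel(fit$weights, list(), character(0)),
                 "empty test set")
})

test_that("per-site evaluation reports sites lacking a class as absent
           and the kfold protocol emits fold rows plus an average", {
    # tiny end-to-end protocol run: 2 s clips, 1-epoch training
    co <- synthesizeCohort(4, 4, 1, synthConfig(seed = 77,
                                                duration = 2))
    cfg <- tinyTapConfig()
    res <- runProtocol(co$clips, co$manifest, cfg, protocol = "kfold",
                       K = 2, seed = 1, epochs = 1,
                       validationFraction = 0)
    expect_equal(res$table$row, c("fold1", "fold2", "average"))
    expect_equal(res$table$accuracy[3],
                 mean(res$table$accuracy[1:2]))
    ev <- res$details$fold1
    expect_true(all(c("accuracy", "sensitivity", "specificity", "ppv",
                      "npv") %in% names(ev$metrics)))
    expect_equal(with(ev$counts, Tp + Tn + Fp + Fn),
                 length(ev$scores))
    # site breakdown covers the five sites
    expect_setequal(ev$perSite$site,
                    c("aortic", "pulmonic", "erb", "tricuspid",
                      "mitral"))
    # single-class site filtering: construct directly
    ev2 <- evaluateModel(
        initWeights(cfg, 257L, 1),
        clipFeatures(co$clips[1:2], cfg),
        co$manifest$label[1:2], sites = co$manifest$site[1:2])
    sel <- ev2$perSite[ev2$perSite$n == 1, ]
    expect_true(all(is.na(sel$specificity) | is.na(sel$sensitivity)))
})

test_that("no subject appears on both sides of any emitted protocol
           split", {
    m <- fakeManifest(8, 6, clipsPerSubject = 3L)
    folds <- kfoldSplit(m, K = 3, seed = 9)
    for (k in seq_along(folds)) {
        train <- setdiff(unique(m$subject_id), folds[[k]])
        expect_length(intersect(train, folds[[k]]), 0L)
    }
})
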