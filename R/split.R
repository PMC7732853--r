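# Subject-exclusive data splitting. Training and test sets must be
# mutually exclusive at the subject level: all clips of a subject stay
# on one side.

subjectTable <- function(manifest) {
    tab <- unique(manifest[, c("subject_id", "label")])
    if (anyDuplicated(tab$subject_id))
        stop("a subject appears with more than one label")
    tab
}

#' Subject-exclusive train/test split
#'
#' Subjects of each class are shuffled (seeded) and assigned to the
#' training side until its clip count reaches the target fraction of
#' the class's clips, always leaving at least one subject per class on
#' each side. Because whole subjects move together, realized clip
#' fractions only approximate the target (they stay within a few
#' percentage points for cohorts of realistic size).
#'
#' @param manifest manifest data.frame (columns `subject_id`, `label`,
#'   and `path` or `clip`).
#' @param trainFraction target fraction of clips in the training set.
#' @param seed integer seed.
#' @return list with character vectors `trainSubjects` and
#'   `testSubjects` (disjoint, covering all subjects).
#' @export
splitTrainTest <- function(manifest, trainFraction = 0.7, seed = 1L) {
    tab <- subjectTable(manifest)
    set.seed(seed)
    labs <- unique(tab$label)
    ordered <- list(); cums <- list(); ks <- integer(length(labs))
    for (i in seq_along(labs)) {
        subs <- tab$subject_id[tab$label == labs[i]]
        if (length(subs) < 2L)
            stop("class '", labs[i], "' has a single subject; ",
                 "a subject-exclusive split is impossible")
        subs <- sample(subs)
        clipCounts <- vapply(subs, function(s)
            sum(manifest$subject_id == s), numeric(1))
        cum <- cumsum(clipCounts)
        target <- trainFraction * sum(clipCounts)
        ordered[[i]] <- subs
        cums[[i]] <- cum
        ks[i] <- max(1L, min(which.min(abs(cum - target)),
                             length(subs) - 1L))
    }
    # per-class rounding can drift from the overall target; nudge class
    # boundaries one subject at a time while that improves the realized
    # overall train fraction
    target <- trainFraction * nrow(manifest)
    realized <- function(ks) sum(vapply(seq_along(ks), function(i)
        cums[[i]][ks[i]], numeric(1)))
    repeat {
        best <- ks; bestErr <- abs(realized(ks) - target)
        for (i in seq_along(ks)) for (d in c(-1L, 1L)) {
            kk <- ks; kk[i] <- kk[i] + d
            if (kk[i] < 1L || kk[i] > length(ordered[[i]]) - 1L) next
            err <- abs(realized(kk) - target)
            if (err < bestErr - 1e-9) { best <- kk; bestErr <- err }
        }
        if (identical(best, ks)) break
        ks <- best
    }
    train <- unlist(lapply(seq_along(ks), function(i)
        ordered[[i]][seq_len(ks[i])]))
    list(trainSubjects = sort(train),
         testSubjects = sort(setdiff(tab$subject_id, train)))
}

#' Subject-exclusive K-fold split with per-class balance
#'
#' Subjects of each class are shuffled (seeded) and dealt round-robin
#' into K folds, so per-class subject counts across folds differ by at
#' most one; e.g. 51 murmur and 25 normal subjects at K = 4 give
#' per-fold murmur counts in \{12, 13\} and normal counts in \{6, 7\}.
#'
#' @param manifest manifest data.frame.
#' @param K number of folds (>= 2).
#' @param seed integer seed.
#' @return list of K character vectors of subject ids (pairwise
#'   disjoint, union = all subjects).
#' @export
kfoldSplit <- function(manifest, K = 4L, seed = 1L) {
    K <- as.integer(K)
    if (K < 2L)
        stop("K must be at least 2 (K = 1 leaves no held-out fold)")
    tab <- subjectTable(manifest)
    set.seed(seed)
    folds <- replicate(K, character(0), simplify = FALSE)
    for (lab in unique(tab$label)) {
        subs <- tab$subject_id[tab$label == lab]
        if (length(subs) < K)
            stop("class '", lab, "' has ", length(subs),
                 " subjects, fewer than K = ", K)
        subs <- sample(subs)
        f <- rep_len(seq_len(K), length(subs))
        for (k in seq_len(K))
            folds[[k]] <- c(folds[[k]], subs[f == k])
    }
    lapply(folds, sort)
}
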