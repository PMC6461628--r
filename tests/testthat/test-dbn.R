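test_that("quantile discretization bins a uniform grid into tertiles", {
    m <- matrix(as.numeric(1:9), nrow = 1, dimnames = list("A", NULL))
    p <- MediatorPanel(m, subject = paste0("s", 1:9), time = 1, group = "g")
    dp <- discretizePanel(p, levels = 3L)
    expect_equal(unname(dp$levels["A", ]),
                 rep(0:2, each = 3))                  # {1-3},{4-6},{7-9}
    expect_equal(dp$n_levels[["A"]], 3L)
})

test_that("a constant mediator collapses to a single level", {
    m <- rbind(A = rep(5, 6), B = as.numeric(1:6))
    p <- MediatorPanel(m, subject = paste0("s", 1:6), time = 1, group = "g")
    dp <- discretizePanel(p, levels = 3L)
    expect_true(all(dp$levels["A", ] == 0L))
    expect_equal(dp$n_levels[["A"]], 1L)
    expect_equal(dp$n_levels[["B"]], 3L)
})

test_that("quantile bins are balanced on a continuous sample", {
    x <- withr::with_seed(9, rlnorm(30))
    m <- matrix(x, nrow = 1, dimnames = list("A", NULL))
    p <- MediatorPanel(m, subject = paste0("s", 1:30), time = 1,
                       group = "g")
    dp <- discretizePanel(p, levels = 3L)
    counts <- tabulate(dp$levels["A", ] + 1L, 3L)
    expect_true(all(abs(counts - 10) <= 1))
    # missing values stay missing
    m[1, 5] <- NA
    p2 <- MediatorPanel(m, subject = paste0("s", 1:30), time = 1,
                        group = "g")
    expect_true(is.na(discretizePanel(p2)$levels["A", 5]))
})

test_that("transitions pair only consecutive samples of one subject", {
    m <- matrix(as.numeric(1:14), nrow = 2,
                dimnames = list(c("A", "B"), NULL))
    p <- MediatorPanel(m,
                       subject = c("s1", "s1", "s1", "s2", "s2", "s3", "s3"),
                       time = c(0, 1, 2, 0, 2, 5, 6), group = "g")
    tt <- buildTransitions(discretizePanel(p))
    # s1 {0,1,2} -> 2 rows; s2 {0,2} gap -> 0; s3 {5,6} -> 1
    expect_equal(nrow(tt$prev), 3L)
    expect_setequal(unique(tt$subject), c("s1", "s3"))
    tg <- buildTransitions(discretizePanel(p), gap_tolerant = TRUE)
    expect_equal(nrow(tg$prev), 4L)           # s2's 0 -> 2 now counts
    # never a cross-subject transition
    expect_true(all(tt$time_to > 0))
})

test_that("the family score prefers the truth on planted dynamics", {
    # independent child: adding any parent should usually hurt
    worse <- 0L
    for (seed in 1:20) {
        tt <- transitionsFor(arSpec(c("A", "B"), self = "A",
                                    n_subjects = 30L), seed)
        s0 <- scoreFamily("B", character(), tt)
        s1 <- scoreFamily("B", "A", tt)
        if (s0 > s1) worse <- worse + 1L
    }
    expect_gte(worse, 18L)                    # >= 90% of seeds
    # a self-copying mediator scores better with its own lag as parent
    tt <- transitionsFor(arSpec(c("A", "B"), self = "A",
                                n_subjects = 40L, noise = 0.1), 1)
    expect_gt(scoreFamily("A", "A", tt), scoreFamily("A", character(), tt))
})

test_that("the family score is invariant to relabeling discrete levels", {
    tt <- transitionsFor(arSpec(c("A", "B"), self = "A"), 4)
    s <- scoreFamily("A", c("A", "B"), tt)
    perm <- c(2L, 0L, 1L)
    tt2 <- tt
    tt2$prev[] <- perm[tt$prev + 1L]
    tt2$cur[] <- perm[tt$cur + 1L]
    expect_equal(scoreFamily("A", c("A", "B"), tt2), s, tolerance = 1e-12)
})

test_that("greedy search matches exhaustive enumeration on small systems", {
    for (seed in 1:8) {
        tt <- transitionsFor(arSpec(c("A", "B", "C"),
                                    edges = data.frame(from = "A",
                                                       to = "B",
                                                       weight = 0.9),
                                    self = "A", n_subjects = 25L), seed)
        model <- learnStructure(tt, max_parents = 2L, restarts = 5L,
                                seed = seed)
        e <- edges(model)
        for (ch in c("A", "B", "C")) {
            got <- sort(e$parent[e$child == ch])
            expect_identical(got,
                             sort(oracleParents(ch, tt, 2L)$parents),
                             info = paste("seed", seed, "child", ch))
        }
    }
})

test_that("structure search is deterministic and monotone in score", {
    tt <- transitionsFor(arSpec(c("A", "B", "C"), self = "A"), 2)
    m1 <- learnStructure(tt, restarts = 5L, seed = 99L)
    m2 <- learnStructure(tt, restarts = 5L, seed = 99L)
    expect_identical(edges(m1), edges(m2))
    expect_identical(m1@score, m2@score)
    for (tr in attr(m1, "trace"))
        expect_true(all(diff(tr) > 0))        # accepted moves improve
})

test_that("constant mediators learn an empty structure", {
    m <- rbind(A = rep(5, 8), B = rep(3, 8))
    p <- MediatorPanel(m, subject = rep(c("s1", "s2"), each = 4),
                       time = rep(0:3, 2), group = "g")
    model <- learnStructure(buildTransitions(discretizePanel(p)),
                            seed = 1L)
    expect_equal(nrow(edges(model)), 0L)
})

test_that("a self-driven mediator is recovered; white noise stays isolated", {
    hits_self <- 0L; clean_B <- 0L
    for (seed in 1:20) {
        # ~300 transitions: 30 subjects x 11 daily samples
        tt <- transitionsFor(arSpec(c("A", "B"), self = "A",
                                    n_subjects = 30L, times = 0:10), seed)
        e <- edges(learnStructure(tt, restarts = 5L, seed = seed))
        if (any(e$parent == "A" & e$child == "A")) hits_self <- hits_self + 1L
        if (!any(e$child == "B")) clean_B <- clean_B + 1L
    }
    expect_gte(hits_self, 18L)
    expect_gte(clean_B, 18L)
})

test_that("bootstrap confidence is bounded, reproducible and near 1 for strong edges", {
    spec <- arSpec(c("A", "B"), self = "A", n_subjects = 20L, times = 0:7,
                   noise = 0.15)
    co <- generateCohort(spec, seed = 5)
    c1 <- edgeConfidence(panel(co), "g", n_boot = 20L, seed = 3L,
                         restarts = 2L)
    c2 <- edgeConfidence(panel(co), "g", n_boot = 20L, seed = 3L,
                         restarts = 2L)
    expect_identical(c1, c2)
    expect_true(all(c1$confidence >= 0 & c1$confidence <= 1))
    self <- c1$confidence[c1$parent == "A" & c1$child == "A"]
    expect_gte(self, 0.9)
})

test_that("central nodes are the confident self-loops, sorted by support", {
    mk <- function(e) new("DbnModel", mediators = c("HMGB1", "IL-6", "TNF-a"),
                          edges = e, score = 0,
                          config = list(max_parents = 3L))
    only <- mk(data.frame(parent = "HMGB1", child = "HMGB1",
                          confidence = NA_real_))
    expect_identical(selfFeedbackNodes(only), "HMGB1")
    none <- mk(data.frame(parent = "HMGB1", child = "IL-6",
                          confidence = 0.9))
    expect_length(selfFeedbackNodes(none), 0L)
    two <- mk(data.frame(parent = c("HMGB1", "IL-6", "IL-6"),
                         child = c("HMGB1", "IL-6", "TNF-a"),
                         confidence = c(0.9, 0.4, 1)))
    expect_identical(selfFeedbackNodes(two, 0.5), "HMGB1")
    expect_identical(selfFeedbackNodes(two, 0), c("HMGB1", "IL-6"))
})

test_that("DBN outputs serialize to CSV and JSON", {
    tt <- transitionsFor(arSpec(c("A", "B"), self = "A"), 3)
    model <- learnStructure(tt, seed = 1L)
    f <- tempfile(fileext = ".csv")
    writeDbnEdges(model, f)
    e <- read.csv(f)
    expect_true(all(c("parent", "child", "confidence", "self_loop") %in%
                    colnames(e)))
    j <- tempfile(fileext = ".json")
    writeDbnJson(model, j)
    dump <- jsonlite::read_json(j)
    expect_equal(unlist(dump$mediators), mediators(model))
    expect_equal(dump$score, model@score, tolerance = 1e-9)
})
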