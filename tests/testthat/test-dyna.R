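w01 <- timeWindow("w", 0, 2)

test_that("network complexity is the degree sum over n - 1", {
    k4 <- utils::combn(LETTERS[1:4], 2)
    net <- DynaNetwork(LETTERS[1:4],
                       data.frame(a = k4[1, ], b = k4[2, ], r = 0.9,
                                  sign = "+", n_pairs = 5L))
    expect_equal(networkComplexity(net), 4.0)          # complete K4
    one <- DynaNetwork(LETTERS[1:3],
                       data.frame(a = "A", b = "B", r = 0.8, sign = "+",
                                  n_pairs = 5L))
    expect_equal(networkComplexity(one), 1.0)          # (1+1+0)/2
    expect_equal(networkComplexity(DynaNetwork(LETTERS[1:5])), 0)
    expect_error(networkComplexity(DynaNetwork("A")), ">= 2")
    # degree-sum identity on an arbitrary network
    expect_equal(networkComplexity(net) * (length(mediators(net)) - 1),
                 2 * nrow(edges(net)))
})

test_that("perfectly parallel and anti-parallel trajectories give signed edges", {
    x <- c(3, 1, 4, 1, 5, 9)
    p <- panelFromObs(cbind(A = x, B = x, C = 10 - x))
    net <- buildNetwork(p, "g", w01, min_pairs = 4L)
    e <- edges(net)
    expect_equal(e$sign[e$a == "A" & e$b == "B"], "+")
    expect_equal(e$r[e$a == "A" & e$b == "B"], 1)
    expect_equal(e$sign[e$a == "A" & e$b == "C"], "-")
    expect_equal(e$r[e$a == "A" & e$b == "C"], -1)
})

test_that("constant vectors and short pairs never form edges", {
    p <- panelFromObs(cbind(A = c(1, 2, 3, 4, 5), B = rep(7, 5),
                            C = c(1, 2, 3, NA, NA)))
    net <- buildNetwork(p, "g", w01, min_pairs = 4L)
    expect_equal(nrow(edges(net)), 0L)   # B constant; A-C only 3 pairs
    net2 <- buildNetwork(p, "g", w01, min_pairs = 3L)
    expect_true("C" %in% c(edges(net2)$a, edges(net2)$b))
    expect_error(buildNetwork(p, "nope", w01), "unknown group")
})

test_that("edge sets match the brute-force all-pairs oracle", {
    for (seed in 1:10) {
        obs <- withr::with_seed(seed, randomObs(10, 6))
        net <- buildNetwork(panelFromObs(obs), "g", w01)
        expect_identical(edgeKey(edges(net)), edgeKey(oracleEdges(obs)),
                         info = paste("seed", seed))
    }
})

test_that("raising the stringency can only remove edges", {
    obs <- withr::with_seed(42, randomObs(12, 7))
    p <- panelFromObs(obs)
    prev <- NULL
    for (s in c(0.5, 0.7, 0.9, 0.99)) {
        keys <- edgeKey(edges(buildNetwork(p, "g", w01, stringency = s)))
        if (!is.null(prev)) expect_true(all(keys %in% prev))
        prev <- keys
    }
})

test_that("mediator and subject relabeling leave the network invariant", {
    obs <- withr::with_seed(11, randomObs(10, 6, miss = 0))
    net <- buildNetwork(panelFromObs(obs), "g", w01)
    perm <- withr::with_seed(1, sample(ncol(obs)))
    net2 <- buildNetwork(panelFromObs(obs[, perm]), "g", w01)
    expect_identical(edgeKey(edges(net)), edgeKey(edges(net2)))
    expect_equal(networkComplexity(net), networkComplexity(net2))
    rperm <- withr::with_seed(2, sample(nrow(obs)))
    net3 <- buildNetwork(panelFromObs(obs[rperm, ]), "g", w01)
    expect_identical(edgeKey(edges(net)), edgeKey(edges(net3)))
})

test_that("reflecting one mediator flips exactly that mediator's edge signs", {
    obs <- withr::with_seed(5, randomObs(10, 6, miss = 0))
    base <- edges(buildNetwork(panelFromObs(obs), "g", w01))
    m <- "M1"
    obs2 <- obs
    obs2[, m] <- max(obs[, m]) + min(obs[, m]) - obs[, m]  # affine reflect
    flip <- edges(buildNetwork(panelFromObs(obs2), "g", w01))
    key <- function(e) paste(e$a, e$b)
    expect_setequal(key(base), key(flip))
    i <- match(key(base), key(flip))
    touches <- base$a == m | base$b == m
    expect_true(all(flip$sign[i][touches] != base$sign[touches]))
    expect_true(all(flip$sign[i][!touches] == base$sign[!touches]))
})

test_that("total connections sum edge counts across a group's windows", {
    traj <- data.frame(group = "g",
                       window = paste0("w", 1:7),
                       edges = c(3L, 5L, 0L, 2L, 1L, 0L, 4L),
                       complexity = 0)
    expect_identical(totalConnections(traj), 15L)
    expect_identical(totalConnections(list(DynaNetwork(LETTERS[1:3]))), 0L)
    traj2 <- traj; traj2$group <- rep(c("g", "h"), length.out = 7)
    expect_error(totalConnections(traj2), "several groups")
})

test_that("negative-edge accounting reports counts, fraction and flag", {
    mk <- function(n_pos, n_neg, meds = LETTERS[1:10]) {
        cmb <- utils::combn(meds, 2)
        idx <- seq_len(n_pos + n_neg)
        DynaNetwork(meds, data.frame(
            a = cmb[1, idx], b = cmb[2, idx],
            r = c(rep(0.9, n_pos), rep(-0.9, n_neg)),
            sign = c(rep("+", n_pos), rep("-", n_neg)),
            n_pairs = 6L))
    }
    nf <- negativeFraction(list(mk(6, 2), mk(4, 0)))
    expect_equal(nf$negatives, 2L)
    expect_equal(nf$total, 12L)
    expect_equal(nf$fraction, 2 / 12)
    expect_false(nf$undefined)
    allpos <- negativeFraction(mk(5, 0))
    expect_equal(allpos$negatives, 0L)
    expect_equal(allpos$fraction, 0)
    empty <- negativeFraction(DynaNetwork(LETTERS[1:4]))
    expect_true(empty$undefined)
    expect_equal(empty$fraction, 0)
})

test_that("the focused subnetwork keeps exactly the edges touching a mediator", {
    meds <- c("HMGB1", "IL-6", "IL-8", "IP-10", "IL-4", "IL-5")
    e <- data.frame(a = c("HMGB1", "HMGB1", "HMGB1", "IL-4"),
                    b = c("IL-6", "IL-8", "IP-10", "IL-5"),
                    r = 0.9, sign = "+", n_pairs = 5L)
    net <- DynaNetwork(meds, e)
    sub <- focusSubnetwork(net, "HMGB1")
    expect_equal(nrow(edges(sub)), 3L)
    expect_true(all(edges(sub)$a == "HMGB1" | edges(sub)$b == "HMGB1"))
    expect_identical(mediators(sub), meds)     # node set unchanged
    expect_equal(nrow(edges(focusSubnetwork(net, "IL-5"))), 1L)
    none <- focusSubnetwork(DynaNetwork(meds), "HMGB1")
    expect_equal(nrow(edges(none)), 0L)
    # star centered on the mediator is untouched
    star <- DynaNetwork(meds, e[1:3, ])
    expect_equal(edges(focusSubnetwork(star, "HMGB1")), edges(star))
    expect_error(focusSubnetwork(net, "IL-99"), "IL-99")
})

test_that("complexity trajectories follow the schedule and planted structure", {
    co <- generateCohort(examplePlantedSpec(), seed = 21)
    traj <- complexityTrajectory(panel(co), "planted", dailySchedule())
    expect_equal(nrow(traj), 7L)
    expect_identical(traj$window, dailySchedule()$label)
    expect_equal(traj$complexity, 2 * traj$edges / (8 - 1))
    nets <- attr(traj, "networks")
    expect_length(nets, 7L)
    expect_identical(totalConnections(traj), totalConnections(nets))
    # an all-missing group yields a zero trajectory and a warning
    m <- matrix(NA_real_, 2, 6, dimnames = list(c("A", "B"), NULL))
    m[, 1] <- 1            # one informative sample so the panel is sane
    pe <- MediatorPanel(m, subject = rep(c("x", "y"), each = 3),
                        time = rep(0:2, 2), group = "g")
    expect_warning(tr0 <- complexityTrajectory(pe, "g", dailySchedule()),
                   "without observations")
    expect_true(all(tr0$complexity == 0))
})

test_that("log-scale correlation option preserves monotone co-movement", {
    x <- exp(c(1, 2, 3, 4, 5))
    p <- panelFromObs(cbind(A = x, B = x^2, C = c(5, 1, 4, 2, 8)))
    raw <- buildNetwork(p, "g", w01, min_pairs = 4L)
    logn <- buildNetwork(p, "g", w01, min_pairs = 4L, transform = "log10")
    # A and B are log-linear: r -> 1 on the log scale (up to the 1 + x
    # offset), while raw r is diluted by the curvature
    el <- edges(logn)
    expect_equal(el$r[el$a == "A" & el$b == "B"], 1, tolerance = 1e-3)
    expect_s4_class(raw, "DynaNetwork")
})

test_that("edge list export is sorted, complete and re-readable", {
    co <- generateCohort(examplePlantedSpec(), seed = 2)
    nets <- attr(complexityTrajectory(panel(co), "planted",
                                      dailySchedule()), "networks")
    f <- tempfile(fileext = ".csv")
    writeEdgeList(nets, f)
    e <- read.csv(f, check.names = FALSE)
    expect_identical(colnames(e),
                     c("group", "window", "mediator_a", "mediator_b", "r",
                       "sign", "n_pairs"))
    expect_true(all(e$mediator_a < e$mediator_b))
    expect_equal(nrow(e), totalConnections(nets))
    fs <- tempfile(fileext = ".sif")
    writeSif(nets, fs)
    expect_equal(length(readLines(fs)), totalConnections(nets))
})
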