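#' Discretize a mediator panel into quantile levels
#'
#' Per-mediator quantile binning of the pooled (all samples of the panel
#' passed in — subset with [subsetGroup()] first to discretize within one
#' group) non-missing concentrations into `levels` roughly equally
#' populated levels `0 .. levels-1`. Missing values stay missing. A
#' mediator with fewer distinct values than requested falls back to as many
#' bins as its quantiles support (a constant mediator collapses to the
#' single level 0); the per-mediator bin edges are returned for
#' reproducibility.
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param levels integer >= 2 (default 3: low / medium / high).
#' @return a `DiscretizedPanel`: list with `levels` (integer matrix,
#'   mediators x samples), `n_levels` (named integer per mediator),
#'   `breaks` (named list of bin edges), `subject`, `time`, `group`,
#'   `mediators`.
#' @export
discretizePanel <- function(panel, levels = 3L) {
    stopifnot(levels >= 2L)
    v <- assay(panel, "conc")
    cd <- colData(panel)
    lev <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
    n_levels <- structure(integer(nrow(v)), names = rownames(v))
    breaks <- vector("list", nrow(v))
    names(breaks) <- rownames(v)
    for (i in seq_len(nrow(v))) {
        x <- v[i, ]
        ok <- !is.na(x)
        if (!any(ok)) {
            n_levels[i] <- 1L
            breaks[[i]] <- numeric()
            next
        }
        br <- unique(stats::quantile(x[ok],
                                     probs = seq(0, 1, length.out = levels + 1),
                                     names = FALSE, type = 7))
        if (length(br) < 3L) {            # constant (or near): single level
            lev[i, ok] <- 0L
            n_levels[i] <- 1L
        } else {
            lev[i, ok] <- as.integer(
                cut(x[ok], br, include.lowest = TRUE, labels = FALSE)) - 1L
            n_levels[i] <- length(br) - 1L
        }
        breaks[[i]] <- br
    }
    structure(list(levels = lev, n_levels = n_levels, breaks = breaks,
                   subject = as.character(cd$subject),
                   time = as.numeric(cd$time),
                   group = as.character(cd$group),
                   mediators = rownames(v)),
              class = "DiscretizedPanel")
}

#' Build the lagged transition table of a discretized panel
#'
#' One row per consecutive (t-1, t) observation pair of the same subject:
#' the discretized mediator vector at the earlier time is the parent
#' ("prev") configuration, the vector at the later time the child ("cur")
#' configuration. Subjects' series are never concatenated across subjects.
#' By default only pairs exactly `step` time units apart qualify, so gaps
#' (a missing day) produce no row; `gap_tolerant = TRUE` instead treats any
#' adjacent pair of observed times as one step.
#'
#' @param dp a `DiscretizedPanel` from [discretizePanel()].
#' @param step the exact time difference forming a transition (default 1,
#'   i.e. consecutive daily samples).
#' @param gap_tolerant allow unequal gaps (default `FALSE`).
#' @return a `TransitionTable`: list with integer matrices `prev` and `cur`
#'   (transitions x mediators), `subject`, `time_to`, `n_levels`,
#'   `mediators`.
#' @export
buildTransitions <- function(dp, step = 1, gap_tolerant = FALSE) {
    stopifnot(inherits(dp, "DiscretizedPanel"))
    ord <- order(dp$subject, dp$time)
    subj <- dp$subject[ord]; tim <- dp$time[ord]
    lev <- dp$levels[, ord, drop = FALSE]
    from <- integer(); to <- integer()
    for (s in unique(subj)) {
        idx <- which(subj == s)
        if (length(idx) < 2L) next
        dt <- diff(tim[idx])
        take <- if (gap_tolerant) dt > 0 else abs(dt - step) < 1e-9
        from <- c(from, idx[-length(idx)][take])
        to <- c(to, idx[-1L][take])
    }
    structure(list(prev = t(lev[, from, drop = FALSE]),
                   cur = t(lev[, to, drop = FALSE]),
                   subject = subj[to], time_to = tim[to],
                   n_levels = dp$n_levels, mediators = dp$mediators),
              class = "TransitionTable")
}

#' @export
print.TransitionTable <- function(x, ...) {
    cat(sprintf("TransitionTable: %d transitions x %d mediators (%d subjects)\n",
                nrow(x$prev), length(x$mediators),
                length(unique(x$subject))))
    invisible(x)
}

#' BDeu family score of a child given a lagged parent set
#'
#' Log marginal likelihood of the child's discretized value at time t given
#' the parents' values at t-1, under Dirichlet priors with equivalent
#' sample size `ess` spread uniformly over parent configurations
#' (Bayesian-Dirichlet equivalent uniform score). Decomposable over
#' children, so structure search optimizes each child independently.
#' Transitions with a missing child or parent value are dropped for that
#' family. Higher is better; the score of the empty parent set is the
#' marginal Dirichlet-multinomial likelihood of the child alone. Level
#' cardinalities are taken from the discretization, so a constant
#' (single-level) mediator contributes a factor of one: it can neither
#' gain parents nor improve any child's score, and stays isolated.
#'
#' @param child mediator name.
#' @param parents character vector of parent mediator names (the child
#'   itself is a legal parent: a self-loop); may be empty.
#' @param table a `TransitionTable`.
#' @param ess equivalent sample size of the Dirichlet prior (default 1).
#' @return numeric(1) log score.
#' @export
scoreFamily <- function(child, parents, table, ess = 1) {
    stopifnot(inherits(table, "TransitionTable"))
    if (nrow(table$prev) == 0L) stop("empty transition table")
    meds <- table$mediators
    stopifnot(child %in% meds, all(parents %in% meds))
    y <- table$cur[, match(child, meds)]
    r <- table$n_levels[[child]]
    ok <- !is.na(y)
    if (length(parents)) {
        P <- table$prev[, match(parents, meds), drop = FALSE]
        ok <- ok & !apply(is.na(P), 1L, any)
        P <- P[ok, , drop = FALSE]
        rl <- table$n_levels[parents]
        q <- prod(rl)
        # mixed-radix parent configuration index, 0-based
        j <- integer(sum(ok))
        mult <- 1L
        for (k in seq_along(parents)) {
            j <- j + P[, k] * mult
            mult <- mult * rl[k]
        }
    } else {
        q <- 1L
        j <- integer(sum(ok))
    }
    y <- y[ok]
    if (!length(y)) stop("no complete transitions for child ", child)
    cell <- j * r + y + 1L
    Njk <- tabulate(cell, nbins = q * r)
    Njk <- matrix(Njk, nrow = r)
    Nj <- colSums(Njk)
    a_jk <- ess / (q * r)
    a_j <- ess / q
    sum(lgamma(a_j) - lgamma(a_j + Nj)) +
        sum(lgamma(a_jk + Njk) - lgamma(a_jk))
}

# greedy add/remove hill climb for one child; returns list(parents, score,
# trace of accepted scores)
.greedyFamily <- function(child, table, max_parents, ess, init) {
    meds <- table$mediators
    cur <- sort(init)
    best <- scoreFamily(child, cur, table, ess = ess)
    trace <- best
    repeat {
        cand_best <- best
        cand_set <- NULL
        if (length(cur) < max_parents)
            for (p in setdiff(meds, cur)) {
                s <- scoreFamily(child, c(cur, p), table, ess = ess)
                if (s > cand_best + 1e-9) {
                    cand_best <- s; cand_set <- sort(c(cur, p))
                }
            }
        for (p in cur) {
            s <- scoreFamily(child, setdiff(cur, p), table, ess = ess)
            if (s > cand_best + 1e-9) {
                cand_best <- s; cand_set <- setdiff(cur, p)
            }
        }
        if (is.null(cand_set)) break
        cur <- cand_set
        best <- cand_best
        trace <- c(trace, best)
    }
    list(parents = cur, score = best, trace = trace)
}

#' Learn the structure of a first-order dynamic Bayesian network
#'
#' Because the BDeu score decomposes over children, the most likely
#' structure is found per child by greedy hill climbing over lagged parent
#' sets: starting from an initial set, repeatedly apply the single
#' add-or-remove move with the largest strict score improvement until a
#' local optimum; the best of `restarts` random initial parent sets (plus
#' the empty set) is kept. A mediator's own lag is a candidate parent like
#' any other, so self-feedback loops are learned, not assumed.
#' Deterministic given `seed`.
#'
#' @param table a `TransitionTable` (non-empty).
#' @param max_parents maximum parents per child (default 3).
#' @param restarts random restarts per child in addition to the empty
#'   start (default 10).
#' @param seed integer seed for the restart draws.
#' @param ess BDeu equivalent sample size (default 1).
#' @return a \linkS4class{DbnModel}; `attr(, "trace")` holds the accepted
#'   score sequence per child (each strictly increasing).
#' @export
learnStructure <- function(table, max_parents = 3L, restarts = 10L,
                           seed = 1L, ess = 1) {
    stopifnot(inherits(table, "TransitionTable"), nrow(table$prev) > 0L)
    meds <- table$mediators
    fams <- withSeed(seed, lapply(meds, function(ch) {
        inits <- c(list(character()),
                   lapply(seq_len(restarts), function(i) {
                       k <- sample.int(max_parents, 1L)
                       sample(meds, min(k, length(meds)))
                   }))
        best <- NULL
        for (ini in inits) {
            fit <- .greedyFamily(ch, table, max_parents, ess, ini)
            if (is.null(best) || fit$score > best$score + 1e-9) best <- fit
        }
        best
    }))
    names(fams) <- meds
    e <- do.call(rbind, lapply(meds, function(ch) {
        ps <- fams[[ch]]$parents
        if (!length(ps)) return(NULL)
        data.frame(parent = ps, child = ch, confidence = NA_real_)
    }))
    if (is.null(e))
        e <- data.frame(parent = character(), child = character(),
                        confidence = numeric())
    model <- new("DbnModel", mediators = meds, edges = e,
                 score = sum(vapply(fams, `[[`, 1.0, "score")),
                 config = list(levels = max(table$n_levels),
                               max_parents = max_parents,
                               restarts = restarts, seed = as.integer(seed),
                               ess = ess))
    attr(model, "trace") <- lapply(fams, `[[`, "trace")
    model
}

#' Bootstrap edge confidence by resampling subjects
#'
#' Resamples subjects with replacement `n_boot` times; each resample is
#' re-discretized, its transition table rebuilt, and a structure learned.
#' The confidence of a directed edge is the fraction of resamples whose
#' learned structure contains it — the quantity edge thickness encodes in
#' the usual network figures. Reproducible given `seed`.
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param group group to analyze (`NULL` = whole panel).
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param levels,max_parents,restarts,ess passed to the discretizer and
#'   learner (fewer restarts than a final fit is customary: the bootstrap
#'   averages over resamples).
#' @param step,gap_tolerant passed to [buildTransitions()].
#' @return data.frame `parent`, `child`, `confidence`, sorted by
#'   confidence, containing every edge seen in at least one resample.
#' @export
edgeConfidence <- function(panel, group = NULL, n_boot = 100L, seed = 1L,
                           levels = 3L, max_parents = 3L, restarts = 3L,
                           ess = 1, step = 1, gap_tolerant = FALSE) {
    stopifnot(n_boot >= 1L)
    if (!is.null(group)) panel <- subsetGroup(panel, group)
    cd <- colData(panel)
    subs <- unique(cd$subject)
    counts <- new.env(parent = emptyenv())
    for (b in seq_len(n_boot)) {
        take <- withSeed(deriveSeed(seed, "boot", b),
                         sample(subs, length(subs), replace = TRUE))
        idx_list <- lapply(take, function(s) which(cd$subject == s))
        idx <- unlist(idx_list)
        # re-key duplicated subjects so their series stay separate
        reps <- rep(seq_along(take), lengths(idx_list))
        sub <- MediatorPanel(assay(panel, "conc")[, idx, drop = FALSE],
                             subject = paste0(cd$subject[idx], ".b", reps),
                             time = cd$time[idx],
                             group = cd$group[idx],
                             time_unit = timeUnit(panel))
        tt <- buildTransitions(discretizePanel(sub, levels = levels),
                               step = step, gap_tolerant = gap_tolerant)
        if (nrow(tt$prev) == 0L) next
        m <- learnStructure(tt, max_parents = max_parents,
                            restarts = restarts,
                            seed = deriveSeed(seed, "learn", b), ess = ess)
        ed <- m@edges
        for (k in seq_len(nrow(ed))) {
            key <- paste(ed$parent[k], ed$child[k], sep = "\r")
            counts[[key]] <- (if (is.null(counts[[key]])) 0L
                              else counts[[key]]) + 1L
        }
    }
    keys <- ls(counts)
    if (!length(keys))
        return(data.frame(parent = character(), child = character(),
                          confidence = numeric()))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(parent = vapply(parts, `[`, "", 1L),
                      child = vapply(parts, `[`, "", 2L),
                      confidence = vapply(keys, function(k)
                          counts[[k]] / n_boot, 1.0))
    out <- out[order(-out$confidence, out$parent, out$child), ]
    rownames(out) <- NULL
    out
}

#' Fit a dynamic Bayesian network to one group
#'
#' Convenience wrapper: subset to the group, discretize, build transitions,
#' learn the structure, and (when `n_boot > 0`) attach bootstrap confidence
#' to every learned edge.
#'
#' @inheritParams edgeConfidence
#' @return a \linkS4class{DbnModel}.
#' @export
fitDbn <- function(panel, group = NULL, levels = 3L, max_parents = 3L,
                   restarts = 10L, seed = 1L, ess = 1, n_boot = 0L,
                   step = 1, gap_tolerant = FALSE) {
    if (!is.null(group)) panel <- subsetGroup(panel, group)
    tt <- buildTransitions(discretizePanel(panel, levels = levels),
                           step = step, gap_tolerant = gap_tolerant)
    model <- learnStructure(tt, max_parents = max_parents,
                            restarts = restarts, seed = seed, ess = ess)
    if (n_boot > 0L && nrow(model@edges)) {
        conf <- edgeConfidence(panel, NULL, n_boot = n_boot, seed = seed,
                               levels = levels, max_parents = max_parents,
                               restarts = max(1L, restarts %/% 2L),
                               ess = ess, step = step,
                               gap_tolerant = gap_tolerant)
        key <- function(d) paste(d$parent, d$child, sep = "\r")
        i <- match(key(model@edges), key(conf))
        model@edges$confidence <- ifelse(is.na(i), 0, conf$confidence[i])
    }
    model
}

#' Central nodes: mediators with a self-feedback loop
#'
#' A central node of the dynamic network is a mediator inferred to drive
#' its own expression: its self-loop (own lag as parent) is present in the
#' learned structure with bootstrap confidence at least `min_confidence`.
#' Returned sorted by confidence, highest first. Edges whose confidence was
#' never computed (`NA`) qualify only when `min_confidence` is 0.
#'
#' @param model a \linkS4class{DbnModel}.
#' @param min_confidence minimum bootstrap support in [0, 1] (default 0).
#' @return character vector of mediator names.
#' @export
selfFeedbackNodes <- function(model, min_confidence = 0) {
    e <- model@edges
    e <- e[e$parent == e$child, , drop = FALSE]
    conf <- e$confidence
    keep <- ifelse(is.na(conf), min_confidence <= 0, conf >= min_confidence)
    e <- e[keep, , drop = FALSE]
    e$parent[order(-ifelse(is.na(e$confidence), 1, e$confidence))]
}

#' Write a DBN edge table to CSV / dump a model to JSON
#'
#' The CSV has columns `parent`, `child`, `confidence`, `self_loop`;
#' the JSON dump includes the node list, edges, score and config.
#'
#' @param model a \linkS4class{DbnModel}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDbnEdges <- function(model, path) {
    e <- model@edges
    e$self_loop <- e$parent == e$child
    utils::write.csv(e, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDbnEdges
#' @export
writeDbnJson <- function(model, path) {
    jsonlite::write_json(
        list(mediators = model@mediators, edges = model@edges,
             score = model@score, config = model@config),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
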