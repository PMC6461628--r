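#' Build a signed correlation network for one time window
#'
#' The dynamic network analysis (DyNA) primitive. For one sub-group and one
#' time window, all (subject, time) samples of the group falling inside the
#' window are pooled. For every unordered mediator pair the Pearson
#' correlation is computed over the samples where both mediators are
#' non-missing, and an edge is created iff (i) at least `min_pairs` complete
#' pairs exist, (ii) neither paired vector is constant, and (iii)
#' `|r| >= stringency`. The edge carries `sign(r)`: a negative edge marks a
#' mediator pair moving in an anti-correlated fashion within the window.
#'
#' Correlations are computed on raw concentrations by default;
#' `transform = "log10"` uses `log10(1 + x)` instead for right-skewed
#' panels. No multiple-testing machinery is involved: edge creation is a
#' fixed-threshold rule, and ties at exactly the threshold are kept.
#'
#' @param panel a \linkS4class{MediatorPanel} (>= 2 mediators).
#' @param group sub-group label (must exist in the panel).
#' @param window a [timeWindow()] or one-row schedule slice.
#' @param stringency correlation-magnitude threshold in (0, 1]; default 0.7.
#' @param min_pairs minimum complete observation pairs per edge; default 4.
#' @param transform `"identity"` (default) or `"log10"`.
#' @return a \linkS4class{DynaNetwork}.
#' @examples
#' co <- generateCohort(examplePlantedSpec(), seed = 7)
#' net <- buildNetwork(panel(co), "planted", timeWindow("d1-2", 1, 2))
#' net
#' @export
buildNetwork <- function(panel, group, window, stringency = 0.7,
                         min_pairs = 4L,
                         transform = c("identity", "log10")) {
    transform <- match.arg(transform)
    stopifnot(stringency > 0, stringency <= 1, min_pairs >= 2L)
    if (nrow(panel) < 2L) stop("need at least 2 mediators")
    w <- asWindow(window)
    m <- windowMatrix(panel, w, group)
    if (transform == "log10") m <- log10(1 + m)
    meds <- colnames(m)
    edges <- list()
    k <- 0L
    for (i in seq_len(ncol(m) - 1L)) {
        xi <- m[, i]
        for (j in seq(i + 1L, ncol(m))) {
            yj <- m[, j]
            ok <- !is.na(xi) & !is.na(yj)
            n <- sum(ok)
            if (n < min_pairs) next
            x <- xi[ok]; y <- yj[ok]
            if (stats::sd(x) == 0 || stats::sd(y) == 0) next
            r <- stats::cor(x, y)
            if (is.na(r) || abs(r) < stringency) next
            k <- k + 1L
            edges[[k]] <- data.frame(
                a = meds[i], b = meds[j], r = r,
                sign = if (r >= 0) "+" else "-", n_pairs = n)
        }
    }
    edges <- if (k) do.call(rbind, edges) else NULL
    DynaNetwork(meds, edges, window = w, group = group,
                stringency = stringency)
}

#' Network complexity of a window network
#'
#' The degree-sum complexity statistic
#' \deqn{\mathrm{complexity} = \frac{N_1 + N_2 + \dots + N_n}{n - 1}
#'       = \frac{2\,|E|}{n - 1},}
#' where \eqn{N_i} is the number of connections of mediator \eqn{i} and
#' \eqn{n} the total number of mediators analyzed (connected or not).
#' Negative edges count in degrees exactly like positive ones. Zero iff the
#' network has no edges.
#'
#' @param net a \linkS4class{DynaNetwork} with >= 2 mediators.
#' @return non-negative numeric(1).
#' @export
networkComplexity <- function(net) {
    n <- length(net@mediators)
    if (n < 2L) stop("complexity needs >= 2 mediators")
    sum(degrees(net)) / (n - 1)
}

#' Complexity trajectory of a group over a window schedule
#'
#' Applies [buildNetwork()] to each window of a schedule in order and
#' returns one row per window with the edge count and the network
#' complexity. Windows in which no mediator pair reaches `min_pairs`
#' complete observations yield zero complexity (with a warning).
#'
#' @inheritParams buildNetwork
#' @param schedule schedule data.frame, e.g. [dailySchedule()].
#' @param networks also return the per-window \linkS4class{DynaNetwork}
#'   objects (as the `"networks"` attribute).
#' @return data.frame with columns `group`, `window`, `edges`,
#'   `complexity`.
#' @export
complexityTrajectory <- function(panel, group, schedule, stringency = 0.7,
                                 min_pairs = 4L,
                                 transform = c("identity", "log10"),
                                 networks = TRUE) {
    stopifnot(nrow(schedule) >= 1L)
    transform <- match.arg(transform)
    nets <- lapply(scheduleWindows(schedule), function(w)
        buildNetwork(panel, group, w, stringency = stringency,
                     min_pairs = min_pairs, transform = transform))
    ne <- vapply(nets, function(x) nrow(x@edges), 1L)
    usable <- vapply(nets, function(x)
        any(!is.na(windowMatrix(panel, x@window, group))), TRUE)
    if (any(!usable))
        warning(sprintf("%d window(s) without observations for group %s",
                        sum(!usable), group))
    out <- data.frame(group = group, window = schedule$label, edges = ne,
                      complexity = vapply(nets, networkComplexity, 1.0))
    if (networks) attr(out, "networks") <- nets
    out
}

#' Total number of network connections for one group
#'
#' Sums edge counts over all time windows of a group: the summary used to
#' rank cohort sub-groups by overall dynamic network connectivity.
#'
#' @param x a complexity trajectory data.frame from
#'   [complexityTrajectory()], or a list of \linkS4class{DynaNetwork}
#'   objects for one group.
#' @return integer(1).
#' @export
totalConnections <- function(x) {
    if (is.data.frame(x)) {
        stopifnot("edges" %in% colnames(x))
        if (length(unique(x$group)) > 1L)
            stop("trajectories of several groups; total is per group")
        return(as.integer(sum(x$edges)))
    }
    stopifnot(is.list(x), all(vapply(x, is, TRUE, "DynaNetwork")))
    if (length(x) && length(unique(vapply(x, slot, "", "group"))) > 1L)
        stop("networks of several groups; total is per group")
    as.integer(sum(vapply(x, function(n) nrow(n@edges), 1L)))
}

#' Negative-edge accounting across a condition's windows
#'
#' Counts signed edges over all windows of one condition and reports the
#' fraction of negative (anti-correlated) connections. When there are no
#' edges at all the fraction is reported as 0 with `undefined = TRUE`.
#'
#' @param networks list of \linkS4class{DynaNetwork} objects (one
#'   condition), or a single network.
#' @return list with `negatives`, `total`, `fraction`, `undefined`.
#' @examples
#' # 2 negative of 8 edges -> 25%
#' @export
negativeFraction <- function(networks) {
    if (is(networks, "DynaNetwork")) networks <- list(networks)
    stopifnot(all(vapply(networks, is, TRUE, "DynaNetwork")))
    signs <- unlist(lapply(networks, function(n) n@edges$sign))
    total <- length(signs)
    neg <- sum(signs == "-")
    list(negatives = as.integer(neg), total = as.integer(total),
         fraction = if (total == 0L) 0 else neg / total,
         undefined = total == 0L)
}

#' Subnetwork of connections involving one mediator
#'
#' Restricts a window network to the edges incident to a single mediator
#' (e.g. the HMGB1-focused view of each window). The node set is unchanged;
#' only edges touching the mediator are kept.
#'
#' @param net a \linkS4class{DynaNetwork}.
#' @param mediator mediator name (must be a node).
#' @return a \linkS4class{DynaNetwork}.
#' @export
focusSubnetwork <- function(net, mediator) {
    if (!mediator %in% net@mediators)
        stop("mediator not in network: ", mediator)
    e <- net@edges
    e <- e[e$a == mediator | e$b == mediator, , drop = FALSE]
    DynaNetwork(net@mediators, e, window = net@window, group = net@group,
                stringency = net@stringency)
}

#' Write window networks as a flat edge list
#'
#' CSV columns: `group`, `window`, `mediator_a`, `mediator_b`, `r`, `sign`,
#' `n_pairs`, with `mediator_a < mediator_b` lexicographically.
#' `writeSif()` emits a SIF file (`node relation node`, relations `pp`/`pn`
#' for positive/negative) for graph viewers.
#'
#' @param networks list of \linkS4class{DynaNetwork} objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(networks, path) {
    if (is(networks, "DynaNetwork")) networks <- list(networks)
    rows <- lapply(networks, function(n) {
        e <- n@edges
        if (!nrow(e))
            return(data.frame(group = character(), window = character(),
                              mediator_a = character(),
                              mediator_b = character(), r = numeric(),
                              sign = character(), n_pairs = integer()))
        data.frame(group = n@group, window = n@window$label,
                   mediator_a = e$a, mediator_b = e$b, r = e$r,
                   sign = e$sign, n_pairs = e$n_pairs)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeSif <- function(networks, path) {
    if (is(networks, "DynaNetwork")) networks <- list(networks)
    lines <- unlist(lapply(networks, function(n) {
        e <- n@edges
        if (!nrow(e)) return(character())
        sprintf("%s\t%s\t%s", e$a, ifelse(e$sign == "+", "pp", "pn"), e$b)
    }))
    writeLines(lines, path)
    invisible(path)
}
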