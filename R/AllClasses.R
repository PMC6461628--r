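#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' MediatorPanel: a longitudinal multiplex mediator panel
#'
#' The central container of the package: one assay matrix of mediator
#' concentrations (rows = mediators, columns = samples, i.e. one
#' subject at one time point), with per-sample `subject`, `time` and `group`
#' annotation in `colData`. Concentrations are non-negative reals
#' (pg/ml for cytokines and chemokines, µM for nitrite/nitrate); missing
#' measurements are stored as `NA`, never imputed. The measurement time unit
#' (`"day"` or `"hour"`) lives in `metadata(x)$time_unit`.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}; the single
#'   assay is named `"conc"`.
#' @seealso [MediatorPanel()] for construction, [loadPanel()] to read CSV.
#' @export
setClass("MediatorPanel", contains = "SummarizedExperiment")

.validMediatorPanel <- function(object) {
    msg <- NULL
    if (!"conc" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'conc' is required")
    med <- rownames(object)
    if (is.null(med) || anyDuplicated(med))
        msg <- c(msg, "mediator names must be present and unique")
    cd <- colData(object)
    for (f in c("subject", "time", "group"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData field '%s' is required", f))
    if (is.null(msg)) {
        if (!is.numeric(cd$time) || any(!is.finite(cd$time)))
            msg <- c(msg, "time must be finite numeric")
        if (any(is.na(cd$group)) || any(is.na(cd$subject)))
            msg <- c(msg, "every sample needs a subject and a group label")
        key <- paste(cd$subject, cd$time, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (subject, time) samples")
        byS <- split(as.character(cd$group), as.character(cd$subject))
        if (any(vapply(byS, function(g) length(unique(g)), 1L) > 1L))
            msg <- c(msg, "a subject cannot belong to two groups")
        v <- assay(object, "conc")
        if (any(v[!is.na(v)] < 0))
            msg <- c(msg, "concentrations must be >= 0 or NA")
        tu <- metadata(object)$time_unit
        if (is.null(tu) || !tu %in% c("day", "hour"))
            msg <- c(msg, "metadata time_unit must be 'day' or 'hour'")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MediatorPanel", .validMediatorPanel)

#' Construct a MediatorPanel
#'
#' @param conc numeric matrix, mediators in rows (rownames mandatory),
#'   samples in columns. Values are concentrations; `NA` marks a missing
#'   measurement.
#' @param subject character vector, one entry per column of `conc`.
#' @param time numeric vector of measurement times, one per column.
#' @param group group label per column; must be constant within a subject.
#' @param time_unit `"day"` or `"hour"`.
#' @return a validated \linkS4class{MediatorPanel}.
#' @examples
#' m <- matrix(rexp(12, 1 / 100), nrow = 3,
#'             dimnames = list(c("IL-6", "IL-8", "HMGB1"), NULL))
#' p <- MediatorPanel(m, subject = rep(c("s1", "s2"), each = 2),
#'                    time = rep(0:1, 2), group = "ctrl")
#' @export
MediatorPanel <- function(conc, subject, time, group, time_unit = "day") {
    conc <- as.matrix(conc)
    storage.mode(conc) <- "double"
    n <- ncol(conc)
    cd <- DataFrame(subject = as.character(rep_len(subject, n)),
                    time = as.numeric(rep_len(time, n)),
                    group = as.character(rep_len(group, n)))
    colnames(conc) <- paste(cd$subject, cd$time, sep = "@")
    se <- SummarizedExperiment(assays = list(conc = conc), colData = cd)
    metadata(se)$time_unit <- time_unit
    new("MediatorPanel", se)
}

#' DynaNetwork: one time window's signed correlation network
#'
#' An undirected graph over the assayed mediators for a single time window:
#' an edge links two mediators whose pooled within-window Pearson correlation
#' satisfies `|r| >= stringency`, signed by the sign of `r`. Degrees of this
#' graph feed the network complexity statistic.
#'
#' @slot mediators character, the node set (all assayed mediators, connected
#'   or not).
#' @slot edges data.frame with columns `a`, `b` (mediator names, `a < b`
#'   lexicographically), `r`, `sign` (`"+"`/`"-"`), `n_pairs` (complete
#'   observation pairs used).
#' @slot window list with `label`, `start`, `end`.
#' @slot group character(1), the cohort sub-group the network belongs to.
#' @slot stringency numeric(1), the correlation-magnitude threshold.
#' @export
setClass("DynaNetwork",
    representation(mediators = "character", edges = "data.frame",
                   window = "list", group = "character",
                   stringency = "numeric"))

.validDynaNetwork <- function(object) {
    msg <- NULL
    e <- object@edges
    need <- c("a", "b", "r", "sign", "n_pairs")
    if (!all(need %in% colnames(e)))
        return(sprintf("edges needs columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(object@mediators))
        msg <- c(msg, "duplicate mediator names")
    if (nrow(e)) {
        if (any(e$a == e$b)) msg <- c(msg, "self-edges are not allowed")
        if (any(e$a > e$b)) msg <- c(msg, "edges must satisfy a < b")
        if (anyDuplicated(paste(e$a, e$b, sep = "\r")))
            msg <- c(msg, "duplicate edges")
        if (!all(c(e$a, e$b) %in% object@mediators))
            msg <- c(msg, "edge endpoints must be listed mediators")
        if (any(abs(e$r) < object@stringency - 1e-12))
            msg <- c(msg, "edge |r| below stringency")
        if (any(e$sign != ifelse(e$r >= 0, "+", "-")))
            msg <- c(msg, "edge sign must match sign(r)")
    }
    w <- object@window
    if (!all(c("label", "start", "end") %in% names(w)) ||
        !(w$start < w$end))
        msg <- c(msg, "window must have label and start < end")
    if (is.null(msg)) TRUE else msg
}
setValidity("DynaNetwork", .validDynaNetwork)

#' Construct a DynaNetwork from an explicit edge table
#'
#' Mostly internal; analyses create networks with [buildNetwork()].
#' @param mediators node set.
#' @param edges data.frame (`a`,`b`,`r`,`sign`,`n_pairs`); zero-row allowed.
#' @param window a [timeWindow()] (or list with label/start/end).
#' @param group sub-group label.
#' @param stringency threshold the edges satisfy.
#' @export
DynaNetwork <- function(mediators, edges = NULL,
                        window = timeWindow("w", 0, 1),
                        group = "all", stringency = 0.7) {
    if (is.null(edges) || nrow(edges) == 0L)
        edges <- data.frame(a = character(), b = character(),
                            r = numeric(), sign = character(),
                            n_pairs = integer())
    else {
        swap <- edges$a > edges$b
        tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]
        edges$b[swap] <- tmp
        edges <- edges[order(edges$a, edges$b), , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("DynaNetwork", mediators = as.character(mediators), edges = edges,
        window = as.list(window[c("label", "start", "end")]),
        group = group, stringency = stringency)
}

#' DbnModel: a first-order dynamic Bayesian network over mediators
#'
#' Directed edges run from a mediator's discretized level at time t-1
#' (parent) to a mediator's level at time t (child); self-loops
#' (`parent == child`) encode self-feedback and mark central nodes.
#'
#' @slot mediators node set.
#' @slot edges data.frame with columns `parent`, `child`, `confidence`
#'   (bootstrap support in [0,1]; `NA` until [edgeConfidence()] is run).
#' @slot score numeric(1), total log marginal-likelihood (BDeu) of the
#'   structure on the transition table it was learned from.
#' @slot config list: levels, max_parents, restarts, seed, ess.
#' @export
setClass("DbnModel",
    representation(mediators = "character", edges = "data.frame",
                   score = "numeric", config = "list"))

.validDbnModel <- function(object) {
    msg <- NULL
    e <- object@edges
    if (!all(c("parent", "child", "confidence") %in% colnames(e)))
        return("edges needs columns parent, child, confidence")
    if (nrow(e)) {
        if (!all(c(e$parent, e$child) %in% object@mediators))
            msg <- c(msg, "edge endpoints must be listed mediators")
        if (anyDuplicated(paste(e$parent, e$child, sep = "\r")))
            msg <- c(msg, "duplicate directed edges")
        conf <- e$confidence[!is.na(e$confidence)]
        if (length(conf) && (any(conf < 0) || any(conf > 1)))
            msg <- c(msg, "confidence must lie in [0, 1]")
        mp <- object@config$max_parents
        if (!is.null(mp) && any(table(e$child) > mp))
            msg <- c(msg, "a child exceeds max_parents")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("DbnModel", .validDbnModel)

#' SyntheticCohort: a generated panel plus its ground truth
#'
#' @slot panel the generated \linkS4class{MediatorPanel}.
#' @slot truth per-group list: signed adjacency matrix (column drives row at
#'   the next time step), self-feedback hub set, optional per-window
#'   adjacency overrides.
#' @slot spec the generator specification (see [syntheticSpec()]).
#' @slot seed integer seed the cohort was generated from.
#' @export
setClass("SyntheticCohort",
    representation(panel = "MediatorPanel", truth = "list", spec = "list",
                   seed = "integer"))
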