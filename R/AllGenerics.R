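#' @rdname MediatorPanel-accessors
#' @export
setGeneric("mediators", function(x) standardGeneric("mediators"))

#' @rdname MediatorPanel-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname MediatorPanel-accessors
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' @rdname MediatorPanel-accessors
#' @export
setGeneric("timeUnit", function(x) standardGeneric("timeUnit"))

#' @rdname DynaNetwork-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname DynaNetwork-accessors
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' Accessors for MediatorPanel
#'
#' `mediators()` returns the assayed mediator names; `subjects()` the unique
#' subject identifiers; `subjectGroups()` a named character vector mapping
#' subject to group label; `timeUnit()` `"day"` or `"hour"`;
#' `concentrations()` the assay matrix (mediators x samples).
#'
#' @param x a \linkS4class{MediatorPanel}.
#' @name MediatorPanel-accessors
#' @aliases mediators subjects subjectGroups timeUnit concentrations
NULL

#' @rdname MediatorPanel-accessors
#' @export
setMethod("mediators", "MediatorPanel", function(x) rownames(x))

#' @rdname MediatorPanel-accessors
#' @export
setMethod("subjects", "MediatorPanel",
          function(x) unique(colData(x)$subject))

#' @rdname MediatorPanel-accessors
#' @export
setMethod("subjectGroups", "MediatorPanel", function(x) {
    cd <- colData(x)
    g <- vapply(split(as.character(cd$group), cd$subject), `[`, "", 1L)
    g[unique(cd$subject)]
})

#' @rdname MediatorPanel-accessors
#' @export
setMethod("timeUnit", "MediatorPanel",
          function(x) metadata(x)$time_unit)

#' @rdname MediatorPanel-accessors
#' @export
concentrations <- function(x) assay(x, "conc")

#' @rdname DynaNetwork-accessors
#' @export
setMethod("mediators", "DynaNetwork", function(x) x@mediators)

#' Accessors for DynaNetwork and DbnModel
#'
#' `edges()` returns the edge table; `degrees()` the per-mediator connection
#' count of a window network (every listed mediator appears, isolated nodes
#' with degree 0).
#'
#' @param x a \linkS4class{DynaNetwork} or \linkS4class{DbnModel}.
#' @name DynaNetwork-accessors
#' @aliases edges degrees
NULL

#' @rdname DynaNetwork-accessors
#' @export
setMethod("edges", "DynaNetwork", function(x) x@edges)

#' @rdname DynaNetwork-accessors
#' @export
setMethod("edges", "DbnModel", function(x) x@edges)

#' @rdname DynaNetwork-accessors
#' @export
setMethod("degrees", "DynaNetwork", function(x) {
    d <- structure(integer(length(x@mediators)), names = x@mediators)
    if (nrow(x@edges)) {
        tab <- table(c(x@edges$a, x@edges$b))
        d[names(tab)] <- as.integer(tab)
    }
    d
})

#' @rdname DynaNetwork-accessors
#' @export
setMethod("mediators", "DbnModel", function(x) x@mediators)

#' @rdname SyntheticCohort-accessors
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' Accessors for SyntheticCohort
#'
#' `panel()` extracts the generated \linkS4class{MediatorPanel};
#' `truthAdjacency()` the planted signed adjacency for one group;
#' `truthSelfLoops()` the planted self-feedback hubs.
#'
#' @param x a \linkS4class{SyntheticCohort}.
#' @param group group name.
#' @name SyntheticCohort-accessors
NULL

#' @rdname SyntheticCohort-accessors
#' @export
setMethod("panel", "SyntheticCohort", function(x) x@panel)

#' @rdname SyntheticCohort-accessors
#' @export
truthAdjacency <- function(x, group) x@truth[[group]]$adjacency

#' @rdname SyntheticCohort-accessors
#' @export
truthSelfLoops <- function(x, group) x@truth[[group]]$self_loops

setMethod("show", "MediatorPanel", function(object) {
    cd <- colData(object)
    cat(sprintf(
        "MediatorPanel: %d mediators, %d samples, %d subjects, %d groups\n",
        nrow(object), ncol(object), length(unique(cd$subject)),
        length(unique(cd$group))))
    cat(sprintf("  time: %s %s..%s | missing cells: %d\n",
        timeUnit(object), min(cd$time), max(cd$time),
        sum(is.na(assay(object, "conc")))))
})

setMethod("show", "DynaNetwork", function(object) {
    e <- object@edges
    cat(sprintf(
        "DynaNetwork [%s, group %s]: %d mediators, %d edges (%d negative), |r| >= %g\n",
        object@window$label, object@group, length(object@mediators),
        nrow(e), sum(e$sign == "-"), object@stringency))
})

setMethod("show", "DbnModel", function(object) {
    e <- object@edges
    cat(sprintf(
        "DbnModel: %d mediators, %d edges (%d self-loops), score %.3f\n",
        length(object@mediators), nrow(e),
        sum(e$parent == e$child), object@score))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf("SyntheticCohort (seed %d):\n", object@seed))
    show(object@panel)
})
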