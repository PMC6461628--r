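#' Time windows and window schedules
#'
#' A time window is a closed interval `[start, end]` on the panel's time
#' axis. Windows in a schedule are consecutive and share endpoints, and a
#' sample taken exactly on a shared endpoint (e.g. day 1 for windows d0-d1
#' and d1-2) contributes to both adjacent windows — with sparse daily
#' sampling this maximizes the observations available to each window.
#'
#' `dailySchedule()` returns the seven consecutive one-day windows d0-d1
#' through d6-d7 used for daily serum sampling; `hourSchedule()` the three
#' consecutive windows 1-3 h, 3-6 h and 6-24 h used for supernatant
#' sampling at 1, 3, 6 and 24 h.
#'
#' @param label window name, e.g. `"d1-2"`.
#' @param start,end window bounds, `start < end`, in the panel's time unit.
#' @return `timeWindow()`: a list with `label`, `start`, `end`;
#'   the schedule builders: a data.frame with those columns, one row per
#'   window, in temporal order.
#' @examples
#' dailySchedule()
#' timeWindow("d2-3", 2, 3)
#' @export
timeWindow <- function(label, start, end) {
    stopifnot(is.numeric(start), is.numeric(end), start < end)
    list(label = as.character(label), start = start, end = end)
}

#' @rdname timeWindow
#' @export
dailySchedule <- function() {
    data.frame(label = c("d0-d1", "d1-2", "d2-3", "d3-4", "d4-5", "d5-6",
                         "d6-7"),
               start = 0:6, end = 1:7)
}

#' @rdname timeWindow
#' @export
hourSchedule <- function() {
    data.frame(label = c("1-3h", "3-6h", "6-24h"),
               start = c(1, 3, 6), end = c(3, 6, 24))
}

# coerce a one-row schedule slice or a timeWindow() list to a window list
asWindow <- function(w) {
    if (is.data.frame(w)) {
        stopifnot(nrow(w) == 1L)
        w <- as.list(w)
    }
    stopifnot(all(c("label", "start", "end") %in% names(w)),
              w$start < w$end)
    w[c("label", "start", "end")]
}

# iterate a schedule data.frame as a list of windows
scheduleWindows <- function(schedule) {
    lapply(seq_len(nrow(schedule)), function(i) asWindow(schedule[i, ]))
}

#' Extract the observations falling inside a time window
#'
#' Returns the long-format observations of a panel whose time `t` satisfies
#' `start <= t <= end` (both endpoints included). Ordering is deterministic:
#' by subject, then time, then mediator (panel order).
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param window a [timeWindow()] or one-row schedule slice.
#' @param group optional group label; restricts to that group's subjects.
#' @param drop_missing drop rows whose value is `NA` (default `FALSE`).
#' @return data.frame with columns `subject`, `time`, `mediator`, `value`,
#'   `group`.
#' @export
windowObservations <- function(panel, window, group = NULL,
                               drop_missing = FALSE) {
    w <- asWindow(window)
    cd <- colData(panel)
    keep <- cd$time >= w$start & cd$time <= w$end
    if (!is.null(group)) {
        if (!group %in% cd$group)
            stop("unknown group: ", group)
        keep <- keep & cd$group == group
    }
    idx <- which(keep)
    idx <- idx[order(cd$subject[idx], cd$time[idx])]
    v <- assay(panel, "conc")[, idx, drop = FALSE]
    out <- data.frame(
        subject = rep(cd$subject[idx], each = nrow(panel)),
        time = rep(cd$time[idx], each = nrow(panel)),
        mediator = rep(rownames(panel), times = length(idx)),
        value = as.vector(v),
        group = rep(as.character(cd$group[idx]), each = nrow(panel)))
    if (drop_missing) out <- out[!is.na(out$value), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# wide matrix of pooled observations in a window: rows = (subject,time)
# samples of the group, columns = mediators; NAs preserved
windowMatrix <- function(panel, window, group = NULL) {
    w <- asWindow(window)
    cd <- colData(panel)
    keep <- cd$time >= w$start & cd$time <= w$end
    if (!is.null(group)) {
        if (!group %in% cd$group)
            stop("unknown group: ", group)
        keep <- keep & cd$group == group
    }
    idx <- which(keep)
    idx <- idx[order(cd$subject[idx], cd$time[idx])]
    t(assay(panel, "conc")[, idx, drop = FALSE])
}
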