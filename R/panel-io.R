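#' Read a mediator panel from CSV
#'
#' Two dialects are supported. `layout = "long"`: columns `subject`, `time`,
#' `mediator`, `value`, `group`, one row per measurement. `layout = "wide"`:
#' columns `subject`, `time`, `group`, then one column per mediator, one row
#' per (subject, time) sample. Cells that fail numeric parsing (and blank
#' cells) become explicit `NA` missing values and are counted in the load
#' report attached as `metadata(panel)$load_report` and emitted as a
#' message.
#'
#' @param path CSV file, UTF-8, header row mandatory.
#' @param layout `"wide"` or `"long"`.
#' @param time_unit `"day"` or `"hour"`.
#' @param verbose emit the load report as a message.
#' @return a validated \linkS4class{MediatorPanel}.
#' @section Errors: a duplicated (subject, time, mediator) triple aborts,
#'   naming the offending triple.
#' @export
loadPanel <- function(path, layout = c("wide", "long"), time_unit = "day",
                      verbose = TRUE) {
    layout <- match.arg(layout)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
    if (layout == "long") {
        need <- c("subject", "time", "mediator", "value", "group")
        if (!all(need %in% colnames(raw)))
            stop("long layout needs columns ", paste(need, collapse = ", "))
        long <- raw[, need]
    } else {
        need <- c("subject", "time", "group")
        if (!all(need %in% colnames(raw)))
            stop("wide layout needs columns ", paste(need, collapse = ", "))
        meds <- setdiff(colnames(raw), need)
        if (!length(meds)) stop("wide layout has no mediator columns")
        long <- data.frame(
            subject = rep(raw$subject, times = length(meds)),
            time = rep(raw$time, times = length(meds)),
            mediator = rep(meds, each = nrow(raw)),
            value = unlist(raw[meds], use.names = FALSE),
            group = rep(raw$group, times = length(meds)))
    }
    long$time <- as.numeric(long$time)
    if (any(is.na(long$time))) stop("unparseable time values")
    key <- paste(long$subject, long$time, long$mediator, sep = " / ")
    if (anyDuplicated(key))
        stop("duplicate (subject, time, mediator) triple: ",
             key[duplicated(key)][1L])
    val <- suppressWarnings(as.numeric(long$value))
    n_bad <- sum(is.na(val) & !is.na(long$value) &
                 nzchar(trimws(long$value)))
    mediators <- unique(long$mediator)
    sampKey <- paste(long$subject, long$time, sep = "@")
    samples <- unique(sampKey)
    conc <- matrix(NA_real_, nrow = length(mediators),
                   ncol = length(samples),
                   dimnames = list(mediators, samples))
    conc[cbind(match(long$mediator, mediators), match(sampKey, samples))] <-
        val
    first <- !duplicated(sampKey)
    p <- MediatorPanel(conc,
                       subject = long$subject[first],
                       time = long$time[first],
                       group = long$group[first],
                       time_unit = time_unit)
    report <- list(rows = nrow(raw), samples = length(samples),
                   subjects = length(subjects(p)),
                   mediators = length(mediators),
                   missing_cells = sum(is.na(assay(p, "conc"))),
                   unparseable_cells = n_bad)
    metadata(p)$load_report <- report
    dnMessage(
        "loadPanel: %d rows -> %d subjects x %d mediators, %d samples, %d missing (%d unparseable)",
        report$rows, report$subjects, report$mediators, report$samples,
        report$missing_cells, n_bad, verbose = verbose)
    p
}

#' Write a mediator panel to CSV
#'
#' Inverse of [loadPanel()]: the written file reloads to an identical panel
#' (values, labels and mediator order round-trip exactly).
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    cd <- colData(panel)
    v <- assay(panel, "conc")
    if (layout == "wide") {
        out <- data.frame(subject = cd$subject, time = cd$time,
                          group = cd$group, check.names = FALSE)
        out <- cbind(out, as.data.frame(t(v), check.names = FALSE))
    } else {
        out <- windowObservations(
            panel, timeWindow("all", min(cd$time) - 1, max(cd$time) + 1))
        out <- out[, c("subject", "time", "mediator", "value", "group")]
    }
    utils::write.csv(out, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Keep only subjects sampled at enough distinct time points
#'
#' Retains subjects with at least `min_times` distinct time points at which
#' at least one mediator was measured (non-missing). The default of 3
#' mirrors the usual longitudinal inclusion rule of at least three daily
#' samples per subject. Idempotent; an empty result is legal and reported.
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param min_times integer >= 1.
#' @param verbose report retained/dropped counts.
#' @return the filtered panel (group labels preserved).
#' @export
filterMinSamples <- function(panel, min_times = 3L, verbose = TRUE) {
    stopifnot(min_times >= 1L)
    cd <- colData(panel)
    informative <- colSums(!is.na(assay(panel, "conc"))) > 0L
    nt <- tapply(cd$time[informative], cd$subject[informative],
                 function(t) length(unique(t)))
    keepSubj <- names(nt)[nt >= min_times]
    out <- panel[, cd$subject %in% keepSubj]
    dnMessage("filterMinSamples: %d of %d subjects retained (>= %d times)",
              length(keepSubj), length(unique(cd$subject)), min_times,
              verbose = verbose)
    out
}

#' Background-correct one mediator
#'
#' Subtracts the mean of a set of blank (background) measurements from every
#' observation of a single mediator, clamping results at zero. Used e.g.
#' when culture medium itself contains measurable HMGB1 that must be
#' removed before network analysis. Other mediators are untouched; missing
#' values stay missing.
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param mediator mediator name (must exist).
#' @param blank_values non-empty numeric vector of blank measurements.
#' @return the corrected panel.
#' @export
backgroundCorrect <- function(panel, mediator, blank_values) {
    if (!mediator %in% rownames(panel))
        stop("mediator not in panel: ", mediator)
    stopifnot(length(blank_values) >= 1L, is.numeric(blank_values))
    bg <- mean(blank_values)
    v <- assay(panel, "conc")
    v[mediator, ] <- pmax(v[mediator, ] - bg, 0)
    SummarizedExperiment::assay(panel, "conc") <- v
    panel
}

#' Restrict a panel to one group's subjects
#'
#' @param panel a \linkS4class{MediatorPanel}.
#' @param group group label (must exist).
#' @return the sub-panel.
#' @export
subsetGroup <- function(panel, group) {
    cd <- colData(panel)
    if (!group %in% cd$group) stop("unknown group: ", group)
    panel[, cd$group == group]
}
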