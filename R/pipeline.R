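#' Configure a full analysis run
#'
#' Collects every knob of the end-to-end pipeline. Exactly one of `input`
#' (a CSV readable by [loadPanel()]) or `preset` (`"human"` / `"mouse"`,
#' see [cohortPresets()]) must be given. All randomness in a run — synthetic
#' generation, DBN restarts, bootstrap — is derived from the single `seed`,
#' so any stage can be re-run in isolation reproducibly.
#'
#' @param input path to a panel CSV, or `NULL`.
#' @param layout CSV dialect for `input` (`"wide"`/`"long"`).
#' @param preset synthetic preset name, or `NULL`.
#' @param schedule `"daily"`, `"hours"`, or a custom schedule data.frame.
#' @param time_unit time unit when loading `input`.
#' @param stringency DyNA correlation threshold (default 0.7).
#' @param min_pairs minimum complete pairs per DyNA edge (default 4).
#' @param min_times subject inclusion: minimum sampled times (default 3).
#' @param focus mediator for the focused subnetwork report (default
#'   `"HMGB1"`; `NULL` skips).
#' @param transform correlation scale, `"identity"` or `"log10"`.
#' @param dbn list of DBN settings: `levels`, `max_parents`, `restarts`,
#'   `n_boot`; set `n_boot = 0` to skip the bootstrap, or `run_dbn = FALSE`
#'   to skip DBN inference entirely.
#' @param seed master seed.
#' @param outdir output directory.
#' @param verbose stage-by-stage log lines.
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(input = NULL, layout = "wide", preset = NULL,
                      schedule = "daily", time_unit = "day",
                      stringency = 0.7, min_pairs = 4L, min_times = 3L,
                      focus = "HMGB1",
                      transform = c("identity", "log10"),
                      dbn = list(), seed = 1L, outdir = tempfile("dynanet_"),
                      verbose = TRUE) {
    transform <- match.arg(transform)
    if (is.null(input) == is.null(preset))
        stop("give exactly one of 'input' or 'preset'")
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("human", "mouse"))
        if (identical(schedule, "daily") && preset == "mouse")
            schedule <- "hours"
    }
    if (is.character(schedule))
        schedule <- switch(match.arg(schedule, c("daily", "hours")),
                           daily = dailySchedule(), hours = hourSchedule())
    stopifnot(is.data.frame(schedule),
              all(c("label", "start", "end") %in% colnames(schedule)),
              stringency > 0, stringency <= 1, min_pairs >= 2L,
              min_times >= 1L)
    dbn_defaults <- list(run_dbn = TRUE, levels = 3L, max_parents = 3L,
                         restarts = 5L, n_boot = 20L, ess = 1,
                         step = 1, gap_tolerant = FALSE,
                         min_confidence = 0.5)
    # hour grids are unevenly spaced; let adjacent samples form transitions
    if (identical(preset, "mouse") && is.null(dbn$gap_tolerant))
        dbn_defaults$gap_tolerant <- TRUE
    dbn <- utils::modifyList(dbn_defaults, dbn)
    structure(list(input = input, layout = layout, preset = preset,
                   schedule = schedule, time_unit = time_unit,
                   stringency = stringency, min_pairs = as.integer(min_pairs),
                   min_times = as.integer(min_times), focus = focus,
                   transform = transform, dbn = dbn,
                   seed = as.integer(seed), outdir = outdir,
                   verbose = isTRUE(verbose)),
              class = "RunConfig")
}

#' Run the full dynamic-network pipeline
#'
#' Load (or generate) the panel, apply the minimum-samples inclusion rule,
#' then per group: window networks over the schedule, complexity
#' trajectory, connection totals with negative-edge accounting, the focused
#' subnetwork report, and (optionally) DBN structure learning with
#' bootstrap confidence. Writes, under `config$outdir`:
#' `edges_<group>.csv`, `complexity.csv`, `totals.csv`,
#' `focus_<group>.csv`, `dbn_<group>.csv`, and `manifest.json` (config
#' echo, seed, versions, row counts). Rerunning with the same config and
#' seed reproduces every numeric output exactly.
#'
#' @param config a [runConfig()].
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    vb <- config$verbose
    if (!is.null(config$preset)) {
        spec <- cohortPresets()[[config$preset]]
        cohort <- generateCohort(spec, seed = deriveSeed(config$seed, "sim"))
        pan <- panel(cohort)
        dnMessage("simulate: preset '%s' -> %d subjects, %d samples",
                  config$preset, length(subjects(pan)), ncol(pan),
                  verbose = vb)
    } else {
        pan <- loadPanel(config$input, layout = config$layout,
                         time_unit = config$time_unit, verbose = vb)
    }
    pan <- filterMinSamples(pan, config$min_times, verbose = vb)
    if (ncol(pan) == 0L) stop("no subjects left after filtering")
    groups <- unique(colData(pan)$group)
    complexity <- list(); totals <- list(); files <- character()
    dbn_summary <- list()
    for (g in groups) {
        nsub <- sum(subjectGroups(pan) == g)
        if (nsub == 0L) { warning("group ", g, " empty; skipped"); next }
        traj <- complexityTrajectory(pan, g, config$schedule,
                                     stringency = config$stringency,
                                     min_pairs = config$min_pairs,
                                     transform = config$transform)
        nets <- attr(traj, "networks")
        attr(traj, "networks") <- NULL
        complexity[[g]] <- traj
        nf <- negativeFraction(nets)
        totals[[g]] <- data.frame(
            group = g, n_subjects = nsub,
            total_connections = totalConnections(nets),
            negative = nf$negatives, fraction_negative = nf$fraction)
        f <- file.path(config$outdir,
                       sprintf("edges_%s.csv", slugify(g)))
        writeEdgeList(nets, f); files <- c(files, f)
        dnMessage("dyna: group %s -> %d connections (%d negative)",
                  g, totals[[g]]$total_connections, nf$negatives,
                  verbose = vb)
        if (!is.null(config$focus) &&
            config$focus %in% mediators(pan)) {
            sub <- lapply(nets, focusSubnetwork, mediator = config$focus)
            f <- file.path(config$outdir,
                           sprintf("focus_%s.csv", slugify(g)))
            writeEdgeList(sub, f); files <- c(files, f)
        }
        if (isTRUE(config$dbn$run_dbn)) {
            d <- config$dbn
            model <- tryCatch(fitDbn(pan, g, levels = d$levels,
                            max_parents = d$max_parents,
                            restarts = d$restarts,
                            seed = deriveSeed(config$seed, "dbn",
                                              match(g, groups)),
                            ess = d$ess, n_boot = d$n_boot,
                            step = d$step, gap_tolerant = d$gap_tolerant),
                            error = function(e) {
                                warning("dbn skipped for group ", g, ": ",
                                        conditionMessage(e))
                                NULL
                            })
            if (is.null(model)) next
            f <- file.path(config$outdir,
                           sprintf("dbn_%s.csv", slugify(g)))
            writeDbnEdges(model, f); files <- c(files, f)
            central <- selfFeedbackNodes(model, d$min_confidence)
            dbn_summary[[g]] <- list(edges = nrow(edges(model)),
                                     self_loops = sum(
                                         edges(model)$parent ==
                                         edges(model)$child),
                                     central_nodes = central)
            dnMessage("dbn: group %s -> %d edges, central: %s", g,
                      nrow(edges(model)),
                      paste(central, collapse = ", "), verbose = vb)
        }
    }
    complexity <- do.call(rbind, complexity)
    totals <- do.call(rbind, totals)
    rownames(complexity) <- rownames(totals) <- NULL
    fc <- file.path(config$outdir, "complexity.csv")
    ft <- file.path(config$outdir, "totals.csv")
    utils::write.csv(complexity, fc, row.names = FALSE)
    utils::write.csv(totals, ft, row.names = FALSE)
    files <- c(files, fc, ft)
    manifest <- list(
        config = config[setdiff(names(config), "schedule")],
        schedule = config$schedule, seed = config$seed,
        versions = list(dynanet = as.character(
            utils::packageVersion("dynanet")),
            R = paste(R.version$major, R.version$minor, sep = ".")),
        groups = as.list(table(subjectGroups(pan))),
        totals = totals, dbn = dbn_summary,
        files = basename(files))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
}

#' Compare the groups of a finished run
#'
#' Reads `totals.csv` and `complexity.csv` from a run directory (or takes
#' the manifest returned by [runPipeline()]) and tabulates, per group, the
#' total connections, the peak complexity and the window where it occurs,
#' and the negative-edge fraction. Ties for the peak window are reported
#' joined with `"|"`, not broken.
#'
#' @param run a run output directory, or a manifest list.
#' @param write also write `comparison.csv` into the run directory.
#' @return data.frame, one row per group, sorted by total connections
#'   (descending).
#' @export
compareGroups <- function(run, write = TRUE) {
    dir <- if (is.list(run)) run$config$outdir else run
    totals <- utils::read.csv(file.path(dir, "totals.csv"),
                              check.names = FALSE)
    cx <- utils::read.csv(file.path(dir, "complexity.csv"),
                          check.names = FALSE)
    if (length(unique(totals$group)) < 2L)
        stop("compareGroups needs at least 2 groups")
    rows <- lapply(split(cx, cx$group), function(d) {
        peak <- max(d$complexity)
        at <- d$window[abs(d$complexity - peak) < 1e-12]
        data.frame(group = d$group[1L], peak_complexity = peak,
                   peak_window = paste(at, collapse = "|"))
    })
    out <- merge(totals, do.call(rbind, rows), by = "group")
    out <- out[order(-out$total_connections, out$group), ]
    rownames(out) <- NULL
    if (write)
        utils::write.csv(out, file.path(dir, "comparison.csv"),
                         row.names = FALSE)
    out
}
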