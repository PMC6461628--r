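#' Mediator name sets for the two assay designs
#'
#' `humanMediators()`: the 25 analytes of a human 25-plex serum
#' cytokine/chemokine bead panel, plus HMGB1 (ELISA) and the nitric-oxide
#' reaction products NO2-+NO3- (27 in total).
#' `mouseMediators()`: the 20 analytes of a mouse cytokine/chemokine bead
#' panel plus the same two extra assays (22 in total).
#'
#' @return character vector of mediator names.
#' @export
humanMediators <- function() {
    c("Eotaxin", "GM-CSF", "IFN-a2", "IFN-g", "IL-1b", "IL-1RA", "IL-2",
      "sIL-2Ra", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-10",
      "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17A", "IP-10",
      "MCP-1", "MIG", "MIP-1a", "MIP-1b", "TNF-a", "HMGB1", "NO2-+NO3-")
}

#' @rdname humanMediators
#' @export
mouseMediators <- function() {
    c("GM-CSF", "IFN-g", "IL-1a", "IL-1b", "IL-2", "IL-4", "IL-5", "IL-6",
      "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-17", "IP-10", "KC",
      "MCP-1", "MIG", "MIP-1a", "TNF-a", "VEGF", "HMGB1", "NO2-+NO3-")
}

#' Signed coupling matrix from an edge table
#'
#' Builds the square adjacency used by the generator: entry `A[to, from]`
#' is the signed weight with which mediator `from` at time t-1 drives
#' mediator `to` at time t. `self_drive` mediators get `self_weight` on the
#' diagonal, making them persistent self-feedback hubs.
#'
#' @param mediators mediator names (matrix dimnames).
#' @param edges optional data.frame `from`, `to`, `weight` (signed,
#'   magnitude <= 1).
#' @param self_drive mediators given a diagonal self-weight.
#' @param self_weight diagonal weight for `self_drive` (default 0.9).
#' @return m x m numeric matrix.
#' @export
couplingMatrix <- function(mediators, edges = NULL, self_drive = character(),
                           self_weight = 0.9) {
    m <- length(mediators)
    A <- matrix(0, m, m, dimnames = list(mediators, mediators))
    if (!is.null(edges) && nrow(edges)) {
        stopifnot(all(c(edges$from, edges$to) %in% mediators),
                  all(abs(edges$weight) <= 1))
        A[cbind(match(edges$to, mediators), match(edges$from, mediators))] <-
            edges$weight
    }
    stopifnot(all(self_drive %in% mediators))
    diag(A)[match(self_drive, mediators)] <- self_weight
    A
}

#' Specify a synthetic mediator cohort
#'
#' Defines the generative model from which [generateCohort()] draws.
#' Latent per-subject log-concentrations follow a first-order
#' autoregressive system along the sampling grid,
#' \deqn{x_t = A\,x_{t-1} + \varepsilon_t, \qquad
#'       \varepsilon_t \sim N(0, \sigma^2 I),}
#' with the subject's initial state \eqn{x_{t_1} \sim N(0,
#' \texttt{subject\_sd}^2 I)} supplying the between-subject spread that
#' pooled within-window correlations detect. The observed concentration is
#' `baseline * exp(x)` — positive, right-skewed, multiplicative noise, as
#' multiplex immunoassay panels are. Whole (subject, time) samples are
#' deleted with probability `missing_rate`; subjects left with fewer than
#' `min_times` sampled times are redrawn.
#'
#' @param mediators mediator names.
#' @param groups named list; each element a list with `n_subjects`,
#'   optional `adjacency` (from [couplingMatrix()]; default all-zero),
#'   optional `self_drive` hub set (diagonal 0.9 if `adjacency` absent),
#'   optional `window_modifiers`: named list mapping a schedule window
#'   label to a replacement adjacency active for transitions landing in
#'   that window.
#' @param times sampling grid (e.g. `0:7` days or `c(1, 3, 6, 24)` hours).
#' @param time_unit `"day"` or `"hour"`.
#' @param schedule window schedule the modifiers refer to (default
#'   [dailySchedule()] for days, [hourSchedule()] for hours).
#' @param noise_sigma log-scale innovation SD per step (default 0.3).
#' @param subject_sd log-scale SD of the subject's initial state
#'   (default 1).
#' @param baseline per-mediator median concentration, pg/ml (default 100
#'   for all; named vector to vary).
#' @param missing_rate probability a (subject, time) sample is absent, in
#'   [0, 1) (default 0.1).
#' @param min_times minimum sampled times per retained subject (default 3).
#' @return a validated spec (list, class `SyntheticSpec`).
#' @export
syntheticSpec <- function(mediators, groups, times = 0:7,
                          time_unit = c("day", "hour"), schedule = NULL,
                          noise_sigma = 0.3, subject_sd = 1,
                          baseline = 100, missing_rate = 0.1,
                          min_times = 3L) {
    time_unit <- match.arg(time_unit)
    if (is.null(schedule))
        schedule <- if (time_unit == "day") dailySchedule() else
            hourSchedule()
    stopifnot(length(mediators) >= 2L, !anyDuplicated(mediators),
              length(times) >= 2L, !is.unsorted(times),
              noise_sigma >= 0, subject_sd >= 0,
              missing_rate >= 0, missing_rate < 1, min_times >= 1L)
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
        stop("groups must be a named list")
    m <- length(mediators)
    bl <- if (length(baseline) == 1L)
        structure(rep(baseline, m), names = mediators) else baseline
    stopifnot(all(mediators %in% names(bl)), all(bl[mediators] > 0))
    groups <- lapply(groups, function(g) {
        stopifnot(!is.null(g$n_subjects), g$n_subjects >= 1L)
        if (is.null(g$adjacency))
            g$adjacency <- couplingMatrix(mediators,
                                          self_drive = g$self_drive %||%
                                              character())
        stopifnot(identical(dim(g$adjacency), c(m, m)),
                  all(abs(g$adjacency) <= 1))
        dimnames(g$adjacency) <- list(mediators, mediators)
        g$self_drive <- g$self_drive %||%
            mediators[diag(g$adjacency) != 0]
        if (!is.null(g$window_modifiers)) {
            stopifnot(all(names(g$window_modifiers) %in% schedule$label))
            for (w in names(g$window_modifiers))
                stopifnot(identical(dim(g$window_modifiers[[w]]), c(m, m)),
                          all(abs(g$window_modifiers[[w]]) <= 1))
        }
        g
    })
    structure(list(mediators = mediators, groups = groups, times = times,
                   time_unit = time_unit, schedule = schedule,
                   noise_sigma = noise_sigma, subject_sd = subject_sd,
                   baseline = bl[mediators], missing_rate = missing_rate,
                   min_times = as.integer(min_times)),
              class = "SyntheticSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjacency in force for a transition landing at time t (start < t <= end)
.activeAdjacency <- function(g, spec, t) {
    if (!is.null(g$window_modifiers)) {
        sch <- spec$schedule
        for (i in seq_len(nrow(sch))) {
            if (sch$start[i] < t && t <= sch$end[i] &&
                sch$label[i] %in% names(g$window_modifiers))
                return(g$window_modifiers[[sch$label[i]]])
        }
    }
    g$adjacency
}

#' Generate a synthetic cohort with ground truth attached
#'
#' Draws a cohort from a [syntheticSpec()]: bit-identical for identical
#' (spec, seed). The returned \linkS4class{SyntheticCohort} carries, per
#' group, the planted signed adjacency, the self-feedback hub set and any
#' per-window overrides, so network-recovery tests can be scored against
#' the generating truth.
#'
#' @param spec a `SyntheticSpec`.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' co <- generateCohort(examplePlantedSpec(), seed = 1)
#' panel(co)
#' @export
generateCohort <- function(spec, seed = 1L) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    m <- length(spec$mediators)
    Tn <- length(spec$times)
    conc <- list(); subj <- character(); tim <- numeric(); grp <- character()
    withSeed(seed, {
        for (gname in names(spec$groups)) {
            g <- spec$groups[[gname]]
            for (s in seq_len(g$n_subjects)) {
                sid <- sprintf("%s_s%02d", slugify(gname), s)
                for (attempt in seq_len(100L)) {
                    x <- matrix(0, m, Tn)
                    x[, 1L] <- stats::rnorm(m, 0, spec$subject_sd)
                    for (k in seq_len(Tn)[-1L]) {
                        A <- .activeAdjacency(g, spec, spec$times[k])
                        x[, k] <- as.vector(A %*% x[, k - 1L]) +
                            stats::rnorm(m, 0, spec$noise_sigma)
                    }
                    present <- stats::runif(Tn) >= spec$missing_rate
                    if (sum(present) >= spec$min_times) break
                }
                obs <- spec$baseline * exp(x[, present, drop = FALSE])
                conc[[length(conc) + 1L]] <- obs
                subj <- c(subj, rep(sid, sum(present)))
                tim <- c(tim, spec$times[present])
                grp <- c(grp, rep(gname, sum(present)))
            }
        }
    })
    conc <- do.call(cbind, conc)
    rownames(conc) <- spec$mediators
    p <- MediatorPanel(conc, subject = subj, time = tim, group = grp,
                       time_unit = spec$time_unit)
    truth <- lapply(spec$groups, function(g)
        list(adjacency = g$adjacency, self_loops = g$self_drive,
             window_modifiers = g$window_modifiers))
    new("SyntheticCohort", panel = p, truth = truth,
        spec = unclass(spec), seed = as.integer(seed))
}

#' Undirected mediator pairs implied by a planted adjacency
#'
#' The pairs a within-window correlation analysis is expected to connect:
#' directly coupled pairs (a nonzero off-diagonal entry in either
#' direction) plus, optionally, pairs sharing a common driver (two targets
#' of the same parent co-move even though neither drives the other).
#'
#' @param A signed coupling matrix.
#' @param include_common_driver also return sibling pairs (default `TRUE`).
#' @return data.frame `a`, `b` with `a < b`.
#' @export
truthPairs <- function(A, include_common_driver = TRUE) {
    meds <- rownames(A)
    off <- A
    diag(off) <- 0
    pairs <- which(off != 0, arr.ind = TRUE)
    res <- unique(data.frame(
        a = pmin(meds[pairs[, 1L]], meds[pairs[, 2L]]),
        b = pmax(meds[pairs[, 1L]], meds[pairs[, 2L]])))
    if (include_common_driver) {
        for (p in seq_len(ncol(off))) {
            kids <- meds[off[, p] != 0]
            if (length(kids) >= 2L) {
                cmb <- utils::combn(sort(kids), 2L)
                res <- unique(rbind(res, data.frame(a = cmb[1L, ],
                                                    b = cmb[2L, ])))
            }
        }
    }
    res <- res[order(res$a, res$b), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' A small planted-hub spec for examples and validation
#'
#' Eight mediators, one group of 12 subjects sampled daily d0-d7; HMGB1 is
#' a self-feedback hub driving IL-6, IL-8 and IP-10 with coupling 0.9; the
#' remaining four mediators are independent noise.
#'
#' @param n_subjects subjects in the group (default 12).
#' @param coupling hub-to-target weight (default 0.9).
#' @param missing_rate sample dropout probability (default 0.1).
#' @return a `SyntheticSpec`.
#' @export
examplePlantedSpec <- function(n_subjects = 12L, coupling = 0.9,
                               missing_rate = 0.1) {
    meds <- c("HMGB1", "IL-6", "IL-8", "IP-10", "IL-4", "IL-5", "IL-10",
              "TNF-a")
    A <- couplingMatrix(
        meds,
        edges = data.frame(from = "HMGB1", to = c("IL-6", "IL-8", "IP-10"),
                           weight = coupling),
        self_drive = "HMGB1")
    syntheticSpec(meds,
                  groups = list(planted = list(n_subjects = n_subjects,
                                               adjacency = A,
                                               self_drive = "HMGB1")),
                  times = 0:7, time_unit = "day",
                  missing_rate = missing_rate)
}

# planted couplings for the two cohort presets ------------------------------

.presetHumanGroups <- function(meds) {
    hub <- function(targets, w = 0.8)
        data.frame(from = "HMGB1", to = targets, weight = w)
    chain <- function(from, to, w = 0.8)
        data.frame(from = from, to = to, weight = w)
    # moderate planted structure shared by the NAC survivor groups
    survNAC <- couplingMatrix(meds, rbind(
        hub(c("IL-6", "IL-8")),
        chain("IL-6", c("IL-10", "MCP-1")),
        chain("IP-10", "MIG"),
        chain("TNF-a", "IL-1b")), self_drive = "HMGB1")
    # sparsest: the non-APAPo non-NAC survivors, few weak couplings
    survPlain <- couplingMatrix(meds, rbind(
        chain("IL-6", "IL-10", 0.75),
        chain("MCP-1", "MIP-1a", 0.75)), self_drive = character())
    # densest: non-survivors, with an extra burst of coupling at d1-3
    nonsurvBase <- couplingMatrix(meds, rbind(
        hub(c("IL-6", "IL-8", "IP-10", "MCP-1")),
        chain("IL-6", c("IL-10", "IL-1RA")),
        chain("IL-8", "MIP-1a"),
        chain("IP-10", c("MIG", "MCP-1")),
        chain("TNF-a", c("IL-1b", "IFN-g")),
        chain("IL-2", "sIL-2Ra")), self_drive = "HMGB1")
    nonsurvBurst <- couplingMatrix(meds, rbind(
        hub(c("IL-6", "IL-8", "IP-10", "MCP-1", "MIG", "TNF-a"), 0.9),
        chain("IL-6", c("IL-10", "IL-1RA", "IL-1b", "IL-15")),
        chain("IL-8", c("MIP-1a", "MIP-1b")),
        chain("IP-10", c("MIG", "MCP-1")),
        chain("TNF-a", c("IL-1b", "IFN-g", "IL-17A")),
        chain("IL-2", "sIL-2Ra"),
        chain("GM-CSF", "IL-7")), self_drive = "HMGB1")
    list(
        "APAPo+NAC" = list(n_subjects = 13L, adjacency = survNAC,
                           self_drive = "HMGB1"),
        "non-APAPo+NAC" = list(n_subjects = 8L, adjacency = survNAC,
                               self_drive = "HMGB1"),
        "non-APAPo non-NAC" = list(n_subjects = 40L,
                                   adjacency = survPlain),
        "non-survivor" = list(
            n_subjects = 12L, adjacency = nonsurvBase,
            self_drive = "HMGB1",
            window_modifiers = list("d1-2" = nonsurvBurst,
                                    "d2-3" = nonsurvBurst)))
}

.presetMouseGroups <- function(meds) {
    cm <- function(edges, hubs = character())
        couplingMatrix(meds, edges, self_drive = hubs)
    ed <- function(from, to, w)
        data.frame(from = from, to = to, weight = w)
    ctrl <- cm(rbind(ed("IL-6", "IL-10", 0.75), ed("MCP-1", "KC", 0.75)))
    # APAP injury: dense positive coupling radiating from HMGB1
    apap <- cm(rbind(
        ed("HMGB1", c("IL-6", "KC", "MCP-1", "TNF-a", "IP-10"), 0.9),
        ed("IL-6", c("IL-10", "GM-CSF"), 0.85),
        ed("TNF-a", c("IL-1b", "IFN-g"), 0.85),
        ed("MCP-1", "MIP-1a", 0.85),
        ed("IP-10", "MIG", 0.85)), hubs = "HMGB1")
    # NAC alone: light coupling
    nac <- cm(rbind(ed("IL-6", "IL-10", 0.8), ed("MCP-1", "KC", 0.8),
                    ed("TNF-a", "IL-1b", 0.75)))
    # APAP + NAC: moderate, with anti-correlated (negative) couplings as
    # the antidote pushes repair mediators against the injury axis
    apapnac <- cm(rbind(
        ed("HMGB1", c("IL-6", "KC"), 0.85),
        ed("HMGB1", c("IL-10", "IL-13", "VEGF"), -0.85),
        ed("IL-6", "GM-CSF", 0.8),
        ed("TNF-a", "IL-1b", 0.8),
        ed("MCP-1", "MIP-1a", 0.8)), hubs = "HMGB1")
    list(
        "Control" = list(n_subjects = 12L, adjacency = ctrl),
        "APAP" = list(n_subjects = 3L, adjacency = apap,
                      self_drive = "HMGB1"),
        "NAC" = list(n_subjects = 9L, adjacency = nac),
        "APAP+NAC" = list(n_subjects = 3L, adjacency = apapnac,
                          self_drive = "HMGB1"))
}

#' Preset cohort specifications mirroring the two study designs
#'
#' `human`: four patient sub-groups — APAPo+NAC (13 subjects),
#' non-APAPo+NAC (8), non-APAPo non-NAC (40) and non-survivor (12) — on
#' the 27-mediator serum panel sampled daily d0-d7. The non-survivor group
#' carries the densest planted coupling, with an additional coupling burst
#' during d1-3 (emulating an early surge of network connectivity in
#' non-survivors); the non-APAPo non-NAC group carries the sparsest.
#' `mouse`: four in-vitro hepatocyte conditions — Control (12), APAP (3),
#' NAC (9), APAP+NAC (3) — on the 22-mediator supernatant panel sampled at
#' 1, 3, 6 and 24 h. APAP carries dense positive coupling around an HMGB1
#' hub; APAP+NAC mixes in negative couplings so anti-correlated edges
#' appear; the minimum samples per subject is 2 (hour grids are short).
#'
#' @return named list of two `SyntheticSpec` objects, `human` and `mouse`.
#' @export
cohortPresets <- function() {
    hm <- humanMediators()
    mm <- mouseMediators()
    list(
        human = syntheticSpec(hm, .presetHumanGroups(hm), times = 0:7,
                              time_unit = "day", missing_rate = 0.1,
                              min_times = 3L),
        mouse = syntheticSpec(mm, .presetMouseGroups(mm),
                              times = c(1, 3, 6, 24), time_unit = "hour",
                              missing_rate = 0.05, min_times = 2L))
}

#' Write a synthetic cohort's ground truth to CSV
#'
#' One adjacency CSV per group (`truth_<group>.csv`, entries `A[to, from]`)
#' in `dir`.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeTruth <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(cohort@truth), function(g) {
        p <- file.path(dir, sprintf("truth_%s.csv", slugify(g)))
        utils::write.csv(cohort@truth[[g]]$adjacency, p)
        p
    }, "")
    invisible(paths)
}
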