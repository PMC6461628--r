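# fixtures and independent oracles used across test files

# panel from an observations matrix (rows = pooled samples, cols =
# mediators): one synthetic subject per row, all inside window [0, 2]
panelFromObs <- function(obs, group = "g") {
    obs <- as.matrix(obs)
    if (is.null(colnames(obs)))
        colnames(obs) <- paste0("M", seq_len(ncol(obs)))
    MediatorPanel(t(obs),
                  subject = sprintf("s%03d", seq_len(nrow(obs))),
                  time = rep(1, nrow(obs)), group = group)
}

# independent brute-force DyNA oracle: whole-matrix pairwise-complete
# correlation, then threshold/filter; returns sorted a,b,sign
oracleEdges <- function(obs, stringency = 0.7, min_pairs = 4L) {
    obs <- as.matrix(obs)
    meds <- colnames(obs)
    R <- suppressWarnings(stats::cor(obs, use = "pairwise.complete.obs"))
    out <- NULL
    cmb <- utils::combn(seq_along(meds), 2L)
    for (k in seq_len(ncol(cmb))) {
        i <- cmb[1L, k]; j <- cmb[2L, k]
        ok <- stats::complete.cases(obs[, c(i, j)])
        if (sum(ok) < min_pairs) next
        if (length(unique(obs[ok, i])) < 2L ||
            length(unique(obs[ok, j])) < 2L) next
        r <- R[i, j]
        if (is.na(r) || abs(r) < stringency) next
        out <- rbind(out, data.frame(
            a = min(meds[i], meds[j]), b = max(meds[i], meds[j]),
            sign = if (r >= 0) "+" else "-"))
    }
    if (is.null(out))
        out <- data.frame(a = character(), b = character(),
                          sign = character())
    out[order(out$a, out$b), , drop = FALSE]
}

edgeKey <- function(e) sort(paste(e$a, e$b, e$sign))

# random small panel with missingness for fuzz tests (call under a seed)
randomObs <- function(n_obs, n_med, miss = 0.1) {
    obs <- matrix(rlnorm(n_obs * n_med, meanlog = 4, sdlog = 1),
                  n_obs, n_med,
                  dimnames = list(NULL, paste0("M", seq_len(n_med))))
    # plant a few couplings so edges actually occur at threshold
    if (n_med >= 4L && runif(1) < 0.7) {
        obs[, 2L] <- obs[, 1L] * exp(rnorm(n_obs, 0, 0.2))
        if (runif(1) < 0.5)
            obs[, 4L] <- exp(2 * mean(log(obs[, 3L])) - log(obs[, 3L]) +
                             rnorm(n_obs, 0, 0.2))
    }
    obs[matrix(runif(length(obs)) < miss, nrow(obs))] <- NA
    obs
}

# exhaustive DBN family-search oracle: best-scoring parent set by
# enumeration of every subset up to max_parents
oracleParents <- function(child, table, max_parents = 2L, ess = 1) {
    meds <- table$mediators
    best <- list(parents = character(),
                 score = scoreFamily(child, character(), table, ess = ess))
    for (k in seq_len(max_parents)) {
        sets <- utils::combn(meds, k, simplify = FALSE)
        for (ps in sets) {
            s <- scoreFamily(child, ps, table, ess = ess)
            if (s > best$score + 1e-9)
                best <- list(parents = sort(ps), score = s)
        }
    }
    best
}

# AR(1) cohort for DBN tests: mediators with given self-weights and
# directed couplings, n_subjects x times grid, no missingness
arSpec <- function(mediators, edges = NULL, self = character(),
                   n_subjects = 30L, times = 0:10, noise = 0.3,
                   self_weight = 0.9) {
    A <- couplingMatrix(mediators, edges = edges, self_drive = self,
                        self_weight = self_weight)
    syntheticSpec(mediators,
                  groups = list(g = list(n_subjects = n_subjects,
                                         adjacency = A,
                                         self_drive = self)),
                  times = times, time_unit = "day", noise_sigma = noise,
                  missing_rate = 0)
}

transitionsFor <- function(spec, seed, levels = 3L) {
    co <- generateCohort(spec, seed = seed)
    buildTransitions(discretizePanel(panel(co), levels = levels))
}
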