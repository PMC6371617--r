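## Metabolic-module inference: per (sample, phylum) KO detection, step
## coverage, the 1/3 inference threshold, abundance and redundancy classes.

#' Detected KO terms per sample and phylum
#'
#' A KO term is detected for `(sample, phylum)` when at least one microbial
#' protein group with that KO and that phylum is identified in the sample.
#' Human and unassigned groups contribute nothing.
#'
#' @param annotated group annotations from [annotateGroups()].
#' @param identification logical matrix groups x samples from
#'   [identifyGroups()].
#' @return a `data.frame` with columns `sample_id`, `phylum`, `ko_term`,
#'   one row per detected (sample, phylum, KO) triple.
#' @export
detectedKoSets <- function(annotated, identification) {
    stopifnot(identical(as.character(annotated$group_id),
                        rownames(identification)))
    usable <- annotated$category == "microbial" & !is.na(annotated$ko_term)
    out <- list()
    for (s in colnames(identification)) {
        idx <- which(usable & identification[, s])
        if (length(idx) == 0) next
        df <- unique(data.frame(
            sample_id = s,
            phylum = as.character(annotated$phylum[idx]),
            ko_term = as.character(annotated$ko_term[idx]),
            stringsAsFactors = FALSE))
        out[[s]] <- df
    }
    if (length(out) == 0)
        return(data.frame(sample_id = character(0), phylum = character(0),
                          ko_term = character(0), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$sample_id, res$phylum, res$ko_term), , drop = FALSE]
}

#' Module step coverage for a KO set
#'
#' A step is covered when every one of its AND-components has at least one
#' OR-alternative KO present in `koSet`. Coverage is the fraction of covered
#' steps.
#'
#' @param module a single module as returned by `moduleSet[[i]]` (a list
#'   with a `steps` element), or a bare list of steps.
#' @param koSet character vector of detected KO terms.
#' @return coverage fraction in `[0, 1]`.
#' @examples
#' mod <- list(steps = list(list(c("K00001", "K00002")), list("K00003")))
#' computeCoverage(mod, c("K00002"))  # 0.5
#' @export
computeCoverage <- function(module, koSet) {
    steps <- if (!is.null(module$steps)) module$steps else module
    covered <- vapply(steps, function(st)
        all(vapply(st, function(comp) any(comp %in% koSet), logical(1))),
        logical(1))
    sum(covered) / length(covered)
}

#' Infer metabolic modules per sample and phylum
#'
#' A module is inferred for `(sample, phylum)` when the fraction of its
#' enzymatic steps covered by that phylum's detected KO set reaches the
#' threshold (default 1/3, with `>=` comparison, so a 3-step module with one
#' covered step is inferred). Coverage is evaluated within each phylum
#' separately; evidence is never pooled across phyla.
#'
#' @param modules a [ModuleSet].
#' @param detected detection table from [detectedKoSets()].
#' @param threshold coverage threshold in (0, 1]; default `1/3`.
#' @return a `data.frame` of module calls: `sample_id`, `phylum`,
#'   `module_id`, `coverage`, `inferred`, one row per
#'   (sample, phylum, module) for every phylum with any detection in the
#'   sample.
#' @export
inferModules <- function(modules, detected, threshold = 1/3) {
    stopifnot(is(modules, "ModuleSet"))
    .checkThreshold(threshold, "threshold")
    strata <- unique(detected[, c("sample_id", "phylum")])
    if (nrow(strata) == 0)
        return(data.frame(sample_id = character(0), phylum = character(0),
                          module_id = character(0), coverage = numeric(0),
                          inferred = logical(0), stringsAsFactors = FALSE))
    res <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        s <- strata$sample_id[i]; p <- strata$phylum[i]
        koSet <- detected$ko_term[detected$sample_id == s &
                                  detected$phylum == p]
        cov <- vapply(modules@steps, computeCoverage, numeric(1),
                      koSet = koSet)
        data.frame(sample_id = s, phylum = p, module_id = modules@moduleId,
                   coverage = cov, inferred = cov >= threshold,
                   stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    res[order(res$sample_id, res$phylum, res$module_id), , drop = FALSE]
}

#' Quantify module abundance per call
#'
#' For each (sample, phylum, module) call, the groups "mapping to" the
#' module are the microbial groups of that phylum whose KO term appears as
#' any OR-alternative in any step and that are identified in the sample.
#' `abundance_mean` is the mean balanced spectral count of those groups in
#' the sample; `abundance_fraction` is their summed balanced counts divided
#' by the sample's total (retained) spectra. Both are 0 when no group maps.
#'
#' @param calls module calls from [inferModules()].
#' @param modules the [ModuleSet] used for the calls.
#' @param annotated group annotations from [annotateGroups()].
#' @param se balanced-count [SummarizedExperiment::SummarizedExperiment]
#'   from [balanceSpectra()].
#' @param identification logical identification matrix groups x samples.
#' @return `calls` with `abundance_mean` and `abundance_fraction` columns
#'   appended.
#' @export
moduleAbundance <- function(calls, modules, annotated, se, identification) {
    stopifnot(is(modules, "ModuleSet"))
    bal <- SummarizedExperiment::assay(se, "balanced")
    totals <- SummarizedExperiment::colData(se)$total_spectra
    names(totals) <- colnames(se)
    moduleKos <- lapply(moduleSteps(modules), function(st)
        unique(unlist(st, use.names = FALSE)))
    gid <- as.character(annotated$group_id)
    am <- numeric(nrow(calls)); af <- numeric(nrow(calls))
    for (i in seq_len(nrow(calls))) {
        s <- calls$sample_id[i]
        mapIdx <- which(annotated$category == "microbial" &
                        !is.na(annotated$phylum) &
                        annotated$phylum == calls$phylum[i] &
                        !is.na(annotated$ko_term) &
                        annotated$ko_term %in% moduleKos[[calls$module_id[i]]] &
                        identification[, s])
        if (length(mapIdx) == 0) next
        counts <- bal[gid[mapIdx], s]
        am[i] <- mean(counts)
        af[i] <- if (totals[s] > 0) sum(counts) / totals[s] else 0
    }
    calls$abundance_mean <- am
    calls$abundance_fraction <- af
    calls
}

#' Phylum-redundancy classes of inferred modules
#'
#' For each module ever inferred, collects the set of phyla providing
#' inference in any sample and classifies the module: `"single_phylum"`
#' (one phylum only), `"multi_phylum"` (two or more), or `"all_major"`
#' (evidence in all four major gut phyla: Firmicutes, Bacteroidetes,
#' Actinobacteria and Proteobacteria).
#'
#' @param calls module calls from [inferModules()].
#' @return a `data.frame`: `module_id`, `phyla` (semicolon-joined),
#'   `n_phyla`, `class`.
#' @export
redundancyClasses <- function(calls) {
    inf <- calls[calls$inferred, , drop = FALSE]
    if (nrow(inf) == 0)
        return(data.frame(module_id = character(0), phyla = character(0),
                          n_phyla = integer(0), class = character(0),
                          stringsAsFactors = FALSE))
    phylaBy <- split(inf$phylum, inf$module_id)
    phylaBy <- lapply(phylaBy, function(p) sort(unique(p)))
    cls <- vapply(phylaBy, function(p) {
        if (all(.MAJOR_PHYLA %in% p)) "all_major"
        else if (length(p) >= 2) "multi_phylum"
        else "single_phylum"
    }, character(1))
    out <- data.frame(
        module_id = names(phylaBy),
        phyla = vapply(phylaBy, paste, "", collapse = ";"),
        n_phyla = lengths(phylaBy),
        class = cls,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$module_id), , drop = FALSE]
}

#' Phylum-switch events in module evidence across time
#'
#' Detects, per individual and module, consecutive time points whose sets of
#' inferring phyla are both non-empty yet different - the signature of the
#' same metabolic function being carried by different phyla at different
#' times.
#'
#' @param calls module calls from [inferModules()].
#' @param sampleInfo `data.frame` with `sample_id`, `individual_id`, `day`.
#' @return a `data.frame` of switch events: `individual_id`, `module_id`,
#'   `day_from`, `day_to`, `phyla_from`, `phyla_to`.
#' @export
phylumSwitchEvents <- function(calls, sampleInfo) {
    inf <- calls[calls$inferred, , drop = FALSE]
    si <- sampleInfo[order(sampleInfo$individual_id, sampleInfo$day), ,
                     drop = FALSE]
    out <- list()
    for (ind in unique(si$individual_id)) {
        samples <- si[si$individual_id == ind, , drop = FALSE]
        if (nrow(samples) < 2) next
        for (m in unique(inf$module_id)) {
            phySets <- lapply(samples$sample_id, function(s)
                sort(unique(inf$phylum[inf$sample_id == s &
                                       inf$module_id == m])))
            for (t in seq_len(nrow(samples) - 1)) {
                a <- phySets[[t]]; b <- phySets[[t + 1]]
                if (length(a) > 0 && length(b) > 0 && !identical(a, b))
                    out[[length(out) + 1L]] <- data.frame(
                        individual_id = ind, module_id = m,
                        day_from = samples$day[t], day_to = samples$day[t + 1],
                        phyla_from = paste(a, collapse = ";"),
                        phyla_to = paste(b, collapse = ";"),
                        stringsAsFactors = FALSE)
            }
        }
    }
    if (length(out) == 0)
        return(data.frame(individual_id = character(0),
                          module_id = character(0), day_from = integer(0),
                          day_to = integer(0), phyla_from = character(0),
                          phyla_to = character(0), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
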