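## Persistence, functional influence, sample similarity and clustering.

#' Build presence matrices at the three entity levels
#'
#' Derives binary entity x sample presence matrices from pipeline results:
#' protein-group level from the identification matrix (microbial groups
#' only), KO level from per-sample detected KO terms (any phylum), and
#' module level from inferred module calls (any phylum). Entities never
#' observed in any sample are excluded.
#'
#' @param identification logical matrix groups x samples.
#' @param annotated group annotations from [annotateGroups()].
#' @param detected detection table from [detectedKoSets()].
#' @param calls module calls from [inferModules()].
#' @return a named list of three logical matrices: `protein_group`,
#'   `ko_term`, `module`.
#' @export
presenceMatrices <- function(identification, annotated, detected, calls) {
    samples <- colnames(identification)
    microbial <- annotated$category == "microbial"
    pg <- identification[microbial, , drop = FALSE]
    pg <- pg[rowSums(pg) > 0, , drop = FALSE]

    kos <- sort(unique(detected$ko_term))
    ko <- matrix(FALSE, length(kos), length(samples),
                 dimnames = list(kos, samples))
    if (length(kos))
        ko[cbind(match(detected$ko_term, kos),
                 match(detected$sample_id, samples))] <- TRUE

    inf <- calls[calls$inferred, , drop = FALSE]
    mods <- sort(unique(inf$module_id))
    mod <- matrix(FALSE, length(mods), length(samples),
                  dimnames = list(mods, samples))
    if (length(mods))
        mod[cbind(match(inf$module_id, mods),
                  match(inf$sample_id, samples))] <- TRUE

    list(protein_group = pg, ko_term = ko, module = mod)
}

.categorize <- function(nSeen, nTotal) {
    ifelse(nSeen == nTotal, "all",
    ifelse(nSeen > 1L, "multiple_not_all", "single"))
}

#' Within-individual persistence of entities across time points
#'
#' For each individual, every entity observed at least once is assigned to
#' exactly one category: seen at *all* time points, at *more than one but
#' not all*, or at *exactly one*. The three categories partition the
#' observed entities.
#'
#' @param presence logical entity x sample matrix.
#' @param sampleInfo `data.frame` with `sample_id`, `individual_id`, `day`;
#'   every individual needs at least two time points.
#' @return a `data.frame` with one row per individual: counts and fractions
#'   per category plus `n_observed`.
#' @export
persistenceByIndividual <- function(presence, sampleInfo) {
    stopifnot(all(colnames(presence) %in% sampleInfo$sample_id))
    out <- lapply(unique(sampleInfo$individual_id), function(ind) {
        cols <- sampleInfo$sample_id[sampleInfo$individual_id == ind]
        cols <- intersect(colnames(presence), cols)
        if (length(cols) < 2)
            stop("individual ", ind, " has fewer than 2 time points",
                 call. = FALSE)
        sub <- presence[, cols, drop = FALSE]
        nSeen <- rowSums(sub)
        nSeen <- nSeen[nSeen > 0]
        cat3 <- .categorize(nSeen, length(cols))
        n <- length(nSeen)
        data.frame(
            individual_id = ind,
            n_timepoints = length(cols),
            n_observed = n,
            all_timepoints = sum(cat3 == "all"),
            multiple_not_all = sum(cat3 == "multiple_not_all"),
            single = sum(cat3 == "single"),
            frac_all_timepoints = if (n) sum(cat3 == "all") / n else 0,
            frac_multiple_not_all = if (n) sum(cat3 == "multiple_not_all") / n else 0,
            frac_single = if (n) sum(cat3 == "single") / n else 0,
            stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Across-individual persistence of entities
#'
#' Each entity observed in at least one sample is assigned to exactly one
#' category by the number of individuals it was ever observed in: all
#' individuals, more than one but not all, or exactly one.
#'
#' @inheritParams persistenceByIndividual
#' @return a one-row `data.frame` of counts and fractions per category.
#' @export
persistenceAcrossIndividuals <- function(presence, sampleInfo) {
    inds <- unique(sampleInfo$individual_id)
    if (length(inds) < 2)
        stop("at least 2 individuals required", call. = FALSE)
    indOf <- sampleInfo$individual_id[match(colnames(presence),
                                            sampleInfo$sample_id)]
    seenIn <- vapply(seq_len(nrow(presence)), function(i)
        length(unique(indOf[presence[i, ]])), integer(1))
    seenIn <- seenIn[seenIn > 0]
    cat3 <- .categorize(seenIn, length(inds))
    n <- length(seenIn)
    data.frame(
        n_individuals = length(inds),
        n_observed = n,
        all_individuals = sum(cat3 == "all"),
        multiple_not_all = sum(cat3 == "multiple_not_all"),
        single = sum(cat3 == "single"),
        frac_all_individuals = if (n) sum(cat3 == "all") / n else 0,
        frac_multiple_not_all = if (n) sum(cat3 == "multiple_not_all") / n else 0,
        frac_single = if (n) sum(cat3 == "single") / n else 0,
        stringsAsFactors = FALSE)
}

#' Functional influence of each phylum per sample
#'
#' The fraction of KO terms predicted in a sample's protein database that
#' have protein-level evidence in a given phylum: detected KO terms of the
#' (sample, phylum) stratum divided by the size of the database KO universe
#' of the sample's individual.
#'
#' @param detected detection table from [detectedKoSets()].
#' @param koUniverse named list, per individual, of the distinct KO terms
#'   predicted in that individual's protein database.
#' @param sampleInfo `data.frame` with `sample_id`, `individual_id`.
#' @return a `data.frame`: `sample_id`, `phylum`, `n_detected`,
#'   `universe_size`, `influence`.
#' @export
functionalInfluence <- function(detected, koUniverse, sampleInfo) {
    strata <- unique(detected[, c("sample_id", "phylum")])
    out <- lapply(seq_len(nrow(strata)), function(i) {
        s <- strata$sample_id[i]; p <- strata$phylum[i]
        ind <- sampleInfo$individual_id[match(s, sampleInfo$sample_id)]
        universe <- koUniverse[[ind]]
        if (is.null(universe) || length(universe) == 0)
            stop("empty KO universe for individual ", ind, call. = FALSE)
        kos <- unique(detected$ko_term[detected$sample_id == s &
                                       detected$phylum == p])
        if (!all(kos %in% universe))
            stop("detected KO term(s) outside the database universe for ",
                 "sample ", s, call. = FALSE)
        data.frame(sample_id = s, phylum = p, n_detected = length(kos),
                   universe_size = length(universe),
                   influence = length(kos) / length(universe),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        return(data.frame(sample_id = character(0), phylum = character(0),
                          n_detected = integer(0), universe_size = integer(0),
                          influence = numeric(0), stringsAsFactors = FALSE))
    rownames(res) <- NULL
    res[order(res$sample_id, res$phylum), , drop = FALSE]
}

#' Spearman correlation matrix between samples
#'
#' Rank correlation between sample columns of an abundance matrix (rows are
#' the union of entities, absent entities carried as zeros and entering the
#' ranking as ties). Ranks use average tie handling; the diagonal is 1.
#'
#' @param abundance numeric entity x sample matrix with >= 2 columns.
#' @return symmetric samples x samples correlation matrix.
#' @export
spearmanMatrix <- function(abundance) {
    if (ncol(abundance) < 2)
        stop("at least 2 samples required", call. = FALSE)
    sds <- apply(abundance, 2, stats::sd)
    if (any(sds == 0 | is.na(sds)))
        stop("zero-variance abundance column(s): ",
             paste(colnames(abundance)[sds == 0 | is.na(sds)],
                   collapse = ", "), call. = FALSE)
    rho <- stats::cor(abundance, method = "spearman")
    diag(rho) <- 1
    rho
}

#' Hierarchically cluster samples from their correlation structure
#'
#' Samples are clustered agglomeratively (average linkage by default) on the
#' Euclidean distance between their rows of the Spearman correlation matrix
#' (`distanceMode = "rho_rows"`), or alternatively on `1 - rho` directly
#' (`distanceMode = "one_minus_rho"`). Columns are processed in sample-id
#' order so ties break deterministically.
#'
#' @param rho correlation matrix from [spearmanMatrix()].
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param distanceMode `"rho_rows"` (default) or `"one_minus_rho"`.
#' @return a list with `hclust` (the tree), `order` (leaf labels in
#'   dendrogram order) and `newick` (the tree as a Newick string with merge
#'   heights as branch lengths).
#' @export
clusterSamples <- function(rho, linkage = "average",
                           distanceMode = c("rho_rows", "one_minus_rho")) {
    distanceMode <- match.arg(distanceMode)
    ord <- order(rownames(rho))
    rho <- rho[ord, ord, drop = FALSE]
    d <- switch(distanceMode,
        rho_rows = stats::dist(rho, method = "euclidean"),
        one_minus_rho = stats::as.dist(1 - rho))
    hc <- stats::hclust(d, method = linkage)
    newick <- ape::write.tree(ape::as.phylo(hc))
    list(hclust = hc, order = hc$labels[hc$order], newick = newick)
}

#' Individual coherence of the sample clustering
#'
#' Two complementary statistics of how personalised the metaproteomes are:
#' the fraction of samples whose highest-correlation partner belongs to the
#' same individual, and the adjusted Rand index between the true individual
#' labels and the k-cluster cut of the dendrogram, with k the number of
#' individuals.
#'
#' @param rho correlation matrix from [spearmanMatrix()].
#' @param clustering result of [clusterSamples()].
#' @param sampleInfo `data.frame` with `sample_id`, `individual_id`.
#' @return a list with `nn_same_individual` and `adjusted_rand`.
#' @export
individualCoherence <- function(rho, clustering, sampleInfo) {
    individuals <- sampleInfo$individual_id[match(rownames(rho),
                                                  sampleInfo$sample_id)]
    if (length(unique(individuals)) < 2)
        stop("at least 2 individuals required", call. = FALSE)
    nn <- vapply(seq_len(nrow(rho)), function(i) {
        r <- rho[i, ]; r[i] <- -Inf
        individuals[which.max(r)] == individuals[i]
    }, logical(1))
    k <- length(unique(individuals))
    cut <- stats::cutree(clustering$hclust, k = k)
    cutLabels <- cut[match(rownames(rho), names(cut))]
    ari <- mclust::adjustedRandIndex(cutLabels, individuals)
    list(nn_same_individual = mean(nn), adjusted_rand = ari)
}
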