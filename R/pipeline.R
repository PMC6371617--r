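## End-to-end orchestration: group -> identify -> balance -> annotate ->
## infer modules -> persistence / similarity, with deterministic outputs.

#' Run the full analysis on in-memory inputs
#'
#' Executes every stage of the analysis in order and returns all
#' intermediate and final results. This is the computational core of
#' [runPipeline()], usable directly on the output of [simulateCohort()].
#'
#' @param database union protein database, a named
#'   [Biostrings::AAStringSet] with `mcols(database)$individual_id`.
#' @param psms aggregated PSM `data.frame` (see [readPsmTable()]).
#' @param annotation annotation `data.frame` (see [readAnnotationTable()]).
#' @param modules a [ModuleSet].
#' @param identityThreshold protein-group clustering identity threshold
#'   (default 0.90).
#' @param coverageThreshold module inference coverage threshold (default
#'   1/3).
#' @param minDistinctPeptides,minUniquePeptides identification rule
#'   parameters (defaults 2 and 1).
#' @param linkage clustering linkage for sample dendrograms (default
#'   `"average"`).
#' @param distanceMode `"rho_rows"` or `"one_minus_rho"` (see
#'   [clusterSamples()]).
#' @param ileLeuEquivalent treat I/L as equivalent in alignment and peptide
#'   matching (default `FALSE`).
#' @return a named list with elements `groups`, `peptideMap`,
#'   `identification`, `abundance` (SummarizedExperiment), `annotated`,
#'   `ambiguity`, `detected`, `moduleCalls`, `redundancy`, `switches`,
#'   `presence`, `persistenceByIndividual` (per entity level),
#'   `persistenceAcross` (per entity level), `influence`, `rho`,
#'   `clustering`, `coherence`, `sampleInfo`.
#' @export
analyzeCohort <- function(database, psms, annotation, modules,
                          identityThreshold = 0.90,
                          coverageThreshold = 1/3,
                          minDistinctPeptides = 2L,
                          minUniquePeptides = 1L,
                          linkage = "average",
                          distanceMode = "rho_rows",
                          ileLeuEquivalent = FALSE) {
    groups <- clusterProteins(database, threshold = identityThreshold,
                              ileLeuEquivalent = ileLeuEquivalent)
    peptideMap <- mapPeptides(unique(psms$peptide), groups,
                              ileLeuEquivalent = ileLeuEquivalent)
    identification <- identifyGroups(groups, peptideMap, psms,
                                     minDistinct = minDistinctPeptides,
                                     minUnique = minUniquePeptides)
    abundance <- balanceSpectra(groups, peptideMap, psms, identification)
    annotated <- annotateGroups(groups, annotation)
    ambiguity <- ambiguityReport(groups, annotation)
    detected <- detectedKoSets(annotated, identification)
    moduleCalls <- inferModules(modules, detected,
                                threshold = coverageThreshold)
    moduleCalls <- moduleAbundance(moduleCalls, modules, annotated,
                                   abundance, identification)
    redundancy <- redundancyClasses(moduleCalls)
    sampleInfo <- as.data.frame(SummarizedExperiment::colData(abundance))[,
        c("sample_id", "individual_id", "day")]
    switches <- phylumSwitchEvents(moduleCalls, sampleInfo)
    presence <- presenceMatrices(identification, annotated, detected,
                                 moduleCalls)
    persistenceInd <- lapply(presence, persistenceByIndividual,
                             sampleInfo = sampleInfo)
    persistenceAcross <- lapply(presence, persistenceAcrossIndividuals,
                                sampleInfo = sampleInfo)
    ## per-individual database KO universe for functional influence
    indOfAcc <- S4Vectors::mcols(database)$individual_id
    koUniverse <- lapply(split(names(database), indOfAcc), function(accs) {
        kos <- annotation$ko_term[match(accs, annotation$accession)]
        sort(unique(kos[!is.na(kos)]))
    })
    influence <- functionalInfluence(detected, koUniverse, sampleInfo)
    rho <- spearmanMatrix(SummarizedExperiment::assay(abundance, "balanced"))
    clustering <- clusterSamples(rho, linkage = linkage,
                                 distanceMode = distanceMode)
    coherence <- individualCoherence(rho, clustering, sampleInfo)
    list(groups = groups, peptideMap = peptideMap,
         identification = identification, abundance = abundance,
         annotated = annotated, ambiguity = ambiguity, detected = detected,
         moduleCalls = moduleCalls, redundancy = redundancy,
         switches = switches, presence = presence,
         persistenceByIndividual = persistenceInd,
         persistenceAcross = persistenceAcross, influence = influence,
         rho = rho, clustering = clustering, coherence = coherence,
         sampleInfo = sampleInfo)
}

.writeGroupsTsv <- function(groups, path) {
    .writeTsv(data.frame(
        group_id = groupIds(groups),
        seed_accession = seedAccessions(groups),
        member_accessions = vapply(as.list(groups@members), paste, "",
                                   collapse = ";"),
        stringsAsFactors = FALSE), path)
}

.writePeptideMapTsv <- function(pm, path) {
    .writeTsv(data.frame(
        peptide = peptides(pm),
        group_ids = vapply(as.list(pm@groups), paste, "", collapse = ";"),
        unique = unname(isUnique(pm)),
        stringsAsFactors = FALSE), path)
}

.writeMatrixTsv <- function(m, path, rowLabel) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- rowLabel
    .writeTsv(df, path)
}

#' Run the pipeline from files to an output directory
#'
#' Reads every input, runs [analyzeCohort()], and writes all result tables
#' as tab-separated files plus a run manifest (input checksums, parameter
#' values, package version). Outputs are pure functions of inputs and
#' parameters: re-running yields byte-identical files.
#'
#' @param fastaPaths named character vector of per-individual protein FASTA
#'   paths (names are individual ids).
#' @param psmPath path to the PSM TSV.
#' @param annotationPath path to the annotation TSV.
#' @param modulePath path to the module definition file.
#' @param outDir output directory (created if needed).
#' @inheritParams analyzeCohort
#' @param minPeptideLength peptide length floor applied on read (default 6).
#' @return invisibly, the [analyzeCohort()] result list.
#' @export
runPipeline <- function(fastaPaths, psmPath, annotationPath, modulePath,
                        outDir, identityThreshold = 0.90,
                        coverageThreshold = 1/3, minDistinctPeptides = 2L,
                        minUniquePeptides = 1L, linkage = "average",
                        distanceMode = "rho_rows", ileLeuEquivalent = FALSE,
                        minPeptideLength = 6L) {
    inputs <- c(fastaPaths, psm = psmPath, annotation = annotationPath,
                modules = modulePath)
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
    database <- readProteinDatabases(fastaPaths)
    psms <- readPsmTable(psmPath, minPeptideLength = minPeptideLength)
    annotation <- readAnnotationTable(annotationPath)
    modules <- readModuleDefinitions(modulePath)
    res <- analyzeCohort(database, psms, annotation, modules,
                         identityThreshold = identityThreshold,
                         coverageThreshold = coverageThreshold,
                         minDistinctPeptides = minDistinctPeptides,
                         minUniquePeptides = minUniquePeptides,
                         linkage = linkage, distanceMode = distanceMode,
                         ileLeuEquivalent = ileLeuEquivalent)

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeGroupsTsv(res$groups, file.path(outDir, "protein_groups.tsv"))
    .writePeptideMapTsv(res$peptideMap, file.path(outDir, "peptide_map.tsv"))
    .writeMatrixTsv(res$identification * 1L,
                    file.path(outDir, "identification_matrix.tsv"),
                    "group_id")
    bal <- SummarizedExperiment::assay(res$abundance, "balanced")
    .writeMatrixTsv(round(bal, 6), file.path(outDir, "abundance.tsv"),
                    "group_id")
    .writeTsv(as.data.frame(SummarizedExperiment::colData(res$abundance)),
              file.path(outDir, "sample_totals.tsv"))
    .writeTsv(as.data.frame(res$annotated),
              file.path(outDir, "annotated_groups.tsv"))
    .writeTsv(res$moduleCalls, file.path(outDir, "module_calls.tsv"))
    .writeTsv(res$redundancy, file.path(outDir, "module_redundancy.tsv"))
    .writeTsv(res$switches, file.path(outDir, "phylum_switches.tsv"))
    for (lvl in names(res$persistenceByIndividual))
        .writeTsv(res$persistenceByIndividual[[lvl]],
                  file.path(outDir, sprintf("persistence_%s.tsv", lvl)))
    .writeTsv(do.call(rbind, lapply(names(res$persistenceAcross), function(l)
        cbind(entity_level = l, res$persistenceAcross[[l]]))),
        file.path(outDir, "persistence_across_individuals.tsv"))
    .writeTsv(res$influence, file.path(outDir, "functional_influence.tsv"))
    .writeMatrixTsv(round(res$rho, 6), file.path(outDir, "rho_matrix.tsv"),
                    "sample_id")
    writeLines(res$clustering$newick, file.path(outDir, "dendrogram.nwk"))
    .writeTsv(data.frame(metric = c("nn_same_individual", "adjusted_rand"),
                         value = c(res$coherence$nn_same_individual,
                                   res$coherence$adjusted_rand)),
              file.path(outDir, "coherence.tsv"))

    params <- data.frame(
        key = c("identity_threshold", "coverage_threshold",
                "min_distinct_peptides", "min_unique_peptides", "linkage",
                "distance_mode", "ile_leu_equivalent", "min_peptide_length",
                "package_version"),
        value = c(identityThreshold, coverageThreshold, minDistinctPeptides,
                  minUniquePeptides, linkage, distanceMode,
                  ileLeuEquivalent, minPeptideLength,
                  as.character(utils::packageVersion("ProteoPersist"))),
        stringsAsFactors = FALSE)
    checks <- data.frame(key = paste0("md5_", names(inputs)),
                         value = unname(tools::md5sum(inputs)),
                         stringsAsFactors = FALSE)
    .writeTsv(rbind(params, checks), file.path(outDir, "manifest.tsv"))
    invisible(res)
}
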