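## Spectral balancing: distribute peptide spectral counts over identified
## protein groups, unique evidence first, shared evidence proportionally.

#' Balance spectral counts across identified protein groups
#'
#' For each sample, distributes the spectral counts of observed peptides over
#' the protein groups identified in that sample. The allocation is a single
#' pass: (1) every unique peptide's count goes wholly to its group; (2) every
#' shared peptide's count is split across its identified carrier groups in
#' proportion to those groups' step-1 unique-count totals, or equally when
#' all carriers have zero unique counts. Peptides whose carriers are all
#' unidentified (or that are unmapped) are dropped from the conserved total
#' and reported. Column sums of the result equal the per-sample retained
#' peptide counts exactly (up to floating-point tolerance), and the result
#' does not depend on peptide or group processing order.
#'
#' @param groups a [ProteinGroupSet].
#' @param peptideMap a [PeptideMap].
#' @param psms aggregated PSM `data.frame` (see [readPsmTable()]).
#' @param identification logical matrix groups x samples from
#'   [identifyGroups()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"balanced"` (groups x samples, non-negative reals), `rowData` carrying
#'   seed accessions and group sizes, and `colData` carrying `sample_id`,
#'   `individual_id`, `day`, `total_spectra` (retained, balanced total) and
#'   `dropped_spectra` (counts of peptides with no identified carrier).
#' @export
balanceSpectra <- function(groups, peptideMap, psms, identification) {
    stopifnot(is(groups, "ProteinGroupSet"), is(peptideMap, "PeptideMap"))
    gids <- groupIds(groups)
    stopifnot(identical(rownames(identification), gids))
    sampleIds <- colnames(identification)
    stopifnot(all(psms$sample_id %in% sampleIds))

    mat <- matrix(0, nrow = length(gids), ncol = length(sampleIds),
                  dimnames = list(gids, sampleIds))
    totals <- numeric(length(sampleIds)); names(totals) <- sampleIds
    dropped <- numeric(length(sampleIds)); names(dropped) <- sampleIds

    pepIdx <- match(psms$peptide, peptideMap@peptide)
    groupList <- as.list(peptideMap@groups)

    for (s in sampleIds) {
        rows <- which(psms$sample_id == s)
        idGroups <- gids[identification[, s]]
        colUnique <- numeric(length(gids)); names(colUnique) <- gids
        sharedRows <- list()
        for (r in rows) {
            pi <- pepIdx[r]
            cnt <- psms$spectral_count[r]
            if (is.na(pi)) { dropped[s] <- dropped[s] + cnt; next }
            carriers <- intersect(groupList[[pi]], idGroups)
            if (length(carriers) == 0) {
                dropped[s] <- dropped[s] + cnt
            } else if (length(groupList[[pi]]) == 1L) {
                # unique peptide: full count to its (identified) group
                colUnique[carriers] <- colUnique[carriers] + cnt
                totals[s] <- totals[s] + cnt
            } else {
                sharedRows[[length(sharedRows) + 1L]] <-
                    list(carriers = carriers, count = cnt)
                totals[s] <- totals[s] + cnt
            }
        }
        colBalanced <- colUnique
        for (sh in sharedRows) {
            w <- colUnique[sh$carriers]
            if (sum(w) == 0) w <- rep(1, length(w))
            colBalanced[sh$carriers] <- colBalanced[sh$carriers] +
                sh$count * w / sum(w)
        }
        mat[, s] <- colBalanced
    }

    sampleMeta <- unique(psms[, c("sample_id", "individual_id", "day")])
    sampleMeta <- sampleMeta[match(sampleIds, sampleMeta$sample_id), ,
                             drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(balanced = mat),
        rowData = S4Vectors::DataFrame(
            group_id = gids,
            seed_accession = seedAccessions(groups),
            n_members = lengths(groups@members)),
        colData = S4Vectors::DataFrame(
            sample_id = sampleIds,
            individual_id = sampleMeta$individual_id,
            day = sampleMeta$day,
            total_spectra = unname(totals),
            dropped_spectra = unname(dropped),
            row.names = sampleIds))
}
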