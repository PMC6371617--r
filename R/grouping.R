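## Protein grouping: global-alignment identity, greedy centroid clustering,
## peptide-to-group mapping, and the per-sample identification rule.

.substitutionMatrix <- local({
    m <- matrix(-1, 20, 20, dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
    diag(m) <- 1
    m
})

.collapseIleLeu <- function(x) chartr("L", "I", x)

## Identity of a set of sequences against one subject from global affine
## alignment (match +1, mismatch -1, gap open 5, gap extend 1):
## identical aligned residue pairs / alignment length in columns
## (gap columns, including terminal ones, count in the denominator).
.identityToSubject <- function(patterns, subject, gapOpening = 5,
                               gapExtension = 1) {
    aln <- Biostrings::pairwiseAlignment(
        pattern = patterns, subject = subject, type = "global",
        substitutionMatrix = .substitutionMatrix,
        gapOpening = gapOpening, gapExtension = gapExtension)
    m <- Biostrings::nmatch(aln)
    mm <- Biostrings::nmismatch(aln)
    ## every alignment column consumes a residue of one or both sequences,
    ## so columns (gap columns included) = la + lb - residue-pair columns
    cols <- Biostrings::width(patterns) + length(subject) - m - mm
    m / cols
}

#' Pairwise global-alignment sequence identity
#'
#' Computes the identity between two protein sequences as the number of
#' identical aligned residue pairs divided by the total global-alignment
#' length in columns (gap columns included). The alignment is global with
#' affine gap costs: match +1, mismatch -1, gap opening 5 and gap extension 1
#' (a length-L gap costs 5 + L). The measure is symmetric.
#'
#' @param a,b non-empty amino-acid sequences (character or
#'   [Biostrings::AAString]).
#' @param ileLeuEquivalent if `TRUE`, isoleucine and leucine are treated as
#'   the same residue (they are isobaric and indistinguishable by most
#'   mass-spectrometry searches). Default `FALSE`.
#' @return a single numeric identity in `[0, 1]`.
#' @examples
#' pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL")  # 1
#' pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKW")  # 0.9
#' @export
pairwiseIdentity <- function(a, b, ileLeuEquivalent = FALSE) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (!nzchar(a) || !nzchar(b))
        stop("sequences must be non-empty", call. = FALSE)
    .validateSequences(c(a, b), c("a", "b"))
    if (ileLeuEquivalent) { a <- .collapseIleLeu(a); b <- .collapseIleLeu(b) }
    as.numeric(.identityToSubject(Biostrings::AAStringSet(a),
                                  Biostrings::AAString(b)))
}

#' Greedy centroid clustering of proteins into protein groups
#'
#' Clusters a protein database into groups at a sequence-identity threshold
#' (default 90%) with a deterministic greedy centroid algorithm: sequences
#' are visited in order of decreasing length (ties broken by lexicographic
#' accession); each sequence joins the first existing seed to which its
#' [pairwiseIdentity()] is at least the threshold, otherwise it founds a new
#' group with itself as seed. The resulting groups partition the database.
#'
#' Candidate seeds whose length ratio with the query already caps the
#' identity below the threshold are skipped without alignment; this bound is
#' exact, so the result equals the all-pairs computation.
#'
#' @param database a named [Biostrings::AAStringSet] (see
#'   [readProteinFasta()]).
#' @param threshold identity threshold in (0, 1]; default 0.90.
#' @param ileLeuEquivalent treat I and L as equivalent (default `FALSE`).
#' @return a [ProteinGroupSet].
#' @export
clusterProteins <- function(database, threshold = 0.90,
                            ileLeuEquivalent = FALSE) {
    .checkThreshold(threshold, "threshold")
    if (length(database) == 0)
        stop("empty protein database", call. = FALSE)
    if (is.null(names(database)) || anyDuplicated(names(database)))
        stop("database must have unique accessions as names", call. = FALSE)
    acc <- names(database)
    ord <- order(-Biostrings::width(database), acc)
    seqs <- as.character(database)[ord]
    accs <- acc[ord]
    if (ileLeuEquivalent) seqs <- .collapseIleLeu(seqs)
    lens <- nchar(seqs)

    seedIdx <- integer(0)          # indices into the sorted order
    assignment <- integer(length(seqs))
    for (i in seq_along(seqs)) {
        joined <- 0L
        if (length(seedIdx)) {
            sl <- lens[seedIdx]
            cand <- which(pmin(sl, lens[i]) / pmax(sl, lens[i]) >= threshold)
            if (length(cand)) {
                ids <- .identityToSubject(
                    Biostrings::AAStringSet(seqs[seedIdx[cand]]),
                    Biostrings::AAString(seqs[i]))
                hit <- which(ids >= threshold)
                if (length(hit)) joined <- cand[hit[1]]
            }
        }
        if (joined > 0L) {
            assignment[i] <- joined
        } else {
            seedIdx <- c(seedIdx, i)
            assignment[i] <- length(seedIdx)
        }
    }
    members <- split(accs, assignment)
    groupId <- sprintf("PG%05d", seq_along(seedIdx))
    new("ProteinGroupSet",
        groupId = groupId,
        seedAccession = accs[seedIdx],
        members = IRanges::CharacterList(unname(members)),
        threshold = threshold,
        database = database)
}

#' Map peptides to the protein groups containing them
#'
#' A peptide maps to a group if and only if it occurs as an exact substring
#' of at least one member sequence of the group. Peptides mapping to exactly
#' one group are *unique*; peptides found in no sequence are reported as
#' unmapped (with a warning) and are excluded downstream.
#'
#' @param peps character vector of peptide sequences (duplicates collapsed).
#' @param groups a [ProteinGroupSet].
#' @param ileLeuEquivalent treat I and L as equivalent when matching
#'   (default `FALSE`; must match the clustering setting).
#' @return a [PeptideMap].
#' @export
mapPeptides <- function(peps, groups, ileLeuEquivalent = FALSE) {
    stopifnot(is(groups, "ProteinGroupSet"))
    peps <- unique(toupper(as.character(peps)))
    db <- database(groups)
    seqs <- as.character(db)
    if (ileLeuEquivalent) {
        seqs <- .collapseIleLeu(seqs)
        searchPeps <- .collapseIleLeu(peps)
    } else searchPeps <- peps
    accToGroup <- rep(groups@groupId, lengths(groups@members))
    names(accToGroup) <- unlist(groups@members, use.names = FALSE)
    groupOfSeq <- unname(accToGroup[names(db)])

    hits <- lapply(searchPeps, function(p) {
        unique(groupOfSeq[grepl(p, seqs, fixed = TRUE)])
    })
    mapped <- lengths(hits) > 0
    if (any(!mapped))
        warning(sum(!mapped), " peptide(s) mapped to no protein group",
                call. = FALSE)
    new("PeptideMap",
        peptide = peps[mapped],
        groups = IRanges::CharacterList(hits[mapped]),
        unmapped = peps[!mapped])
}

#' Per-sample protein-group identification rule
#'
#' A protein group counts as identified in a sample when the observed
#' peptides mapping to it contain at least `minDistinct` distinct peptide
#' sequences of which at least `minUnique` map to that group only.
#'
#' @param peptideMap a [PeptideMap].
#' @param observedPeptides character vector of peptides observed in one
#'   sample.
#' @param groupIds character vector of all group ids (defines the output).
#' @param minDistinct minimum number of distinct peptides (default 2).
#' @param minUnique minimum number of group-unique peptides (default 1).
#' @return named logical vector over `groupIds`.
#' @export
classifyIdentified <- function(peptideMap, observedPeptides, groupIds,
                               minDistinct = 2L, minUnique = 1L) {
    stopifnot(is(peptideMap, "PeptideMap"))
    obs <- intersect(unique(observedPeptides), peptideMap@peptide)
    idx <- match(obs, peptideMap@peptide)
    gl <- as.list(peptideMap@groups[idx])
    uniq <- lengths(gl) == 1L
    long <- data.frame(
        group = unlist(gl, use.names = FALSE),
        unique = rep(uniq, lengths(gl)),
        stringsAsFactors = FALSE)
    nDistinct <- table(factor(long$group, levels = groupIds))
    nUnique <- table(factor(long$group[long$unique], levels = groupIds))
    out <- as.vector(nDistinct) >= minDistinct &
        as.vector(nUnique) >= minUnique
    names(out) <- groupIds
    out
}

#' Identification matrix over all samples
#'
#' Applies [classifyIdentified()] to every sample of a PSM table.
#'
#' @param groups a [ProteinGroupSet].
#' @param peptideMap a [PeptideMap] for the observed peptides.
#' @param psms aggregated PSM `data.frame` (see [readPsmTable()]).
#' @inheritParams classifyIdentified
#' @return logical matrix, groups x samples.
#' @export
identifyGroups <- function(groups, peptideMap, psms,
                           minDistinct = 2L, minUnique = 1L) {
    stopifnot(is(groups, "ProteinGroupSet"))
    sampleIds <- sort(unique(psms$sample_id))
    out <- vapply(sampleIds, function(s) {
        classifyIdentified(peptideMap,
                           psms$peptide[psms$sample_id == s],
                           groupIds(groups), minDistinct, minUnique)
    }, logical(length(groups)))
    out <- matrix(out, nrow = length(groups),
                  dimnames = list(groupIds(groups), sampleIds))
    out
}
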