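## Functional annotation of protein groups: each group inherits the KO term,
## phylum and genus of its seed (centroid) sequence.

#' Annotate protein groups from their seed sequences
#'
#' Each protein group inherits exactly its seed sequence's KO term, phylum
#' and genus from the annotation table. A seed labelled `human` yields
#' category `"human"` (and never a phylum); a seed with a phylum yields
#' `"microbial"`; anything else - including seeds absent from the table,
#' which are reported with a warning - yields `"unassigned"`.
#'
#' @param groups a [ProteinGroupSet].
#' @param annotation annotation `data.frame` (see [readAnnotationTable()]).
#' @return a [S4Vectors::DataFrame] with one row per group: `group_id`,
#'   `seed_accession`, `ko_term`, `phylum`, `genus`, `category`.
#' @export
annotateGroups <- function(groups, annotation) {
    stopifnot(is(groups, "ProteinGroupSet"))
    seeds <- seedAccessions(groups)
    idx <- match(seeds, annotation$accession)
    if (any(is.na(idx)))
        warning(sum(is.na(idx)),
                " seed accession(s) absent from the annotation table; ",
                "their groups are unassigned", call. = FALSE)
    ko <- annotation$ko_term[idx]
    phylum <- annotation$phylum[idx]
    genus <- annotation$genus[idx]
    label <- annotation$organism_label[idx]
    category <- ifelse(is.na(idx), "unassigned",
                ifelse(!is.na(label) & label == "human", "human",
                ifelse(!is.na(phylum), "microbial", "unassigned")))
    phylum[category == "human"] <- NA_character_
    S4Vectors::DataFrame(
        group_id = groupIds(groups),
        seed_accession = seeds,
        ko_term = ko,
        phylum = phylum,
        genus = genus,
        category = category)
}

#' Report annotation ambiguity within protein groups
#'
#' A group is discordant when at least one annotated member disagrees with
#' the seed on the KO term or on the phylum. Members lacking an annotation
#' (or lacking the compared field) never create ambiguity; only positive
#' disagreement counts.
#'
#' @param groups a [ProteinGroupSet].
#' @param annotation annotation `data.frame`.
#' @return a list with `fraction` (discordant groups / all groups) and
#'   `discordant` (character vector of discordant group ids).
#' @export
ambiguityReport <- function(groups, annotation) {
    stopifnot(is(groups, "ProteinGroupSet"))
    seedIdx <- match(seedAccessions(groups), annotation$accession)
    memberList <- as.list(groups@members)
    discordant <- vapply(seq_along(memberList), function(i) {
        mIdx <- match(memberList[[i]], annotation$accession)
        mIdx <- mIdx[!is.na(mIdx)]
        if (length(mIdx) == 0 || is.na(seedIdx[i])) return(FALSE)
        seedKo <- annotation$ko_term[seedIdx[i]]
        seedPh <- annotation$phylum[seedIdx[i]]
        mKo <- annotation$ko_term[mIdx]
        mPh <- annotation$phylum[mIdx]
        koClash <- !is.na(mKo) & !is.na(seedKo) & mKo != seedKo
        phClash <- !is.na(mPh) & !is.na(seedPh) & mPh != seedPh
        any(koClash | phClash)
    }, logical(1))
    list(fraction = if (length(discordant)) mean(discordant) else 0,
         discordant = groupIds(groups)[discordant])
}
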