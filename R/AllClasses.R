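#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges CharacterList
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.KO_PATTERN <- "^K[0-9]{5}$"
.MODULE_ID_PATTERN <- "^MF[0-9]{4}$"
.MAJOR_PHYLA <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
                  "Proteobacteria")

#' ProteinGroupSet: clustered protein sequences
#'
#' Result of greedy centroid clustering of a protein sequence database at a
#' sequence-identity threshold. Each group has a seed (centroid) sequence and
#' an ordered set of member accessions; the groups partition the database.
#'
#' @slot groupId character vector of group identifiers, one per group.
#' @slot seedAccession character vector, the centroid accession of each group.
#' @slot members [IRanges::CharacterList] of member accessions per group;
#'   the seed is always a member.
#' @slot threshold numeric(1), the identity threshold used for clustering.
#' @slot database [Biostrings::AAStringSet] of all clustered sequences, with
#'   `mcols(database)$individual_id` carrying provenance.
#'
#' @seealso [clusterProteins()]
#' @exportClass ProteinGroupSet
setClass("ProteinGroupSet",
    representation(
        groupId = "character",
        seedAccession = "character",
        members = "CharacterList",
        threshold = "numeric",
        database = "AAStringSet"
    )
)

setValidity("ProteinGroupSet", function(object) {
    msg <- NULL
    n <- length(object@groupId)
    if (length(object@seedAccession) != n || length(object@members) != n)
        msg <- c(msg, "groupId, seedAccession and members must have equal length")
    if (anyDuplicated(object@groupId))
        msg <- c(msg, "group ids must be unique")
    if (n > 0 && !all(mapply(function(s, m) s %in% m,
                             object@seedAccession, as.list(object@members))))
        msg <- c(msg, "every seed must be a member of its group")
    allMembers <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(allMembers))
        msg <- c(msg, "groups must partition the database: accession in > 1 group")
    if (!setequal(allMembers, names(object@database)))
        msg <- c(msg, "member accessions must cover the database exactly")
    if (length(object@threshold) != 1 || object@threshold <= 0 ||
        object@threshold > 1)
        msg <- c(msg, "threshold must be a single value in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' PeptideMap: peptide-to-group containment map
#'
#' Maps each peptide to the protein groups whose member sequences contain it
#' as an exact substring. A peptide mapping to exactly one group is *unique*;
#' one mapping to several groups is *shared*. Peptides found in no sequence
#' are retained in `unmapped` for reporting and excluded downstream.
#'
#' @slot peptide character vector of mapped peptide sequences.
#' @slot groups [IRanges::CharacterList] of containing group ids per peptide.
#' @slot unmapped character vector of peptides found in no group.
#'
#' @seealso [mapPeptides()]
#' @exportClass PeptideMap
setClass("PeptideMap",
    representation(
        peptide = "character",
        groups = "CharacterList",
        unmapped = "character"
    )
)

setValidity("PeptideMap", function(object) {
    msg <- NULL
    if (length(object@peptide) != length(object@groups))
        msg <- c(msg, "peptide and groups must have equal length")
    if (anyDuplicated(object@peptide))
        msg <- c(msg, "peptides must be unique")
    if (length(object@groups) > 0 && any(lengths(object@groups) == 0))
        msg <- c(msg, "every mapped peptide must map to at least one group")
    if (length(intersect(object@peptide, object@unmapped)) > 0)
        msg <- c(msg, "a peptide cannot be both mapped and unmapped")
    if (is.null(msg)) TRUE else msg
})

#' ModuleSet: metabolic module definitions
#'
#' A collection of metabolic modules in the gut-metabolic-module style. Each
#' module is an ordered list of enzymatic steps; each step is a list of
#' AND-components that must all be satisfied; each component is a non-empty
#' set of OR-alternative KEGG Orthology (KO) terms, any one of which
#' satisfies the component.
#'
#' @slot moduleId character vector of module ids (pattern `MF` + 4 digits).
#' @slot moduleName character vector of human-readable names.
#' @slot steps list (one element per module) of lists of steps; each step is
#'   a list of character vectors of KO terms (the OR-alternatives of each
#'   AND-component).
#'
#' @seealso [readModuleDefinitions()], [computeCoverage()]
#' @exportClass ModuleSet
setClass("ModuleSet",
    representation(
        moduleId = "character",
        moduleName = "character",
        steps = "list"
    )
)

setValidity("ModuleSet", function(object) {
    msg <- NULL
    n <- length(object@moduleId)
    if (length(object@moduleName) != n || length(object@steps) != n)
        msg <- c(msg, "moduleId, moduleName and steps must have equal length")
    if (anyDuplicated(object@moduleId))
        msg <- c(msg, "module ids must be unique")
    if (n > 0 && !all(grepl(.MODULE_ID_PATTERN, object@moduleId)))
        msg <- c(msg, "module ids must match MF####")
    for (i in seq_len(n)) {
        st <- object@steps[[i]]
        if (length(st) < 1) {
            msg <- c(msg, sprintf("module %s has no steps", object@moduleId[i]))
            next
        }
        kos <- unlist(st, use.names = FALSE)
        badStep <- vapply(st, function(s) {
            !is.list(s) || length(s) == 0 || any(lengths(s) == 0)
        }, logical(1))
        if (any(badStep))
            msg <- c(msg, sprintf("module %s has an empty component",
                                  object@moduleId[i]))
        if (length(kos) == 0 || !all(grepl(.KO_PATTERN, kos)))
            msg <- c(msg, sprintf("module %s has a malformed KO term",
                                  object@moduleId[i]))
    }
    if (is.null(msg)) TRUE else msg
})

#' SimulationConfig: parameters of the synthetic longitudinal cohort
#'
#' Holds every tunable of the synthetic metaproteome generator. Defaults
#' describe a five-individual, five-time-point cohort with strongly
#' personalised expression profiles, high protein turnover with KO-term
#' preservation, and KO terms encoded redundantly across phyla.
#'
#' @slot nIndividuals integer, number of individuals (>= 2).
#' @slot nTimepoints integer, time points per individual (>= 2).
#' @slot proteinsPerIndividual integer, approximate microbial database size
#'   per individual.
#' @slot nKoTerms integer, size of the simulated KO universe.
#' @slot phyla character, phylum names; the first four are treated as the
#'   major phyla.
#' @slot koPhylumRedundancy numeric in `[0, 1]`, fraction of KO terms encoded
#'   in two or more phyla.
#' @slot turnover numeric in `[0, 1]`, fraction of expressed proteins replaced
#'   between consecutive time points.
#' @slot koPreservation numeric in `[0, 1]`, probability that a replacement
#'   protein carries the departing protein's KO term.
#' @slot individualEffect numeric >= 0, standard deviation (natural-log scale)
#'   of individual-specific expression offsets per sequence family; larger
#'   values give more personalised metaproteomes.
#' @slot humanFraction numeric in `[0, 1]`, fraction of host (human) proteins
#'   in each database.
#' @slot depth integer, total spectra sampled per sample.
#' @slot rngSeed integer seed making the whole simulation deterministic.
#'
#' @seealso [simulationConfig()], [simulateCohort()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nIndividuals = "integer",
        nTimepoints = "integer",
        proteinsPerIndividual = "integer",
        nKoTerms = "integer",
        phyla = "character",
        koPhylumRedundancy = "numeric",
        turnover = "numeric",
        koPreservation = "numeric",
        individualEffect = "numeric",
        humanFraction = "numeric",
        depth = "integer",
        rngSeed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    inUnit <- function(x) length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
    if (object@nIndividuals < 2L) msg <- c(msg, "nIndividuals must be >= 2")
    if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
    if (object@proteinsPerIndividual < 10L)
        msg <- c(msg, "proteinsPerIndividual must be >= 10")
    if (object@nKoTerms < 2L) msg <- c(msg, "nKoTerms must be >= 2")
    if (length(object@phyla) < 1L || anyDuplicated(object@phyla))
        msg <- c(msg, "phyla must be a non-empty set of distinct names")
    for (s in c("koPhylumRedundancy", "turnover", "koPreservation",
                "humanFraction"))
        if (!inUnit(slot(object, s)))
            msg <- c(msg, sprintf("%s must be a single value in [0, 1]", s))
    if (object@koPhylumRedundancy > 0 && length(object@phyla) < 2L)
        msg <- c(msg, "koPhylumRedundancy > 0 needs at least 2 phyla")
    if (length(object@individualEffect) != 1 || object@individualEffect < 0)
        msg <- c(msg, "individualEffect must be a single value >= 0")
    if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
    if (is.null(msg)) TRUE else msg
})
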