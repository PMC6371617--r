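## Synthetic longitudinal metaproteome generator. The cohort emulates the
## statistical structure the analysis assumes: individual-specific protein
## repertoires drawn from shared KO-level sequence families, KO terms encoded
## redundantly across phyla, high protein turnover with KO preservation
## between time points, a host-protein fraction, and multinomial spectral
## sampling over in-silico tryptic peptides.

#' Construct a simulation configuration
#'
#' Builds a validated [SimulationConfig]. The defaults describe the study
#' conditions the package is designed around: 5 individuals sampled at 5
#' time points ~90 days apart, strongly personalised expression, half of the
#' expressed proteins replaced between consecutive time points with 90%
#' KO-term preservation, 80% of KO terms encoded in two or more phyla, and
#' 20,000 spectra per sample.
#'
#' @param nIndividuals number of individuals (default 5).
#' @param nTimepoints time points per individual (default 5).
#' @param proteinsPerIndividual approximate annotated microbial database
#'   size per individual (default 200).
#' @param nKoTerms size of the simulated KO universe (default 50).
#' @param phyla phylum names; the first four are the major phyla (default
#'   the four dominant gut phyla plus Verrucomicrobia as a minor one).
#' @param koPhylumRedundancy fraction of KO terms encoded in >= 2 phyla
#'   (default 0.8).
#' @param turnover fraction of expressed proteins replaced between
#'   consecutive time points (default 0.5).
#' @param koPreservation probability that a replacement carries the
#'   departing protein's KO term (default 0.9).
#' @param individualEffect sd (log scale) of individual-specific expression
#'   offsets (default 2).
#' @param humanFraction fraction of host proteins per database (default
#'   0.05).
#' @param depth spectra per sample (default 20000).
#' @param rngSeed integer seed (default 1).
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(nIndividuals = 5L, nTimepoints = 5L,
                             proteinsPerIndividual = 200L, nKoTerms = 50L,
                             phyla = c("Firmicutes", "Bacteroidetes",
                                       "Actinobacteria", "Proteobacteria",
                                       "Verrucomicrobia"),
                             koPhylumRedundancy = 0.8, turnover = 0.5,
                             koPreservation = 0.9, individualEffect = 2,
                             humanFraction = 0.05, depth = 20000L,
                             rngSeed = 1L) {
    new("SimulationConfig",
        nIndividuals = as.integer(nIndividuals),
        nTimepoints = as.integer(nTimepoints),
        proteinsPerIndividual = as.integer(proteinsPerIndividual),
        nKoTerms = as.integer(nKoTerms),
        phyla = phyla,
        koPhylumRedundancy = koPhylumRedundancy,
        turnover = turnover,
        koPreservation = koPreservation,
        individualEffect = individualEffect,
        humanFraction = humanFraction,
        depth = as.integer(depth),
        rngSeed = as.integer(rngSeed))
}

.randomSequence <- function(len) {
    paste(sample(.AA_ALPHABET, len, replace = TRUE), collapse = "")
}

.mutateSequence <- function(seq, rate = 0.02) {
    chars <- strsplit(seq, "")[[1]]
    n <- max(1L, stats::rbinom(1, length(chars), rate))
    pos <- sample.int(length(chars), n)
    for (p in pos) {
        chars[p] <- sample(setdiff(.AA_ALPHABET, chars[p]), 1)
    }
    paste(chars, collapse = "")
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R not followed by P (no
#' missed cleavages) and keeps fragments within the retained length range.
#'
#' @param seq amino-acid sequence.
#' @param minLength,maxLength retained peptide length range (default 6-40).
#' @return character vector of retained peptides in sequence order.
#' @examples
#' digestTryptic("MKAAAAAARGGGGGGK")
#' @export
digestTryptic <- function(seq, minLength = 6L, maxLength = 40L) {
    chars <- strsplit(toupper(seq), "")[[1]]
    n <- length(chars)
    cut <- which(chars %in% c("K", "R"))
    cut <- cut[cut < n & chars[pmin(cut + 1L, n)] != "P" | cut == n]
    bounds <- unique(c(0L, cut, n))
    starts <- head(bounds, -1) + 1L
    ends <- bounds[-1]
    peps <- substring(seq, starts, ends)
    peps[nchar(peps) >= minLength & nchar(peps) <= maxLength]
}

.hasEnoughPeptides <- function(seq, k = 2L) {
    length(unique(digestTryptic(seq))) >= k
}

.sequenceWithPeptides <- function(len, k = 3L, maxTries = 25L) {
    for (i in seq_len(maxTries)) {
        s <- .randomSequence(len)
        if (.hasEnoughPeptides(s, k)) return(s)
    }
    stop("could not generate a sequence with enough tryptic peptides",
         call. = FALSE)
}

#' Generate the static part of a synthetic cohort
#'
#' Builds the per-individual protein databases, the annotation table and a
#' module set, entirely determined by the configuration seed.
#'
#' KO terms are assigned to one phylum, or to 2-4 major phyla for the
#' redundant fraction. Each (KO, phylum) pair owns one to three sequence
#' *families* (a base sequence of length 80-600 under a uniform residue
#' model); each individual that carries a family holds its own variants at
#' ~98% identity to the base, so grouping collapses within-family variants
#' while distinct families stay apart. Host proteins are identical sequences
#' shared by all individuals. A module set is drawn from the simulated KO
#' pool.
#'
#' @param config a [SimulationConfig].
#' @return a list with `database` (union [Biostrings::AAStringSet] with
#'   per-record `individual_id`), `annotation` (data.frame), `modules`
#'   ([ModuleSet]), `proteins` (ground-truth data.frame: accession,
#'   individual, family, KO, phylum, human flag, expression mean) and
#'   `koPhyla` (data.frame of KO-phylum assignments).
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@rngSeed)
    phyla <- config@phyla
    majors <- phyla[seq_len(min(4L, length(phyla)))]

    kos <- sprintf("K%05d", sort(sample.int(99999L, config@nKoTerms)))
    nRed <- round(config@koPhylumRedundancy * config@nKoTerms)
    redundant <- seq_along(kos) <= nRed
    maxRed <- min(4L, length(majors))
    if (config@koPhylumRedundancy > 0 && maxRed < 2L)
        stop("redundancy requires at least 2 (major) phyla", call. = FALSE)
    phylaWeight <- ifelse(phyla %in% majors, 1, 0.25)
    koPhyla <- lapply(seq_along(kos), function(i) {
        if (redundant[i]) {
            k <- if (maxRed == 2L) 2L else sample(2:maxRed, 1)
            sample(majors, k)
        } else sample(phyla, 1, prob = phylaWeight)
    })

    ## sequence families per (KO, phylum)
    fam <- list()
    for (i in seq_along(kos)) {
        for (p in koPhyla[[i]]) {
            nFam <- sample(1:2, 1, prob = c(0.4, 0.6))
            for (f in seq_len(nFam)) {
                fam[[length(fam) + 1L]] <- list(
                    family_id = sprintf("F%04d", length(fam) + 1L),
                    ko_term = kos[i], phylum = p,
                    base = .sequenceWithPeptides(sample(80:600, 1), k = 3L),
                    mu = stats::rnorm(1, 0, 1))
            }
        }
    }
    nFam <- length(fam)

    individuals <- sprintf("I%02d", seq_len(config@nIndividuals))
    nHuman <- max(1L, round(config@humanFraction *
                            config@proteinsPerIndividual))
    humanBases <- replicate(nHuman, .sequenceWithPeptides(
        sample(80:600, 1), k = 3L))
    humanMu <- stats::rnorm(nHuman, 1.5, 0.5)
    nUnannot <- round(0.08 * config@proteinsPerIndividual)

    pInclude <- min(1, config@proteinsPerIndividual / (nFam * 1.5))
    rows <- list()
    seqs <- character(0); seqNames <- character(0); seqInd <- character(0)
    for (ind in individuals) {
        counter <- 0L
        for (fm in fam) {
            if (stats::runif(1) > pInclude) next
            nVar <- sample(1:2, 1)
            for (v in seq_len(nVar)) {
                repeat {
                    s <- .mutateSequence(fm$base, rate = 0.02)
                    if (.hasEnoughPeptides(s, 2L)) break
                }
                counter <- counter + 1L
                acc <- sprintf("%s_M%05d", ind, counter)
                seqs <- c(seqs, s); seqNames <- c(seqNames, acc)
                seqInd <- c(seqInd, ind)
                rows[[length(rows) + 1L]] <- data.frame(
                    accession = acc, individual_id = ind,
                    family_id = fm$family_id, ko_term = fm$ko_term,
                    phylum = fm$phylum, is_human = FALSE, mu = fm$mu,
                    stringsAsFactors = FALSE)
            }
        }
        ## unannotated, individual-specific proteins
        for (j in seq_len(nUnannot)) {
            acc <- sprintf("%s_U%03d", ind, j)
            s <- .sequenceWithPeptides(sample(80:600, 1), k = 2L)
            withPhylum <- j %% 2L == 0L
            seqs <- c(seqs, s); seqNames <- c(seqNames, acc)
            seqInd <- c(seqInd, ind)
            rows[[length(rows) + 1L]] <- data.frame(
                accession = acc, individual_id = ind,
                family_id = NA_character_, ko_term = NA_character_,
                phylum = if (withPhylum)
                    sample(phyla, 1, prob = phylaWeight) else NA_character_,
                is_human = FALSE, mu = stats::rnorm(1, -0.5, 1),
                stringsAsFactors = FALSE)
        }
        ## shared host proteins (identical sequences in every database)
        for (j in seq_len(nHuman)) {
            acc <- sprintf("%s_HUM%03d", ind, j)
            seqs <- c(seqs, humanBases[j]); seqNames <- c(seqNames, acc)
            seqInd <- c(seqInd, ind)
            rows[[length(rows) + 1L]] <- data.frame(
                accession = acc, individual_id = ind,
                family_id = sprintf("HF%03d", j), ko_term = NA_character_,
                phylum = NA_character_, is_human = TRUE, mu = humanMu[j],
                stringsAsFactors = FALSE)
        }
    }
    proteins <- do.call(rbind, rows)
    database <- Biostrings::AAStringSet(seqs)
    names(database) <- seqNames
    S4Vectors::mcols(database) <- S4Vectors::DataFrame(individual_id = seqInd)

    famIdx <- as.integer(factor(proteins$family_id,
                                levels = unique(proteins$family_id)))
    genusIdx <- ifelse(is.na(famIdx), 0L, famIdx %% 7L + 1L)
    annotation <- data.frame(
        accession = proteins$accession,
        ko_term = proteins$ko_term,
        phylum = proteins$phylum,
        genus = ifelse(is.na(proteins$phylum), NA_character_,
                       paste0(substr(proteins$phylum, 1, 4), "_g", genusIdx)),
        organism_label = ifelse(proteins$is_human, "human",
                         ifelse(is.na(proteins$phylum), "unassigned",
                                proteins$phylum)),
        stringsAsFactors = FALSE)
    annotation$genus[proteins$is_human] <- NA_character_

    ## module set drawn from the simulated KO pool
    nModules <- 20L
    modIds <- sprintf("MF%04d", seq_len(nModules))
    modNames <- sprintf("synthetic module %d", seq_len(nModules))
    steps <- lapply(seq_len(nModules), function(m) {
        nSteps <- sample(2:5, 1)
        lapply(seq_len(nSteps), function(st) {
            nComp <- if (stats::runif(1) < 0.9) 1L else 2L
            lapply(seq_len(nComp), function(cp)
                sample(kos, sample(1:3, 1)))
        })
    })
    modules <- new("ModuleSet", moduleId = modIds, moduleName = modNames,
                   steps = steps)

    koPhylaDf <- do.call(rbind, lapply(seq_along(kos), function(i)
        data.frame(ko_term = kos[i], phylum = koPhyla[[i]],
                   stringsAsFactors = FALSE)))

    list(database = database, annotation = annotation, modules = modules,
         proteins = proteins, koPhyla = koPhylaDf)
}

#' Simulate expressed protein sets and abundances across time
#'
#' Each individual starts from a log-normal baseline over a random subset of
#' its proteins; the per-family log-mean is shifted by an individual-specific
#' offset with standard deviation `individualEffect`. Between consecutive
#' time points a `turnover` fraction of the expressed microbial proteins is
#' replaced: with probability `koPreservation` the replacement is an
#' unexpressed protein of the same individual sharing the departing
#' protein's KO term (any phylum; the protein is retained when no such
#' candidate exists), otherwise a random unexpressed protein. This single
#' mechanism yields protein-level volatility, KO-level stability and
#' phylum switching of module evidence. Host proteins are expressed stably.
#'
#' @param config a [SimulationConfig].
#' @param cohort result of [generateCohort()].
#' @return a `data.frame` of expressed proteins: `sample_id`,
#'   `individual_id`, `day`, `accession`, `abundance`.
#' @export
simulateTimepoints <- function(config, cohort) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@rngSeed + 1L)
    pr <- cohort$proteins
    days <- as.integer((seq_len(config@nTimepoints) - 1L) * 90L)
    out <- list()
    for (ind in unique(pr$individual_id)) {
        mine <- pr[pr$individual_id == ind, , drop = FALSE]
        micro <- mine$accession[!mine$is_human]
        human <- mine$accession[mine$is_human]
        ## individual-specific offset per family (shared by its variants)
        famIds <- unique(mine$family_id[!is.na(mine$family_id) &
                                        !mine$is_human])
        offsets <- stats::rnorm(length(famIds), 0, config@individualEffect)
        names(offsets) <- famIds
        off <- rep(0, nrow(mine)); names(off) <- mine$accession
        hasFam <- !is.na(mine$family_id) & !mine$is_human
        off[hasFam] <- offsets[mine$family_id[hasFam]]
        off[!hasFam & !mine$is_human] <-
            stats::rnorm(sum(!hasFam & !mine$is_human), 0,
                         config@individualEffect)
        logA <- mine$mu + off + stats::rnorm(nrow(mine), 0, 0.3)
        names(logA) <- mine$accession

        ## under half the repertoire is expressed at a time: real protein
        ## databases dwarf the expressed proteome, and turnover needs
        ## unexpressed same-KO spares to draw from
        expressed <- sample(micro, max(2L, round(0.4 * length(micro))))
        expressedHuman <- sample(human, max(1L, round(0.7 * length(human))))
        koOf <- mine$ko_term; names(koOf) <- mine$accession

        for (t in seq_len(config@nTimepoints)) {
            if (t > 1L) {
                nRep <- round(config@turnover * length(expressed))
                departing <- sample(expressed, nRep)
                prev <- expressed
                cur <- expressed
                for (p in departing) {
                    cur <- setdiff(cur, p)
                    ## replacements come from proteins new to this time
                    ## point: not currently expressed and not expressed at
                    ## the previous one (departing proteins cannot return)
                    unexpressed <- setdiff(setdiff(micro, cur), prev)
                    preserve <- stats::runif(1) < config@koPreservation
                    if (preserve) {
                        ## same-KO spare (unannotated proteins count as
                        ## sharing the "no KO" state); retain when none
                        cand <- if (is.na(koOf[p]))
                            unexpressed[is.na(koOf[unexpressed])]
                        else
                            unexpressed[!is.na(koOf[unexpressed]) &
                                        koOf[unexpressed] == koOf[p]]
                        if (length(cand)) {
                            cur <- c(cur, sample(cand, 1))
                        } else {
                            cur <- c(cur, p)
                        }
                    } else {
                        if (length(unexpressed)) {
                            cur <- c(cur, sample(unexpressed, 1))
                        } else cur <- c(cur, p)
                    }
                }
                expressed <- cur
            }
            accs <- c(expressed, expressedHuman)
            jitter <- stats::rnorm(length(accs), 0, 0.2)
            out[[length(out) + 1L]] <- data.frame(
                sample_id = sprintf("%s_d%03d", ind, days[t]),
                individual_id = ind,
                day = days[t],
                accession = accs,
                abundance = exp(logA[accs] + jitter),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Draw peptide spectral counts for one sample
#'
#' Digests the expressed proteins in silico (tryptic rule, no missed
#' cleavages, peptides of 6-40 residues retained) and draws `depth` spectra
#' from a multinomial over (protein, peptide) pairs with weights
#' proportional to protein abundance. Counts are aggregated per peptide.
#'
#' @param database [Biostrings::AAStringSet] holding the protein sequences.
#' @param expressed `data.frame` with `accession` and `abundance` for one
#'   sample.
#' @param depth total spectra to draw.
#' @param rngSeed integer seed for this sample's draw.
#' @return a `data.frame` with `peptide` and `spectral_count` (counts >= 1).
#' @export
samplePsms <- function(database, expressed, depth, rngSeed) {
    set.seed(as.integer(rngSeed))
    seqs <- as.character(database[expressed$accession])
    pepList <- lapply(seqs, digestTryptic)
    nPeps <- lengths(pepList)
    if (any(nPeps == 0))
        stop("no tryptic peptides in the retained length range for: ",
             paste(expressed$accession[nPeps == 0], collapse = ", "),
             call. = FALSE)
    pairPep <- unlist(pepList, use.names = FALSE)
    pairW <- rep(expressed$abundance, nPeps)
    counts <- as.vector(stats::rmultinom(1, size = depth, prob = pairW))
    keep <- counts > 0
    agg <- rowsum(counts[keep], group = pairPep[keep], reorder = TRUE)
    data.frame(peptide = rownames(agg),
               spectral_count = as.integer(agg[, 1]),
               stringsAsFactors = FALSE)
}

#' Simulate a complete longitudinal cohort
#'
#' Runs [generateCohort()], [simulateTimepoints()] and [samplePsms()] for
#' every sample, returning everything the analysis pipeline consumes plus
#' the ground truth. Fully determined by `config@rngSeed`; optionally writes
#' all external files via [writeCohort()].
#'
#' @param config a [SimulationConfig].
#' @param dir optional output directory for the emitted files.
#' @return a list: `config`, `database`, `annotation`, `modules`, `psms`
#'   (full five-column PSM table), `expressed` (ground-truth expression),
#'   `proteins` (ground-truth protein table), `koPhyla`, `sampleInfo`.
#' @export
simulateCohort <- function(config = simulationConfig(), dir = NULL) {
    cohort <- generateCohort(config)
    expressed <- simulateTimepoints(config, cohort)
    sampleInfo <- unique(expressed[, c("sample_id", "individual_id", "day")])
    sampleInfo <- sampleInfo[order(sampleInfo$individual_id,
                                   sampleInfo$day), , drop = FALSE]
    rownames(sampleInfo) <- NULL
    psms <- do.call(rbind, lapply(seq_len(nrow(sampleInfo)), function(i) {
        s <- sampleInfo$sample_id[i]
        exp1 <- expressed[expressed$sample_id == s, , drop = FALSE]
        p <- samplePsms(cohort$database, exp1, config@depth,
                        rngSeed = config@rngSeed + 1000L + i)
        data.frame(sample_id = s,
                   individual_id = sampleInfo$individual_id[i],
                   day = sampleInfo$day[i],
                   peptide = p$peptide,
                   spectral_count = p$spectral_count,
                   stringsAsFactors = FALSE)
    }))
    rownames(psms) <- NULL
    sim <- list(config = config, database = cohort$database,
                annotation = cohort$annotation, modules = cohort$modules,
                psms = psms, expressed = expressed,
                proteins = cohort$proteins, koPhyla = cohort$koPhyla,
                sampleInfo = sampleInfo)
    if (!is.null(dir)) writeCohort(sim, dir)
    sim
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the readers consume: one FASTA per individual,
#' the annotation TSV, the module definition file, the PSM TSV, and
#' ground-truth TSVs. Re-running with the same seed gives byte-identical
#' files.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohort <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    indIds <- unique(S4Vectors::mcols(sim$database)$individual_id)
    for (ind in indIds) {
        sel <- S4Vectors::mcols(sim$database)$individual_id == ind
        p <- file.path(dir, paste0("proteins_", ind, ".fasta"))
        writeProteinFasta(sim$database[sel], p)
        paths[paste0("fasta_", ind)] <- p
    }
    paths["annotation"] <- writeAnnotationTable(
        sim$annotation, file.path(dir, "annotation.tsv"))
    paths["modules"] <- writeModuleDefinitions(
        sim$modules, file.path(dir, "modules.txt"))
    paths["psms"] <- writePsmTable(sim$psms, file.path(dir, "psms.tsv"))
    truth <- sim$proteins
    paths["truth_proteins"] <- .writeTsv(
        truth, file.path(dir, "ground_truth_proteins.tsv"))
    paths["truth_expressed"] <- .writeTsv(
        sim$expressed, file.path(dir, "ground_truth_expressed.tsv"))
    invisible(paths)
}
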