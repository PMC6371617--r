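smallConfig <- function(...) {
    simulationConfig(nIndividuals = 3, nTimepoints = 3,
                     proteinsPerIndividual = 40, nKoTerms = 10,
                     depth = 1500, rngSeed = 11, ...)
}

test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(nIndividuals = 1), "nIndividuals")
    expect_error(simulationConfig(nTimepoints = 1), "nTimepoints")
    expect_error(simulationConfig(turnover = 1.5), "turnover")
    expect_error(simulationConfig(depth = 0), "depth")
    expect_error(simulationConfig(koPhylumRedundancy = 0.5,
                                  phyla = "Firmicutes"), "2 phyla")
})

test_that("tryptic digestion cleaves after K/R except before P", {
    expect_equal(digestTryptic("MKAAAAAARGGGGGGK"),
                 c("AAAAAAR", "GGGGGGK"))
    ## K before P is not a cleavage site
    expect_equal(digestTryptic("AAAAAKPAAAAK"), "AAAAAKPAAAAK")
    ## length filter 6-40
    expect_equal(digestTryptic("AAKCCK"), character(0))
    long <- paste(rep("A", 45), collapse = "")
    expect_equal(digestTryptic(long), character(0))
})

test_that("the same seed reproduces byte-identical cohort files", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p1 <- simulateCohort(smallConfig(), dir = d1)
    p2 <- simulateCohort(smallConfig(), dir = d2)
    f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
    expect_equal(f1, f2)
    for (f in f1)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("emitted files round-trip through the readers", {
    d <- withr::local_tempdir()
    sim <- simulateCohort(smallConfig(), dir = d)
    fasta <- sort(list.files(d, pattern = "^proteins_.*fasta$",
                             full.names = TRUE))
    names(fasta) <- sub("^proteins_(.*)\\.fasta$", "\\1", basename(fasta))
    db <- readProteinDatabases(fasta)
    expect_setequal(names(db), names(sim$database))
    expect_equal(as.character(db[names(sim$database)]),
                 as.character(sim$database))
    psms <- readPsmTable(file.path(d, "psms.tsv"))
    expect_equal(psms, aggregatePsms(sim$psms))
    ann <- readAnnotationTable(file.path(d, "annotation.tsv"))
    expect_equal(ann$accession, sim$annotation$accession)
    expect_equal(ann$ko_term, sim$annotation$ko_term)
    mods <- readModuleDefinitions(file.path(d, "modules.txt"))
    expect_equal(moduleSteps(mods), moduleSteps(sim$modules))
})

test_that("redundancy parameter controls multi-phylum KO encoding", {
    full <- generateCohort(smallConfig(koPhylumRedundancy = 1))
    perKo <- table(unique(full$koPhyla)$ko_term)
    expect_true(all(perKo >= 2))
    none <- generateCohort(smallConfig(koPhylumRedundancy = 0))
    perKo0 <- table(unique(none$koPhyla)$ko_term)
    expect_true(all(perKo0 == 1))
})

test_that("zero turnover keeps expressed sets constant across time", {
    cfg <- smallConfig(turnover = 0)
    sim <- simulateCohort(cfg)
    for (ind in unique(sim$sampleInfo$individual_id)) {
        ids <- sim$sampleInfo$sample_id[sim$sampleInfo$individual_id == ind]
        sets <- lapply(ids, function(s)
            sort(sim$expressed$accession[sim$expressed$sample_id == s]))
        for (k in seq_along(sets)[-1])
            expect_identical(sets[[k]], sets[[1]])
    }
})

test_that("full turnover with full KO preservation keeps the KO set, not proteins", {
    ## enough proteins per KO that same-KO spares are almost always
    ## available; the residual overlap is proteins retained for lack of one
    cfg <- simulationConfig(nIndividuals = 3, nTimepoints = 3,
                            proteinsPerIndividual = 80, nKoTerms = 8,
                            depth = 1500, rngSeed = 11,
                            turnover = 1, koPreservation = 1)
    cohort <- generateCohort(cfg)
    expressed <- simulateTimepoints(cfg, cohort)
    koOf <- setNames(cohort$proteins$ko_term, cohort$proteins$accession)
    isHuman <- setNames(cohort$proteins$is_human, cohort$proteins$accession)
    overlaps <- c()
    for (ind in unique(expressed$individual_id)) {
        days <- sort(unique(expressed$day[expressed$individual_id == ind]))
        sets <- lapply(days, function(d) {
            a <- expressed$accession[expressed$individual_id == ind &
                                     expressed$day == d]
            a[!isHuman[a]]
        })
        for (k in seq_along(sets)[-1]) {
            prev <- sets[[k - 1]]; curr <- sets[[k]]
            overlaps <- c(overlaps,
                          length(intersect(prev, curr)) / length(prev))
            koPrev <- sort(unique(stats::na.omit(koOf[prev])))
            koCurr <- sort(unique(stats::na.omit(koOf[curr])))
            expect_identical(koCurr, koPrev)
        }
    }
    expect_lt(mean(overlaps), 0.2)
})

test_that("KO-preserving turnover with redundancy switches module phyla", {
    fx <- defaultCohortFixture()
    sw <- fx$res$switches
    expect_gt(nrow(sw), 0)
    expect_true(all(sw$phyla_from != sw$phyla_to))
})

test_that("PSM sampling conserves depth and respects digestion", {
    sim <- simulateCohort(smallConfig())
    perSample <- tapply(sim$psms$spectral_count, sim$psms$sample_id, sum)
    expect_true(all(perSample == 1500))
    ## every sampled peptide is a tryptic fragment of an expressed protein
    s <- sim$sampleInfo$sample_id[1]
    exp1 <- sim$expressed[sim$expressed$sample_id == s, ]
    validPeps <- unique(unlist(lapply(
        as.character(sim$database[exp1$accession]), digestTryptic)))
    expect_true(all(sim$psms$peptide[sim$psms$sample_id == s] %in%
                    validPeps))
})

test_that("doubling a protein's abundance doubles its expected counts", {
    set.seed(91)
    db <- Biostrings::AAStringSet(c(
        x = paste0("AAADDDEEEK", "CCCFFFGGGK", "MMMNNNQQQK"),
        y = paste0("WWWYYYVVVK", "TTTSSSHHHK", "IIIMMMCCCK")))
    draw <- function(abX, seed) {
        expressed <- data.frame(accession = c("x", "y"),
                                abundance = c(abX, 1))
        p <- samplePsms(db, expressed, depth = 2000, rngSeed = seed)
        xPeps <- digestTryptic(as.character(db[["x"]]))
        sum(p$spectral_count[p$peptide %in% xPeps])
    }
    m1 <- mean(vapply(1:100, function(i) draw(1, i), numeric(1)))
    m2 <- mean(vapply(1:100, function(i) draw(2, 1000 + i), numeric(1)))
    expect_equal(m2 / m1, 2000 * (2/3) / (2000 * 0.5) , tolerance = 0.05)
})

test_that("sampling errors on proteins with no usable peptides", {
    db <- Biostrings::AAStringSet(c(bad = "AAKCCK"))
    expressed <- data.frame(accession = "bad", abundance = 1)
    expect_error(samplePsms(db, expressed, 100, 1), "no tryptic peptides")
})
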