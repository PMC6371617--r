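test_that("step coverage follows the AND/OR semantics", {
    ## 3-step module, one step covered -> 1/3
    m3 <- simpleSteps("K00001", "K00002", "K00003")
    expect_equal(computeCoverage(m3, "K00001"), 1/3)
    expect_equal(computeCoverage(m3, character(0)), 0)
    ## OR-alternatives: either KO satisfies the component
    m2 <- simpleSteps(c("K00001", "K00002"), "K00003")
    expect_equal(computeCoverage(m2, "K00002"), 0.5)
    ## AND-components: all must be satisfied
    mAnd <- list(list(list("K00001"), list("K00002")))
    expect_equal(computeCoverage(mAnd, "K00001"), 0)
    expect_equal(computeCoverage(mAnd, c("K00001", "K00002")), 1)
})

test_that("coverage matches truth-table enumeration for small random modules", {
    set.seed(41)
    pool <- sprintf("K%05d", 1:12)
    for (rep in 1:30) {
        steps <- lapply(seq_len(sample(1:4, 1)), function(s)
            lapply(seq_len(sample(1:2, 1)), function(cp)
                sample(pool, sample(1:3, 1))))
        koSet <- sample(pool, sample(0:8, 1))
        expect_equal(computeCoverage(steps, koSet),
                     oracleCoverage(steps, koSet))
    }
})

test_that("coverage is monotone in the KO set and 1 only at full coverage", {
    set.seed(43)
    pool <- sprintf("K%05d", 1:15)
    steps <- lapply(1:4, function(s) list(sample(pool, 2)))
    small <- sample(pool, 4)
    for (extra in 1:5) {
        big <- union(small, sample(pool, extra))
        expect_gte(computeCoverage(steps, big), computeCoverage(steps, small))
    }
    allKos <- unique(unlist(steps))
    expect_equal(computeCoverage(steps, allKos), 1)
})

test_that("module inference applies >= 1/3 within a single phylum only", {
    ms <- toyModuleSet(list(
        simpleSteps("K00001", "K00002", "K00003"),              # 3 steps
        simpleSteps("K00011", "K00012", "K00013", "K00014")))   # 4 steps
    detected <- data.frame(
        sample_id = "S1",
        phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
        ko_term = c("K00001", "K00011", "K00012"),
        stringsAsFactors = FALSE)
    calls <- inferModules(ms, detected)
    getCall <- function(p, m) calls[calls$phylum == p & calls$module_id == m, ]
    ## 1/3 of steps in one phylum: inferred (>= includes equality)
    expect_true(getCall("Firmicutes", "MF0001")$inferred)
    expect_equal(getCall("Firmicutes", "MF0001")$coverage, 1/3)
    ## 1/4 in one phylum: below threshold
    expect_false(getCall("Firmicutes", "MF0002")$inferred)
    ## union across phyla (2/4) would pass, but must not be used
    expect_false(getCall("Bacteroidetes", "MF0002")$inferred)
    expect_false(any(calls$inferred[calls$module_id == "MF0002"]))

    expect_error(inferModules(ms, detected, threshold = 0), "0, 1")
})

test_that("the inferred set is monotone in KO detections and threshold", {
    set.seed(47)
    pool <- sprintf("K%05d", 1:20)
    ms <- toyModuleSet(lapply(1:6, function(i)
        simpleSteps(sample(pool, 2), sample(pool, 2), sample(pool, 2))))
    det1 <- data.frame(sample_id = "S1", phylum = "Firmicutes",
                       ko_term = sample(pool, 5), stringsAsFactors = FALSE)
    det2 <- rbind(det1, data.frame(sample_id = "S1", phylum = "Firmicutes",
                                   ko_term = setdiff(pool, det1$ko_term)[1:4],
                                   stringsAsFactors = FALSE))
    c1 <- inferModules(ms, det1); c2 <- inferModules(ms, det2)
    expect_true(all(c2$inferred[c1$inferred]))
    cLoose <- inferModules(ms, det1, threshold = 0.2)
    expect_true(all(cLoose$inferred[c1$inferred]))
})

test_that("detected KO sets come from identified microbial groups only", {
    annotated <- S4Vectors::DataFrame(
        group_id = c("PG1", "PG2", "PG3", "PG4"),
        seed_accession = c("a", "b", "c", "d"),
        ko_term = c("K00925", "K00925", "K01443", NA),
        phylum = c("Firmicutes", "Bacteroidetes", NA, NA),
        genus = NA_character_,
        category = c("microbial", "microbial", "human", "unassigned"))
    ident <- matrix(c(TRUE, TRUE, TRUE, TRUE,
                      FALSE, TRUE, TRUE, FALSE), ncol = 2,
                    dimnames = list(c("PG1", "PG2", "PG3", "PG4"),
                                    c("S1", "S2")))
    det <- detectedKoSets(annotated, ident)
    ## same KO in two phyla is represented in both
    s1 <- det[det$sample_id == "S1", ]
    expect_setequal(s1$phylum, c("Firmicutes", "Bacteroidetes"))
    expect_equal(unique(s1$ko_term), "K00925")
    ## human and unassigned groups contribute nothing
    expect_false("K01443" %in% det$ko_term)
    ## identification gates detection
    s2 <- det[det$sample_id == "S2", ]
    expect_equal(s2$phylum, "Bacteroidetes")
})

test_that("module abundance means identified mapping groups and fractions totals", {
    fxDb <- Biostrings::AAStringSet(c(
        a = paste0("AAAAAAAAAK", "CCDDEEFFGGK", "MMMMMMMMMK"),
        b = paste0("WWWWWWWWWK", "HHIIKKLLMMK", "TTTTTTTTTK")))
    groups <- clusterProteins(fxDb)
    pm <- mapPeptides(c("AAAAAAAAAK", "CCDDEEFFGGK", "WWWWWWWWWK",
                        "HHIIKKLLMMK"), groups)
    psms <- toyPsms(list(
        list("S1", "I01", 0, "AAAAAAAAAK", 3),
        list("S1", "I01", 0, "CCDDEEFFGGK", 1),
        list("S1", "I01", 0, "WWWWWWWWWK", 4),
        list("S1", "I01", 0, "HHIIKKLLMMK", 2)))
    ident <- identifyGroups(groups, pm, psms)
    se <- balanceSpectra(groups, pm, psms, ident)
    gidOf <- function(acc) {
        ml <- as.list(groupMembers(groups))
        names(ml)[vapply(ml, function(m) acc %in% m, logical(1))]
    }
    annotated <- S4Vectors::DataFrame(
        group_id = groupIds(groups),
        seed_accession = seedAccessions(groups),
        ko_term = c("K00001", "K00002")[match(groupIds(groups),
                                              c(gidOf("a"), gidOf("b")))],
        phylum = "Firmicutes", genus = NA_character_,
        category = "microbial")
    ms <- toyModuleSet(list(simpleSteps(c("K00001", "K00002"), "K00099")))
    det <- detectedKoSets(annotated, ident)
    calls <- inferModules(ms, det)
    calls <- moduleAbundance(calls, ms, annotated, se, ident)
    ## both groups map (KO in step 1 alternatives): balanced counts 4 and 6
    expect_equal(calls$abundance_mean, 5)
    expect_equal(calls$abundance_fraction, 1)   # 10 of 10 total spectra
})

test_that("abundance is zero when no group maps", {
    annotated <- S4Vectors::DataFrame(
        group_id = "PG1", seed_accession = "a", ko_term = "K00001",
        phylum = "Firmicutes", genus = NA_character_,
        category = "microbial")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(balanced = matrix(5, 1, 1,
                                        dimnames = list("PG1", "S1"))),
        colData = S4Vectors::DataFrame(sample_id = "S1",
                                       individual_id = "I01", day = 0L,
                                       total_spectra = 5,
                                       row.names = "S1"))
    ident <- matrix(TRUE, 1, 1, dimnames = list("PG1", "S1"))
    ms <- toyModuleSet(list(simpleSteps("K09999", "K09998", "K09997")))
    calls <- data.frame(sample_id = "S1", phylum = "Firmicutes",
                        module_id = "MF0001", coverage = 0,
                        inferred = FALSE, stringsAsFactors = FALSE)
    calls <- moduleAbundance(calls, ms, annotated, se, ident)
    expect_equal(calls$abundance_mean, 0)
    expect_equal(calls$abundance_fraction, 0)
})

test_that("redundancy classes follow the single / multi / all-major scheme", {
    calls <- data.frame(
        sample_id = rep(c("S1", "S2"), each = 4),
        phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes",
                   "Actinobacteria", "Firmicutes", "Proteobacteria",
                   "Bacteroidetes", "Verrucomicrobia"),
        module_id = c("MF0001", "MF0002", "MF0002", "MF0003", "MF0003",
                      "MF0003", "MF0003", "MF0004"),
        coverage = 1, inferred = TRUE, stringsAsFactors = FALSE)
    rc <- redundancyClasses(calls)
    cls <- setNames(rc$class, rc$module_id)
    expect_equal(cls[["MF0001"]], "single_phylum")
    expect_equal(cls[["MF0002"]], "multi_phylum")
    expect_equal(cls[["MF0003"]], "all_major")
    expect_equal(cls[["MF0004"]], "single_phylum")
})

test_that("phylum switches are consecutive same-individual evidence changes", {
    calls <- data.frame(
        sample_id = c("A_d000", "A_d090", "A_d090", "B_d000", "B_d090"),
        phylum = c("Firmicutes", "Bacteroidetes", "Firmicutes",
                   "Firmicutes", "Firmicutes"),
        module_id = "MF0001", coverage = 1, inferred = TRUE,
        stringsAsFactors = FALSE)
    si <- data.frame(
        sample_id = c("A_d000", "A_d090", "B_d000", "B_d090"),
        individual_id = c("A", "A", "B", "B"),
        day = c(0L, 90L, 0L, 90L), stringsAsFactors = FALSE)
    sw <- phylumSwitchEvents(calls, si)
    ## A: {Firmicutes} -> {Bacteroidetes, Firmicutes} is a switch; B stable
    expect_equal(nrow(sw), 1L)
    expect_equal(sw$individual_id, "A")
    expect_equal(sw$phyla_from, "Firmicutes")
    expect_equal(sw$phyla_to, "Bacteroidetes;Firmicutes")
})
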