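test_that("pairwise identity matches hand cases and the DP oracle", {
    expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL"), 1.0)
    expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKW"), 0.9)
    ## one-residue truncation: 9 matches over 10 alignment columns
    expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIK"),
                 oracleIdentity("ACDEFGHIKL", "ACDEFGHIK"))
    expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIK"), 0.9)
    expect_error(pairwiseIdentity("", "ACD"), "non-empty")
})

test_that("pairwise identity is symmetric and agrees with the oracle on random pairs", {
    set.seed(101)
    for (i in 1:25) {
        a <- randomAASeq(sample(15:50, 1))
        b <- mutateSeq(a, nSub = sample(0:5, 1), nDel = sample(0:3, 1))
        expect_equal(pairwiseIdentity(a, b), oracleIdentity(a, b),
                     tolerance = 1e-12)
        expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a),
                     tolerance = 1e-12)
    }
})

test_that("I/L equivalence is an explicit, off-by-default switch", {
    expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKI"), 0.9)
    expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKI",
                                  ileLeuEquivalent = TRUE), 1.0)
})

test_that("greedy clustering handles singleton, tie and mixed cases", {
    one <- Biostrings::AAStringSet(c(x = "ACDEFGHIKLMNPQRSTVWY"))
    g1 <- clusterProteins(one)
    expect_length(g1, 1L)
    expect_equal(seedAccessions(g1), "x")

    ## two identical sequences: seed is the lexicographically smaller accession
    twins <- Biostrings::AAStringSet(c(zz = "ACDEFGHIKLMNPQRSTVWY",
                                       aa = "ACDEFGHIKLMNPQRSTVWY"))
    g2 <- clusterProteins(twins)
    expect_length(g2, 1L)
    expect_equal(seedAccessions(g2), "aa")

    ## A and B at >= 90%, C unrelated (verified against the oracle)
    A <- "AAACCDDEEKFFGGHHIIKK"; B <- "AAACCDDEEKFFGGHHIIKW"
    C <- "WWYYVVTTSSKMMNNPPQQR"
    expect_gte(oracleIdentity(A, B), 0.9)
    expect_lt(oracleIdentity(A, C), 0.9)
    expect_lt(oracleIdentity(B, C), 0.9)
    g3 <- clusterProteins(Biostrings::AAStringSet(c(a = A, b = B, c = C)))
    expect_equal(sort(unname(vapply(as.list(groupMembers(g3)), paste, "",
                                    collapse = "+"))), c("a+b", "c"))

    expect_error(clusterProteins(one, threshold = 0), "0, 1")
    expect_error(clusterProteins(one, threshold = 1.2), "0, 1")
})

test_that("clustering partitions the database and matches the oracle on small sets", {
    set.seed(7)
    for (rep in 1:6) {
        n <- sample(4:8, 1)
        base <- randomAASeq(sample(25:50, 1))
        seqs <- vapply(seq_len(n), function(i) {
            if (i <= 2) mutateSeq(base, nSub = sample(0:2, 1))
            else if (i == 3) mutateSeq(base, nSub = sample(1:2, 1),
                                       nDel = sample(0:1, 1))
            else randomAASeq(sample(20:55, 1))
        }, "")
        names(seqs) <- sprintf("s%02d", sample(n))
        db <- Biostrings::AAStringSet(seqs)
        got <- clusterProteins(db, 0.9)
        ## partition
        members <- unlist(as.list(groupMembers(got)), use.names = FALSE)
        expect_setequal(members, names(seqs))
        expect_equal(length(members), length(seqs))
        ## exact agreement with the independently re-run greedy procedure
        want <- oracleGreedyClusters(seqs, 0.9)
        expect_setequal(vapply(as.list(groupMembers(got)), paste, "",
                               collapse = "+"),
                        vapply(want, paste, "", collapse = "+"))
        ## every member meets the threshold to its seed, per the oracle
        for (k in seq_along(got)) {
            sd <- seedAccessions(got)[k]
            for (m in as.list(groupMembers(got))[[k]])
                expect_gte(oracleIdentity(seqs[[sd]], seqs[[m]]), 0.9)
        }
    }
})

test_that("lowering the identity threshold never increases the group count", {
    set.seed(19)
    base <- randomAASeq(40)
    seqs <- c(vapply(1:4, function(i) mutateSeq(base, nSub = i), ""),
              vapply(1:4, function(i) randomAASeq(sample(30:50, 1)), ""))
    names(seqs) <- sprintf("q%d", seq_along(seqs))
    db <- Biostrings::AAStringSet(seqs)
    counts <- vapply(c(0.95, 0.9, 0.8, 0.6, 0.4),
                     function(th) length(clusterProteins(db, th)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("peptides map by exact substring containment with unique/shared status", {
    g <- clusterProteins(toyDatabase())          # {p1,p2}, {p3}
    expect_length(g, 2L)
    pm <- suppressWarnings(mapPeptides(
        c("AAACCDDEEK", "FFGGHHIIK", "MMNNPPQQR", "WWWWWWWW"), g))
    pg <- peptideGroups(pm)
    expect_length(pg[["AAACCDDEEK"]], 1L)        # only group {p1,p2}
    expect_true(isUnique(pm)[["AAACCDDEEK"]])
    expect_true(isUnique(pm)[["MMNNPPQQR"]])
    expect_equal(unmappedPeptides(pm), "WWWWWWWW")
    expect_warning(mapPeptides("WWWWWWWW", g), "no protein group")
})

test_that("a peptide spanning two groups is shared and maps to both", {
    ## two unrelated proteins engineered to share one tryptic peptide
    shared <- "CCDDEEFFGGK"
    db <- Biostrings::AAStringSet(c(
        x = paste0("AAAAAAAAAK", shared, "MMMMMMMMMK"),
        y = paste0("WWWWWWWWWK", shared, "TTTTTTTTTK")))
    g <- clusterProteins(db)
    expect_length(g, 2L)
    pm <- mapPeptides(shared, g)
    expect_length(peptideGroups(pm)[[shared]], 2L)
    expect_false(isUnique(pm)[[shared]])
})

test_that("identification needs two distinct peptides including one unique", {
    g <- clusterProteins(toyDatabase())
    gidOf <- function(acc) {
        ml <- as.list(groupMembers(g))
        names(ml)[vapply(ml, function(m) acc %in% m, logical(1))]
    }
    g12 <- gidOf("p1"); g3 <- gidOf("p3")
    pm <- suppressWarnings(mapPeptides(
        c("AAACCDDEEK", "FFGGHHIIK", "MMNNPPQQR"), g))

    ## one unique + one more distinct peptide -> identified
    id1 <- classifyIdentified(pm, c("AAACCDDEEK", "FFGGHHIIK"), groupIds(g))
    expect_true(id1[[g12]])
    ## a single distinct peptide is not enough, unique or not
    id2 <- classifyIdentified(pm, "AAACCDDEEK", groupIds(g))
    expect_false(id2[[g12]])
    ## two distinct peptides but on another group only
    expect_false(id1[[g3]])
})

test_that("groups with only shared peptides are never identified", {
    shared1 <- "CCDDEEFFGGK"; shared2 <- "HHIIMMNNPPK"
    db <- Biostrings::AAStringSet(c(
        x = paste0("AAAAAAAAAK", shared1, shared2, "MMMMMMMMMK"),
        y = paste0("WWWWWWWWWK", shared1, shared2, "TTTTTTTTTK")))
    g <- clusterProteins(db)
    pm <- mapPeptides(c(shared1, shared2), g)
    id <- classifyIdentified(pm, c(shared1, shared2), groupIds(g))
    expect_false(any(id))
})

test_that("adding observed peptides never revokes identification", {
    set.seed(23)
    sim <- simulateCohort(simulationConfig(
        nIndividuals = 2, nTimepoints = 2, proteinsPerIndividual = 30,
        nKoTerms = 8, depth = 800, rngSeed = 23))
    g <- clusterProteins(sim$database)
    peps <- unique(sim$psms$peptide)
    pm <- suppressWarnings(mapPeptides(peps, g))
    for (rep in 1:5) {
        subsetPeps <- sample(peps, length(peps) %/% 2)
        small <- classifyIdentified(pm, subsetPeps, groupIds(g))
        big <- classifyIdentified(pm, union(subsetPeps,
                                            sample(peps, 20)), groupIds(g))
        expect_true(all(big[small]))
    }
})
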