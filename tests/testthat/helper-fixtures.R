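## Shared fixtures. The default synthetic cohort and its full analysis are
## computed once per test session and reused by every file that needs them.

.fixtureEnv <- new.env(parent = emptyenv())

defaultCohortFixture <- function() {
    if (!exists("cohort", envir = .fixtureEnv)) {
        sim <- simulateCohort(simulationConfig())
        res <- analyzeCohort(sim$database, sim$psms, sim$annotation,
                             sim$modules)
        assign("cohort", list(sim = sim, res = res), envir = .fixtureEnv)
    }
    get("cohort", envir = .fixtureEnv)
}

## A tiny hand-built database of three 20-residue proteins: p1/p2 identical
## except one substitution (identity 0.95), p3 unrelated. Shared tryptic
## structure makes peptide mapping and balancing exercisable by hand.
toyDatabase <- function() {
    db <- Biostrings::AAStringSet(c(
        p1 = "AAACCDDEEKFFGGHHIIKK",
        p2 = "AAACCDDEEKFFGGHHIIKW",
        p3 = "WWYYVVTTSSKMMNNPPQQR"))
    S4Vectors::mcols(db) <- S4Vectors::DataFrame(
        individual_id = rep("I01", 3))
    db
}

toyModuleSet <- function(steps, ids = sprintf("MF%04d", seq_along(steps))) {
    new("ModuleSet", moduleId = ids,
        moduleName = paste0("toy_", seq_along(steps)), steps = steps)
}

## Wrap bare character vectors into the steps/AND/OR structure:
## list of steps, each a list of components, each a character vector.
simpleSteps <- function(...) lapply(list(...), function(kos) list(kos))

## Build a ProteinGroupSet / PeptideMap pair with an arbitrary peptide ->
## carrier-group structure (one placeholder member sequence per group), for
## driving balanceSpectra on randomly generated allocation instances.
syntheticBalanceInstance <- function(gids, peps, carriers) {
    db <- Biostrings::AAStringSet(setNames(rep("ACDEFGHIK", length(gids)),
                                           paste0("acc_", gids)))
    groups <- new("ProteinGroupSet", groupId = gids,
                  seedAccession = paste0("acc_", gids),
                  members = IRanges::CharacterList(
                      as.list(paste0("acc_", gids))),
                  threshold = 0.9, database = db)
    pm <- new("PeptideMap", peptide = peps,
              groups = IRanges::CharacterList(carriers),
              unmapped = character(0))
    list(groups = groups, pm = pm)
}

toyPsms <- function(rows) {
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(sample_id = r[[1]], individual_id = r[[2]],
                   day = as.integer(r[[3]]), peptide = r[[4]],
                   spectral_count = as.integer(r[[5]]),
                   stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    df
}
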