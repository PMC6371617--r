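## Independent oracles used to verify the implementation. These deliberately
## share no code with the package: a plain Gotoh dynamic-programming aligner,
## a double-loop module-coverage evaluator, a brute-force greedy-clustering
## verifier, a step-by-step balancing re-implementation, and the adjusted
## Rand index from its contingency-table formula.

## Global affine-gap alignment (match +1, mismatch -1, gap of length L costs
## 5 + L), with traceback. Returns matches and residue-pair columns; identity
## is matches / (la + lb - residue pairs).
oracleIdentity <- function(a, b, match = 1, mismatch = -1,
                           gapOpen = 5, gapExt = 1) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)   # ends with A residue over gap
    Y <- matrix(NEG, n + 1, m + 1)   # ends with gap over B residue
    M[1, 1] <- 0
    if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -(gapOpen + (i - 1) * gapExt)
    if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -(gapOpen + (j - 1) * gapExt)
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- if (A[i - 1] == B[j - 1]) match else mismatch
            M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                           Y[i - 1, j - 1]) + s
            X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt,
                           X[i - 1, j] - gapExt,
                           Y[i - 1, j] - gapOpen - gapExt)
            Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt,
                           Y[i, j - 1] - gapExt,
                           X[i, j - 1] - gapOpen - gapExt)
        }
    }
    ## traceback, preferring the match/mismatch state on ties so the counted
    ## alignment maximises residue pairs among optimal alignments
    i <- n + 1; j <- m + 1
    state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
    nMatch <- 0L; nPairs <- 0L
    while (i > 1 || j > 1) {
        if (state == 1L) {
            s <- if (A[i - 1] == B[j - 1]) match else mismatch
            nPairs <- nPairs + 1L
            if (A[i - 1] == B[j - 1]) nMatch <- nMatch + 1L
            prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
            state <- which.max(prev)
            i <- i - 1; j <- j - 1
        } else if (state == 2L) {
            cand <- c(M[i - 1, j] - gapOpen - gapExt,
                      X[i - 1, j] - gapExt,
                      Y[i - 1, j] - gapOpen - gapExt)
            state <- which.max(cand)
            i <- i - 1
        } else {
            cand <- c(M[i, j - 1] - gapOpen - gapExt,
                      Y[i, j - 1] - gapExt,
                      X[i, j - 1] - gapOpen - gapExt)
            state <- c(1L, 3L, 2L)[which.max(cand)]
            j <- j - 1
        }
        if (i == 1 && j > 1) state <- 3L
        if (j == 1 && i > 1) state <- 2L
    }
    nMatch / (n + m - nPairs)
}

## Module coverage by exhaustive evaluation: loops over steps, components
## and alternatives without any set operations.
oracleCoverage <- function(steps, koSet) {
    covered <- 0L
    for (st in steps) {
        stepOk <- TRUE
        for (comp in st) {
            compOk <- FALSE
            for (alt in comp) {
                for (k in koSet) if (identical(alt, k)) compOk <- TRUE
            }
            if (!compOk) stepOk <- FALSE
        }
        if (stepOk) covered <- covered + 1L
    }
    covered / length(steps)
}

## Re-runs the greedy centroid procedure from scratch with the oracle
## aligner and returns the member sets, for comparison against the package.
oracleGreedyClusters <- function(seqs, threshold) {
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]
    seeds <- integer(0)
    assign <- integer(length(seqs))
    for (i in seq_along(seqs)) {
        placed <- FALSE
        for (k in seq_along(seeds)) {
            if (oracleIdentity(seqs[[seeds[k]]], seqs[[i]]) >= threshold) {
                assign[i] <- k; placed <- TRUE; break
            }
        }
        if (!placed) { seeds <- c(seeds, i); assign[i] <- length(seeds) }
    }
    lapply(seq_along(seeds), function(k) unname(names(seqs)[assign == k]))
}

## Spectral balancing by literal two-step enumeration for one sample.
## peptideGroups: named list peptide -> all carrier group ids;
## counts: named numeric; identified: character vector of identified groups.
oracleBalance <- function(peptideGroups, counts, identified) {
    out <- setNames(numeric(length(identified)), identified)
    uniqueTotals <- setNames(numeric(length(identified)), identified)
    for (p in names(counts)) {
        g <- peptideGroups[[p]]
        if (length(g) == 1 && g %in% identified)
            uniqueTotals[g] <- uniqueTotals[g] + counts[p]
    }
    out <- uniqueTotals
    for (p in names(counts)) {
        g <- intersect(peptideGroups[[p]], identified)
        if (length(peptideGroups[[p]]) > 1 && length(g) > 0) {
            w <- uniqueTotals[g]
            if (sum(w) == 0) w <- rep(1, length(g))
            out[g] <- out[g] + counts[p] * w / sum(w)
        }
    }
    out
}

## Adjusted Rand index straight from the contingency-table formula.
oracleARI <- function(x, y) {
    tab <- table(x, y)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    a <- sum(choose(rowSums(tab), 2))
    b <- sum(choose(colSums(tab), 2))
    expected <- a * b / choose(n, 2)
    maxidx <- (a + b) / 2
    if (maxidx == expected) return(0)
    (sumij - expected) / (maxidx - expected)
}

## Random amino-acid sequence helpers for property tests.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
randomAASeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")
mutateSeq <- function(s, nSub = 0, nDel = 0) {
    ch <- strsplit(s, "")[[1]]
    if (nSub > 0) {
        pos <- sample(length(ch), nSub)
        for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    }
    if (nDel > 0) ch <- ch[-sample(length(ch), nDel)]
    paste(ch, collapse = "")
}
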