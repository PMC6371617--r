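#' Read a protein sequence database from FASTA
#'
#' Reads an amino-acid FASTA file into a named [Biostrings::AAStringSet].
#' The accession of each record is the header token before the first
#' whitespace. Sequences are upper-cased and validated against the 20
#' canonical amino-acid letters; duplicate accessions are rejected.
#'
#' @param path path to a protein FASTA file.
#' @param individualId optional individual label stored in
#'   `mcols(x)$individual_id` for every record.
#' @return an [Biostrings::AAStringSet] named by accession.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDE"), tf)
#' db <- readProteinFasta(tf, individualId = "P1")
#' names(db)
#' @export
readProteinFasta <- function(path, individualId = NA_character_) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    raw <- readLines(path, warn = FALSE)
    nonEmpty <- raw[nzchar(trimws(raw))]
    if (length(nonEmpty) == 0) {
        warning("empty FASTA file: ", path, call. = FALSE)
        out <- Biostrings::AAStringSet()
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            individual_id = character(0))
        return(out)
    }
    if (!startsWith(nonEmpty[1], ">")) {
        lineNo <- which(nzchar(trimws(raw)))[1]
        stop(sprintf("malformed FASTA: line %d does not start a record header",
                     lineNo), call. = FALSE)
    }
    x <- Biostrings::readAAStringSet(path)
    accession <- sub("\\s.*$", "", names(x))
    if (any(!nzchar(accession)))
        stop("malformed FASTA header: empty accession", call. = FALSE)
    if (anyDuplicated(accession))
        stop("duplicate accession(s) in ", path, ": ",
             paste(unique(accession[duplicated(accession)]), collapse = ", "),
             call. = FALSE)
    seqs <- toupper(as.character(x))
    .validateSequences(seqs, accession)
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- accession
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        individual_id = rep(individualId, length(out)))
    out
}

#' Read several per-individual FASTA databases into one set
#'
#' @param paths named character vector of FASTA paths; names are individual
#'   ids attached to each record.
#' @return a single [Biostrings::AAStringSet] with per-record
#'   `individual_id`; accessions must be unique across files.
#' @export
readProteinDatabases <- function(paths) {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
        stop("paths must be named by individual id", call. = FALSE)
    parts <- lapply(names(paths), function(ind)
        readProteinFasta(paths[[ind]], individualId = ind))
    out <- do.call(c, parts)
    if (anyDuplicated(names(out)))
        stop("duplicate accession(s) across databases: ",
             paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
             call. = FALSE)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        individual_id = unlist(lapply(parts, function(p)
            S4Vectors::mcols(p)$individual_id), use.names = FALSE))
    out
}

#' Write a protein database to FASTA
#'
#' @param x a named [Biostrings::AAStringSet].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
    Biostrings::writeXStringSet(x, filepath = path, width = 70L)
    invisible(path)
}

#' Read a peptide-spectrum-match (PSM) table
#'
#' Reads the five-column tab-separated PSM contract: `sample_id`,
#' `individual_id`, `day`, `peptide`, `spectral_count`. The table stands in
#' for FDR-filtered database-search output; counts for identical
#' `(sample_id, peptide)` rows are summed, zero-count rows are dropped with a
#' warning, and negative counts are an error. Peptides shorter than
#' `minPeptideLength` are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @param minPeptideLength minimum retained peptide length (default 6, the
#'   usual tryptic-search floor).
#' @return a `data.frame` with the five columns above, one row per
#'   `(sample_id, peptide)`, integer counts >= 1.
#' @export
readPsmTable <- function(path, minPeptideLength = 6L) {
    df <- .readTsv(path)
    .requireColumns(df, c("sample_id", "individual_id", "day", "peptide",
                          "spectral_count"), "PSM table")
    df$sample_id <- as.character(df$sample_id)
    df$individual_id <- as.character(df$individual_id)
    df$day <- as.integer(df$day)
    df$peptide <- toupper(as.character(df$peptide))
    cnt <- suppressWarnings(as.numeric(df$spectral_count))
    if (any(is.na(cnt)))
        stop("PSM table: non-numeric spectral_count", call. = FALSE)
    if (any(cnt < 0))
        stop("PSM table: negative spectral_count", call. = FALSE)
    df$spectral_count <- as.integer(round(cnt))
    if (any(df$spectral_count == 0L)) {
        warning(sum(df$spectral_count == 0L),
                " zero-count PSM row(s) dropped", call. = FALSE)
        df <- df[df$spectral_count > 0L, , drop = FALSE]
    }
    short <- nchar(df$peptide) < minPeptideLength
    if (any(short)) {
        warning(sum(short), " PSM row(s) below the peptide length floor (",
                minPeptideLength, ") dropped", call. = FALSE)
        df <- df[!short, , drop = FALSE]
    }
    .validateSequences(df$peptide, paste0("peptide:", df$peptide))
    aggregatePsms(df)
}

#' Aggregate PSM rows so that `(sample_id, peptide)` is unique
#'
#' Sums spectral counts over duplicate `(sample_id, peptide)` rows. The
#' operation is idempotent: aggregating an already-aggregated table changes
#' nothing.
#'
#' @param psms a PSM `data.frame` (see [readPsmTable()]).
#' @return the aggregated `data.frame`, ordered by sample then peptide.
#' @export
aggregatePsms <- function(psms) {
    key <- paste(psms$sample_id, psms$peptide, sep = "\r")
    firstIdx <- !duplicated(key)
    meta <- psms[firstIdx, c("sample_id", "individual_id", "day", "peptide"),
                 drop = FALSE]
    counts <- rowsum(psms$spectral_count, group = key, reorder = FALSE)
    out <- cbind(meta, spectral_count = as.integer(counts[, 1]))
    out <- out[order(out$sample_id, out$peptide), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a PSM table
#' @param psms PSM `data.frame`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePsmTable <- function(psms, path) {
    .writeTsv(psms[, c("sample_id", "individual_id", "day", "peptide",
                       "spectral_count")], path)
}

#' Read a protein annotation table
#'
#' Reads the tab-separated annotation contract: `accession`, `ko_term`,
#' `phylum`, `genus`, `organism_label`. Empty fields are absent (`NA`).
#' KO terms must match `K` + 5 digits; records labelled `human` may not
#' carry a phylum.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with the five columns above.
#' @export
readAnnotationTable <- function(path) {
    df <- .readTsv(path)
    .requireColumns(df, c("accession", "ko_term", "phylum", "genus",
                          "organism_label"), "annotation table")
    for (cl in colnames(df)) df[[cl]] <- as.character(df[[cl]])
    if (anyDuplicated(df$accession))
        stop("annotation table: duplicate accession(s)", call. = FALSE)
    present <- !is.na(df$ko_term)
    badKo <- present & !grepl(.KO_PATTERN, df$ko_term)
    if (any(badKo))
        stop("annotation table: malformed KO term(s): ",
             paste(unique(df$ko_term[badKo]), collapse = ", "), call. = FALSE)
    humanWithPhylum <- !is.na(df$organism_label) &
        df$organism_label == "human" & !is.na(df$phylum)
    if (any(humanWithPhylum))
        stop("annotation table: human record(s) carrying a phylum: ",
             paste(df$accession[humanWithPhylum], collapse = ", "),
             call. = FALSE)
    df[is.na(df$organism_label), "organism_label"] <- "unassigned"
    rownames(df) <- NULL
    df
}

#' Write an annotation table
#' @param ann annotation `data.frame`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotationTable <- function(ann, path) {
    .writeTsv(ann[, c("accession", "ko_term", "phylum", "genus",
                      "organism_label")], path)
}

#' Read metabolic module definitions
#'
#' Parses the plain-text gut-metabolic-module dialect: a header line
#' `MF####<TAB>name`, then one line per enzymatic step where tabs separate
#' AND-components and commas separate OR-alternative KO terms, and a record
#' terminator line `///`. The published gut metabolic module set can be
#' dropped in unchanged.
#'
#' @param path path to the module definition file.
#' @return a [ModuleSet].
#' @examples
#' tf <- tempfile()
#' writeLines(c("MF0001\ttoy", "K00001,K00002", "K00003", "///"), tf)
#' readModuleDefinitions(tf)
#' @export
readModuleDefinitions <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    ids <- character(0); nms <- character(0); steps <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
        header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(header) < 2L || !grepl(.MODULE_ID_PATTERN, header[1]))
            stop(sprintf("module file line %d: expected 'MF####<TAB>name' header, got '%s'",
                         i, lines[i]), call. = FALSE)
        id <- header[1]; nm <- header[2]
        i <- i + 1L
        recSteps <- list()
        terminated <- FALSE
        while (i <= length(lines)) {
            ln <- lines[i]
            if (trimws(ln) == "///") { terminated <- TRUE; i <- i + 1L; break }
            comps <- strsplit(ln, "\t", fixed = TRUE)[[1]]
            if (length(comps) == 0 || any(!nzchar(comps)))
                stop(sprintf("module file line %d: empty AND-component", i),
                     call. = FALSE)
            parsed <- lapply(comps, function(cmp) {
                kos <- strsplit(cmp, ",", fixed = TRUE)[[1]]
                kos <- trimws(kos)
                if (length(kos) == 0 || any(!nzchar(kos)) ||
                    !all(grepl(.KO_PATTERN, kos)))
                    stop(sprintf("module file line %d: malformed KO term in '%s'",
                                 i, cmp), call. = FALSE)
                kos
            })
            recSteps[[length(recSteps) + 1L]] <- parsed
            i <- i + 1L
        }
        if (!terminated)
            stop(sprintf("module file: record %s not terminated by '///'", id),
                 call. = FALSE)
        if (length(recSteps) == 0)
            stop(sprintf("module file: record %s has no steps", id),
                 call. = FALSE)
        ids <- c(ids, id); nms <- c(nms, nm)
        steps[[length(steps) + 1L]] <- recSteps
    }
    if (anyDuplicated(ids))
        stop("module file: duplicate module id(s)", call. = FALSE)
    new("ModuleSet", moduleId = ids, moduleName = nms, steps = steps)
}

#' Write metabolic module definitions
#'
#' Writes a [ModuleSet] in the same dialect that [readModuleDefinitions()]
#' reads, so that write-then-read round-trips exactly.
#'
#' @param modules a [ModuleSet].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeModuleDefinitions <- function(modules, path) {
    stopifnot(is(modules, "ModuleSet"))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_along(modules@moduleId)) {
        writeLines(paste(modules@moduleId[i], modules@moduleName[i],
                         sep = "\t"), con)
        for (st in modules@steps[[i]]) {
            writeLines(paste(vapply(st, paste, "", collapse = ","),
                             collapse = "\t"), con)
        }
        writeLines("///", con)
    }
    invisible(path)
}
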