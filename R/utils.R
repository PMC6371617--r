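## Internal helpers shared across modules.

.validateSequences <- function(seqs, accessions) {
    bad <- grepl(sprintf("[^%s]", paste(.AA_ALPHABET, collapse = "")), seqs)
    if (any(bad))
        stop("illegal residue(s) outside the 20 canonical amino acids in: ",
             paste(accessions[bad], collapse = ", "), call. = FALSE)
    if (any(nchar(seqs) < 1L))
        stop("zero-length sequence(s) for: ",
             paste(accessions[nchar(seqs) < 1L], collapse = ", "),
             call. = FALSE)
    invisible(TRUE)
}

## Tab-delimited writer used by every exporter: UTF-8, stable column order,
## newline-terminated, no quoting.
.writeTsv <- function(df, path) {
    utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "",
                       fileEncoding = "UTF-8", eol = "\n")
    invisible(path)
}

.readTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", ""))
}

.requireColumns <- function(df, cols, what) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        stop(sprintf("%s: missing required column(s): %s", what,
                     paste(missing, collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}

.checkThreshold <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1)
        stop(name, " must be a single value in (0, 1]", call. = FALSE)
    invisible(TRUE)
}
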