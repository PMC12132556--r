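#' Read a multiple sequence alignment (A3M or aligned FASTA)
#'
#' Reads an alignment whose first record is the target (query) sequence.
#' For \code{format = "a3m"} the lowercase letters, which mark insertions
#' relative to the query, and the \code{"."} padding characters are removed,
#' restoring the rectangular query column space; for \code{format = "fasta"},
#' \code{"."} and \code{"*"} are normalised to \code{"-"}.  Record ids are
#' taken up to the first whitespace.
#'
#' @param path path to the alignment file.
#' @param format \code{"a3m"}, \code{"fasta"}, or \code{"auto"} (by file
#'   extension; \code{.a3m} means A3M, anything else aligned FASTA).
#' @param dedup if \code{TRUE}, drop duplicate rows after reading
#'   (see [dedupMSA]).
#' @return An [MSA-class] object.
#' @seealso [writeMSA], [dedupMSA]
#' @examples
#' f <- tempfile(fileext = ".a3m")
#' writeLines(c(">q", "ACDE", ">h1", "AcC-E"), f)
#' msa <- readMSA(f)          # lowercase insertion removed -> "AC-E"
#' msaRows(msa)
#' @export
readMSA <- function(path, format = c("auto", "a3m", "fasta"), dedup = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("alignment file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
    recs <- tryCatch(Biostrings::readBStringSet(path),
                     error = function(e) stop("cannot parse '", path, "': ",
                                              conditionMessage(e), call. = FALSE))
    if (length(recs) == 0L) stop("empty alignment file: ", path)
    ids <- sub("\\s.*$", "", names(recs))
    rows <- as.character(recs)
    if (format == "a3m") {
        rows <- gsub("[a-z.]", "", rows)
    } else {
        rows <- chartr(".*", "--", rows)
    }
    rows <- toupper(rows)
    bad <- grepl("[^A-Z-]", rows)
    if (any(bad))
        stop("record '", ids[which(bad)[1L]], "' contains invalid characters")
    w <- nchar(rows)
    if (length(unique(w)) != 1L) {
        off <- which(w != w[[1L]])[1L]
        stop("ragged alignment after insertion removal: record '", ids[[off]],
             "' has ", w[[off]], " columns, expected ", w[[1L]])
    }
    msa <- MSA(ids, rows)
    if (dedup) dedupMSA(msa) else msa
}

#' Write an alignment to A3M or aligned FASTA
#'
#' The target sequence is written first.  Rows carry no insertion states
#' (they were removed at read time), so the A3M and FASTA serialisations
#' coincide; sequences are written on a single line as A3M tools expect.
#'
#' @param msa an [MSA-class] object.
#' @param path output file path.
#' @param format \code{"a3m"} or \code{"fasta"} (same bytes; kept for
#'   symmetry with [readMSA]).
#' @return The output path, invisibly.
#' @export
writeMSA <- function(msa, path, format = c("a3m", "fasta")) {
    format <- match.arg(format)
    stopifnot(is(msa, "MSA"))
    validObject(msa)
    if (nSequences(msa) == 0L) stop("refusing to write an empty alignment")
    set <- Biostrings::BStringSet(stats::setNames(msa@rows, msa@ids))
    tryCatch(
        Biostrings::writeXStringSet(set, filepath = path,
                                    width = max(nColumns(msa), 80L)),
        error = function(e) stop("cannot write '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    invisible(path)
}

#' Remove duplicate alignment rows
#'
#' Keeps the first occurrence of each distinct row string; the target row is
#' record 1 and is therefore always retained.
#'
#' @param msa an [MSA-class] object.
#' @return A deduplicated [MSA-class].
#' @export
dedupMSA <- function(msa) {
    stopifnot(is(msa, "MSA"))
    keep <- !duplicated(msa@rows)
    MSA(msa@ids[keep], msa@rows[keep])
}
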