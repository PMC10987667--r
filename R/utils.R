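#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Read a tab-delimited table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used for
#' all tables in this package: tab separator, no factor conversion, strings
#' kept as-is, `check.names = FALSE` so MaxQuant-style column names survive.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Write a tab-delimited table
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Amino-acid alphabet and the MaxQuant window padding character.
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD <- "_"

is_flag <- function(x) {
  ## MaxQuant marks contaminant/reverse rows with "+"
  !is.na(x) & (x == "+" | x == "TRUE" | x == "True")
}
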