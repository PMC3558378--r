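#' Character matrix of taxa over (at most) three-state characters
#'
#' A `character_matrix` holds `n >= 1` taxa (rows) scored on `m >= 1`
#' discrete characters (columns), each character taking between 2 and 3
#' states after canonicalization (constant characters are dropped with a
#' warning: they are compatible with every tree and carry no signal).
#' States are stored as 0-based integers.  Missing values are not
#' supported: every correctness guarantee of the construction pipeline
#' assumes fully observed taxa, so a missing marker (`*`, `?`, or `NA`)
#' is an error, not an imputation request.
#'
#' Canonicalization maps the symbols of each column to `0:(k-1)`.  A
#' column whose values already are exactly the integers `0:(k-1)` is kept
#' verbatim; any other column (letters, gapped integers) is recoded in
#' order of first appearance down the column.  Canonicalization is
#' idempotent.
#'
#' @param states a matrix (integer or character) of state symbols, taxa
#'   in rows, characters in columns.
#' @param taxa optional taxon names (defaults to rownames or `t1..tn`).
#' @param characters optional character names (defaults to colnames or
#'   `c1..cm`).
#' @return an object of class `character_matrix` with fields `states`
#'   (0-based integer matrix), `taxa`, `characters`, `n`, `m`, and
#'   `dropped_constant` (names of dropped constant columns).
#' @examples
#' M <- character_matrix(rbind(c(0, 0), c(1, 1), c(2, 2)))
#' M$m
#' @export
character_matrix <- function(states, taxa = NULL, characters = NULL) {
  if (!is.matrix(states)) states <- as.matrix(states)
  if (nrow(states) < 1L || ncol(states) < 1L)
    pp_format_error("a character matrix needs at least one taxon and one character")
  if (is.null(taxa)) taxa <- rownames(states)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(states)))
  if (is.null(characters)) characters <- colnames(states)
  if (is.null(characters)) characters <- paste0("c", seq_len(ncol(states)))
  if (anyDuplicated(taxa)) taxa <- make.unique(taxa)

  sym <- matrix(as.character(states), nrow(states), ncol(states))
  if (anyNA(sym) || any(sym %in% c("*", "?")))
    pp_missing_value_error("missing values ('*', '?', NA) are not supported")

  cols <- lapply(seq_len(ncol(sym)), function(j) canonicalize_column(sym[, j], characters[j]))
  arities <- vapply(cols, function(x) max(x) + 1L, integer(1))
  keep <- arities >= 2L
  dropped <- characters[!keep]
  if (length(dropped) && any(keep))
    warning(sprintf("dropped %d constant character(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  if (!any(keep)) {
    # an all-constant matrix (e.g. a single taxon) is kept whole: it is
    # trivially displayed on a one-node phylogeny
    warning("all characters are constant; keeping the degenerate matrix",
            call. = FALSE)
    keep <- rep(TRUE, length(cols))
    dropped <- character(0)
  }
  st <- do.call(cbind, cols[keep])
  dimnames(st) <- list(taxa, characters[keep])
  structure(
    list(states = st, taxa = taxa, characters = characters[keep],
         n = nrow(st), m = ncol(st), dropped_constant = dropped),
    class = "character_matrix"
  )
}

canonicalize_column <- function(x, name) {
  vals <- unique(x)
  if (length(vals) > 3L)
    pp_state_arity_error(sprintf(
      "character '%s' has %d distinct states; at most 3 are supported",
      name, length(vals)))
  num <- suppressWarnings(as.integer(x))
  if (!anyNA(num) && setequal(num, seq_len(length(vals)) - 1L))
    return(num)                      # already canonical: keep labels as-is
  match(x, vals) - 1L                # recode by first appearance
}

#' Number of states of each character
#' @param M a [character_matrix()].
#' @return integer vector of per-character state counts.
#' @export
character_arities <- function(M) {
  stopifnot(inherits(M, "character_matrix"))
  setNames(apply(M$states, 2, max) + 1L, M$characters)
}

#' @export
as.matrix.character_matrix <- function(x, ...) x$states

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (arities: %s)\n",
              x$n, x$m, paste(character_arities(x), collapse = ",")))
  print(x$states)
  invisible(x)
}

#' Read a character matrix
#'
#' Supported dialects: `csv`/`tsv` (first row character names, first
#' column taxon names, cells state symbols) and `phylip` (header
#' `"n m"`, then one line per taxon: name, whitespace, `m` single-digit
#' states).  Input is validated and canonicalized; columns with four or
#' more states raise an error, constant columns are dropped with a
#' warning.
#'
#' @param file path or connection.
#' @param format one of `"csv"`, `"tsv"`, `"phylip"`.
#' @param text optional literal text used instead of `file`.
#' @return a [character_matrix()].
#' @export
read_character_matrix <- function(file, format = c("csv", "tsv", "phylip"),
                                  text = NULL) {
  format <- match.arg(format)
  if (!is.null(text)) file <- textConnection(text)
  if (is.character(file) && !file.exists(file))
    pp_format_error(paste("no such file:", file))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      read.delim(file, sep = sep, header = TRUE, row.names = 1,
                 colClasses = "character", check.names = FALSE,
                 strip.white = TRUE),
      error = function(e) pp_format_error(paste("malformed table:", conditionMessage(e))))
    if (nrow(df) < 1L || ncol(df) < 1L)
      pp_format_error("table has no data cells")
    character_matrix(as.matrix(df))
  } else {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) pp_format_error("phylip input too short")
    hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
    if (length(hdr) != 2L || anyNA(hdr))
      pp_format_error("phylip header must be 'n m'")
    n <- hdr[1]; m <- hdr[2]
    if (length(lines) != n + 1L)
      pp_format_error(sprintf("expected %d taxon lines, found %d", n, length(lines) - 1L))
    taxa <- character(n); st <- matrix("", n, m)
    for (i in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
      if (length(parts) != 2L || nchar(parts[2]) != m)
        pp_format_error(sprintf("malformed phylip line %d", i + 1L))
      taxa[i] <- parts[1]
      st[i, ] <- strsplit(parts[2], "")[[1]]
    }
    character_matrix(st, taxa = taxa)
  }
}

#' Write a character matrix
#'
#' Round-trips with [read_character_matrix()]: reading the written file
#' reproduces the matrix.  The `phylip` dialect is only valid when all
#' state symbols are single digits, which canonical matrices always
#' satisfy.
#'
#' @param M a [character_matrix()].
#' @param file path or connection.
#' @param format one of `"csv"`, `"tsv"`, `"phylip"`.
#' @return `file`, invisibly.
#' @export
write_character_matrix <- function(M, file, format = c("csv", "tsv", "phylip")) {
  stopifnot(inherits(M, "character_matrix"))
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(M$states)
    write.table(cbind(taxon = M$taxa, df), file, sep = sep,
                quote = FALSE, row.names = FALSE)
  } else {
    rows <- apply(M$states, 1, paste0, collapse = "")
    writeLines(c(sprintf("%d %d", M$n, M$m), paste(M$taxa, rows)), file)
  }
  invisible(file)
}

#' Packaged example matrices
#'
#' Five small matrices exercising every branch of the pipeline:
#' \describe{
#'   \item{F1}{4x3, compatible; its phylogeny needs two inferred
#'     (Steiner) species and its partition intersection graph has one
#'     chordless 4-cycle on three colors.}
#'   \item{F2}{4x3 all-binary, compatible; the phylogeny is a path and
#'     the graph is already chordal.}
#'   \item{F3}{3x2, compatible; the graph is disconnected, exercising
#'     the empty separator.}
#'   \item{F4}{4x2, incompatible; a two-character four-gamete cycle,
#'     rejected at step 1.}
#'   \item{F5}{5x3, incompatible although every character pair is
#'     acyclic: the graph has a chordless 5-cycle, rejected at step 3.}
#' }
#' @return named list of [character_matrix()] objects.
#' @export
pp_fixtures <- function() {
  list(
    F1 = character_matrix(rbind(t1 = c(0, 0, 1), t2 = c(1, 0, 2),
                                t3 = c(1, 1, 0), t4 = c(0, 2, 0))),
    F2 = character_matrix(rbind(a = c(0, 0, 0), b = c(1, 0, 0),
                                c = c(1, 1, 0), d = c(1, 1, 1))),
    F3 = character_matrix(rbind(t1 = c(0, 0), t2 = c(1, 1), t3 = c(2, 2))),
    F4 = character_matrix(rbind(t1 = c(0, 0), t2 = c(0, 1),
                                t3 = c(1, 1), t4 = c(1, 0))),
    F5 = character_matrix(rbind(t1 = c(0, 0, 1), t2 = c(1, 0, 1),
                                t3 = c(1, 2, 0), t4 = c(2, 1, 0),
                                t5 = c(0, 1, 1)))
  )
}
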