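#' Supported RNA secondary structure formats
#'
#' Eight format identifiers are recognized: `"DB"` (dot-bracket with
#' sequence), `"DB_NO_SEQ"` (dot-bracket, structure line only), `"RNAML"`,
#' `"CT"`, `"BPSEQ"`, `"AAS"` (arc-annotated sequence with sequence line),
#' `"AAS_NO_SEQ"`, and `"FASTA"` (primary sequence only).
#'
#' @return Character vector of the eight format identifiers.
#' @export
#' @examples
#' rna_formats()
rna_formats <- function() {
  c("DB", "DB_NO_SEQ", "RNAML", "CT", "BPSEQ", "AAS", "AAS_NO_SEQ", "FASTA")
}

.check_format <- function(fmt) {
  if (!is.character(fmt) || length(fmt) != 1L || !(fmt %in% rna_formats())) {
    stop("unknown format identifier: ", paste(fmt, collapse = ", "),
         " (expected one of ", paste(rna_formats(), collapse = ", "), ")",
         call. = FALSE)
  }
  fmt
}

#' Build a base-pair matrix
#'
#' Normalizes pair input to an integer matrix with columns `five` and
#' `three` (1-based 5' and 3' nucleotide indices, `five < three` in every
#' row), sorted by `five`. Accepts a two-column matrix or data frame, a
#' list of length-2 vectors, or `NULL` (no pairs).
#'
#' @param x Pairs in any accepted form.
#' @return Integer matrix with columns `five`, `three`, zero or more rows.
#' @export
#' @examples
#' base_pairs(list(c(2, 8), c(1, 9)))
base_pairs <- function(x = NULL) {
  if (is.null(x) || (is.atomic(x) && length(x) == 0L)) {
    m <- matrix(integer(0), ncol = 2L)
  } else if (is.list(x) && !is.data.frame(x)) {
    if (!all(lengths(x) == 2L)) stop("each pair must have two indices", call. = FALSE)
    m <- matrix(as.integer(unlist(x)), ncol = 2L, byrow = TRUE)
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("pairs must have two columns", call. = FALSE)
    storage.mode(m) <- "integer"
  }
  if (anyNA(m)) stop("pair indices must be integers", call. = FALSE)
  # normalize orientation so the 5' index comes first
  flip <- m[, 1L] > m[, 2L]
  if (any(flip)) m[flip, ] <- m[flip, c(2L, 1L), drop = FALSE]
  m <- m[order(m[, 1L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("five", "three"))
  m
}

#' Construct a validated RNA secondary structure
#'
#' The canonical in-memory representation is an arc diagram: nucleotides
#' `1..length` on a backbone, base pairs as arcs. The sequence is optional
#' (structure-only encodings such as dot-bracket without a sequence line);
#' when present it is upper-cased and must match `length`. Each nucleotide
#' may take part in at most one base pair.
#'
#' @param sequence Nucleotide string (IUPAC letters) or `""` for
#'   structure-only input. `T` is accepted and preserved.
#' @param pairs Base pairs in any form accepted by [base_pairs()].
#' @param length Number of nucleotides; defaults to `nchar(sequence)` when a
#'   sequence is given, otherwise to the largest paired index.
#' @param header Character vector of verbatim header lines (the format's
#'   designated metadata slot, e.g. a `>` line or the CT name field).
#' @param comments Character vector of verbatim `#` comment lines.
#' @param source_format Format the structure was read from, or `NA`.
#' @return An object of class `rna_structure` with fields `sequence`,
#'   `length`, `pairs`, `header`, `comments`, `source_format`.
#' @export
#' @examples
#' hp <- rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
#' hp$length
#' is_pseudoknotted(hp)
rna_structure <- function(sequence = "", pairs = NULL, length = NULL,
                          header = character(), comments = character(),
                          source_format = NA_character_) {
  if (is.null(sequence) || is.na(sequence)) sequence <- ""
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  m <- base_pairs(pairs)
  if (is.null(length)) {
    length <- if (nzchar(sequence)) nchar(sequence) else if (nrow(m)) max(m) else 0L
  }
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop("length must be a non-negative integer", call. = FALSE)
  if (nzchar(sequence) && nchar(sequence) != length) {
    stop("sequence has ", nchar(sequence), " letters but length is ", length, call. = FALSE)
  }
  if (nrow(m)) {
    bad <- which(m[, "five"] >= m[, "three"])
    if (base::length(bad)) {
      stop("invalid pair (", m[bad[1L], 1L], ",", m[bad[1L], 2L],
           "): 5' index must be smaller than 3' index", call. = FALSE)
    }
    oob <- which(m < 1L | m > length)
    if (base::length(oob)) {
      r <- ((oob[1L] - 1L) %% nrow(m)) + 1L
      stop("pair (", m[r, 1L], ",", m[r, 2L], ") has index outside 1..",
           length, call. = FALSE)
    }
    idx <- as.vector(m)
    dup <- idx[duplicated(idx)]
    if (base::length(dup)) {
      stop("nucleotide ", dup[1L], " occurs in more than one base pair", call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence, length = length, pairs = m,
         header = as.character(header), comments = as.character(comments),
         source_format = source_format),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure: ", x$length, " nt, ", nrow(x$pairs),
      " base pair", if (nrow(x$pairs) != 1L) "s", sep = "")
  if (!is.na(x$source_format)) cat(" [", x$source_format, "]", sep = "")
  cat("\n")
  if (nzchar(x$sequence)) {
    s <- if (x$length > 60L) paste0(substr(x$sequence, 1L, 57L), "...") else x$sequence
    cat("  ", s, "\n", sep = "")
  }
  if (nrow(x$pairs) && x$length <= 200L) {
    cat("  ", render_brackets(x$pairs, x$length), "\n", sep = "")
  }
  cat("  pseudoknotted: ", is_pseudoknotted(x), "\n", sep = "")
  invisible(x)
}

#' Do two arcs cross?
#'
#' Two base pairs (arcs) cross when their intervals interleave:
#' `p1 < q1 < p2 < q2` or `q1 < p1 < q2 < p2`. Crossing arcs are the
#' defining feature of a pseudoknot.
#'
#' @param p,q Length-2 vectors `(five, three)` with `five < three`.
#' @return `TRUE` if the arcs cross.
#' @export
#' @examples
#' crosses(c(1, 5), c(3, 7)) # TRUE: interleaved
#' crosses(c(1, 9), c(2, 8)) # FALSE: nested
crosses <- function(p, q) {
  (p[1L] < q[1L] && q[1L] < p[2L] && p[2L] < q[2L]) ||
  (q[1L] < p[1L] && p[1L] < q[2L] && q[2L] < p[2L])
}

# Vectorized crossing test over a pair matrix (assumed sorted by five).
# Returns logical: does pair i cross any other pair?
.crossing_flags <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(FALSE, n))
  f <- m[, 1L]; t3 <- m[, 2L]
  out <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    # f[j] > f[i] by sort order; crossing iff f[j] < t3[i] < t3[j]
    x <- f[j] < t3[i] & t3[i] < t3[j]
    if (any(x)) {
      out[i] <- TRUE
      out[j[x]] <- TRUE
    }
  }
  out
}

#' Does a structure contain a pseudoknot?
#'
#' A structure is pseudoknotted when its arc diagram contains at least one
#' pair of crossing arcs; otherwise it is pseudoknot-free (fully nested).
#'
#' @param ss An `rna_structure`, or a pair matrix as from [base_pairs()].
#' @return `TRUE` if any two arcs cross.
#' @export
#' @examples
#' is_pseudoknotted(rna_structure(pairs = list(c(1, 5), c(3, 7)), length = 8))
is_pseudoknotted <- function(ss) {
  m <- if (inherits(ss, "rna_structure")) ss$pairs else base_pairs(ss)
  any(.crossing_flags(m))
}

# First header line with any leading '>' stripped; "molecule" if none.
.header_name <- function(ss, default = "molecule") {
  if (base::length(ss$header)) {
    nm <- trimws(sub("^>", "", ss$header[1L]))
    if (nzchar(nm)) return(nm)
  }
  default
}
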