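# Per-molecule and dataset-level statistics: sequence length, nucleotide
# counts, number of base pairs, and base-pair class counts (G-C, A-U, G-U
# in either order). T is counted as U. Letters outside ACGU go into
# `other` and their pairs count toward `bonds` only.

#' Per-molecule structure statistics
#'
#' @param ss An [rna_structure()].
#' @param file Optional label for the `file` column.
#' @return One-row data frame with columns `file`, `length`, `bonds`, `A`,
#'   `C`, `G`, `U`, `other`, `GC`, `AU`, `GU`. For structure-only input
#'   (no sequence) the nucleotide and pair-class columns are `NA`.
#' @export
#' @examples
#' hp <- rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
#' structure_stats(hp)
structure_stats <- function(ss, file = NA_character_) {
  stopifnot(inherits(ss, "rna_structure"))
  bonds <- nrow(ss$pairs)
  if (nzchar(ss$sequence) || ss$length == 0L) {
    chars <- chartr("T", "U", .seq_chars(ss))
    if (ss$length == 0L) chars <- character()
    nA <- sum(chars == "A"); nC <- sum(chars == "C")
    nG <- sum(chars == "G"); nU <- sum(chars == "U")
    other <- ss$length - nA - nC - nG - nU
    if (bonds) {
      key <- paste0(pmin(chars[ss$pairs[, 1L]], chars[ss$pairs[, 2L]]),
                    pmax(chars[ss$pairs[, 1L]], chars[ss$pairs[, 2L]]))
      gc <- sum(key == "CG"); au <- sum(key == "AU"); gu <- sum(key == "GU")
    } else {
      gc <- au <- gu <- 0L
    }
  } else {
    nA <- nC <- nG <- nU <- other <- gc <- au <- gu <- NA_integer_
  }
  data.frame(file = file, length = ss$length, bonds = bonds,
             A = nA, C = nC, G = nG, U = nU, other = other,
             GC = gc, AU = au, GU = gu, stringsAsFactors = FALSE)
}

#' Aggregate statistics over a collection of molecules
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' numeric column. The deviation row is `NA` when fewer than two molecules
#' are supplied.
#'
#' @param stats Data frame of per-molecule rows from [structure_stats()]
#'   (rbind them for a collection).
#' @return Data frame with rows `Mean` and `St.Dev` and the numeric columns
#'   of the input.
#' @export
#' @examples
#' s <- rbind(structure_stats(rna_structure("ACGUACGU")),
#'            structure_stats(rna_structure("ACGUACGUAC")))
#' aggregate_stats(s) # mean length 9, st. dev. sqrt(2)
aggregate_stats <- function(stats) {
  if (is.null(stats) || !nrow(stats)) {
    stop("cannot aggregate an empty statistics table", call. = FALSE)
  }
  num <- stats[, vapply(stats, is.numeric, logical(1L)), drop = FALSE]
  means <- vapply(num, function(x) mean(x), numeric(1L))
  sds <- if (nrow(num) >= 2L) {
    vapply(num, function(x) stats::sd(x), numeric(1L))
  } else {
    rep(NA_real_, ncol(num))
  }
  out <- rbind(Mean = means, St.Dev = sds)
  as.data.frame(out)
}

.STATS_COLS <- c("length", "bonds", "A", "C", "G", "U", "GC", "AU", "GU")

#' Statistics table as CSV
#'
#' One row per molecule followed by `Mean` and `St.Dev` footer rows, with
#' the column order `file,length,bonds,A,C,G,U,GC,AU,GU`. Aggregate values
#' are printed to two decimals.
#'
#' @param stats Per-molecule data frame from [structure_stats()].
#' @param aggregate Aggregate data frame from [aggregate_stats()], or
#'   `NULL` to omit the footer.
#' @return CSV text (character scalar, trailing newline).
#' @export
stats_csv <- function(stats, aggregate = NULL) {
  header <- paste(c("file", .STATS_COLS), collapse = ",")
  lines <- header
  if (!is.null(stats) && nrow(stats)) {
    cols <- c(list(as.character(stats$file)),
              lapply(stats[.STATS_COLS], as.character))
    body <- do.call(paste, c(cols, sep = ","))
    lines <- c(lines, body)
  }
  if (!is.null(aggregate)) {
    agg <- aggregate[, .STATS_COLS, drop = FALSE]
    fmt_row <- function(label, row) {
      vals <- vapply(as.numeric(row), function(v) {
        if (is.na(v)) "" else sprintf("%.2f", v)
      }, character(1L))
      paste(c(label, vals), collapse = ",")
    }
    lines <- c(lines, fmt_row("Mean", agg["Mean", ]))
    if (!all(is.na(as.numeric(agg["St.Dev", ])))) {
      lines <- c(lines, fmt_row("St.Dev", agg["St.Dev", ]))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
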