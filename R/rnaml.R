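# RNAML reader/writer. The dialect is the interoperable core of RNAML: one
# molecule element, absolute 1-based positions, sequence in
# sequence/seq-data, pairs in str-annotation as base-pair elements (helix
# elements are expanded to stacked pairs on read, never written). Output of
# structure-extraction tools such as RNAView fits this dialect and may
# contain non-canonical pairs, which are partitioned out on read.

#' Is a base pair canonical?
#'
#' Canonical pairs are the Watson-Crick-Franklin pairs A-U and G-C plus the
#' G-U wobble pair, in either order. `T` is treated as `U`.
#'
#' @param b1,b2 Single nucleotide letters (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' is_canonical_pair("G", "U") # TRUE (wobble)
#' is_canonical_pair("C", "C") # FALSE
is_canonical_pair <- function(b1, b2) {
  b1 <- chartr("Tt", "Uu", toupper(b1))
  b2 <- chartr("Tt", "Uu", toupper(b2))
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  key %in% c("AU", "CG", "GU")
}

.xml_position <- function(node, xpath) {
  v <- xml2::xml_find_first(node, xpath)
  if (inherits(v, "xml_missing")) return(NA_integer_)
  suppressWarnings(as.integer(trimws(xml2::xml_text(v))))
}

#' Read an RNAML document
#'
#' Extracts the first molecule's sequence and base pairs. Pairs are taken
#' from `base-pair` elements and from `helix` elements (expanded to their
#' `length` stacked pairs); only the first `model` element is consulted when
#' several are present. Pairs are then partitioned by [is_canonical_pair()]:
#' canonical pairs populate the returned structure, non-canonical pairs
#' (common in RNAView output) are returned as records for CSV export and
#' never enter the structure.
#'
#' In strict mode a nucleotide left paired twice after the canonical
#' partition is an error; lenient mode keeps the first-encountered pair.
#'
#' @param xml RNAML text, an `xml_document`, or a file path.
#' @param strict Fail on pairing conflicts? Default `TRUE`.
#' @return List with `structure` (an [rna_structure()]) and `noncanonical`
#'   (data frame with columns `five_idx`, `three_idx`, `five_base`,
#'   `three_base`).
#' @export
read_rnaml <- function(xml, strict = TRUE) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  root <- xml2::xml_name(doc)
  if (root != "rnaml") {
    stop("not an RNAML document (root element is <", root, ">)", call. = FALSE)
  }
  mol <- xml2::xml_find_first(doc, ".//molecule")
  if (inherits(mol, "xml_missing")) {
    stop("RNAML: no molecule element found", call. = FALSE)
  }
  name_node <- xml2::xml_find_first(mol, "./identity/name")
  name <- if (inherits(name_node, "xml_missing")) {
    id <- xml2::xml_attr(mol, "id")
    if (is.na(id)) character() else id
  } else trimws(xml2::xml_text(name_node))
  seq_node <- xml2::xml_find_first(mol, ".//sequence/seq-data")
  seq <- if (inherits(seq_node, "xml_missing")) "" else
    toupper(gsub("[^A-Za-z]", "", xml2::xml_text(seq_node)))
  # pairing annotation: first model if present, else the whole molecule
  scope <- xml2::xml_find_first(mol, ".//model")
  if (inherits(scope, "xml_missing")) scope <- mol
  five <- integer(0); three <- integer(0)
  for (bp in xml2::xml_find_all(scope, ".//base-pair")) {
    i <- .xml_position(bp, "./base-id-5p/base-id/position")
    j <- .xml_position(bp, "./base-id-3p/base-id/position")
    if (is.na(i) || is.na(j)) {
      stop("RNAML: base-pair element without 5p/3p positions", call. = FALSE)
    }
    five <- c(five, i); three <- c(three, j)
  }
  for (hx in xml2::xml_find_all(scope, ".//helix")) {
    i <- .xml_position(hx, "./base-id-5p/base-id/position")
    j <- .xml_position(hx, "./base-id-3p/base-id/position")
    len_node <- xml2::xml_find_first(hx, "./length")
    len <- if (inherits(len_node, "xml_missing")) NA_integer_ else
      suppressWarnings(as.integer(trimws(xml2::xml_text(len_node))))
    if (is.na(i) || is.na(j) || is.na(len)) {
      stop("RNAML: helix element without 5p/3p positions and length",
           call. = FALSE)
    }
    k <- seq_len(len) - 1L
    five <- c(five, i + k); three <- c(three, j - k)
  }
  # normalize orientation, drop exact duplicates (a pair listed twice)
  lo <- pmin(five, three); hi <- pmax(five, three)
  if (any(lo == hi)) {
    stop("RNAML: base pair with identical 5p and 3p position ", lo[lo == hi][1L],
         call. = FALSE)
  }
  dup <- duplicated(paste(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  n <- if (nzchar(seq)) nchar(seq) else if (length(hi)) max(hi) else 0L
  if (length(lo) && (min(lo) < 1L || max(hi) > n)) {
    bad <- which(lo < 1L | hi > n)[1L]
    stop("RNAML: pair (", lo[bad], ",", hi[bad], ") outside positions 1..",
         n, call. = FALSE)
  }
  # canonical partition (identity-based; structure-only input keeps all)
  if (nzchar(seq) && length(lo)) {
    letters5 <- substring(seq, lo, lo)
    letters3 <- substring(seq, hi, hi)
    canon <- is_canonical_pair(letters5, letters3)
  } else {
    canon <- rep(TRUE, length(lo))
    letters5 <- letters3 <- rep(NA_character_, length(lo))
  }
  nc <- data.frame(five_idx = lo[!canon], three_idx = hi[!canon],
                   five_base = letters5[!canon], three_base = letters3[!canon],
                   stringsAsFactors = FALSE)
  nc <- nc[order(nc$five_idx), , drop = FALSE]
  row.names(nc) <- NULL
  lo <- lo[canon]; hi <- hi[canon]
  # conflicts among canonical pairs: a base paired twice
  idx <- c(lo, hi)
  if (anyDuplicated(idx)) {
    if (strict) {
      d <- idx[duplicated(idx)][1L]
      at <- which(lo == d | hi == d)
      stop("RNAML: nucleotide ", d, " is paired twice (pairs (",
           lo[at[1L]], ",", hi[at[1L]], ") and (", lo[at[2L]], ",",
           hi[at[2L]], "))", call. = FALSE)
    }
    keep <- logical(length(lo))
    seen <- logical(n)
    for (k in seq_along(lo)) {
      if (!seen[lo[k]] && !seen[hi[k]]) {
        keep[k] <- TRUE
        seen[lo[k]] <- seen[hi[k]] <- TRUE
      }
    }
    lo <- lo[keep]; hi <- hi[keep]
  }
  ss <- rna_structure(seq, cbind(lo, hi), n,
                      header = name, source_format = "RNAML")
  list(structure = ss, noncanonical = nc)
}

#' Write an RNA secondary structure as RNAML
#'
#' Emits a single `molecule` with an `identity/name`, the sequence as
#' `sequence/seq-data`, and one `base-pair` element per pair inside
#' `structure/model/str-annotation`. Reading the output back with
#' [read_rnaml()] reproduces the sequence and pair set.
#'
#' @param ss An [rna_structure()] with a sequence (RNAML carries one).
#' @param name Molecule name; defaults to the structure's header.
#' @return RNAML text (character scalar).
#' @export
write_rnaml <- function(ss, name = NULL) {
  stopifnot(inherits(ss, "rna_structure"))
  if (!nzchar(ss$sequence) && ss$length > 0L) {
    stop("RNAML output requires a sequence but the structure has none",
         call. = FALSE)
  }
  if (is.null(name)) name <- .header_name(ss)
  doc <- xml2::xml_new_root("rnaml", version = "1.1")
  mol <- xml2::xml_add_child(doc, "molecule", id = "1")
  ident <- xml2::xml_add_child(mol, "identity")
  xml2::xml_add_child(ident, "name", name)
  sq <- xml2::xml_add_child(mol, "sequence")
  xml2::xml_add_child(sq, "seq-data", ss$sequence)
  str <- xml2::xml_add_child(mol, "structure")
  model <- xml2::xml_add_child(str, "model", id = "1")
  ann <- xml2::xml_add_child(model, "str-annotation")
  if (nrow(ss$pairs)) {
    for (k in seq_len(nrow(ss$pairs))) {
      bp <- xml2::xml_add_child(ann, "base-pair")
      p5 <- xml2::xml_add_child(bp, "base-id-5p")
      b5 <- xml2::xml_add_child(p5, "base-id")
      xml2::xml_add_child(b5, "position", as.character(ss$pairs[k, 1L]))
      p3 <- xml2::xml_add_child(bp, "base-id-3p")
      b3 <- xml2::xml_add_child(p3, "base-id")
      xml2::xml_add_child(b3, "position", as.character(ss$pairs[k, 2L]))
    }
  }
  paste0(as.character(doc))
}

#' Non-canonical base pairs as CSV
#'
#' Serializes the non-canonical records from [read_rnaml()] to CSV with
#' header `molecule,position_5p,base_5p,position_3p,base_3p`, rows sorted by
#' 5' position. Non-canonical pairs are exported this way because the
#' plain-text structure formats cannot carry them.
#'
#' @param records Data frame as returned in `read_rnaml()$noncanonical`.
#' @param molecule Molecule name for the first column.
#' @return CSV text (character scalar, trailing newline).
#' @export
#' @examples
#' cat(noncanonical_csv(data.frame(five_idx = 4, three_idx = 6,
#'                                 five_base = "A", three_base = "A"), "toy"))
noncanonical_csv <- function(records, molecule) {
  header <- "molecule,position_5p,base_5p,position_3p,base_3p"
  if (is.null(records) || !nrow(records)) {
    return(paste0(header, "\n"))
  }
  records <- records[order(records$five_idx), , drop = FALSE]
  rows <- paste(molecule, records$five_idx, records$five_base,
                records$three_idx, records$three_base, sep = ",")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}
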