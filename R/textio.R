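# Readers and writers for the five plain-text encodings. All readers
# tolerate blank lines and '\r\n' endings, capture '#' comment lines
# verbatim, and put the format's designated metadata (a '>' line, the CT
# name field) into `header`. Writers emit '\n' endings and never emit blank
# lines.

.split_lines <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  sub("\r$", "", lines)
}

.is_comment <- function(lines) grepl("^[[:space:]]*#", lines)
.is_blank <- function(lines) !nzchar(trimws(lines))

.seq_line_re <- "^[A-Za-z]+$"

#' Parse a plain-text RNA secondary structure
#'
#' Dispatches on `fmt` to the BPSEQ, CT, dot-bracket, arc-annotated-sequence
#' or FASTA reader. RNAML is XML and handled separately by [read_rnaml()].
#'
#' In strict mode (default) irregular input is an error: non-contiguous
#' BPSEQ/CT indices, asymmetric pairing records, a CT length mismatching the
#' row count, unbalanced brackets. Lenient mode fills missing BPSEQ/CT
#' positions as unpaired (`N`) and accepts `-` as an unpaired dot-bracket
#' symbol. Concatenated CT/BPSEQ records are accepted; the first record is
#' returned.
#'
#' @param text Character scalar (or vector of lines) with the file content.
#' @param fmt One of [rna_formats()] except `"RNAML"`.
#' @param strict Reject recoverable irregularities? Default `TRUE`.
#' @return An [rna_structure()].
#' @export
#' @examples
#' parse_rna("GGGAAACCC\n(((...)))", "DB")
parse_rna <- function(text, fmt, strict = TRUE) {
  .check_format(fmt)
  if (fmt == "RNAML") {
    stop("RNAML is XML; use read_rnaml()", call. = FALSE)
  }
  lines <- .split_lines(text)
  switch(fmt,
    BPSEQ = .parse_bpseq(lines, strict),
    CT = .parse_ct(lines, strict),
    DB = .parse_db(lines, with_seq = TRUE, strict = strict),
    DB_NO_SEQ = .parse_db(lines, with_seq = FALSE, strict = strict),
    AAS = .parse_aas(lines, with_seq = TRUE, strict = strict),
    AAS_NO_SEQ = .parse_aas(lines, with_seq = FALSE, strict = strict),
    FASTA = .parse_fasta(lines, strict)
  )
}

# -- pairing-column formats (BPSEQ, CT) --------------------------------------

# Shared core: given vectors pos, base, mate (one row per nucleotide),
# validate contiguity/symmetry and build the structure.
.pairing_table_to_structure <- function(pos, base, mate, strict, fmt,
                                        header = character(),
                                        comments = character()) {
  n <- length(pos)
  if (anyDuplicated(pos)) {
    stop(fmt, ": duplicated position ", pos[duplicated(pos)][1L], call. = FALSE)
  }
  full <- if (n) seq_len(max(pos)) else integer(0)
  if (length(full) != n) {
    missing <- setdiff(full, pos)
    if (strict) {
      stop(fmt, ": positions are not contiguous 1..n (missing ",
           paste(utils::head(missing, 3L), collapse = ", "),
           if (length(missing) > 3L) ", ...", ")", call. = FALSE)
    }
    pos <- c(pos, missing)
    base <- c(base, rep("N", length(missing)))
    mate <- c(mate, rep(0L, length(missing)))
    o <- order(pos)
    pos <- pos[o]; base <- base[o]; mate <- mate[o]
    n <- length(pos)
  } else {
    o <- order(pos)
    pos <- pos[o]; base <- base[o]; mate <- mate[o]
  }
  if (n && pos[1L] != 1L) {
    stop(fmt, ": positions must start at 1, got ", pos[1L], call. = FALSE)
  }
  bad <- which(mate < 0L | mate > n)
  if (length(bad)) {
    stop(fmt, ": line for position ", pos[bad[1L]], " pairs with ",
         mate[bad[1L]], ", outside 1..", n, call. = FALSE)
  }
  if (any(mate == pos)) {
    stop(fmt, ": position ", pos[which(mate == pos)[1L]],
         " is paired with itself", call. = FALSE)
  }
  paired <- which(mate > 0L)
  if (length(paired)) {
    asym <- paired[mate[mate[paired]] != paired]
    if (length(asym)) {
      i <- asym[1L]
      stop(fmt, ": asymmetric pairing: line ", i, " pairs with ", mate[i],
           " but line ", mate[i], " pairs with ", mate[mate[i]], call. = FALSE)
    }
  }
  keep <- paired[paired < mate[paired]]
  rna_structure(paste(base, collapse = ""),
                cbind(keep, mate[keep]), n,
                header = header, comments = comments, source_format = fmt)
}

.parse_bpseq <- function(lines, strict) {
  comments <- lines[.is_comment(lines)]
  data <- lines[!.is_comment(lines) & !.is_blank(lines)]
  if (!length(data)) {
    return(rna_structure("", NULL, 0L, comments = comments,
                         source_format = "BPSEQ"))
  }
  toks <- strsplit(trimws(data), "[[:space:]]+")
  nt <- lengths(toks)
  if (any(nt != 3L)) {
    stop("BPSEQ: line ", which(nt != 3L)[1L],
         " does not have 3 fields (position, base, paired position)",
         call. = FALSE)
  }
  tm <- matrix(unlist(toks), ncol = 3L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(tm[, 1L]))
  mate <- suppressWarnings(as.integer(tm[, 3L]))
  if (anyNA(pos) || anyNA(mate)) {
    stop("BPSEQ: non-numeric position field on line ",
         which(is.na(pos) | is.na(mate))[1L], call. = FALSE)
  }
  # concatenated records: keep rows up to the second '1'
  restart <- which(pos == 1L)
  if (length(restart) > 1L) {
    keep <- seq_len(restart[2L] - 1L)
    pos <- pos[keep]; mate <- mate[keep]; tm <- tm[keep, , drop = FALSE]
  }
  .pairing_table_to_structure(pos, toupper(tm[, 2L]), mate, strict, "BPSEQ",
                              comments = comments)
}

.parse_ct <- function(lines, strict) {
  comments <- lines[.is_comment(lines)]
  data <- lines[!.is_comment(lines) & !.is_blank(lines)]
  if (!length(data)) {
    return(rna_structure("", NULL, 0L, comments = comments,
                         source_format = "CT"))
  }
  first <- trimws(data[1L])
  ft <- strsplit(first, "[[:space:]]+")[[1L]]
  n_declared <- suppressWarnings(as.integer(ft[1L]))
  if (is.na(n_declared) || n_declared < 0L) {
    stop("CT: first line must start with the sequence length, got '",
         ft[1L], "'", call. = FALSE)
  }
  name <- trimws(sub("^[[:space:]]*[0-9]+", "", first))
  header <- if (nzchar(name)) name else character()
  rows <- data[-1L]
  # concatenated records: a CT record has exactly n_declared rows
  if (length(rows) > n_declared) {
    extra <- rows[n_declared + 1L]
    et <- strsplit(trimws(extra), "[[:space:]]+")[[1L]]
    looks_header <- !is.na(suppressWarnings(as.integer(et[1L]))) &&
      length(et) < 6L
    if (looks_header) {
      rows <- rows[seq_len(n_declared)]
    }
  }
  if (strict && length(rows) != n_declared) {
    stop("CT: first line declares ", n_declared, " nucleotides but ",
         length(rows), " data rows follow", call. = FALSE)
  }
  if (!length(rows)) {
    return(rna_structure("", NULL, 0L, header = header, comments = comments,
                         source_format = "CT"))
  }
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  nt <- lengths(toks)
  if (any(nt < 6L)) {
    stop("CT: data line ", which(nt < 6L)[1L],
         " has fewer than 6 fields", call. = FALSE)
  }
  tm <- t(vapply(toks, function(x) x[1:6], character(6L)))
  pos <- suppressWarnings(as.integer(tm[, 1L]))
  mate <- suppressWarnings(as.integer(tm[, 5L]))
  if (anyNA(pos) || anyNA(mate)) {
    stop("CT: non-numeric index on data line ",
         which(is.na(pos) | is.na(mate))[1L], call. = FALSE)
  }
  .pairing_table_to_structure(pos, toupper(tm[, 2L]), mate, strict, "CT",
                              header = header, comments = comments)
}

# -- dot-bracket -------------------------------------------------------------

.parse_db <- function(lines, with_seq, strict) {
  comments <- lines[.is_comment(lines)]
  header <- lines[grepl("^>", lines)]
  body <- lines[!.is_comment(lines) & !.is_blank(lines) & !grepl("^>", lines)]
  fmt <- if (with_seq) "DB" else "DB_NO_SEQ"
  if (!length(body)) {
    return(rna_structure("", NULL, 0L, header = header, comments = comments,
                         source_format = fmt))
  }
  if (with_seq) {
    if (length(body) < 2L) {
      stop("dot-bracket: expected a sequence line and a structure line",
           call. = FALSE)
    }
    if (length(body) > 2L) {
      stop("dot-bracket: expected exactly 2 body lines, found ",
           length(body), call. = FALSE)
    }
    seq <- trimws(body[1L])
    struct <- trimws(body[2L])
    if (!grepl(.seq_line_re, seq)) {
      stop("dot-bracket: sequence line contains a non-letter character",
           call. = FALSE)
    }
    if (nchar(seq) != nchar(struct)) {
      stop("dot-bracket: sequence has ", nchar(seq),
           " letters but structure line has ", nchar(struct), call. = FALSE)
    }
  } else {
    if (length(body) > 1L) {
      stop("dot-bracket (no sequence): expected a single structure line, found ",
           length(body), call. = FALSE)
    }
    seq <- ""
    struct <- trimws(body[1L])
  }
  if (!strict) struct <- gsub("-", ".", struct, fixed = TRUE)
  pairs <- parse_brackets(struct)
  rna_structure(seq, pairs, nchar(struct), header = header,
                comments = comments, source_format = fmt)
}

# -- arc-annotated sequence --------------------------------------------------

.AAS_LEN_RE <- "^[[:space:]]*#[[:space:]]*length[[:space:]]*=[[:space:]]*([0-9]+)[[:space:]]*$"

.parse_aas_pairlist <- function(line, strict) {
  line <- trimws(line)
  if (!nzchar(line)) return(base_pairs(NULL))
  matches <- gregexpr("\\(([0-9]+)[[:space:]]*,[[:space:]]*([0-9]+)\\)", line)[[1L]]
  if (strict) {
    residue <- gsub("\\(([0-9]+)[[:space:]]*,[[:space:]]*([0-9]+)\\)", "", line)
    residue <- gsub("[;[:space:]]", "", residue)
    if (nzchar(residue)) {
      stop("arc-annotated sequence: unexpected text '", residue,
           "' in pair list", call. = FALSE)
    }
  }
  if (matches[1L] == -1L) return(base_pairs(NULL))
  toks <- regmatches(line, gregexpr("[0-9]+", line))[[1L]]
  nums <- as.integer(toks)
  if (length(nums) %% 2L != 0L) {
    stop("arc-annotated sequence: malformed pair list", call. = FALSE)
  }
  base_pairs(matrix(nums, ncol = 2L, byrow = TRUE))
}

.parse_aas <- function(lines, with_seq, strict) {
  comments <- lines[.is_comment(lines)]
  header <- lines[grepl("^>", lines)]
  if (strict && length(header)) {
    # the arc-annotated dialect has no header slot; rejecting '>' lines also
    # keeps detection from mistaking FASTA records for pairless AAS input
    stop("arc-annotated sequence: unexpected '>' header line", call. = FALSE)
  }
  body <- lines[!.is_comment(lines) & !.is_blank(lines) & !grepl("^>", lines)]
  fmt <- if (with_seq) "AAS" else "AAS_NO_SEQ"
  seq <- ""
  if (with_seq && !length(body)) {
    # empty structure: nothing to carry
    return(rna_structure("", NULL, 0L, comments = comments,
                         source_format = fmt))
  }
  if (with_seq) {
    seq <- trimws(body[1L])
    if (!grepl(.seq_line_re, seq)) {
      stop("arc-annotated sequence: sequence line contains a non-letter character",
           call. = FALSE)
    }
    body <- body[-1L]
  }
  if (length(body) > 1L) {
    stop("arc-annotated sequence: expected a single pair-list line, found ",
         length(body), call. = FALSE)
  }
  pairs <- if (length(body)) .parse_aas_pairlist(body[1L], strict) else base_pairs(NULL)
  len <- if (nzchar(seq)) nchar(seq) else if (nrow(pairs)) max(pairs) else 0L
  # structure-only files cannot encode trailing unpaired residues in the
  # pair list; the writer records the total length in a '# length=' comment
  hint <- grep(.AAS_LEN_RE, comments, value = TRUE)
  if (!nzchar(seq) && length(hint)) {
    len <- max(len, as.integer(sub(.AAS_LEN_RE, "\\1", hint[1L])))
  }
  rna_structure(seq, pairs, len, header = header, comments = comments,
                source_format = fmt)
}

# -- FASTA -------------------------------------------------------------------

.parse_fasta <- function(lines, strict) {
  comments <- lines[.is_comment(lines) | grepl("^;", lines)]
  lines <- lines[!.is_comment(lines) & !grepl("^;", lines) & !.is_blank(lines)]
  if (!length(lines)) {
    return(rna_structure("", NULL, 0L, source_format = "FASTA"))
  }
  hdr_idx <- which(grepl("^>", lines))
  if (!length(hdr_idx)) {
    if (strict) stop("FASTA: missing '>' header line", call. = FALSE)
    hdr_idx <- 0L
    header <- character()
    seq_lines <- lines
  } else {
    if (hdr_idx[1L] != 1L) {
      stop("FASTA: sequence data before the first '>' header", call. = FALSE)
    }
    end <- if (length(hdr_idx) > 1L) hdr_idx[2L] - 1L else length(lines)
    header <- lines[1L]
    seq_lines <- if (end >= 2L) lines[2:end] else character()
  }
  seq <- gsub("[[:space:]]", "", paste(seq_lines, collapse = ""))
  if (nzchar(seq) && !grepl(.seq_line_re, seq)) {
    stop("FASTA: sequence contains a non-letter character", call. = FALSE)
  }
  rna_structure(seq, NULL, nchar(seq), header = header, comments = comments,
                source_format = "FASTA")
}

# -- rendering ---------------------------------------------------------------

#' Render an RNA secondary structure in a plain-text format
#'
#' Produces text that [parse_rna()] maps back to a structure with the same
#' length, sequence (when the format carries one) and pair set. Headers and
#' comments are emitted only when the corresponding flag is set; formats
#' without a comment slot in their dialect (arc-annotated sequence) drop
#' carried header/comment lines with a warning.
#'
#' @param ss An [rna_structure()].
#' @param fmt One of [rna_formats()] except `"RNAML"` (see [write_rnaml()]).
#' @param keep_header Emit retained header lines? Default `TRUE`.
#' @param keep_comments Emit retained `#` comment lines? Default `TRUE`.
#' @return Character scalar ending in a newline (or `""` for an empty
#'   structure in a body-only format).
#' @export
#' @examples
#' hp <- rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
#' cat(render_rna(hp, "BPSEQ"))
render_rna <- function(ss, fmt, keep_header = TRUE, keep_comments = TRUE) {
  stopifnot(inherits(ss, "rna_structure"))
  .check_format(fmt)
  if (fmt == "RNAML") {
    return(write_rnaml(ss, name = .header_name(ss)))
  }
  needs_seq <- fmt %in% c("DB", "AAS", "FASTA", "BPSEQ", "CT")
  if (needs_seq && !nzchar(ss$sequence) && ss$length > 0L) {
    stop("format ", fmt, " requires a sequence but the structure has none",
         call. = FALSE)
  }
  comments <- if (keep_comments) ss$comments else character()
  out <- switch(fmt,
    BPSEQ = .render_bpseq(ss, keep_header, comments),
    CT = .render_ct(ss, keep_header, comments),
    DB = .render_db(ss, TRUE, keep_header, comments),
    DB_NO_SEQ = .render_db(ss, FALSE, keep_header, comments),
    AAS = .render_aas(ss, TRUE, keep_header, keep_comments),
    AAS_NO_SEQ = .render_aas(ss, FALSE, keep_header, keep_comments),
    FASTA = .render_fasta(ss, keep_header, comments)
  )
  if (!length(out)) return("")
  paste0(paste(out, collapse = "\n"), "\n")
}

.mate_vector <- function(ss) {
  mate <- integer(ss$length)
  if (nrow(ss$pairs)) {
    mate[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    mate[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  mate
}

.seq_chars <- function(ss) {
  if (nzchar(ss$sequence)) strsplit(ss$sequence, "")[[1L]] else
    rep("N", ss$length)
}

# headers carried into formats whose only metadata slot is a '#' comment
.header_as_comments <- function(ss, keep_header) {
  if (!keep_header || !length(ss$header)) return(character())
  paste0("# ", sub("^#[[:space:]]?", "", ss$header))
}

.render_bpseq <- function(ss, keep_header, comments) {
  pre <- c(comments, .header_as_comments(ss, keep_header))
  if (!ss$length) return(pre)
  mate <- .mate_vector(ss)
  c(pre, paste(seq_len(ss$length), .seq_chars(ss), mate))
}

.render_ct <- function(ss, keep_header, comments) {
  name <- if (keep_header) .header_name(ss) else "molecule"
  first <- paste(ss$length, name)
  if (!ss$length) return(c(comments, first))
  mate <- .mate_vector(ss)
  i <- seq_len(ss$length)
  c(comments, first, paste(i, .seq_chars(ss), i - 1L, i + 1L, mate, i))
}

.render_db <- function(ss, with_seq, keep_header, comments) {
  hdr <- if (keep_header && length(ss$header)) {
    ifelse(grepl("^>", ss$header), ss$header, paste0(">", ss$header))
  } else character()
  body <- character()
  if (ss$length) {
    struct <- render_brackets(ss$pairs, ss$length)
    body <- if (with_seq) c(ss$sequence, struct) else struct
  }
  c(comments, hdr, body)
}

.render_aas <- function(ss, with_seq, keep_header, keep_comments) {
  # the arc-annotated dialect has no header/comment slot
  carried <- length(ss$header) && keep_header
  carried_c <- length(ss$comments) &&
    !all(grepl(.AAS_LEN_RE, ss$comments)) && keep_comments
  if (carried || carried_c) {
    warning("arc-annotated sequence output has no header/comment slot; ",
            "retained lines dropped", call. = FALSE)
  }
  out <- character()
  if (with_seq) {
    if (ss$length) out <- c(out, ss$sequence)
  } else {
    # record total length when the pair list alone cannot recover it
    maxidx <- if (nrow(ss$pairs)) max(ss$pairs) else 0L
    if (ss$length > maxidx) out <- c(out, paste0("# length=", ss$length))
  }
  if (nrow(ss$pairs)) {
    out <- c(out, paste0("(", ss$pairs[, 1L], ",", ss$pairs[, 2L], ")",
                         collapse = ";"))
  }
  out
}

.render_fasta <- function(ss, keep_header, comments) {
  hdr <- if (keep_header && length(ss$header)) {
    h <- ss$header[1L]
    if (!grepl("^>", h)) h <- paste0(">", h)
    h
  } else {
    paste0(">", .header_name(ss))
  }
  body <- if (ss$length) {
    # wrap at 60 columns
    starts <- seq(1L, ss$length, by = 60L)
    substring(ss$sequence, starts, pmin(starts + 59L, ss$length))
  } else character()
  c(comments, hdr, body)
}

# -- format detection --------------------------------------------------------

#' Detect the format of a secondary-structure text
#'
#' Tries each supported grammar and returns the identifier of the first that
#' accepts the text, in the precedence order RNAML, CT, BPSEQ, dot-bracket
#' (with then without sequence), arc-annotated sequence (with then without
#' sequence), FASTA. CT precedes BPSEQ because its rows are a superset
#' pattern, and dot-bracket precedes the arc-annotated grammar.
#'
#' @param text Character scalar or vector of lines; must be non-empty.
#' @return A format identifier from [rna_formats()].
#' @export
#' @examples
#' detect_rna_format("1 G 9\n2 A 0\n3 C 0\n4 U 0\n5 A 0\n6 A 0\n7 A 0\n8 A 0\n9 C 1")
detect_rna_format <- function(text) {
  lines <- .split_lines(text)
  if (!length(lines) || all(.is_blank(lines))) {
    stop("cannot detect format of empty input", call. = FALSE)
  }
  body <- lines[!.is_blank(lines) & !.is_comment(lines)]
  if (length(body) && grepl("^[[:space:]]*<", body[1L])) return("RNAML")
  for (fmt in c("CT", "BPSEQ", "DB", "DB_NO_SEQ", "AAS", "AAS_NO_SEQ", "FASTA")) {
    ok <- tryCatch({ parse_rna(lines, fmt, strict = TRUE); TRUE },
                   error = function(e) FALSE)
    if (ok) return(fmt)
  }
  stop("input matches no supported secondary-structure format", call. = FALSE)
}

#' Read an RNA secondary structure file
#'
#' Convenience wrapper: reads the file, detects the format unless one is
#' given, and parses. RNAML input is routed through [read_rnaml()] with
#' non-canonical pairs dropped from the returned structure (use
#' [read_rnaml()] directly to keep the non-canonical records).
#'
#' @param path File path.
#' @param format Format identifier, or `NULL` to auto-detect.
#' @param strict Passed to the parser.
#' @return An [rna_structure()].
#' @export
read_rna <- function(path, format = NULL, strict = TRUE) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (is.null(format)) format <- detect_rna_format(text)
  if (format == "RNAML") {
    read_rnaml(text, strict = strict)$structure
  } else {
    parse_rna(text, format, strict = strict)
  }
}

#' Write an RNA secondary structure file
#'
#' @param ss An [rna_structure()].
#' @param path Output file path.
#' @param format Target format identifier.
#' @param keep_header,keep_comments Passed to [render_rna()].
#' @return `path`, invisibly.
#' @export
write_rna <- function(ss, path, format, keep_header = TRUE,
                      keep_comments = TRUE) {
  txt <- render_rna(ss, format, keep_header = keep_header,
                    keep_comments = keep_comments)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}
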