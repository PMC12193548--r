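# Format-to-format translation. The compatibility matrix encodes which
# hops are possible: formats carrying sequence + structure translate into
# anything; structure-only formats interconvert only with each other;
# FASTA (sequence only) is a sink, never a source.

.SEQ_STRUCT_FORMATS <- c("DB", "RNAML", "CT", "BPSEQ", "AAS")
.STRUCT_ONLY_FORMATS <- c("DB_NO_SEQ", "AAS_NO_SEQ")

#' Is a translation between two formats possible?
#'
#' A format carrying both sequence and structure (dot-bracket, RNAML, CT,
#' BPSEQ, arc-annotated sequence) converts into any format. The
#' structure-only variants convert only into each other, since no sequence
#' can be invented. FASTA carries no structure and converts into nothing.
#' Identity translation is always allowed (it acts as a normalizer).
#'
#' @param source,target Format identifiers from [rna_formats()].
#' @return `TRUE` if the translation is possible.
#' @export
#' @examples
#' can_translate("BPSEQ", "FASTA")      # TRUE
#' can_translate("FASTA", "CT")         # FALSE
#' can_translate("DB_NO_SEQ", "AAS_NO_SEQ") # TRUE
can_translate <- function(source, target) {
  .check_format(source)
  .check_format(target)
  if (source == target) return(TRUE)
  if (source %in% .SEQ_STRUCT_FORMATS) return(TRUE)
  if (source == "DB_NO_SEQ") return(target == "AAS_NO_SEQ")
  if (source == "AAS_NO_SEQ") return(target == "DB_NO_SEQ")
  FALSE # FASTA
}

#' The full 8x8 format compatibility matrix
#'
#' @return Logical matrix with source formats as rows and target formats as
#'   columns.
#' @export
compatibility_matrix <- function() {
  fmts <- rna_formats()
  m <- outer(fmts, fmts, Vectorize(can_translate))
  dimnames(m) <- list(source = fmts, target = fmts)
  m
}

.FORMAT_EXT <- c(DB = "db", DB_NO_SEQ = "db", RNAML = "xml", CT = "ct",
                 BPSEQ = "bpseq", AAS = "aas", AAS_NO_SEQ = "aas",
                 FASTA = "fasta")

#' File extension used for a format
#' @param fmt Format identifier.
#' @return Character scalar extension (without dot).
#' @export
format_extension <- function(fmt) unname(.FORMAT_EXT[.check_format(fmt)])

#' Translate one secondary-structure file
#'
#' Parses the input in its (declared or detected) source format, and
#' renders it in the target format, preserving the structural content
#' (sequence when carried, canonical pair set) across the hop. For RNAML
#' input the pairs are first partitioned into canonical and non-canonical;
#' only canonical pairs enter the output, and with `retain_noncanonical`
#' the excluded pairs are kept as a CSV side file.
#'
#' @param input Path to the input file.
#' @param target Target format identifier.
#' @param source Source format, or `NULL` to auto-detect.
#' @param keep_header,keep_comments Retain metadata lines? Default `TRUE`.
#' @param retain_noncanonical Export non-canonical pairs from RNAML input
#'   to CSV (`TRUE`, default) or discard them silently (`FALSE`).
#' @param emit_stats Also compute a per-molecule statistics CSV?
#' @param out_dir Directory to write output files to, or `NULL` to return
#'   text only. Output names follow `<input stem>.<target extension>`,
#'   with `<stem>.noncanonical.csv` and `<stem>.stats.csv` side files.
#' @param strict Passed to the parsers.
#' @return Invisibly, a list with `text`, `structure`, `noncanonical`
#'   (data frame or `NULL`), `noncanonical_csv`, `stats_csv`, and (when
#'   `out_dir` is given) `output` path.
#' @export
translate_file <- function(input, target, source = NULL,
                           keep_header = TRUE, keep_comments = TRUE,
                           retain_noncanonical = TRUE, emit_stats = FALSE,
                           out_dir = NULL, strict = TRUE) {
  .check_format(target)
  if (!is.null(source)) {
    .check_format(source)
    if (!can_translate(source, target)) {
      stop("translation ", source, " -> ", target,
           " is not possible (see compatibility_matrix())", call. = FALSE)
    }
  }
  text <- paste(readLines(input, warn = FALSE), collapse = "\n")
  if (is.null(source)) {
    source <- detect_rna_format(text)
    if (!can_translate(source, target)) {
      stop("translation ", source, " -> ", target,
           " is not possible (see compatibility_matrix())", call. = FALSE)
    }
  }
  noncanonical <- NULL
  if (source == "RNAML") {
    parsed <- tryCatch(read_rnaml(text, strict = strict),
                       error = function(e) {
                         stop(input, ": ", conditionMessage(e), call. = FALSE)
                       })
    ss <- parsed$structure
    if (nrow(parsed$noncanonical)) noncanonical <- parsed$noncanonical
  } else {
    ss <- tryCatch(parse_rna(text, source, strict = strict),
                   error = function(e) {
                     stop(input, ": ", conditionMessage(e), call. = FALSE)
                   })
  }
  out_text <- render_rna(ss, target, keep_header = keep_header,
                         keep_comments = keep_comments)
  nc_csv <- if (!is.null(noncanonical) && retain_noncanonical) {
    noncanonical_csv(noncanonical, .header_name(ss,
      default = tools::file_path_sans_ext(basename(input))))
  } else NULL
  st_csv <- if (emit_stats) {
    st <- structure_stats(ss, file = basename(input))
    stats_csv(st, aggregate_stats(st))
  } else NULL
  result <- list(text = out_text, structure = ss, noncanonical = noncanonical,
                 noncanonical_csv = nc_csv, stats_csv = st_csv,
                 source = source, target = target)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- tools::file_path_sans_ext(basename(input))
    out_path <- file.path(out_dir, paste0(stem, ".", format_extension(target)))
    writeLines(sub("\n$", "", out_text), out_path)
    result$output <- out_path
    if (!is.null(nc_csv)) {
      p <- file.path(out_dir, paste0(stem, ".noncanonical.csv"))
      writeLines(sub("\n$", "", nc_csv), p)
      result$noncanonical_output <- p
    }
    if (!is.null(st_csv)) {
      p <- file.path(out_dir, paste0(stem, ".stats.csv"))
      writeLines(sub("\n$", "", st_csv), p)
      result$stats_output <- p
    }
  }
  invisible(result)
}

#' Translate a batch of files
#'
#' Processes the inputs independently in lexicographic path order; a
#' per-file failure is recorded in the report and does not stop the batch.
#'
#' @param inputs Character vector of input file paths.
#' @param target Target format identifier.
#' @param ... Further arguments passed to [translate_file()].
#' @param out_dir Output directory (created if needed), or `NULL`.
#' @return Data frame with one row per input: `file`, `status`
#'   (`"ok"`/`"error"`), `output` (path or `NA`), `message` (error text or
#'   `""`).
#' @export
batch_translate <- function(inputs, target, ..., out_dir = NULL) {
  inputs <- sort(as.character(inputs), method = "radix")
  rows <- lapply(inputs, function(path) {
    res <- tryCatch(
      translate_file(path, target, ..., out_dir = out_dir),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(file = path, status = "error", output = NA_character_,
                 message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(file = path, status = "ok",
                 output = if (!is.null(res$output)) res$output else NA_character_,
                 message = "", stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), status = character(),
               output = character(), message = character(),
               stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}
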