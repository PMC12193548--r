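# Synthetic secondary structures with controlled motif content. Structures
# are assembled from a "segment program": a sequence of stem-opening,
# stem-closing and loop segments laid left to right on the backbone. Stems
# are perfect stacks; bulges are modelled as a nested stem separated by one
# unpaired nucleotide on the 5' side. Sequence letters are drawn so that
# every generated pair is canonical (G-C, A-U or G-U).

# program entries: list(op = "open"/"close"/"loop", id = stem id, n = count)
.seg_open <- function(id, n) list(op = "open", id = id, n = as.integer(n))
.seg_close <- function(id) list(op = "close", id = id)
.seg_loop <- function(n) list(op = "loop", n = as.integer(n))

# lay out a program on the backbone and return list(pairs, length)
.build_program <- function(prog) {
  pos <- 0L
  opens <- list()
  five <- integer(0); three <- integer(0)
  for (seg in prog) {
    if (seg$op == "loop") {
      pos <- pos + seg$n
    } else if (seg$op == "open") {
      idx <- pos + seq_len(seg$n)
      pos <- pos + seg$n
      opens[[seg$id]] <- idx
    } else {
      idx <- opens[[seg$id]]
      if (is.null(idx)) stop("internal: closing unopened stem ", seg$id)
      d <- length(idx)
      cl <- pos + seq_len(d)
      pos <- pos + d
      five <- c(five, idx)
      three <- c(three, rev(cl))
      opens[[seg$id]] <- NULL
    }
  }
  if (length(opens) && any(!vapply(opens, is.null, logical(1L)))) {
    stop("internal: unclosed stem in segment program")
  }
  list(pairs = base_pairs(cbind(five, three)), length = pos)
}

# run fn with a private RNG stream seeded by `seed` (or the current stream
# when seed is NULL), restoring the caller's RNG state afterwards
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# canonical pair letters with fixed weights; helix pairs only
.PAIR_TYPES <- c("GC", "CG", "AU", "UA", "GU", "UG")
.PAIR_WEIGHTS <- c(0.30, 0.30, 0.15, 0.15, 0.05, 0.05)

# assign a sequence to a pair layout: canonical letters on pairs, uniform
# ACGU on unpaired positions
.assign_sequence <- function(pairs, length) {
  chars <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
  if (nrow(pairs)) {
    type <- sample(.PAIR_TYPES, nrow(pairs), replace = TRUE,
                   prob = .PAIR_WEIGHTS)
    chars[pairs[, 1L]] <- substr(type, 1L, 1L)
    chars[pairs[, 2L]] <- substr(type, 2L, 2L)
  }
  paste(chars, collapse = "")
}

#' Build an H-type pseudoknot
#'
#' Two mutually crossing stems: stem 1 opens, stem 2 opens, stem 1 closes,
#' stem 2 closes, with the three loop lengths in between. The shape
#' abstraction of any such structure is `([)]`.
#'
#' @param stem1,stem2 Stack depths (>= 1) of the two crossing stems.
#' @param loops Integer vector of three loop lengths (>= 0) separating the
#'   four stem segments.
#' @param seed Optional seed for the sequence letters; the arc layout is
#'   deterministic.
#' @return An [rna_structure()] with a canonical-pair sequence.
#' @export
#' @examples
#' h_pseudoknot(1, 1, c(1, 1, 1))$pairs # arcs (1,5) and (3,7)
h_pseudoknot <- function(stem1 = 3L, stem2 = 3L, loops = c(3L, 3L, 3L),
                         seed = NULL) {
  stopifnot(stem1 >= 1L, stem2 >= 1L, length(loops) == 3L, all(loops >= 0L))
  prog <- list(.seg_open("s1", stem1), .seg_loop(loops[1L]),
               .seg_open("s2", stem2), .seg_loop(loops[2L]),
               .seg_close("s1"), .seg_loop(loops[3L]),
               .seg_close("s2"))
  lay <- .build_program(prog)
  sq <- .with_seed(seed, function() .assign_sequence(lay$pairs, lay$length))
  rna_structure(sq, lay$pairs, lay$length)
}

# one hairpin module program: stem (optionally split by a 1-nt bulge on the
# 5' side) around a terminal loop
.hairpin_program <- function(id, stem, loop, bulge_at = NULL) {
  if (is.null(bulge_at) || bulge_at <= 0L || bulge_at >= stem) {
    list(.seg_open(id, stem), .seg_loop(loop), .seg_close(id))
  } else {
    outer_id <- paste0(id, "o"); inner_id <- paste0(id, "i")
    list(.seg_open(outer_id, bulge_at), .seg_loop(1L),
         .seg_open(inner_id, stem - bulge_at), .seg_loop(loop),
         .seg_close(inner_id), .seg_close(outer_id))
  }
}

# nested H-type program: outer crossing stems A/B with a complete H-type
# (C/D) inside B's span, after A closes; shape "([)([)]]"
.nested_pk_program <- function(depths, loops) {
  list(.seg_open("A", depths[1L]), .seg_loop(loops[1L]),
       .seg_open("B", depths[2L]), .seg_loop(loops[2L]),
       .seg_close("A"), .seg_loop(loops[3L]),
       .seg_open("C", depths[3L]), .seg_loop(loops[4L]),
       .seg_open("D", depths[4L]), .seg_loop(loops[5L]),
       .seg_close("C"), .seg_loop(loops[6L]),
       .seg_close("D"), .seg_loop(loops[7L]),
       .seg_close("B"))
}

#' Generate a random secondary structure with controlled motifs
#'
#' Deterministic given `seed`. The structure contains `helix_count` hairpin
#' modules (stems in the `helix_len` range around loops of 3-6 nt, each
#' split by a one-nucleotide bulge with probability `bulge_prob`),
#' `pseudoknot_count` H-type pseudoknot modules, and, when `nested_pk` is
#' set, one module in which a complete H-type pseudoknot is nested inside
#' the span of a larger one. Modules are separated by short unpaired
#' spacers and the backbone is padded with unpaired nucleotides up to
#' `length`. With `pseudoknot_count = 0` and `nested_pk = FALSE` the result
#' is always pseudoknot-free; any pseudoknot module makes it pseudoknotted.
#' Sequence letters are drawn so every pair is canonical.
#'
#' @param length Total number of nucleotides; must accommodate the modules.
#' @param helix_count Number of plain hairpin modules.
#' @param helix_len Length-2 range of stem depths.
#' @param bulge_prob Per-hairpin probability of a 1-nt bulge.
#' @param pseudoknot_count Number of H-type pseudoknot modules.
#' @param nested_pk Add a nested H-type pseudoknot module?
#' @param seed Optional integer seed; identical seeds give identical
#'   structures.
#' @return An [rna_structure()].
#' @export
#' @examples
#' ss <- random_structure(60, helix_count = 2, seed = 7)
#' is_pseudoknotted(ss)
random_structure <- function(length = 80L, helix_count = 2L,
                             helix_len = c(2L, 6L), bulge_prob = 0.1,
                             pseudoknot_count = 0L, nested_pk = FALSE,
                             seed = NULL) {
  .with_seed(seed, function() {
    prog <- list()
    nmod <- 0L
    add_spacer <- function(prog) {
      n <- sample(0:3, 1L)
      if (n > 0L) c(prog, list(.seg_loop(n))) else prog
    }
    if (isTRUE(nested_pk)) {
      depths <- sample(seq(helix_len[1L], helix_len[2L]), 4L, replace = TRUE)
      loops <- sample(1:3, 7L, replace = TRUE)
      prog <- c(prog, .nested_pk_program(depths, loops))
      prog <- add_spacer(prog)
    }
    if (pseudoknot_count > 0L) {
      for (k in seq_len(pseudoknot_count)) {
        s1 <- sample(seq(helix_len[1L], helix_len[2L]), 1L)
        s2 <- sample(seq(helix_len[1L], helix_len[2L]), 1L)
        lp <- sample(1:3, 3L, replace = TRUE)
        prog <- c(prog, list(.seg_open(paste0("p", k, "a"), s1),
                             .seg_loop(lp[1L]),
                             .seg_open(paste0("p", k, "b"), s2),
                             .seg_loop(lp[2L]),
                             .seg_close(paste0("p", k, "a")),
                             .seg_loop(lp[3L]),
                             .seg_close(paste0("p", k, "b"))))
        prog <- add_spacer(prog)
      }
    }
    if (helix_count > 0L) {
      for (k in seq_len(helix_count)) {
        stem <- sample(seq(helix_len[1L], helix_len[2L]), 1L)
        loop <- sample(3:6, 1L)
        bulge <- if (stem >= 2L && stats::runif(1L) < bulge_prob) {
          sample(seq_len(stem - 1L), 1L)
        } else NULL
        prog <- c(prog, .hairpin_program(paste0("h", k), stem, loop, bulge))
        prog <- add_spacer(prog)
      }
    }
    lay <- .build_program(prog)
    if (lay$length > length) {
      stop("requested length ", length, " is too small for the generated ",
           "modules (need at least ", lay$length, ")", call. = FALSE)
    }
    # remaining positions up to `length` stay unpaired padding
    sq <- .assign_sequence(lay$pairs, length)
    rna_structure(sq, lay$pairs, length)
  })
}
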