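# Arc-diagram abstractions. All three operators reduce a structure to a
# topological skeleton rendered in dot-bracket:
#   core      = collapse_parallel(remove_unpaired(x))
#   core plus = remove_unpaired(collapse_parallel(x))   (no second collapse)
#   shape     = drop non-crossing arcs, remove unpaired, collapse
# Two arcs are parallel when they are nested with adjacent endpoints on both
# sides (i2 = i1+1 and j1 = j2+1, no nucleotide in between); bulges and
# loops therefore block collapsing until unpaired positions are removed,
# which is what makes core and core plus differ.

# delete the given backbone positions and renumber pairs/sequence
.drop_positions <- function(ss, drop) {
  if (!length(drop)) return(ss)
  drop <- sort(unique(drop))
  keep <- setdiff(seq_len(ss$length), drop)
  remap <- integer(ss$length)
  remap[keep] <- seq_along(keep)
  m <- ss$pairs
  if (nrow(m)) {
    if (any(m %in% drop)) stop("internal: dropping a paired position")
    m <- cbind(remap[m[, 1L]], remap[m[, 2L]])
  }
  seq <- if (nzchar(ss$sequence)) {
    paste(strsplit(ss$sequence, "")[[1L]][keep], collapse = "")
  } else ""
  rna_structure(seq, m, length(keep), header = ss$header,
                comments = ss$comments, source_format = ss$source_format)
}

#' Remove unpaired nucleotides
#'
#' Deletes every nucleotide that takes part in no base pair and renumbers
#' the remainder 1..m, remapping pair endpoints. Nesting and crossing
#' relations among the arcs are unchanged.
#'
#' @param ss An [rna_structure()].
#' @return The reduced [rna_structure()].
#' @export
#' @examples
#' hp <- rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
#' remove_unpaired(hp)$pairs
remove_unpaired <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  unpaired <- setdiff(seq_len(ss$length), as.vector(ss$pairs))
  .drop_positions(ss, unpaired)
}

#' Collapse parallel arcs to fixpoint
#'
#' Repeatedly merges any two arcs `(i1,j1)`, `(i2,j2)` with `i2 = i1+1` and
#' `j1 = j2+1` (nested, no vertex between the 5' endpoints nor between the
#' 3' endpoints) into the outer arc, deleting the inner arc's two positions
#' and renumbering. Iterated until no parallel pair remains; the merge
#' order does not affect the result.
#'
#' @param ss An [rna_structure()].
#' @return The reduced [rna_structure()].
#' @export
#' @examples
#' helix <- rna_structure(pairs = list(c(1, 6), c(2, 5), c(3, 4)), length = 6)
#' collapse_parallel(helix)$pairs # single arc (1,2)
collapse_parallel <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  repeat {
    m <- ss$pairs
    if (nrow(m) < 2L) return(ss)
    key <- paste(m[, 1L], m[, 2L])
    inner <- match(paste(m[, 1L] + 1L, m[, 2L] - 1L), key)
    hit <- which(!is.na(inner))[1L]
    if (is.na(hit)) return(ss)
    inner_row <- inner[hit]
    drop <- m[inner_row, ]
    ss$pairs <- m[-inner_row, , drop = FALSE]
    ss <- .drop_positions(ss, drop)
  }
}

#' Core abstraction
#'
#' Removes unpaired nucleotides first, then collapses parallel arcs to
#' fixpoint. Stacked helices reduce to single arcs even across bulges and
#' internal loops, because the interrupting unpaired nucleotides are gone
#' before collapsing.
#'
#' @param ss An [rna_structure()].
#' @return The reduced [rna_structure()].
#' @export
core <- function(ss) {
  collapse_parallel(remove_unpaired(ss))
}

#' Core plus abstraction
#'
#' Collapses parallel arcs first, then removes unpaired nucleotides; no
#' second collapse pass follows. Bulges and loops block the collapse, so
#' core plus retains more arcs than core (a bulged helix keeps one arc per
#' uninterrupted stack).
#'
#' @param ss An [rna_structure()].
#' @return The reduced [rna_structure()].
#' @export
core_plus <- function(ss) {
  remove_unpaired(collapse_parallel(ss))
}

#' Shape abstraction
#'
#' Retains only the crossing skeleton: arcs that cross no other arc are
#' deleted, all now-unpaired nucleotides are removed, and parallel arcs are
#' collapsed. A pseudoknot-free structure reduces to the empty structure
#' (the "null shape"); an H-type pseudoknot reduces to `([)]`.
#'
#' @param ss An [rna_structure()].
#' @return The reduced [rna_structure()] (empty when pseudoknot-free).
#' @export
shape <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  keep <- .crossing_flags(ss$pairs)
  ss$pairs <- ss$pairs[keep, , drop = FALSE]
  collapse_parallel(remove_unpaired(ss))
}

#' Dot-bracket string of an abstraction
#'
#' Applies the chosen operator and renders the reduced structure as a
#' structure-only extended dot-bracket string. The shape of a
#' pseudoknot-free molecule is the empty string; census output labels it
#' `"Null Shape"` (see [abstraction_label()]).
#'
#' @param ss An [rna_structure()].
#' @param kind `"core"`, `"coreplus"`, or `"shape"`.
#' @return Dot-bracket string (possibly `""`).
#' @export
#' @examples
#' pk <- rna_structure(pairs = list(c(1, 5), c(3, 7)), length = 8)
#' abstraction_string(pk, "shape") # "([)]"
abstraction_string <- function(ss, kind = c("core", "coreplus", "shape")) {
  kind <- match.arg(kind)
  red <- switch(kind, core = core(ss), coreplus = core_plus(ss),
                shape = shape(ss))
  render_brackets(red$pairs, red$length)
}

#' Census label of an abstraction
#'
#' Like [abstraction_string()] but maps the empty shape to the literal
#' label `"Null Shape"` used in motif census tables.
#'
#' @inheritParams abstraction_string
#' @return Character scalar.
#' @export
abstraction_label <- function(ss, kind = c("core", "coreplus", "shape")) {
  kind <- match.arg(kind)
  s <- abstraction_string(ss, kind)
  if (kind == "shape" && !nzchar(s)) "Null Shape" else s
}
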