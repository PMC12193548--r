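# Extended dot-bracket page machinery.
#
# A "page" is one bracket symbol family; arcs on the same page never cross,
# so a pseudoknot-free structure needs only "()" while crossing arcs spill
# onto further families. Pages are assigned greedily, first come first
# served: pairs are visited in ascending 5' index and each takes the lowest
# page where it crosses nothing already placed there.

.PAGE_OPEN  <- c("(", "[", "{", "<", LETTERS)
.PAGE_CLOSE <- c(")", "]", "}", ">", letters)
.MAX_PAGES  <- length(.PAGE_OPEN) # 4 bracket families + 26 letter families

#' First-come-first-served page assignment
#'
#' Visits base pairs in ascending 5' index and assigns each to the smallest
#' 0-based page on which it crosses no previously assigned pair. A
#' pseudoknot-free pair set ends up entirely on page 0.
#'
#' @param pairs Base pairs in any form accepted by [base_pairs()].
#' @return List with `pairs` (the sorted pair matrix) and `page` (integer
#'   vector of 0-based page indices, one per row).
#' @export
#' @examples
#' assign_pages(list(c(1, 4), c(2, 5), c(3, 6)))$page # 0 1 2: mutual crossing
assign_pages <- function(pairs) {
  m <- base_pairs(pairs)
  n <- nrow(m)
  page <- integer(n)
  if (n > 1L) {
    # per page, track the pairs already assigned there
    members <- list()
    for (i in seq_len(n)) {
      p <- 0L
      repeat {
        idx <- if (p + 1L <= length(members)) members[[p + 1L]] else integer(0)
        if (!length(idx)) break
        f <- m[idx, 1L]; t3 <- m[idx, 2L]
        # m is sorted by five, so f < m[i,1]; crossing iff f < i5 < t3 < i3
        # or i5 < f is impossible here except equal-start (cannot happen)
        clash <- any(f < m[i, 1L] & m[i, 1L] < t3 & t3 < m[i, 2L])
        if (!clash) break
        p <- p + 1L
      }
      page[i] <- p
      if (p + 1L > length(members)) members[[p + 1L]] <- integer(0)
      members[[p + 1L]] <- c(members[[p + 1L]], i)
    }
  }
  list(pairs = m, page = page)
}

#' Render a pair set as an extended dot-bracket string
#'
#' Unpaired positions become `.`; page *p* (from [assign_pages()]) uses the
#' *p*-th symbol family in the fixed order `()`, `[]`, `{}`, `<>`, then
#' `Aa` .. `Zz` (uppercase opens, lowercase closes).
#'
#' @param pairs Base pairs in any form accepted by [base_pairs()].
#' @param length Total number of nucleotides (string length).
#' @return Dot-bracket string of `length` characters (`""` when length 0).
#' @export
#' @examples
#' render_brackets(list(c(1, 9), c(2, 8), c(3, 7)), 9) # "(((...)))"
#' render_brackets(list(c(1, 5), c(3, 7)), 8)          # "(.[.).]."
render_brackets <- function(pairs, length) {
  length <- as.integer(length)
  pa <- assign_pages(pairs)
  m <- pa$pairs
  if (nrow(m) && max(m) > length) {
    stop("pair index ", max(m), " exceeds length ", length, call. = FALSE)
  }
  if (nrow(m) && max(pa$page) + 1L > .MAX_PAGES) {
    stop("structure needs ", max(pa$page) + 1L,
         " bracket families but only ", .MAX_PAGES, " are available",
         call. = FALSE)
  }
  chars <- rep(".", length)
  if (nrow(m)) {
    chars[m[, 1L]] <- .PAGE_OPEN[pa$page + 1L]
    chars[m[, 2L]] <- .PAGE_CLOSE[pa$page + 1L]
  }
  paste(chars, collapse = "")
}

#' Parse an extended dot-bracket string into base pairs
#'
#' Runs one stack per symbol family; a closer pops its own family's most
#' recent opener. Dots are unpaired. In lenient contexts `-` may be mapped
#' to `.` by the caller before parsing.
#'
#' @param s Dot-bracket string.
#' @return Integer pair matrix as from [base_pairs()].
#' @export
#' @examples
#' parse_brackets("(.[.).].") # rows (1,5) and (3,7)
parse_brackets <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stacks <- vector("list", .MAX_PAGES)
  five <- integer(0); three <- integer(0)
  open_idx <- match(chars, .PAGE_OPEN)
  close_idx <- match(chars, .PAGE_CLOSE)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == ".") next
    oi <- open_idx[i]
    if (!is.na(oi)) {
      stacks[[oi]] <- c(stacks[[oi]], i)
      next
    }
    ci <- close_idx[i]
    if (!is.na(ci)) {
      st <- stacks[[ci]]
      if (!length(st)) {
        stop("unmatched '", ch, "' at position ", i, call. = FALSE)
      }
      five <- c(five, st[length(st)])
      three <- c(three, i)
      stacks[[ci]] <- st[-length(st)]
      next
    }
    stop("unexpected character '", ch, "' at position ", i,
         " in structure line", call. = FALSE)
  }
  left <- unlist(stacks)
  if (length(left)) {
    stop(length(left), " unmatched opening bracket",
         if (length(left) > 1L) "s", " (first at position ", min(left), ")",
         call. = FALSE)
  }
  base_pairs(cbind(five, three))
}
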