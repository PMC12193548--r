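# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's internal code paths: crossing is re-derived from the
# definition, parallel-arc collapsing works in original coordinates with
# random merge order, and page counts are checked against an exhaustive
# graph coloring of the crossing graph.

toy_hairpin <- function() {
  rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
}

h_type_toy <- function() {
  rna_structure(pairs = list(c(1, 5), c(3, 7)), length = 8)
}

bulged_helix <- function() {
  rna_structure(pairs = list(c(1, 10), c(2, 9), c(4, 8)), length = 10)
}

expect_same_structure <- function(a, b) {
  expect_equal(a$length, b$length)
  expect_identical(unname(a$pairs), unname(b$pairs))
  if (nzchar(a$sequence) && nzchar(b$sequence)) {
    expect_identical(a$sequence, b$sequence)
  }
}

# random valid pair set: k pairs over n positions (no structure semantics)
rand_pair_set <- function(n, k) {
  idx <- sort(sample.int(n, 2L * k))
  perm <- sample.int(2L * k)
  base_pairs(matrix(idx[perm], ncol = 2L))
}

# brute-force pseudoknot oracle straight from the crossing definition
oracle_pseudoknotted <- function(pairs) {
  m <- base_pairs(pairs)
  n <- nrow(m)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- m[i, ]; b <- m[j, ]
      if ((a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) ||
          (b[1] < a[1] && a[1] < b[2] && b[2] < a[2])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# independent collapse-to-fixpoint: keeps original coordinates, merges a
# randomly chosen parallel pair each round, renumbers only at the end
oracle_collapse <- function(ss, seed) {
  set.seed(seed)
  pos <- seq_len(ss$length)
  ps <- lapply(seq_len(nrow(ss$pairs)), function(i) ss$pairs[i, ])
  repeat {
    cand <- list()
    if (length(ps) >= 2L) {
      for (a in seq_along(ps)) {
        for (b in seq_along(ps)) {
          if (a == b) next
          A <- ps[[a]]; B <- ps[[b]]
          if (A[1] < B[1] && B[2] < A[2] &&
              !any(pos > A[1] & pos < B[1]) &&
              !any(pos > B[2] & pos < A[2])) {
            cand[[length(cand) + 1L]] <- c(a, b)
          }
        }
      }
    }
    if (!length(cand)) break
    pick <- cand[[sample.int(length(cand), 1L)]]
    B <- ps[[pick[2L]]]
    pos <- setdiff(pos, B)
    ps[[pick[2L]]] <- NULL
  }
  m <- if (length(ps)) do.call(rbind, ps) else matrix(integer(0), ncol = 2L)
  spos <- sort(pos)
  if (nrow(m)) {
    m <- cbind(match(m[, 1L], spos), match(m[, 2L], spos))
  }
  list(pairs = base_pairs(m), length = length(spos))
}

# exact chromatic number of the crossing graph by exhaustive search
# (feasible for <= 8 arcs)
oracle_min_pages <- function(pairs) {
  m <- base_pairs(pairs)
  n <- nrow(m)
  if (n == 0L) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) adj[i, j] <- crosses(m[i, ], m[j, ])
    }
  }
  for (k in 1:n) {
    grid <- rep(list(seq_len(k)), n)
    combos <- do.call(expand.grid, grid)
    for (r in seq_len(nrow(combos))) {
      col <- as.integer(combos[r, ])
      ok <- TRUE
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (adj[i, j] && col[i] == col[j]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) return(k)
    }
  }
  n
}

# expected compatibility matrix, hand-coded cell by cell: rows = source,
# columns = target; sequence+structure sources convert to everything,
# structure-only sources only to each other, FASTA to nothing, identity
# always allowed
expected_matrix <- function() {
  fmts <- c("DB_NO_SEQ", "DB", "RNAML", "CT", "BPSEQ", "AAS", "AAS_NO_SEQ",
            "FASTA")
  rows <- rbind(
    DB_NO_SEQ  = c(TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE),
    DB         = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    RNAML      = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    CT         = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    BPSEQ      = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    AAS        = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE),
    AAS_NO_SEQ = c(TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE),
    FASTA      = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  dimnames(rows) <- list(fmts, fmts)
  rows
}

# a pool of structures covering hairpins, multi-helix, bulges, pseudoknots
random_fixture <- function(seed) {
  set.seed(seed)
  kind <- sample(4L, 1L)
  spec_seed <- sample.int(1e6, 1L)
  switch(kind,
    random_structure(60, helix_count = 2, bulge_prob = 0.3, seed = spec_seed),
    random_structure(70, helix_count = 1, pseudoknot_count = 1,
                     bulge_prob = 0.2, seed = spec_seed),
    random_structure(110, helix_count = 1, nested_pk = TRUE, seed = spec_seed),
    random_structure(50, helix_count = 3, helix_len = c(2, 4),
                     seed = spec_seed)
  )
}
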