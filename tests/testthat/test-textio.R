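toy_bpseq <- "1 G 9\n2 G 8\n3 G 7\n4 A 0\n5 A 0\n6 A 0\n7 C 3\n8 C 2\n9 C 1"

test_that("BPSEQ parsing reads position/base/mate triples", {
  ss <- parse_rna(toy_bpseq, "BPSEQ")
  expect_identical(ss$sequence, "GGGAAACCC")
  expect_identical(unname(ss$pairs), cbind(1:3, 9:7))
  expect_identical(ss$source_format, "BPSEQ")
})

test_that("BPSEQ irregularities are format errors naming the lines", {
  expect_error(parse_rna("1 G 2\n2 C 3\n3 A 2", "BPSEQ"), "asymmetric")
  expect_error(parse_rna("1 G 2\n2 C 3", "BPSEQ"), "outside")
  expect_error(parse_rna("1 G 0\n3 G 0", "BPSEQ"), "not contiguous")
  expect_error(parse_rna("1 G 0\n2 C", "BPSEQ"), "3 fields")
  expect_error(parse_rna("1 G 5\n2 C 0", "BPSEQ"), "outside")
  expect_error(parse_rna("1 G 1", "BPSEQ"), "itself")
  # lenient mode fills missing positions as unpaired
  ss <- parse_rna("1 G 0\n3 G 0", "BPSEQ", strict = FALSE)
  expect_equal(ss$length, 3L)
  expect_identical(ss$sequence, "GNG")
})

test_that("CT parsing honors the declared length and name", {
  ct <- "9 toy\n1 G 0 2 9 1\n2 G 1 3 8 2\n3 G 2 4 7 3\n4 A 3 5 0 4\n5 A 4 6 0 5\n6 A 5 7 0 6\n7 C 6 8 3 7\n8 C 7 9 2 8\n9 C 8 10 1 9"
  ss <- parse_rna(ct, "CT")
  expect_identical(ss$sequence, "GGGAAACCC")
  expect_identical(unname(ss$pairs), cbind(1:3, 9:7))
  expect_identical(ss$header, "toy")
  expect_error(parse_rna("3 short\n1 G 0 2 0 1", "CT"), "declares 3")
  expect_error(parse_rna("1 x\n1 G 0 2", "CT"), "fewer than 6")
})

test_that("dot-bracket parsing matches brackets by family", {
  ss <- parse_rna(">toy\nGGGAAACCC\n(((...)))", "DB")
  expect_identical(ss$sequence, "GGGAAACCC")
  expect_identical(unname(ss$pairs), cbind(1:3, 9:7))
  expect_identical(ss$header, ">toy")

  mixed <- parse_rna("AGCUAGCU\n(.[.).].", "DB")
  expect_identical(unname(mixed$pairs), cbind(c(1L, 3L), c(5L, 7L)))

  only <- parse_rna("(.[.).].", "DB_NO_SEQ")
  expect_identical(only$sequence, "")
  expect_equal(only$length, 8L)

  expect_error(parse_rna("GGGG\n(((", "DB"), "4 letters but structure line has 3")
  expect_error(parse_rna("GGG\n(()", "DB"), "unmatched")
  expect_error(parse_rna("GG\n(-", "DB"), "unexpected character")
  # lenient: '-' treated as unpaired
  expect_equal(nrow(parse_rna("GG\n--", "DB", strict = FALSE)$pairs), 0L)
})

test_that("arc-annotated sequence parsing reads the coordinate list", {
  ss <- parse_rna("GGGAAACCC\n(1,9);(2,8);(3,7)", "AAS")
  expect_identical(ss$sequence, "GGGAAACCC")
  expect_identical(unname(ss$pairs), cbind(1:3, 9:7))

  noseq <- parse_rna("(1,5);(3,7)", "AAS_NO_SEQ")
  expect_identical(noseq$sequence, "")
  expect_equal(noseq$length, 7L)

  expect_error(parse_rna("GGG\n(1,3);x", "AAS"), "unexpected text")
})

test_that("FASTA carries the sequence only", {
  ss <- parse_rna(">x some description\nGGGA\nAACCC", "FASTA")
  expect_identical(ss$sequence, "GGGAAACCC")
  expect_equal(nrow(ss$pairs), 0L)
  expect_identical(ss$header, ">x some description")
  expect_error(parse_rna("GGGA", "FASTA"), "header")
})

test_that("rendering emits the exact dialect text", {
  hp <- toy_hairpin()
  expect_identical(render_rna(hp, "BPSEQ"), paste0(toy_bpseq, "\n"))
  ct_lines <- strsplit(render_rna(hp, "CT"), "\n")[[1]]
  expect_identical(ct_lines[1], "9 molecule")
  expect_identical(ct_lines[2], "1 G 0 2 9 1")
  expect_identical(ct_lines[10], "9 C 8 10 1 9")
  # mate column follows the pairing 9 8 7 0 0 0 3 2 1
  mates <- vapply(strsplit(ct_lines[-1], " "), `[`, character(1), 5)
  expect_identical(mates, as.character(c(9, 8, 7, 0, 0, 0, 3, 2, 1)))

  expect_identical(render_rna(h_type_toy(), "DB_NO_SEQ"), "(.[.).].\n")
  fasta <- render_rna(hp, "FASTA")
  expect_identical(fasta, ">molecule\nGGGAAACCC\n")
})

test_that("header and comment flags control metadata emission", {
  ss <- parse_rna("# a comment\n>toy\nGGGAAACCC\n(((...)))", "DB")
  expect_identical(ss$comments, "# a comment")
  full <- render_rna(ss, "DB")
  expect_match(full, ">toy", fixed = TRUE)
  expect_match(full, "# a comment", fixed = TRUE)
  bare <- render_rna(ss, "DB", keep_header = FALSE, keep_comments = FALSE)
  expect_false(grepl(">", bare, fixed = TRUE))
  expect_false(grepl("#", bare, fixed = TRUE))
  # headers survive a hop into CT's name slot and BPSEQ's comment slot
  expect_identical(strsplit(render_rna(ss, "CT"), "\n")[[1]][2], "9 toy")
  expect_match(render_rna(ss, "BPSEQ"), "# >toy", fixed = TRUE)
})

test_that("structure-only targets refuse structures they cannot carry", {
  noseq <- h_type_toy()
  expect_error(render_rna(noseq, "BPSEQ"), "requires a sequence")
  expect_error(render_rna(noseq, "FASTA"), "requires a sequence")
  expect_error(write_rnaml(noseq), "requires a sequence")
})

test_that("format detection picks the unique accepting grammar", {
  expect_identical(detect_rna_format(toy_bpseq), "BPSEQ")
  expect_identical(detect_rna_format("9 toy\n1 G 0 2 9 1\n2 G 1 3 8 2\n3 G 2 4 7 3\n4 A 3 5 0 4\n5 A 4 6 0 5\n6 A 5 7 0 6\n7 C 6 8 3 7\n8 C 7 9 2 8\n9 C 8 10 1 9"), "CT")
  expect_identical(detect_rna_format(">x\nGGGA"), "FASTA")
  expect_identical(detect_rna_format("(1,9);(2,8)"), "AAS_NO_SEQ")
  expect_identical(detect_rna_format("GGGA\n(1,3);(2,4)"), "AAS")
  expect_identical(detect_rna_format(">t\nGGGAAACCC\n(((...)))"), "DB")
  expect_identical(detect_rna_format("(((...)))"), "DB_NO_SEQ")
  expect_identical(detect_rna_format("<rnaml></rnaml>"), "RNAML")
  expect_error(detect_rna_format("!!!"), "no supported")
})

test_that("round trips preserve length, sequence and pairs per format", {
  formats <- c("BPSEQ", "CT", "DB", "AAS")
  for (seed in 1:60) {
    ss <- random_fixture(seed)
    for (fmt in formats) {
      back <- parse_rna(render_rna(ss, fmt), fmt)
      expect_same_structure(back, ss)
    }
    # structure-only variants drop the sequence but keep geometry
    for (fmt in c("DB_NO_SEQ", "AAS_NO_SEQ")) {
      back <- parse_rna(render_rna(ss, fmt), fmt)
      expect_equal(back$length, ss$length)
      expect_identical(unname(back$pairs), unname(ss$pairs))
    }
    # FASTA keeps the sequence exactly (wrapping ignored)
    expect_identical(parse_rna(render_rna(ss, "FASTA"), "FASTA")$sequence,
                     ss$sequence)
  }
})

test_that("empty structures round-trip through structure formats", {
  empty <- rna_structure("", NULL, 0)
  for (fmt in c("BPSEQ", "CT", "DB", "DB_NO_SEQ", "AAS", "AAS_NO_SEQ")) {
    back <- parse_rna(render_rna(empty, fmt), fmt)
    expect_equal(back$length, 0L)
    expect_equal(nrow(back$pairs), 0L)
  }
})

test_that("concatenated CT/BPSEQ records yield the first molecule", {
  two <- paste(toy_bpseq, toy_bpseq, sep = "\n")
  ss <- parse_rna(two, "BPSEQ")
  expect_equal(ss$length, 9L)
  expect_identical(ss$sequence, "GGGAAACCC")
})

test_that("file-level read/write round-trips with auto-detection", {
  dir <- withr::local_tempdir()
  ss <- random_structure(70, helix_count = 2, pseudoknot_count = 1, seed = 3)
  for (fmt in c("BPSEQ", "CT", "DB", "AAS")) {
    p <- file.path(dir, paste0("m.", format_extension(fmt)))
    write_rna(ss, p, fmt)
    back <- read_rna(p) # format auto-detected
    expect_same_structure(back, ss)
  }
})
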