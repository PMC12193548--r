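test_that("can_translate reproduces the compatibility matrix cell by cell", {
  exp <- expected_matrix()
  for (src in rownames(exp)) {
    for (tgt in colnames(exp)) {
      expect_identical(can_translate(src, tgt), unname(exp[src, tgt]),
                       label = paste(src, "->", tgt))
    }
  }
  got <- compatibility_matrix()
  expect_identical(unname(got[rownames(exp), colnames(exp)]), unname(exp))
})

test_that("translate_file preserves structural content across a hop", {
  dir <- withr::local_tempdir()
  hp <- toy_hairpin()
  p <- file.path(dir, "toy.bpseq")
  write_rna(hp, p, "BPSEQ")
  res <- translate_file(p, "CT", out_dir = dir)
  expect_identical(res$output, file.path(dir, "toy.ct"))
  back <- parse_rna(paste(readLines(res$output), collapse = "\n"), "CT")
  expect_same_structure(back, hp)
})

test_that("matrix violations are capability errors before any parsing", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.db")
  writeLines("(((...)))", p)
  expect_error(translate_file(p, "CT", source = "DB_NO_SEQ"), "not possible")
  # also with auto-detection
  expect_error(translate_file(p, "CT"), "not possible")
  p2 <- file.path(dir, "y.fasta")
  writeLines(c(">y", "ACGU"), p2)
  expect_error(translate_file(p2, "BPSEQ"), "not possible")
})

test_that("non-canonical RNAML pairs are diverted to CSV, never to output", {
  dir <- withr::local_tempdir()
  xml <- paste0(
    "<rnaml><molecule><identity><name>toy</name></identity>",
    "<sequence><seq-data>GGGAACCCC</seq-data></sequence>",
    "<structure><model><str-annotation>",
    "<base-pair><base-id-5p><base-id><position>1</position></base-id></base-id-5p>",
    "<base-id-3p><base-id><position>9</position></base-id></base-id-3p></base-pair>",
    "<base-pair><base-id-5p><base-id><position>6</position></base-id></base-id-5p>",
    "<base-id-3p><base-id><position>8</position></base-id></base-id-3p></base-pair>",
    "</str-annotation></model></structure></molecule></rnaml>")
  p <- file.path(dir, "toy.xml")
  writeLines(xml, p)
  res <- translate_file(p, "BPSEQ", out_dir = dir)
  # pair (6,8) is C-C: excluded from BPSEQ, exported as CSV
  out <- paste(readLines(res$output), collapse = "\n")
  back <- parse_rna(out, "BPSEQ")
  expect_identical(unname(back$pairs), cbind(1L, 9L))
  expect_true(file.exists(file.path(dir, "toy.noncanonical.csv")))
  csv <- readLines(file.path(dir, "toy.noncanonical.csv"))
  expect_identical(csv[2], "toy,6,C,8,C")
  # discard mode: no CSV side file
  res2 <- translate_file(p, "CT", retain_noncanonical = FALSE,
                         out_dir = file.path(dir, "d2"))
  expect_false(file.exists(file.path(dir, "d2", "toy.noncanonical.csv")))
})

test_that("translation is path-independent across sequence formats", {
  fmts <- c("DB", "RNAML", "CT", "BPSEQ", "AAS")
  for (seed in 1:10) {
    ss <- random_fixture(seed)
    # carried metadata warnings (formats without a header slot) are not
    # under test here
    hop <- function(s, fmt) {
      if (fmt == "RNAML") read_rnaml(write_rnaml(s))$structure
      else parse_rna(suppressWarnings(render_rna(s, fmt)), fmt)
    }
    for (f in fmts) {
      one <- hop(ss, f)
      for (g in setdiff(fmts, f)) {
        two <- hop(one, g)
        for (h in setdiff(fmts, c(f, g))) {
          expect_same_structure(hop(two, h), hop(one, h))
        }
      }
    }
  }
})

test_that("batch translation records failures without stopping", {
  dir <- withr::local_tempdir()
  write_rna(toy_hairpin(), file.path(dir, "a.bpseq"), "BPSEQ")
  write_rna(h_pseudoknot(2, 2, c(1, 1, 1), seed = 1),
            file.path(dir, "b.bpseq"), "BPSEQ")
  writeLines("1 G 5\n2 C 0", file.path(dir, "c.bpseq")) # corrupt
  rep <- batch_translate(list.files(dir, full.names = TRUE), "CT",
                         out_dir = file.path(dir, "out"))
  expect_equal(nrow(rep), 3L)
  expect_identical(rep$status, c("ok", "ok", "error"))
  expect_match(rep$message[3], "no supported")
  expect_true(all(file.exists(rep$output[1:2])))
  # deterministic lexicographic order
  expect_identical(basename(rep$file), c("a.bpseq", "b.bpseq", "c.bpseq"))
  # empty batch
  expect_equal(nrow(batch_translate(character(), "CT")), 0L)
})

test_that("translation conserves the canonical pair set", {
  dir <- withr::local_tempdir()
  for (seed in 1:10) {
    ss <- random_fixture(seed)
    p <- file.path(dir, sprintf("m%02d.bpseq", seed))
    write_rna(ss, p, "BPSEQ")
    for (tgt in c("CT", "DB", "AAS", "RNAML")) {
      res <- translate_file(p, tgt)
      got <- if (tgt == "RNAML") read_rnaml(res$text)$structure
             else parse_rna(res$text, tgt)
      expect_identical(unname(got$pairs), unname(ss$pairs))
    }
  }
})
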