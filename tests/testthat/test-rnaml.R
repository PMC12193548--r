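minimal_rnaml <- function(seq, pairs, helices = NULL, name = "toy") {
  bp <- paste(vapply(pairs, function(p) sprintf(
    "<base-pair><base-id-5p><base-id><position>%d</position></base-id></base-id-5p><base-id-3p><base-id><position>%d</position></base-id></base-id-3p></base-pair>",
    p[1], p[2]), character(1)), collapse = "")
  hx <- if (!is.null(helices)) {
    paste(vapply(helices, function(h) sprintf(
      "<helix><base-id-5p><base-id><position>%d</position></base-id></base-id-5p><base-id-3p><base-id><position>%d</position></base-id></base-id-3p><length>%d</length></helix>",
      h[1], h[2], h[3]), character(1)), collapse = "")
  } else ""
  sprintf(paste0(
    "<rnaml version=\"1.1\"><molecule id=\"1\"><identity><name>%s</name>",
    "</identity><sequence><seq-data>%s</seq-data></sequence><structure>",
    "<model id=\"1\"><str-annotation>%s%s</str-annotation></model>",
    "</structure></molecule></rnaml>"), name, seq, bp, hx)
}

test_that("canonical pair classification covers WCF and wobble pairs", {
  expect_true(is_canonical_pair("G", "U"))
  expect_true(is_canonical_pair("U", "A")) # order-independent
  expect_true(is_canonical_pair("g", "c"))
  expect_true(is_canonical_pair("A", "T")) # T treated as U
  expect_false(is_canonical_pair("C", "C"))
  expect_false(is_canonical_pair("G", "G"))
  expect_false(is_canonical_pair("A", "C"))
})

test_that("RNAML reading collects base-pair elements", {
  xml <- minimal_rnaml("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
  res <- read_rnaml(xml)
  expect_identical(res$structure$sequence, "GGGAAACCC")
  expect_identical(unname(res$structure$pairs), cbind(1:3, 9:7))
  expect_identical(res$structure$header, "toy")
  expect_equal(nrow(res$noncanonical), 0L)
})

test_that("non-canonical pairs are partitioned out, not kept", {
  xml <- minimal_rnaml("GGGAAACCC",
                       list(c(1, 9), c(2, 8), c(3, 7), c(4, 6)))
  res <- read_rnaml(xml)
  expect_identical(unname(res$structure$pairs), cbind(1:3, 9:7))
  expect_equal(nrow(res$noncanonical), 1L)
  expect_equal(res$noncanonical$five_idx, 4L)
  expect_identical(res$noncanonical$five_base, "A")
  expect_identical(res$noncanonical$three_base, "A")
  # partition property: canonical + non-canonical = all input pairs
  all_idx <- rbind(res$structure$pairs,
                   cbind(res$noncanonical$five_idx, res$noncanonical$three_idx))
  expect_equal(nrow(all_idx), 4L)
})

test_that("helix elements expand to stacked pairs", {
  xml <- minimal_rnaml("GGGAAACCC", list(), helices = list(c(1, 9, 3)))
  res <- read_rnaml(xml)
  expect_identical(unname(res$structure$pairs), cbind(1:3, 9:7))
})

test_that("pairing conflicts after filtering are strict errors", {
  xml <- minimal_rnaml("GGGAAACCC", list(c(1, 9), c(1, 8)))
  expect_error(read_rnaml(xml), "paired twice")
  # lenient: first-encountered pair wins
  res <- read_rnaml(xml, strict = FALSE)
  expect_identical(unname(res$structure$pairs), cbind(1L, 9L))
})

test_that("malformed input is rejected", {
  expect_error(read_rnaml("<rnaml><molecule>"), regexp = ".")
  expect_error(read_rnaml("<notrnaml/>"), "root element")
  expect_error(read_rnaml(minimal_rnaml("GGG", list(c(1, 9)))), "outside")
})

test_that("write then read is the identity on sequence and pairs", {
  for (seed in 1:20) {
    ss <- random_fixture(seed)
    res <- read_rnaml(write_rnaml(ss, "x"))
    expect_same_structure(res$structure, ss)
  }
  # crossing pairs survive the round trip
  pk <- rna_structure("GAAUCCUU", list(c(1, 5), c(3, 7)))
  back <- read_rnaml(write_rnaml(pk))$structure
  expect_true(is_pseudoknotted(back))
  # empty structure with sequence
  e <- rna_structure("ACGU")
  expect_identical(read_rnaml(write_rnaml(e))$structure$sequence, "ACGU")
})

test_that("non-canonical CSV is sorted with the documented header", {
  rec <- data.frame(five_idx = c(12L, 4L), three_idx = c(20L, 6L),
                    five_base = c("G", "A"), three_base = c("G", "A"))
  csv <- noncanonical_csv(rec, "toy")
  lines <- strsplit(csv, "\n")[[1]]
  expect_identical(lines[1], "molecule,position_5p,base_5p,position_3p,base_3p")
  expect_identical(lines[2], "toy,4,A,6,A")
  expect_identical(lines[3], "toy,12,G,20,G")
  expect_identical(noncanonical_csv(rec[0, ], "toy"),
                   "molecule,position_5p,base_5p,position_3p,base_3p\n")
})
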