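# reference with a homopolymer run at positions 7-10 (AAAA)
REF20 <- c(ref = "GCGCGTAAAAGTCGTACGTC")

test_that("perfect, substituted and clipped reads code as expected", {
  path <- withr::local_tempfile(fileext = ".sam")
  refseq <- unname(REF20)
  sub5 <- refseq
  substr(sub5, 5, 5) <- "A"  # G -> A substitution at position 5
  write_test_sam(path, "ref", 20L, c(
    sam_record("perfect", "ref", 1L, "20M", refseq),
    sam_record("sub5", "ref", 1L, "20M", sub5),
    sam_record("clipped", "ref", 2L, "1S19M",
               paste0("T", substr(refseq, 2, 20)))))
  bv <- extract_bitvectors(path, REF20, min_coverage = 0.9)
  expect_identical(bv$read_id, c("perfect", "sub5", "clipped"))
  expect_true(all(bv$codes["perfect" == bv$read_id, ] == 0L))
  sub_codes <- bv$codes[bv$read_id == "sub5", ]
  expect_identical(which(sub_codes == 1L), 5L)
  expect_identical(sum(sub_codes), 1L)
  # soft-clipped read: position 1 masked, rest matches
  cl <- bv$codes[bv$read_id == "clipped", ]
  expect_true(is.na(cl[1]))
  expect_true(all(cl[-1] == 0L))
  # partition invariant: every position carries exactly one code
  counts <- apply(bv$codes, 1, function(r)
    sum(r == 0L, na.rm = TRUE) + sum(r == 1L, na.rm = TRUE) + sum(is.na(r)))
  expect_true(all(counts == 20L))
})

test_that("a deletion inside a homopolymer run masks the whole run", {
  path <- withr::local_tempfile(fileext = ".sam")
  refseq <- unname(REF20)
  # delete one A from the AAAA run (positions 7-10): read has 19 bases
  readseq <- paste0(substr(refseq, 1, 7), substr(refseq, 9, 20))
  write_test_sam(path, "ref", 20L, c(
    sam_record("delA", "ref", 1L, "7M1D12M", readseq)))
  bv <- extract_bitvectors(path, REF20, min_coverage = 0.9)
  codes <- bv$codes[1, ]
  expect_true(all(is.na(codes[7:10])))
  expect_true(all(codes[-(7:10)] == 0L))
})

test_that("an unambiguous deletion codes 1 at the deleted position", {
  path <- withr::local_tempfile(fileext = ".sam")
  refseq <- unname(REF20)
  # delete position 6 (T, neighbours G and A: no homopolymer)
  readseq <- paste0(substr(refseq, 1, 5), substr(refseq, 7, 20))
  write_test_sam(path, "ref", 20L, c(
    sam_record("delT", "ref", 1L, "5M1D14M", readseq)))
  bv <- extract_bitvectors(path, REF20, min_coverage = 0.9)
  codes <- bv$codes[1, ]
  expect_identical(which(codes == 1L), 6L)
})

test_that("secondary, unmapped, short and foreign-reference reads are dropped", {
  path <- withr::local_tempfile(fileext = ".sam")
  refseq <- unname(REF20)
  write_test_sam(path, "ref", 20L, c(
    sam_record("good", "ref", 1L, "20M", refseq),
    sam_record("secondary", "ref", 1L, "20M", refseq, flag = 256L),
    sam_record("short", "ref", 1L, "10M10S",
               paste0(substr(refseq, 1, 10), "AAAAAAAAAA")),
    sam_record("unmapped", "*", 0L, "*", refseq, flag = 4L)))
  expect_silent(bv <- extract_bitvectors(path, REF20, min_coverage = 0.9))
  expect_identical(bv$read_id, "good")
  # a read aligned to a different reference is skipped with a warning
  path_foreign <- withr::local_tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:ref\tLN:20", "@SQ\tSN:other\tLN:20")
  writeLines(c(header,
               sam_record("good", "ref", 1L, "20M", refseq),
               sam_record("stray", "other", 1L, "20M", refseq)),
             path_foreign)
  expect_warning(bvf <- extract_bitvectors(path_foreign, REF20),
                 "different reference")
  expect_identical(bvf$read_id, "good")
  # insertions do not occupy reference positions but are counted
  path2 <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(path2, "ref", 20L, c(
    sam_record("ins", "ref", 1L, "10M2I10M",
               paste0(substr(refseq, 1, 10), "TT", substr(refseq, 11, 20)))))
  bv2 <- extract_bitvectors(path2, REF20)
  expect_true(all(bv2$codes[1, ] == 0L))
  expect_identical(bv2$n_insertions, 2L)
})

test_that("extraction is deterministic and bit-vector tables round-trip", {
  toy <- toy_threeway()
  cfg <- simulation_config(toy$sequence, toy$conformations, c(0.7, 0.2, 0.1),
                           n_molecules = 30L, seed = 7L)
  sim <- simulate_probing(cfg)
  path <- withr::local_tempfile(fileext = ".sam")
  emit_sam(sim$plus, toy$sequence, path)
  bv1 <- extract_bitvectors(path, c(ref = toy$sequence))
  bv2 <- extract_bitvectors(path, c(ref = toy$sequence))
  expect_identical(bv1$codes, bv2$codes)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bitvectors(bv1, tsv)
  back <- read_bitvectors(tsv)
  expect_identical(back$codes, unname(bv1$codes))
  expect_identical(back$read_id, bv1$read_id)
})

test_that("optional base-quality masking hides low-quality calls", {
  path <- withr::local_tempfile(fileext = ".sam")
  refseq <- unname(REF20)
  qual <- paste(rep("I", 20), collapse = "")   # Q40 everywhere
  substr(qual, 5, 5) <- "#"                    # Q2 at position 5
  write_test_sam(path, "ref", 20L, c(
    sam_record("q", "ref", 1L, "20M", refseq, qual = qual)))
  bv <- extract_bitvectors(path, REF20, min_base_quality = 10)
  expect_true(is.na(bv$codes[1, 5]))
  expect_true(all(bv$codes[1, -5] == 0L))
  # default: no quality filter
  bv0 <- extract_bitvectors(path, REF20)
  expect_true(all(bv0$codes[1, ] == 0L))
})

test_that("isoform assignment maximises score with lexicographic ties", {
  expect_identical(assign_isoform(c(II.i = 540, II.ii = 310)), "II.i")
  expect_identical(assign_isoform(c(II.ii = 400, II.i = 400)), "II.i")
  expect_identical(assign_isoform(numeric(0)), NA_character_)
  expect_identical(assign_isoform(c(a = NA_real_)), NA_character_)
})
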