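mk_bv <- function(codes, channel = "plus")
  bitvector_set("ref", sprintf("r%d", seq_len(nrow(codes))), channel, codes)

test_that("mutation rates exclude masked codes from the denominator", {
  codes <- rbind(c(0L, 1L, NA), c(0L, 0L, NA), c(0L, NA, NA), c(0L, 1L, NA))
  mr <- mutation_rates(mk_bv(codes))
  expect_equal(mr$rate[1], 0)
  expect_equal(mr$rate[2], 2 / 3)       # MASK dropped from denominator
  expect_true(is.na(mr$rate[3]))        # all masked -> undefined, not 0
  expect_identical(mr$coverage, c(4L, 3L, 0L))
})

test_that("raw reactivity matches the positive-likelihood-ratio formula", {
  expect_equal(raw_reactivity(0.08, 0), 0.08)
  expect_equal(raw_reactivity(0.08, 0.02), 0.06 / 0.98)
  expect_equal(raw_reactivity(0.05, 0.05), 0)
  expect_equal(raw_reactivity(0.01, 0.03), 0)   # clamped at 0
  expect_true(is.na(raw_reactivity(0.5, 1)))    # undefined denominator
  # pure function of rates: independent of how many reads produced them
  expect_equal(raw_reactivity(0.2, 0.1), raw_reactivity(0.2, 0.1))
})

test_that("2%/8% normalization matches its defining example", {
  raw <- as.numeric(1:100)
  norm <- normalize_reactivity(raw)
  # divisor = mean(91..98) = 94.5
  expect_equal(norm, raw / 94.5)
  expect_equal(norm[which(raw == 94.5)], numeric(0))  # no exact 94.5 input
  # flat profile normalizes to all ones
  expect_equal(normalize_reactivity(rep(2.5, 30)), rep(1, 30))
  # undefined entries pass through
  raw2 <- c(raw, NA, NA)
  norm2 <- normalize_reactivity(raw2)
  expect_true(all(is.na(norm2[101:102])))
  expect_equal(norm2[1:100], norm[1:100])
  expect_error(normalize_reactivity(c(1, 2, 3)), "too few")
})

test_that("replicate correlation behaves at the degenerate extremes", {
  x <- c(0.1, 0.5, 0.9, 0.2, 0.7)
  expect_equal(replicate_correlation(x, x)$r, 1)
  expect_equal(replicate_correlation(x, -x + 2 * mean(x))$r, -1)
  expect_message(res <- replicate_correlation(c(1, NA, NA), c(1, NA, NA)),
                 "fewer than 3")
  expect_true(is.na(res$r))
})

test_that("specificity identity: 1 - MR(-) equals the fraction of zeros", {
  set.seed(11)
  codes <- matrix(rbinom(400, 1L, 0.1), 40, 10)
  codes[sample(400, 60)] <- NA
  bv <- mk_bv(codes, "minus")
  mr <- mutation_rates(bv)
  for (p in 1:10) {
    col <- codes[, p]
    informative <- col[!is.na(col)]
    if (length(informative) == 0) next
    expect_equal(1 - mr$rate[p], mean(informative == 0L))
  }
})

test_that("simulated unpaired positions score higher normalized reactivity", {
  toy <- toy_threeway()
  cfg <- simulation_config(toy$sequence, toy$conformations[1], 1,
                           n_molecules = 400L, seed = 5L)
  sim <- simulate_probing(cfg)
  prof <- reactivity_profile(sim$plus, sim$minus, sequence = toy$sequence)
  paired <- strsplit(toy$conformations[[1]], "")[[1]] != "."
  expect_gt(mean(prof$normalized[!paired], na.rm = TRUE),
            mean(prof$normalized[paired], na.rm = TRUE))
  expect_identical(attr(prof, "reference_id"), "ref")
})

test_that("two replicate simulations correlate strongly", {
  toy <- toy_threeway()
  mk <- function(seed) {
    cfg <- simulation_config(toy$sequence, toy$conformations, c(0.7, 0.2, 0.1),
                             n_molecules = 2000L, seed = seed)
    sim <- simulate_probing(cfg)
    reactivity_profile(sim$plus, sim$minus, normalize = FALSE)
  }
  a <- mk(101L)
  b <- mk(202L)
  res <- replicate_correlation(a, b, value = "raw")
  expect_gt(res$r, 0.9)
  expect_gte(res$n, 100L)
})

test_that("reactivity export encodes undefined values as -999", {
  toy <- toy_threeway()
  cfg <- simulation_config(toy$sequence, toy$conformations, c(0.7, 0.2, 0.1),
                           n_molecules = 50L, seed = 9L)
  sim <- simulate_probing(cfg)
  prof <- reactivity_profile(sim$plus, sim$minus, sequence = toy$sequence)
  prof$raw[3] <- NA
  prof$normalized[3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reactivity(prof, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$raw[3], -999)
  expect_equal(tab$normalized[3], -999)
})
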