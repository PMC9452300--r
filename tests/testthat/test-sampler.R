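test_that("inside totals equal brute-force enumeration on short sequences", {
  g <- scfg_grammar()
  for (s in sampler_fixtures()) {
    structs <- enum_structures(s, g$min_hairpin)
    w <- vapply(structs, oracle_weight, numeric(1), seq = s, grammar = g)
    expect_equal(inside_partition(s, g), log(sum(w)), tolerance = 1e-10,
                 label = sprintf("logZ(%s)", s))
  }
})

test_that("degenerate sequences admit only the open chain", {
  expect_equal(inside_partition("AAAA"), 0)  # log(q_u^4) with q_u = 1
  expect_identical(unique(sample_structures("AAAA", n_samples = 10, seed = 3)),
                   "....")
  # full constraint collapses any sequence to the open chain
  L <- 12L
  cons <- rep(TRUE, L)
  expect_equal(inside_partition("GGGGAAAACCCC", constraints = cons), 0)
  expect_identical(unique(sample_structures("GGGGAAAACCCC",
                                            constraints = cons,
                                            n_samples = 5, seed = 1)),
                   strrep(".", L))
})

test_that("force_unpaired constraints are honoured in every sample", {
  seqs <- c("GGGGAAAACCCC", "GCAGCAAACUGCAA", "CCGGAAAAUUGG")
  for (s in seqs) {
    L <- nchar(s)
    for (trial in 1:5) {
      cons <- (seq_len(L) * 7L + trial) %% 4L == 0L  # deterministic pattern
      draws <- sample_structures(s, constraints = cons,
                                 n_samples = 200, seed = trial)
      mat <- do.call(rbind, strsplit(draws, ""))
      expect_identical(sum(mat[, cons] != "."), 0L,
                       label = sprintf("violations for %s trial %d", s, trial))
    }
  }
})

test_that("identical seeds reproduce identical structure streams", {
  s <- "GCAGCAAACUGCAA"
  a <- sample_structures(s, n_samples = 50, seed = 42)
  b <- sample_structures(s, n_samples = 50, seed = 42)
  expect_identical(a, b)
  c <- sample_structures(s, n_samples = 50, seed = 43)
  expect_false(identical(a, c))
})

test_that("empirical frequencies track exact probabilities on a 12-mer", {
  s <- "GGGGAAAACCCC"
  p <- oracle_distribution(s)
  draws <- sample_structures(s, n_samples = 20000, seed = 7)
  expect_true(all(draws %in% names(p)))
  emp <- table(factor(draws, levels = names(p))) / length(draws)
  tv <- 0.5 * sum(abs(as.numeric(emp) - p))
  expect_lt(tv, 0.03)
})

test_that("destroying the only helix zeroes its pairing frequency", {
  g <- scfg_grammar()
  s1 <- "GGGGGGGAAAACCCCCCC"
  s2 <- "GGGGGGGAAAAGGGGGGG"   # mutation removes all canonical partners
  d1 <- in_silico_ensemble(s1, g, n_samples = 2000, seed = 2)
  d2 <- in_silico_ensemble(s2, g, n_samples = 2000, seed = 2)
  frac_paired <- function(draws) mean(vapply(draws, function(db)
    nrow(db_to_pairs(db)) > 0, logical(1)))
  expect_gt(frac_paired(d1), 0.5)
  expect_identical(frac_paired(d2), 0)
})

test_that("per-molecule sampling tags reads and respects its constraints", {
  toy <- toy_threeway()
  cfg <- simulation_config(toy$sequence, toy$conformations, c(0.7, 0.2, 0.1),
                           n_molecules = 25L, seed = 13L)
  sim <- simulate_probing(cfg)
  tab <- sample_per_molecule(sim$plus, toy$sequence, seed = 99L)
  expect_identical(nrow(tab), 25L)
  expect_identical(tab$read_id, sim$plus$read_id)
  for (m in seq_len(25L)) {
    forced <- constraints_from_codes(sim$plus$codes[m, ])
    chars <- strsplit(tab$db[m], "")[[1]]
    expect_true(all(chars[forced] == "."))
  }
  # order-independence: a molecule's structure only depends on the root
  # seed and its own index in the seed stream
  tab3 <- sample_per_molecule(sim$plus, toy$sequence, seed = 99L,
                              samples_per_molecule = 2L)
  expect_identical(nrow(tab3), 50L)
  # all-ones bit vector folds to the open chain
  bv1 <- bitvector_set("ref", "allmod", "plus",
                       matrix(1L, 1, nchar(toy$sequence)))
  t1 <- sample_per_molecule(bv1, toy$sequence, seed = 1L)
  expect_identical(t1$db, strrep(".", nchar(toy$sequence)))
})

test_that("unconstrained ensembles are byte-identical across reruns", {
  s <- "GGGGAAAACCCC"
  expect_identical(in_silico_ensemble(s, n_samples = 500, seed = 10),
                   in_silico_ensemble(s, n_samples = 500, seed = 10))
})
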