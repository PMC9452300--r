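two_group_elements <- function(n1 = 10, n2 = 5) {
  # two well-separated synthetic conformations as element strings
  g1 <- strrep("s", 8)
  g2 <- strrep("h", 8)
  els <- c(rep(g1, n1), rep(g2, n2))
  names(els) <- sprintf("m%02d", seq_along(els))
  els
}

test_that("PCA embedding is deterministic with the sign convention fixed", {
  m <- element_matrix(two_group_elements())
  e1 <- embed_structures(m, d = 2)
  e2 <- embed_structures(m, d = 2)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(15L, 2L))
  # identical rows embed to coincident points
  expect_equal(max(dist(e1[1:10, ])), 0)
  # two groups are separated along PC1
  expect_gt(min(abs(e1[1:10, 1] - e1[11:15, 1])), 1)
  expect_error(embed_structures(m[1, , drop = FALSE]), "at least 2")
})

test_that("MDS embedding reproduces pairwise separation", {
  m <- element_matrix(two_group_elements())
  e <- embed_structures(m, method = "mds", d = 2)
  expect_identical(nrow(e), 15L)
  expect_gt(min(abs(e[1:10, 1] - e[11:15, 1])), 1)
})

test_that("clustering recovers sizes, orders labels by abundance", {
  m <- element_matrix(two_group_elements(70, 30))
  e <- embed_structures(m, d = 2)
  cl <- cluster_structures(e, k = 2, seed = 4)
  expect_identical(cl$proportions, c(0.7, 0.3))
  expect_true(all(cl$labels[1:70] == 1L))
  expect_true(all(cl$labels[71:100] == 2L))
  # determinism
  cl2 <- cluster_structures(e, k = 2, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  # k = 1 and error contracts
  expect_identical(cluster_structures(e, k = 1, seed = 1)$proportions, 1)
  expect_error(cluster_structures(e[1:3, ], k = 5, seed = 1), "exceeds")
})

test_that("cluster numbering is invariant to the k-means seed", {
  m <- element_matrix(two_group_elements(60, 40))
  e <- embed_structures(m, d = 2)
  l1 <- cluster_structures(e, k = 2, seed = 1)$labels
  l2 <- cluster_structures(e, k = 2, seed = 999)$labels
  expect_identical(l1, l2)
})

test_that("silhouette table flags the right k on ideal blobs", {
  set.seed(8)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  e2 <- rbind(blob(0, 0, 30), blob(5, 5, 30))
  tab <- suggest_k(e2, k_range = 2:5, seed = 3)
  expect_identical(tab$k[which.max(tab$silhouette)], 2L)
  expect_gt(max(tab$silhouette), 0.8)
  # single blob: every k >= 2 scores low
  tab1 <- suggest_k(blob(0, 0, 60), k_range = 2:4, seed = 3)
  expect_lt(max(tab1$silhouette), 0.6)
  # empty range
  expect_identical(nrow(suggest_k(e2, k_range = integer(0))), 0L)
})

test_that("representative selection is consensus-first, centroid-second", {
  els <- c(a = "sssshhhh", b = "sssshhhh", c = "sssshhht")
  dbs <- c("((..))..", "((..))..", "((..))..")
  coords <- rbind(c(0, 0), c(1, 0), c(0.1, 0))
  rep1 <- representative_structure(dbs, els, coords, names(els))
  expect_identical(rep1$consensus, "sssshhhh")
  expect_identical(rep1$read_id, "a")  # hamming tie with b, a nearer centroid?
  # two members tied on hamming: the one nearer the centroid wins
  els2 <- c(x = "ssshhh", y = "sstthh", z = "ssthhh")
  coords2 <- rbind(c(5, 0), c(0.4, 0), c(0.5, 0.01))
  # consensus = "ssthhh" (t wins position 3 by 2:1); z matches exactly
  rep2 <- representative_structure(c("d1", "d2", "d3"), els2, coords2,
                                   names(els2))
  expect_identical(rep2$read_id, "z")
  expect_identical(rep2$hamming, 0L)
  # identical cluster: hamming 0, first read id
  rep3 <- representative_structure(c("d", "d"), c(m2 = "ss", m1 = "ss"),
                                   rbind(c(0, 0), c(0, 0)), c("m2", "m1"))
  expect_identical(rep3$read_id, "m1")
  expect_identical(rep3$hamming, 0L)
})

test_that("full landscape recovers a constructed two-conformation mixture", {
  dbs <- c(rep("((((....))))....", 14), rep("....((((....))))", 6))
  ids <- sprintf("m%02d", 1:20)
  land <- conformation_landscape(data.frame(read_id = ids, db = dbs),
                                 k = 2, seed = 2)
  expect_equal(land$molecule_proportions, c(0.7, 0.3))
  expect_identical(land$representatives[[1]]$db, dbs[1])
  expect_identical(land$representatives[[2]]$db, dbs[20])
  expect_identical(land$consensus_elements[1], to_elements(dbs[1]))
  # per-molecule fractions: a molecule with two samples in different
  # clusters contributes half to each
  dbs2 <- c(dbs, "((((....))))....", "....((((....))))")
  ids2 <- c(ids, "extra", "extra")
  land2 <- conformation_landscape(data.frame(read_id = ids2, db = dbs2),
                                  k = 2, seed = 2)
  expect_equal(land2$molecule_proportions,
               c((14 + 0.5) / 21, (6 + 0.5) / 21))
})

test_that("landscape artifacts are written with stable names", {
  dbs <- c(rep("((((....))))....", 7), rep("....((((....))))", 3))
  land <- conformation_landscape(dbs, k = 2, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_landscape(land, dir)
  expect_true(all(file.exists(paths)))
  emb <- read.csv(file.path(dir, "landscape_embedding.csv"))
  expect_identical(nrow(emb), 10L)
  props <- jsonlite::read_json(file.path(dir, "landscape_proportions.json"),
                               simplifyVector = TRUE)
  expect_equal(sum(props$proportions), 1, tolerance = 1e-9)
})
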