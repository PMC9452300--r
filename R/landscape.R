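#' Embed an element matrix in low dimension
#'
#' PCA (default) or classical MDS of the one-hot element matrix. The PCA
#' sign convention is fixed so that the loading with the largest magnitude
#' on each component is positive, making the embedding fully
#' deterministic.
#'
#' @param matrix numeric matrix, rows = structures (see
#'   [element_matrix()]).
#' @param method `"pca"` or `"mds"`.
#' @param d number of output dimensions (default 2; truncated to the
#'   available rank).
#' @return An `n x d` coordinate matrix with columns `PC1..PCd` (or
#'   `MDS1..`), row names preserved.
#' @export
embed_structures <- function(matrix, method = c("pca", "mds"), d = 2L) {
  method <- match.arg(method)
  n <- nrow(matrix)
  if (n < 2L) .stopf("need at least 2 structures to embed (got %d)", n)
  d <- min(as.integer(d), n - 1L, ncol(matrix))
  if (method == "pca") {
    p <- prcomp(matrix, center = TRUE, scale. = FALSE)
    d <- min(d, ncol(p$rotation))
    scores <- p$x[, seq_len(d), drop = FALSE]
    for (c in seq_len(d)) {
      load <- p$rotation[, c]
      if (load[which.max(abs(load))] < 0) scores[, c] <- -scores[, c]
    }
    colnames(scores) <- paste0("PC", seq_len(d))
  } else {
    scores <- cmdscale(dist(matrix), k = d)
    # classical MDS axes share PCA's sign indeterminacy; anchor each axis
    # so its largest-magnitude coordinate is positive
    for (c in seq_len(ncol(scores))) {
      if (scores[which.max(abs(scores[, c])), c] < 0)
        scores[, c] <- -scores[, c]
    }
    colnames(scores) <- paste0("MDS", seq_len(ncol(scores)))
  }
  rownames(scores) <- rownames(matrix)
  scores
}

#' Cluster embedded structures into conformations
#'
#' k-means (Hartigan-Wong, 10 random restarts, fixed seed) on the
#' embedding. Clusters are relabelled in decreasing order of abundance, so
#' cluster 1 is always the most populated conformation, independent of the
#' k-means initialisation.
#'
#' @param embedding coordinate matrix from [embed_structures()].
#' @param k number of conformations.
#' @param seed integer seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return A list with `labels` (integer per structure), `proportions`
#'   (decreasing, summing to 1) and `centers`.
#' @export
cluster_structures <- function(embedding, k, seed = 1L, nstart = 10L) {
  n <- nrow(embedding)
  if (!.is_count(k) || k < 1L) .stopf("k must be a positive integer")
  if (k > n) .stopf("k = %d exceeds the number of structures (%d)", k, n)
  km <- withr::with_seed(as.integer(seed),
                         kmeans(embedding, centers = k, nstart = nstart,
                                iter.max = 100L))
  labels <- km$cluster
  sizes <- tabulate(labels, nbins = k)
  # decreasing abundance; ties broken by original label for determinism
  remap <- integer(k)
  remap[order(-sizes, seq_len(k))] <- seq_len(k)
  labels <- remap[labels]
  centers <- km$centers[order(-sizes, seq_len(k)), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(labels = labels,
       proportions = tabulate(labels, nbins = k) / n,
       centers = centers)
}

#' Cluster-number diagnostics
#'
#' The number of conformations is a judgement call; this table makes it
#' auditable by reporting the mean silhouette width and the total
#' within-cluster sum of squares for each candidate `k`. No automatic
#' selection is made.
#'
#' @inheritParams cluster_structures
#' @param k_range integer vector of candidate `k` (each in `[2, n - 1]`).
#' @return A data.frame with columns `k`, `silhouette`, `inertia`.
#' @export
suggest_k <- function(embedding, k_range = 2:6, seed = 1L, nstart = 10L) {
  k_range <- as.integer(k_range)
  if (length(k_range) == 0L)
    return(data.frame(k = integer(0), silhouette = numeric(0),
                      inertia = numeric(0)))
  n <- nrow(embedding)
  if (any(k_range < 2L) || any(k_range > n - 1L))
    .stopf("k_range must lie within [2, n - 1]")
  dd <- dist(embedding)
  rows <- lapply(k_range, function(k) {
    km <- withr::with_seed(as.integer(seed),
                           kmeans(embedding, centers = k, nstart = nstart,
                                  iter.max = 100L))
    sil <- cluster::silhouette(km$cluster, dd)
    data.frame(k = k, silhouette = mean(sil[, "sil_width"]),
               inertia = km$tot.withinss)
  })
  do.call(rbind, rows)
}

#' Positionwise consensus element string of a set of structures
#'
#' The most common element at each position; ties are broken by the fixed
#' element order `f < t < s < h < i < m`.
#'
#' @param element_strings equal-length element strings.
#' @return A single element string.
#' @export
consensus_elements <- function(element_strings) {
  chars <- matrix(unlist(strsplit(element_strings, "")),
                  nrow = length(element_strings), byrow = TRUE)
  cons <- apply(chars, 2L, function(col) {
    counts <- tabulate(match(col, .ELEMENTS), nbins = 6L)
    .ELEMENTS[which.max(counts)]  # which.max takes the first = fixed order
  })
  paste(cons, collapse = "")
}

#' Representative structure of one cluster
#'
#' Per-cluster consensus-first selection: the positionwise most common
#' element string is the cluster's maximum-expected-accuracy object; the
#' member structure closest to it in Hamming distance is returned, with
#' ties broken by Euclidean distance to the cluster centroid in the
#' embedding and finally by read id.
#'
#' @param dbs dot-bracket strings of the cluster members.
#' @param element_strings their element strings.
#' @param coords their embedding coordinates (matrix, same order).
#' @param read_ids member identifiers.
#' @return A list with `read_id`, `db`, `consensus`, `hamming`.
#' @export
representative_structure <- function(dbs, element_strings, coords, read_ids) {
  stopifnot(length(dbs) >= 1L, length(dbs) == length(element_strings),
            length(dbs) == nrow(coords), length(dbs) == length(read_ids))
  cons <- consensus_elements(element_strings)
  cons_chars <- strsplit(cons, "")[[1]]
  hamming <- unname(vapply(strsplit(element_strings, ""),
                           function(ch) sum(ch != cons_chars), integer(1)))
  centroid <- colMeans(coords)
  cdist <- sqrt(colSums((t(coords) - centroid)^2))
  ord <- order(hamming, cdist, read_ids)
  best <- ord[1L]
  list(read_id = read_ids[best], db = dbs[best], consensus = cons,
       hamming = hamming[best])
}

#' Build the conformational landscape of a structure collection
#'
#' End-to-end landscape stage: element encoding, embedding, k-means
#' clustering, abundance-ordered cluster proportions, per-cluster
#' consensus element strings and representative structures. When several
#' structures were sampled per molecule, proportions are computed over
#' molecules: each molecule contributes its per-cluster sample fractions,
#' so the reported proportions are population fractions of molecules, not
#' of samples.
#'
#' @param structures data.frame with columns `read_id` and `db` (as
#'   returned by [sample_per_molecule()]), or a character vector of
#'   dot-bracket strings (then each structure is its own molecule).
#' @param k number of conformations.
#' @param method,d embedding method and dimension (see
#'   [embed_structures()]).
#' @param seed integer seed for clustering.
#' @param nstart k-means restarts.
#' @param cluster_on `"embedding"` (default) or `"matrix"` to cluster the
#'   full one-hot matrix instead of the embedded coordinates.
#' @param encoding element-matrix encoding.
#' @return An object of class `conformation_landscape`: list with
#'   `embedding`, `method`, `labels`, `k`, `proportions`,
#'   `molecule_proportions`, `representatives`, `consensus_elements`,
#'   `structures` (input table with a `cluster` column), `elements`.
#' @export
conformation_landscape <- function(structures, k, method = "pca", d = 2L,
                                   seed = 1L, nstart = 10L,
                                   cluster_on = c("embedding", "matrix"),
                                   encoding = "onehot") {
  cluster_on <- match.arg(cluster_on)
  if (is.character(structures))
    structures <- data.frame(read_id = as.character(seq_along(structures)),
                             db = structures, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "db") %in% names(structures)))
  n <- nrow(structures)
  elems <- vapply(structures$db, to_elements, character(1), USE.NAMES = FALSE)
  names(elems) <- structures$read_id
  mat <- element_matrix(elems, encoding = encoding)
  emb <- embed_structures(mat, method = method, d = d)
  cl <- cluster_structures(if (cluster_on == "embedding") emb else mat,
                           k = k, seed = seed, nstart = nstart)
  labels <- cl$labels

  # molecule-level proportions: each molecule contributes its own sample
  # fractions (identical to label frequencies when one sample/molecule)
  mol_frac <- rowsum(outer(labels, seq_len(k), "==") + 0,
                     group = structures$read_id)
  mol_frac <- mol_frac / rowSums(mol_frac)
  mol_prop <- colMeans(mol_frac)

  # relabel by decreasing molecule-level abundance
  remap <- integer(k)
  remap[order(-mol_prop, seq_len(k))] <- seq_len(k)
  labels <- remap[labels]
  mol_prop <- sort(mol_prop, decreasing = TRUE)
  names(mol_prop) <- seq_len(k)

  reps <- vector("list", k)
  cons <- character(k)
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    reps[[c]] <- representative_structure(structures$db[idx], elems[idx],
                                          emb[idx, , drop = FALSE],
                                          structures$read_id[idx])
    cons[c] <- reps[[c]]$consensus
  }
  structures$cluster <- labels
  structure(list(embedding = emb, method = method, labels = labels, k = k,
                 proportions = unname(tabulate(labels, nbins = k) / n),
                 molecule_proportions = unname(mol_prop),
                 representatives = reps, consensus_elements = cons,
                 structures = structures, elements = elems),
            class = "conformation_landscape")
}

#' @export
print.conformation_landscape <- function(x, ...) {
  cat(sprintf("conformation_landscape: %d structures, k = %d (%s)\n",
              length(x$labels), x$k, x$method))
  cat("  molecule proportions:",
      paste(sprintf("%.1f%%", 100 * x$molecule_proportions),
            collapse = " / "), "\n")
  invisible(x)
}

#' Write landscape artifacts
#'
#' Writes the embedding (CSV with read id, coordinates and cluster), the
#' proportions (JSON) and the representative structures (dot-bracket
#' file).
#'
#' @param landscape a [conformation_landscape()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_landscape <- function(landscape, dir, prefix = "landscape") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_embedding.csv"))
  df <- data.frame(read_id = landscape$structures$read_id,
                   landscape$embedding,
                   cluster = landscape$labels)
  utils::write.csv(df, p1, row.names = FALSE, quote = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_proportions.json"))
  jsonlite::write_json(list(k = landscape$k,
                            proportions = landscape$molecule_proportions),
                       p2, auto_unbox = TRUE, digits = NA)
  p3 <- file.path(dir, paste0(prefix, "_representatives.dbn"))
  reps <- vapply(landscape$representatives, `[[`, character(1), "db")
  names(reps) <- sprintf("conformation_%d|%s", seq_along(reps),
                         vapply(landscape$representatives, `[[`,
                                character(1), "read_id"))
  write_dotbracket(reps, p3)
  p4 <- file.path(dir, paste0(prefix, "_consensus_elements.tsv"))
  write.table(data.frame(cluster = seq_len(landscape$k),
                         consensus = landscape$consensus_elements),
              p4, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
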