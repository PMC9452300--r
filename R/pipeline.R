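#' Read reference sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("reference FASTA not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences))), path)
  invisible(path)
}

.default_config <- function() {
  list(
    out_dir = "foldscape_out",
    seed = 1L,
    paths = list(reference = NULL, alignments_plus = NULL,
                 alignments_minus = NULL, grammar = NULL),
    bitvector = list(min_coverage = 0.9, min_base_quality = NULL),
    reactivity = list(normalization = "percentile", min_defined = 20L,
                      low_confidence_coverage = 50L),
    sampler = list(samples_per_molecule = 1L),
    landscape = list(method = "pca", d = 2L, k = 3L, nstart = 10L,
                     cluster_on = "embedding"),
    simulation = list(toy = TRUE, sequence = NULL, conformations = NULL,
                      weights = c(0.7, 0.2, 0.1), n_molecules = 1000L,
                      p_unpaired_mod = 0.06, p_paired_mod = 0.005,
                      p_background = 0.002)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills unset fields with package
#' defaults and validates the schema. Unknown top-level fields are
#' rejected so typos fail loudly.
#'
#' @param config path to a YAML file, a list, or `NULL` for defaults.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "pipeline_config")) return(config)
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    .stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, config)
  if (!.is_count(merged$seed)) .stopf("config field 'seed' must be an integer")
  if (!merged$landscape$method %in% c("pca", "mds"))
    .stopf("config field 'landscape$method' must be 'pca' or 'mds'")
  if (!.is_count(merged$landscape$k) || merged$landscape$k < 1)
    .stopf("config field 'landscape$k' must be a positive integer")
  class(merged) <- "pipeline_config"
  merged
}

.resolve_grammar <- function(config) {
  if (!is.null(config$paths$grammar)) read_grammar(config$paths$grammar)
  else scfg_grammar()
}

.log_run <- function(config, stage, inputs = character(0)) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(config$out_dir, "config_resolved.yaml"))
  sums <- if (length(inputs)) tools::md5sum(inputs[file.exists(inputs)])
          else character(0)
  lines <- c(sprintf("stage: %s", stage),
             sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("foldscape: %s",
                     as.character(utils::packageVersion("foldscape"))),
             sprintf("R: %s", R.version.string),
             sprintf("seed: %d", config$seed),
             sprintf("input %s md5 %s", names(sums), unname(sums)))
  cat(lines, file = file.path(config$out_dir, "run_log.txt"),
      sep = "\n", append = TRUE)
}

#' Run one pipeline stage
#'
#' Command-line style orchestration over the package's functions. Stages
#' write plain-text artifacts with stable names under `config$out_dir` and
#' append to a run log recording versions, seeds and input checksums.
#' `"all"` chains `bitvec`, `reactivity`, `sample`, `landscape` and
#' `stats`. The root seed in the config governs every stochastic stage.
#'
#' @param name one of `"simulate"`, `"bitvec"`, `"reactivity"`,
#'   `"sample"`, `"landscape"`, `"stats"`, `"compare"`, `"all"`.
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @param ... stage-specific arguments: `compare` takes `predicted` and
#'   `reference` dot-bracket file paths.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_subcommand <- function(name = c("simulate", "bitvec", "reactivity",
                                    "sample", "landscape", "stats",
                                    "compare", "all"),
                           config = NULL, ...) {
  name <- match.arg(name)
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  switch(name,
    simulate = .stage_simulate(config),
    bitvec = .stage_bitvec(config),
    reactivity = .stage_reactivity(config),
    sample = .stage_sample(config),
    landscape = .stage_landscape(config),
    stats = .stage_stats(config),
    compare = .stage_compare(config, ...),
    all = {
      a <- .stage_bitvec(config)
      b <- .stage_reactivity(config)
      c <- .stage_sample(config)
      d <- .stage_landscape(config)
      e <- .stage_stats(config)
      invisible(c(a, b, c, d, e))
    })
}

.stage_simulate <- function(config) {
  sim <- config$simulation
  if (isTRUE(sim$toy)) {
    toy <- toy_threeway()
    sequence <- toy$sequence
    conformations <- toy$conformations
  } else {
    sequence <- sim$sequence
    conformations <- unlist(sim$conformations)
    if (is.null(sequence) || is.null(conformations))
      .stopf("simulation block needs 'sequence' and 'conformations' (or toy: true)")
  }
  sc <- simulation_config(sequence, conformations,
                          weights = unlist(sim$weights),
                          n_molecules = sim$n_molecules,
                          p_unpaired_mod = sim$p_unpaired_mod,
                          p_paired_mod = sim$p_paired_mod,
                          p_background = sim$p_background,
                          seed = config$seed)
  res <- simulate_probing(sc)
  out <- config$out_dir
  paths <- c(
    reference = file.path(out, "reference.fasta"),
    plus = file.path(out, "bitvectors_plus.tsv"),
    minus = file.path(out, "bitvectors_minus.tsv"),
    truth = file.path(out, "truth.csv"),
    sam_plus = file.path(out, "simulated_plus.sam"))
  write_fasta(c(ref = sequence), paths["reference"])
  write_bitvectors(res$plus, paths["plus"])
  write_bitvectors(res$minus, paths["minus"])
  utils::write.csv(res$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  emit_sam(res$plus, sequence, paths["sam_plus"])
  .log_run(config, "simulate")
  invisible(as.list(paths))
}

.reference_from_config <- function(config) {
  path <- config$paths$reference
  if (is.null(path)) path <- file.path(config$out_dir, "reference.fasta")
  if (!file.exists(path)) .stopf("missing reference FASTA: %s", path)
  refs <- read_fasta(path)
  refs[1L]
}

.stage_bitvec <- function(config) {
  ref <- .reference_from_config(config)
  out <- config$out_dir
  paths <- character(0)
  for (ch in c("plus", "minus")) {
    aln <- config$paths[[paste0("alignments_", ch)]]
    if (is.null(aln)) next
    if (!file.exists(aln)) .stopf("missing alignment file: %s", aln)
    bv <- extract_bitvectors(aln, ref, channel = ch,
                             min_coverage = config$bitvector$min_coverage,
                             min_base_quality = config$bitvector$min_base_quality)
    if (nrow(bv$codes) == 0L)
      .warnf("no usable %s-channel reads; writing an empty table", ch)
    p <- file.path(out, sprintf("bitvectors_%s.tsv", ch))
    write_bitvectors(bv, p)
    paths[ch] <- p
  }
  if (!length(paths)) .stopf("no alignment inputs configured")
  .log_run(config, "bitvec", unlist(config$paths))
  invisible(as.list(paths))
}

.stage_reactivity <- function(config) {
  out <- config$out_dir
  pp <- file.path(out, "bitvectors_plus.tsv")
  pm <- file.path(out, "bitvectors_minus.tsv")
  if (!file.exists(pp)) .stopf("missing bit-vector table: %s", pp)
  if (!file.exists(pm)) .stopf("missing bit-vector table: %s", pm)
  ref <- tryCatch(.reference_from_config(config), error = function(e) NULL)
  prof <- reactivity_profile(read_bitvectors(pp), read_bitvectors(pm),
                             sequence = unname(ref),
                             method = config$reactivity$normalization,
                             min_defined = config$reactivity$min_defined,
                             low_confidence_coverage =
                               config$reactivity$low_confidence_coverage)
  paths <- c(map = file.path(out, "reactivity_map.tsv"),
             shape = file.path(out, "reactivity.shape"))
  write_reactivity(prof, paths["map"], dialect = "map")
  write_reactivity(prof, paths["shape"], dialect = "shape")
  .log_run(config, "reactivity", c(pp, pm))
  invisible(as.list(paths))
}

.stage_sample <- function(config) {
  out <- config$out_dir
  pp <- file.path(out, "bitvectors_plus.tsv")
  if (!file.exists(pp)) .stopf("missing bit-vector table: %s", pp)
  ref <- .reference_from_config(config)
  bv <- read_bitvectors(pp)
  tab <- sample_per_molecule(bv, unname(ref), .resolve_grammar(config),
                             samples_per_molecule =
                               config$sampler$samples_per_molecule,
                             seed = config$seed)
  p <- file.path(out, "structures.dbn")
  dbs <- tab$db
  names(dbs) <- sprintf("%s/%d", tab$read_id, tab$sample)
  write_dotbracket(dbs, p)
  .log_run(config, "sample", pp)
  invisible(list(structures = p))
}

.structures_from_dbn <- function(path) {
  dbs <- read_dotbracket(path)
  data.frame(read_id = sub("/[0-9]+$", "", names(dbs)),
             db = unname(dbs), stringsAsFactors = FALSE)
}

.stage_landscape <- function(config) {
  out <- config$out_dir
  ps <- file.path(out, "structures.dbn")
  if (!file.exists(ps)) .stopf("missing structure file: %s", ps)
  tab <- .structures_from_dbn(ps)
  ls <- config$landscape
  if (ls$k > nrow(tab))
    .stopf("landscape k = %d exceeds the %d available structures",
           ls$k, nrow(tab))
  land <- conformation_landscape(tab, k = ls$k, method = ls$method,
                                 d = ls$d, seed = config$seed,
                                 nstart = ls$nstart,
                                 cluster_on = ls$cluster_on)
  paths <- write_landscape(land, out)
  .log_run(config, "landscape", ps)
  invisible(as.list(paths))
}

.stage_stats <- function(config) {
  out <- config$out_dir
  ps <- file.path(out, "structures.dbn")
  pe <- file.path(out, "landscape_embedding.csv")
  if (!file.exists(ps)) .stopf("missing structure file: %s", ps)
  tab <- .structures_from_dbn(ps)
  whole <- ensemble_stats(tab$db)
  paths <- write_ensemble_stats(whole, out, prefix = "ensemble_all")
  if (file.exists(pe)) {
    emb <- utils::read.csv(pe)
    by_cluster <- per_cluster_stats(emb$cluster, tab$db)
    for (cname in names(by_cluster)) {
      paths <- c(paths, write_ensemble_stats(by_cluster[[cname]], out,
                                             prefix = paste0("ensemble_cluster", cname)))
    }
  }
  .log_run(config, "stats", ps)
  invisible(as.list(paths))
}

.stage_compare <- function(config, predicted, reference) {
  if (missing(predicted) || missing(reference))
    .stopf("compare needs 'predicted' and 'reference' dot-bracket files")
  for (p in c(predicted, reference))
    if (!file.exists(p)) .stopf("missing input: %s", p)
  pred <- read_dotbracket(predicted)
  ref <- read_dotbracket(reference)
  res <- structure_ppv(pred[[1L]], ref[[1L]])
  out_path <- file.path(config$out_dir, "compare.json")
  jsonlite::write_json(unclass(res), out_path, auto_unbox = TRUE,
                       digits = NA)
  .log_run(config, "compare", c(predicted, reference))
  invisible(list(report = out_path))
}
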