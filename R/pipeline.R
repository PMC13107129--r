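#' Derive a stage seed from the global seed by stable string hashing
#'
#' Polynomial hash of the stage name folded with the global seed, modulo
#' 2^31 - 1. Adding a stage therefore never shifts another stage's
#' randomness.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
stage_seed <- function(seed, stage) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% mod
  as.integer(h)
}

.fnv_hash <- function(x) {
  # tiny content hash for the run manifest (polynomial over the
  # serialization, kept below 2^31 so double arithmetic stays exact)
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' Nested sections mirror the pipeline stages: `simulate` (synthetic
#' dataset), `cluster` (redundancy thresholds and pLDDT gate),
#' `structures` (domain span), `tree` (alignment gaps and bootstrap),
#' `family` (block/nearest-family analysis), `ori` (scanner thresholds
#' and replicon batch). Unknown keys are rejected by
#' [pipeline_config()].
#'
#' @param seed Global seed (fanned out per stage via [stage_seed()]).
#' @return Nested configuration list of class `PipelineConfig`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_families = 5L, members_per_family = 4L,
                    chain_length = 120L, coord_noise_sigma = 0.8,
                    substitution_rate = 0.3, indel_rate = 0.02,
                    related_pair = NULL, related_sigma = 1.5,
                    n_replicons = 1L),
    cluster = list(min_identity = 0.9, min_coverage = 0.9,
                   min_mean_plddt = 70),
    structures = list(domain_start = NULL, domain_end = NULL),
    tree = list(gap_open = 5.0, gap_extend = 0.1, n_bootstrap = 1500L),
    family = list(query_family = NULL),
    ori = list(window = 270L, min_arm = 4L, max_spacer = 10L,
               max_mismatch = 1L, max_gap = 40L, min_score = 12,
               mutations = NULL)
  ), class = "PipelineConfig")
}

#' Build and validate a pipeline configuration
#'
#' Starts from [default_config()] and overrides with the supplied nested
#' list (or a YAML file); unknown sections or keys are an error.
#'
#' @param overrides Nested list of overrides, or a path to a YAML file.
#' @param seed Global seed.
#' @return A `PipelineConfig`.
#' @export
pipeline_config <- function(overrides = list(), seed = 1L) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- default_config(seed = seed)
  if (!is.null(overrides$seed)) cfg$seed <- as.integer(overrides$seed)
  for (sec in setdiff(names(overrides), "seed")) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(overrides[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][[key]] <- overrides[[sec]][[key]]
    }
  }
  cfg
}

.write_manifest <- function(out_dir, cfg, counts) {
  manifest <- list(
    tool = "repscan",
    version = as.character(utils::packageVersion("repscan")),
    config_hash = .fnv_hash(cfg),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the structure-based family-delineation pipeline
#'
#' Stage order: synthetic dataset generation, mean-pLDDT filter, greedy
#' sequence-redundancy clustering, domain extraction, all-vs-all
#' TM-score similarity matrix, block/agreement and nearest-family
#' analysis, structural-alphabet encoding, progressive alignment, and
#' UPGMA dendrogram with bootstrap supports. With `out_dir` set, writes
#' `matrix.tsv`, `tree.nwk`, `report.json` and `manifest.json`.
#'
#' @param config A `PipelineConfig` (see [pipeline_config()]).
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Log stage progress (default TRUE).
#' @return List: `dataset`, `filter_report`, `clusters`, `matrix`,
#'   `agreement`, `nearest`, `msa`, `tree`, `report`.
#' @export
run_family_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                                verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[family] ", ...)
  sim <- config$simulate
  fc <- family_config(
    n_families = sim$n_families,
    members_per_family = sim$members_per_family,
    chain_length = sim$chain_length,
    coord_noise_sigma = sim$coord_noise_sigma,
    substitution_rate = sim$substitution_rate,
    indel_rate = sim$indel_rate,
    seed = stage_seed(config$seed, "simulate_families"),
    related_pair = sim$related_pair, related_sigma = sim$related_sigma)
  dataset <- make_family_dataset(fc)
  say("simulated ", length(dataset$structures), " structures in ",
      sim$n_families, " families")

  filt <- filter_mean_plddt(dataset$structures,
                            min_mean = config$cluster$min_mean_plddt)
  say("pLDDT filter: ", length(filt$retained), "/",
      length(dataset$structures), " retained")
  kept_ids <- vapply(filt$retained, function(s) s$id, "")

  seqs <- dataset$sequences[dataset$sequences$id %in% kept_ids, , drop = FALSE]
  cs <- greedy_cluster(seqs, min_identity = config$cluster$min_identity,
                       min_coverage = config$cluster$min_coverage)
  rep_ids <- vapply(cs$clusters, function(cl) cl$representative, "")
  say("redundancy clustering: ", length(rep_ids), " representatives")

  reps <- filt$retained[match(rep_ids, kept_ids)]
  ds <- config$structures$domain_start
  de <- config$structures$domain_end
  domains <- lapply(reps, function(s) {
    L <- length(s$resno)
    extract_domain(s, if (is.null(ds)) 1L else ds,
                   if (is.null(de)) L else min(de, L))
  })

  fam_map <- setNames(dataset$labels$family, dataset$labels$id)
  simmat <- similarity_matrix(domains, families = fam_map)
  say("similarity matrix: ", nrow(simmat$values), " x ", nrow(simmat$values))

  agree <- partition_agreement(simmat)
  say("blocks: ", agree$block_count, ", ARI ",
      round(agree$adjusted_rand_index, 3))
  query <- config$family$query_family
  if (is.null(query)) query <- sort(unique(fam_map))[1L]
  nearest <- nearest_family(simmat, query)

  strings <- lapply(domains, encode_structure)
  msa <- progressive_align(strings, gap_open = config$tree$gap_open,
                           gap_extend = config$tree$gap_extend)
  tree <- bootstrap_tree(msa, n_reps = config$tree$n_bootstrap,
                         seed = stage_seed(config$seed, "bootstrap"))
  say("dendrogram with ", config$tree$n_bootstrap, " bootstrap replicates")

  report <- list(
    n_structures = length(dataset$structures),
    n_retained = length(filt$retained),
    n_representatives = length(rep_ids),
    block_count = agree$block_count,
    adjusted_rand_index = agree$adjusted_rand_index,
    purity = agree$purity,
    query_family = query,
    nearest_family = nearest$family[1L],
    nearest_mean_tm = nearest$mean_tm[1L])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(simmat, file.path(out_dir, "matrix.tsv"))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .write_manifest(out_dir, config, list(
      structures = length(dataset$structures),
      retained = length(filt$retained),
      representatives = length(rep_ids)))
  }
  invisible(list(dataset = dataset, filter_report = filt$report,
                 clusters = cs, matrix = simmat, agreement = agree,
                 nearest = nearest, msa = msa, tree = tree,
                 report = report))
}

#' Run the origin-characterization pipeline
#'
#' Simulates a batch of replicons with planted bipartite origins, scans
#' each for (inverted repeat, hairpin) candidates, scores planted-origin
#' recovery, and optionally classifies a mutation table against the
#' top candidate of the first replicon. With `out_dir` set, writes
#' `ori.tsv`, `mutations.tsv` and `manifest.json`.
#'
#' @param config A `PipelineConfig`.
#' @param out_dir Optional output directory.
#' @param verbose Log stage progress (default TRUE).
#' @return List: `replicons`, `candidates` (list of scan tables),
#'   `recovery` (logical vector), `mutation_classes` (or NULL).
#' @export
run_ori_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                             verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message("[ori] ", ...)
  n_rep <- config$simulate$n_replicons
  oc <- config$ori
  replicons <- lapply(seq_len(n_rep), function(k)
    make_replicon(replicon_config(
      seed = stage_seed(config$seed, paste0("replicon_", k)))))
  candidates <- vector("list", n_rep)
  recovery <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    rp <- replicons[[k]]
    orf <- rp$annotations[rp$annotations$feature == "rep_orf", , drop = FALSE]
    cand <- scan_replicon(rp$record$residues, orf, window = oc$window,
                          min_arm = oc$min_arm, max_spacer = oc$max_spacer,
                          max_mismatch = oc$max_mismatch,
                          max_gap = oc$max_gap, min_score = oc$min_score)
    candidates[[k]] <- cand
    hp <- rp$planted$hairpin$span
    ir <- rp$planted$ir
    # recovered when some reported candidate hits both planted elements
    recovery[k] <- nrow(cand) > 0L && any(
      cand$region_hairpin_start <= hp[2L] & cand$region_hairpin_end >= hp[1L] &
        cand$region_ir_start <= ir$right_arm[2L] &
        cand$region_ir_end >= ir$left_arm[1L])
  }
  say("planted-origin recovery: ", sum(recovery), "/", n_rep)

  mut_out <- NULL
  if (!is.null(oc$mutations)) {
    # mutation specs use region coordinates of the canonical SNJ2-layout
    # hairpin (the published compensatory design pairs 188 with 195)
    elem <- snj2_origin_element()
    mut_out <- data.frame(
      spec = oc$mutations,
      class = vapply(oc$mutations, function(m)
        classify_mutation(elem, m)$class, ""),
      stringsAsFactors = FALSE)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    all_cand <- do.call(rbind, lapply(seq_len(n_rep), function(k) {
      if (nrow(candidates[[k]]) == 0L) return(NULL)
      cbind(replicon = replicons[[k]]$record$id, candidates[[k]])
    }))
    if (is.null(all_cand)) all_cand <- data.frame()
    utils::write.table(all_cand, file.path(out_dir, "ori.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mut_out)) {
      utils::write.table(mut_out, file.path(out_dir, "mutations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .write_manifest(out_dir, config,
                    list(replicons = n_rep, recovered = sum(recovery)))
  }
  invisible(list(replicons = replicons, candidates = candidates,
                 recovery = recovery, mutation_classes = mut_out))
}
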