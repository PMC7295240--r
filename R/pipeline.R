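#' Pipeline configuration
#'
#' Bundles every tunable of the inference pipeline with its default. All
#' defaults are overridable here or through the CLI; a configuration
#' round-trips through YAML unchanged.
#'
#' @param k Seed k-mer length (default 10).
#' @param num_seeds Number of abundant k-mers used as seeds, `m`
#'   (default 600; 300 suits mouse-sized D-gene loci).
#' @param alpha Stopping-rule significance threshold (default 1e-30).
#' @param branch_alpha Runner-up branching threshold (default `alpha`).
#' @param max_dist Similarity-graph edge threshold (default 2).
#' @param k_min Minimum unique-substring length for usage (default 8).
#' @param extension `in_db` end-extension allowance (default 3).
#' @param identity_threshold Novel-variation identity boundary (default 75).
#' @param min_dataset_size Minimum distinct CDR3s per dataset (default 15000).
#' @param max_len Extension length cap (default 50).
#' @param max_branches Live-branch cap per seed (default 8).
#' @param min_core Minimum clique common-substring length (default 6).
#' @param consensus Build consensus CDR3s before inference (default FALSE;
#'   enable for raw, error-prone repertoires).
#' @param max_mismatches Consensus grouping radius (default 3).
#' @param keep_unidirectional Disable the unidirectional-extension filter.
#' @param rng_seed Seed for the simulator when the pipeline generates its own
#'   input; inference itself is deterministic.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 10, num_seeds = 600, alpha = 1e-30,
                            branch_alpha = alpha, max_dist = 2, k_min = 8,
                            extension = 3, identity_threshold = 75,
                            min_dataset_size = 15000, max_len = 50,
                            max_branches = 8, min_core = 6,
                            consensus = FALSE, max_mismatches = 3,
                            keep_unidirectional = FALSE, rng_seed = NULL) {
  cfg <- list(k = as.integer(k), num_seeds = as.integer(num_seeds),
              alpha = alpha, branch_alpha = branch_alpha,
              max_dist = as.integer(max_dist), k_min = as.integer(k_min),
              extension = as.integer(extension),
              identity_threshold = identity_threshold,
              min_dataset_size = as.integer(min_dataset_size),
              max_len = as.integer(max_len),
              max_branches = as.integer(max_branches),
              min_core = as.integer(min_core),
              consensus = isTRUE(consensus),
              max_mismatches = as.integer(max_mismatches),
              keep_unidirectional = isTRUE(keep_unidirectional),
              rng_seed = rng_seed)
  stopifnot(cfg$k >= 1, cfg$num_seeds >= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$branch_alpha > 0, cfg$branch_alpha < 1,
            cfg$max_dist >= 0, cfg$k_min >= 1, cfg$extension >= 0,
            cfg$identity_threshold > 0, cfg$identity_threshold < 100,
            cfg$max_len >= cfg$k, cfg$max_branches >= 1, cfg$min_core >= 1)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full D-gene inference pipeline
#'
#' Orchestrates, per dataset: optional consensus construction, k-mer
#' counting, seed selection, chi-square extension with branching, the
#' unidirectional filter, deduplication, relative-position classification
#' (keeping the central, D-like cluster), and clique merging. Candidates are
#' then consolidated across datasets, optionally classified against a
#' germline database, and their usage profile is computed on the pooled
#' input. Inference contains no randomness: identical inputs and
#' configuration give identical results.
#'
#' @param datasets A CDR3 set, or a named list of CDR3 sets.
#' @param db Optional germline database tibble; when `NULL` the annotation
#'   stage is skipped and candidates are exported unclassified.
#' @param config A [pipeline_config()].
#' @param compute_usage_profile Compute the usage profile of the final
#'   candidates on the pooled CDR3s (default TRUE).
#' @return An object of class `d_mining`: list with `candidates` (tibble),
#'   `extensions`, `funnel` (per-stage counts), `per_dataset`, `usage`,
#'   `config`, `skipped`.
#' @export
run_pipeline <- function(datasets, db = NULL, config = pipeline_config(),
                         compute_usage_profile = TRUE) {
  if (is.data.frame(datasets)) {
    datasets <- list(dataset = datasets)
  }
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  skipped <- character()
  per_dataset <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    if (config$consensus) {
      d <- build_consensus_cdr3s(d, config$max_mismatches)
    }
    if (nrow(d) < config$min_dataset_size) {
      inform(sprintf("Skipping dataset '%s': %d distinct CDR3s (< %d).",
                     nm, nrow(d), config$min_dataset_size))
      skipped <- c(skipped, nm)
      next
    }
    per_dataset[[nm]] <- infer_dataset(d, config)
  }
  if (length(per_dataset) == 0) {
    abort("No dataset passes the size filter.", class = "dminer_input_error")
  }

  candidates <- merge_across_datasets(
    lapply(per_dataset, function(x) x$candidates),
    max_dist = config$max_dist, min_core = config$min_core)
  cand_tbl <- tibble(sequence = sort(candidates), length = nchar(sort(candidates)))

  if (!is.null(db) && nrow(db) > 0) {
    ann <- annotate_candidates(cand_tbl$sequence, db,
                               extension = config$extension,
                               identity_threshold = config$identity_threshold)
    cand_tbl <- left_join(cand_tbl, ann, by = "sequence")
  } else {
    cand_tbl$classification <- NA_character_
  }

  usage <- NULL
  if (compute_usage_profile && nrow(cand_tbl) > 0) {
    pooled <- unique(unlist(lapply(datasets[setdiff(names(datasets), skipped)],
                                   function(d) d$sequence), use.names = FALSE))
    cand_db <- germline_db(sprintf("cand%02d", seq_len(nrow(cand_tbl))),
                           cand_tbl$sequence)
    usage <- compute_usage(pooled, cand_db, k_min = config$k_min)
  }

  funnel <- bind_rows(lapply(names(per_dataset), function(nm) {
    dplyr::mutate(per_dataset[[nm]]$funnel, dataset = nm, .before = 1)
  }))

  structure(list(candidates = cand_tbl,
                 extensions = bind_rows(lapply(names(per_dataset), function(nm) {
                   dplyr::mutate(per_dataset[[nm]]$extensions,
                                 dataset = nm, .before = 1)
                 })),
                 funnel = funnel,
                 per_dataset = per_dataset,
                 usage = usage,
                 config = config,
                 skipped = skipped),
            class = "d_mining")
}

# single-dataset inference: seeds -> extensions -> filters -> merged candidates
infer_dataset <- function(cdr3s, config) {
  kmers <- count_kmers(cdr3s, config$k)
  seeds <- select_seeds(kmers, m = config$num_seeds)
  exts <- extend_seeds(cdr3s, k = config$k, num_seeds = config$num_seeds,
                       alpha = config$alpha,
                       branch_alpha = config$branch_alpha,
                       max_len = config$max_len,
                       max_branches = config$max_branches)
  bidir <- filter_unidirectional(exts, keep = config$keep_unidirectional)
  uniq <- distinct(bidir, .data$sequence, .keep_all = TRUE)

  if (nrow(uniq) > 0) {
    pos <- mean_relative_positions(uniq, cdr3s)
    pos <- classify_by_position(pos)
    central <- filter(pos, .data$segment_class == "D")
  } else {
    pos <- uniq
    central <- uniq
  }
  merged <- if (nrow(central) > 0) {
    merge_cliques(central$sequence, cdr3s, max_dist = config$max_dist,
                  alpha = config$alpha, min_core = config$min_core,
                  max_len = config$max_len)
  } else {
    character()
  }
  list(
    extensions = if (nrow(uniq) > 0) pos else uniq,
    candidates = merged,
    funnel = tibble(
      n_cdr3s = nrow(cdr3s),
      seeds = nrow(seeds),
      extensions = nrow(exts),
      after_unidirectional = nrow(bidir),
      unique = nrow(uniq),
      central_cluster = nrow(central),
      post_merge = length(merged)
    )
  )
}

#' @export
print.d_mining <- function(x, ...) {
  cat(sprintf("<d_mining> %d candidate D genes from %d dataset(s)\n",
              nrow(x$candidates), length(x$per_dataset)))
  print(x$funnel)
  if (!is.null(x$candidates$classification) &&
      !all(is.na(x$candidates$classification))) {
    print(count(x$candidates, .data$classification))
  }
  invisible(x)
}

#' @export
tidy.d_mining <- function(x, ...) x$candidates

#' @export
glance.d_mining <- function(x, ...) {
  tibble(
    n_datasets = length(x$per_dataset),
    n_skipped = length(x$skipped),
    seeds = sum(x$funnel$seeds),
    extensions = sum(x$funnel$extensions),
    after_unidirectional = sum(x$funnel$after_unidirectional),
    unique = sum(x$funnel$unique),
    central_cluster = sum(x$funnel$central_cluster),
    post_merge = sum(x$funnel$post_merge),
    candidates = nrow(x$candidates),
    traceable_fraction = if (is.null(x$usage)) NA_real_
                         else x$usage$traceable_fraction
  )
}

#' Write pipeline results to a run directory
#'
#' Writes the candidate FASTA (provenance in the description line), the
#' extension table, the usage tables, and a manifest (configuration, stage
#' counts, package version) as YAML.
#'
#' @param result A `d_mining` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cand <- result$candidates
  if (nrow(cand) > 0) {
    seqs <- Biostrings::DNAStringSet(cand$sequence)
    names(seqs) <- sprintf("candidate_%02d len=%d class=%s",
                           seq_len(nrow(cand)), cand$length,
                           ifelse(is.na(cand$classification), "unclassified",
                                  cand$classification))
    Biostrings::writeXStringSet(seqs, file.path(dir, "candidates.fasta"))
  }
  utils::write.table(result$extensions, file.path(dir, "extensions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$usage)) {
    utils::write.table(result$usage$gene_usage,
                       file.path(dir, "usage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = as.character(utils::packageVersion("dminer")),
    config = unclass(result$config),
    config_hash = rlang::hash(unclass(result$config)),
    skipped = as.list(result$skipped),
    funnel = lapply(seq_len(nrow(result$funnel)),
                    function(i) as.list(result$funnel[i, ]))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
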