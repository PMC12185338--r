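## End-to-end orchestration: data -> multi-seed training -> reliability
## selection -> feature mapping -> RSA comparison -> relevance, driven by a
## single YAML-able config, with content-hash stage caching and a
## machine-readable manifest.

#' Build a pipeline configuration
#'
#' Either supply a `synth` block (planted ground truth; see
#' [generate_embedding()] / [simulate_dataset()]) or paths to existing
#' `triplets` (and optionally `features`) files in the package's tab-separated
#' formats. Training runs once per seed; the most reproducible run is carried
#' forward to the mapping, comparison and relevance stages.
#'
#' @param out_dir Output directory for all stages.
#' @param synth Optional list: `m`, `k`, `sparsity`, `scale`, `d`,
#'   `noise_sd`, `n`, `mode`, `temperature`, `seed`.
#' @param triplets,features Optional input file paths (used when `synth` is
#'   absent).
#' @param train List of [train_config()] overrides.
#' @param prior List of [prior_spec()] overrides.
#' @param n_seeds Number of training seeds (32 mirrors the full-scale
#'   protocol; small studies use fewer).
#' @param base_seed Seeds are `base_seed + 0:(n_seeds-1)`.
#' @param compare List: `fractions` for cumulative RSA (default 0.95).
#' @param relevance List: `n_triplets` scored for the relevance stage,
#'   `labels` optional path to a two-column `dim<TAB>label` file.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synth = NULL, triplets = NULL,
                            features = NULL, train = list(), prior = list(),
                            n_seeds = 32L, base_seed = 1L,
                            compare = list(fractions = 0.95),
                            relevance = list(n_triplets = 500L)) {
  if (is.null(synth) && is.null(triplets)) {
    stop("config needs either a synth block or a triplets path")
  }
  for (p in c(triplets, features, relevance$labels)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(list(out_dir = out_dir, synth = synth, triplets = triplets,
                 features = features, train = train, prior = prior,
                 n_seeds = as.integer(n_seeds),
                 base_seed = as.integer(base_seed),
                 compare = compare, relevance = relevance),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

## content hash for stage caching: md5 of a canonical JSON rendering of the
## stage parameters plus md5s of any input files
stage_hash <- function(params, files = character(0)) {
  files <- files[!vapply(files, is.null, TRUE)]
  fh <- if (length(files)) unname(tools::md5sum(unlist(files))) else character(0)
  blob <- jsonlite::toJSON(list(params = params, files = fh), auto_unbox = TRUE)
  tf <- tempfile(); writeLines(as.character(blob), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

log_line <- function(stage, ...) {
  msg <- list(stage = stage, ...)
  message(jsonlite::toJSON(msg, auto_unbox = TRUE))
}

#' Run the full pipeline
#'
#' Executes the stages in order, skipping any stage whose parameter/input
#' hash matches the manifest from a previous run and whose outputs still
#' exist. Writes `manifest.json` in the run directory recording, per stage,
#' the content hash, outputs and headline metrics, plus every training seed.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return The run directory, invisibly; the manifest as attribute
#'   `"manifest"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(package_version = as.character(utils::packageVersion("repalign")),
              stages = list())

  fresh <- function(name, hash, outputs) {
    st <- manifest$stages[[name]]
    !is.null(st) && identical(st$hash, hash) && all(file.exists(unlist(outputs)))
  }
  record <- function(name, hash, outputs, metrics = list()) {
    manifest$stages[[name]] <<- list(hash = hash, outputs = outputs,
                                     metrics = metrics)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  ## ---- stage: data -------------------------------------------------------
  data_dir <- file.path(out, "data")
  dir.create(data_dir, showWarnings = FALSE)
  trip_path <- file.path(data_dir, "triplets.tsv")
  feat_path <- file.path(data_dir, "features.tsv")
  truth_path <- file.path(data_dir, "truth_embedding.tsv")
  h <- stage_hash(config[c("synth")], c(config$triplets, config$features))
  data_out <- list(triplets = trip_path)
  if (!fresh("data", h, data_out)) {
    if (!is.null(config$synth)) {
      s <- modifyList(list(m = 60, k = 6, sparsity = 0.6, scale = 1, d = NULL,
                           noise_sd = 0, n = 20000, mode = "argmax",
                           temperature = 1, seed = 1), config$synth)
      planted <- generate_embedding(s$m, s$k, s$sparsity, s$scale, s$seed)
      truth <- ground_truth(planted, noise_sd = s$noise_sd, seed = s$seed)
      write_embedding(planted, truth_path)
      d <- if (is.null(s$d)) 2L * s$k else s$d
      write_features(generate_features(truth, d), feat_path)
      write_triplets(simulate_dataset(truth, s$n, mode = s$mode,
                                      temperature = s$temperature,
                                      seed = s$seed + 1L), trip_path)
    } else {
      file.copy(config$triplets, trip_path, overwrite = TRUE)
      if (!is.null(config$features)) {
        file.copy(config$features, feat_path, overwrite = TRUE)
      }
    }
    record("data", h, data_out, list(n_trials = nrow(read_triplets(trip_path))))
    log_line("data", status = "done")
  } else log_line("data", status = "cached")
  choices <- read_triplets(trip_path)
  m_objects <- max(choices$k)

  ## ---- stage: train ------------------------------------------------------
  seeds <- config$base_seed + seq_len(config$n_seeds) - 1L
  run_dir <- file.path(out, "runs")
  dir.create(run_dir, showWarnings = FALSE)
  run_paths <- file.path(run_dir, sprintf("embedding_seed%03d.tsv", seeds))
  h <- stage_hash(list(train = config$train, prior = config$prior,
                       seeds = seeds), trip_path)
  if (!fresh("train", h, as.list(run_paths))) {
    dims <- integer(length(seeds))
    for (s in seq_along(seeds)) {
      cfg <- do.call(train_config, modifyList(config$train,
                                              list(seed = seeds[s])))
      pr <- do.call(prior_spec, config$prior)
      fit <- vice_train(choices, cfg, pr, m = m_objects)
      emb <- point_estimate(fit)
      write_embedding(emb, run_paths[s])
      dims[s] <- ncol(emb)
      log_line("train", seed = seeds[s], dims = ncol(emb),
               epochs = fit$epochs,
               final_loss = utils::tail(fit$trajectory$loss, 1))
    }
    record("train", h, as.list(run_paths), list(dims = dims))
  } else log_line("train", status = "cached")
  runs <- lapply(run_paths, read_embedding)

  ## ---- stage: reliability ------------------------------------------------
  rel_path <- file.path(out, "reliability.tsv")
  sel_path <- file.path(out, "selected_embedding.tsv")
  h <- stage_hash(list(seeds = seeds), run_paths)
  if (!fresh("reliability", h, list(rel_path, sel_path))) {
    rel <- split_half_reliability(runs)
    best <- select_best_run(runs, rel)
    write.table(data.frame(seed = seeds, reliability = rel$per_run_r,
                           selected = seq_along(seeds) == best),
                rel_path, sep = "\t", row.names = FALSE, quote = FALSE)
    file.copy(run_paths[best], sel_path, overwrite = TRUE)
    record("reliability", h, list(rel_path, sel_path),
           list(best_seed = seeds[best],
                best_reliability = rel$per_run_r[best]))
    log_line("reliability", best_seed = seeds[best],
             r = rel$per_run_r[best])
  } else log_line("reliability", status = "cached")
  selected <- read_embedding(sel_path)

  ## ---- stage: map (needs features) ---------------------------------------
  if (file.exists(feat_path)) {
    map_path <- file.path(out, "map_r2.tsv")
    h <- stage_hash(list(), c(feat_path, sel_path))
    if (!fresh("map", h, list(map_path))) {
      X <- read_features(feat_path)
      map <- fit_ridge(X, selected)
      write.table(data.frame(dim = colnames(selected),
                             lambda = map$lambda, r2 = map$r2_per_dim),
                  map_path, sep = "\t", row.names = FALSE, quote = FALSE)
      record("map", h, list(map_path),
             list(median_r2 = stats::median(map$r2_per_dim)))
      log_line("map", median_r2 = stats::median(map$r2_per_dim))
    } else log_line("map", status = "cached")
  }

  ## ---- stage: compare (against planted truth when synthetic) -------------
  if (file.exists(truth_path)) {
    cmp_path <- file.path(out, "comparison.json")
    h <- stage_hash(config$compare, c(truth_path, sel_path))
    if (!fresh("compare", h, list(cmp_path))) {
      planted <- read_embedding(truth_path)
      rec <- recovery_report(planted, selected)
      ref_rsm <- rsm_from_embedding(planted)
      rsm_r <- rsm_correlation(rsm_from_embedding(selected), ref_rsm)
      ranking <- match_dimensions(planted, selected, unique = TRUE)$dim_b
      ranking <- c(ranking, setdiff(seq_len(ncol(selected)), ranking))
      cum <- cumulative_rsa(selected, ref_rsm, ranking,
                            fractions = config$compare$fractions)
      cmp <- list(median_matched_r = rec$median_r,
                  dim_difference = rec$dim_difference,
                  rsm_correlation = rsm_r,
                  dims_needed = as.list(cum$dims_needed))
      jsonlite::write_json(cmp, cmp_path, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      record("compare", h, list(cmp_path), cmp)
      log_line("compare", rsm_r = rsm_r, median_matched_r = rec$median_r)
    } else log_line("compare", status = "cached")
  }

  ## ---- stage: relevance --------------------------------------------------
  relv_path <- file.path(out, "relevance.tsv")
  n_rel <- if (is.null(config$relevance$n_triplets)) 500L else
    as.integer(config$relevance$n_triplets)
  h <- stage_hash(list(n = n_rel), c(sel_path, config$relevance$labels))
  if (!fresh("relevance", h, list(relv_path))) {
    trips <- sample_triplets(nrow(selected), n_rel,
                             seed = config$base_seed + 1000L)
    rows <- lapply(seq_len(nrow(trips)), function(s) {
      pr <- dimension_relevance(selected, trips[s, ])
      data.frame(i = pr$triplet[1] - 1L, j = pr$triplet[2] - 1L,
                 k = pr$triplet[3] - 1L, top_dim = pr$top_dim - 1L,
                 delta_top = pr$delta[pr$top_dim], p_full = pr$p_full)
    })
    write.table(do.call(rbind, rows), relv_path, sep = "\t",
                row.names = FALSE, quote = FALSE)
    metrics <- list(n_triplets = n_rel)
    if (!is.null(config$relevance$labels)) {
      lab <- read.delim(config$relevance$labels, header = TRUE)
      counts <- aggregate_relevance(selected, trips,
                                    lab$label[match(seq_len(ncol(selected)),
                                                    lab$dim + 1L)])
      write.table(data.frame(category = names(counts), count = counts),
                  file.path(out, "relevance_categories.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      metrics$categories <- as.list(counts)
    }
    record("relevance", h, list(relv_path), metrics)
    log_line("relevance", n = n_rel)
  } else log_line("relevance", status = "cached")

  out_manifest <- jsonlite::read_json(manifest_path)
  structure(invisible(out), manifest = out_manifest)
}
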