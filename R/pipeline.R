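# End-to-end orchestration from a single JSON config: synthesize (or load)
# inputs, compute WMM features, build the gold-standard split, train and
# apply the classifier, sweep clustering parameters, assemble the tiered
# complex map, and run the interpretation stages (structural exclusivity,
# ALL-IN, annotation transfer). Stages are cached by content hash so an
# unchanged re-run is skip-only, and every published constant lives in the
# config, never in the code path.

#' Default demo run configuration
#'
#' A complete synthetic-data run configuration with every threshold at its
#' published default. Time-to-complete on one CPU is a couple of minutes.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @return A named config list, serializable with [write_config()].
#' @export
demo_config <- function(out_dir, seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    synthetic = list(
      n_complexes = 20L, size_min = 3L, size_max = 8L, overlap_fraction = 0.1,
      n_me_pairs = 8L, n_sc_pairs = 8L,
      pulldowns = list(n_baits_per_complex = 8L, detect_prob = 0.8,
                       background_rate = 0.01, n_background_proteins = 20L),
      expression = list(n_lineages = 8L, n_lines_per_lineage = 15L,
                        me_mode = "anticorrelated", noise_sd = 0.3),
      trimers = list(n_each = 5L, n_residues_per_chain = 32L)
    ),
    features = list(min_pair_count = 1L),
    benchmark = list(merge_threshold = 0.6, size_threshold = 30L),
    training = list(n_negatives = 10000L, backend = "glmnet", lambda = 1e-3),
    clustering = list(
      grids = list(score_threshold = c(0.95, 0.8, 0.5, 0.3),
                   c1_density = c(0.2, 0.3), c1_overlap = c(0.7),
                   mcl_inflation = c(2, 4)),
      n_tiers = 4L, reduce_jaccard = 0.7, max_size = 100L),
    exclusivity = list(pdockq_min = 0.23, if_plddt_min = 70,
                       max_chain_clashes = 5, rmsd_max = 10,
                       interface_cutoff = 4.0, overlap_min = 10,
                       clash_plddt_sum_max = 500),
    allin = list(min_detect = 50L, impute_mean = -4, impute_sd = 0.3,
                 n_extreme = 50L),
    interactome = list(min_partners = 3L, conf_min = 0.8),
    annotation = list(p_max = 0.01, share_min = 0.5, score_max = 4L)
  )
}

#' Write / read a run configuration
#'
#' @param config Config list.
#' @param path JSON path.
#' @return `path` / the config list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$synthetic$pulldowns <- as.list(cfg$synthetic$pulldowns)
  cfg
}

#' Validate a run configuration
#'
#' Rejects unknown top-level keys and missing required sections before any
#' stage runs.
#'
#' @param config Config list.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
validate_config <- function(config) {
  known <- names(demo_config("."))
  unknown <- setdiff(names(config), known)
  assert_that(length(unknown) == 0L,
              sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  required <- c("out_dir", "seed", "synthetic", "features", "benchmark",
                "training", "clustering")
  missing <- setdiff(required, names(config))
  assert_that(length(missing) == 0L,
              sprintf("missing config sections: %s", paste(missing, collapse = ", ")))
  invisible(TRUE)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

stage_hash <- function(config_part, input_files = character(0)) {
  cfg <- jsonlite::toJSON(config_part, auto_unbox = TRUE, digits = NA)
  sums <- if (length(input_files) > 0L)
    paste(tools::md5sum(input_files), collapse = "") else ""
  as.character(tools::md5sum(
    local({ f <- tempfile(); writeLines(c(as.character(cfg), sums), f); f })))
}

#' Run the full pipeline from a configuration
#'
#' Executes stages in dependency order, skipping any stage whose inputs,
#' parameters, and outputs are unchanged since the recorded manifest. Any
#' stage failure aborts with the stage name; completed outputs persist.
#'
#' @param config Config list (see [demo_config()]) or a JSON path.
#' @return The run manifest (also written to `out_dir/run_manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "run_manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  p <- function(...) file.path(out, ...)
  seed <- as.integer(config$seed)

  run_stage <- function(name, config_part, inputs, outputs, fun) {
    h <- stage_hash(config_part, inputs)
    prev <- manifest[[name]]
    if (!is.null(prev) && identical(prev$hash, h) && all(file.exists(outputs))) {
      log_stage(name, "up to date; skipped")
      return(invisible(NULL))
    }
    log_stage(name, "running")
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest[[name]] <<- list(hash = h, outputs = outputs,
                              seed = seed, when = "run")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(NULL)
  }

  # -- synthesize fixtures -------------------------------------------------
  syn <- config$synthetic
  run_stage("synthesize", syn, character(0),
            c(p("truth.json"), p("obs.tsv"), p("expression.tsv"),
              p("lineages.tsv")), function() {
    truth <- make_planted_complexes(syn$n_complexes,
                                    c(syn$size_min, syn$size_max),
                                    syn$overlap_fraction, seed = seed,
                                    n_me_pairs = syn$n_me_pairs,
                                    n_sc_pairs = syn$n_sc_pairs)
    write_truth(truth, p("truth.json"))
    obs <- do.call(simulate_pulldowns,
                   c(list(truth = truth, seed = seed + 1L), syn$pulldowns))
    write_observations(obs, p("obs.tsv"))
    expr <- do.call(simulate_expression,
                    c(list(truth = truth, seed = seed + 2L),
                      as.list(syn$expression)))
    write_expression(expr, p("expression.tsv"), p("lineages.tsv"))
  })
  truth <- read_truth(p("truth.json"))

  # -- WMM features --------------------------------------------------------
  run_stage("features", config$features, p("obs.tsv"), p("features.tsv"),
            function() {
    obs <- read_observations(p("obs.tsv"))
    feats <- compute_wmm(obs, min_pair_count = config$features$min_pair_count)
    names(feats)[names(feats) == "pair_count"] <- "wmm_paircount_demo_raw"
    names(feats)[names(feats) == "neg_ln_pval"] <- "wmm_negln_demo_raw"
    write_pairs(feats, p("features.tsv"))
  })

  # -- gold standard -------------------------------------------------------
  run_stage("benchmark", config$benchmark, p("truth.json"),
            c(p("gold.train.txt"), p("gold.test.txt")), function() {
    reduced <- reduce_redundancy(truth$complexes,
                                 merge_threshold = config$benchmark$merge_threshold,
                                 size_threshold = config$benchmark$size_threshold)
    split <- split_benchmark(reduced, seed = seed + 3L)
    check_split_invariants(split)
    write_benchmark_split(split, out, prefix = "gold")
  })

  # -- train + score -------------------------------------------------------
  run_stage("train", config$training,
            c(p("features.tsv"), p("gold.train_ppis.txt"),
              p("gold.neg_train_ppis.txt")),
            c(p("model/schema.json"), p("network.tsv")), function() {
    feats <- read_pairs(p("features.tsv"))
    gold <- list(positives = read_pairs(p("gold.train_ppis.txt")),
                 negatives = read_pairs(p("gold.neg_train_ppis.txt")))
    labeled <- assemble_training(feats, gold,
                                 n_negatives = config$training$n_negatives,
                                 seed = seed + 4L)
    model <- train_classifier(labeled, backend = config$training$backend,
                              seed = seed + 5L,
                              lambda = config$training$lambda)
    save_model(model, p("model"))
    net <- score_all_pairs(model, impute_missing(feats))
    write_network(net, p("network.tsv"))
  })

  # -- clustering sweep + tier assembly ------------------------------------
  run_stage("cluster", config$clustering,
            c(p("network.tsv"), p("gold.train.txt")),
            c(p("sweep.tsv"), p("complex_map.txt"),
              p("complex_map_reduced.txt"), p("map_manifest.json")),
            function() {
    net <- read_network(p("network.tsv"))
    gold_train <- read_complexes(p("gold.train.txt"), "gold_train")
    grids <- lapply(config$clustering$grids, as.numeric)
    sweep <- parameter_sweep(net, grids, gold_train,
                             cache_dir = p("sweep_cache"),
                             kclique_seed = seed + 6L)
    utils::write.table(as.data.frame(sweep), p("sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    selected <- select_tier_sets(sweep, n_tiers = config$clustering$n_tiers)
    map <- assemble_tiers(selected)
    write_complex_map(map, p("complex_map.txt"), p("map_manifest.json"))
    reduced <- reduce_map(map, config$clustering$reduce_jaccard)
    write_complex_map(reduced, p("complex_map_reduced.txt"))
  })

  # -- structural mutual exclusivity on generated trimers ------------------
  run_stage("exclusivity", config$exclusivity, p("truth.json"),
            p("exclusivity.tsv"), function() {
    n_each <- syn$trimers$n_each
    calls <- list()
    for (i in seq_len(n_each)) {
      for (ov in c(TRUE, FALSE)) {
        tri <- make_toy_trimer(ov, syn$trimers$n_residues_per_chain,
                               seed = seed + 100L + i * 2L + ov)
        calls[[length(calls) + 1L]] <-
          classify_trimer(tri, thresholds = config$exclusivity)
      }
    }
    write_pairs(stats::setNames(do.call(rbind, calls), c(
      "id_a", "id_b", "common_protein", "verdict", "rmsd_align",
      "n_overlap_interface", "clash_plddt_sum", "filter_reasons")),
      p("exclusivity.tsv"))
  })

  # -- ALL-IN + Jaccard interactome ----------------------------------------
  run_stage("allin", config$allin,
            c(p("expression.tsv"), p("lineages.tsv"), p("truth.json"),
              p("network.tsv")), p("allin.tsv"), function() {
    expr <- read_expression(p("expression.tsv"), p("lineages.tsv"))
    tab <- allin_scores(expr, truth$complexes, seed = seed + 7L,
                        sub3_args = config$allin)
    net <- read_network(p("network.tsv"))
    tab$jaccard_interactome <- vapply(seq_len(nrow(tab)), function(r) {
      jaccard_interactome(net, c(tab$id_a[r], tab$id_b[r]),
                          min_partners = config$interactome$min_partners,
                          conf_min = config$interactome$conf_min)
    }, 0)
    write_pairs(tab, p("allin.tsv"))
  })

  # -- annotation enrichment + transfer ------------------------------------
  run_stage("annotate", config$annotation,
            c(p("complex_map.txt"), p("truth.json"), p("obs.tsv")),
            c(p("enrichment.tsv"), p("transfers.tsv")), function() {
    map <- read_complex_map(p("complex_map.txt"))
    obs <- read_observations(p("obs.tsv"))
    background <- rownames(obs$presence)
    # synthetic annotation: one term per planted complex (the ground-truth
    # functional module), annotating every member except the first, which
    # plays the uncharacterized transfer target below
    terms <- setNames(lapply(truth$complexes, function(cx) cx[-1L]),
                      sprintf("T%04d", seq_along(truth$complexes)))
    anno <- as_annotation_set(terms, ontology_tag = "synthetic_truth")
    enr <- enrich_map(map, anno, background)
    utils::write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    proteins <- sort(unique(unlist(truth$complexes)))
    scores <- setNames(rep(5L, length(proteins)), proteins)
    understudied <- vapply(truth$complexes, `[[`, "", 1L)
    scores[understudied] <- 2L
    tr <- transfer_annotations(map, enr, anno, scores,
                               p_max = config$annotation$p_max,
                               share_min = config$annotation$share_min,
                               score_max = config$annotation$score_max)
    utils::write.table(tr, p("transfers.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  jsonlite::read_json(manifest_path, simplifyVector = TRUE)
}

#' Validate the outputs of a pipeline run
#'
#' Re-checks the module-level invariants on the files a run produced:
#' leak-freedom of the six gold-standard pair sets, score ranges of the
#' network, the cluster edge-weight post-filter, ALL-IN sub-score counts,
#' and exclusivity verdict consistency.
#'
#' @param out_dir A run's output directory.
#' @return Data frame `check`, `pass`, `detail`; attribute `ok` is the
#'   conjunction.
#' @export
validate_outputs <- function(out_dir) {
  p <- function(...) file.path(out_dir, ...)
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  split <- list(train = list(positives = read_pairs(p("gold.train_ppis.txt")),
                             negatives = read_pairs(p("gold.neg_train_ppis.txt"))),
                test = list(positives = read_pairs(p("gold.test_ppis.txt")),
                            negatives = read_pairs(p("gold.neg_test_ppis.txt"))))
  ok <- tryCatch({ check_split_invariants(split); TRUE },
                 error = function(e) conditionMessage(e))
  add("gold_pair_disjointness", isTRUE(ok), if (isTRUE(ok)) "" else ok)
  net <- read_network(p("network.tsv"))
  add("network_score_range", all(net$score >= 0 & net$score <= 1),
      sprintf("%d edges", nrow(net)))
  map <- read_complex_map(p("complex_map.txt"))
  if (length(map$clusters) == 0L) {
    add("complex_map_nonempty", FALSE, "zero clusters in map")
  } else {
    add("complex_map_nonempty", TRUE, sprintf("%d clusters", length(map$clusters)))
    manifest <- jsonlite::read_json(p("map_manifest.json"), simplifyVector = TRUE)
    thr_by_tier <- if (is.data.frame(manifest$tiers))
      manifest$tiers$score_threshold
    else vapply(manifest$tiers, function(t) t$score_threshold, 0)
    edge_w <- setNames(net$score, pair_key(net$id_a, net$id_b))
    bad <- character(0)
    for (i in seq_along(map$clusters)) {
      cl <- map$clusters[[i]]
      thr <- thr_by_tier[map$tier[i]]
      if (length(cl) < 2L) { bad <- c(bad, map$cluster_id[i]); next }
      prs <- utils::combn(cl, 2L)
      w <- edge_w[pair_key(prs[1L, ], prs[2L, ])]
      w[is.na(w)] <- 0
      wmax <- vapply(cl, function(m)
        max(w[prs[1L, ] == m | prs[2L, ] == m]), 0)
      if (any(wmax <= thr)) bad <- c(bad, map$cluster_id[i])
    }
    add("cluster_edge_post_filter", length(bad) == 0L,
        if (length(bad)) paste("failing clusters:", paste(bad, collapse = ","))
        else "")
    add("cluster_size_range",
        all(lengths(map$clusters) >= 2L & lengths(map$clusters) <= 100L), "")
  }
  if (file.exists(p("allin.tsv"))) {
    allin <- read_pairs(p("allin.tsv"))
    add("allin_min_subscores", all(allin$n_subscores >= 2L),
        sprintf("%d pairs", nrow(allin)))
  }
  if (file.exists(p("exclusivity.tsv"))) {
    ex <- read_pairs(p("exclusivity.tsv"))
    me_ok <- all(ex$n_overlap_interface[ex$verdict == "mutually_exclusive"] > 10,
                 na.rm = TRUE)
    sc_ok <- all(ex$n_overlap_interface[ex$verdict == "structurally_consistent"] == 0,
                 na.rm = TRUE)
    add("exclusivity_verdict_invariants", me_ok && sc_ok, "")
  }
  out <- do.call(rbind, checks)
  structure(out, ok = all(out$pass))
}
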