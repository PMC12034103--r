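#' Pipeline stage functions
#'
#' Each stage reads the documented artifacts of the previous stage from an
#' output directory and writes its own, so a run can be driven stage by
#' stage (or from the shell via the `inst/cli/rnaloopclust` script) and
#' rerun idempotently given identical inputs and seed. `run_pipeline()`
#' chains the training stages and the clustering stages end to end.
#'
#' Artifacts, all plain text except the model checkpoint:
#' `loops.tsv` + `coords.tsv` (loop and coordinate files), `manifest.csv`,
#' `graphs.jsonl`, `model.rds` + `model.json` sidecar, `embeddings.csv`,
#' `kselect.csv`, `clusters.csv`, `qscores.csv`, `evaluation.json`.
#'
#' @param outdir run directory.
#' @param n_per_family,loop_type,noise,seed simulation parameters;
#'   `loop_type` selects internal-loop templates, hairpin templates or both.
#' @return each stage invisibly returns its main artifact path.
#' @name pipeline
NULL

read_required <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing input file: ", path)
  path
}

#' @rdname pipeline
#' @export
stage_simulate <- function(outdir, n_per_family = 50L,
                           loop_type = c("internal", "hairpin", "both"),
                           noise = noise_spec(), seed = 0L) {
  loop_type <- match.arg(loop_type)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- builtin_templates()
  tmpl <- switch(loop_type,
                 internal = tmpl[c("SR", "KT", "TS", "HT", "EL", "CL")],
                 hairpin = tmpl[c("TL", "GL")],
                 both = tmpl)
  ds <- generate_dataset(tmpl, n_per_family, noise, seed)
  write_loop_file(ds$loops, file.path(outdir, "loops.tsv"))
  write_coordinate_file(loops_to_coordinates(ds$loops),
                        file.path(outdir, "coords.tsv"))
  utils::write.csv(ds$manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  freq <- frequency_table_from_loops(ds$loops)
  utils::write.table(freq, file.path(outdir, "frequency.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(outdir, "loops.tsv"))
}

#' @rdname pipeline
#' @param distance_mode distance definition for the edge features.
#' @export
stage_encode <- function(outdir, distance_mode = "center_euclidean") {
  loops <- read_loop_file(read_required(file.path(outdir, "loops.tsv"), "encode"))
  loops <- attach_coordinates(loops,
    read_required(file.path(outdir, "coords.tsv"), "encode"))
  graphs <- lapply(loops, encode_loop, distance_mode = distance_mode)
  write_graphs_jsonl(graphs, file.path(outdir, "graphs.jsonl"))
  invisible(file.path(outdir, "graphs.jsonl"))
}

read_manifest_split <- function(outdir, graphs) {
  man <- utils::read.csv(read_required(file.path(outdir, "manifest.csv"),
                                       "train"), stringsAsFactors = FALSE)
  ids <- vapply(graphs, `[[`, character(1), "loop_id")
  pos <- match(man$loop_id, ids)
  list(train = pos[man$split == "train"], val = pos[man$split == "val"],
       test = pos[man$split == "test"])
}

#' @rdname pipeline
#' @param config a [gin_config()].
#' @export
stage_train <- function(outdir, config = gin_config()) {
  graphs <- read_graphs_jsonl(read_required(file.path(outdir, "graphs.jsonl"),
                                            "train"))
  split <- read_manifest_split(outdir, graphs)
  model <- gin_train(graphs, split, config)
  saveRDS(model, file.path(outdir, "model.rds"))
  sidecar <- list(config = unclass(config),
                  label_vocabulary = model$label_vocabulary,
                  best_val_accuracy = model$best_val_accuracy,
                  test_accuracy = model$test_accuracy,
                  schema = model$schema)
  jsonlite::write_json(sidecar, file.path(outdir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(model$log, file.path(outdir, "training_log.csv"),
                   row.names = FALSE)
  invisible(file.path(outdir, "model.rds"))
}

#' @rdname pipeline
#' @export
stage_embed <- function(outdir) {
  model <- readRDS(read_required(file.path(outdir, "model.rds"), "embed"))
  graphs <- read_graphs_jsonl(read_required(file.path(outdir, "graphs.jsonl"),
                                            "embed"))
  emb <- gin_embed(model, graphs)
  write_embeddings(emb, file.path(outdir, "embeddings.csv"))
  invisible(file.path(outdir, "embeddings.csv"))
}

#' @rdname pipeline
#' @param k_grid,smcr_max K-selection parameters (see [select_k()]).
#' @export
stage_select_k <- function(outdir, k_grid = NULL, smcr_max = 0.05, seed = 0L) {
  emb <- read_embeddings(read_required(file.path(outdir, "embeddings.csv"),
                                       "select-k"))
  sel <- select_k(emb, k_grid, smcr_max, seed)
  rep <- sel$report
  rep$chosen <- rep$k == sel$chosen_k
  utils::write.csv(rep, file.path(outdir, "kselect.csv"), row.names = FALSE)
  invisible(file.path(outdir, "kselect.csv"))
}

#' @rdname pipeline
#' @param K number of clusters; if `NULL`, the chosen K of `kselect.csv`.
#' @export
stage_cluster <- function(outdir, K = NULL, seed = 0L) {
  emb <- read_embeddings(read_required(file.path(outdir, "embeddings.csv"),
                                       "cluster"))
  if (is.null(K)) {
    ks <- utils::read.csv(read_required(file.path(outdir, "kselect.csv"),
                                        "cluster"))
    K <- ks$k[ks$chosen][1]
  }
  cl <- kmeans_cluster(emb, K, seed)
  utils::write.csv(data.frame(loop_id = names(cl), cluster = unname(cl)),
                   file.path(outdir, "clusters.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(file.path(outdir, "clusters.csv"))
}

#' @rdname pipeline
#' @param linkage,distance_threshold agglomerative parameters (see
#'   [subcluster()]).
#' @export
stage_subcluster <- function(outdir, linkage = "average",
                             distance_threshold = 6) {
  emb <- read_embeddings(read_required(file.path(outdir, "embeddings.csv"),
                                       "subcluster"))
  cl <- utils::read.csv(read_required(file.path(outdir, "clusters.csv"),
                                      "subcluster"), stringsAsFactors = FALSE)
  assign <- stats::setNames(cl$cluster, cl$loop_id)[rownames(emb)]
  out <- subcluster(emb, assign, linkage, distance_threshold)
  utils::write.csv(out, file.path(outdir, "clusters.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(file.path(outdir, "clusters.csv"))
}

#' @rdname pipeline
#' @param render_cmd optional shell command template run once per
#'   subcluster (an image-rendering hook); occurrences of `{subcluster}`
#'   and `{loops}` are substituted by the subcluster id and a
#'   comma-separated member list.
#' @export
stage_qscore <- function(outdir, render_cmd = NULL) {
  cl <- utils::read.csv(read_required(file.path(outdir, "clusters.csv"),
                                      "qscore"), stringsAsFactors = FALSE)
  if (is.null(cl$subcluster)) stop("qscore stage needs subcluster output")
  loops <- read_loop_file(read_required(file.path(outdir, "loops.tsv"), "qscore"))
  loops <- attach_coordinates(loops,
    read_required(file.path(outdir, "coords.tsv"), "qscore"))
  names(loops) <- vapply(loops, loop_id, character(1))
  stats_rows <- lapply(sort(unique(cl$subcluster)), function(sid) {
    mem <- loops[cl$loop_id[cl$subcluster == sid]]
    subcluster_stats(mem, sid)
  })
  qs <- q_scores(do.call(rbind, stats_rows))
  utils::write.csv(qs, file.path(outdir, "qscores.csv"), row.names = FALSE)
  if (!is.null(render_cmd)) {
    for (sid in qs$subcluster_id) {
      members <- paste(cl$loop_id[cl$subcluster == sid], collapse = ",")
      cmd <- gsub("{subcluster}", sid, render_cmd, fixed = TRUE)
      cmd <- gsub("{loops}", members, cmd, fixed = TRUE)
      system(cmd)
    }
  }
  invisible(file.path(outdir, "qscores.csv"))
}

#' @rdname pipeline
#' @export
stage_evaluate <- function(outdir) {
  cl <- utils::read.csv(read_required(file.path(outdir, "clusters.csv"),
                                      "evaluate"), stringsAsFactors = FALSE)
  if (is.null(cl$subcluster)) stop("evaluate stage needs subcluster output")
  loops <- read_loop_file(read_required(file.path(outdir, "loops.tsv"),
                                        "evaluate"))
  fams <- vapply(loops, function(l)
    if (is.null(l$family)) NA_character_ else l$family, character(1))
  ids <- vapply(loops, loop_id, character(1))
  if (all(is.na(fams)))
    stop("evaluate stage needs family labels in loops.tsv; none found")
  truth <- stats::setNames(fams[!is.na(fams)], ids[!is.na(fams)])
  fa <- map_clusters_to_labels(cl, truth)
  rep <- classification_report(cl, truth, fa)
  mcas <- vapply(sort(unique(truth)), function(f)
    mca(f, fa, cl, truth), numeric(1))
  truth_vec <- truth[cl$loop_id[cl$loop_id %in% names(truth)]]
  pred_vec <- cl$subcluster[cl$loop_id %in% names(truth)]
  agree <- compare_clusterings(stats::setNames(pred_vec, names(truth_vec)),
                               truth_vec)
  out <- list(accuracy = rep$accuracy, weighted = as.list(rep$weighted),
              per_family = rep$per_family, mca = as.list(mcas),
              ari = agree$ari, ami = agree$ami)
  jsonlite::write_json(out, file.path(outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame.matrix(rep$confusion),
                   file.path(outdir, "confusion.csv"))
  invisible(file.path(outdir, "evaluation.json"))
}

#' Run the whole pipeline
#'
#' Chains simulate (optional) -> encode -> train -> embed -> select-k ->
#' cluster -> subcluster -> qscore -> evaluate with one seed threaded
#' through every stage.
#'
#' @param outdir run directory.
#' @param simulate if `TRUE`, generate the synthetic corpus first;
#'   otherwise `loops.tsv`, `coords.tsv` and `manifest.csv` must already be
#'   in `outdir`.
#' @param n_per_family,loop_type,noise simulation parameters.
#' @param config a [gin_config()] (its seed is overridden by `seed`).
#' @param k_grid,smcr_max,linkage,distance_threshold clustering parameters.
#' @param seed master seed for every random stage.
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(outdir, simulate = TRUE, n_per_family = 50L,
                         loop_type = "internal", noise = noise_spec(),
                         config = gin_config(), k_grid = NULL,
                         smcr_max = 0.05, linkage = "average",
                         distance_threshold = 6, seed = 0L) {
  config$seed <- as.integer(seed)
  paths <- list()
  if (simulate)
    paths$loops <- stage_simulate(outdir, n_per_family, loop_type, noise, seed)
  paths$graphs <- stage_encode(outdir)
  paths$model <- stage_train(outdir, config)
  paths$embeddings <- stage_embed(outdir)
  paths$kselect <- stage_select_k(outdir, k_grid, smcr_max, seed)
  paths$clusters <- stage_cluster(outdir, seed = seed)
  paths$subclusters <- stage_subcluster(outdir, linkage, distance_threshold)
  paths$qscores <- stage_qscore(outdir)
  paths$evaluation <- stage_evaluate(outdir)
  invisible(paths)
}

#' Read a flat key-value run configuration file
#'
#' YAML with flat keys (paths, seed, model and clustering settings); CLI
#' flags override file values.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
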