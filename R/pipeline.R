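# End-to-end pipeline: structures -> GI vectors -> flexibility labels ->
# stratified split -> cross-validation -> retrain -> holdout evaluation.

#' Run the full structure-to-flexibility pipeline
#'
#' Reads every structure under `input_dir/structures` (PDB or mmCIF, first
#' chain by default), computes the 30-component GI vector per chain, obtains
#' per-protein RMSF either from multi-model trajectory PDBs under
#' `input_dir/trajectories` (matched by file name) or from an
#' `input_dir/rmsf.tsv` table (`protein_id`, `rmsf_scalar`), labels proteins
#' against the dataset-mean threshold, then runs the training protocol
#' (stratified holdout, k-fold cross-validation, best-fold retrain) and
#' writes `gi.tsv`, `rmsf.tsv`, `pca.tsv`, `clusters.tsv`, `report.json` to
#' `output_dir`.
#'
#' @param input_dir directory described above.
#' @param output_dir output directory (created if needed).
#' @param architecture model architecture, see [model_spec()].
#' @param task `"classification"` or `"regression"`.
#' @param config a [train_config].
#' @param paper_mode if `TRUE`, fit the variance scaler on the whole dataset
#'   rather than the training pool only.
#' @param seed integer seed (overrides `config$seed`).
#' @return Invisibly, a list with the evaluation report, cluster assignment
#'   and output paths.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         architecture = "cnn_attention",
                         task = "classification",
                         config = train_config(), paper_mode = FALSE,
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  struct_dir <- file.path(input_dir, "structures")
  if (!dir.exists(struct_dir)) {
    stop(sprintf("stage structure_io: input directory not found: %s", struct_dir),
         call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(struct_dir, pattern = "\\.(pdb|cif)$", full.names = TRUE)
  if (!length(files)) {
    stop("stage structure_io: no structure files found", call. = FALSE)
  }

  registry <- default_registry()
  gi <- do.call(rbind, lapply(files, function(f) {
    id <- sub("\\.(pdb|cif)$", "", basename(f))
    model <- tryCatch(read_structure(f), error = function(e) {
      stop(sprintf("stage structure_io [%s]: %s", id, conditionMessage(e)),
           call. = FALSE)
    })
    chain <- model$atom$chain[model$atom$type == "ATOM"][1L]
    tr <- suppressWarnings(extract_ca_trace(model, chain))
    v <- compute_gi_vector(tr, registry)
    cbind(data.frame(protein_id = id, chain = chain, n_residues = tr$n_residues),
          as.data.frame(t(v)))
  }))

  # RMSF per protein
  traj_dir <- file.path(input_dir, "trajectories")
  rmsf_tab <- file.path(input_dir, "rmsf.tsv")
  if (dir.exists(traj_dir)) {
    rmsf <- vapply(gi$protein_id, function(id) {
      tf <- list.files(traj_dir, pattern = paste0("^", id, "(_rep[0-9]+)?\\.pdb$"),
                       full.names = TRUE)
      if (!length(tf)) {
        stop(sprintf("stage dynamics [%s]: no trajectory found", id), call. = FALSE)
      }
      profiles <- lapply(tf, function(p) {
        mm <- read_structure(p)
        frames <- lapply(seq_len(nrow(mm$xyz)), function(m)
          matrix(mm$xyz[m, ], ncol = 3, byrow = TRUE))
        rmsf_profile(frames)
      })
      aggregate_rmsf(profiles)
    }, numeric(1))
  } else if (file.exists(rmsf_tab)) {
    tab <- utils::read.delim(rmsf_tab, comment.char = "#")
    rmsf <- tab$rmsf_scalar[match(gi$protein_id, tab$protein_id)]
    if (any(is.na(rmsf))) {
      stop("stage dynamics: rmsf.tsv is missing some protein ids", call. = FALSE)
    }
    names(rmsf) <- gi$protein_id
  } else {
    stop("stage dynamics: need either trajectories/ or rmsf.tsv", call. = FALSE)
  }
  labels <- flexibility_labels(rmsf)

  X_raw <- as.matrix(gi[, -(1:3)])
  rownames(X_raw) <- gi$protein_id
  y <- if (task == "classification") {
    as.integer(labels$label == "flexible")
  } else as.numeric(rmsf)

  split <- holdout_split(nrow(X_raw), config$holdout_fraction, seed = config$seed,
                         stratify_labels = if (task == "classification") y else NULL)
  if (paper_mode) {
    norm <- normalize_features(X_raw, "fit")
    Xn <- norm$X
  } else {
    norm <- normalize_features(X_raw[split$train, , drop = FALSE], "fit")
    Xn <- normalize_features(X_raw, "apply", scaler = norm$scaler)$X
  }

  pca <- gi_pca(Xn, k = 2L)
  k_clusters <- min(4L, nrow(Xn))
  clusters <- cluster_scores(pca, k = k_clusters, seed = config$seed)
  names(clusters) <- gi$protein_id

  spec <- model_spec(architecture, task, seed = config$seed)
  cvr <- cross_validate_then_retrain(Xn[split$train, , drop = FALSE], y[split$train],
                                     spec, config)
  scores <- predict(cvr$model, Xn[split$test, , drop = FALSE])
  report <- if (task == "classification") {
    eval_report(y[split$test], as.numeric(scores),
                clusters = clusters[split$test], seed = config$seed)
  } else {
    regression_metrics(y[split$test], as.numeric(scores))
  }

  hdr <- sprintf("# gaussflex %s | seed %d",
                 as.character(utils::packageVersion("gaussflex")), config$seed)
  write_with_header <- function(df, path) {
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  paths <- list(
    gi = write_with_header(gi, file.path(output_dir, "gi.tsv")),
    rmsf = write_with_header(labels, file.path(output_dir, "rmsf.tsv")),
    pca = write_with_header(
      data.frame(protein_id = gi$protein_id, pca$scores,
                 cluster = as.vector(clusters)),
      file.path(output_dir, "pca.tsv")))
  rep_out <- c(list(seed = config$seed, architecture = architecture, task = task,
                    n_train = length(split$train), n_test = length(split$test),
                    selected_fold = cvr$selected_fold,
                    fold_metrics = cvr$cv$metric),
               report_to_list(report))
  jsonlite::write_json(rep_out, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$report <- file.path(output_dir, "report.json")

  invisible(list(report = report, clusters = clusters, cv = cvr$cv,
                 split = split, paths = paths))
}

report_to_list <- function(report) {
  if (inherits(report, "eval_report")) {
    list(auc = report$auc, auc_ci = report$auc_ci,
         average_precision = report$average_precision, max_f1 = report$max_f1,
         youden_threshold = report$youden_threshold,
         confusion = as.vector(report$confusion),
         per_cluster_auc = report$per_cluster_auc)
  } else {
    report
  }
}
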