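# End-to-end orchestration: simulate/load -> embed -> split -> fit
# (augmentation inside) -> evaluate, with one global seed fanned out to
# per-stage sub-seeds and artifacts written to a run directory.

#' Pipeline run configuration
#'
#' @param profile Simulation profile name (see [downscale_profile()]), or
#'   `NULL` to load data from files.
#' @param phage_fasta,bacterium_fasta,interactions Input paths used when
#'   `profile` is `NULL`.  FASTA record ids of the form
#'   `organism|protein` are grouped into proteomes by the prefix before
#'   the `|`.
#' @param d_e,d_h Embedder dimensions.
#' @param pretrained_dir Optional directory of pretrained embedder weights;
#'   default uses seeded random weights.
#' @param holdout_fraction Stratified test fraction.
#' @param k_neighbors SMOTE neighbor count.
#' @param variant `"full"`, `"PBIP3"`, `"PBIP4"` or `"PBIP5"`.
#' @param filters,gru_hidden,attention_units,cnn_dropout,gru_dropout
#'   Architecture settings (see [model_config()]).
#' @param learning_rate,batch_size,epochs Training settings (see
#'   [train_config()]).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return List of class `pbip_run_config`.
#' @export
run_config <- function(profile = "desk", phage_fasta = NULL,
                       bacterium_fasta = NULL, interactions = NULL,
                       d_e = 10L, d_h = 16L, pretrained_dir = NULL,
                       holdout_fraction = 0.2, k_neighbors = 5L,
                       variant = "full",
                       filters = c(8L, 16L), gru_hidden = 8L,
                       attention_units = 8L, cnn_dropout = 0.5,
                       gru_dropout = 0.5,
                       learning_rate = 3e-3, batch_size = 16L,
                       epochs = 30L, seed = 1L) {
  cfg <- list(profile = profile, phage_fasta = phage_fasta,
              bacterium_fasta = bacterium_fasta, interactions = interactions,
              d_e = d_e, d_h = d_h, pretrained_dir = pretrained_dir,
              holdout_fraction = holdout_fraction,
              k_neighbors = k_neighbors, variant = variant,
              filters = filters, gru_hidden = gru_hidden,
              attention_units = attention_units, cnn_dropout = cnn_dropout,
              gru_dropout = gru_dropout, learning_rate = learning_rate,
              batch_size = batch_size, epochs = epochs, seed = seed)
  class(cfg) <- "pbip_run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Every key maps to one [run_config()] argument.
#'
#' @param path YAML file.
#' @return `pbip_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# Group a multi-record FASTA into proteomes by the id prefix before "|".
fasta_to_proteomes <- function(path, role) {
  seqs <- parse_protein_fasta(path)
  org_ids <- sub("\\|.*$", "", names(seqs))
  lapply(unique(org_ids), function(id) {
    proteome(id, role, seqs[org_ids == id])
  })
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> embed -> stratified split -> SMOTE +
#' train -> evaluate, writing every artifact (embeddings, pair tables,
#' loss history, metrics, curve points, resolved configuration snapshot
#' and a stage log) into `out_dir`.  Re-running with the same
#' configuration reproduces the metrics exactly.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @param out_dir Run directory to create/write (default: a temporary
#'   directory).
#' @param verbose Log stage progress to the console.
#' @return List of class `pbip_run`: `model`, `metrics`, `test_scores`,
#'   `split`, `data`, `embeddings`, `config`, `out_dir`, `log`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pbip_run_"),
                         verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "pbip_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pbip(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
  }

  # -- data ----------------------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$profile)) {
      sim <- generate_dataset(downscale_profile(
        config$profile, seed = stage_seed(config$seed, "simulate")))
      say("simulate: %d phages x %d bacteria, %d pairs (%d positive)",
          length(sim$phages), length(sim$bacteria), nrow(sim$table),
          sum(sim$table$label))
      sim
    } else {
      ph <- fasta_to_proteomes(config$phage_fasta, "phage")
      ba <- fasta_to_proteomes(config$bacterium_fasta, "bacterium")
      tbl <- load_interaction_table(config$interactions)
      say("load: %d phages, %d bacteria, %d pairs", length(ph), length(ba),
          nrow(tbl))
      list(phages = ph, bacteria = ba, table = tbl)
    }
  })

  # -- embed ---------------------------------------------------------------
  emb <- stage("embed", {
    params <- if (!is.null(config$pretrained_dir)) {
      load_pretrained_weights(config$pretrained_dir, config$d_e, config$d_h)
    } else {
      random_embedder_params(config$d_e, config$d_h,
                             seed = stage_seed(config$seed, "embed"))
    }
    P <- embed_organisms(data$phages, params)
    B <- embed_organisms(data$bacteria, params)
    say("embed: %d organisms -> d_h = %d", nrow(P) + nrow(B), config$d_h)
    list(phage = P, bacterium = B, params = params)
  })
  pairs <- pair_embedding_table(data$table, emb$phage, emb$bacterium)

  # -- split ---------------------------------------------------------------
  split <- stage("split", {
    k <- max(2L, round(1 / config$holdout_fraction))
    fold <- stratified_folds(pairs$y, k, stage_seed(config$seed, "split"))
    te <- fold == 1L
    say("split: %d train pairs, %d test pairs (stratified holdout)",
        sum(!te), sum(te))
    te
  })
  train_pairs <- pairs[!split]
  test_pairs <- pairs[split]

  # -- fit (augment + train) ----------------------------------------------
  mcfg <- model_config(filters = config$filters,
                       gru_hidden = config$gru_hidden,
                       attention_units = config$attention_units,
                       cnn_dropout = config$cnn_dropout,
                       gru_dropout = config$gru_dropout,
                       variant = config$variant)
  tcfg <- train_config(learning_rate = config$learning_rate,
                       batch_size = config$batch_size,
                       epochs = config$epochs)
  model <- stage("train", {
    if (config$variant == "PBIP5") say("augment: skipped (variant PBIP5)")
    m <- pbip_fit(train_pairs, config = mcfg, train = tcfg,
                  k_neighbors = config$k_neighbors,
                  seed = config$seed, verbose = verbose)
    say("train: %d pairs in (%d synthetic added), %d epochs, final loss %.4f",
        m$n_train, m$n_synthetic, config$epochs,
        utils::tail(m$loss_history, 1L))
    m
  })

  # -- evaluate ------------------------------------------------------------
  metrics <- stage("evaluate", {
    sc <- predict(model, test_pairs)
    r <- evaluate_predictions(sc, test_pairs$y)
    say("evaluate: %d pairs out, accuracy %.3f, MCC %.3f, AUC %.3f",
        length(sc), r$metrics["accuracy"], r$metrics["mcc"],
        r$metrics["auc"])
    list(report = r, scores = sc)
  })

  # -- artifacts -----------------------------------------------------------
  emb_df <- function(M, role) {
    data.frame(id = rownames(M), role = role, unname(as.data.frame(M)))
  }
  utils::write.csv(rbind(emb_df(emb$phage, "phage"),
                         emb_df(emb$bacterium, "bacterium")),
                   file.path(out_dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(phage_id = test_pairs$phage_id,
                              bacterium_id = test_pairs$bacterium_id,
                              score = metrics$scores,
                              label = test_pairs$y),
                   file.path(out_dir, "test_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(epoch = seq_along(model$loss_history),
                              loss = model$loss_history),
                   file.path(out_dir, "loss_history.csv"), row.names = FALSE)
  utils::write.csv(data.frame(metric = names(metrics$report$metrics),
                              value = unname(metrics$report$metrics)),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(metrics$report$roc_curve,
                   file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
  utils::write.csv(metrics$report$pr_curve,
                   file.path(out_dir, "pr_curve.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  structure(list(model = model, metrics = metrics$report,
                 test_scores = metrics$scores, split = split,
                 data = data, embeddings = emb[c("phage", "bacterium")],
                 config = config, out_dir = out_dir, log = log_lines),
            class = "pbip_run")
}

#' @export
print.pbip_run <- function(x, ...) {
  cat("<pbip_run>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat(sprintf("  artifacts: %s\n", x$out_dir))
  invisible(x)
}
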