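# Planted-motif synthetic data: desk-scale proteomes whose interaction
# labels follow a known motif-compatibility rule, so the whole pipeline is
# testable without external data.

#' Simulation configuration
#'
#' Each organism receives a latent motif class; one fixed motif string per
#' class is inserted at a random position into one of the organism's
#' otherwise-random proteins.  A pair's label is
#' `compatibility[phage class, bacterium class]`, optionally flipped with
#' probability `noise_rate`.  The default compatibility is a rank-1
#' "receptor" rule -- only class-1 phages infect, and only class-1 bacteria
#' are susceptible -- and the class-1 assignment probabilities are solved
#' from `positive_rate_target` so the matrix matches the sparse positive
#' rate of real strain-level infection data.
#'
#' @param n_phages,n_bacteria Organism counts.
#' @param proteins_per_organism Inclusive range, e.g. `c(3, 6)`.
#' @param protein_length Inclusive residue-count range, e.g. `c(80, 200)`.
#' @param n_motif_classes Number of latent motif classes.
#' @param motif_length Inserted motif length (default 8).
#' @param compatibility Binary `n_motif_classes` square matrix; default has
#'   a single 1 at `[1, 1]`.
#' @param background_frequencies 20 residue probabilities (alphabet order
#'   of [AA_ALPHABET20]); default uniform.
#' @param positive_rate_target Desired expected positive fraction (used to
#'   set class probabilities under the default rank-1 compatibility).
#' @param noise_rate Independent label-flip probability.
#' @param phage_class_probs,bacterium_class_probs Optional explicit class
#'   probability vectors (override the rate-derived ones).
#' @param seed Integer seed.
#' @return An object of class `pbip_sim_config`.
#' @export
simulation_config <- function(n_phages = 40L, n_bacteria = 40L,
                              proteins_per_organism = c(3L, 6L),
                              protein_length = c(80L, 200L),
                              n_motif_classes = 4L, motif_length = 8L,
                              compatibility = NULL,
                              background_frequencies = rep(1 / 20, 20L),
                              positive_rate_target = 0.0722,
                              noise_rate = 0,
                              phage_class_probs = NULL,
                              bacterium_class_probs = NULL,
                              seed = 1L) {
  K <- as.integer(n_motif_classes)
  stopifnot(n_phages >= 1L, n_bacteria >= 1L, K >= 1L, motif_length >= 1L,
            length(proteins_per_organism) == 2L, length(protein_length) == 2L,
            noise_rate >= 0, noise_rate <= 1,
            length(background_frequencies) == 20L,
            all(background_frequencies >= 0))
  if (abs(sum(background_frequencies) - 1) > 1e-9) {
    stop_pbip("background frequencies must sum to 1")
  }
  if (motif_length > protein_length[1]) {
    stop_pbip(sprintf("motif length %d exceeds minimum protein length %d",
                      motif_length, protein_length[1]))
  }
  default_compat <- is.null(compatibility)
  if (default_compat) {
    compatibility <- matrix(0L, K, K)
    compatibility[1L, 1L] <- 1L
  }
  stopifnot(identical(dim(compatibility), c(K, K)),
            all(compatibility %in% c(0L, 1L)))
  solve_probs <- function() {
    # rank-1 default: rate = P(phage class 1) * P(bacterium class 1)
    p1 <- sqrt(positive_rate_target)
    if (K == 1L) return(1)
    c(p1, rep((1 - p1) / (K - 1L), K - 1L))
  }
  if (is.null(phage_class_probs)) {
    phage_class_probs <- if (default_compat) solve_probs() else rep(1 / K, K)
  }
  if (is.null(bacterium_class_probs)) {
    bacterium_class_probs <- if (default_compat) solve_probs() else rep(1 / K, K)
  }
  stopifnot(length(phage_class_probs) == K,
            length(bacterium_class_probs) == K)
  structure(list(n_phages = as.integer(n_phages),
                 n_bacteria = as.integer(n_bacteria),
                 proteins_per_organism = as.integer(proteins_per_organism),
                 protein_length = as.integer(protein_length),
                 n_motif_classes = K,
                 motif_length = as.integer(motif_length),
                 compatibility = compatibility,
                 background_frequencies = background_frequencies,
                 positive_rate_target = positive_rate_target,
                 noise_rate = noise_rate,
                 phage_class_probs = phage_class_probs,
                 bacterium_class_probs = bacterium_class_probs,
                 seed = as.integer(seed)),
            class = "pbip_sim_config")
}

#' Preset simulation profiles
#'
#' `"unit"`: 6 x 6 organisms, 2 proteins each of 30-60 residues (fast unit
#' tests, positive rate 0.25).  `"desk"`: 40 x 40 organisms, 3-6 proteins
#' of 80-200 residues, positive rate ~7.2% (full-pipeline runs on one
#' CPU).  `"paper-shape"`: 104 phages x 120 bacteria with the same ~7.2%
#' positive rate, mimicking the shape of the strain-level infection
#' matrix.
#'
#' @param name Profile name.
#' @param seed Integer seed stored in the config.
#' @return A [simulation_config()].
#' @export
downscale_profile <- function(name = c("unit", "desk", "paper-shape"),
                              seed = 1L) {
  name <- match.arg(name)
  switch(name,
    unit = simulation_config(n_phages = 6L, n_bacteria = 6L,
                             proteins_per_organism = c(2L, 2L),
                             protein_length = c(30L, 60L),
                             positive_rate_target = 0.25, seed = seed),
    desk = simulation_config(n_phages = 40L, n_bacteria = 40L,
                             proteins_per_organism = c(3L, 6L),
                             protein_length = c(80L, 200L),
                             positive_rate_target = 0.0722, seed = seed),
    `paper-shape` = simulation_config(n_phages = 104L, n_bacteria = 120L,
                                      proteins_per_organism = c(3L, 6L),
                                      protein_length = c(80L, 200L),
                                      positive_rate_target = 0.0722,
                                      seed = seed))
}

sample_residues <- function(n, freqs) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE, prob = freqs), collapse = "")
}

#' Generate a planted-motif dataset
#'
#' Draws one proteome per organism with background residues from the
#' configured frequencies, inserts the organism's class motif into one
#' protein at a random position, and emits the complete interaction matrix
#' labeled by the compatibility rule (with optional label noise).  All
#' randomness comes from `config$seed`, so the output is byte-identical
#' across runs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes
#'   `phages.faa` / `bacteria.faa` (record ids `organism|protein`),
#'   `interactions.csv` and `ground_truth.csv` into it.
#' @return List of class `pbip_sim_data`: `phages`, `bacteria` (lists of
#'   [proteome()]), `table` (`pbip_interactions`), `truth` (data frame
#'   `organism_id`, `role`, `motif_class`, `protein_index`,
#'   `insert_position`), `motifs` (class motif strings), `config`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pbip_sim_config"))
  with_seed(config$seed, {
    K <- config$n_motif_classes
    motifs <- character(K)
    repeat {
      for (i in seq_len(K)) {
        motifs[i] <- sample_residues(config$motif_length,
                                     config$background_frequencies)
      }
      if (!anyDuplicated(motifs)) break
    }
    make_side <- function(n, prefix, role, class_probs) {
      ids <- sprintf("%s%03d", prefix, seq_len(n))
      classes <- sample.int(K, n, replace = TRUE, prob = class_probs)
      orgs <- vector("list", n)
      truth <- data.frame(organism_id = ids, role = role,
                          motif_class = classes, protein_index = 0L,
                          insert_position = 0L)
      for (i in seq_len(n)) {
        np <- sample(config$proteins_per_organism[1]:config$proteins_per_organism[2], 1L)
        lens <- sample(config$protein_length[1]:config$protein_length[2],
                       np, replace = TRUE)
        prots <- vapply(lens, sample_residues, character(1),
                        freqs = config$background_frequencies)
        carrier <- sample.int(np, 1L)
        pos <- sample.int(lens[carrier] - config$motif_length + 1L, 1L)
        substr(prots[carrier], pos, pos + config$motif_length - 1L) <-
          motifs[classes[i]]
        names(prots) <- sprintf("%s|p%02d", ids[i], seq_len(np))
        orgs[[i]] <- proteome(ids[i], role, prots)
        truth$protein_index[i] <- carrier
        truth$insert_position[i] <- pos
      }
      list(orgs = orgs, classes = classes, truth = truth, ids = ids)
    }
    ph <- make_side(config$n_phages, "PH", "phage", config$phage_class_probs)
    ba <- make_side(config$n_bacteria, "BA", "bacterium",
                    config$bacterium_class_probs)
    grid <- expand.grid(p = seq_len(config$n_phages),
                        b = seq_len(config$n_bacteria))
    y <- config$compatibility[cbind(ph$classes[grid$p], ba$classes[grid$b])]
    if (config$noise_rate > 0) {
      flip <- stats::runif(length(y)) < config$noise_rate
      y <- ifelse(flip, 1L - y, y)
    }
    table <- interaction_table(data.frame(phage_id = ph$ids[grid$p],
                                          bacterium_id = ba$ids[grid$b],
                                          label = as.integer(y)))
    out <- structure(list(phages = ph$orgs, bacteria = ba$orgs,
                          table = table,
                          truth = rbind(ph$truth, ba$truth),
                          motifs = motifs, config = config),
                     class = "pbip_sim_data")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      all_prot <- function(orgs) do.call(c, lapply(orgs, `[[`, "proteins"))
      write_protein_fasta(all_prot(ph$orgs), file.path(out_dir, "phages.faa"))
      write_protein_fasta(all_prot(ba$orgs), file.path(out_dir, "bacteria.faa"))
      utils::write.csv(as.data.frame(table),
                       file.path(out_dir, "interactions.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(out$truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    out
  })
}

#' @export
print.pbip_sim_data <- function(x, ...) {
  cat(sprintf(
    "<pbip_sim_data> %d phages x %d bacteria, %d records (%.1f%% positive), %d motif classes\n",
    length(x$phages), length(x$bacteria), nrow(x$table),
    100 * mean(x$table$label), x$config$n_motif_classes))
  invisible(x)
}
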