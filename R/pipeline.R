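#' Configuration of a full analysis run
#'
#' Exactly one of `simulation_spec` (a [family_spec()], for the synthetic
#' path) or `inputs` (paths to an aligned FASTA, a Newick tree, and a label
#' TSV) must be supplied. A single master seed is fanned out to per-stage
#' seeds as `seed + stage index`, so stages are reproducible independently.
#'
#' @param simulation_spec A [family_spec()], or `NULL`.
#' @param inputs List with `alignment`, `tree`, `labels`, `reference`, and
#'   optionally `positions` (active-site reference positions), or `NULL`.
#' @param seed Master seed.
#' @param dist_config A [distribution_config()].
#' @param training A [train_config()]; its seed is derived from the master
#'   seed.
#' @param asr_nodes Internal-node names to reconstruct and classify;
#'   default the named ancestors AncA-AncE of the synthetic topology.
#' @param n_bayes_samples Bayesian ancestor draws per node (default 100).
#' @param output_dir Directory for stage outputs; `NULL` keeps everything
#'   in memory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation_spec = family_spec(), inputs = NULL,
                       seed = 1L, dist_config = distribution_config(),
                       training = NULL,
                       asr_nodes = c("AncA", "AncB", "AncC", "AncD", "AncE"),
                       n_bayes_samples = 100L, output_dir = NULL) {
  if (is.null(simulation_spec) == is.null(inputs)) {
    stop("exactly one of 'simulation_spec' or 'inputs' must be supplied")
  }
  seed <- as.integer(seed)
  if (is.null(training)) training <- train_config(seed = seed + 4L)
  stopifnot(inherits(training, "train_config"))
  structure(list(simulation_spec = simulation_spec, inputs = inputs,
                 seed = seed, dist_config = dist_config, training = training,
                 asr_nodes = asr_nodes,
                 n_bayes_samples = as.integer(n_bayes_samples),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full metal-dependence analysis
#'
#' Executes the stages in dependency order: family simulation (or input
#' loading), active-site extraction, marginal ancestral reconstruction with
#' support summaries and Bayesian sampling, feature encoding, classifier
#' training with replicated out-of-sample evaluation, classification of
#' uncharacterized and ancestral sequences under both the sequence encoding
#' and the posterior-distribution encoding, PCA separability, identity
#' comparisons at active-site and full scope, and pocket volumes of the
#' analytic receptor fixtures. Fails at the first stage error; a fixed seed
#' gives an identical report.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report` (a list of per-stage results).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  model <- substitution_model()

  # stage 1: data
  if (!is.null(config$simulation_spec)) {
    spec <- config$simulation_spec
    spec$seed <- spec$seed + config$seed
    fam <- generate_family(spec, model)
    alignment <- fam$alignment
    tree <- fam$tree
    positions <- spec$plan$positions
    clades <- fam$truth$clades
  } else {
    alignment <- read_labeled_alignment(config$inputs$alignment,
                                        config$inputs$labels,
                                        config$inputs$reference)
    tree <- ape::read.tree(config$inputs$tree)
    positions <- config$inputs$positions
    if (is.null(positions)) stop("stage data: 'inputs$positions' is required")
    clades <- alignment$labels
    fam <- NULL
  }

  # stage 2: active-site extraction
  active <- extract_active_site(alignment, positions)
  columns <- alignment_columns(alignment, positions)

  # stage 3: ancestral reconstruction
  post <- site_posteriors(tree, alignment, model)
  nodes <- intersect(config$asr_nodes, names(post$posteriors))
  if (length(nodes) == 0) stop("stage asr: none of the requested nodes exist")
  support <- lapply(nodes, function(nd) {
    list(full = posterior_support_summary(post, nd),
         active_site = posterior_support_summary(post, nd, columns))
  })
  names(support) <- nodes
  ml_seqs <- vapply(nodes, function(nd) as.character(ml_ancestor(post, nd)),
                    character(1))
  bayes <- lapply(seq_along(nodes), function(i) {
    sample_ancestors(post, nodes[i], config$n_bayes_samples,
                     seed = config$seed + 30L + i)
  })
  names(bayes) <- nodes

  # stage 4: encoding + training
  labeled <- alignment$labels != "unknown"
  X <- encode_extant(active, model, config$dist_config)
  clf <- train_metal_classifier(X[labeled, , drop = FALSE],
                                alignment$labels[labeled], config$training)

  # stage 5: classification of uncharacterized and ancestral sequences
  unk <- classify_metal(clf, X[!labeled, , drop = FALSE])
  anc_seq_aln <- labeled_alignment(
    vapply(ml_seqs, function(s) paste(strsplit(s, "")[[1]][columns],
                                      collapse = ""), character(1)))
  anc_X_seq <- encode_extant(anc_seq_aln, model, config$dist_config)
  anc_seq_cls <- classify_metal(clf, anc_X_seq)
  anc_post_cls <- do.call(rbind, lapply(nodes, function(nd) {
    classify_metal(clf, encode_ancestor(post, nd, columns,
                                        on_gap = "regularizer",
                                        model = model,
                                        config = config$dist_config))
  }))
  pca <- pca_separability(X[labeled, , drop = FALSE],
                          alignment$labels[labeled])

  # stage 6: identity comparisons
  ident_active <- group_mean_identity(alignment, clades, "active-site",
                                      positions = positions)
  ident_full <- group_mean_identity(alignment, clades, "full")
  uniq <- unique_residues(active)

  # stage 7: pocket volumes on analytic fixtures
  shell <- generate_pocket_fixture("sphere-shell", list(radius = 8))
  chambers <- generate_pocket_fixture("two-chamber",
                                      list(radius_a = 8, radius_b = 5.5))
  vol_shell <- pocket_volume(shell$structure, shell$region)
  vol_chambers <- pocket_volume(chambers$structure, chambers$region)

  report <- structure(list(
    seed = config$seed,
    replicate_accuracy = clf$replicate_report,
    classifier = clf,
    unknown_classification = unk,
    ancestor_classification = list(sequence_encoding = anc_seq_cls,
                                   posterior_encoding = anc_post_cls),
    ml_ancestors = ml_seqs,
    bayes_ancestors = bayes,
    support = support,
    pca = pca,
    identity = list(active_site = ident_active, full = ident_full),
    unique_residues = uniq,
    pocket = list(shell = list(volume = vol_shell$volume,
                               expected = shell$expected_volume),
                  two_chamber = list(volume = vol_chambers$volume,
                                     expected = chambers$expected_volume)),
    truth = if (!is.null(fam)) fam$truth else NULL),
    class = "run_report")

  if (!is.null(config$output_dir)) {
    write_run_outputs(report, alignment, tree, config)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, ")\n", sep = "")
  cat("  replicate out-of-sample accuracy: ",
      paste(format(x$replicate_accuracy$accuracy), collapse = " "), "\n")
  cat("  ancestor labels (posterior encoding): ",
      paste(x$ancestor_classification$posterior_encoding$name,
            x$ancestor_classification$posterior_encoding$predicted,
            sep = "=", collapse = " "), "\n")
  cat("  unique residues recovered:", nrow(x$unique_residues), "\n")
  invisible(x)
}

write_run_outputs <- function(report, alignment, tree, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  write_labeled_alignment(alignment, out("alignment.fasta"), out("labels.tsv"))
  ape::write.tree(tree, out("tree.nwk"))
  utils::write.table(report$replicate_accuracy, out("replicate_accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$unique_residues, out("unique_residues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(group = rownames(report$identity$active_site$group_mean),
          as.data.frame(report$identity$active_site$group_mean)),
    out("identity_active_site.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    cbind(group = rownames(report$identity$full$group_mean),
          as.data.frame(report$identity$full$group_mean)),
    out("identity_full.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  anc <- rbind(cbind(encoding = "sequence",
                     report$ancestor_classification$sequence_encoding),
               cbind(encoding = "posterior",
                     report$ancestor_classification$posterior_encoding))
  utils::write.table(anc, out("ancestor_classification.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", names(report$ml_ancestors), "\n",
                    unname(report$ml_ancestors)), out("ml_ancestors.fasta"))
  invisible(config$output_dir)
}

#' Write a reproducibility manifest for a completed run
#'
#' Lists the run's seed, configuration fingerprint, and an md5 checksum per
#' output file, so any later rerun (or tampering) is detectable with
#' [verify_manifest()].
#'
#' @param config The [run_config()] used (must have `output_dir` set).
#' @param path Manifest path; default `manifest.json` inside the output
#'   directory.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$output_dir)) stop("config has no output_dir")
  if (is.null(path)) path <- file.path(config$output_dir, "manifest.json")
  files <- setdiff(list.files(config$output_dir, full.names = TRUE),
                   file.path(config$output_dir, "manifest.json"))
  sums <- tools::md5sum(files)
  cfg_repr <- paste(deparse(config[c("seed", "asr_nodes",
                                     "n_bayes_samples")]), collapse = "")
  tf <- tempfile()
  writeLines(cfg_repr, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config_hash = cfg_hash,
    outputs = lapply(seq_along(sums), function(i) {
      list(file = basename(files[i]), md5 = unname(sums[i]))
    }))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Verify the outputs listed in a run manifest
#'
#' @param path Manifest path.
#' @return `TRUE` when every checksum matches; otherwise an error naming the
#'   first mismatching file.
#' @export
verify_manifest <- function(path) {
  manifest <- jsonlite::read_json(path)
  dir <- dirname(path)
  for (entry in manifest$outputs) {
    f <- file.path(dir, entry$file)
    if (!file.exists(f)) stop("manifest output missing: ", entry$file)
    if (unname(tools::md5sum(f)) != entry$md5) {
      stop("checksum mismatch for ", entry$file)
    }
  }
  TRUE
}
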