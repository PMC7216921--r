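#' Encode extant active-site sequences as probability features
#'
#' Each sequence row becomes the concatenation, in site order, of the
#' three-component amino-acid distributions ([site_distribution()]) of its
#' active-site residues: one 20-probability block per site.
#'
#' @param active_site_alignment A [labeled_alignment()] restricted to the
#'   active-site columns (e.g. from [extract_active_site()]).
#' @param model A [substitution_model()].
#' @param config A [distribution_config()].
#' @return Numeric matrix (sequences x 20*sites) with row names from the
#'   alignment and the site order stored in attribute `"positions"`.
#' @export
encode_extant <- function(active_site_alignment, model,
                          config = distribution_config()) {
  stopifnot(inherits(active_site_alignment, "labeled_alignment"))
  m <- alignment_matrix(active_site_alignment)
  n_sites <- ncol(m)
  # site_distribution is memoized over the observed residue: identical
  # residues share one distribution, so precompute per unique character
  chars <- sort(unique(as.vector(m)))
  lookup <- vapply(chars, function(ch) site_distribution(ch, model, config),
                   numeric(20))
  X <- matrix(NA_real_, nrow(m), 20 * n_sites)
  rownames(X) <- rownames(m)
  for (s in seq_len(n_sites)) {
    block <- t(lookup[, match(m[, s], chars), drop = FALSE])
    X[, (20 * (s - 1) + 1):(20 * s)] <- block
  }
  colnames(X) <- paste0("p", rep(seq_len(n_sites), each = 20), "_",
                        rep(amino_acids(), n_sites))
  pos <- attr(active_site_alignment, "positions")
  attr(X, "positions") <- if (is.null(pos)) seq_len(n_sites) else pos
  X
}

#' Encode a reconstructed ancestor from its site posteriors
#'
#' The ancestral feature row uses the marginal posterior distributions at
#' the active-site alignment columns directly as the 20-probability blocks;
#' no re-averaging is applied, so reconstruction uncertainty is carried into
#' classification.
#'
#' @param posteriors An `asr_posteriors` object.
#' @param node Internal node name or number.
#' @param columns Alignment column indices of the active-site positions (see
#'   [alignment_columns()]).
#' @param on_gap Policy for gap-flagged active-site positions: `"error"`
#'   (default) or `"regularizer"`, which substitutes the diffuse background
#'   distribution.
#' @param model,config Used only to resolve the regularizer when
#'   `on_gap = "regularizer"`.
#' @return One-row feature matrix compatible with [encode_extant()] output.
#' @export
encode_ancestor <- function(posteriors, node, columns,
                            on_gap = c("error", "regularizer"),
                            model = NULL, config = distribution_config()) {
  stopifnot(inherits(posteriors, "asr_posteriors"))
  on_gap <- match.arg(on_gap)
  node <- resolve_node(posteriors, node)
  post <- posteriors$posteriors[[node]]
  gap <- posteriors$gap_flags[[node]][columns]
  rows <- post[columns, , drop = FALSE]
  if (any(gap)) {
    if (on_gap == "error") {
      stop("ancestor '", node, "' is gap-flagged at active-site column(s) ",
           paste(columns[gap], collapse = ", "),
           "; set on_gap = \"regularizer\" to substitute the diffuse background")
    }
    if (is.null(model)) stop("'model' required for the regularizer fallback")
    rows[gap, ] <- matrix(resolve_regularizer(model, config), sum(gap), 20,
                          byrow = TRUE)
  }
  X <- matrix(as.vector(t(rows)), nrow = 1)
  rownames(X) <- node
  colnames(X) <- paste0("p", rep(seq_along(columns), each = 20), "_",
                        rep(amino_acids(), length(columns)))
  X
}

#' Training configuration for the metal-dependence classifier
#'
#' @param train_fraction Fraction of labeled data used for training in each
#'   evaluation replicate (default 0.6, i.e. a 60/40 split).
#' @param n_replicates Number of random split/train/test replicates
#'   (default 10).
#' @param cv_folds Folds for the cross-validated choice of the
#'   regularization parameter (default 5).
#' @param C_grid Candidate regularization (cost) values.
#' @param seed Integer seed controlling splits, folds, and hence the whole
#'   training procedure.
#' @param stratified Stratify the train/test split by class (off by
#'   default; the plain split mirrors an unstratified random division).
#' @return Object of class `train_config`.
#' @export
train_config <- function(train_fraction = 0.6, n_replicates = 10,
                         cv_folds = 5, C_grid = c(0.1, 1, 10, 100),
                         seed = 1L, stratified = FALSE) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie strictly between 0 and 1")
  }
  if (cv_folds < 2) stop("'cv_folds' must be at least 2")
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  if (any(C_grid <= 0)) stop("'C_grid' values must be positive")
  structure(list(train_fraction = train_fraction, n_replicates = n_replicates,
                 cv_folds = cv_folds, C_grid = C_grid, seed = as.integer(seed),
                 stratified = stratified),
            class = "train_config")
}

#' Class weights from label frequencies
#'
#' The weight for samples of cofactor class `c` is
#' `n_samples / (n_classes * count(c))`, the inverse-frequency convention
#' that balances the three metal classes.
#'
#' @param labels Character or factor vector of class labels.
#' @param n_classes Number of classes in the weighting denominator; default
#'   the number of distinct labels observed.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels, n_classes = length(unique(labels))) {
  counts <- table(as.character(labels))
  w <- length(labels) / (n_classes * as.numeric(counts))
  stats::setNames(w, names(counts))
}

#' Radial-basis kernel coefficient
#'
#' `gamma = 1 / (n_features * Var(features))`, with `Var(features)` the
#' population variance of the pooled training feature matrix.
#'
#' @param features Numeric feature matrix.
#' @return Scalar kernel coefficient.
#' @export
rbf_gamma <- function(features) {
  v <- mean((features - mean(features))^2)
  if (v <= 0) stop("features have zero variance; kernel coefficient undefined")
  1 / (ncol(features) * v)
}

fit_ovr <- function(X, y, C, gamma, weights) {
  classes <- sort(unique(y))
  fits <- lapply(classes, function(cl) {
    ybin <- factor(ifelse(y == cl, cl, ".rest"), levels = c(cl, ".rest"))
    n_pos <- sum(y == cl)
    # rest weight = average per-sample weight of the pooled negatives
    w_rest <- sum(weights[setdiff(names(weights), cl)] *
                    table(y)[setdiff(names(weights), cl)]) /
      (length(y) - n_pos)
    cw <- stats::setNames(c(weights[[cl]], w_rest), c(cl, ".rest"))
    e1071::svm(X, ybin, scale = FALSE, kernel = "radial", gamma = gamma,
               cost = C, class.weights = cw)
  })
  names(fits) <- classes
  fits
}

ovr_decision <- function(fits, X) {
  d <- vapply(names(fits), function(cl) {
    pred <- stats::predict(fits[[cl]], X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")[, 1]
    # e1071 signs decision values toward the first factor level; the first
    # level is always the positive class here, but guard against flips
    if (colnames(attr(pred, "decision.values"))[1] != paste0(cl, "/.rest")) dv <- -dv
    dv
  }, numeric(nrow(X)))
  if (nrow(X) == 1) d <- matrix(d, 1, dimnames = list(rownames(X), names(fits)))
  d
}

cv_choose_C <- function(X, y, config, gamma, weights) {
  # stratified folds so every fold's training part keeps all classes
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
  }
  acc <- vapply(config$C_grid, function(C) {
    hits <- 0L
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) next
      fits <- fit_ovr(X[tr, , drop = FALSE], y[tr], C, gamma, weights)
      d <- ovr_decision(fits, X[!tr, , drop = FALSE])
      pred <- colnames(d)[max.col(d, ties.method = "first")]
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  config$C_grid[which.max(acc)]  # ties resolve to the smallest C
}

#' Train the metal-dependence support-vector classifier
#'
#' Trains a weighted one-versus-rest support-vector classifier with a radial
#' basis kernel on active-site probability features. Each evaluation
#' replicate draws a random train/test split (default 60/40), computes class
#' weights and the kernel coefficient on the training split, chooses the
#' regularization parameter by cross-validation, and records out-of-sample
#' accuracy. The deployed model is refit on all labeled data after the
#' evaluation replicates; the final replicate's evaluation model is retained
#' alongside it.
#'
#' @param features Feature matrix from [encode_extant()]; rows with label
#'   `"unknown"` must be removed beforehand.
#' @param labels Class labels (`Nif`/`Vnf`/`Anf`), one per feature row.
#' @param config A [train_config()].
#' @return Object of class `metal_classifier` with the deployed one-vs-rest
#'   fits, classes, kernel coefficient, class weights, chosen cost, the
#'   replicate accuracy report, and the last evaluation model.
#' @export
train_metal_classifier <- function(features, labels, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  y <- as.character(labels)
  if (length(y) != nrow(features)) stop("one label per feature row required")
  counts <- table(y)
  if (length(counts) < 2) stop("training requires at least 2 classes")
  if (any(counts < 2)) {
    stop("class with fewer than 2 members: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  set.seed(config$seed)
  n <- length(y)
  n_train <- max(2L, floor(config$train_fraction * n))
  replicates <- vector("list", config$n_replicates)
  last_model <- NULL
  for (r in seq_len(config$n_replicates)) {
    repeat {
      tr_idx <- if (config$stratified) {
        unlist(lapply(unique(y), function(cl) {
          idx <- which(y == cl)
          sample(idx, max(1L, round(config$train_fraction * length(idx))))
        }))
      } else {
        sample(n, n_train)
      }
      # resample in the rare event a split drops a class entirely
      if (length(unique(y[tr_idx])) == length(counts) &&
          all(table(y[tr_idx]) >= 2)) break
    }
    Xtr <- features[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    w <- class_weights(ytr, n_classes = length(counts))
    gamma <- rbf_gamma(Xtr)
    C <- cv_choose_C(Xtr, ytr, config, gamma, w)
    fits <- fit_ovr(Xtr, ytr, C, gamma, w)
    d <- ovr_decision(fits, features[-tr_idx, , drop = FALSE])
    pred <- colnames(d)[max.col(d, ties.method = "first")]
    replicates[[r]] <- list(C = C, accuracy = mean(pred == y[-tr_idx]),
                            n_train = length(tr_idx),
                            n_test = n - length(tr_idx))
    last_model <- list(fits = fits, gamma = gamma, weights = w, C = C)
  }
  # deployment model: refit on 100% of the labeled data
  w_all <- class_weights(y, n_classes = length(counts))
  gamma_all <- rbf_gamma(features)
  C_all <- cv_choose_C(features, y, config, gamma_all, w_all)
  fits_all <- fit_ovr(features, y, C_all, gamma_all, w_all)
  structure(
    list(fits = fits_all, classes = sort(unique(y)), gamma = gamma_all,
         class_weights = w_all, C = C_all,
         replicate_report = data.frame(
           replicate = seq_len(config$n_replicates),
           C = vapply(replicates, `[[`, numeric(1), "C"),
           accuracy = vapply(replicates, `[[`, numeric(1), "accuracy")),
         evaluation_model = last_model, config = config),
    class = "metal_classifier")
}

#' @export
print.metal_classifier <- function(x, ...) {
  cat("metal_classifier: one-vs-rest RBF SVM over",
      length(x$classes), "classes (", paste(x$classes, collapse = ", "), ")\n")
  cat("  gamma =", format(x$gamma), " C =", x$C, "\n")
  cat("  replicate out-of-sample accuracy:",
      paste(format(x$replicate_report$accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Classify feature rows with hyperplane-distance support
#'
#' Applies the one-versus-rest decision rule: each row is assigned the class
#' whose defining hyperplane it lies furthest on the positive side of, and
#' the signed distance to every class hyperplane is reported as
#' classification support (greater distance, greater support).
#'
#' @param classifier A [train_metal_classifier()] result.
#' @param feature_rows Feature matrix with the training dimensionality.
#' @return Data frame with `name`, `predicted`, and one signed-distance
#'   column per class.
#' @export
classify_metal <- function(classifier, feature_rows) {
  stopifnot(inherits(classifier, "metal_classifier"))
  sv_dim <- ncol(classifier$fits[[1]]$SV)
  if (ncol(feature_rows) != sv_dim) {
    stop("feature dimensionality ", ncol(feature_rows),
         " does not match training dimensionality ", sv_dim)
  }
  d <- ovr_decision(classifier$fits, feature_rows)
  pred <- colnames(d)[max.col(d, ties.method = "first")]
  nm <- rownames(feature_rows)
  if (is.null(nm)) nm <- paste0("row", seq_len(nrow(feature_rows)))
  out <- data.frame(name = nm, predicted = pred, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(d))
}

#' Principal-component separability of the metal classes
#'
#' Projects the features onto principal components and reports, for each
#' contrast, the smallest number of leading components on which the two
#' groups are perfectly linearly separable: at one component this is a
#' threshold test on disjoint score ranges; at two or more a hard linear
#' boundary is sought (a linear support-vector machine at a very large cost
#' must reach zero training errors).
#'
#' @param features Feature matrix.
#' @param labels Class labels per row.
#' @param contrasts List of two-element lists naming the label groups to
#'   contrast; default Nif vs Vnf+Anf and Vnf vs Anf.
#' @param max_k Largest number of components to try (default 3).
#' @return Data frame with one row per contrast: `contrast` and
#'   `min_components` (`NA` when not separable within `max_k`).
#' @export
pca_separability <- function(features, labels,
                             contrasts = list(
                               list(a = "Nif", b = c("Vnf", "Anf")),
                               list(a = "Vnf", b = "Anf")),
                             max_k = 3) {
  y <- as.character(labels)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  scores <- pc$x
  res <- lapply(contrasts, function(ct) {
    ia <- y %in% ct$a
    ib <- y %in% ct$b
    if (!any(ia) || !any(ib)) stop("contrast group absent from labels")
    min_k <- NA_integer_
    for (k in seq_len(min(max_k, ncol(scores)))) {
      sep <- if (k == 1) {
        max(scores[ia, 1]) < min(scores[ib, 1]) ||
          max(scores[ib, 1]) < min(scores[ia, 1])
      } else {
        S <- scores[ia | ib, seq_len(k), drop = FALSE]
        g <- factor(ifelse(ia[ia | ib], "a", "b"))
        fit <- e1071::svm(S, g, scale = FALSE, kernel = "linear", cost = 1e6)
        all(stats::predict(fit, S) == g)
      }
      if (sep) { min_k <- k; break }
    }
    data.frame(contrast = paste(paste(ct$a, collapse = "+"), "vs",
                                paste(ct$b, collapse = "+")),
               min_components = min_k, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
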