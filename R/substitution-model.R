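#' @useDynLib paleonif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in the fixed order used throughout the
#' package (the order of the shipped rate-table file): A R N D C Q E G H I L K
#' M F P S T W Y V. All probability vectors, feature blocks, and posterior
#' matrices are indexed in this order.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Read an amino-acid exchangeability table in PAML dat layout
#'
#' Parses the plain-text layout used by the classic PAML model files: 19 rows
#' forming the lower triangle of the symmetric 20x20 exchangeability matrix,
#' followed by a row of 20 equilibrium frequencies. Comment lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the table file.
#' @return List with `exchangeabilities` (symmetric 20x20 matrix) and
#'   `equilibrium_freqs` (named 20-vector summing to 1).
#' @export
read_paml_matrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 20) {
    stop("expected 19 lower-triangle rows plus one frequency row in ", path)
  }
  aa <- amino_acids()
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (i in 2:20) {
    vals <- as.numeric(strsplit(lines[i - 1], "[[:space:]]+")[[1]])
    if (length(vals) != i - 1 || anyNA(vals)) {
      stop("malformed lower-triangle row ", i - 1, " in ", path)
    }
    S[i, seq_len(i - 1)] <- vals
  }
  S <- S + t(S)
  freqs <- as.numeric(strsplit(lines[20], "[[:space:]]+")[[1]])
  if (length(freqs) != 20 || anyNA(freqs) || any(freqs <= 0)) {
    stop("malformed frequency row in ", path)
  }
  freqs <- freqs / sum(freqs)
  names(freqs) <- aa
  list(exchangeabilities = S, equilibrium_freqs = freqs)
}

#' Construct a reversible amino-acid substitution model
#'
#' Builds a general time-reversible rate matrix `Q` from an exchangeability
#' matrix `S` and equilibrium frequencies `pi`, with `q_ij = s_ij * pi_j` for
#' `i != j`, diagonal set so rows sum to zero, and the whole matrix rescaled
#' so the expected substitution rate at equilibrium,
#' `sum_i pi_i * (-q_ii)`, equals one. Time is then measured in expected
#' substitutions per site.
#'
#' @param name Model name; `"JTT"` (the default) loads the shipped
#'   Jones-Taylor-Thornton table.
#' @param exchangeabilities,equilibrium_freqs Optional explicit tables
#'   overriding `name`; both must be supplied together.
#' @return Object of class `substitution_model` with fields
#'   `exchangeabilities`, `equilibrium_freqs`, `rate_matrix`, `name`, and the
#'   spectral decomposition used for fast matrix exponentials.
#' @export
substitution_model <- function(name = "JTT", exchangeabilities = NULL,
                               equilibrium_freqs = NULL) {
  if (is.null(exchangeabilities) != is.null(equilibrium_freqs)) {
    stop("supply both 'exchangeabilities' and 'equilibrium_freqs', or neither")
  }
  if (is.null(exchangeabilities)) {
    if (!identical(toupper(name), "JTT")) {
      stop("unknown built-in model '", name, "'; only JTT is shipped")
    }
    tab <- read_paml_matrix(system.file("extdata", "jtt.dat",
                                        package = "paleonif", mustWork = TRUE))
    exchangeabilities <- tab$exchangeabilities
    equilibrium_freqs <- tab$equilibrium_freqs
  }
  aa <- amino_acids()
  S <- as.matrix(exchangeabilities)
  if (!all(dim(S) == c(20, 20))) stop("exchangeability matrix must be 20x20")
  if (max(abs(S - t(S))) > 1e-8) stop("exchangeability matrix must be symmetric")
  if (any(S < 0)) stop("exchangeabilities must be non-negative")
  pi <- as.numeric(equilibrium_freqs)
  if (length(pi) != 20 || any(pi <= 0)) {
    stop("equilibrium frequencies must be 20 strictly positive values")
  }
  pi <- pi / sum(pi)
  names(pi) <- aa
  dimnames(S) <- list(aa, aa)

  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate

  # Reversibility makes D^(1/2) Q D^(-1/2) symmetric, so Q is diagonalizable
  # with real eigenvalues; cache the decomposition for transition_matrix().
  sp <- sqrt(pi)
  sym <- Q * (sp %o% (1 / sp))
  sym <- (sym + t(sym)) / 2
  eig <- eigen(sym, symmetric = TRUE)
  right <- eig$vectors / sp         # columns: right eigenvectors of Q
  left <- t(eig$vectors * sp)       # rows: left eigenvectors of Q

  structure(
    list(name = name, exchangeabilities = S, equilibrium_freqs = pi,
         rate_matrix = Q,
         eigenvalues = eig$values, right_vectors = right, left_vectors = left),
    class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Reversible amino-acid substitution model:", x$name, "\n")
  cat("  expected rate at equilibrium:",
      format(-sum(x$equilibrium_freqs * diag(x$rate_matrix))), "sub/site\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [substitution_model()].
#' @param t Evolutionary distance in expected substitutions per site; must be
#'   a single non-negative number.
#' @return Row-stochastic 20x20 matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("evolutionary distance 't' must be a single non-negative number")
  }
  P <- model$right_vectors %*% (exp(model$eigenvalues * t) * model$left_vectors)
  # clip eigen-roundoff; rows renormalized to machine-exact stochasticity
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$rate_matrix)
  P
}

#' Configuration for three-component site distributions
#'
#' @param evo_distance Evolutionary distance (substitutions/site) for the
#'   mutational-neighbourhood component; default 0.01.
#' @param component_weights Weights of the (observed, neighbourhood,
#'   regularizer) components; normalized to sum to 1. Default uniform.
#' @param regularizer Diffuse background distribution over the 20 amino
#'   acids; strictly positive, normalized to sum to 1. Default `NULL` uses
#'   the model's equilibrium frequencies at evaluation time.
#' @return Object of class `distribution_config`.
#' @export
distribution_config <- function(evo_distance = 0.01,
                                component_weights = c(1, 1, 1) / 3,
                                regularizer = NULL) {
  if (!is.numeric(evo_distance) || length(evo_distance) != 1 || evo_distance < 0) {
    stop("'evo_distance' must be a single non-negative number")
  }
  w <- as.numeric(component_weights)
  if (length(w) != 3 || any(w < 0) || sum(w) <= 0) {
    stop("'component_weights' must be 3 non-negative values with positive sum")
  }
  w <- w / sum(w)
  if (!is.null(regularizer)) {
    regularizer <- as.numeric(regularizer)
    if (length(regularizer) != 20 || any(regularizer <= 0)) {
      stop("'regularizer' must be 20 strictly positive probabilities")
    }
    regularizer <- regularizer / sum(regularizer)
    names(regularizer) <- amino_acids()
  }
  structure(list(evo_distance = evo_distance, component_weights = w,
                 regularizer = regularizer),
            class = "distribution_config")
}

gap_chars <- function() c("-", ".", "X", "B", "Z", "J", "U", "O", "*", "?")

resolve_regularizer <- function(model, config) {
  if (is.null(config$regularizer)) model$equilibrium_freqs else config$regularizer
}

#' Amino-acid probability distribution for one observed residue
#'
#' The feature distribution assigned to a single active-site residue: the
#' weighted average of (a) a point mass on the observed residue, (b) the
#' JTT transition-probability row from that residue over a short evolutionary
#' distance, and (c) a diffuse regularizer distribution. Gap and ambiguity
#' symbols carry no residue information and return the regularizer alone.
#'
#' @param observed_residue Single one-letter amino-acid code, or a gap or
#'   ambiguity symbol (`-`, `.`, `X`, ...).
#' @param model A [substitution_model()].
#' @param config A [distribution_config()].
#' @param position Optional position reported in error messages.
#' @return Named 20-vector of probabilities summing to 1.
#' @export
site_distribution <- function(observed_residue, model,
                              config = distribution_config(), position = NA) {
  stopifnot(inherits(model, "substitution_model"),
            inherits(config, "distribution_config"))
  aa <- amino_acids()
  r <- toupper(as.character(observed_residue))
  if (length(r) != 1 || nchar(r) != 1) {
    stop("'observed_residue' must be a single character")
  }
  reg <- resolve_regularizer(model, config)
  if (r %in% gap_chars()) {
    return(reg)
  }
  idx <- match(r, aa)
  if (is.na(idx)) {
    stop("unknown residue character '", r, "'",
         if (!is.na(position)) paste0(" at position ", position) else "",
         "; expected one of ", paste(aa, collapse = ""),
         " or a gap/ambiguity symbol")
  }
  w <- config$component_weights
  point <- numeric(20)
  point[idx] <- 1
  neighbour <- transition_matrix(model, config$evo_distance)[idx, ]
  out <- w[1] * point + w[2] * neighbour + w[3] * reg
  names(out) <- aa
  out
}
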