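## Re-derivation of group contributions from a training table: occurrence
## (design) matrix, Gauss-Seidel solution of the normal equations, k-fold
## cross-validation, iterative outlier rejection, summary statistics.

#' Build the design system (occurrence matrix + response) from records
#'
#' Each record is a list with elements \code{counts} (named non-negative
#' integer vector of group counts, as from \code{\link{groupCounts}}),
#' \code{hc} (experimental heat of combustion, kJ/mol) and optionally
#' \code{name} and \code{uncovered}. Records with uncovered atoms or empty
#' count vectors are excluded with a message. Vocabulary columns that no
#' record uses are dropped with a warning.
#'
#' @param records list of records.
#' @param vocab optional character vector fixing the column universe;
#'   default: union of keys over the records.
#' @return list with \code{X} (M x N integer matrix, column names are
#'   group keys), \code{y} (numeric response), \code{names},
#'   \code{excluded} (indices of dropped records).
#' @export
buildDesignSystem <- function(records, vocab = NULL) {
  if (!length(records)) stop("no training records")
  ok <- vapply(records, function(r) {
    length(r$counts) > 0 && is.finite(r$hc) &&
      (is.null(r$uncovered) || length(r$uncovered) == 0)
  }, logical(1))
  excluded <- which(!ok)
  if (length(excluded))
    message(length(excluded), " record(s) excluded (uncovered atoms or empty counts)")
  records <- records[ok]
  if (!length(records)) stop("no usable training records")
  keys_used <- unique(unlist(lapply(records, function(r) names(r$counts))))
  if (is.null(vocab)) vocab <- keys_used
  unused <- setdiff(vocab, keys_used)
  if (length(unused) == length(vocab))
    stop("vocabulary has no overlap with the records")
  if (length(unused))
    warning(length(unused), " unused vocabulary column(s) dropped")
  cols <- intersect(vocab, keys_used)
  miss <- setdiff(keys_used, vocab)
  if (length(miss))
    stop("records contain group(s) outside the vocabulary: ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- matrix(0, nrow = length(records), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_along(records)) {
    cnt <- records[[i]]$counts
    X[i, names(cnt)] <- as.numeric(cnt)
  }
  y <- vapply(records, function(r) as.numeric(r$hc), numeric(1))
  nms <- vapply(seq_along(records), function(i) {
    nm <- records[[i]]$name
    if (is.null(nm) || !nzchar(nm)) paste0("record", i) else nm
  }, character(1))
  list(X = X, y = y, names = nms, excluded = excluded)
}

#' Solve the least-squares system by Gauss-Seidel on the normal equations
#'
#' The occurrence matrix is normalized into the square system
#' \code{t(X) X b = t(X) y} and balanced by coordinate-wise Gauss-Seidel
#' sweeps in fixed column order, starting from zero, until the largest
#' coordinate update falls below \code{tol}.
#'
#' @param X design matrix (M x N, column names are group keys).
#' @param y response vector.
#' @param tol convergence tolerance on the largest coordinate update,
#'   kJ/mol (default 1e-6).
#' @param max_iter sweep limit (default 10000).
#' @return list with \code{x} (named solution), \code{iterations},
#'   \code{max_update}, \code{dropped} (all-zero columns removed).
#' @section Errors: a rank-deficient system (perfectly collinear columns)
#'   raises an error of class \code{hcgroups_nonidentifiable}; exceeding
#'   \code{max_iter} raises \code{hcgroups_convergence_error} carrying the
#'   last iterate in its \code{x} field.
#' @export
gaussSeidelSolve <- function(X, y, tol = 1e-6, max_iter = 10000L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  zero <- colSums(abs(X)) == 0
  dropped <- colnames(X)[zero]
  if (any(zero)) {
    warning(sum(zero), " zero-occurrence column(s) removed")
    X <- X[, !zero, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop(errorCondition(
      "non-identifiable system: design matrix is rank-deficient (collinear groups)",
      class = c("hcgroups_nonidentifiable", "error", "condition")))
  G <- crossprod(X)
  g <- drop(crossprod(X, y))
  n <- ncol(X)
  x <- numeric(n)
  iter <- 0L
  delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- 0
    for (j in seq_len(n)) {
      newx <- (g[j] - sum(G[j, -j] * x[-j])) / G[j, j]
      delta <- max(delta, abs(newx - x[j]))
      x[j] <- newx
    }
    if (delta < tol) break
  }
  names(x) <- colnames(X)
  if (delta >= tol)
    stop(errorCondition(
      sprintf("Gauss-Seidel did not converge in %d sweeps (last update %.3g)",
              max_iter, delta),
      class = c("hcgroups_convergence_error", "error", "condition"),
      x = x, iterations = iter, max_update = delta))
  list(x = x, iterations = iter, max_update = delta, dropped = dropped)
}

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' k-fold cross-validation of the group-contribution fit
#'
#' Deterministic seeded shuffle into folds as equal as possible; every
#' record is used exactly once as a test sample. Test records whose groups
#' do not all occur in the corresponding training part are not evaluable
#' and get NA predictions (this mirrors the shrinking compound counts of
#' the published statistics).
#'
#' @param X,y design system (see \code{\link{buildDesignSystem}}).
#' @param folds number of folds (default 10; \code{folds = nrow(X)} gives
#'   leave-one-out).
#' @param seed integer seed for the fold shuffle.
#' @param tol,max_iter passed to \code{\link{gaussSeidelSolve}}.
#' @return list with \code{fold} (assignment), \code{pred} (out-of-fold
#'   predictions, NA when not evaluable).
#' @export
crossValidate <- function(X, y, folds = 10L, seed = 1L,
                          tol = 1e-6, max_iter = 10000L) {
  M <- nrow(X)
  if (folds < 2 || folds > M) stop("need 2 <= folds <= number of records")
  fold <- withLocalSeed(seed, {
    rep_len(seq_len(folds), M)[sample.int(M)]
  })
  pred <- rep(NA_real_, M)
  for (f in seq_len(folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    Xt <- X[train, , drop = FALSE]
    seen <- colSums(abs(Xt)) > 0
    fit <- gaussSeidelSolve(Xt[, seen, drop = FALSE], y[train],
                            tol = tol, max_iter = max_iter)
    for (i in test) {
      needed <- X[i, ] > 0
      if (all(colnames(X)[needed] %in% names(fit$x)))
        pred[i] <- sum(X[i, names(fit$x)] * fit$x)
    }
  }
  list(fold = fold, pred = pred)
}

#' Goodness-of-fit summary statistics
#'
#' @param y_exp experimental values.
#' @param y_pred calculated values (same length; NA pairs are dropped).
#' @param p number of fitted parameters used in the \code{n - p}
#'   denominator of \code{sigma} (0 gives the plain RMS convention used
#'   for cross-validated errors).
#' @return list: \code{r2} (squared Pearson correlation), \code{sigma}
#'   (root mean squared residual with \code{n - p} denominator),
#'   \code{sigma_n} (n denominator), \code{avg_dev} (mean absolute
#'   residual), \code{mad_percent} (mean absolute percentage deviation),
#'   \code{n}.
#' @export
computeStats <- function(y_exp, y_pred, p = 0L) {
  stopifnot(length(y_exp) == length(y_pred))
  ok <- is.finite(y_exp) & is.finite(y_pred)
  y_exp <- y_exp[ok]; y_pred <- y_pred[ok]
  n <- length(y_exp)
  if (n < 2) stop("need at least two finite pairs")
  if (stats::sd(y_exp) == 0) stop("r2 undefined: zero variance in y_exp")
  res <- y_exp - y_pred
  r2 <- suppressWarnings(stats::cor(y_exp, y_pred)^2)
  list(r2 = r2,
       sigma = if (n > p) sqrt(sum(res^2) / (n - p)) else NA_real_,
       sigma_n = sqrt(mean(res^2)),
       avg_dev = mean(abs(res)),
       mad_percent = mean(abs(res / y_exp)) * 100,
       n = n)
}

#' Fit group contributions with cross-validated outlier rejection
#'
#' The full training loop: solve the normal equations for all records, run
#' k-fold cross-validation, compute the cross-validated standard error S,
#' discard records whose cross-validated residual exceeds
#' \code{outlier_k * S}, and repeat until no record is discarded (or run a
#' single pass with \code{single_pass = TRUE}). Contributions are fitted
#' on all surviving records; the accuracy statistics are evaluated only
#' over compounds all of whose groups are valid (supported by at least
#' \code{min_molecules} surviving molecules), which is why the evaluated
#' compound count is smaller than the fitted one.
#'
#' @param records training records (see \code{\link{buildDesignSystem}}).
#' @param min_molecules validity threshold for the evaluation statistics.
#' @param outlier_k rejection multiple of the cross-validated standard
#'   error (default 3).
#' @param folds,seed cross-validation controls.
#' @param tol,max_iter solver controls.
#' @param single_pass run the rejection once instead of to a fixed point.
#' @param max_rounds safety bound on rejection rounds.
#' @return list with components \code{fit} (contributions, per-group
#'   occurrences/molecules, r2, sigma, sigma_n, avg_dev, n_compounds_fit,
#'   n_compounds_evaluated), \code{cv} (q2, s_cv, avg_dev_cv, fold,
#'   pred, n_evaluated), \code{outliers} (names of rejected records),
#'   \code{rounds}, and \code{table} (a \linkS4class{ContributionTable}
#'   built from the fit).
#' @export
fitContributions <- function(records, min_molecules = 3L, outlier_k = 3,
                             folds = 10L, seed = 1L, tol = 1e-6,
                             max_iter = 10000L, single_pass = FALSE,
                             max_rounds = 25L) {
  sys <- buildDesignSystem(records)
  X <- sys$X; y <- sys$y; nms <- sys$names
  if (nrow(X) < folds) stop("need at least as many records as folds")
  keep <- seq_len(nrow(X))
  outliers <- character()
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("outlier rejection did not reach a fixed point within ",
           max_rounds, " rounds")
    Xk <- X[keep, , drop = FALSE]
    seen <- colSums(abs(Xk)) > 0
    Xk <- Xk[, seen, drop = FALSE]
    cv <- crossValidate(Xk, y[keep], folds = min(folds, nrow(Xk)), seed = seed,
                        tol = tol, max_iter = max_iter)
    res_cv <- y[keep] - cv$pred
    S <- sqrt(mean(res_cv^2, na.rm = TRUE))
    ## no rejection below numerical precision: a perfect (noise-free) fit
    ## must not discard records over rounding-level residuals
    floor_S <- 10 * tol
    bad <- which(!is.na(res_cv) & abs(res_cv) > outlier_k * S & S > floor_S)
    if (!length(bad) || single_pass) break
    outliers <- c(outliers, nms[keep][bad])
    keep <- keep[-bad]
  }
  Xk <- X[keep, , drop = FALSE]
  seen <- colSums(abs(Xk)) > 0
  Xk <- Xk[, seen, drop = FALSE]
  yk <- y[keep]
  fit <- gaussSeidelSolve(Xk, yk, tol = tol, max_iter = max_iter)
  y_hat <- drop(Xk %*% fit$x[colnames(Xk)])
  molecules <- colSums(Xk > 0)
  occurrences <- colSums(Xk)
  valid <- molecules >= min_molecules
  evaluable <- apply(Xk, 1, function(r) all(valid[r > 0]))
  fit_stats <- if (sum(evaluable) >= 2)
    computeStats(yk[evaluable], y_hat[evaluable], p = ncol(Xk)) else NULL
  cv_eval <- evaluable & !is.na(cv$pred)
  cv_stats <- if (sum(cv_eval) >= 2)
    computeStats(yk[cv_eval], cv$pred[cv_eval], p = 0L) else NULL
  tab <- makeContributionTable(colnames(Xk), fit$x[colnames(Xk)],
                               occurrences = as.integer(occurrences),
                               molecules = as.integer(molecules),
                               min_molecules = min_molecules)
  list(
    fit = list(contributions = fit$x,
               occurrences = occurrences, molecules = molecules,
               r2 = if (!is.null(fit_stats)) fit_stats$r2 else NA_real_,
               sigma = if (!is.null(fit_stats)) fit_stats$sigma else NA_real_,
               sigma_n = if (!is.null(fit_stats)) fit_stats$sigma_n else NA_real_,
               avg_dev = if (!is.null(fit_stats)) fit_stats$avg_dev else NA_real_,
               n_compounds_fit = nrow(Xk),
               n_compounds_evaluated = sum(evaluable),
               iterations = fit$iterations),
    cv = list(q2 = if (!is.null(cv_stats)) cv_stats$r2 else NA_real_,
              s_cv = if (!is.null(cv_stats)) cv_stats$sigma_n else NA_real_,
              avg_dev_cv = if (!is.null(cv_stats)) cv_stats$avg_dev else NA_real_,
              fold = cv$fold, pred = cv$pred,
              n_evaluated = sum(cv_eval)),
    outliers = outliers,
    rounds = rounds,
    kept = nms[keep],
    table = tab)
}

#' Build trainer records from molecules and experimental values
#'
#' @param mols list of \linkS4class{MolecularGraph} (or SMILES strings).
#' @param hc_exp experimental heats of combustion, kJ/mol (or kcal/mol
#'   with \code{units = "kcal"}; converted with the factor 4.1858).
#' @param table optional \linkS4class{ContributionTable} used to flag
#'   uncovered atoms.
#' @param units \code{"kJ"} or \code{"kcal"}.
#' @param geometry_policy,zwitterion_policy pipeline controls.
#' @return list of records for \code{\link{buildDesignSystem}}.
#' @export
recordsFromMolecules <- function(mols, hc_exp, table = NULL,
                                 units = c("kJ", "kcal"),
                                 geometry_policy = "topology_only",
                                 zwitterion_policy = "as_drawn") {
  units <- match.arg(units)
  if (units == "kcal") hc_exp <- kcalToKj(hc_exp)
  stopifnot(length(mols) == length(hc_exp))
  lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    if (is.character(m)) m <- parseSmiles(m, name = m)
    m <- normalizeConventions(m, zwitterion_policy)
    d <- decompose(m, table, geometry_policy)
    list(counts = groupCounts(d), hc = hc_exp[i], name = molName(m),
         uncovered = uncoveredAtoms(d))
  })
}
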