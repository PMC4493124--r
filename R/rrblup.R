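#' Variance components and heritability by one-way ANOVA
#'
#' Classical expected-mean-squares estimators from a one-way (line) ANOVA
#' of plot phenotypes: `Ve = MS_within`, `Vg = (MS_between - MS_within) / r`
#' (truncated at 0) with `r` the number of plots per line (harmonic mean
#' for unbalanced data), and heritability on the line-mean basis
#' `h2 = Vg / (Vg + Ve / r)`.
#'
#' @param plots tibble of plot phenotypes with columns `line`, `value`
#'   (and optionally `replicate`).
#' @return one-row tibble of class `gs_varcomp`: `Vg`, `Ve`, `h2`,
#'   `n_reps`, `n_lines`, `ms_between`, `ms_within`, `balanced`.
#' @export
estimate_variance_anova <- function(plots) {
  stopifnot(is.data.frame(plots), all(c("line", "value") %in% names(plots)))
  reps <- table(plots$line)
  if (length(reps) < 2) abort("need at least 2 lines")
  if (all(reps == 1)) {
    abort(paste0("single plot per line: Ve is unidentifiable from a one-way ",
                 "ANOVA; supply h2/Vg directly (e.g. via variance_components())"))
  }
  fit <- lm(value ~ factor(line), data = plots)
  an <- suppressWarnings(anova(fit))  # perfect fits (h2 = 1) are legitimate
  ms_between <- an$`Mean Sq`[1]
  ms_within <- an$`Mean Sq`[2]
  r <- length(reps) / sum(1 / as.numeric(reps))  # harmonic mean of reps
  vg <- max(0, (ms_between - ms_within) / r)
  ve <- ms_within
  h2 <- if (vg == 0 && ve == 0) NA_real_ else vg / (vg + ve / r)
  out <- tibble(Vg = vg, Ve = ve, h2 = h2, n_reps = r,
                n_lines = length(reps), ms_between = ms_between,
                ms_within = ms_within,
                balanced = length(unique(as.integer(reps))) == 1)
  class(out) <- c("gs_varcomp", class(out))
  out
}

#' Assemble variance components directly
#'
#' For workflows where Vg/Ve/h2 are known (e.g. taken from a previous
#' trial) rather than estimated with [estimate_variance_anova()].
#'
#' @param Vg genetic variance.
#' @param Ve residual (plot) variance.
#' @param n_reps plots per line underlying the line means.
#' @return a `gs_varcomp` one-row tibble.
#' @export
variance_components <- function(Vg, Ve, n_reps) {
  stopifnot(Vg >= 0, Ve >= 0, n_reps >= 1)
  h2 <- if (Vg == 0 && Ve == 0) NA_real_ else Vg / (Vg + Ve / n_reps)
  out <- tibble(Vg = Vg, Ve = Ve, h2 = h2, n_reps = n_reps,
                n_lines = NA_integer_, ms_between = NA_real_,
                ms_within = NA_real_, balanced = NA)
  class(out) <- c("gs_varcomp", class(out))
  out
}

#' Fit RR-BLUP marker effects
#'
#' Fits `y = mu * 1 + X g + e` with marker effects shrunk by the ridge
#' parameter `lambda = (Ve / n_reps) / (Vg / N_M)`: the per-marker prior
#' variance is `Vg / N_M` and the residual variance on line means is
#' `Ve / n_reps`. Genotype codes are kept at \{0, 2\}; the intercept
#' absorbs the coding shift.
#'
#' Two mathematically equivalent solvers are provided: the primal solve of
#' the (N_M + 1) mixed-model equations and the dual (observation-
#' dimension) solve via `g = X' (XX' + lambda I)^{-1} (y - mu 1)` with the
#' GLS intercept; `method = "auto"` picks the cheaper one (dual whenever
#' N_M > N_P).
#'
#' @param geno training `gs_geno` (no missing codes), or a bare numeric
#'   matrix of codes with line rownames.
#' @param y named numeric vector of line-mean phenotypes, or a tibble with
#'   columns `line`, `mean_value` (as from [line_means()]); aligned to the
#'   training lines by name.
#' @param var a `gs_varcomp` supplying Vg, Ve and n_reps.
#' @param method `"auto"`, `"primal"` or `"dual"`.
#' @param lambda optional explicit ridge parameter overriding `var`.
#' @return a `gs_rrblup` object: `mu`, `effects` (tibble marker, effect),
#'   `lambda`, `method`, `training_ids`, `markers`, `var`.
#' @export
fit_rrblup <- function(geno, y, var = NULL,
                       method = c("auto", "primal", "dual"), lambda = NULL) {
  method <- match.arg(method)
  X <- if (inherits(geno, "gs_geno")) geno$codes else geno
  stopifnot(is.matrix(X))
  if (anyNA(X)) abort("training genotypes contain missing codes; impute first")

  if (is.data.frame(y)) {
    yv <- setNames(y$mean_value, y$line)
  } else {
    yv <- y
  }
  if (!is.null(names(yv)) && !is.null(rownames(X))) {
    missing_y <- setdiff(rownames(X), names(yv))
    if (length(missing_y) > 0) {
      abort(paste0("no phenotype for line(s): ",
                   paste(head(missing_y, 5), collapse = ", ")))
    }
    yv <- yv[rownames(X)]
  }
  n <- nrow(X)
  m <- ncol(X)
  if (n < 2) abort("need at least 2 training lines")
  if (length(yv) != n) abort("y length does not match training lines")

  if (is.null(lambda)) {
    if (is.null(var)) abort("supply variance components or an explicit lambda")
    if (var$Vg <= 0) abort("lambda undefined: Vg must be > 0 (or pass lambda)")
    lambda <- (var$Ve / var$n_reps) / (var$Vg / m)
  }
  if (lambda <= 0) {
    abort("lambda must be > 0 (ridge-free least squares is singular when N_M >= N_P)")
  }

  if (method == "auto") method <- if (m > n) "dual" else "primal"
  yv <- as.numeric(yv)
  if (method == "primal") {
    # mixed-model equations for (mu, g)
    ones <- rep(1, n)
    C <- rbind(
      c(n, colSums(X)),
      cbind(colSums(X), crossprod(X) + diag(lambda, m))
    )
    rhs <- c(sum(yv), crossprod(X, yv))
    sol <- solve(C, rhs)
    mu <- sol[1]
    g <- sol[-1]
  } else {
    V <- tcrossprod(X) + diag(lambda, n)
    Vi <- solve(V)
    ones <- rep(1, n)
    mu <- as.numeric((crossprod(ones, Vi %*% yv)) / (crossprod(ones, Vi %*% ones)))
    g <- as.numeric(crossprod(X, Vi %*% (yv - mu)))
  }
  structure(list(
    mu = as.numeric(mu),
    effects = tibble(marker = colnames(X) %||% paste0("m", seq_len(m)),
                     effect = as.numeric(g)),
    lambda = lambda,
    method = method,
    training_ids = rownames(X),
    markers = colnames(X),
    var = var
  ), class = "gs_rrblup")
}

#' @export
print.gs_rrblup <- function(x, ...) {
  cat("<gs_rrblup> ", length(x$training_ids %||% character()),
      " training lines, ", nrow(x$effects), " markers, lambda = ",
      signif(x$lambda, 6), " (", x$method, " solve)\n", sep = "")
  invisible(x)
}

#' @describeIn fit_rrblup marker effects as a tibble.
#' @param x a `gs_rrblup`.
#' @param ... unused.
#' @export
tidy.gs_rrblup <- function(x, ...) x$effects

#' @describeIn fit_rrblup one-row model summary.
#' @export
glance.gs_rrblup <- function(x, ...) {
  tibble(mu = x$mu, lambda = x$lambda, n_train = length(x$training_ids %||% character()),
         n_markers = nrow(x$effects), method = x$method)
}

#' Predict genomic estimated breeding values
#'
#' `y_hat = mu + X_new g` for lines genotyped at exactly the training
#' marker set (same markers, same order).
#'
#' @param object a `gs_rrblup` fit.
#' @param newdata a `gs_geno` or code matrix for the lines to predict.
#' @param ... unused.
#' @return tibble with columns `line`, `gebv`.
#' @export
predict.gs_rrblup <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "gs_geno")) newdata$codes else newdata
  stopifnot(is.matrix(X))
  trained <- object$markers %||% object$effects$marker
  if (!is.null(colnames(X)) && !is.null(trained)) {
    missing_m <- setdiff(trained, colnames(X))
    extra_m <- setdiff(colnames(X), trained)
    if (length(missing_m) > 0 || length(extra_m) > 0) {
      abort(paste0(
        "marker set mismatch: ",
        if (length(missing_m) > 0) paste0("missing [", paste(head(missing_m, 5), collapse = ", "), "] "),
        if (length(extra_m) > 0) paste0("extra [", paste(head(extra_m, 5), collapse = ", "), "]")))
    }
    X <- X[, trained, drop = FALSE]
  } else if (ncol(X) != nrow(object$effects)) {
    abort("newdata marker count does not match the fitted model")
  }
  tibble(line = rownames(X) %||% paste0("L", seq_len(nrow(X))),
         gebv = as.numeric(object$mu + X %*% object$effects$effect))
}

#' Prediction accuracy on the genotypic-value scale
#'
#' `r_MP` is the Pearson correlation between predicted and observed line
#' means; the accuracy of genomic selection is `r_MG = r_MP / h` with `h`
#' the square root of heritability. `r_MG` is reported uncapped: values
#' above 1 are possible by construction.
#'
#' @param predicted,observed paired numeric vectors (at least 3 pairs).
#' @param h2 heritability used for the rescaling, in (0, 1].
#' @return one-row tibble: `r_MP`, `r_MG`, `h_used`, `n`.
#' @export
accuracy <- function(predicted, observed, h2) {
  stopifnot(length(predicted) == length(observed), h2 > 0, h2 <= 1)
  if (length(predicted) < 3) abort("need at least 3 paired values")
  if (sd(predicted) == 0 || sd(observed) == 0) {
    warn("zero variance in predicted or observed values; accuracy undefined")
    r_mp <- NA_real_
  } else {
    r_mp <- cor(predicted, observed)
  }
  tibble(r_MP = r_mp, r_MG = r_mp / sqrt(h2), h_used = sqrt(h2),
         n = length(predicted))
}
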