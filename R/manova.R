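# One-way MANOVA machinery for branch genotype classes: Wilk's lambda from
# the within/between SSCP matrices, Rao's F transformation, the partial
# (conditional) Wilk's statistic that isolates one phenotype's contribution
# given the others, its exact partial F, and univariate follow-up F tests.

# within-class (E) and between-class (H) SSCP matrices of a one-way layout
sscp_matrices <- function(Y, classes) {
  Y <- as.matrix(Y)
  classes <- as.factor(classes)
  k <- nlevels(classes)
  n <- nrow(Y)
  if (k < 2) abort("need at least two classes")
  if (n <= k) abort("need more individuals than classes")
  gm <- colMeans(Y)
  Yc <- sweep(Y, 2, gm)
  Tm <- crossprod(Yc)
  ng <- tabulate(classes)
  means <- rowsum(Y, classes) / ng
  Mc <- sweep(means, 2, gm)
  H <- crossprod(Mc * sqrt(ng))
  E <- Tm - H
  list(E = E, H = H, N = n, k = k, p = ncol(Y))
}

safe_det_ratio <- function(E, EH) {
  # det(E)/det(E+H) via Cholesky with a conditioning guard
  dE <- determinant(E, logarithm = TRUE)
  dEH <- determinant(EH, logarithm = TRUE)
  if (dE$sign <= 0 || dEH$sign <= 0 || !is.finite(dE$modulus)) {
    abort("singular within-class SSCP matrix (degenerate phenotypes)")
  }
  if (rcond(EH) < 1e-12) {
    abort("ill-conditioned SSCP matrix (condition estimate above 1e12)")
  }
  exp(as.numeric(dE$modulus - dEH$modulus))
}

#' Wilk's lambda for a one-way MANOVA
#'
#' `lambda = det(E) / det(E + H)` with `E` and `H` the within- and
#' between-class sums-of-squares-and-cross-products matrices.  Smaller values
#' indicate stronger multivariate separation of the genotype classes.
#'
#' @param Y numeric matrix (or data frame) of adjusted phenotypes, one column
#'   per phenotype.
#' @param classes factor (or coercible) of genotype classes.
#' @return list with `lambda`, `E`, `H`, `N`, `k`, `p`, `v_E = N - k`,
#'   `v_H = k - 1`.
#' @export
wilks_lambda <- function(Y, classes) {
  s <- sscp_matrices(Y, classes)
  s$lambda <- safe_det_ratio(s$E, s$E + s$H)
  s$v_E <- s$N - s$k
  s$v_H <- s$k - 1
  s
}

#' F transformation of Wilk's lambda (Rao)
#'
#' Rao's approximation, which is exact when `p <= 2` or `v_H <= 2`
#' (in particular for the three genotype classes of a biallelic branch).
#'
#' @param lambda Wilk's lambda.
#' @param p number of phenotypes.
#' @param v_H hypothesis degrees of freedom (k - 1).
#' @param v_E error degrees of freedom (N - k).
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
wilks_full_model_p <- function(lambda, p, v_H, v_E) {
  if (v_E < p) abort("insufficient error degrees of freedom (v_E < p)")
  t <- if (p^2 + v_H^2 - 5 > 0) {
    sqrt((p^2 * v_H^2 - 4) / (p^2 + v_H^2 - 5))
  } else {
    1
  }
  w <- v_E + v_H - (p + v_H + 1) / 2
  df1 <- p * v_H
  df2 <- w * t - (p * v_H - 2) / 2
  lam_t <- lambda^(1 / t)
  Fstat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  list(F = Fstat, df1 = df1, df2 = df2, p_value = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Partial (conditional) Wilk's statistic for one phenotype
#'
#' Ratio of the full-model Wilk's lambda over `p` phenotypes to the
#' reduced-model lambda with phenotype `g` excluded; measures the unique
#' contribution of `g` to the genotype association given the other
#' phenotypes.
#'
#' @inheritParams wilks_lambda
#' @param g column index (or name) of the phenotype of interest.
#' @return partial lambda in (0, 1].
#' @export
partial_wilks <- function(Y, classes, g) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) abort("partial Wilk's test needs at least two phenotypes")
  if (is.character(g)) g <- match(g, colnames(Y))
  full <- wilks_lambda(Y, classes)
  red <- wilks_lambda(Y[, -g, drop = FALSE], classes)
  full$lambda / red$lambda
}

#' Exact partial F for a partial Wilk's statistic
#'
#' `F = ((1 - lambda) / lambda) * ((v_E - p + 1) / v_H)` on
#' `(v_H, v_E - p + 1)` degrees of freedom.
#'
#' @param lambda_partial partial Wilk's statistic from [partial_wilks()].
#' @inheritParams wilks_full_model_p
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
partial_F <- function(lambda_partial, p, v_H, v_E) {
  df2 <- v_E - p + 1
  if (df2 < 1) abort("nonpositive denominator degrees of freedom (v_E - p + 1 < 1)")
  Fstat <- ((1 - lambda_partial) / lambda_partial) * (df2 / v_H)
  list(F = Fstat, df1 = v_H, df2 = df2, p_value = pf(Fstat, v_H, df2, lower.tail = FALSE))
}

# one-way ANOVA F for a single response; returns c(F, df1, df2)
anova_F <- function(y, classes) {
  classes <- as.factor(classes)
  ng <- tabulate(classes)
  k <- length(ng)
  n <- length(y)
  sums <- rowsum(y, classes)
  ssb <- sum(sums^2 / ng) - sum(y)^2 / n
  sst <- sum(y^2) - sum(y)^2 / n
  ssw <- sst - ssb
  if (ssw <= 0) {
    f <- if (ssb <= 1e-12) 0 else Inf
  } else {
    f <- (ssb / (k - 1)) / (ssw / (n - k))
  }
  c(F = f, df1 = k - 1, df2 = n - k)
}

#' Univariate follow-up F tests
#'
#' Standard one-way ANOVA per phenotype column; all-constant columns are
#' flagged degenerate and excluded with a warning.
#'
#' @inheritParams wilks_lambda
#' @return tibble: phenotype, F, df1, df2, p_value.
#' @export
univariate_followups <- function(Y, classes) {
  Y <- as.matrix(Y)
  cols <- colnames(Y)
  if (is.null(cols)) cols <- paste0("y", seq_len(ncol(Y)))
  keep <- apply(Y, 2, function(col) var(col) > 0)
  if (any(!keep)) {
    warn(paste0("degenerate constant phenotype(s) excluded: ", paste(cols[!keep], collapse = ", ")))
  }
  purrr::map(which(keep), function(j) {
    a <- anova_F(Y[, j], classes)
    tibble(
      phenotype = cols[j], F = a[["F"]], df1 = a[["df1"]], df2 = a[["df2"]],
      p_value = pf(a[["F"]], a[["df1"]], a[["df2"]], lower.tail = FALSE)
    )
  }) %>% bind_rows()
}

#' One-way MANOVA of a branch's genotype classes
#'
#' Full multivariate test plus, per phenotype, the univariate follow-up F and
#' the partial Wilk's test with its exact partial F.  This is the follow-up
#' analysis run on branches flagged by the scan: the phenotype with the
#' smallest partial lambda is the one driving the multivariate association
#' in the presence of the others.
#'
#' @param data data frame holding the (already adjusted) phenotype columns.
#' @param classes genotype class per row of `data` (factor or coercible).
#' @param phenotypes character vector of phenotype column names; total
#'   cholesterol, being a composite of the other lipids, should be excluded
#'   and is not part of the default phenotype set used by [treescan()].
#' @return An object of class `branch_manova`; see [tidy.branch_manova()]
#'   and [glance.branch_manova()].
#' @export
branch_manova <- function(data, classes, phenotypes) {
  Y <- as.matrix(data[, phenotypes, drop = FALSE])
  ok <- complete.cases(Y) & !is.na(classes)
  Y <- Y[ok, , drop = FALSE]
  classes <- droplevels(as.factor(classes[ok]))
  full <- wilks_lambda(Y, classes)
  fm <- wilks_full_model_p(full$lambda, full$p, full$v_H, full$v_E)
  per <- purrr::map(seq_along(phenotypes), function(g) {
    uni <- anova_F(Y[, g], classes)
    lam_g <- if (full$p >= 2) partial_wilks(Y, classes, g) else NA_real_
    pF <- if (full$p >= 2) partial_F(lam_g, full$p, full$v_H, full$v_E) else NULL
    tibble(
      phenotype = phenotypes[g],
      F_univariate = uni[["F"]],
      p_univariate = pf(uni[["F"]], uni[["df1"]], uni[["df2"]], lower.tail = FALSE),
      lambda_partial = lam_g,
      F_partial = if (is.null(pF)) NA_real_ else pF$F,
      p_partial = if (is.null(pF)) NA_real_ else pF$p_value
    )
  }) %>% bind_rows()
  structure(
    list(
      lambda = full$lambda, E = full$E, H = full$H, N = full$N, k = full$k,
      p = full$p, v_E = full$v_E, v_H = full$v_H,
      F = fm$F, df1 = fm$df1, df2 = fm$df2, p_value = fm$p_value,
      per_phenotype = per
    ),
    class = "branch_manova"
  )
}

#' @export
print.branch_manova <- function(x, ...) {
  cat(sprintf(
    "<branch_manova> Wilk's lambda = %.4f, F(%g, %.1f) = %.3f, p = %.4g (N = %d, k = %d)\n",
    x$lambda, x$df1, x$df2, x$F, x$p_value, x$N, x$k
  ))
  print(x$per_phenotype)
  invisible(x)
}

#' Per-phenotype tests of a branch MANOVA
#'
#' @param x a `branch_manova`.
#' @param ... unused.
#' @return tibble with univariate and partial Wilk's tests per phenotype.
#' @export
tidy.branch_manova <- function(x, ...) x$per_phenotype

#' One-row summary of a branch MANOVA
#'
#' @param x a `branch_manova`.
#' @param ... unused.
#' @return one-row tibble: lambda, F, df1, df2, p_value, N, k, p.
#' @export
glance.branch_manova <- function(x, ...) {
  tibble(
    lambda = x$lambda, F = x$F, df1 = x$df1, df2 = x$df2,
    p_value = x$p_value, N = x$N, k = x$k, n_phenotypes = x$p
  )
}
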