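# Branch-by-branch genotype/phenotype association scanning.
#
# Every branch of the (tree-shaped) haplotype network bipartitions the
# haplotypes; an individual's genotype class at a branch is the number of
# its two haplotypes falling on the derived side (0/1/2).  Each testable
# branch is tested by one-way permutation ANOVA per phenotype and, jointly,
# by a one-way MANOVA; multiple testing across branches is corrected by a
# step-down max-statistic permutation procedure that shares one permutation
# stream across branches, so correlation between branch tests is respected.

#' Adjust phenotypes for covariates
#'
#' Replaces each phenotype by the residuals of an ordinary least-squares fit
#' on the covariates plus intercept.
#'
#' @param data data frame with phenotype and covariate columns.
#' @param phenotypes character vector of phenotype column names.
#' @param covariates character vector of covariate column names; may be
#'   empty, in which case phenotypes are mean-centred.
#' @return `data` with the phenotype columns replaced by residuals.
#' @export
adjust_phenotypes <- function(data, phenotypes, covariates = c("age", "sex", "bmi")) {
  stopifnot(all(phenotypes %in% names(data)))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) not in data: ", paste(missing_cov, collapse = ", ")))
  }
  # constant covariates carry no information beyond the intercept
  keep <- covariates[vapply(covariates, function(cv) var(data[[cv]]) > 0, TRUE)]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, keep, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) abort("collinear covariate matrix")
  Y <- as.matrix(data[, phenotypes, drop = FALSE])
  fit <- lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  for (j in seq_along(phenotypes)) data[[phenotypes[j]]] <- res[, j]
  data
}

#' Genotype classes of a branch
#'
#' Counts, per individual, the copies of the derived-side allele of a branch
#' bipartition (0, 1 or 2, i.e. the AA/AB/BB classes), and applies the
#' minimum class-size filter: classes with fewer than `min_count`
#' individuals are excluded and their individuals dropped from this branch's
#' test.  A branch with fewer than two included classes is untestable.
#'
#' @param data data frame with `hap_a` and `hap_b` columns.
#' @param side_b character vector: haplotypes on the derived side.
#' @param min_count minimum class size, default 5.
#' @return list with `classes` (integer 0/1/2 per row), `counts` (named
#'   length-3), `included` (logical per row), `included_classes`, `testable`.
#' @export
genotype_classes <- function(data, side_b, min_count = 5L) {
  cl <- (data$hap_a %in% side_b) + (data$hap_b %in% side_b)
  counts <- c(AA = sum(cl == 0), AB = sum(cl == 1), BB = sum(cl == 2))
  keep_cl <- unname(which(counts >= min_count) - 1L)
  included <- cl %in% keep_cl
  list(
    classes = cl, counts = counts, included = included,
    included_classes = keep_cl, testable = length(keep_cl) >= 2
  )
}

#' Univariate permutation test for one branch
#'
#' One-way ANOVA F across the included genotype classes, with a permutation
#' p-value: phenotype rows are permuted and the add-one estimator
#' `(1 + #{F* >= F}) / (1 + B)` is used so the p-value is never zero.
#'
#' @param y numeric phenotype (already adjusted).
#' @param classes genotype classes for the same rows (after class filtering).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return tibble: F, df1, df2, p_nominal.
#' @export
univariate_branch_test <- function(y, classes, n_perm = 10000L, seed = 1L) {
  classes <- as.factor(classes)
  if (nlevels(classes) < 2) abort("need at least two genotype classes")
  obs <- anova_F(y, classes)
  n <- length(y)
  perm_F <- with_seed(derive_seed(seed, "branch-test"), {
    vapply(seq_len(n_perm), function(b) anova_F(y[sample.int(n)], classes)[["F"]], 0)
  })
  tibble(
    F = obs[["F"]], df1 = obs[["df1"]], df2 = obs[["df2"]],
    p_nominal = (1 + sum(perm_F >= obs[["F"]])) / (1 + n_perm)
  )
}

# permutation index matrix, optionally stratified (permutes within strata)
permutation_indices <- function(n, n_perm, seed, strata = NULL) {
  with_seed(seed, {
    if (is.null(strata)) {
      matrix(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)), n, n_perm)
    } else {
      idx <- seq_len(n)
      groups <- split(idx, strata)
      out <- matrix(0L, n, n_perm)
      for (b in seq_len(n_perm)) {
        col <- idx
        for (g in groups) col[g] <- g[sample.int(length(g))]
        out[, b] <- col
      }
      out
    }
  })
}

# Westfall-Young step-down maxT corrected p-values.
# obs: m observed statistics; perm: m x B matrix on a shared stream.
stepdown_maxT <- function(obs, perm) {
  m <- length(obs)
  B <- ncol(perm)
  ord <- order(obs, decreasing = TRUE)
  perm_sorted <- perm[ord, , drop = FALSE]
  # successive maxima from the bottom of the sorted list upwards
  u <- perm_sorted
  if (m > 1) {
    for (i in (m - 1):1) u[i, ] <- pmax(u[i, ], u[i + 1, ])
  }
  p_sorted <- (1 + rowSums(u >= obs[ord])) / (1 + B)
  p_sorted <- cummax(p_sorted) # enforce monotonicity down the sorted list
  p <- numeric(m)
  p[ord] <- p_sorted
  p
}

# Per-branch test machinery via QR projections.  X0 is the conditioning
# design (intercept, plus blocking-factor dummies for a second-round scan),
# X1 adds the branch's genotype-class dummies.  Works on the branch's
# included rows; permuted phenotypes are the globally permuted columns
# restricted to those rows.
branch_test_engine <- function(classes, included, strata = NULL) {
  ni <- sum(included)
  cl <- factor(classes[included])
  X0 <- matrix(1, ni, 1)
  if (!is.null(strata)) {
    s <- factor(strata[included])
    if (nlevels(s) > 1) X0 <- model.matrix(~s)
  }
  X1 <- cbind(X0, model.matrix(~cl)[, -1, drop = FALSE])
  q0 <- qr(X0)
  q1 <- qr(X1)
  r0 <- q0$rank
  r1 <- q1$rank
  Q0 <- qr.Q(q0)[, seq_len(r0), drop = FALSE]
  Q1 <- qr.Q(q1)[, seq_len(r1), drop = FALSE]
  list(
    included = included, Q0 = Q0, Q1 = Q1,
    df_h = r1 - r0, df_e = ni - r1, ni = ni, k = nlevels(cl)
  )
}

# F statistics for a matrix of phenotype columns (ni x B) under one engine
engine_F <- function(eng, Ym) {
  css <- colSums(Ym^2)
  rss0 <- css - colSums(crossprod(eng$Q0, Ym)^2)
  rss1 <- css - colSums(crossprod(eng$Q1, Ym)^2)
  if (eng$df_h == 0) {
    return(rep(0, ncol(Ym)))
  }
  den <- rss1 / eng$df_e
  f <- ((rss0 - rss1) / eng$df_h) / den
  f[den <= 1e-12] <- ifelse((rss0 - rss1)[den <= 1e-12] <= 1e-12, 0, Inf)
  f
}

# Wilk's lambda comparing X1 vs X0 for a multivariate response; Yl is a list
# of p matrices (ni x B).  Returns a vector of B lambdas.
engine_lambda <- function(eng, Yl) {
  p <- length(Yl)
  B <- ncol(Yl[[1]])
  C0 <- vector("list", p)
  C1 <- vector("list", p)
  for (j in seq_len(p)) {
    C0[[j]] <- crossprod(eng$Q0, Yl[[j]])
    C1[[j]] <- crossprod(eng$Q1, Yl[[j]])
  }
  cross <- array(0, dim = c(p, p, B))
  e0 <- array(0, dim = c(p, p, B))
  e1 <- array(0, dim = c(p, p, B))
  for (j in seq_len(p)) {
    for (l in j:p) {
      cj <- colSums(Yl[[j]] * Yl[[l]])
      a0 <- cj - colSums(C0[[j]] * C0[[l]])
      a1 <- cj - colSums(C1[[j]] * C1[[l]])
      e0[j, l, ] <- e0[l, j, ] <- a0
      e1[j, l, ] <- e1[l, j, ] <- a1
    }
  }
  vapply(seq_len(B), function(b) {
    d1 <- determinant(e1[, , b], logarithm = TRUE)
    d0 <- determinant(e0[, , b], logarithm = TRUE)
    if (d1$sign <= 0 || d0$sign <= 0) {
      return(NA_real_)
    }
    exp(as.numeric(d1$modulus - d0$modulus))
  }, 0)
}

#' Scan a haplotype network for phenotype associations
#'
#' For every testable branch of the network (after the minimum class-size
#' filter), runs a one-way permutation ANOVA per phenotype and, if
#' `multivariate = TRUE`, a one-way MANOVA over all phenotypes jointly.
#' Nominal p-values use the add-one permutation estimator; corrected
#' p-values use the step-down max-statistic procedure over branches with a
#' shared permutation stream, so correlated branches are not over-penalised.
#' Passing `condition_on` re-runs the scan of a second round with that
#' branch's genotype class as a blocking factor: branch effects are tested
#' after the conditioning factor and permutations are restricted within its
#' strata.
#'
#' @param data data frame with columns `hap_a`, `hap_b`, the phenotypes and
#'   covariates, and optionally `population`.
#' @param network a tree-shaped `haplotype_network` (see [resolve_loops()]),
#'   or a branch table from [enumerate_branches()].
#' @param phenotypes phenotype column names to test.  Total cholesterol is a
#'   composite of the other lipids and should not be included in the
#'   multivariate test.
#' @param covariates covariates adjusted out by OLS before testing; use
#'   `character(0)` if `data` is already adjusted.
#' @param population if given, restrict the scan to this population.
#' @param min_class_count minimum genotype-class size (default 5).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param multivariate also run the branch-wise MANOVA.
#' @param condition_on branch id whose genotype class is used as a blocking
#'   factor (second-round conditional scan).
#' @return An object of class `treescan_result` with elements `univariate`
#'   (tibble: branch, phenotype, class counts, F, p_nominal, p_corrected),
#'   `multivariate` (tibble: branch, lambda, F, df1, df2, p_parametric,
#'   p_nominal, p_corrected), `untestable`, and `config`.
#' @export
treescan <- function(data, network, phenotypes = c("tg", "hdl", "vldl", "ldl"),
                     covariates = c("age", "sex", "bmi"),
                     population = NULL,
                     min_class_count = 5L, n_perm = 10000L, seed = 1L,
                     multivariate = TRUE, condition_on = NULL) {
  branches <- if (inherits(network, "haplotype_network")) {
    enumerate_branches(network)
  } else {
    network
  }
  if (!is.null(population)) data <- data %>% filter(.data$population %in% !!population)
  used_cols <- c(phenotypes, covariates)
  ok <- complete.cases(data[, used_cols, drop = FALSE]) &
    !is.na(data$hap_a) & !is.na(data$hap_b)
  n_dropped_rows <- sum(!ok)
  data <- data[ok, , drop = FALSE]
  known <- unique(c(branches$side_a %>% unlist(), branches$side_b %>% unlist()))
  bad_hap <- setdiff(unique(c(data$hap_a, data$hap_b)), known)
  if (length(bad_hap)) {
    abort(paste0("diplotypes reference haplotype(s) absent from the network: ",
      paste(bad_hap, collapse = ", ")))
  }
  if (length(covariates)) data <- adjust_phenotypes(data, phenotypes, covariates)
  n <- nrow(data)

  strata <- NULL
  if (!is.null(condition_on)) {
    row <- branches %>% filter(.data$branch == condition_on)
    if (nrow(row) != 1) abort(paste0("unknown conditioning branch: ", condition_on))
    strata <- genotype_classes(data, row$side_b[[1]], min_count = 1L)$classes
  }

  # classing per branch
  classing <- purrr::map(seq_len(nrow(branches)), function(i) {
    genotype_classes(data, branches$side_b[[i]], min_count = min_class_count)
  })
  testable <- vapply(classing, `[[`, TRUE, "testable")
  untestable <- tibble(
    branch = branches$branch[!testable],
    reason = "fewer than two genotype classes pass the size filter"
  )
  if (!any(testable)) abort("no testable branch (all filtered by class size)")
  bidx <- which(testable)
  m <- length(bidx)

  perm <- permutation_indices(n, n_perm, derive_seed(seed, "scan"), strata = strata)
  engines <- purrr::map(bidx, function(i) {
    branch_test_engine(classing[[i]]$classes, classing[[i]]$included, strata = strata)
  })

  # univariate: observed and permuted F per phenotype and branch
  uni_rows <- list()
  for (ph in phenotypes) {
    y <- data[[ph]]
    Yp <- matrix(y[perm], n, n_perm)
    obs <- numeric(m)
    permF <- matrix(0, m, n_perm)
    for (e in seq_len(m)) {
      eng <- engines[[e]]
      obs[e] <- engine_F(eng, matrix(y[eng$included], ncol = 1))
      permF[e, ] <- engine_F(eng, Yp[eng$included, , drop = FALSE])
    }
    p_nom <- (1 + rowSums(permF >= obs)) / (1 + n_perm)
    p_cor <- stepdown_maxT(obs, permF)
    uni_rows[[ph]] <- tibble(
      branch = branches$branch[bidx], phenotype = ph,
      n_AA = vapply(classing[bidx], function(cc) unname(cc$counts["AA"] * (0 %in% cc$included_classes)), 0),
      n_AB = vapply(classing[bidx], function(cc) unname(cc$counts["AB"] * (1 %in% cc$included_classes)), 0),
      n_BB = vapply(classing[bidx], function(cc) unname(cc$counts["BB"] * (2 %in% cc$included_classes)), 0),
      F = obs,
      p_nominal = p_nom, p_corrected = pmax(p_cor, p_nom)
    )
  }
  univariate <- bind_rows(uni_rows) %>% arrange(.data$branch, .data$phenotype)

  multiv <- NULL
  if (multivariate && length(phenotypes) >= 2) {
    Yl <- purrr::map(phenotypes, function(ph) matrix(data[[ph]][perm], n, n_perm))
    p <- length(phenotypes)
    obsF <- numeric(m)
    permF <- matrix(0, m, n_perm)
    lam <- numeric(m)
    dfs <- matrix(0, m, 2)
    p_param <- numeric(m)
    for (e in seq_len(m)) {
      eng <- engines[[e]]
      Yobs <- purrr::map(phenotypes, function(ph) matrix(data[[ph]][eng$included], ncol = 1))
      lam[e] <- engine_lambda(eng, Yobs)
      fm <- wilks_full_model_p(lam[e], p, eng$df_h, eng$df_e)
      obsF[e] <- fm$F
      dfs[e, ] <- c(fm$df1, fm$df2)
      p_param[e] <- fm$p_value
      lam_perm <- engine_lambda(eng, purrr::map(Yl, function(M) M[eng$included, , drop = FALSE]))
      lam_perm[is.na(lam_perm)] <- 1
      permF[e, ] <- vapply(lam_perm, function(lb) wilks_full_model_p(lb, p, eng$df_h, eng$df_e)$F, 0)
    }
    p_nom <- (1 + rowSums(permF >= obsF)) / (1 + n_perm)
    p_cor <- stepdown_maxT(obsF, permF)
    multiv <- tibble(
      branch = branches$branch[bidx], lambda = lam, F = obsF,
      df1 = dfs[, 1], df2 = dfs[, 2],
      p_parametric = p_param, p_nominal = p_nom, p_corrected = pmax(p_cor, p_nom)
    )
  }

  structure(
    list(
      univariate = univariate, multivariate = multiv, untestable = untestable,
      config = list(
        phenotypes = phenotypes, covariates = covariates,
        population = population, min_class_count = min_class_count,
        n_perm = n_perm, seed = seed, condition_on = condition_on,
        n_individuals = n, n_dropped_rows = n_dropped_rows,
        n_branches = nrow(branches), n_testable = m
      )
    ),
    class = "treescan_result"
  )
}

#' @export
print.treescan_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<treescan_result> %d/%d testable branches, %d individuals, %d permutations%s\n",
    cfg$n_testable, cfg$n_branches, cfg$n_individuals, cfg$n_perm,
    if (!is.null(cfg$condition_on)) paste0(", conditioned on ", cfg$condition_on) else ""
  ))
  top <- x$univariate %>% arrange(.data$p_corrected, .data$p_nominal) %>% head(5)
  print(top)
  invisible(x)
}

#' Per-branch univariate scan results
#'
#' @param x a `treescan_result`.
#' @param ... unused.
#' @return the univariate results tibble.
#' @export
tidy.treescan_result <- function(x, ...) x$univariate

#' One-row scan summary
#'
#' @param x a `treescan_result`.
#' @param ... unused.
#' @return one-row tibble with counts and the best corrected p-value.
#' @export
glance.treescan_result <- function(x, ...) {
  tibble(
    n_branches = x$config$n_branches, n_testable = x$config$n_testable,
    n_individuals = x$config$n_individuals, n_perm = x$config$n_perm,
    min_p_corrected = min(x$univariate$p_corrected),
    top_branch = x$univariate$branch[which.min(x$univariate$p_corrected)]
  )
}

#' Plot scan results
#'
#' -log10 nominal and corrected p-values per branch and phenotype.
#'
#' @param object a `treescan_result`.
#' @param alpha significance line, default 0.05.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.treescan_result <- function(object, alpha = 0.05, ...) {
  d <- object$univariate %>%
    tidyr::pivot_longer(c("p_nominal", "p_corrected"),
      names_to = "type", values_to = "p"
    ) %>%
    mutate(type = sub("p_", "", .data$type))
  ggplot2::ggplot(d, ggplot2::aes(.data$branch, -log10(.data$p),
    colour = .data$type, shape = .data$type
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::labs(x = "branch", y = expression(-log[10](p)), colour = NULL, shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
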