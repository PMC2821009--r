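test_that("covariate adjustment matches closed-form least squares", {
  # constant covariates: intercept-only fit, i.e. mean-centring
  d <- tibble::tibble(age = rep(5, 6), sex = rep(1, 6), bmi = rep(2, 6), y = c(1, 2, 3, 4, 5, 6))
  adj <- adjust_phenotypes(d, "y")
  expect_equal(adj$y, d$y - mean(d$y))

  # 6-row example against explicit normal equations
  d2 <- tibble::tibble(
    age = c(20, 30, 40, 50, 60, 25), sex = c(0, 1, 0, 1, 0, 1),
    bmi = c(22, 25, 28, 31, 27, 24),
    y = c(1.2, 2.1, 0.3, 4.2, 1.1, 2.5)
  )
  X <- cbind(1, d2$age, d2$sex, d2$bmi)
  beta <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(adjust_phenotypes(d2, "y")$y, as.numeric(d2$y - X %*% beta))

  # residuals orthogonal to covariates
  set.seed(1)
  d3 <- tibble::tibble(age = runif(200, 18, 65), sex = rbinom(200, 1, .5), bmi = rnorm(200, 28, 5))
  d3$y <- 2 * d3$age + rnorm(200)
  expect_lt(abs(cor(adjust_phenotypes(d3, "y")$y, d3$age)), 1e-10)

  expect_error(
    adjust_phenotypes(dplyr::mutate(d3, age2 = 2 * age), "y", c("age", "age2")),
    "collinear"
  )
  expect_error(adjust_phenotypes(d3, "y", "missing_cov"), "not in data")
})

test_that("genotype classing applies the minimum-count filter", {
  mk <- function(n0, n1, n2) {
    tibble::tibble(
      hap_a = c(rep("anc", n0 + n1), rep("der", n2)),
      hap_b = c(rep("anc", n0), rep("der", n1 + n2))
    )
  }
  # the common/heterozygote/rare-homozygote pattern of a real branch
  gc <- genotype_classes(mk(1263, 156, 7), side_b = "der", min_count = 5)
  expect_equal(unname(gc$counts), c(1263, 156, 7))
  expect_setequal(gc$included_classes, 0:2)
  expect_true(gc$testable)

  gc2 <- genotype_classes(mk(100, 4, 0), side_b = "der", min_count = 5)
  expect_equal(gc2$included_classes, 0L)
  expect_false(gc2$testable)
  expect_equal(sum(gc2$included), 100)

  gc3 <- genotype_classes(mk(50, 0, 0), side_b = "der")
  expect_false(gc3$testable)
  expect_equal(sum(gc$counts), 1263 + 156 + 7)
})

test_that("univariate branch F matches a hand-computed ANOVA and flags perfect separation", {
  y <- c(3, 4, 5, 6, 1, 2, 2, 3, 7, 8, 9, 6)
  cl <- rep(1:3, each = 4)
  res <- univariate_branch_test(y, cl, n_perm = 199, seed = 5)
  grand <- mean(y)
  ssb <- sum(tapply(y, cl, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, cl, function(v) sum((v - mean(v))^2)))
  expect_equal(res$F, (ssb / 2) / (ssw / 9))
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 9)

  # perfect separation: observed F is maximal over permutations
  sep <- univariate_branch_test(c(1, 1, 1, 2, 2, 2), rep(1:2, each = 3),
    n_perm = 499, seed = 2
  )
  expect_true(is.infinite(sep$F))
  # p equals the proportion of permutations reproducing the separation
  set.seed(phyloscan:::derive_seed(2, "branch-test"))
  hits <- 0
  for (b in 1:499) {
    yp <- c(1, 1, 1, 2, 2, 2)[sample.int(6)]
    if (length(unique(yp[1:3])) == 1 && length(unique(yp[4:6])) == 1) hits <- hits + 1
  }
  expect_equal(sep$p_nominal, (1 + hits) / 500)
})

test_that("a single testable branch gets corrected p equal to nominal p", {
  fx <- toy_scan_fixture(n = 80, seed = 3)
  # network with a single branch: two haplotypes only
  haps <- tibble::tibble(haplotype = c("h1", "h2"), sequence = c("A", "T"), freq = c(.6, .4))
  net <- build_network(haps, limit = 1)
  ind <- fx$individuals
  ind$hap_a <- ifelse(ind$hap_a == "h3", "h2", ind$hap_a)
  ind$hap_b <- ifelse(ind$hap_b == "h3", "h2", ind$hap_b)
  sc <- treescan(ind, net, phenotypes = "hdl", n_perm = 300, seed = 4, multivariate = FALSE)
  expect_equal(sc$univariate$p_corrected, sc$univariate$p_nominal)
})

test_that("perfectly correlated branches are not penalised by the correction", {
  fx <- toy_scan_fixture(n = 100, seed = 6)
  br <- enumerate_branches(fx$network)
  twin <- br[c(1, 1), ] # two branches inducing the identical bipartition
  twin$branch <- c("b1", "b1_copy")
  sc <- treescan(fx$individuals, twin,
    phenotypes = "tg", n_perm = 300, seed = 9,
    multivariate = FALSE
  )
  u <- sc$univariate
  expect_equal(u$p_corrected, u$p_nominal, tolerance = 1e-12)
})

test_that("step-down correction matches a brute-force max-statistic oracle", {
  fx <- toy_scan_fixture(n = 50, seed = 12)
  br <- enumerate_branches(fx$network)
  n_perm <- 200
  sc <- treescan(fx$individuals, br,
    phenotypes = "hdl", covariates = c("age", "sex", "bmi"),
    min_class_count = 2, n_perm = n_perm, seed = 31, multivariate = FALSE
  )
  u <- sc$univariate
  # oracle: same permutation stream, F via stats::lm/anova, definitionally
  adj <- adjust_phenotypes(fx$individuals, "hdl")
  n <- nrow(adj)
  perm <- phyloscan:::permutation_indices(n, n_perm, phyloscan:::derive_seed(31, "scan"))
  m <- nrow(br)
  obs <- numeric(m)
  permF <- matrix(0, m, n_perm)
  for (i in seq_len(m)) {
    gc <- genotype_classes(adj, br$side_b[[i]], min_count = 2)
    incl <- gc$included
    cl <- factor(gc$classes[incl])
    f_of <- function(y) {
      a <- anova(lm(y ~ cl))
      a[["F value"]][1]
    }
    obs[i] <- f_of(adj$hdl[incl])
    for (b in seq_len(n_perm)) permF[i, b] <- f_of(adj$hdl[perm[, b]][incl])
  }
  oracle_p <- oracle_maxT(obs, permF)
  got <- u[match(br$branch, u$branch), ]
  expect_equal(got$F, obs, tolerance = 1e-10)
  expect_equal(got$p_corrected, pmax(oracle_p, got$p_nominal), tolerance = 1e-12)
  # nominal from the same stream
  expect_equal(got$p_nominal, (1 + rowSums(permF >= obs)) / (1 + n_perm), tolerance = 1e-12)
})

test_that("corrected p-values dominate nominal ones and stay monotone", {
  fx <- toy_scan_fixture(n = 120, seed = 17)
  sc <- treescan(fx$individuals, fx$network, n_perm = 200, seed = 1, min_class_count = 3)
  expect_true(all(sc$univariate$p_corrected >= sc$univariate$p_nominal))
  expect_true(all(sc$multivariate$p_corrected >= sc$multivariate$p_nominal))
  for (ph in unique(sc$univariate$phenotype)) {
    u <- sc$univariate[sc$univariate$phenotype == ph, ]
    u <- u[order(-u$F), ]
    expect_true(all(diff(u$p_corrected) >= -1e-12))
  }
})

test_that("conditioning on the tested branch itself leaves nothing to test", {
  fx <- toy_scan_fixture(n = 150, seed = 23)
  br <- enumerate_branches(fx$network)
  sc <- treescan(fx$individuals, fx$network,
    phenotypes = "hdl", n_perm = 100,
    seed = 3, multivariate = FALSE, condition_on = br$branch[1]
  )
  self <- sc$univariate[sc$univariate$branch == br$branch[1], ]
  expect_equal(self$F, 0)
  expect_equal(self$p_nominal, 1)
})

test_that("conditioning on an unrelated branch preserves a true branch effect", {
  # effect on the h2-side branch; condition on an independent rare branch
  set.seed(41)
  n <- 800
  haps <- tibble::tibble(
    haplotype = c("h1", "h2", "h3"),
    sequence = c("AAAA", "AATT", "TAAA"), # h2 and h3 attach to h1 independently
    freq = c(0.6, 0.25, 0.15)
  )
  net <- resolve_loops(build_network(haps, limit = 2))
  ind <- tibble::tibble(
    id = as.character(1:n), population = "P",
    hap_a = sample(haps$haplotype, n, TRUE, haps$freq),
    hap_b = sample(haps$haplotype, n, TRUE, haps$freq),
    age = runif(n, 18, 65), sex = rbinom(n, 1, .5), bmi = rnorm(n, 28, 5)
  )
  g <- (ind$hap_a == "h2") + (ind$hap_b == "h2")
  ind$hdl <- 0.4 * g + rnorm(n)
  ind$tg <- rnorm(n)
  ind$vldl <- rnorm(n)
  ind$ldl <- rnorm(n)
  br <- enumerate_branches(net)
  target <- br$branch[vapply(br$side_b, function(s) setequal(s, "h2"), TRUE)]
  other <- br$branch[vapply(br$side_b, function(s) setequal(s, "h3"), TRUE)]
  un <- treescan(ind, net, phenotypes = "hdl", n_perm = 300, seed = 5, multivariate = FALSE)
  cond <- treescan(ind, net,
    phenotypes = "hdl", n_perm = 300, seed = 5,
    multivariate = FALSE, condition_on = other
  )
  p_un <- un$univariate$p_nominal[un$univariate$branch == target]
  p_cond <- cond$univariate$p_nominal[cond$univariate$branch == target]
  expect_lt(p_cond, 0.05) # effect survives irrelevant conditioning
  expect_lt(abs(p_cond - p_un), 0.05)
})

test_that("merging excluded-class singletons changes nothing for the other branches", {
  fx <- toy_scan_fixture(n = 200, seed = 51)
  # add one singleton haplotype carried by a single individual
  haps <- dplyr::bind_rows(
    fx$haplotypes,
    tibble::tibble(haplotype = "h4", sequence = "AAAC", freq = 0)
  )
  haps$freq <- c(0.6, 0.3, 0.095, 0.005)
  net <- resolve_loops(build_network(haps))
  ind <- fx$individuals
  ind$hap_b[1] <- "h4" # h4 attaches to h1; its carrier was h?/h? before
  ind$hap_a[1] <- "h1"
  sc_with <- treescan(ind, net, phenotypes = "hdl", n_perm = 200, seed = 7, multivariate = FALSE)
  # merge the singleton back into its parent and rescan on the smaller network
  ind2 <- ind
  ind2$hap_a[ind2$hap_a == "h4"] <- "h1"
  ind2$hap_b[ind2$hap_b == "h4"] <- "h1"
  sc_without <- treescan(ind2, fx$network,
    phenotypes = "hdl", n_perm = 200, seed = 7,
    multivariate = FALSE
  )
  shared <- intersect(sc_with$univariate$branch, sc_without$univariate$branch)
  expect_true(length(shared) >= 1)
  a <- sc_with$univariate[sc_with$univariate$branch %in% shared, ]
  b <- sc_without$univariate[sc_without$univariate$branch %in% shared, ]
  expect_equal(a$F, b$F, tolerance = 1e-12)
  expect_equal(a$p_nominal, b$p_nominal, tolerance = 1e-12)
  # the singleton's own pendant branch was untestable
  expect_true(any(grepl("h4", sc_with$untestable$branch)))
})

test_that("scan output is invariant to the phasing of a singleton heterozygote", {
  set.seed(61)
  n <- 120
  # backgrounds b1 and b2 differ at site 2; the singleton variant at site 4
  # can be phased onto either background
  base <- tibble::tibble(
    haplotype = c("b1", "b2"), sequence = c("AAAA", "ATAA"), freq = c(.6, .4)
  )
  ind <- tibble::tibble(
    id = as.character(1:n), population = "P",
    hap_a = sample(base$haplotype, n, TRUE, base$freq),
    hap_b = sample(base$haplotype, n, TRUE, base$freq),
    age = runif(n, 18, 65), sex = rbinom(n, 1, .5), bmi = rnorm(n, 28, 5),
    tg = rnorm(n), hdl = rnorm(n), vldl = rnorm(n), ldl = rnorm(n)
  )
  phase_a <- list(
    haps = dplyr::bind_rows(base, tibble::tibble(haplotype = "s", sequence = "AAAT", freq = 0.004)),
    pair = c("s", "b2")
  )
  phase_b <- list(
    haps = dplyr::bind_rows(base, tibble::tibble(haplotype = "s", sequence = "ATAT", freq = 0.004)),
    pair = c("b1", "s")
  )
  run <- function(ph) {
    ind2 <- ind
    ind2$hap_a[1] <- ph$pair[1]
    ind2$hap_b[1] <- ph$pair[2]
    net <- resolve_loops(build_network(ph$haps))
    treescan(ind2, net,
      phenotypes = c("tg", "hdl"), n_perm = 150, seed = 13,
      min_class_count = 1, multivariate = FALSE
    )
  }
  res_a <- run(phase_a)
  res_b <- run(phase_b)
  # identify corresponding branches: the background split and the pendant edge
  get <- function(res, branch) {
    out <- res$univariate[res$univariate$branch == branch, c("F", "p_nominal", "p_corrected")]
    out[order(res$univariate$phenotype[res$univariate$branch == branch]), ]
  }
  expect_identical(get(res_a, "b1-b2"), get(res_b, "b1-b2"))
  pend_a <- grep("s", res_a$univariate$branch, value = TRUE)[1]
  pend_b <- grep("s", res_b$univariate$branch, value = TRUE)[1]
  expect_identical(get(res_a, pend_a), get(res_b, pend_b))
})

test_that("diplotypes referencing unknown haplotypes are rejected", {
  fx <- toy_scan_fixture(n = 30, seed = 2)
  ind <- fx$individuals
  ind$hap_a[5] <- "ghost"
  expect_error(
    treescan(ind, fx$network, n_perm = 10, seed = 1),
    "ghost"
  )
})

test_that("tidy and glance expose the scan results", {
  fx <- toy_scan_fixture(n = 80, seed = 7)
  sc <- treescan(fx$individuals, fx$network,
    phenotypes = c("tg", "hdl"),
    n_perm = 50, seed = 1, multivariate = FALSE
  )
  expect_identical(tidy(sc), sc$univariate)
  g <- glance(sc)
  expect_equal(g$n_testable, sc$config$n_testable)
  expect_s3_class(autoplot(sc), "ggplot")
})
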