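# Independent oracle implementations used across the suite.  Each is coded
# from the definition, independently of the package's own code paths.

# two-tailed Fisher exact p by full enumeration of the hypergeometric support
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[, 1]) # column-1 total
  n2 <- sum(tab[, 2])
  k <- sum(tab[1, ]) # row-1 total
  supp <- max(0, k - n2):min(k, m)
  pr <- dhyper(supp, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# conditional-MLE odds ratio: psi solving E_psi[A] = a under the noncentral
# hypergeometric distribution with the table's margins
oracle_cml_or <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[, 1])
  n2 <- sum(tab[, 2])
  k <- sum(tab[1, ])
  supp <- max(0, k - n2):min(k, m)
  mean_a <- function(log_psi) {
    w <- dhyper(supp, m, n2, k) * exp(supp * log_psi)
    sum(supp * w) / sum(w)
  }
  if (a == min(supp)) return(0)
  if (a == max(supp)) return(Inf)
  exp(uniroot(function(lp) mean_a(lp) - a, c(-30, 30), tol = 1e-12)$root)
}

# step-down max-statistic corrected p-values, straight from the definition
oracle_maxT <- function(obs, perm) {
  m <- length(obs)
  B <- ncol(perm)
  ord <- order(obs, decreasing = TRUE)
  p <- numeric(m)
  for (r in seq_len(m)) {
    i <- ord[r]
    later <- ord[r:m]
    count <- 0
    for (b in seq_len(B)) {
      if (max(perm[later, b]) >= obs[i]) count <- count + 1
    }
    p[i] <- (1 + count) / (1 + B)
  }
  # monotonicity down the sorted list
  for (r in 2:m) p[ord[r]] <- max(p[ord[r]], p[ord[r - 1]])
  p
}

# Independent coding of the parsimony-probability computation: same model
# (Poisson hits per site, Jukes-Cantor multiple-hit correction, ML divergence
# estimate), written from the closed forms rather than the package's code.
oracle_parsimony_limit <- function(L, conf = 0.95) {
  p_pars <- function(j) {
    if (j == 0) return(1)
    q <- j / L
    if (q >= 0.75) return(0)
    th <- -3 / 4 * log1p(-4 * q / 3)
    exp(j * (log(th) - th - log(0.75 * (1 - exp(-4 * th / 3)))) +
      (L - j) * (-th - log1p(-0.75 * (1 - exp(-4 * th / 3)))))
  }
  j <- 1
  while (j < L && p_pars(j + 1) > conf) j <- j + 1
  j
}

# minimum number of mutations on a rooted tree by exhaustive enumeration of
# all internal-node labelings (tiny trees only)
oracle_min_mutations <- function(edges, tip_states, states) {
  internals <- setdiff(unique(edges$parent), names(tip_states))
  internals <- union(internals, setdiff(unique(edges$child), c(names(tip_states), internals)))
  grid <- expand.grid(rep(list(states), length(internals)), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_states, setNames(unlist(grid[r, ]), internals))
    cost <- sum(lab[edges$parent] != lab[edges$child])
    best <- min(best, cost)
  }
  best
}

# small-cohort builder shared by scan tests: explicit haplotypes + network
toy_scan_fixture <- function(n = 60, seed = 11) {
  haps <- tibble::tibble(
    haplotype = c("h1", "h2", "h3"),
    sequence = c("AAAA", "AAAT", "AATT"),
    freq = c(0.6, 0.3, 0.1)
  )
  net <- resolve_loops(build_network(haps))
  set.seed(seed)
  ind <- tibble::tibble(
    id = sprintf("i%03d", 1:n),
    population = "P1",
    hap_a = sample(haps$haplotype, n, replace = TRUE, prob = haps$freq),
    hap_b = sample(haps$haplotype, n, replace = TRUE, prob = haps$freq),
    age = runif(n, 18, 65), sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 28, 5),
    tg = rnorm(n), hdl = rnorm(n), vldl = rnorm(n), ldl = rnorm(n)
  )
  ind$chol <- ind$ldl + ind$hdl + ind$vldl + rnorm(n, sd = 0.1)
  list(haplotypes = haps, network = net, individuals = ind)
}
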