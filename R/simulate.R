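# Synthetic cohort generator.
#
# Emulates the data structure the scan assumes: a small set of haplotypes
# dominated by two common ones, with every derived haplotype one mutational
# step from its parent; diplotypes drawn under Hardy-Weinberg within each
# population; and correlated quantitative lipid phenotypes adjusted for
# age/sex/BMI, with an optional additive genetic effect tied to one branch
# of the haplotype genealogy.

#' Configuration for the synthetic cohort simulator
#'
#' Bundles and validates all simulation parameters.  Defaults emulate the
#' structure of a resequenced candidate-gene study: three populations of
#' realistic size, 45 haplotypes over a ~1.2 kb coding region where the two
#' common haplotypes carry just over three quarters of the chromosomes, four
#' correlated lipid phenotypes (triglycerides, HDL, VLDL, LDL) plus total
#' cholesterol as a composite, and a 0.5 SD HDL effect on a haplotype branch
#' of ~5 percent frequency.
#'
#' @param n_individuals named integer vector, individuals per population.
#' @param n_haplotypes total number of haplotypes to generate.
#' @param seq_length number of nucleotide sites (must allow one new mutated
#'   site per derived haplotype).
#' @param two_common_freq overall frequencies of the two dominant haplotypes.
#' @param effect_branch haplotype id naming the branch that carries the
#'   genetic effect: the pendant edge above that haplotype; the derived side
#'   is the haplotype plus all of its descendants in the simulated genealogy.
#' @param effect_sizes named numeric vector of per-phenotype additive shifts,
#'   in phenotype SD units per copy of the derived allele.
#' @param phenotype_corr 4x4 correlation matrix for the multivariate noise of
#'   tg, hdl, vldl, ldl (must be symmetric positive definite).
#' @param covariate_effects named numeric vector of coefficients for
#'   age, sex and bmi, applied to every phenotype.
#' @param seed integer seed; together with the config it fully determines the
#'   simulated cohort.
#' @return An object of class `phyloscan_sim_config` (a validated list).
#' @export
simulation_config <- function(n_individuals = c(AA = 1830L, EA = 1045L, MA = 601L),
                              n_haplotypes = 45L,
                              seq_length = 1218L,
                              two_common_freq = c(0.512, 0.260),
                              effect_branch = "h3",
                              effect_sizes = c(hdl = 0.5),
                              phenotype_corr = default_phenotype_corr(),
                              covariate_effects = c(age = 0.01, sex = 0.25, bmi = 0.03),
                              seed = 1L) {
  if (is.null(names(n_individuals)) || any(!nzchar(names(n_individuals)))) {
    abort("`n_individuals` must be a named vector (one entry per population).")
  }
  if (any(n_individuals < 1)) abort("`n_individuals` entries must be positive.")
  if (n_haplotypes < 2) abort("need at least two haplotypes")
  if (n_haplotypes - 1 > seq_length) {
    abort(sprintf(
      "infeasible config: %d haplotypes need %d mutated sites but seq_length is only %d",
      n_haplotypes, n_haplotypes - 1, seq_length
    ))
  }
  if (length(two_common_freq) != 2 || any(two_common_freq <= 0) ||
    sum(two_common_freq) >= 1) {
    abort("`two_common_freq` must be two positive frequencies summing to < 1.")
  }
  if (two_common_freq[1] < two_common_freq[2]) {
    abort("`two_common_freq` must be in decreasing order.")
  }
  phenos <- c("tg", "hdl", "vldl", "ldl")
  pc <- as.matrix(phenotype_corr)
  if (!isTRUE(all.equal(pc, t(pc))) ||
    !all(eigen(pc, symmetric = TRUE, only.values = TRUE)$values > 1e-10)) {
    abort("`phenotype_corr` must be symmetric positive-definite.")
  }
  if (nrow(pc) != 4) abort("`phenotype_corr` must be 4x4 (tg, hdl, vldl, ldl).")
  dimnames(pc) <- list(phenos, phenos)
  es <- setNames(rep(0, 4), phenos)
  if (length(effect_sizes)) {
    if (is.null(names(effect_sizes)) || !all(names(effect_sizes) %in% phenos)) {
      abort("`effect_sizes` must be named with a subset of tg, hdl, vldl, ldl.")
    }
    es[names(effect_sizes)] <- effect_sizes
  }
  ce <- c(age = 0, sex = 0, bmi = 0)
  ce[names(covariate_effects)] <- covariate_effects
  structure(
    list(
      n_individuals = as.integer(n_individuals) |> setNames(names(n_individuals)),
      n_haplotypes = as.integer(n_haplotypes),
      seq_length = as.integer(seq_length),
      two_common_freq = as.numeric(two_common_freq),
      effect_branch = effect_branch,
      effect_sizes = es,
      phenotype_corr = pc,
      covariate_effects = ce,
      seed = as.integer(seed)
    ),
    class = "phyloscan_sim_config"
  )
}

#' Default correlation matrix of the lipid phenotype noise
#'
#' Triglycerides and VLDL are strongly positively correlated (VLDL is carried
#' in triglyceride-rich particles), both are moderately anti-correlated with
#' HDL, and LDL is weakly correlated with the rest.
#'
#' @return a 4x4 correlation matrix over tg, hdl, vldl, ldl.
#' @export
default_phenotype_corr <- function() {
  p <- c("tg", "hdl", "vldl", "ldl")
  m <- diag(4)
  dimnames(m) <- list(p, p)
  m["tg", "vldl"] <- m["vldl", "tg"] <- 0.85
  m["tg", "hdl"] <- m["hdl", "tg"] <- -0.40
  m["hdl", "vldl"] <- m["vldl", "hdl"] <- -0.40
  m["tg", "ldl"] <- m["ldl", "tg"] <- 0.15
  m["vldl", "ldl"] <- m["ldl", "vldl"] <- 0.15
  m["hdl", "ldl"] <- m["ldl", "hdl"] <- 0.05
  m
}

# Overall haplotype frequency spectrum: the two configured common frequencies
# followed by a power-law tail (exponent 1.2), so a handful of intermediate
# haplotypes and many rare ones, mirroring observed candidate-gene spectra.
haplotype_frequency_spectrum <- function(n_haplotypes, two_common_freq) {
  rest <- n_haplotypes - 2L
  if (rest == 0L) {
    f <- two_common_freq / sum(two_common_freq)
  } else {
    w <- (seq_len(rest))^(-1.2)
    f <- c(two_common_freq, (1 - sum(two_common_freq)) * w / sum(w))
  }
  setNames(f, paste0("h", seq_len(n_haplotypes)))
}

#' Simulate a haplotype set
#'
#' Generates `n_haplotypes` aligned sequences by a frequency-weighted random
#' attachment process: the second haplotype differs from the first at one
#' site, and every further haplotype mutates one previously unused site off a
#' parent chosen with probability proportional to its frequency.  Every
#' haplotype therefore differs from its nearest neighbour at exactly one
#' site, giving the star-like single-step genealogy typical of within-species
#' candidate-gene data.
#'
#' @param config a [simulation_config()].
#' @return A list with `sequences` (tibble: haplotype, sequence),
#'   `frequencies` (tibble: haplotype, population, freq; includes an `"All"`
#'   population with the overall spectrum) and `genealogy` (tibble: child,
#'   parent, site, from, to).
#' @export
simulate_haplotype_set <- function(config) {
  stopifnot(inherits(config, "phyloscan_sim_config"))
  n <- config$n_haplotypes
  L <- config$seq_length
  f_all <- haplotype_frequency_spectrum(n, config$two_common_freq)
  with_seed(derive_seed(config$seed, "haplotypes"), {
    bases <- c("A", "C", "G", "T")
    seqs <- matrix("", nrow = n, ncol = L)
    seqs[1, ] <- sample(bases, L, replace = TRUE)
    free_sites <- sample.int(L) # order in which new mutated sites are used
    genealogy <- vector("list", n - 1L)
    for (k in 2:n) {
      parent <- if (k == 2) 1L else {
        sample.int(k - 1L, 1L, prob = f_all[seq_len(k - 1L)])
      }
      site <- free_sites[k - 1L]
      from <- seqs[parent, site]
      to <- sample(setdiff(bases, from), 1L)
      seqs[k, ] <- seqs[parent, ]
      seqs[k, site] <- to
      genealogy[[k - 1L]] <- tibble(
        child = paste0("h", k), parent = paste0("h", parent),
        site = site, from = from, to = to
      )
    }
    ids <- paste0("h", seq_len(n))
    # Per-population spectra: Dirichlet jitter around the overall spectrum
    # with a high concentration so the two common haplotypes stay dominant
    # in every population while rare-haplotype frequencies fluctuate.
    pops <- names(config$n_individuals)
    freq <- purrr::map(pops, function(p) {
      g <- stats::rgamma(n, shape = 400 * f_all)
      tibble(haplotype = ids, population = p, freq = g / sum(g))
    }) %>% bind_rows()
    freq <- bind_rows(tibble(haplotype = ids, population = "All", freq = unname(f_all)), freq)
    list(
      sequences = tibble(haplotype = ids, sequence = apply(seqs, 1, paste0, collapse = "")),
      frequencies = freq,
      genealogy = bind_rows(genealogy)
    )
  })
}

# Haplotypes on the derived side of the branch above `branch_hap`: the
# haplotype itself plus all its descendants in the genealogy.
derived_side_haplotypes <- function(genealogy, branch_hap) {
  if (!branch_hap %in% c(genealogy$child, genealogy$parent)) {
    abort(sprintf("effect_branch haplotype '%s' not in the genealogy", branch_hap))
  }
  out <- branch_hap
  frontier <- branch_hap
  while (length(frontier)) {
    kids <- genealogy$child[genealogy$parent %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  out
}

mvn_noise <- function(n, corr) {
  z <- matrix(rnorm(n * ncol(corr)), n, ncol(corr))
  z %*% chol(corr)
}

#' Simulate phenotypes for a cohort
#'
#' Each of tg, hdl, vldl and ldl is a covariate term plus an additive
#' branch-genotype effect (0/1/2 copies of the derived allele of the
#' configured effect branch, in SD units) plus correlated multivariate normal
#' noise with unit marginal SD.  Total cholesterol is the composite
#' `ldl + hdl + vldl` plus small independent noise, so excluding it from the
#' multivariate analysis is meaningful.
#'
#' @param individuals tibble with columns id, population, hap_a, hap_b,
#'   age, sex, bmi.
#' @param config a [simulation_config()].
#' @param genealogy genealogy tibble from [simulate_haplotype_set()] (used to
#'   resolve the derived side of the effect branch).
#' @return `individuals` with phenotype columns tg, hdl, vldl, ldl, chol.
#' @export
simulate_phenotypes <- function(individuals, config, genealogy) {
  stopifnot(inherits(config, "phyloscan_sim_config"))
  derived <- derived_side_haplotypes(genealogy, config$effect_branch)
  g <- (individuals$hap_a %in% derived) + (individuals$hap_b %in% derived)
  n <- nrow(individuals)
  ce <- config$covariate_effects
  covterm <- ce[["age"]] * individuals$age + ce[["sex"]] * individuals$sex +
    ce[["bmi"]] * individuals$bmi
  with_seed(derive_seed(config$seed, "phenotypes"), {
    noise <- mvn_noise(n, config$phenotype_corr)
    ph <- sweep(noise, 1, covterm, "+") +
      outer(g, config$effect_sizes)
    colnames(ph) <- colnames(config$phenotype_corr)
    individuals$tg <- ph[, "tg"]
    individuals$hdl <- ph[, "hdl"]
    individuals$vldl <- ph[, "vldl"]
    individuals$ldl <- ph[, "ldl"]
    individuals$chol <- ph[, "ldl"] + ph[, "hdl"] + ph[, "vldl"] + rnorm(n, sd = 0.1)
    individuals
  })
}

#' Simulate a full cohort
#'
#' Haplotype set, Hardy-Weinberg diplotypes within each population,
#' covariates (age uniform on 18-65, sex Bernoulli(0.5), BMI normal(28, 5))
#' and correlated phenotypes.  Identical config (including seed) yields an
#' identical cohort.
#'
#' @param config a [simulation_config()].
#' @return An object of class `phyloscan_cohort`: a list with `haplotypes`,
#'   `frequencies`, `genealogy`, `individuals` and the echoed `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  hs <- simulate_haplotype_set(config)
  pops <- names(config$n_individuals)
  inds <- with_seed(derive_seed(config$seed, "diplotypes"), {
    purrr::map(pops, function(p) {
      n <- config$n_individuals[[p]]
      f <- hs$frequencies %>% filter(.data$population == p)
      tibble(
        population = p,
        hap_a = sample(f$haplotype, n, replace = TRUE, prob = f$freq),
        hap_b = sample(f$haplotype, n, replace = TRUE, prob = f$freq),
        age = runif(n, 18, 65),
        sex = rbinom(n, 1, 0.5),
        bmi = rnorm(n, 28, 5)
      )
    }) %>%
      bind_rows() %>%
      mutate(id = sprintf("ind%05d", row_number()), .before = 1)
  })
  inds <- simulate_phenotypes(inds, config, hs$genealogy)
  structure(
    list(
      haplotypes = hs$sequences, frequencies = hs$frequencies,
      genealogy = hs$genealogy, individuals = inds, config = config
    ),
    class = "phyloscan_cohort"
  )
}

#' @export
print.phyloscan_cohort <- function(x, ...) {
  cat(sprintf(
    "<phyloscan_cohort> %d individuals in %d population(s), %d haplotypes, %d sites\n",
    nrow(x$individuals), length(unique(x$individuals$population)),
    nrow(x$haplotypes), nchar(x$haplotypes$sequence[1])
  ))
  invisible(x)
}

#' Carriers of a haplotype branch
#'
#' Flags the individuals carrying at least one haplotype from the derived
#' side of a branch of the simulated genealogy; useful for re-running
#' analyses with known rare-variant carriers removed.
#'
#' @param cohort a `phyloscan_cohort`.
#' @param branch_hap haplotype id naming the branch (as in
#'   [simulation_config()]'s `effect_branch`).
#' @return logical vector along `cohort$individuals`.
#' @export
branch_carriers <- function(cohort, branch_hap) {
  derived <- derived_side_haplotypes(cohort$genealogy, branch_hap)
  cohort$individuals$hap_a %in% derived | cohort$individuals$hap_b %in% derived
}
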