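# Readers, writers and pipeline orchestration.  TSV is the canonical
# tabular dialect (tab-separated, header, UTF-8, '.' decimal); FASTA wraps
# at 60 columns; every run writes a JSON manifest echoing the resolved
# configuration and seed so outputs are bit-reproducible from
# (inputs, config, seed).

required_cohort_cols <- c(
  "id", "population", "hap_a", "hap_b", "age", "sex", "bmi",
  "tg", "hdl", "vldl", "ldl", "chol"
)

write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(unlist(seqs)), names(seqs))
}

#' Write a simulated cohort to disk
#'
#' Writes `haplotypes.fasta`, `cohort.tsv` (one row per individual) and a
#' `cohort.json` sidecar echoing the simulation config and seed.
#'
#' @param cohort a `phyloscan_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phyloscan_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "haplotypes.fasta")
  tsv <- file.path(dir, "cohort.tsv")
  js <- file.path(dir, "cohort.json")
  write_fasta(setNames(cohort$haplotypes$sequence, cohort$haplotypes$haplotype), fa)
  readr::write_tsv(cohort$individuals[, required_cohort_cols], tsv)
  cfg <- unclass(cohort$config)
  cfg$phenotype_corr <- as.data.frame(cfg$phenotype_corr)
  jsonlite::write_json(cfg, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, tsv = tsv, json = js))
}

#' Read a cohort table
#'
#' Validates the header, flags duplicated individual ids, and (when a
#' haplotype FASTA is supplied) checks that every diplotype references a
#' known haplotype.
#'
#' @param path cohort TSV path.
#' @param fasta optional haplotype FASTA path for referential checks.
#' @return list with `individuals` (tibble) and `haplotypes` (tibble or
#'   NULL).
#' @export
read_cohort <- function(path, fasta = NULL) {
  ind <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), population = readr::col_character(),
    hap_a = readr::col_character(), hap_b = readr::col_character(),
    .default = readr::col_double()
  ))
  miss <- setdiff(required_cohort_cols, names(ind))
  if (length(miss)) abort(paste0("cohort file missing column(s): ", paste(miss, collapse = ", ")))
  dup <- ind$id[duplicated(ind$id)]
  if (length(dup)) abort(paste0("duplicated individual id(s): ", paste(unique(dup), collapse = ", ")))
  haps <- NULL
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    unknown <- setdiff(unique(c(ind$hap_a, ind$hap_b)), names(seqs))
    if (length(unknown)) {
      abort(paste0(
        "cohort references haplotype(s) absent from FASTA: ",
        paste(unknown, collapse = ", ")
      ))
    }
    haps <- tibble(haplotype = names(seqs), sequence = unname(seqs))
  }
  list(individuals = ind, haplotypes = haps)
}

#' Write a network edge list
#'
#' @param net a `haplotype_network`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path) {
  readr::write_tsv(
    net$edges %>% select("node_a", "node_b", "steps", "site", "change", "aa_change"),
    path
  )
  invisible(path)
}

#' Run the full scanning pipeline
#'
#' Orchestrates simulation (or reading) of a cohort, network construction
#' and loop resolution, the branch scan, and MANOVA follow-ups (with partial
#' Wilk's tests) on every branch whose multivariate corrected p-value passes
#' `followup_alpha`.  All outputs plus a JSON manifest are written to
#' `out_dir` when it is given.
#'
#' @param cohort a `phyloscan_cohort`, or a list with `individuals` and
#'   `haplotypes` tibbles as returned by [read_cohort()].
#' @param phenotypes,covariates,min_class_count,n_perm,seed,population,condition_on
#'   passed to [treescan()].
#' @param break_edges forced loop breaks passed to [resolve_loops()].
#' @param followup_alpha corrected-p threshold for MANOVA follow-ups.
#' @param out_dir optional output directory.
#' @return list with `network`, `scan` (a `treescan_result`), `followups`
#'   (named list of `branch_manova`), and `manifest`.
#' @export
run_pipeline <- function(cohort,
                         phenotypes = c("tg", "hdl", "vldl", "ldl"),
                         covariates = c("age", "sex", "bmi"),
                         population = NULL,
                         min_class_count = 5L, n_perm = 10000L, seed = 1L,
                         condition_on = NULL, break_edges = NULL,
                         followup_alpha = 0.05, out_dir = NULL) {
  haps <- cohort$haplotypes
  individuals <- cohort$individuals
  if (is.null(haps)) abort("cohort must carry haplotype sequences")
  # observed overall frequencies orient branches and drive loop resolution
  hap_counts <- table(c(individuals$hap_a, individuals$hap_b))
  haps$freq <- as.numeric(hap_counts[haps$haplotype])
  haps$freq[is.na(haps$freq)] <- 0
  haps$freq <- haps$freq / sum(haps$freq)
  observed <- haps %>% filter(.data$freq > 0)
  net <- build_network(observed) %>% resolve_loops(break_edges = break_edges)
  scan <- treescan(individuals, net,
    phenotypes = phenotypes, covariates = covariates,
    population = population, min_class_count = min_class_count,
    n_perm = n_perm, seed = seed, condition_on = condition_on
  )
  followups <- list()
  if (!is.null(scan$multivariate)) {
    sig <- scan$multivariate %>% filter(.data$p_corrected < followup_alpha)
    branches <- enumerate_branches(net)
    adj <- individuals
    if (!is.null(population)) adj <- adj %>% filter(.data$population %in% !!population)
    adj <- adj[complete.cases(adj[, c(phenotypes, covariates)]), ]
    if (length(covariates)) adj <- adjust_phenotypes(adj, phenotypes, covariates)
    for (b in sig$branch) {
      row <- branches %>% filter(.data$branch == b)
      gc <- genotype_classes(adj, row$side_b[[1]], min_count = min_class_count)
      followups[[b]] <- branch_manova(
        adj[gc$included, ], gc$classes[gc$included], phenotypes
      )
    }
  }
  manifest <- list(
    phenotypes = phenotypes, covariates = covariates, population = population,
    min_class_count = min_class_count, n_perm = n_perm, seed = seed,
    condition_on = condition_on, break_edges = break_edges,
    followup_alpha = followup_alpha,
    n_haplotypes = nrow(observed), n_branches = scan$config$n_branches,
    n_testable = scan$config$n_testable,
    n_dropped_rows = scan$config$n_dropped_rows,
    untestable_branches = scan$untestable$branch,
    removed_edges = net$removed_edges$edge
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_network(net, file.path(out_dir, "network.tsv"))
    readr::write_tsv(scan$univariate, file.path(out_dir, "scan_univariate.tsv"))
    if (!is.null(scan$multivariate)) {
      readr::write_tsv(scan$multivariate, file.path(out_dir, "scan_multivariate.tsv"))
    }
    if (length(followups)) {
      fu <- purrr::imap(followups, function(m, b) tidy(m) %>% mutate(branch = b, .before = 1)) %>%
        bind_rows()
      readr::write_tsv(fu, file.path(out_dir, "manova_followups.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(network = net, scan = scan, followups = followups, manifest = manifest)
}
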