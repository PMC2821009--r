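# Statistical-parsimony haplotype network: pairwise differences, the
# parsimony connection limit, network construction with retained alternative
# connections (loops), loop resolution by coalescent-motivated rules, and
# enumeration of branch bipartitions used as biallelic markers by the scan.

#' Pairwise nucleotide differences between aligned sequences
#'
#' @param seqs named character vector of aligned sequences, or a tibble with
#'   columns `haplotype` and `sequence`.
#' @return symmetric integer matrix of per-pair counts of differing sites.
#'   Ambiguity codes are not special-cased: any differing characters count as
#'   a difference.
#' @export
pairwise_differences <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$haplotype)
  if (length(unique(nchar(seqs))) != 1) {
    abort("sequences must be aligned (equal lengths)")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

# Probability that a pair of sequences showing j differences over L sites is
# connected parsimoniously, i.e. that no site experienced a superimposed
# change.  Sites mutate as independent Poisson processes with a common
# expected number of hits theta on the path joining the pair; multiple hits
# follow a Jukes-Cantor chain, so a site shows a difference with probability
# (3/4)(1 - exp(-4 theta / 3)).  theta is estimated by maximum likelihood
# from the observed proportion j/L, and the parsimony probability is the
# posterior probability that every differing site had exactly one hit and
# every identical site had none.
parsimony_probability <- function(j, seq_length) {
  if (j == 0) {
    return(1)
  }
  p_obs <- j / seq_length
  if (p_obs >= 0.75) {
    return(0)
  }
  theta <- -0.75 * log(1 - 4 * p_obs / 3)
  p_diff <- 0.75 * (1 - exp(-4 * theta / 3))
  p_one_given_diff <- theta * exp(-theta) / p_diff
  p_zero_given_same <- exp(-theta) / (1 - p_diff)
  p_one_given_diff^j * p_zero_given_same^(seq_length - j)
}

#' Parsimony connection limit
#'
#' Largest number of mutational steps at which two haplotypes may be
#' connected while the probability that the connection is parsimonious (no
#' superimposed change at any site) still exceeds `confidence`.  See the
#' methods vignette for the probability model.
#'
#' @param seq_length number of aligned nucleotide sites.
#' @param confidence required parsimony probability, default 0.95.
#' @return integer number of steps (always at least 1: single steps are
#'   parsimonious by construction).
#' @export
parsimony_connection_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length >= 1, confidence > 0, confidence < 1)
  j <- 1L
  while (j < seq_length && parsimony_probability(j + 1L, seq_length) > confidence) {
    j <- j + 1L
  }
  j
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects haplotypes in ascending order of pairwise distance, up to the
#' parsimony connection limit.  At each distance level, every pair of
#' haplotypes that still lie in different components is connected, so
#' alternative equal-length connections are retained as loops for later
#' resolution with [resolve_loops()].
#'
#' @param haplotypes tibble with columns `haplotype`, `sequence` and
#'   optionally `freq` (overall relative frequency, used by loop resolution
#'   and to orient branches).
#' @param limit maximum number of steps per connection; default is the
#'   95 percent parsimony limit from [parsimony_connection_limit()].
#' @param reading_frame 1-based position of the first codon base, or `NULL`
#'   to skip amino-acid annotation of edges.
#' @return An object of class `haplotype_network`: list with `nodes`,
#'   `edges` (tibble: edge, node_a, node_b, steps, site, change, aa_change),
#'   `graph` (igraph), `connection_limit`, and `removed_edges` (populated by
#'   [resolve_loops()]).
#' @export
build_network <- function(haplotypes, limit = NULL, reading_frame = 1L) {
  stopifnot(is.data.frame(haplotypes), all(c("haplotype", "sequence") %in% names(haplotypes)))
  d <- pairwise_differences(haplotypes)
  L <- nchar(haplotypes$sequence[1])
  if (is.null(limit)) limit <- parsimony_connection_limit(L)
  ids <- haplotypes$haplotype
  n <- length(ids)
  comp <- seq_len(n) # union-find by relabelling (small n)
  edges <- list()
  for (dd in sort(unique(d[upper.tri(d)]))) {
    if (dd == 0 || dd > limit) next
    pairs <- which(d == dd & upper.tri(d), arr.ind = TRUE)
    # evaluate component membership at the start of the level so that all
    # alternative connections of equal length are retained (loops)
    comp_at_level <- comp
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]
      j <- pairs[r, 2]
      if (comp_at_level[i] != comp_at_level[j]) {
        edges[[length(edges) + 1L]] <- tibble(
          node_a = ids[i], node_b = ids[j], steps = as.integer(dd)
        )
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  if (length(unique(comp)) > 1) {
    groups <- split(ids, comp)
    abort(paste0(
      "haplotypes not connectable within the parsimony limit (", limit,
      " steps); disconnected component(s): ",
      paste(vapply(groups[-1], paste, "", collapse = ","), collapse = " | ")
    ))
  }
  edges <- bind_rows(edges) %>%
    mutate(edge = edge_key(.data$node_a, .data$node_b), .before = 1) %>%
    distinct(.data$edge, .keep_all = TRUE)
  edges <- annotate_edges(edges, haplotypes, reading_frame)
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = haplotypes$haplotype
  )
  structure(
    list(
      nodes = as_tibble(haplotypes), edges = edges, graph = g,
      connection_limit = limit, removed_edges = tibble()
    ),
    class = "haplotype_network"
  )
}

# Label each edge with its mutational change(s); single-site changes on a
# supplied reading frame additionally get amino-acid notation (e.g. E40K,
# 1-based codon numbering).
annotate_edges <- function(edges, haplotypes, reading_frame) {
  seqs <- setNames(haplotypes$sequence, haplotypes$haplotype)
  lab <- purrr::pmap(edges, function(edge, node_a, node_b, steps, ...) {
    a <- strsplit(seqs[[node_a]], "")[[1]]
    b <- strsplit(seqs[[node_b]], "")[[1]]
    sites <- which(a != b)
    change <- paste0(a[sites], sites, b[sites], collapse = ";")
    aa <- NA_character_
    if (length(sites) == 1 && !is.null(reading_frame)) {
      aa <- aa_change_label(seqs[[node_a]], seqs[[node_b]], sites, reading_frame)
    }
    tibble(site = paste(sites, collapse = ";"), change = change, aa_change = aa)
  })
  bind_cols(edges, bind_rows(lab))
}

aa_change_label <- function(seq_a, seq_b, site, reading_frame) {
  offset <- site - reading_frame
  if (offset < 0) {
    return(NA_character_)
  }
  codon_idx <- offset %/% 3L
  start <- reading_frame + 3L * codon_idx
  if (start + 2L > nchar(seq_a)) {
    return(NA_character_)
  }
  ca <- substr(seq_a, start, start + 2L)
  cb <- substr(seq_b, start, start + 2L)
  aa_a <- seqinr::translate(strsplit(tolower(ca), "")[[1]])
  aa_b <- seqinr::translate(strsplit(tolower(cb), "")[[1]])
  if (identical(aa_a, aa_b)) {
    return(NA_character_)
  }
  paste0(aa_a, codon_idx + 1L, aa_b)
}

#' Resolve loops of a haplotype network
#'
#' Breaks every cycle so that the network becomes a tree.  The edge removed
#' from each cycle is chosen by coalescent-motivated criteria, in fixed
#' priority order: prefer removing longer (multi-step) connections; then the
#' edge whose two endpoints have the smallest summed frequency (rare
#' haplotypes are more likely tips than interior nodes); then the edge
#' incident to the fewest interior (multi-degree) nodes; ties broken by edge
#' id for determinism.  Implemented as a maximum-preference spanning tree, so
#' each independent cycle is broken at its least-preferred edge.  Specific
#' breaks can be forced via `break_edges`.
#'
#' @param net a `haplotype_network`.
#' @param break_edges optional character vector of edge ids
#'   (`"hA-hB"`) to remove first, overriding the automatic criteria.
#' @return the network with acyclic `edges`/`graph`; removed edges are
#'   recorded in `removed_edges`.
#' @export
resolve_loops <- function(net, break_edges = NULL) {
  stopifnot(inherits(net, "haplotype_network"))
  edges <- net$edges
  removed <- tibble()
  if (!is.null(break_edges)) {
    bad <- setdiff(break_edges, edges$edge)
    if (length(bad)) abort(paste0("unknown edge(s) in break_edges: ", paste(bad, collapse = ", ")))
    g_try <- igraph::graph_from_data_frame(
      edges %>% filter(!.data$edge %in% break_edges) %>% select("node_a", "node_b"),
      directed = FALSE, vertices = net$nodes$haplotype
    )
    if (igraph::components(g_try)$no > 1) {
      abort("removing the requested break_edges would disconnect the network")
    }
    removed <- edges %>% filter(.data$edge %in% break_edges)
    edges <- edges %>% filter(!.data$edge %in% break_edges)
  }
  freq <- if ("freq" %in% names(net$nodes)) {
    setNames(net$nodes$freq, net$nodes$haplotype)
  } else {
    setNames(rep(1, nrow(net$nodes)), net$nodes$haplotype)
  }
  deg <- table(c(edges$node_a, edges$node_b))
  interior <- names(deg)[deg >= 2]
  pref <- edges %>% mutate(
    freq_sum = freq[.data$node_a] + freq[.data$node_b],
    n_interior = (.data$node_a %in% interior) + (.data$node_b %in% interior)
  )
  ord <- order(pref$steps, -pref$freq_sum, -pref$n_interior, pref$edge)
  # Kruskal: keep most-preferred edges that do not close a cycle.
  ids <- net$nodes$haplotype
  comp <- setNames(seq_along(ids), ids)
  keep <- logical(nrow(pref))
  for (r in ord) {
    a <- pref$node_a[r]
    b <- pref$node_b[r]
    if (comp[a] != comp[b]) {
      keep[r] <- TRUE
      comp[comp == comp[b]] <- comp[a]
    }
  }
  removed <- bind_rows(removed, edges[!keep, intersect(names(edges), names(net$edges))])
  net$edges <- edges[keep, ]
  net$graph <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")],
    directed = FALSE, vertices = ids
  )
  net$removed_edges <- removed
  net
}

is_tree <- function(net) {
  nrow(net$edges) == nrow(net$nodes) - 1 &&
    igraph::components(net$graph)$no == 1
}

#' Enumerate branch bipartitions of a tree-shaped network
#'
#' Removing each edge of a tree splits the haplotypes into two sides; each
#' such bipartition acts as a biallelic marker for the scan.  The derived
#' side (`side_b`) is the side not containing the most frequent haplotype
#' (the conventional ancestral proxy under coalescent reasoning); without
#' frequencies it is the smaller side.
#'
#' @param net an acyclic, connected `haplotype_network`.
#' @return tibble with one row per branch: branch id, node_a, node_b,
#'   mutation label, aa_change, and list-columns side_a / side_b.
#' @export
enumerate_branches <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  if (!is_tree(net)) abort("network must be a tree (run resolve_loops() first)")
  anchor <- if ("freq" %in% names(net$nodes)) {
    net$nodes$haplotype[which.max(net$nodes$freq)]
  } else {
    net$nodes$haplotype[1]
  }
  res <- purrr::pmap(net$edges, function(edge, node_a, node_b, ...) {
    g2 <- igraph::delete_edges(net$graph, paste(node_a, node_b, sep = "|"))
    cm <- igraph::components(g2)$membership
    side1 <- names(cm)[cm == cm[[node_a]]]
    side2 <- names(cm)[cm == cm[[node_b]]]
    if (anchor %in% side2) {
      tmp <- side1
      side1 <- side2
      side2 <- tmp
    }
    tibble(
      branch = edge, node_a = node_a, node_b = node_b,
      side_a = list(side1), side_b = list(side2)
    )
  }) %>% bind_rows()
  res %>% left_join(net$edges %>% select("edge", "change", "aa_change"),
    by = c(branch = "edge")
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "<haplotype_network> %d haplotypes, %d edges (limit %d step%s)%s\n",
    nrow(x$nodes), nrow(x$edges), x$connection_limit,
    if (x$connection_limit == 1) "" else "s",
    if (is_tree(x)) ", tree" else ""
  ))
  if (nrow(x$removed_edges)) {
    cat("  loops resolved by removing:", paste(x$removed_edges$edge, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a haplotype network
#'
#' Nodes are scaled by frequency (when available) and edges carrying
#' nonsynonymous changes are labelled.
#'
#' @param object a `haplotype_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.haplotype_network <- function(object, ...) {
  xy <- with_seed(1L, igraph::layout_with_fr(object$graph)) # layout only
  nodes <- object$nodes %>% mutate(x = xy[, 1], y = xy[, 2])
  if (!"freq" %in% names(nodes)) nodes$freq <- 1 / nrow(nodes)
  edges <- object$edges %>%
    left_join(nodes %>% select("haplotype", xa = "x", ya = "y"), by = c(node_a = "haplotype")) %>%
    left_join(nodes %>% select("haplotype", xb = "x", yb = "y"), by = c(node_b = "haplotype"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$freq),
      colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_text(
      data = edges %>% filter(!is.na(.data$aa_change)),
      ggplot2::aes((.data$xa + .data$xb) / 2, (.data$ya + .data$yb) / 2, label = .data$aa_change),
      size = 3, vjust = -0.5
    ) +
    ggplot2::geom_text(
      data = nodes %>% filter(.data$freq > 0.02),
      ggplot2::aes(.data$x, .data$y, label = .data$haplotype),
      size = 3, vjust = 2
    ) +
    ggplot2::scale_size_area(max_size = 10, guide = "none") +
    ggplot2::theme_void()
}
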