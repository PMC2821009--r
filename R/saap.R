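# Physicochemical scoring of amino-acid substitutions.
#
# Substitution events are read off a haplotype tree after Fitch parsimony
# ancestral reconstruction.  For each physicochemical property, the observed
# magnitudes of change are binned into 8 equal-width categories spanning the
# property's full single-mutation change range and compared, category by
# category, with the distribution expected under completely random amino
# acid replacement (all replacements reachable by one nucleotide change,
# weighted uniformly).  Changes landing in categories 6-8 of a significantly
# enriched category are considered radical.

AA_ONE <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# name -> AAindex accession for the default 31-property set (see vignette)
DEFAULT_PROPERTY_ACCESSIONS <- c(
  alpha_helical_tendency = "CHOP780201",
  avg_surrounding_residues = "PONP800108",
  beta_structure_tendency = "CHOP780202",
  bulkiness = "ZIMJ680102",
  buriedness = "JANJ780102",
  chromatographic_index = "WEBA780101",
  coil_tendency = "NAGK730103",
  composition = "GRAR740101",
  pK_COOH = "JOND750102",
  buried_residue_volume = "CHOC750101",
  hydropathy = "KYTJ820101",
  isoelectric_point = "ZIMJ680104",
  long_range_nonbonded_energy = "OOBM770103",
  mean_rms_fluctuation = "VINM940101",
  molecular_volume = "GRAR740103",
  molecular_weight = "FASG760101",
  consensus_hydrophobicity = "EISD840101",
  partial_specific_volume = "COHE430101",
  polar_requirement = "WOEC730101",
  polarity = "GRAR740102",
  c_terminal_helix_freq = "CHOP780205",
  middle_helix_freq = "CRAJ730101",
  n_terminal_helix_freq = "CHOP780204",
  refractivity = "MCMT640101",
  short_medium_nonbonded_energy = "OOBM770102",
  accessibility_reduction_ratio = "PONP800107",
  surrounding_hydrophobicity = "MANP780101",
  transfer_hydrophobicity = "JANJ790102",
  total_nonbonded_energy = "OOBM770101",
  turn_tendency = "CHOP780101",
  helix_coil_equilibrium = "FINA770101"
)

#' Amino-acid physicochemical property table
#'
#' The default set of 31 properties is drawn from the AAindex database
#' shipped with seqinr, selected to cover the classical structural,
#' energetic and hydrophobicity indices used in radical-substitution
#' scoring.  Any custom table with the same schema is accepted by the
#' scoring functions.
#'
#' @param properties optional character vector restricting the default set,
#'   or a data frame with columns `property`, `amino_acid`, `value`
#'   (20 rows per property, one-letter amino-acid codes).
#' @return tibble with columns `property`, `amino_acid`, `value`.
#' @export
aa_properties <- function(properties = NULL) {
  if (is.data.frame(properties)) {
    req <- c("property", "amino_acid", "value")
    if (!all(req %in% names(properties))) {
      abort("custom property table needs columns property, amino_acid, value")
    }
    tab <- as_tibble(properties[, req])
    chk <- tab %>%
      group_by(.data$property) %>%
      summarise(ok = all(sort(.data$amino_acid) == sort(AA_ONE)) && all(is.finite(.data$value)))
    if (!all(chk$ok)) {
      abort(paste0(
        "property table invalid (need 20 finite values over the standard amino acids) for: ",
        paste(chk$property[!chk$ok], collapse = ", ")
      ))
    }
    return(tab)
  }
  acc <- DEFAULT_PROPERTY_ACCESSIONS
  if (!is.null(properties)) {
    bad <- setdiff(properties, names(acc))
    if (length(bad)) abort(paste0("unknown propert(ies): ", paste(bad, collapse = ", ")))
    acc <- acc[properties]
  }
  aaindex <- NULL # appease R CMD check; filled by data() below
  utils::data("aaindex", package = "seqinr", envir = environment())
  purrr::imap(acc, function(code, nm) {
    vals <- aaindex[[code]]$I # named by three-letter code, Ala, Arg, ...
    one <- vapply(names(vals), function(a3) {
      seqinr::a(paste0(
        toupper(substr(a3, 1, 1)),
        tolower(substr(a3, 2, 3))
      ))
    }, "")
    tibble(property = nm, amino_acid = unname(one), value = unname(vals))
  }) %>% bind_rows()
}

#' Magnitude of physicochemical change for a substitution
#'
#' Absolute difference of the property value between the two amino acids;
#' symmetric in its arguments.
#'
#' @param from_aa,to_aa one-letter amino-acid codes (vectorised).
#' @param property property name present in `table`.
#' @param table property table from [aa_properties()].
#' @return numeric vector of magnitudes.
#' @export
property_change_magnitude <- function(from_aa, to_aa, property, table = aa_properties()) {
  tab <- table %>% filter(.data$property == !!property)
  if (!nrow(tab)) abort(paste0("unknown property: ", property))
  v <- setNames(tab$value, tab$amino_acid)
  bad <- setdiff(unique(c(from_aa, to_aa)), AA_ONE)
  if (length(bad)) abort(paste0("nonstandard residue(s): ", paste(bad, collapse = ", ")))
  abs(v[to_aa] - v[from_aa]) %>% unname()
}

# all amino-acid replacements reachable by a single nucleotide change under
# the standard genetic code (sense codons only, nonsynonymous only),
# weighted uniformly; one row per (codon, position, alternative base)
single_step_replacements <- function() {
  bases <- c("a", "c", "g", "t")
  codons <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE), 1, paste0, collapse = "")
  aa <- vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1]]), "")
  sense <- codons[aa != "*"]
  out <- list()
  for (cd in sense) {
    from <- aa[[cd]]
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        cd2 <- cd
        substr(cd2, pos, pos) <- b
        to <- aa[[cd2]]
        if (to != "*" && to != from) {
          out[[length(out) + 1L]] <- c(from = from, to = to)
        }
      }
    }
  }
  m <- do.call(rbind, out)
  tibble(from_aa = m[, "from"], to_aa = m[, "to"])
}

category_breaks <- function(max_change, n_categories = 8L) {
  seq(0, max_change, length.out = n_categories + 1L)
}

magnitude_category <- function(mag, breaks) {
  k <- length(breaks) - 1L
  cat <- findInterval(mag, breaks, rightmost.closed = TRUE, left.open = TRUE)
  cat[mag <= breaks[2]] <- 1L # zero and first-bin changes are category 1
  pmin(pmax(cat, 1L), k)
}

#' Expected category distribution under random amino-acid replacement
#'
#' Enumerates every nonsynonymous amino-acid replacement reachable by a
#' single nucleotide change under the standard genetic code, weighted
#' uniformly, and bins the property-change magnitudes into `n_categories`
#' equal-width categories spanning `[0, max change]`.
#'
#' @param property property name.
#' @param table property table from [aa_properties()].
#' @param n_categories number of magnitude categories, default 8.
#' @return list with `distribution` (tibble: category, proportion) and
#'   `breaks` (category boundaries).
#' @export
expected_distribution <- function(property, table = aa_properties(), n_categories = 8L) {
  reps <- single_step_replacements()
  mag <- property_change_magnitude(reps$from_aa, reps$to_aa, property, table)
  breaks <- category_breaks(max(mag), n_categories)
  if (max(mag) == 0) { # constant property: all mass in category 1
    prop <- c(1, rep(0, n_categories - 1L))
  } else {
    cat <- magnitude_category(mag, breaks)
    prop <- tabulate(cat, n_categories) / length(cat)
  }
  list(
    distribution = tibble(category = seq_len(n_categories), proportion = prop),
    breaks = breaks
  )
}

# ---- ancestral reconstruction -------------------------------------------

# rooted tree as a child -> parent edge tibble over node ids
as_rooted_edges <- function(tree) {
  if (inherits(tree, "phylo")) {
    labs <- c(tree$tip.label, tree$node.label)
    if (is.null(tree$node.label) || length(tree$node.label) < tree$Nnode) {
      labs <- c(tree$tip.label, paste0("anc", seq_len(tree$Nnode)))
    }
    return(tibble(child = labs[tree$edge[, 2]], parent = labs[tree$edge[, 1]]))
  }
  if (is.data.frame(tree) && all(c("child", "parent") %in% names(tree))) {
    return(as_tibble(tree[, c("child", "parent")]))
  }
  abort("tree must be an ape phylo object or a child/parent edge table")
}

#' Parsimony ancestral reconstruction
#'
#' Reconstructs internal-node sequences on a rooted tree by per-site
#' minimum-mutation (Fitch/Sankoff with unit costs) parsimony, valid for
#' multifurcating nodes.  Ambiguities on the downward pass are resolved
#' deterministically: prefer the parent's assigned state when it is among
#' the minimum-cost states, otherwise the alphabetically first one.
#'
#' @param tree rooted tree: an `ape::phylo` object or a tibble with columns
#'   `child`, `parent` (one row per edge; node ids must match sequence
#'   names; exactly one node, the root, never appears as a child).
#' @param sequences named character vector of aligned sequences for the tips
#'   (sequences supplied for interior nodes are ignored).
#' @return named character vector of sequences for every node.
#' @export
reconstruct_ancestors <- function(tree, sequences) {
  edges <- as_rooted_edges(tree)
  nodes <- unique(c(edges$child, edges$parent))
  root <- setdiff(edges$parent, edges$child)
  if (length(root) != 1) abort("tree must have exactly one root")
  tips <- setdiff(nodes, edges$parent)
  miss <- setdiff(tips, names(sequences))
  if (length(miss)) abort(paste0("no sequence for tip(s): ", paste(miss, collapse = ", ")))
  if (length(unique(nchar(sequences[tips]))) != 1) abort("tip sequences must be aligned")
  L <- nchar(sequences[[tips[1]]])
  children_of <- split(edges$child, edges$parent)
  postorder <- character(0)
  visit <- function(v) {
    for (ch in children_of[[v]]) {
      if (ch %in% names(children_of)) visit(ch)
    }
    postorder <<- c(postorder, v)
  }
  visit(root)
  tipmat <- do.call(rbind, strsplit(toupper(sequences[tips]), ""))
  rownames(tipmat) <- tips
  assigned <- matrix("", length(nodes), L, dimnames = list(nodes, NULL))
  assigned[tips, ] <- tipmat[tips, ]
  for (s in seq_len(L)) {
    states <- sort(unique(tipmat[, s]))
    ns <- length(states)
    if (ns == 1) {
      assigned[, s] <- states
      next
    }
    # upward pass: cost[v, t] = minimal mutations in v's subtree given state t
    cost <- matrix(0, length(nodes), ns, dimnames = list(nodes, states))
    cost[tips, ] <- Inf
    cost[cbind(tips, tipmat[tips, s])] <- 0
    for (v in postorder) {
      for (ch in children_of[[v]]) {
        # min over child states of cost + 1 mutation if it differs
        cmin <- min(cost[ch, ])
        cost[v, ] <- cost[v, ] + pmin(cost[ch, ] , cmin + 1)
      }
    }
    # downward pass with deterministic tie-breaks
    pick <- function(costs, prefer = NULL) {
      best <- states[costs == min(costs)]
      if (!is.null(prefer) && prefer %in% best) prefer else best[1]
    }
    assigned[root, s] <- pick(cost[root, ])
    preorder <- rev(postorder)
    for (v in preorder) {
      for (ch in setdiff(children_of[[v]], tips)) {
        pa <- assigned[v, s]
        assigned[ch, s] <- pick(cost[ch, ] + (states != pa), prefer = pa)
      }
    }
  }
  apply(assigned, 1, paste0, collapse = "")
}

#' Read substitution events off a tree
#'
#' After ancestral reconstruction, every nucleotide difference along an edge
#' is reported as a substitution event with its codon position and
#' amino-acid change under the supplied reading frame.
#'
#' @inheritParams reconstruct_ancestors
#' @param reading_frame 1-based position of the first codon base.
#' @return tibble: branch (child node id), site, from_base, to_base,
#'   codon_site (1-based amino-acid position), from_aa, to_aa, synonymous.
#' @export
substitution_events <- function(tree, sequences, reading_frame = 1L) {
  edges <- as_rooted_edges(tree)
  anc <- reconstruct_ancestors(tree, sequences)
  out <- purrr::pmap(edges, function(child, parent) {
    a <- strsplit(anc[[parent]], "")[[1]]
    b <- strsplit(anc[[child]], "")[[1]]
    sites <- which(a != b)
    if (!length(sites)) {
      return(NULL)
    }
    purrr::map(sites, function(s) {
      lab <- aa_change_label(anc[[parent]], anc[[child]], s, reading_frame)
      codon_site <- (s - reading_frame) %/% 3L + 1L
      if (is.na(lab)) {
        from_aa <- to_aa <- NA_character_
      } else {
        from_aa <- substr(lab, 1, 1)
        to_aa <- substr(lab, nchar(lab), nchar(lab))
      }
      tibble(
        branch = child, site = s, from_base = a[s], to_base = b[s],
        codon_site = codon_site, from_aa = from_aa, to_aa = to_aa,
        synonymous = is.na(lab)
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  out
}

#' Score substitution events against the random-replacement expectation
#'
#' For every property, bins the nonsynonymous events' change magnitudes into
#' the 8 categories of [expected_distribution()] and computes a per-category
#' z score `(obs - n q) / sqrt(n q (1 - q))`, one-sided for excess.  A site
#' is flagged when one of its events falls in a significantly enriched
#' category; the flag is radical when that category is 6 or above.
#'
#' @param events nonsynonymous event table from [substitution_events()]
#'   (synonymous rows are ignored).
#' @param table property table from [aa_properties()].
#' @param z_threshold one-sided significance threshold, default 1.645
#'   (alpha = 0.05).
#' @param n_categories number of magnitude categories, default 8.
#' @return An object of class `saap_result`: list with `categories`
#'   (property, category, observed, expected, z, significant) and `sites`
#'   (codon_site, max_category, radical, properties).
#' @export
score_events <- function(events, table = aa_properties(), z_threshold = 1.645,
                         n_categories = 8L) {
  ev <- events %>% filter(!.data$synonymous, !is.na(.data$from_aa))
  if (!nrow(ev)) abort("no nonsynonymous events to score")
  props <- unique(table$property)
  cat_rows <- list()
  site_rows <- list()
  for (pr in props) {
    exp_d <- expected_distribution(pr, table, n_categories)
    mag <- property_change_magnitude(ev$from_aa, ev$to_aa, pr, table)
    cat <- magnitude_category(mag, exp_d$breaks)
    n <- length(cat)
    obs <- tabulate(cat, n_categories)
    q <- exp_d$distribution$proportion
    z <- rep(NA_real_, n_categories)
    okq <- q > 0 & q < 1
    z[okq] <- (obs[okq] - n * q[okq]) / sqrt(n * q[okq] * (1 - q[okq]))
    surprise <- q == 0 & obs > 0 # observed events in a zero-expectation bin
    sig <- (!is.na(z) & z >= z_threshold) | surprise
    cat_rows[[pr]] <- tibble(
      property = pr, category = seq_len(n_categories),
      observed = obs, expected = n * q, z = z, significant = sig
    )
    hit <- sig[cat]
    if (any(hit)) {
      site_rows[[pr]] <- tibble(
        codon_site = ev$codon_site[hit], property = pr, category = cat[hit]
      )
    }
  }
  categories <- bind_rows(cat_rows)
  sites <- if (length(site_rows)) {
    bind_rows(site_rows) %>%
      group_by(.data$codon_site) %>%
      summarise(
        max_category = max(.data$category),
        radical = max(.data$category) >= 6L,
        properties = paste(
          unique(paste0(.data$property, "(", .data$category, ")")),
          collapse = ";"
        ),
        .groups = "drop"
      ) %>%
      arrange(.data$codon_site)
  } else {
    tibble(
      codon_site = integer(), max_category = integer(),
      radical = logical(), properties = character()
    )
  }
  structure(list(categories = categories, sites = sites), class = "saap_result")
}

#' @export
print.saap_result <- function(x, ...) {
  nsig <- sum(x$categories$significant, na.rm = TRUE)
  cat(sprintf(
    "<saap_result> %d significant property/category cells, %d flagged sites (%d radical)\n",
    nsig, nrow(x$sites), sum(x$sites$radical)
  ))
  invisible(x)
}

#' Flagged sites of a SAAP scoring
#'
#' @param x a `saap_result`.
#' @param ... unused.
#' @return the per-site flag tibble.
#' @export
tidy.saap_result <- function(x, ...) x$sites

#' Observed vs expected category counts plot
#'
#' @param object a `saap_result`.
#' @param property_filter optional property names to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.saap_result <- function(object, property_filter = NULL, ...) {
  d <- object$categories
  if (!is.null(property_filter)) d <- d %>% filter(.data$property %in% property_filter)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$category))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$expected), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, colour = .data$significant)) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "magnitude category", y = "count (bars expected, dots observed)") +
    ggplot2::theme_minimal()
}
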