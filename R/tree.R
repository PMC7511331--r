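# Constraint-based subclone tree reconstruction. Rooted trees over the
# inferred subclones are enumerated exhaustively (depth-first with edge
# pruning) and filtered by the pigeonhole constraint: in every compartment a
# parent's prevalence must cover the sum of its children's within tolerance.
# An edge additionally requires strict overall dominance of the parent (a
# parent identical in prevalence to its child would have no resident
# population; such clusters are treated as sibling lineages). Among feasible
# trees the one with the smallest total edge slack — the prevalence mass lost
# along each parent-to-child edge — is returned, so every subclone attaches
# to its tightest dominating ancestor; ties are broken by lexicographically
# smallest parent assignment.

#' Build a subclone tree from inferred subclones
#'
#' @param subclones A `subclone_clustering` from [cluster_subclones()], or a
#'   list with `prevalence` (K x compartments matrix) and optionally
#'   `mutations` (list of K character vectors).
#' @param epsilon Pigeonhole tolerance per node and compartment
#'   (default 0.05).
#' @param all_trees If `TRUE`, also return every co-optimal feasible tree.
#' @return A [subclone_tree()] with attributes `feasible` (logical; `FALSE`
#'   when no tree satisfies the constraint and the minimum-violation tree is
#'   returned), `slack` (total slack of the returned tree) and, if requested,
#'   `co_optimal` (list of parent vectors).
#' @export
build_tree <- function(subclones, epsilon = 0.05, all_trees = FALSE) {
  prev <- as.matrix(subclones$prevalence)
  k <- nrow(prev)
  muts <- subclones$mutations %||% rep(list(character(0)), k)
  ids <- rownames(prev) %||% paste0("c", seq_len(k))
  if (k == 1L) {
    tr <- subclone_tree(NA_integer_, prev, muts, id = ids)
    attr(tr, "feasible") <- TRUE
    attr(tr, "slack") <- 0
    return(tr)
  }
  sols <- enumerate_trees(prev, epsilon)
  feasible <- length(sols$best) > 0L
  if (!feasible) {
    parent <- greedy_tree(prev)
    slack <- tree_slack(parent, prev)
  } else {
    parent <- sols$best
    slack <- sols$slack
  }
  tr <- subclone_tree(parent, prev, muts, id = ids)
  attr(tr, "feasible") <- feasible
  attr(tr, "slack") <- slack
  if (all_trees) attr(tr, "co_optimal") <- sols$co_optimal
  tr
}

# total edge slack: prevalence mass lost along each parent -> child edge,
# summed over compartments
tree_slack <- function(parent, prev) {
  s <- 0
  for (i in seq_len(nrow(prev))) {
    p <- parent[i]
    if (!is.na(p)) s <- s + sum(prev[p, ] - prev[i, ])
  }
  s
}

max_violation <- function(parent, prev, epsilon) {
  v <- 0
  for (i in seq_len(nrow(prev))) {
    ch <- which(!is.na(parent) & parent == i)
    if (length(ch)) {
      v <- max(v, max(colSums(prev[ch, , drop = FALSE]) - prev[i, ]))
    }
  }
  v
}

# Depth-first enumeration of all rooted labeled trees whose edges satisfy the
# necessary per-edge dominance condition, with incremental child-sum pruning.
enumerate_trees <- function(prev, epsilon) {
  k <- nrow(prev)
  # edge p -> ch admissible only if p dominates ch within epsilon in every
  # compartment (implied by the pigeonhole constraint at p) and strictly
  # overall (the parent must retain a resident population)
  admissible <- matrix(FALSE, k, k)
  for (p in seq_len(k)) {
    for (ch in seq_len(k)) {
      if (p != ch) {
        admissible[p, ch] <- all(prev[p, ] >= prev[ch, ] - epsilon) &&
          sum(prev[p, ] - prev[ch, ]) > 1e-9
      }
    }
  }
  best <- NULL
  best_slack <- Inf
  co_optimal <- list()
  parent <- rep(NA_integer_, k)
  child_sum <- matrix(0, k, ncol(prev))

  consider <- function(parent) {
    if (has_cycle(parent)) return()
    slack <- tree_slack(parent, prev)
    if (slack < best_slack - 1e-12) {
      best_slack <<- slack
      best <<- parent
      co_optimal <<- list(parent)
    } else if (abs(slack - best_slack) <= 1e-12) {
      co_optimal[[length(co_optimal) + 1L]] <<- parent
      # lexicographic tie-break on the parent vector
      if (lex_less(parent, best)) best <<- parent
    }
  }

  assign_next <- function(node, root, slack_so_far) {
    # edge slacks are non-negative, so a partial assignment already worse
    # than the incumbent cannot improve
    if (slack_so_far > best_slack + 1e-12) return()
    if (node > k) {
      consider(parent)
      return()
    }
    if (node == root) {
      assign_next(node + 1L, root, slack_so_far)
      return()
    }
    for (p in seq_len(k)) {
      if (p == node || !admissible[p, node]) next
      new_sum <- child_sum[p, ] + prev[node, ]
      if (any(new_sum > prev[p, ] + epsilon)) next
      parent[node] <<- p
      child_sum[p, ] <<- new_sum
      assign_next(node + 1L, root,
                  slack_so_far + sum(prev[p, ] - prev[node, ]))
      child_sum[p, ] <<- child_sum[p, ] - prev[node, ]
      parent[node] <<- NA_integer_
    }
  }

  for (root in seq_len(k)) {
    parent <- rep(NA_integer_, k)
    child_sum <- matrix(0, k, ncol(prev))
    assign_next(1L, root, 0)
  }
  list(best = best, slack = best_slack, co_optimal = co_optimal)
}

has_cycle <- function(parent) {
  k <- length(parent)
  for (i in seq_len(k)) {
    seen <- logical(k)
    p <- parent[i]
    while (!is.na(p)) {
      if (seen[p]) return(TRUE)
      seen[p] <- TRUE
      p <- parent[p]
    }
  }
  sum(is.na(parent)) != 1L
}

lex_less <- function(a, b) {
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  d <- which(a != b)
  length(d) > 0L && a[d[1]] < b[d[1]]
}

# fallback when no feasible tree exists: attach each node (in decreasing
# total prevalence) to the placed node adding the least violation
greedy_tree <- function(prev) {
  k <- nrow(prev)
  ord <- order(-rowSums(prev))
  parent <- rep(NA_integer_, k)
  placed <- ord[1]
  for (i in ord[-1]) {
    best_p <- placed[1]
    best_v <- Inf
    for (p in placed) {
      trial <- parent
      trial[i] <- p
      v <- max_violation(trial, prev, 0)
      if (v < best_v) {
        best_v <- v
        best_p <- p
      }
    }
    parent[i] <- best_p
    placed <- c(placed, i)
  }
  parent
}

#' Partition mutations into stem and clade fractions
#'
#' Stem subclones are those ancestral to all sampled cells: the chain from the
#' root down to (and including) the last node before the first branching
#' point. All other subclones form the clades. The returned fractions are
#' computed over mutation counts and always sum to 1.
#'
#' @param tree A [subclone_tree()].
#' @return List with `stem_fraction`, `clade_fraction`, `stem_ids`,
#'   `clade_ids`, `n_stem_mutations`, `n_clade_mutations`.
#' @export
partition_stem_clade <- function(tree) {
  stem <- integer(0)
  node <- tree_root(tree)
  repeat {
    stem <- c(stem, node)
    ch <- tree_children(tree, node)
    if (length(ch) != 1L) break
    node <- ch
  }
  clade <- setdiff(seq_len(n_subclones(tree)), stem)
  n_stem <- sum(vapply(tree$mutations[stem], length, integer(1)))
  n_clade <- sum(vapply(tree$mutations[clade], length, integer(1)))
  total <- n_stem + n_clade
  stem_fraction <- if (total == 0L) 1 else n_stem / total
  list(stem_fraction = stem_fraction, clade_fraction = 1 - stem_fraction,
       stem_ids = tree$id[stem], clade_ids = tree$id[clade],
       n_stem_mutations = n_stem, n_clade_mutations = n_clade)
}

#' Compartment separation of the subclone tree
#'
#' Labels every subclone by the compartments where its cellular prevalence
#' reaches `eps_presence`, then reports whether a common ancestral clone
#' (a stem subclone present in both compartments) exists, and the fraction of
#' non-stem subclones private to a single compartment. A score of 1 means the
#' clades of the two compartments are fully separated; a tree with no
#' detectable clades scores 0 (all mutational burden sits in the shared
#' trunk, so there is no separation evidence).
#'
#' @param tree A two-compartment [subclone_tree()].
#' @param eps_presence Presence threshold on prevalence (default 0.05).
#' @param compartments Length-2 compartment labels.
#' @return List with `common_ancestor_present`, `separation_score`,
#'   `presence` (logical matrix subclones x compartments), `stem_ids`.
#' @export
compartment_separation <- function(tree, eps_presence = 0.05,
                                   compartments = c("epidermis", "dermis")) {
  prev <- tree$prevalence[, compartments, drop = FALSE]
  presence <- prev >= eps_presence
  part <- partition_stem_clade(tree)
  stem_idx <- match(part$stem_ids, tree$id)
  clade_idx <- match(part$clade_ids, tree$id)
  common <- any(rowSums(presence[stem_idx, , drop = FALSE]) == 2L)
  clade_present <- clade_idx[rowSums(presence[clade_idx, , drop = FALSE]) > 0L]
  # a tree without detectable clades carries no evidence of compartment
  # separation: everything sits in the shared trunk
  score <- if (length(clade_present) == 0L) {
    0
  } else {
    mean(rowSums(presence[clade_present, , drop = FALSE]) == 1L)
  }
  list(common_ancestor_present = common, separation_score = score,
       presence = presence, stem_ids = part$stem_ids)
}

#' Classify the seeding model of a lesion
#'
#' Rule-based verdict combining clonotype and phylogenetic evidence:
#'
#' * `independent` — the compartments' neoplastic clonotype sets barely
#'   overlap (`jaccard <= j_max`), the clades are separated
#'   (`separation_score >= s_min`) and the epidermal clonotype set is *not* a
#'   subset of the dermal one.
#' * `infiltration` — the estimated epidermal clonotype set is a subset of
#'   the dermal set (at most a fraction `subset_tol` of epidermal clonotypes
#'   outside it) and the clades are not separated
#'   (`separation_score < s_min`).
#' * `ambiguous` — anything else.
#'
#' @param clonotype_overlap Result of [overlap_clonotypes()] for
#'   epidermis vs dermis.
#' @param separation Result of [compartment_separation()].
#' @param epi_set,derm_set Character vectors: the estimated neoplastic
#'   clonotype keys of each compartment.
#' @param j_max Maximum Jaccard for the independent call (default 0.2).
#' @param s_min Minimum separation score for the independent call
#'   (default 0.8).
#' @param subset_tol Tolerated fraction of epidermal clonotypes missing from
#'   the dermal set in the subset test (default 0.1).
#' @return List with `verdict` (`"independent"`, `"infiltration"` or
#'   `"ambiguous"`) and `evidence` (all input statistics).
#' @export
classify_seeding_model <- function(clonotype_overlap, separation, epi_set,
                                   derm_set, j_max = 0.2, s_min = 0.8,
                                   subset_tol = 0.1) {
  if (is.null(clonotype_overlap) || is.null(separation)) {
    stop("pipeline-order error: clonotype overlap and tree separation must be computed first",
         call. = FALSE)
  }
  n_epi <- length(epi_set)
  outside <- length(setdiff(epi_set, derm_set))
  subset_pattern <- n_epi > 0L && (outside / n_epi) <= subset_tol
  sep <- separation$separation_score
  jac <- clonotype_overlap$jaccard
  verdict <- if (jac <= j_max && sep >= s_min && !subset_pattern) {
    "independent"
  } else if (subset_pattern && sep < s_min) {
    "infiltration"
  } else {
    "ambiguous"
  }
  list(verdict = verdict,
       evidence = list(jaccard = jac, separation_score = sep,
                       common_ancestor_present = separation$common_ancestor_present,
                       n_epi = n_epi, n_derm = length(derm_set),
                       n_epi_outside_derm = outside,
                       subset_pattern = subset_pattern,
                       thresholds = list(j_max = j_max, s_min = s_min,
                                         subset_tol = subset_tol)))
}
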