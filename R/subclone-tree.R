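#' Subclone tree objects
#'
#' A `subclone_tree` is a rooted tree of genetic subclones. Each node carries a
#' cellular prevalence per compartment (the fraction of that compartment's
#' tumour cells harbouring the node's genotype or a descendant of it) and a set
#' of mutation ids private to the node (infinite-sites assumption: every
#' mutation belongs to exactly one node).
#'
#' @param parent Integer vector; `parent[i]` is the index of node `i`'s parent,
#'   `NA` for the root.
#' @param prevalence Numeric matrix, nodes x compartments, values in `[0, 1]`.
#' @param mutations List of character vectors of mutation ids, one per node.
#' @param id Optional character node ids (default `"s1"`, `"s2"`, ...).
#'
#' @return An object of class `subclone_tree`.
#' @export
subclone_tree <- function(parent, prevalence, mutations = NULL, id = NULL) {
  prevalence <- as.matrix(prevalence)
  k <- nrow(prevalence)
  parent <- as.integer(parent)
  stopifnot(length(parent) == k, sum(is.na(parent)) == 1L)
  if (is.null(mutations)) mutations <- rep(list(character(0)), k)
  stopifnot(length(mutations) == k)
  if (is.null(id)) id <- paste0("s", seq_len(k))
  rownames(prevalence) <- id
  structure(
    list(id = id, parent = parent, prevalence = prevalence,
         mutations = mutations),
    class = "subclone_tree"
  )
}

n_subclones <- function(tree) length(tree$id)

tree_root <- function(tree) which(is.na(tree$parent))

tree_children <- function(tree, i) which(!is.na(tree$parent) & tree$parent == i)

tree_ancestors <- function(tree, i) {
  out <- integer(0)
  p <- tree$parent[i]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

tree_descendants <- function(tree, i) {
  out <- integer(0)
  frontier <- tree_children(tree, i)
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, tree_children, tree = tree))
  }
  out
}

#' Check the pigeonhole (sum) constraint of a subclone tree
#'
#' For every node and every compartment a parent's cellular prevalence must be
#' at least the sum of its children's prevalences: a cell carrying a child
#' genotype also carries the parent genotype, so child lineages partition a
#' subset of the parent's cells.
#'
#' @param tree A [subclone_tree()].
#' @param tol Numeric slack allowed on each comparison.
#' @return `TRUE` if the constraint holds everywhere, else `FALSE` with
#'   attribute `"violations"` listing offending (node, compartment) pairs.
#' @export
check_pigeonhole <- function(tree, tol = 1e-9) {
  bad <- list()
  for (i in seq_len(n_subclones(tree))) {
    ch <- tree_children(tree, i)
    if (length(ch) == 0L) next
    child_sum <- colSums(tree$prevalence[ch, , drop = FALSE])
    over <- child_sum > tree$prevalence[i, ] + tol
    if (any(over)) {
      bad[[length(bad) + 1L]] <- data.frame(
        node = tree$id[i],
        compartment = colnames(tree$prevalence)[over],
        excess = (child_sum - tree$prevalence[i, ])[over]
      )
    }
  }
  if (length(bad) == 0L) return(TRUE)
  structure(FALSE, violations = do.call(rbind, bad))
}

#' @export
print.subclone_tree <- function(x, ...) {
  cat(sprintf("<subclone_tree> %d subclones, compartments: %s\n",
              n_subclones(x), paste(colnames(x$prevalence), collapse = ", ")))
  df <- data.frame(
    id = x$id,
    parent = ifelse(is.na(x$parent), "-", x$id[x$parent]),
    n_mutations = vapply(x$mutations, length, integer(1))
  )
  print(cbind(df, round(x$prevalence, 3)), row.names = FALSE)
  invisible(x)
}

#' Export a subclone tree as a Newick string
#'
#' Node labels carry the subclone id, mutation count and per-compartment
#' prevalences. Internal structure is preserved by inserting zero-length leaf
#' placeholders for internal node labels where needed.
#'
#' @param tree A [subclone_tree()].
#' @return A Newick string (terminated by `";"`).
#' @export
tree_to_newick <- function(tree) {
  lab <- function(i) {
    prev <- paste(sprintf("%s=%.3f", colnames(tree$prevalence),
                          tree$prevalence[i, ]), collapse = "|")
    sprintf("%s_m%d_%s", tree$id[i], length(tree$mutations[[i]]), prev)
  }
  rec <- function(i) {
    ch <- tree_children(tree, i)
    if (length(ch) == 0L) return(lab(i))
    sprintf("(%s)%s", paste(vapply(ch, rec, character(1)), collapse = ","),
            lab(i))
  }
  paste0(rec(tree_root(tree)), ";")
}

# Restrict a joint tree to one compartment: keep nodes with positive prevalence
# there, re-attaching orphans to their nearest retained ancestor.
restrict_tree <- function(tree, compartment, min_prev = 1e-12) {
  keep <- which(tree$prevalence[, compartment] > min_prev)
  root <- tree_root(tree)
  if (!(root %in% keep)) keep <- sort(unique(c(root, keep)))
  idx <- match(seq_len(n_subclones(tree)), keep)
  new_parent <- integer(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    p <- tree$parent[i]
    while (!is.na(p) && !(p %in% keep)) p <- tree$parent[p]
    new_parent[j] <- if (is.na(p)) NA_integer_ else idx[p]
  }
  subclone_tree(new_parent,
                tree$prevalence[keep, compartment, drop = FALSE],
                tree$mutations[keep],
                id = tree$id[keep])
}
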