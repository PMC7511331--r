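# Neutral branched evolution of subclones within and across compartments.
#
# The lesion is modelled as one joint tree rooted at the circulating common
# ancestor. Under independent seeding the dermal and epidermal founding
# populations branch off the ancestor separately and evolve in isolation;
# under gradual infiltration the epidermal population is founded by a
# subsample of the evolved dermal genotypes and then diversifies further
# in situ.

new_mut_ids <- function(env, n) {
  if (n == 0L) return(character(0))
  ids <- sprintf("m%06d", env$counter + seq_len(n))
  env$counter <- env$counter + n
  ids
}

# Stick-breaking split of a parent's prevalence among k children: Dirichlet
# over k + 1 slots, the last slot staying with the parental genotype, so the
# pigeonhole constraint holds by construction.
stick_break <- function(prev, k) {
  w <- rgamma(k + 1L, shape = 1)
  prev * (w / sum(w))[seq_len(k)]
}

grow_subtree <- function(parent_idx, prev0, compartment, n_generations, rate,
                        state, mutenv) {
  # state: environment holding parent, prevalence (list of per-node named
  # vectors), mutations
  add_node <- function(parent, prev, muts) {
    state$parent <- c(state$parent, parent)
    state$prev[[length(state$prev) + 1L]] <- prev
    state$muts[[length(state$muts) + 1L]] <- muts
    length(state$parent)
  }
  frontier <- parent_idx
  prev_of <- setNames(list(prev0), as.character(parent_idx))
  for (g in seq_len(n_generations)) {
    nxt <- integer(0)
    for (node in frontier) {
      k <- sample(1:3, 1L)
      kid_prev <- stick_break(prev_of[[as.character(node)]], k)
      for (j in seq_len(k)) {
        prev_vec <- numeric(length(COMPARTMENTS_SKIN))
        names(prev_vec) <- COMPARTMENTS_SKIN
        prev_vec[compartment] <- kid_prev[j]
        idx <- add_node(node, prev_vec, new_mut_ids(mutenv, rpois(1L, rate)))
        nxt <- c(nxt, idx)
        prev_of[[as.character(idx)]] <- kid_prev[j]
      }
    }
    frontier <- nxt
  }
  invisible(NULL)
}

COMPARTMENTS_SKIN <- c("epidermis", "dermis")

#' Simulate neutral branched subclonal evolution
#'
#' Builds the lesion's joint subclone tree and its per-compartment
#' restrictions. The root is the circulating common ancestor (carrying
#' `Poisson(ancestral_mutation_rate)` mutations shared by every malignant cell
#' of the lesion). Each compartment's founding population acquires
#' `Poisson(mutation_rate_stem)` clonal (stem) mutations; each subsequent
#' generation every leaf splits into 1–3 children that each acquire
#' `Poisson(mutation_rate_branch)` private mutations, with cellular prevalences
#' assigned by stick-breaking so that a parent's prevalence always bounds the
#' sum of its children's (pigeonhole constraint). Mutations never recur
#' (infinite sites).
#'
#' Under `infiltration` the epidermal founding population is drawn as a
#' Dirichlet-weighted subsample of the evolved dermal genotype composition
#' (so ancestral dermal subclones are present in both compartments) and the
#' dominant invading genotypes then branch further within the epidermis.
#'
#' @param compartment_clones Named list from [simulate_seeding()].
#' @param config A [sim_config()].
#' @return Named list with per-compartment [subclone_tree()]s (`epidermis`,
#'   `dermis`) and the full two-compartment tree as attribute `"joint"`.
#' @export
simulate_branched_evolution <- function(compartment_clones, config) {
  validate_sim_config(config)
  stopifnot(length(compartment_clones$dermis) >= 1L,
            length(compartment_clones$epidermis) >= 1L)
  with_seed(derive_seed(config$rng_seed, "evolution"), {
    mutenv <- new.env()
    mutenv$counter <- 0L
    st <- new.env()
    st$parent <- NA_integer_
    st$prev <- list(setNames(c(1, 1), COMPARTMENTS_SKIN))
    st$muts <- list(new_mut_ids(mutenv, rpois(1L, config$ancestral_mutation_rate)))

    add_node <- function(parent, prev, muts) {
      st$parent <- c(st$parent, parent)
      st$prev[[length(st$prev) + 1L]] <- prev
      st$muts[[length(st$muts) + 1L]] <- muts
      length(st$parent)
    }

    if (config$seeding_mode == "independent") {
      d0 <- add_node(1L, setNames(c(0, 1), COMPARTMENTS_SKIN),
                     new_mut_ids(mutenv, rpois(1L, config$mutation_rate_stem)))
      e0 <- add_node(1L, setNames(c(1, 0), COMPARTMENTS_SKIN),
                     new_mut_ids(mutenv, rpois(1L, config$mutation_rate_stem)))
      grow_subtree(d0, 1, "dermis", config$n_generations,
                   config$mutation_rate_branch, st, mutenv)
      grow_subtree(e0, 1, "epidermis", config$n_generations,
                   config$mutation_rate_branch, st, mutenv)
    } else {
      d0 <- add_node(1L, setNames(c(0, 1), COMPARTMENTS_SKIN),
                     new_mut_ids(mutenv, rpois(1L, config$mutation_rate_stem)))
      grow_subtree(d0, 1, "dermis", config$n_generations,
                   config$mutation_rate_branch, st, mutenv)
      infiltrate_epidermis(st, d0, config, mutenv)
    }

    prevalence <- do.call(rbind, st$prev)
    joint <- subclone_tree(st$parent, prevalence, st$muts)
    out <- list(
      epidermis = restrict_tree(joint, "epidermis"),
      dermis = restrict_tree(joint, "dermis")
    )
    attr(out, "joint") <- joint
    out
  })
}

# Gradual-infiltration epidermal layer: the epidermis is founded by cells
# sampled from the dermal genotype mixture, then diversifies in situ.
infiltrate_epidermis <- function(st, d0, config, mutenv) {
  n <- length(st$parent)
  parent <- st$parent
  derm_prev <- vapply(st$prev, `[[`, numeric(1), "dermis")
  children_of <- function(i) which(!is.na(parent) & parent == i)
  # resident (genotype-exclusive) fraction of each dermal node
  resident <- derm_prev
  for (i in seq_len(n)) {
    ch <- children_of(i)
    if (length(ch)) resident[i] <- resident[i] - sum(derm_prev[ch])
  }
  resident[resident < 0] <- 0
  dermal_nodes <- which(derm_prev > 0)
  # Dirichlet-weighted subsample of the dermal genotype composition; the
  # high concentration models continuous emigration, so the epidermal
  # composition tracks the dermal one rather than drifting to one founder
  w <- numeric(n)
  conc <- 50
  pos <- dermal_nodes[resident[dermal_nodes] > 0]
  w[pos] <- rgamma(length(pos), shape = conc * resident[pos] + 1e-6)
  w <- w / sum(w)
  # epidermal prevalence of an existing node = mass of its subtree + itself
  subtree_mass <- function(i) {
    idx <- c(i, tree_descendants_idx(parent, i))
    sum(w[idx])
  }
  for (i in seq_len(n)) {
    st$prev[[i]]["epidermis"] <- if (i == 1L || i == d0) 1 else subtree_mass(i)
  }
  # in-situ epidermal diversification of the dominant invading genotypes
  invaders <- order(w, decreasing = TRUE)
  invaders <- invaders[w[invaders] > 0.05][seq_len(min(3L, sum(w > 0.05)))]
  gens <- max(1L, min(2L, config$n_generations))
  for (node in invaders) {
    founder_prev <- setNames(c(w[node] * 0.6, 0), COMPARTMENTS_SKIN)
    st$parent <- c(st$parent, node)
    st$prev[[length(st$prev) + 1L]] <- founder_prev
    st$muts[[length(st$muts) + 1L]] <-
      new_mut_ids(mutenv, rpois(1L, config$mutation_rate_branch))
    grow_subtree(length(st$parent), founder_prev[["epidermis"]], "epidermis",
                 gens, config$mutation_rate_branch, st, mutenv)
  }
  invisible(NULL)
}

tree_descendants_idx <- function(parent, i) {
  out <- integer(0)
  frontier <- which(!is.na(parent) & parent == i)
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- which(!is.na(parent) & parent %in% frontier)
  }
  out
}
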