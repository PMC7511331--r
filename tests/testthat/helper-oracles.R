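# Independently coded brute-force oracles. These deliberately avoid the
# package's own code paths: plain loops and explicit set arithmetic only.

# argmin_n | sum_{i<=n} f_i - tcf | by scanning every prefix, smallest n wins
oracle_prefix_count <- function(freqs, tcf) {
  best_n <- 0L
  best_dev <- abs(0 - tcf)
  total <- 0
  for (n in seq_along(freqs)) {
    total <- total + freqs[n]
    dev <- abs(total - tcf)
    if (dev < best_dev - 1e-15) {
      best_dev <- dev
      best_n <- n
    }
  }
  best_n
}

oracle_overlap <- function(a, b) {
  shared <- character(0)
  for (x in unique(a)) if (x %in% b) shared <- c(shared, x)
  uni <- unique(c(a, b))
  list(shared = shared,
       jaccard = if (length(uni) == 0) 0 else length(shared) / length(uni))
}

oracle_venn <- function(e, d, b) {
  u <- unique(c(e, d, b))
  counts <- c(epi_only = 0, derm_only = 0, blood_only = 0, epi_derm = 0,
              epi_blood = 0, derm_blood = 0, all_three = 0)
  for (x in u) {
    ine <- x %in% e; ind <- x %in% d; inb <- x %in% b
    lab <- if (ine && ind && inb) "all_three"
      else if (ine && ind) "epi_derm"
      else if (ine && inb) "epi_blood"
      else if (ind && inb) "derm_blood"
      else if (ine) "epi_only"
      else if (ind) "derm_only"
      else "blood_only"
    counts[lab] <- counts[lab] + 1
  }
  as.list(counts)
}

# worst-severity driver tabulation by explicit per-gene scan
oracle_driver_matrix <- function(variants, genes,
                                 compartments = c("epidermis", "dermis")) {
  sev <- function(consequence, ref, alt) {
    if (consequence %in% c("frameshift", "stop_gain", "stop_loss")) return(3)
    if (consequence == "inframe_indel") {
      return(if (abs(nchar(ref) - nchar(alt)) < 6) 3 else 0)
    }
    if (consequence == "missense") return(2)
    0
  }
  lab <- c("absent", "absent", "missense", "damaging")
  out <- matrix("absent", length(genes), length(compartments),
                dimnames = list(genes, compartments))
  for (g in genes) {
    for (cp in compartments) {
      worst <- 0
      for (r in seq_len(nrow(variants))) {
        if (variants$gene[r] == g && variants$compartment[r] == cp &&
            variants$alt_depth[r] >= 1) {
          worst <- max(worst, sev(variants$consequence[r], variants$ref[r],
                                  variants$alt[r]))
        }
      }
      out[g, cp] <- lab[worst + 1]
    }
  }
  out
}

# independent pigeonhole checker: direct double loop over nodes/compartments
oracle_pigeonhole_ok <- function(parent, prev, tol = 1e-9) {
  for (i in seq_len(nrow(prev))) {
    kids <- which(!is.na(parent) & parent == i)
    if (length(kids) == 0) next
    for (cp in seq_len(ncol(prev))) {
      s <- 0
      for (ch in kids) s <- s + prev[ch, cp]
      if (s > prev[i, cp] + tol) return(FALSE)
    }
  }
  TRUE
}

# Exhaustive tree search for <= 5 nodes, written independently of the
# builder: enumerate every parent vector over all root choices via
# expand.grid, keep acyclic trees meeting the per-node sum constraint and
# the strict-dominance edge rule, minimise total edge slack with
# lexicographic tie-break on the parent vector.
oracle_best_tree <- function(prev, epsilon = 0.05) {
  k <- nrow(prev)
  stopifnot(k <= 5)
  best <- NULL
  best_slack <- Inf
  grid_cols <- rep(list(seq_len(k)), k)
  grid <- as.matrix(do.call(expand.grid, grid_cols))
  for (root in seq_len(k)) {
    for (g in seq_len(nrow(grid))) {
      parent <- grid[g, ]
      parent[root] <- NA
      if (any(parent == seq_len(k), na.rm = TRUE)) next
      # acyclic + connected to root?
      ok <- TRUE
      for (i in seq_len(k)) {
        steps <- 0
        p <- parent[i]
        while (!is.na(p)) {
          steps <- steps + 1
          if (steps > k) { ok <- FALSE; break }
          p <- parent[p]
        }
        if (!ok) break
      }
      if (!ok) next
      # constraints
      feasible <- TRUE
      slack <- 0
      for (i in seq_len(k)) {
        p <- parent[i]
        if (is.na(p)) next
        if (!all(prev[p, ] >= prev[i, ] - epsilon) ||
            sum(prev[p, ] - prev[i, ]) <= 1e-9) { feasible <- FALSE; break }
        slack <- slack + sum(prev[p, ] - prev[i, ])
      }
      if (!feasible) next
      for (i in seq_len(k)) {
        kids <- which(!is.na(parent) & parent == i)
        if (length(kids) &&
            any(colSums(prev[kids, , drop = FALSE]) > prev[i, ] + epsilon)) {
          feasible <- FALSE
          break
        }
      }
      if (!feasible) next
      pv <- parent
      pv[is.na(pv)] <- 0
      if (slack < best_slack - 1e-12 ||
          (abs(slack - best_slack) <= 1e-12 && !is.null(best) &&
           {
             bv <- best
             bv[is.na(bv)] <- 0
             d <- which(pv != bv)
             length(d) > 0 && pv[d[1]] < bv[d[1]]
           })) {
        best_slack <- slack
        best <- parent
      }
    }
  }
  list(parent = best, slack = best_slack)
}

# random feasible prevalence sets built by sampling a random tree and
# assigning prevalences top-down (so a feasible tree is guaranteed)
random_feasible_instance <- function(k, n_comp = 2) {
  parent <- rep(NA_integer_, k)
  for (i in seq_len(k)[-1]) parent[i] <- sample.int(i - 1L, 1L)
  prev <- matrix(0, k, n_comp,
                 dimnames = list(paste0("c", seq_len(k)),
                                 c("epidermis", "dermis")[seq_len(n_comp)]))
  prev[1, ] <- 1
  for (p in seq_len(k)) {
    kids <- which(!is.na(parent) & parent == p)
    if (length(kids) == 0) next
    for (cp in seq_len(n_comp)) {
      w <- runif(length(kids) + 1)
      w <- w / sum(w)
      prev[kids, cp] <- prev[p, cp] * w[seq_along(kids)]
    }
  }
  prev
}
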