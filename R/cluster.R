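# Subclone inference: joint clustering of mutations in two-compartment
# cellular-prevalence space using a finite mixture of binomial components
# fitted by EM, with the number of components selected by BIC. This is a
# deterministic, desk-scale stand-in for MCMC tree samplers such as PhyloWGS.

# Assemble the per-variant count matrices the mixture model consumes.
# variants: long format (one row per variant x compartment).
variant_matrices <- function(variants, tcf, cna = NULL, multiplicity = 1,
                             compartments = c("epidermis", "dermis")) {
  key <- variant_key(variants)
  ukey <- unique(key)
  n <- length(ukey)
  alt <- depth <- conv <- matrix(0, n, length(compartments),
                                 dimnames = list(ukey, compartments))
  first <- variants[match(ukey, key), , drop = FALSE]
  cn <- cn_from_segments(first$chrom, first$pos, cna)
  for (j in seq_along(compartments)) {
    cp <- compartments[j]
    sub <- variants[variants$compartment == cp, , drop = FALSE]
    m <- match(ukey, variant_key(sub))
    alt[, j] <- ifelse(is.na(m), 0L, sub$alt_depth[m])
    depth[, j] <- ifelse(is.na(m), 0L, sub$ref_depth[m] + sub$alt_depth[m])
    conv[, j] <- vaf_factor(tcf[[cp]], cn, multiplicity)
  }
  list(alt = alt, depth = depth, conv = conv, key = ukey, meta = first)
}

# phi point estimates per variant and compartment (clipped to [0, 1])
phi_hat <- function(mats) {
  ph <- mats$alt / pmax(mats$depth, 1) / mats$conv
  pmin(pmax(ph, 0), 1)
}

# k-means++-style seeding of K centres on the phi point cloud
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- apply(x, 1, function(p) {
        min(colSums((t(centers[seq_len(j - 1L), , drop = FALSE]) - p)^2))
      })
      if (sum(d2) == 0) {
        centers[j, ] <- x[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
      }
    }
  }
  centers
}

em_binomial_mixture <- function(mats, k, max_iter = 200, tol = 1e-6,
                                init = c("kmeans", "kmeanspp"),
                                centers = NULL) {
  init <- match.arg(init)
  n <- nrow(mats$alt)
  ph <- phi_hat(mats)
  if (is.null(centers)) {
    centers <- if (init == "kmeans" && k > 1L && nrow(unique(ph)) > k) {
      tryCatch(suppressWarnings(kmeans(ph, k, nstart = 10)$centers),
               error = function(e) kmeanspp_centers(ph, k))
    } else {
      kmeanspp_centers(ph, k)
    }
  }
  phi <- pmin(pmax(centers, 0.01), 1)
  pi_k <- rep(1 / k, k)
  loglik_matrix <- function(phi) {
    # n x k matrix of per-variant component log-likelihoods
    ll <- sapply(seq_len(k), function(j) {
      p <- mats$conv * matrix(phi[j, ], n, ncol(mats$conv), byrow = TRUE)
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      rowSums(dbinom(mats$alt, mats$depth, p, log = TRUE))
    })
    matrix(ll, nrow = n, ncol = k)
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    ll <- loglik_matrix(phi)
    ll <- sweep(ll, 2, log(pi_k), "+")
    mx <- apply(ll, 1, max)
    r <- exp(ll - mx)
    tot <- rowSums(r)
    r <- r / tot
    loglik <- sum(mx + log(tot))
    if (is.finite(ll_old) && abs(loglik - ll_old) < tol * abs(loglik)) break
    ll_old <- loglik
    pi_k <- pmax(colMeans(r), 1e-9)
    pi_k <- pi_k / sum(pi_k)
    for (j in seq_len(k)) {
      num <- colSums(r[, j] * mats$alt)
      den <- colSums(r[, j] * mats$depth * mats$conv)
      phi[j, ] <- pmin(pmax(ifelse(den > 0, num / den, 0), 0), 1)
    }
  }
  ll <- loglik_matrix(phi)
  ll <- sweep(ll, 2, log(pi_k), "+")
  mx <- apply(ll, 1, max)
  loglik <- sum(mx + log(rowSums(exp(ll - mx))))
  assignment <- max.col(ll, ties.method = "first")
  list(phi = phi, pi = pi_k, loglik = loglik, assignment = assignment, k = k)
}

#' Cluster mutations into subclones
#'
#' Jointly clusters mutations in two-compartment cellular-prevalence space
#' with a finite mixture of binomial components: component `j` has a
#' prevalence `phi[j, c]` per compartment `c` and generates the observed alt
#' depth of variant `i` in compartment `c` as
#' `Binomial(depth, phi[j, c] * vaf_factor(TCF_c, CN_i))`. The mixture is
#' fitted by expectation–maximisation (k-means++-style seeded, best of
#' `n_restarts` restarts) and the number of components `K` is selected by the
#' Bayesian information criterion over `K = 1..k_max`. Each component becomes
#' a subclone with prevalence equal to the component mean per compartment.
#'
#' @param variants Long-format variant table (see [read_variant_table()]).
#' @param tcf Named numeric vector of tumour cell fractions per compartment.
#' @param cna Optional BED-like CNA segment table.
#' @param k_max Largest number of components considered (default 10).
#' @param n_restarts EM restarts per `K` (default 10).
#' @param seed RNG seed making the fit deterministic.
#' @param multiplicity Mutation multiplicity passed to the VAF model.
#' @param compartments Compartment labels to use.
#' @return List of class `subclone_clustering`: `k`, `prevalence`
#'   (K x compartments matrix), `weight`, `assignment` (variant key ->
#'   component), `mutations` (list of variant keys per component), `bic`
#'   (vector over candidate K), `loglik`, `meta`.
#' @export
cluster_subclones <- function(variants, tcf, cna = NULL, k_max = 10,
                              n_restarts = 10, seed = 1, multiplicity = 1,
                              compartments = c("epidermis", "dermis")) {
  mats <- variant_matrices(variants, tcf, cna, multiplicity, compartments)
  n <- nrow(mats$alt)
  if (n == 0L) stop("no variants with finite prevalence", call. = FALSE)
  k_max <- min(k_max, n)
  if (n < 2L) {
    warning("fewer variants than clusters; single-cluster fallback")
    k_max <- 1L
  }
  with_seed(seed, {
    bic <- rep(NA_real_, k_max)
    fits <- vector("list", k_max)
    prev_best <- NULL
    for (k in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        # first restart seeds from a k-means partition of the prevalence
        # points, the rest from k-means++ draws
        fit <- em_binomial_mixture(mats, k,
                                   init = if (r == 1L) "kmeans" else "kmeanspp")
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      # hierarchical restarts: refine the best (k-1)-component fit by
      # splitting each component in turn (escapes merge-type local optima
      # that point-space initialisation cannot see)
      if (!is.null(prev_best)) {
        ph <- phi_hat(mats)
        for (j in seq_len(k - 1L)) {
          members <- which(prev_best$assignment == j)
          if (length(members) < 4L) next
          sp <- tryCatch(
            suppressWarnings(kmeans(ph[members, , drop = FALSE], 2L)$centers),
            error = function(e) NULL)
          if (is.null(sp)) next
          centers <- rbind(prev_best$phi[-j, , drop = FALSE], sp)
          fit <- em_binomial_mixture(mats, k, centers = centers)
          if (fit$loglik > best$loglik) best <- fit
        }
      }
      prev_best <- best
      n_par <- k * length(compartments) + (k - 1)
      bic[k] <- -2 * best$loglik + n_par * log(n)
      fits[[k]] <- best
    }
    k_best <- which.min(bic)
    fit <- fits[[k_best]]
    # drop empty components (can arise when K overshoots)
    used <- sort(unique(fit$assignment))
    phi <- fit$phi[used, , drop = FALSE]
    remap <- match(fit$assignment, used)
    ord <- order(-rowSums(phi))
    phi <- phi[ord, , drop = FALSE]
    remap <- match(remap, ord)
    dimnames(phi) <- list(paste0("c", seq_len(nrow(phi))), compartments)
    structure(
      list(k = nrow(phi), prevalence = phi,
           weight = as.vector(table(factor(remap, seq_len(nrow(phi))))) / n,
           assignment = setNames(remap, mats$key),
           mutations = split(mats$key, factor(remap, seq_len(nrow(phi)))),
           bic = bic, loglik = fit$loglik, meta = mats$meta),
      class = "subclone_clustering"
    )
  })
}

#' @export
print.subclone_clustering <- function(x, ...) {
  cat(sprintf("<subclone_clustering> K = %d (BIC-selected)\n", x$k))
  df <- data.frame(round(x$prevalence, 3),
                   n_mutations = vapply(x$mutations, length, integer(1)),
                   weight = round(x$weight, 3))
  print(df)
  invisible(x)
}
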