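#' Remove rare taxa before network inference
#'
#' Keeps taxa that reach at least `min_count` reads in at least
#' `min_samples` samples (default 15 counts in 20 samples); everything else
#' is removed, not pooled. Sporadic taxa produce spurious associations, so
#' this filter precedes every network fit. For small tables (< 100
#' samples) the sample threshold is rescaled proportionally, with a
#' warning, so the rule stays meaningful at reduced scale.
#'
#' @param x a [count_table].
#' @param min_count minimum per-sample count (>= 1).
#' @param min_samples minimum number of samples reaching it (>= 1).
#' @param auto_rescale rescale `min_samples` for tables under 100 samples.
#' @return filtered [count_table].
#' @export
filter_rare_taxa <- function(x, min_count = 15, min_samples = 20,
                             auto_rescale = TRUE) {
  stop_if_not(min_count >= 1 && min_samples >= 1, "thresholds must be >= 1")
  n <- ncol(x$counts)
  ms <- min_samples
  if (auto_rescale && n < 100) {
    ms <- max(1, ceiling(min_samples * n / 100))
    warning(sprintf("table has %d samples (< 100); min_samples rescaled %d -> %d",
                    n, min_samples, ms))
  }
  keep <- rowSums(x$counts >= min_count) >= ms
  if (!any(keep)) {
    stop("no taxa pass the rare-taxon filter; rescale the thresholds for small fixtures",
         call. = FALSE)
  }
  subset_counts(x, taxa = which(keep))
}

#' Settings for co-occurrence network inference
#'
#' @param method `"mb"` for neighborhood-selection (lasso regressions per
#'   taxon) with StARS stability selection, or `"pcor"` for a fast
#'   thresholded partial-correlation backend (ridge-regularized precision
#'   matrix) used where hundreds of networks must be fit.
#' @param n_lambda,lambda_min_ratio regularization path for `"mb"`.
#' @param stars_subsamples,stars_instability,subsample_ratio StARS
#'   parameters: number of random subsamples, target edge instability, and
#'   subsample fraction.
#' @param pcor_threshold absolute partial-correlation cut for `"pcor"`.
#' @param ridge ridge added to the covariance before inversion.
#' @param pseudocount CLR pseudocount.
#' @param seed seed making the fit deterministic.
#' @return a `network_settings` list.
#' @export
network_settings <- function(method = c("mb", "pcor"), n_lambda = 20,
                             lambda_min_ratio = 0.05, stars_subsamples = 50,
                             stars_instability = 0.05, subsample_ratio = 0.8,
                             pcor_threshold = 0.3, ridge = 0.05,
                             pseudocount = 1, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 stars_subsamples = stars_subsamples,
                 stars_instability = stars_instability,
                 subsample_ratio = subsample_ratio,
                 pcor_threshold = pcor_threshold, ridge = ridge,
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "network_settings")
}

new_network <- function(edges, nodes, settings) {
  structure(list(edges = edges, nodes = nodes, settings = settings),
            class = "taxon_network")
}

#' @export
print.taxon_network <- function(x, ...) {
  cat(sprintf("taxon_network: %d nodes, %d signed edges (%s backend)\n",
              length(x$nodes), nrow(x$edges), x$settings$method))
  invisible(x)
}

mb_neighborhood <- function(X, lambdas) {
  p <- ncol(X)
  B <- matrix(0, p, p)
  adj_per_lambda <- array(FALSE, c(p, p, length(lambdas)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j], lambda = lambdas,
                          standardize = FALSE, intercept = TRUE)
    beta <- as.matrix(fit$beta)               # (p-1) x n_lambda
    others <- seq_len(p)[-j]
    for (l in seq_len(ncol(beta))) {
      nz <- beta[, l] != 0
      adj_per_lambda[j, others[nz], l] <- TRUE
    }
    B[j, others] <- beta[, ncol(beta)]        # refit later at chosen lambda
  }
  list(adj = adj_per_lambda)
}

infer_network_mb <- function(X, settings) {
  n <- nrow(X); p <- ncol(X)
  S <- cov(X)
  lam_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lam_max), log(lam_max * settings$lambda_min_ratio),
                     length.out = settings$n_lambda))
  nb <- floor(settings$subsample_ratio * n)
  p2 <- choose(p, 2)
  freq <- array(0, c(p, p, length(lambdas)))
  for (b in seq_len(settings$stars_subsamples)) {
    set.seed(derive_seed(settings$seed, b))
    idx <- sample.int(n, nb)
    Xs <- scale(X[idx, , drop = FALSE])
    res <- mb_neighborhood(Xs, lambdas)
    for (l in seq_along(lambdas)) {
      a <- res$adj[, , l] | t(res$adj[, , l])   # OR rule
      freq[, , l] <- freq[, , l] + a
    }
  }
  theta <- freq / settings$stars_subsamples
  instab <- vapply(seq_along(lambdas), function(l) {
    th <- theta[, , l][upper.tri(theta[, , l])]
    sum(2 * th * (1 - th)) / p2
  }, numeric(1))
  instab_mono <- cummax(instab)                 # lambdas ordered dense <- sparse
  ok <- which(instab_mono <= settings$stars_instability)
  l_star <- if (length(ok) > 0) max(ok) else 1L
  set.seed(derive_seed(settings$seed, 0L))
  Xf <- scale(X)
  Bsel <- matrix(0, p, p)
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(Xf[, -j, drop = FALSE], Xf[, j], lambda = lambdas,
                          standardize = FALSE, intercept = TRUE)
    Bsel[j, seq_len(p)[-j]] <- as.matrix(fit$beta)[, l_star]
  }
  adj <- (Bsel != 0) | (t(Bsel) != 0)
  strength <- (Bsel + t(Bsel)) / 2
  list(adj = adj, strength = strength)
}

infer_network_pcor <- function(X, settings) {
  Xs <- scale(X)
  S <- cov(Xs)
  # CLR rows sum to zero, so S is singular along the constant direction;
  # invert only the informative eigenspace or that null direction floods
  # every partial correlation
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  Om <- e$vectors[, keep, drop = FALSE] %*%
    ((1 / (e$values[keep] + settings$ridge)) *
       t(e$vectors[, keep, drop = FALSE]))
  dd <- sqrt(diag(Om))
  pc <- -Om / outer(dd, dd)
  diag(pc) <- 0
  adj <- abs(pc) >= settings$pcor_threshold
  list(adj = adj, strength = pc)
}

#' Infer a signed co-occurrence network from a filtered count table
#'
#' Estimates a sparse conditional-dependence graph on CLR-transformed
#' counts. The default backend (`"mb"`) runs per-taxon lasso regressions
#' over a regularization path and selects the penalty by StARS stability
#' selection (edge sets refit on random subsamples; the sparsest penalty
#' whose monotonized instability stays within the target is kept); edge
#' strength is the symmetrized regression coefficient, a signed
#' partial-association measure. The `"pcor"` backend thresholds partial
#' correlations from a ridge-regularized precision matrix and is orders of
#' magnitude faster, for ensemble-scale use. Working on CLR values makes
#' the edge set invariant to per-sample sequencing depth.
#'
#' @param x a [count_table] (filter first with [filter_rare_taxa()]).
#' @param settings a [network_settings()].
#' @return a `taxon_network`: `nodes` plus an `edges` data frame
#'   (`taxon_a`, `taxon_b`, `strength`) with `taxon_a < taxon_b`, no
#'   self-edges, all strengths finite and nonzero. Empty edge sets yield a
#'   zero-row frame with a warning.
#' @export
infer_network <- function(x, settings = network_settings()) {
  stop_if_not(inherits(x, "count_table"), "x must be a count_table")
  stop_if_not(nrow(x$counts) >= 3, "need at least 3 taxa")
  X <- clr_transform(x, settings$pseudocount)
  res <- switch(settings$method,
                mb = infer_network_mb(X, settings),
                pcor = infer_network_pcor(X, settings))
  taxa <- colnames(X)
  idx <- which(res$adj & upper.tri(res$adj), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no edges selected at any penalty; returning empty network")
    edges <- data.frame(taxon_a = character(0), taxon_b = character(0),
                        strength = numeric(0))
  } else {
    edges <- data.frame(taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]],
                        strength = res$strength[idx],
                        stringsAsFactors = FALSE)
    swap <- edges$taxon_a > edges$taxon_b
    tmp <- edges$taxon_a[swap]
    edges$taxon_a[swap] <- edges$taxon_b[swap]
    edges$taxon_b[swap] <- tmp
    edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
    rownames(edges) <- NULL
    stop_if_not(all(is.finite(edges$strength)), "non-finite edge strengths")
  }
  new_network(edges, taxa, settings)
}

#' Infer one network per subsample for one group of a variable
#'
#' Applies the rare-taxon filter once to the full table (so the node set is
#' shared), then fits [infer_network()] on the group-of-interest samples of
#' every subsample in the ensemble.
#'
#' @param x a [count_table] over all samples.
#' @param ensemble a `subsample_ensemble` from [subsample_binary()].
#' @param group which group to model (default `"yes"`).
#' @param settings a [network_settings()]; each subsample gets a derived
#'   seed.
#' @param min_count,min_samples rare-taxon filter thresholds.
#' @return a `network_ensemble`: list of `taxon_network`s plus provenance
#'   (variable, group, settings).
#' @export
network_ensemble <- function(x, ensemble, group = "yes",
                             settings = network_settings(method = "pcor"),
                             min_count = 15, min_samples = 20) {
  xf <- filter_rare_taxa(x, min_count, min_samples)
  nets <- vector("list", ensemble$n_reps)
  for (r in seq_len(ensemble$n_reps)) {
    s <- ensemble$sets[[r]]
    ids <- s$sample_id[as.character(s$group) == group]
    st <- settings
    st$seed <- derive_seed(settings$seed, r)
    nets[[r]] <- infer_network(subset_counts(xf, samples = ids), st)
  }
  structure(list(variable = ensemble$variable, group = group,
                 networks = nets, settings = settings),
            class = "network_ensemble")
}

edge_keys <- function(net, sign_sensitive = FALSE) {
  if (nrow(net$edges) == 0) return(character(0))
  k <- paste(net$edges$taxon_a, net$edges$taxon_b, sep = "~")
  if (sign_sensitive) k <- paste0(k, ifelse(net$edges$strength >= 0, "+", "-"))
  k
}

#' Pairwise network-uniqueness scores across variables
#'
#' For each variable `v` the "core" associations are those present in every
#' one of `v`'s subsample networks (strict: an edge seen in 99 of 100
#' networks does not qualify). Against each other variable `w`, the score
#' is the sum over core edges absent from all of `w`'s networks of the mean
#' absolute strength across `v`'s networks — a strength-weighted count of
#' universally reproducible, exclusive associations. Edge identity is the
#' unordered taxon pair, sign-insensitive by default.
#'
#' @param ensembles named list (>= 2) of `network_ensemble`s of equal size,
#'   each holding the group-of-interest networks of one variable.
#' @param sign_sensitive treat same pair with opposite signs as different
#'   associations.
#' @return a `uniqueness_result`: `pair_scores` matrix (rows `v`, columns
#'   `w`, diagonal `NA`) and a `summary` data frame with per-variable
#'   aggregate (sum and mean over pairings) and spread (sd).
#' @export
uniqueness_scores <- function(ensembles, sign_sensitive = FALSE) {
  stop_if_not(length(ensembles) >= 2, "need at least 2 ensembles")
  if (is.null(names(ensembles))) {
    names(ensembles) <- vapply(ensembles, `[[`, character(1), "variable")
  }
  sizes <- vapply(ensembles, function(e) length(e$networks), integer(1))
  stop_if_not(length(unique(sizes)) == 1,
              "ensembles must have equal sizes (got %s)",
              paste(sizes, collapse = ","))
  vars <- names(ensembles)
  keysets <- lapply(ensembles, function(e)
    lapply(e$networks, edge_keys, sign_sensitive = sign_sensitive))
  core <- lapply(seq_along(ensembles), function(i) {
    ks <- keysets[[i]]
    common <- Reduce(intersect, ks)
    if (length(common) == 0) return(list(keys = character(0), w = numeric(0)))
    wts <- sapply(common, function(k) {
      mean(vapply(ensembles[[i]]$networks, function(net) {
        j <- match(k, edge_keys(net, sign_sensitive))
        abs(net$edges$strength[j])
      }, numeric(1)))
    })
    list(keys = common, w = wts)
  })
  anyset <- lapply(keysets, function(ks) unique(unlist(ks)))
  scores <- matrix(NA_real_, length(vars), length(vars),
                   dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i == j) next
      qual <- !(core[[i]]$keys %in% anyset[[j]])
      scores[i, j] <- sum(core[[i]]$w[qual])
    }
  }
  summ <- data.frame(
    variable = vars,
    n_core_edges = vapply(core, function(cc) length(cc$keys), integer(1)),
    sum_score = rowSums(scores, na.rm = TRUE),
    mean_score = rowMeans(scores, na.rm = TRUE),
    sd_score = apply(scores, 1, sd, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(pair_scores = scores, summary = summ),
            class = "uniqueness_result")
}

#' @export
print.uniqueness_result <- function(x, ...) {
  cat("network uniqueness (strength-weighted exclusive core associations)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a network as an edge-list TSV
#'
#' @param net a `taxon_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
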