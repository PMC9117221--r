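#' Consensus PERMANOVA across a subsample ensemble
#'
#' Runs one PERMANOVA per subsample (focal term first, covariates after)
#' and aggregates: mean p (FDR-adjusted within each subsample when several
#' tests form a family, as in one-vs-rest mode), mean R-squared, mean
#' pseudo-F, and the number of subsamples significant at `alpha`.
#'
#' @param d distance matrix over all samples (labels required).
#' @param ensemble a `subsample_ensemble`.
#' @param meta metadata supplying covariates.
#' @param focal focal term: `"group"` uses the ensemble's group labels
#'   (binary yes/no or age-bin factor); `"age"` uses continuous age.
#' @param covariates metadata columns entered after the focal term
#'   (default gender and log town population, plus age when not focal).
#' @param n_perm permutations per test (default 999).
#' @param one_vs_rest when the ensemble groups are age bins: test each bin
#'   against the rest, FDR-adjusting across bins within each subsample.
#' @param alpha significance level for counting.
#' @return for the standard mode a one-row data frame
#'   (`mean_adjusted_p`, `mean_r2`, `mean_f`, `n_significant`,
#'   `n_reps`); in one-vs-rest mode one row per bin.
#' @export
permanova_consensus <- function(d, ensemble, meta, focal = "group",
                                covariates = NULL, n_perm = 999,
                                one_vs_rest = FALSE, alpha = 0.05) {
  m <- as.matrix(d)
  meta2 <- prepare_covariate_frame(meta)
  if (is.null(covariates)) {
    covariates <- intersect(c("gender", "log_population"), names(meta2))
    if (focal != "age" && !one_vs_rest && "age" %in% names(meta2)) {
      covariates <- c(covariates, "age")
    }
  }
  per_rep <- lapply(seq_len(ensemble$n_reps), function(r) {
    s <- ensemble$sets[[r]]
    ids <- s$sample_id
    dsub <- m[ids, ids]
    md <- meta2[match(ids, meta2$sample_id), covariates, drop = FALSE]
    seed_r <- derive_seed(ensemble$seed, 500000L + r)
    if (one_vs_rest) {
      res <- permanova_one_vs_rest(as.dist(dsub), s$group, md,
                                   n_perm = n_perm, seed = seed_r)
      res$padj <- p.adjust(res$p, method = "fdr")
      res
    } else {
      focal_col <- if (focal == "age") {
        data.frame(age = meta2$age[match(ids, meta2$sample_id)])
      } else {
        data.frame(group = s$group)
      }
      dsg <- cbind(focal_col, md)
      res <- permanova(as.dist(dsub), dsg, n_perm = n_perm, seed = seed_r)
      r1 <- res[1, , drop = FALSE]
      data.frame(bin = "(focal)", r2 = r1$r2, f = r1$f, p = r1$p,
                 padj = r1$p)
    }
  })
  all <- do.call(rbind, per_rep)
  agg <- do.call(rbind, lapply(split(all, all$bin), function(g) {
    data.frame(bin = g$bin[1], mean_adjusted_p = mean(g$padj),
               mean_r2 = mean(g$r2), mean_f = mean(g$f),
               n_significant = sum(g$padj < alpha), n_reps = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (!one_vs_rest) agg$bin <- NULL
  agg
}

#' Consensus homogeneity-of-dispersion test across a subsample ensemble
#'
#' Runs [homogeneity_test()] on each subsample's groups and aggregates the
#' ANOVA results and the per-group mean distances to the spatial median.
#'
#' @param d distance matrix over all samples.
#' @param ensemble a `subsample_ensemble` (binary or age-bin).
#' @param alpha significance level for counting.
#' @return list with `mean_p`, `mean_f`, `n_significant`, `n_reps`, and
#'   `group_means` (per-group mean distance to the spatial median, averaged
#'   over subsamples).
#' @export
homogeneity_consensus <- function(d, ensemble, alpha = 0.05) {
  m <- as.matrix(d)
  ps <- numeric(ensemble$n_reps)
  fs <- numeric(ensemble$n_reps)
  gm <- NULL
  for (r in seq_len(ensemble$n_reps)) {
    s <- ensemble$sets[[r]]
    h <- homogeneity_test(as.dist(m[s$sample_id, s$sample_id]), s$group)
    ps[r] <- h$p; fs[r] <- h$f
    gm <- if (is.null(gm)) h$group_means else gm + h$group_means
  }
  list(mean_p = mean(ps), mean_f = mean(fs),
       n_significant = sum(ps < alpha), n_reps = ensemble$n_reps,
       group_means = gm / ensemble$n_reps)
}
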