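#' PERMANOVA on a distance matrix with covariates
#'
#' Permutational multivariate analysis of variance: the Gower-centered
#' inner-product matrix of `d` is partitioned over the model terms with
#' sequential (order-of-entry) sums of squares, so the variable of interest
#' should come first in `design`, followed by the covariates (typically
#' gender, age and town population). Significance is assessed by free
#' permutation of sample labels; the reported p includes the observed
#' statistic in the null set, so `p >= 1/(n_perm+1)`. Computation is
#' delegated to `vegan::adonis2`.
#'
#' @param d a `dist` object or symmetric distance matrix over samples.
#' @param design data frame of model terms, in the order they should enter
#'   the model; rows must align with (or be named by) the samples of `d`.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed optional seed for the permutation stream.
#' @param by `"terms"` for sequential sums of squares (the default) or
#'   `"margin"` for marginal tests; marginal tests of main effects are not
#'   order-dependent but no longer decompose the total sum of squares.
#' @param permutations optional explicit permutation matrix (e.g.
#'   `permute::allPerms(n)` for exhaustive enumeration); overrides
#'   `n_perm`.
#' @return a data frame of class `permanova_result` with one row per term:
#'   `term`, `df`, `ss`, `r2`, `f`, `p`; attribute `residual_r2` completes
#'   the decomposition so that term and residual R-squared values sum to 1.
#' @export
permanova <- function(d, design, n_perm = 999, seed = NULL, by = "terms",
                      permutations = NULL) {
  m <- as.matrix(d)
  validate_distance(m)
  design <- as.data.frame(design)
  stop_if_not(nrow(design) == nrow(m), "design rows must align with d")
  if (!is.null(rownames(m)) && !is.null(rownames(design)) &&
      all(rownames(m) %in% rownames(design))) {
    design <- design[rownames(m), , drop = FALSE]
  }
  keep <- vapply(design, function(col) length(unique(col[!is.na(col)])) > 1,
                 logical(1))
  if (any(!keep)) {
    warning(sprintf("dropping constant/inestimable term(s): %s",
                    paste(names(design)[!keep], collapse = ", ")))
    design <- design[, keep, drop = FALSE]
  }
  stop_if_not(ncol(design) > 0, "no estimable terms in design")
  if (is.null(permutations)) {
    stop_if_not(n_perm >= 99, "n_perm must be at least 99")
    permutations <- n_perm
  }
  dd <- as.dist(m)
  fml <- stats::as.formula(paste("dd ~", paste(names(design), collapse = " + ")),
                           env = environment())
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::adonis2(fml, data = design, permutations = permutations,
                        by = by)
  tab <- as.data.frame(res)
  rows <- !(rownames(tab) %in% c("Residual", "Total"))
  out <- data.frame(term = rownames(tab)[rows], df = tab$Df[rows],
                    ss = tab$SumOfSqs[rows], r2 = tab$R2[rows],
                    f = tab$F[rows], p = tab$`Pr(>F)`[rows],
                    stringsAsFactors = FALSE)
  attr(out, "residual_r2") <- tab["Residual", "R2"]
  attr(out, "n_perm") <- if (is.matrix(permutations)) nrow(permutations) else permutations
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' One-vs-rest PERMANOVA over age bins
#'
#' For each bin, tests a binary indicator (this bin vs all others) as the
#' first term, retaining the supplied covariates; used to locate which age
#' ranges drive a global age effect.
#'
#' @param d distance matrix over samples.
#' @param bins factor of bin labels aligned with `d`.
#' @param design data frame of covariates (without the bin term).
#' @param n_perm,seed see [permanova()].
#' @return data frame with one row per bin: `bin`, `r2`, `f`, `p`.
#' @export
permanova_one_vs_rest <- function(d, bins, design = NULL, n_perm = 999,
                                  seed = NULL) {
  bins <- factor(bins)
  stop_if_not(nlevels(bins) >= 2, "need at least 2 bins")
  tab <- table(bins)
  stop_if_not(all(tab >= 3), "every bin needs at least 3 samples (smallest: %d)",
              min(tab))
  out <- lapply(levels(bins), function(lv) {
    ind <- factor(ifelse(bins == lv, "in", "rest"), levels = c("rest", "in"))
    dsg <- data.frame(bin_indicator = ind)
    if (!is.null(design)) dsg <- cbind(dsg, design)
    r <- permanova(d, dsg, n_perm = n_perm, seed = seed)
    r1 <- r[r$term == "bin_indicator", ]
    data.frame(bin = lv, r2 = r1$r2, f = r1$f, p = r1$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Homogeneity of multivariate dispersion about spatial medians
#'
#' Embeds the distance matrix in principal-coordinate space, locates each
#' group's spatial median (the point minimizing summed Euclidean distance
#' to the group's samples), and compares the per-sample distances to their
#' own group's median across groups with a one-way ANOVA. Distances from
#' non-Euclidean embeddings use the standard correction (squared real-part
#' distance minus squared imaginary-part distance, floored at zero);
#' Aitchison matrices embed exactly, so the correction never fires there.
#' Delegated to `vegan::betadisper(type = "median")`.
#'
#' @param d distance matrix over samples.
#' @param groups factor aligned with `d`; every group needs >= 2 samples.
#' @param bias_adjust apply the small-sample bias correction to the
#'   distances (default `TRUE`): the spatial median overfits small groups,
#'   shrinking their distances and inflating type-I error when group sizes
#'   differ.
#' @return a list of class `homogeneity_result`: per-sample `distances`,
#'   `groups`, per-group mean distances `group_means`, the spatial `medians`
#'   in PCoA coordinates, embedding eigenvalues `eig`, and the ANOVA `f`
#'   and `p`.
#' @export
homogeneity_test <- function(d, groups, bias_adjust = TRUE) {
  groups <- factor(groups)
  tab <- table(groups)
  stop_if_not(all(tab >= 2), "every group needs >= 2 samples (got %s)",
              paste(tab, collapse = ","))
  bd <- vegan::betadisper(as.dist(d), groups, type = "median",
                          bias.adjust = bias_adjust)
  av <- anova(bd)
  structure(list(distances = bd$distances, groups = groups,
                 group_means = tapply(bd$distances, groups, mean),
                 medians = bd$centroids, eig = bd$eig,
                 f = av$`F value`[1], p = av$`Pr(>F)`[1]),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat("homogeneity of dispersion (distance to group spatial median)\n")
  print(round(x$group_means, 4))
  cat(sprintf("ANOVA F = %.3f, p = %.4g\n", x$f, x$p))
  invisible(x)
}

#' Unit-membership vector for a relationship type
#'
#' Maps metadata to the unit assignment used by the similarity tests:
#' family-unit ids filtered to one relationship type, all family members
#' (`"family"`), or school ids (`"classmates"`). Only samples in units of
#' two or more remain; everything else is `NA`.
#'
#' @param meta metadata with `family_unit`, `relationship`, `school`.
#' @param relationship one of `"sibling"`, `"twin"`, `"partner"`,
#'   `"parent-child"`, `"grandparent-grandchild"`, `"family"`,
#'   `"classmates"`.
#' @return named character vector (names = sample ids) of unit ids, `NA`
#'   for excluded samples.
#' @export
unit_membership <- function(meta, relationship) {
  rel <- match.arg(relationship,
                   c("sibling", "twin", "partner", "parent-child",
                     "grandparent-grandchild", "family", "classmates"))
  units <- if (rel == "classmates") {
    meta$school
  } else if (rel == "family") {
    meta$family_unit
  } else {
    ifelse(!is.na(meta$relationship) & meta$relationship == rel,
           meta$family_unit, NA_character_)
  }
  names(units) <- meta$sample_id
  tab <- table(units)
  units[units %in% names(tab)[tab < 2]] <- NA_character_
  units
}

#' Analysis of similarities over family or classroom units
#'
#' Rank-based test of whether samples within a unit are more similar than
#' samples from different units: all pairwise distances are ranked and
#' `R = (mean between-unit rank - mean within-unit rank) / (M/2)` with `M`
#' the number of pairs, so `R` is 1 for perfect separation and near 0 under
#' no unit structure. Only samples belonging to a unit of two or more are
#' included; p is by permutation of unit labels (`vegan::anosim`).
#'
#' @param d distance matrix over samples (labels required).
#' @param units named unit assignment (see [unit_membership()]); `NA`
#'   entries are dropped.
#' @param n_perm permutations (default 999).
#' @param seed optional permutation seed.
#' @return list of class `anosim_result`: `R`, `p`, `n_samples`, `n_units`,
#'   and the `within`/`between` distance samples for plotting.
#' @export
anosim_units <- function(d, units, n_perm = 999, seed = NULL) {
  m <- as.matrix(d)
  units <- units[!is.na(units)]
  keep <- intersect(rownames(m), names(units))
  stop_if_not(length(keep) >= 4, "need at least 4 samples in units")
  g <- factor(units[keep])
  stop_if_not(nlevels(g) >= 2, "all samples fall in a single unit")
  stop_if_not(all(table(g) >= 2), "every unit needs >= 2 samples")
  dsub <- as.dist(m[keep, keep])
  if (!is.null(seed)) set.seed(seed)
  an <- vegan::anosim(dsub, g, permutations = n_perm)
  ms <- as.matrix(dsub)
  same <- outer(g, g, "==")
  ut <- upper.tri(ms)
  structure(list(R = unname(an$statistic), p = an$signif,
                 n_samples = length(keep), n_units = nlevels(g),
                 within = ms[ut & same], between = ms[ut & !same]),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("anosim: R = %.3f, p = %.4g (%d samples in %d units)\n",
              x$R, x$p, x$n_samples, x$n_units))
  invisible(x)
}

#' Within-unit pairwise distances
#'
#' @param d distance matrix over samples.
#' @param units named unit assignment; `NA` excluded.
#' @return numeric vector of all pairwise distances within units.
#' @export
within_unit_distances <- function(d, units) {
  m <- as.matrix(d)
  units <- units[!is.na(units)]
  out <- numeric(0)
  for (u in unique(units)) {
    ids <- intersect(names(units)[units == u], rownames(m))
    if (length(ids) >= 2) {
      sub <- m[ids, ids]
      out <- c(out, sub[upper.tri(sub)])
    }
  }
  out
}

#' Compare within-twin and within-sibling distances
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the Aitchison
#' distances among twins against those among non-twin siblings; a
#' non-significant result indicates twins are no more alike than ordinary
#' siblings, pointing at shared environment rather than host genetics.
#'
#' @param d distance matrix over samples.
#' @param twin_units,sibling_units named unit assignments (see
#'   [unit_membership()]).
#' @return `htest` from [wilcox.test()] with the two distance samples
#'   attached as `twin_distances` / `sibling_distances`.
#' @export
twins_vs_siblings <- function(d, twin_units, sibling_units) {
  tw <- within_unit_distances(d, twin_units)
  sb <- within_unit_distances(d, sibling_units)
  stop_if_not(length(tw) >= 1 && length(sb) >= 1,
              "need at least one within-pair distance per side")
  ht <- wilcox.test(tw, sb, alternative = "two.sided", exact = NULL)
  ht$twin_distances <- tw
  ht$sibling_distances <- sb
  ht
}
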