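#' The six age bins used throughout the pipeline
#'
#' Bins 13-20, 20-30, 30-40, 40-50, 50-60 and >60 years (left-closed).
#' Samples younger than 13 or with missing age map to `NA` and are
#' ineligible for binned analyses.
#'
#' @return a list with `breaks` and `labels`.
#' @export
age_binning <- function() {
  list(breaks = c(13, 20, 30, 40, 50, 60, Inf),
       labels = c("13-20", "20-30", "30-40", "40-50", "50-60", ">60"))
}

#' Assign ages to bins
#' @param age numeric vector of ages in years.
#' @param binning a binning as returned by [age_binning()].
#' @return factor of bin labels (with `NA` for ineligible ages).
#' @export
assign_age_bin <- function(age, binning = age_binning()) {
  cut(age, breaks = binning$breaks, labels = binning$labels, right = FALSE)
}

base_eligible <- function(meta) {
  !is.na(meta$age) & !is.na(meta$gender)
}

is_chronic_flag <- function(meta, variable) {
  fl <- meta[[variable]]
  if (is.null(fl)) return(FALSE)
  chr <- meta$chronic_disorder_any
  if (is.null(chr)) return(FALSE)
  any(fl == "yes" & chr, na.rm = TRUE) &&
    !any(fl == "yes" & !chr, na.rm = TRUE)
}

#' Samples eligible as matched controls for a variable
#'
#' Removes samples with any reported chronic disorder (control groups are
#' always disorder-free, even when the tested variable is itself a
#' disorder), samples missing age or gender, and samples collected in
#' regions where no yes-group sample was collected (controls must match the
#' yes-group's geographic range).
#'
#' @param meta metadata data frame (see [read_metadata()]); needs columns
#'   `sample_id`, `age`, `gender`, `region`, `chronic_disorder_any` and the
#'   flag column `variable`.
#' @param variable name of the binary flag being tested.
#' @return character vector of sample ids eligible as controls.
#' @export
eligible_controls <- function(meta, variable) {
  stop_if_not(variable %in% names(meta), "unknown variable '%s'", variable)
  fl <- meta[[variable]]
  ok <- base_eligible(meta) & !is.na(fl) & fl == "no"
  if (!is.null(meta$chronic_disorder_any)) {
    ok <- ok & !meta$chronic_disorder_any
  }
  yes_regions <- unique(meta$region[!is.na(fl) & fl == "yes" &
                                      base_eligible(meta)])
  ok <- ok & meta$region %in% yes_regions
  ids <- meta$sample_id[ok]
  stop_if_not(length(ids) > 0, "no eligible controls for '%s'", variable)
  ids
}

yes_group <- function(meta, variable) {
  fl <- meta[[variable]]
  ok <- base_eligible(meta) & !is.na(fl) & fl == "yes"
  if (!is_chronic_flag(meta, variable) && !is.null(meta$chronic_disorder_any)) {
    ok <- ok & !meta$chronic_disorder_any   # e.g. a smoker with CF is excluded
  }
  meta$sample_id[ok]
}

matching_report <- function(meta, yes_ids, no_ids) {
  a <- meta[match(yes_ids, meta$sample_id), ]
  b <- meta[match(no_ids, meta$sample_id), ]
  ks <- suppressWarnings(ks.test(a$age, b$age))$p.value
  tab_g <- rbind(table(factor(a$gender, levels = levels(factor(meta$gender)))),
                 table(factor(b$gender, levels = levels(factor(meta$gender)))))
  tab_r <- rbind(table(factor(a$region, levels = levels(factor(meta$region)))),
                 table(factor(b$region, levels = levels(factor(meta$region)))))
  safe_chisq <- function(tab) {
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) return(1)
    suppressWarnings(chisq.test(tab))$p.value
  }
  list(age_ks_p = ks, gender_chisq_p = safe_chisq(tab_g),
       region_chisq_p = safe_chisq(tab_r),
       mean_age = c(yes = mean(a$age), no = mean(b$age)))
}

draw_matched_controls <- function(meta, yes_ids, pool_ids) {
  md <- meta[match(pool_ids, meta$sample_id), ]
  ya <- meta[match(yes_ids, meta$sample_id), ]
  bins <- age_binning()
  stratum <- function(d) paste(d$gender, d$region, assign_age_bin(d$age, bins),
                               sep = "|")
  need <- table(stratum(ya))
  pool_str <- stratum(md)
  chosen <- character(0)
  deficit_from <- list()
  for (s in names(need)) {
    avail <- setdiff(pool_ids[pool_str == s], chosen)
    k <- min(need[[s]], length(avail))
    if (k > 0) chosen <- c(chosen, sample(avail, k))
    if (k < need[[s]]) deficit_from[[s]] <- need[[s]] - k
  }
  # relaxation: nearest age within gender x region, then nearest age overall
  for (s in names(deficit_from)) {
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    want_ages <- ya$age[stratum(ya) == s]
    for (i in seq_len(deficit_from[[s]])) {
      avail <- setdiff(pool_ids, chosen)
      if (length(avail) == 0) break
      ad <- meta[match(avail, meta$sample_id), ]
      same_gr <- ad$gender == parts[1] & ad$region == parts[2]
      cand <- if (any(same_gr)) avail[same_gr] else avail
      ca <- meta$age[match(cand, meta$sample_id)]
      target <- want_ages[min(i, length(want_ages))]
      chosen <- c(chosen, cand[which.min(abs(ca - target))])
    }
  }
  chosen
}

new_ensemble <- function(variable, sets, matching, seed, sizes) {
  structure(list(variable = variable, sets = sets, matching = matching,
                 seed = seed, n_reps = length(sets), sizes = sizes),
            class = "subsample_ensemble")
}

#' @export
print.subsample_ensemble <- function(x, ...) {
  cat(sprintf("subsample_ensemble for '%s': %d sets, group sizes %s\n",
              x$variable, x$n_reps, paste(x$sizes, collapse = "+")))
  invisible(x)
}

#' Repeated matched-control subsampling for a binary variable
#'
#' Draws `n_reps` index sets, each holding an equal number of yes-group
#' samples and matched controls. The common group size is
#' `min(cap, |yes|, |eligible controls|)`: when both groups exceed the cap
#' (default 100), `cap` of each are drawn per repetition; otherwise the
#' smaller group dictates the size. Controls are drawn stratified on the
#' joint gender x region x age-bin distribution of the drawn yes-group,
#' relaxing to nearest-age within gender x region (then overall) when a
#' stratum is exhausted. Every repetition records a matching report
#' (Kolmogorov-Smirnov age p, chi-square gender and region p). Group sizes
#' are identical across all repetitions, and chronically ill or
#' missing-data samples never enter a control group.
#'
#' @param meta metadata data frame.
#' @param variable binary flag column to test.
#' @param n_reps number of repetitions (default 100).
#' @param cap per-group ceiling (default 100).
#' @param min_group refuse if the smaller group is below this (default 10).
#' @param seed master seed; per-repetition seeds are derived by counter and
#'   stored for replay.
#' @return a `subsample_ensemble`: list of per-repetition data frames with
#'   columns `sample_id` and `group` (`"yes"`/`"no"`), plus matching
#'   reports.
#' @export
subsample_binary <- function(meta, variable, n_reps = 100, cap = 100,
                             min_group = 10, seed = 1L) {
  yes_ids <- yes_group(meta, variable)
  pool <- eligible_controls(meta, variable)
  stop_if_not(length(yes_ids) > 0, "empty yes-group for '%s'", variable)
  size <- min(cap, length(yes_ids), length(pool))
  stop_if_not(size >= min_group,
              "smaller group for '%s' has %d samples (< %d); refusing",
              variable, min(length(yes_ids), length(pool)), min_group)
  sets <- vector("list", n_reps)
  matching <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    yr <- if (length(yes_ids) > size) sample(yes_ids, size) else yes_ids
    nr <- draw_matched_controls(meta, yr, pool)
    sets[[r]] <- data.frame(sample_id = c(yr, nr),
                            group = factor(rep(c("yes", "no"), c(length(yr), length(nr))),
                                           levels = c("no", "yes")),
                            stringsAsFactors = FALSE)
    matching[[r]] <- matching_report(meta, yr, nr)
  }
  new_ensemble(variable, sets, matching, seed, c(yes = size, no = size))
}

#' Repeated balanced subsampling over the six age bins
#'
#' Per repetition, draws from every age bin so that the gender x region
#' composition of each bin matches the pooled eligible composition
#' (proportional allocation within joint cells, limited by availability).
#' Realized per-bin sizes are therefore constant across repetitions; they
#' differ between bins only through the availability of balanced samples.
#' Samples with chronic disorders or missing age/gender are excluded. The
#' same ensembles serve tests that use age as a continuous covariate, which
#' is why an even, balanced age spread matters.
#'
#' @param meta metadata data frame.
#' @param binning a binning from [age_binning()].
#' @param n_reps number of repetitions (default 100).
#' @param cap per-bin ceiling (default 100).
#' @param seed master seed.
#' @return a `subsample_ensemble` whose per-repetition data frames have
#'   columns `sample_id` and `group` (the bin label).
#' @export
subsample_age_bins <- function(meta, binning = age_binning(), n_reps = 100,
                               cap = 100, seed = 1L) {
  ok <- base_eligible(meta)
  if (!is.null(meta$chronic_disorder_any)) ok <- ok & !meta$chronic_disorder_any
  md <- meta[ok, , drop = FALSE]
  md$bin <- assign_age_bin(md$age, binning)
  md <- md[!is.na(md$bin), , drop = FALSE]
  occ <- table(md$bin)
  if (any(occ == 0)) {
    stop(sprintf("age bin(s) empty after eligibility: %s",
                 paste(names(occ)[occ == 0], collapse = ", ")), call. = FALSE)
  }
  md$cell <- paste(md$gender, md$region, sep = "|")
  cells <- sort(unique(md$cell))
  avail <- table(factor(md$bin, levels = binning$labels),
                 factor(md$cell, levels = cells))
  # balance is only achievable over gender x region cells occupied in every
  # bin; draws share one composition (the pooled mix over those cells) and
  # each bin's size is limited by its availability relative to that mix
  ok <- apply(avail, 2, min) > 0
  stop_if_not(any(ok), "no gender x region cell is occupied in every bin; cannot balance")
  cells <- cells[ok]
  avail <- avail[, ok, drop = FALSE]
  p_cell <- table(factor(md$cell[md$cell %in% cells], levels = cells))
  p_cell <- as.numeric(p_cell) / sum(p_cell)
  quota <- matrix(0L, nrow(avail), length(cells),
                  dimnames = list(rownames(avail), cells))
  for (b in rownames(avail)) {
    target <- min(cap, floor(min(as.integer(avail[b, ]) / p_cell)))
    t0 <- as.integer(floor(p_cell * target))
    names(t0) <- cells
    deficit <- target - sum(t0)
    while (deficit > 0) {
      spare <- as.integer(avail[b, ]) - t0
      want <- p_cell * target - t0
      cand <- which(spare > 0)
      if (length(cand) == 0) break
      j <- cand[which.max(want[cand])]
      t0[j] <- t0[j] + 1L
      deficit <- deficit - 1L
    }
    quota[b, ] <- t0
  }
  sizes <- rowSums(quota)
  if (any(sizes == 0)) {
    stop(sprintf("age bin(s) empty after balancing: %s",
                 paste(names(sizes)[sizes == 0], collapse = ", ")), call. = FALSE)
  }
  sets <- vector("list", n_reps)
  matching <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    ids <- character(0); grp <- character(0)
    for (b in rownames(quota)) {
      for (cl in cells) {
        k <- quota[b, cl]
        if (k > 0) {
          pool <- md$sample_id[md$bin == b & md$cell == cl]
          pick <- if (length(pool) == k) pool else sample(pool, k)
          ids <- c(ids, pick); grp <- c(grp, rep(b, k))
        }
      }
    }
    sets[[r]] <- data.frame(sample_id = ids,
                            group = factor(grp, levels = binning$labels),
                            stringsAsFactors = FALSE)
    sm <- meta[match(ids, meta$sample_id), ]
    tab_r <- table(grp, as.character(sm$region))
    tab_g <- table(grp, as.character(sm$gender))
    safe_p <- function(tab) {
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2 || nrow(tab) < 2) return(1)
      suppressWarnings(chisq.test(tab))$p.value
    }
    matching[[r]] <- list(region_chisq_p = safe_p(tab_r),
                          gender_chisq_p = safe_p(tab_g))
  }
  new_ensemble("age", sets, matching, seed, sizes)
}

#' Export a subsample ensemble as JSON
#'
#' Index sets plus matching reports, for provenance or external reuse.
#'
#' @param ensemble a `subsample_ensemble`.
#' @param path JSON output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  jsonlite::write_json(
    list(variable = ensemble$variable, seed = ensemble$seed,
         sizes = as.list(ensemble$sizes),
         sets = lapply(ensemble$sets, function(s)
           list(sample_id = s$sample_id, group = as.character(s$group))),
         matching = ensemble$matching),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
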