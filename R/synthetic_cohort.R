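#' Specify one binary condition for the synthetic cohort
#'
#' @param name flag name (metadata column).
#' @param prevalence probability a sample carries the flag, in [0, 1].
#' @param effect_size_clr magnitude of the planted shift, on the CLR scale,
#'   applied (with random signs) to a subset of taxa in flagged samples.
#' @param dispersion_ratio multiplier on the sample-level noise scale for
#'   flagged samples; values below 1 plant a more homogeneous group.
#' @param chronic logical; chronic disorders are assigned mutually
#'   exclusively and are excluded from matched-control pools downstream.
#' @param n_effect_taxa number of taxa carrying the shift (default 8).
#' @param network_strength standard deviation of shared latent factors that
#'   couple pairs of taxa *only in flagged samples*, planting
#'   condition-exclusive co-occurrence edges (0 = none).
#' @param n_network_taxa number of taxa coupled pairwise by those factors
#'   (must be even; `n_network_taxa/2` exclusive edges are planted).
#' @return a `condition_spec` list.
#' @export
condition_spec <- function(name, prevalence, effect_size_clr = 0,
                           dispersion_ratio = 1, chronic = FALSE,
                           n_effect_taxa = 8, network_strength = 0,
                           n_network_taxa = 4) {
  stop_if_not(prevalence >= 0 && prevalence <= 1,
              "prevalence of '%s' must be in [0,1]", name)
  stop_if_not(is.finite(effect_size_clr), "effect size of '%s' must be finite", name)
  stop_if_not(is.finite(dispersion_ratio) && dispersion_ratio > 0,
              "dispersion ratio of '%s' must be positive", name)
  stop_if_not(is.finite(network_strength) && network_strength >= 0,
              "network strength of '%s' must be nonnegative", name)
  stop_if_not(n_network_taxa %% 2 == 0, "n_network_taxa must be even")
  structure(list(name = name, prevalence = prevalence,
                 effect_size_clr = effect_size_clr,
                 dispersion_ratio = dispersion_ratio, chronic = chronic,
                 n_effect_taxa = n_effect_taxa,
                 network_strength = network_strength,
                 n_network_taxa = n_network_taxa), class = "condition_spec")
}

#' Default condition roster of the synthetic cohort
#'
#' Three mutually exclusive chronic disorders (cystic fibrosis, Down
#' syndrome, celiac disease) and four independent lifestyle/health flags
#' (smoking, oral yeast carriage, hypertension, recent antibiotics), with
#' prevalences, CLR effect sizes and dispersion ratios ordered like the
#' relative impacts the pipeline is designed to resolve (chronic disorders
#' strongest, then smoking and yeast). Modify entries to build scenario
#' variants.
#'
#' @return list of [condition_spec()] objects.
#' @export
default_conditions <- function() {
  list(
    condition_spec("cystic_fibrosis", 0.040, 1.00, 0.80, chronic = TRUE),
    condition_spec("down_syndrome",   0.040, 1.00, 0.80, chronic = TRUE),
    condition_spec("celiac",          0.050, 0.80, 0.85, chronic = TRUE),
    condition_spec("smoking",         0.150, 0.60, 0.85),
    condition_spec("yeast",           0.160, 0.50, 1.15),
    condition_spec("hypertension",    0.070, 0.40, 1.00),
    condition_spec("antibiotics",     0.100, 0.40, 1.00)
  )
}

#' Specify a synthetic oral-microbiome cohort
#'
#' Defaults emulate the cohort structure of a large Spanish citizen-science
#' oral-rinse survey: a teen-heavy age distribution over six bins
#' (13-20, 20-30, 30-40, 40-50, 50-60, >60, weighted 964:41:28:85:46:42),
#' mutually exclusive chronic disorders (cystic fibrosis, Down syndrome,
#' celiac disease) plus independent lifestyle flags, family units with
#' labelled relationships, schools for the teenage samples, salivary pH
#' decreasing and BMI increasing with age, and a sample-level noise scale
#' (dispersion curve) that is minimal near age 45 so that middle-aged
#' compositions are the most homogeneous.
#'
#' @param n_samples number of samples.
#' @param n_taxa number of ASVs (>= 2).
#' @param reads_per_sample sequencing depth; every generated sample has
#'   exactly this column sum.
#' @param age_bin_weights six nonnegative weights over the age bins;
#'   normalized internally.
#' @param condition_specs list of [condition_spec()] objects.
#' @param age_slopes per-taxon CLR change per year of age (length `n_taxa`,
#'   recycled); zero means no trend.
#' @param dispersion_curve quadratic coefficients `c(a, b, c)` mapping age
#'   to the noise standard deviation `a*age^2 + b*age + c`; must be
#'   positive everywhere on [7, 85].
#' @param family_effect_sd,classroom_effect_sd standard deviations of the
#'   shared CLR components within family units and schools.
#' @param family_fraction fraction of samples placed in family units.
#' @param baseline_log_sd spread of per-taxon baseline log-abundances
#'   (controls the steepness of the rank-abundance curve).
#' @param ph_quantize quantize pH to 0.5 steps (test-strip resolution).
#' @param seed integer master seed; generation is deterministic given it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 300, n_taxa = 120,
                        reads_per_sample = 20000,
                        age_bin_weights = c(964, 41, 28, 85, 46, 42),
                        condition_specs = default_conditions(),
                        age_slopes = 0,
                        dispersion_curve = c(7e-04, -0.063, 2.3175),
                        family_effect_sd = 0.4, classroom_effect_sd = 0.2,
                        family_fraction = 0.19,
                        baseline_log_sd = 1.5,
                        ph_quantize = TRUE, seed = 1L) {
  stop_if_not(n_samples >= 1, "n_samples must be positive")
  stop_if_not(n_taxa >= 2, "n_taxa must be at least 2")
  stop_if_not(reads_per_sample >= 1, "reads_per_sample must be >= 1")
  stop_if_not(length(age_bin_weights) == 6 && all(age_bin_weights >= 0) &&
                sum(age_bin_weights) > 0,
              "age_bin_weights must be 6 nonnegative weights")
  stop_if_not(all(vapply(condition_specs, inherits, logical(1), "condition_spec")),
              "condition_specs must be condition_spec objects")
  stop_if_not(family_effect_sd >= 0 && classroom_effect_sd >= 0,
              "unit effect sds must be nonnegative")
  age_slopes <- rep_len(age_slopes, n_taxa)
  stop_if_not(all(is.finite(age_slopes)), "age_slopes must be finite")
  stop_if_not(length(dispersion_curve) == 3 && all(is.finite(dispersion_curve)),
              "dispersion_curve must be 3 finite coefficients")
  ages <- seq(7, 85, by = 0.1)
  sc <- dispersion_curve[1] * ages^2 + dispersion_curve[2] * ages + dispersion_curve[3]
  stop_if_not(all(sc > 0),
              "dispersion_curve must be positive over ages 7-85 (min %.3g)", min(sc))
  structure(list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
                 reads_per_sample = as.integer(reads_per_sample),
                 age_bin_weights = age_bin_weights / sum(age_bin_weights),
                 condition_specs = condition_specs, age_slopes = age_slopes,
                 dispersion_curve = dispersion_curve,
                 family_effect_sd = family_effect_sd,
                 classroom_effect_sd = classroom_effect_sd,
                 family_fraction = family_fraction,
                 baseline_log_sd = baseline_log_sd,
                 ph_quantize = ph_quantize, seed = as.integer(seed)),
            class = "cohort_spec")
}

dispersion_at <- function(curve, age) curve[1] * age^2 + curve[2] * age + curve[3]

#' A fully null cohort specification
#'
#' Convenience wrapper: every condition keeps its prevalence but has zero
#' compositional effect and dispersion ratio 1, the dispersion curve is
#' flat, age slopes are zero and family/classroom components are off. Used
#' to validate type-I error control of the downstream tests.
#'
#' @param ... passed on to [cohort_spec()] (e.g. `n_samples`, `seed`).
#' @param noise_sd constant sample-level noise scale.
#' @return a `cohort_spec` with no planted effects.
#' @export
null_cohort_spec <- function(..., noise_sd = 1) {
  conds <- lapply(default_conditions(), function(cs) {
    cs$effect_size_clr <- 0; cs$dispersion_ratio <- 1
    cs$network_strength <- 0; cs
  })
  cohort_spec(..., condition_specs = conds, age_slopes = 0,
              dispersion_curve = c(0, 0, noise_sd),
              family_effect_sd = 0, classroom_effect_sd = 0)
}

#' Generate a random rooted phylogeny over the cohort's taxa
#'
#' Random bifurcating rooted topology with independent exponential branch
#' lengths; tips are labelled `ASV_0001`, ... so they match the taxon ids
#' of [generate_cohort()].
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; the newick string is deterministic given it.
#' @param rate rate of the exponential branch-length distribution.
#' @return a rooted `phylo` object with positive branch lengths.
#' @export
generate_tree <- function(n_taxa, seed = 1L, rate = 10) {
  stop_if_not(n_taxa >= 2, "a tree needs at least 2 tips")
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = TRUE,
                   br = function(n) rexp(n, rate = rate) + 1e-6)
  tr$tip.label <- taxon_names(n_taxa)[as.integer(sub("t", "", tr$tip.label))]
  tr
}

taxon_names <- function(p) sprintf("ASV_%04d", seq_len(p))

age_bin_ranges <- function() {
  list(lo = c(13, 20, 30, 40, 50, 60), hi = c(20, 30, 40, 50, 60, 85))
}

#' Generate a synthetic cohort with planted compositional effects
#'
#' Counts follow a logistic-normal-multinomial model: each sample's latent
#' log-composition is a per-taxon baseline plus an age trend
#' (`age_slopes * (age - 45)`), additive CLR shifts for each condition flag
#' the sample carries, shared family and classroom components, and Gaussian
#' noise whose standard deviation is the dispersion curve evaluated at the
#' sample's age (times the condition dispersion ratios). The latent vector
#' is softmax-transformed and `reads_per_sample` reads are drawn
#' multinomially, so column sums are exact. Effects are planted additively
#' on the CLR scale, the same scale on which the downstream models operate,
#' which makes parameter recovery well-posed.
#'
#' @param spec a [cohort_spec()].
#' @return a `synthetic_cohort` list with elements `counts` (a
#'   [count_table]), `metadata` (data frame), `tree` (rooted `phylo`), and
#'   `truth` (ledger of planted effects: trending taxa with directions,
#'   per-condition shifted taxa and signs, the dispersion curve, unit sds).
#' @export
generate_cohort <- function(spec) {
  stop_if_not(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_taxa
  taxa <- taxon_names(p)
  samples <- sprintf("S%04d", seq_len(n))

  rng <- age_bin_ranges()
  bin <- sample.int(6, n, replace = TRUE, prob = spec$age_bin_weights)
  age <- runif(n, rng$lo[bin], rng$hi[bin])
  gender <- factor(sample(c("female", "male"), n, replace = TRUE),
                   levels = c("female", "male"))
  regions <- c("Catalunya", "Madrid", "Andalucia", "Galicia", "Euskadi", "Valencia")
  region <- factor(sample(regions, n, replace = TRUE,
                          prob = c(0.30, 0.22, 0.15, 0.13, 0.11, 0.09)),
                   levels = regions)
  town_population <- pmax(200, round(rlnorm(n, meanlog = 10, sdlog = 1.3)))

  specs <- spec$condition_specs
  cnames <- vapply(specs, `[[`, character(1), "name")
  chronic <- vapply(specs, `[[`, logical(1), "chronic")
  flags <- matrix(0L, n, length(specs), dimnames = list(samples, cnames))
  if (any(chronic)) {
    # at most one chronic disorder per sample (mutually exclusive)
    pr <- vapply(specs[chronic], `[[`, numeric(1), "prevalence")
    stop_if_not(sum(pr) <= 1, "chronic prevalences must sum to <= 1")
    draw <- sample.int(length(pr) + 1L, n, replace = TRUE,
                       prob = c(pr, 1 - sum(pr)))
    for (j in seq_along(pr)) {
      flags[, which(chronic)[j]] <- as.integer(draw == j)
    }
  }
  for (j in which(!chronic)) {
    flags[, j] <- rbinom(n, 1, specs[[j]]$prevalence)
  }

  # family units with labelled relationships; members share a latent shift
  family_unit <- rep(NA_character_, n)
  relationship <- rep(NA_character_, n)
  rel_types <- c("twin", "sibling", "partner", "parent-child",
                 "grandparent-grandchild")
  n_fam_samples <- round(spec$family_fraction * n)
  fam_pool <- sample.int(n, min(n, n_fam_samples))
  fid <- 0L
  while (length(fam_pool) >= 2) {
    size <- min(length(fam_pool), sample(c(2L, 2L, 2L, 3L), 1))
    fid <- fid + 1L
    members <- fam_pool[seq_len(size)]
    fam_pool <- fam_pool[-seq_len(size)]
    family_unit[members] <- sprintf("F%03d", fid)
    relationship[members] <- sample(rel_types, 1)
  }
  school <- rep(NA_character_, n)
  teens <- which(age < 20)
  if (length(teens) >= 2) {
    n_schools <- max(1L, round(length(teens) / 30))
    school[teens] <- sprintf("SCH%02d", sample.int(n_schools, length(teens),
                                                   replace = TRUE))
  }

  # latent log-composition
  baseline <- rnorm(p, 0, spec$baseline_log_sd)
  eta <- matrix(baseline, n, p, byrow = TRUE,
                dimnames = list(samples, taxa))
  eta <- eta + outer(age - 45, spec$age_slopes)
  cond_truth <- list()
  for (j in seq_along(specs)) {
    cs <- specs[[j]]
    if (cs$effect_size_clr != 0 && cs$n_effect_taxa > 0) {
      k <- min(p, cs$n_effect_taxa)
      idx <- sample.int(p, k)
      signs <- sample(c(-1, 1), k, replace = TRUE)
      u <- numeric(p); u[idx] <- signs * cs$effect_size_clr
      eta <- eta + flags[, j] %*% t(u)
      cond_truth[[cs$name]] <- list(taxa = taxa[idx], signs = signs,
                                    effect_size_clr = cs$effect_size_clr)
    }
    if (cs$network_strength > 0 && cs$n_network_taxa >= 2) {
      # condition-exclusive dependencies: shared latent factor per taxon
      # pair, active only in flagged samples
      k <- min(p - p %% 2, cs$n_network_taxa)
      # couple taxa abundant enough to survive rare-taxon filtering, or the
      # planted edges would be unobservable downstream
      pool <- order(baseline, decreasing = TRUE)[seq_len(ceiling(0.6 * p))]
      net_idx <- sample(pool, k)
      pairs <- matrix(net_idx, ncol = 2, byrow = TRUE)
      for (q in seq_len(nrow(pairs))) {
        f <- rnorm(n, 0, cs$network_strength) * flags[, j]
        eta[, pairs[q, 1]] <- eta[, pairs[q, 1]] + f
        eta[, pairs[q, 2]] <- eta[, pairs[q, 2]] + f
      }
      key <- cs$name
      entry <- cond_truth[[key]] %||% list()
      entry$network_pairs <- data.frame(taxon_a = taxa[pairs[, 1]],
                                        taxon_b = taxa[pairs[, 2]],
                                        stringsAsFactors = FALSE)
      entry$network_strength <- cs$network_strength
      cond_truth[[key]] <- entry
    }
  }
  if (spec$family_effect_sd > 0) {
    for (f in unique(na.omit(family_unit))) {
      z <- rnorm(p, 0, spec$family_effect_sd)
      m <- which(family_unit == f)
      eta[m, ] <- eta[m, ] + matrix(z, length(m), p, byrow = TRUE)
    }
  }
  if (spec$classroom_effect_sd > 0) {
    for (s in unique(na.omit(school))) {
      z <- rnorm(p, 0, spec$classroom_effect_sd)
      m <- which(school == s)
      eta[m, ] <- eta[m, ] + matrix(z, length(m), p, byrow = TRUE)
    }
  }
  noise_sd <- dispersion_at(spec$dispersion_curve, age)
  for (j in seq_along(specs)) {
    noise_sd <- noise_sd * specs[[j]]$dispersion_ratio^flags[, j]
  }
  eta <- eta + matrix(rnorm(n * p), n, p) * noise_sd

  counts <- matrix(0L, p, n, dimnames = list(taxa, samples))
  for (i in seq_len(n)) {
    pr <- exp(eta[i, ] - max(eta[i, ]))
    counts[, i] <- rmultinom(1, spec$reads_per_sample, pr)
  }

  # taxonomy: 3 ASVs per genus, genera grouped into 6 phyla
  g_idx <- (seq_len(p) - 1) %/% 3 + 1
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria", "Actinobacteria",
             "Fusobacteria", "Synergistetes")
  ph_idx <- (g_idx - 1) %% length(phyla) + 1
  taxonomy <- data.frame(taxon = taxa,
                         genus = sprintf("Genus_%03d", g_idx),
                         phylum = phyla[ph_idx])

  ph <- 8.2 - 0.012 * age + rnorm(n, 0, 0.5)
  ph <- pmin(10, pmax(5, ph))
  if (spec$ph_quantize) ph <- round(ph * 2) / 2
  bmi <- 16 + 0.12 * age + rnorm(n, 0, 2.5)

  metadata <- data.frame(
    sample_id = samples, age = age, gender = gender, region = region,
    town_population = town_population, stringsAsFactors = FALSE)
  for (j in seq_along(specs)) {
    metadata[[cnames[j]]] <- factor(ifelse(flags[, j] == 1, "yes", "no"),
                                    levels = c("no", "yes"))
  }
  metadata$chronic_disorder_any <- rowSums(flags[, chronic, drop = FALSE]) > 0
  metadata$family_unit <- family_unit
  metadata$relationship <- relationship
  metadata$school <- school
  metadata$pH <- ph
  metadata$BMI <- bmi
  attr(metadata, "flags") <- cnames

  trending <- which(spec$age_slopes != 0)
  truth <- list(
    trending_taxa = data.frame(
      taxon = taxa[trending],
      genus = taxonomy$genus[trending],
      slope = spec$age_slopes[trending],
      direction = ifelse(spec$age_slopes[trending] > 0, "increase", "decrease"),
      stringsAsFactors = FALSE),
    condition_effects = cond_truth,
    dispersion_curve = spec$dispersion_curve,
    family_effect_sd = spec$family_effect_sd,
    classroom_effect_sd = spec$classroom_effect_sd)

  tree <- generate_tree(p, seed = derive_seed(spec$seed, 104729L))

  structure(list(counts = count_table(counts, taxonomy), metadata = metadata,
                 tree = tree, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d taxa, depth %d, %d planted age trends\n",
              x$spec$n_samples, x$spec$n_taxa, x$spec$reads_per_sample,
              nrow(x$truth$trending_taxa)))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `counts.tsv`, `metadata.tsv`, `tree.nwk` and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_newick(cohort$tree, file.path(dir, "tree.nwk"))
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
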