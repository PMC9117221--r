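# metadata builder with full control over group structure
make_meta <- function(n_yes, n_no, n_chronic_in_yes = 0, seed = 1,
                      regions = c("R1", "R2"), variable = "smoking") {
  set.seed(seed)
  n <- n_yes + n_no
  md <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, 13, 80),
    gender = factor(sample(c("female", "male"), n, TRUE)),
    region = factor(sample(regions, n, TRUE)),
    town_population = rep(1e4, n),
    stringsAsFactors = FALSE)
  md[[variable]] <- factor(rep(c("yes", "no"), c(n_yes, n_no)),
                           levels = c("no", "yes"))
  md$chronic_disorder_any <- FALSE
  if (n_chronic_in_yes > 0) md$chronic_disorder_any[seq_len(n_chronic_in_yes)] <- TRUE
  md
}

test_that("eligibility honors chronic-disorder and missing-data exclusions", {
  md <- make_meta(40, 100)
  md$cystic_fibrosis <- factor(rep("no", 140), levels = c("no", "yes"))
  # sample 50 (a control) has CF -> excluded from the control pool
  md$cystic_fibrosis[50] <- "yes"
  md$chronic_disorder_any[50] <- TRUE
  # sample 41 (a control) is missing age -> excluded
  md$age[41] <- NA
  pool <- eligible_controls(md, "smoking")
  expect_false("S0050" %in% pool)
  expect_false("S0041" %in% pool)
  # a smoker with CF is excluded from the yes-group too
  md$cystic_fibrosis[3] <- "yes"
  md$chronic_disorder_any[3] <- TRUE
  ens <- subsample_binary(md, "smoking", n_reps = 3, seed = 1)
  drawn_yes <- unique(unlist(lapply(ens$sets, function(s)
    s$sample_id[s$group == "yes"])))
  expect_false("S0003" %in% drawn_yes)
  # but when the variable IS the disorder, its carriers form the yes-group
  ens_cf <- subsample_binary(md, "cystic_fibrosis", n_reps = 3, seed = 1,
                             min_group = 2)
  yes_cf <- unique(unlist(lapply(ens_cf$sets, function(s)
    s$sample_id[s$group == "yes"])))
  expect_true(all(c("S0003", "S0050") %in% yes_cf))
  # and controls still exclude every chronically ill sample
  no_cf <- unlist(lapply(ens_cf$sets, function(s) s$sample_id[s$group == "no"]))
  expect_false(any(no_cf %in% md$sample_id[md$chronic_disorder_any]))
})

test_that("regions absent from the yes-group never supply controls", {
  md <- make_meta(30, 200, regions = "R1")
  md$region <- factor(c(rep("R1", 30), rep(c("R1", "R9"), 100)),
                      levels = c("R1", "R9"))
  pool <- eligible_controls(md, "smoking")
  expect_true(all(md$region[match(pool, md$sample_id)] == "R1"))
})

test_that("group sizes follow the smaller-group and cap rules", {
  # 40 yes / 500 eligible controls -> every set 40 + 40
  ens <- subsample_binary(make_meta(40, 500), "smoking", n_reps = 10, seed = 3)
  expect_true(all(vapply(ens$sets, function(s)
    all(table(s$group) == c(no = 40, yes = 40)), logical(1))))
  # 150 yes / 600 controls -> capped at 100 + 100
  ens2 <- subsample_binary(make_meta(150, 600), "smoking", n_reps = 10, seed = 3)
  expect_true(all(vapply(ens2$sets, function(s)
    all(table(s$group) == c(no = 100, yes = 100)), logical(1))))
  # below the minimum -> refuse
  expect_error(subsample_binary(make_meta(5, 500), "smoking", seed = 1),
               "refusing")
})

test_that("ensembles are deterministic given the seed and well-formed", {
  md <- make_meta(60, 400, seed = 4)
  a <- subsample_binary(md, "smoking", n_reps = 8, seed = 99)
  b <- subsample_binary(md, "smoking", n_reps = 8, seed = 99)
  expect_identical(lapply(a$sets, `[[`, "sample_id"),
                   lapply(b$sets, `[[`, "sample_id"))
  c2 <- subsample_binary(md, "smoking", n_reps = 8, seed = 100)
  expect_false(identical(lapply(a$sets, `[[`, "sample_id"),
                         lapply(c2$sets, `[[`, "sample_id")))
  for (s in a$sets) {
    expect_false(anyDuplicated(s$sample_id) > 0)
    expect_length(intersect(s$sample_id[s$group == "yes"],
                            s$sample_id[s$group == "no"]), 0)
  }
  # matching reports exist and contain the balance checks
  expect_true(all(vapply(a$matching, function(m)
    is.numeric(m$age_ks_p) && is.numeric(m$region_chisq_p), logical(1))))
})

test_that("matched controls track the yes-group's age distribution", {
  md <- make_meta(80, 800, seed = 5)
  # make the yes-group strongly age-skewed
  md$age[seq_len(80)] <- runif(80, 13, 25)
  ens <- subsample_binary(md, "smoking", n_reps = 20, seed = 12)
  mean_ages <- vapply(ens$sets, function(s) {
    a <- md$age[match(s$sample_id, md$sample_id)]
    c(mean(a[s$group == "yes"]), mean(a[s$group == "no"]))
  }, numeric(2))
  expect_lt(max(abs(mean_ages[1, ] - mean_ages[2, ])), 4)
})

test_that("control coverage is broad when the pool is large", {
  md <- make_meta(20, 400, seed = 6)
  ens <- subsample_binary(md, "smoking", n_reps = 100, seed = 8)
  drawn <- unlist(lapply(ens$sets, function(s) s$sample_id[s$group == "no"]))
  pool <- eligible_controls(md, "smoking")
  # matched draws live in the strata the yes-group occupies: assess
  # coverage within those strata
  stratum <- function(ids) paste(md$gender[match(ids, md$sample_id)],
                                 md$region[match(ids, md$sample_id)],
                                 assign_age_bin(md$age[match(ids, md$sample_id)]))
  yes_strata <- unique(stratum(md$sample_id[md$smoking == "yes"]))
  pool_in <- pool[stratum(pool) %in% yes_strata]
  expect_gt(length(unique(drawn)) / length(pool_in), 0.9)
})

test_that("age-bin ensembles have constant sizes and balanced composition", {
  co <- quick_cohort(n = 400, p = 10, depth = 300, seed = 31)
  ens <- subsample_age_bins(co$metadata, n_reps = 20, seed = 5)
  sizes <- vapply(ens$sets, function(s) as.integer(table(s$group)), integer(6))
  expect_true(all(sizes == sizes[, 1]))
  expect_true(all(sizes[, 1] >= 1))
  for (s in ens$sets) expect_false(anyDuplicated(s$sample_id) > 0)
  # no chronically ill sample is ever drawn
  drawn <- unique(unlist(lapply(ens$sets, `[[`, "sample_id")))
  expect_false(any(co$metadata$chronic_disorder_any[
    match(drawn, co$metadata$sample_id)]))
  # determinism
  ens2 <- subsample_age_bins(co$metadata, n_reps = 20, seed = 5)
  expect_identical(lapply(ens$sets, `[[`, "sample_id"),
                   lapply(ens2$sets, `[[`, "sample_id"))
})

test_that("the balancer neutralizes a planted region imbalance", {
  # region composition differs sharply across bins in the raw metadata
  set.seed(9)
  n <- 900
  age <- runif(n, 13, 80)
  region <- ifelse(runif(n) < ifelse(age < 40, 0.12, 0.5), "South", "North")
  md <- data.frame(sample_id = sprintf("S%04d", 1:n), age = age,
                   gender = factor(sample(c("female", "male"), n, TRUE)),
                   region = factor(region), town_population = 1e4,
                   chronic_disorder_any = FALSE, stringsAsFactors = FALSE)
  raw_p <- chisq.test(table(assign_age_bin(md$age), md$region))$p.value
  expect_lt(raw_p, 1e-6)          # imbalance really is planted
  ens <- subsample_age_bins(md, n_reps = 40, seed = 2)
  ps <- vapply(ens$sets, function(s) {
    r <- md$region[match(s$sample_id, md$sample_id)]
    tab <- table(as.character(s$group), as.character(r))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    suppressWarnings(chisq.test(tab))$p.value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("single-region cohorts are limited only by bin occupancy", {
  set.seed(10)
  n <- 240
  md <- data.frame(sample_id = sprintf("S%04d", 1:n),
                   age = runif(n, 13, 80),
                   gender = factor(rep(c("female", "male"), n / 2)),
                   region = factor(rep("R1", n)), town_population = 1e4,
                   chronic_disorder_any = FALSE, stringsAsFactors = FALSE)
  ens <- subsample_age_bins(md, n_reps = 2, cap = 1000, seed = 1)
  occ <- table(assign_age_bin(md$age))
  sizes <- table(ens$sets[[1]]$group)
  # with one region, only gender evenness binds: each bin can deliver at
  # least twice its scarcer gender, and never more than its occupancy
  gender_tab <- table(assign_age_bin(md$age), md$gender)
  expect_true(all(sizes >= 2 * apply(gender_tab, 1, min) - 2))
  expect_true(all(sizes <= occ))
})

test_that("ensembles export to JSON with provenance", {
  md <- make_meta(30, 200, seed = 11)
  ens <- subsample_binary(md, "smoking", n_reps = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$variable, "smoking")
  expect_equal(j$seed, 7)
  expect_length(j$sets$sample_id, 3)
})
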