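# exhaustive PERMANOVA oracle: enumerate every relabelling, recompute
# pseudo-F from scratch on Euclidean distances of 1-D data
permanova_enum_oracle <- function(x, g) {
  f_stat <- function(g) {
    sst <- sum((x - mean(x))^2)
    ssw <- sum(unlist(lapply(split(x, g), function(v) sum((v - mean(v))^2))))
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (length(x) - a))
  }
  obs <- f_stat(g)
  perms <- combinat_perms(length(x))
  fs <- apply(perms, 1, function(idx) f_stat(g[idx]))
  mean(fs >= obs - 1e-12)
}
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

test_that("PERMANOVA p equals the exhaustive-enumeration oracle", {
  x <- c(0, 0, 0, 10, 10, 10)
  g <- factor(rep(c("a", "b"), each = 3))
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:6)
  p_oracle <- permanova_enum_oracle(x, g)
  expect_equal(p_oracle, 0.1)          # 2 of the 20 distinct assignments
  res <- permanova(d, data.frame(g = g), permutations = permute::allPerms(6))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_gt(res$r2, 0.9)
})

test_that("PERMANOVA on 1-D Euclidean distances reproduces classical ANOVA F", {
  set.seed(14)
  x <- rnorm(24)
  g <- factor(rep(letters[1:3], each = 8))
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:24)
  res <- permanova(d, data.frame(g = g), n_perm = 99, seed = 1)
  f_aov <- summary(aov(x ~ g))[[1]]$`F value`[1]
  expect_equal(res$f, f_aov, tolerance = 1e-10)
})

test_that("degenerate and malformed PERMANOVA designs are handled", {
  set.seed(15)
  x <- matrix(rnorm(30), 10)
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:10)
  g_const <- factor(rep("a", 10))
  expect_warning(expect_error(permanova(d, data.frame(g = g_const)),
                              "no estimable"), "constant")
  g <- factor(rep(c("a", "b"), 5))
  expect_warning(res <- permanova(d, data.frame(g = g, h = g_const),
                                  n_perm = 99, seed = 1), "constant")
  expect_equal(res$term, "g")
  m <- as.matrix(d); m[1, 2] <- m[1, 2] + 1
  expect_error(permanova(m, data.frame(g = g)), "symmetric")
  # R2 decomposition: terms + residual sum to 1
  res2 <- permanova(d, data.frame(g = g, z = rnorm(10)), n_perm = 99, seed = 1)
  expect_equal(sum(res2$r2) + attr(res2, "residual_r2"), 1, tolerance = 1e-8)
})

test_that("one-vs-rest over a single split matches the binary test", {
  set.seed(16)
  x <- matrix(rnorm(40), 20)
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:20)
  bins <- factor(rep(c("young", "old"), each = 10))
  ovr <- permanova_one_vs_rest(d, bins, n_perm = 199, seed = 5)
  bin_res <- permanova(d, data.frame(g = (bins == "old")), n_perm = 199,
                       seed = 5)
  # both one-vs-rest rows encode the same binary contrast
  expect_equal(ovr$f[1], ovr$f[2], tolerance = 1e-10)
  expect_equal(ovr$f[1], bin_res$f, tolerance = 1e-10)
  expect_equal(ovr$r2[1], bin_res$r2, tolerance = 1e-10)
  expect_error(permanova_one_vs_rest(d, factor(rep("a", 20))), "at least 2")
  expect_error(
    permanova_one_vs_rest(d, factor(c(rep("a", 18), "b", "b"))), "at least 3")
})

test_that("homogeneity test locates the geometric median and ranks spreads", {
  # geometric median oracle by grid search on {(0,0),(2,0),(1,1)}
  pts <- rbind(c(0, 0), c(2, 0), c(1, 1))
  gr <- expand.grid(x = seq(0, 2, 0.002), y = seq(0, 1, 0.002))
  ss <- vapply(seq_len(nrow(gr)), function(i)
    sum(sqrt(rowSums((pts - matrix(as.numeric(gr[i, ]), 3, 2,
                                   byrow = TRUE))^2))), numeric(1))
  med_oracle <- as.numeric(gr[which.min(ss), ])
  d_oracle <- sqrt(rowSums((pts - matrix(med_oracle, 3, 2, byrow = TRUE))^2))
  far <- pts + 100
  m <- rbind(pts, far)
  rownames(m) <- paste0("s", 1:6)
  # bias adjustment off: the oracle checks the median location itself
  h <- homogeneity_test(dist(m), factor(rep(c("a", "b"), each = 3)),
                        bias_adjust = FALSE)
  expect_equal(unname(h$distances[1:3]), d_oracle, tolerance = 1e-3)

  # planted dispersion: group B = group A scaled x3 about its centroid
  set.seed(17)
  a <- matrix(rnorm(40 * 3), 40)
  b <- 3 * scale(matrix(rnorm(40 * 3), 40), scale = FALSE)
  m2 <- rbind(a, b)
  rownames(m2) <- paste0("s", 1:80)
  h2 <- homogeneity_test(dist(m2), factor(rep(c("A", "B"), each = 40)))
  expect_gt(h2$group_means["B"], h2$group_means["A"])
  expect_lt(h2$p, 0.01)
  expect_error(homogeneity_test(dist(m2), factor(c("A", rep("B", 79)))),
               ">= 2 samples")
})

test_that("Aitchison distances embed without negative eigenvalues", {
  co <- quick_cohort(n = 40, p = 20, depth = 2000)
  d <- aitchison_distance(co$counts)
  h <- homogeneity_test(d, assign_age_bin(co$metadata$age))
  expect_gte(min(h$eig), -1e-8 * max(h$eig))
})

test_that("anosim separates perfect pairs and respects rank invariance", {
  # two tight, well-separated pairs -> R = 1
  m <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.1))
  rownames(m) <- paste0("s", 1:4)
  units <- setNames(c("u1", "u1", "u2", "u2"), rownames(m))
  a <- anosim_units(dist(m), units, n_perm = 99, seed = 1)
  expect_equal(a$R, 1)
  expect_true(all(a$within < min(a$between)))
  # R invariant under monotone transformation of the distances
  d2 <- as.dist(as.matrix(dist(m))^2)
  a2 <- anosim_units(d2, units, n_perm = 99, seed = 1)
  expect_equal(a$R, a2$R)
  # 70 samples in 34 units (paper-shaped input) is a valid shape
  set.seed(18)
  m3 <- matrix(rnorm(70 * 4), 70)
  rownames(m3) <- paste0("s", 1:70)
  u3 <- setNames(c(rep(sprintf("g%02d", 1:34), 2), "g01", "g02"),
                 rownames(m3))
  a3 <- anosim_units(dist(m3), u3, n_perm = 99, seed = 2)
  expect_equal(a3$n_units, 34)
  expect_equal(a3$n_samples, 70)
  expect_true(abs(a3$R) < 1)
  expect_error(anosim_units(dist(m3), setNames(rep("u", 70), rownames(m3))),
               "single unit")
})

test_that("anosim R is centred at zero under random unit labels", {
  set.seed(19)
  rs <- replicate(200, {
    m <- matrix(rnorm(16 * 3), 16)
    rownames(m) <- paste0("s", 1:16)
    u <- setNames(sample(rep(c("a", "b", "c", "d"), 4)), rownames(m))
    anosim_units(dist(m), u, n_perm = 0 + 99, seed = NULL)$R
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("twins-vs-siblings matches exact rank-sum enumeration", {
  labs <- paste0("s", 1:20)
  m <- matrix(rnorm(20 * 3), 20, dimnames = list(labs, NULL))
  d <- dist(m)
  tw <- setNames(rep(NA_character_, 20), labs)
  sb <- tw
  tw[1:10] <- rep(paste0("t", 1:5), each = 2)
  sb[11:20] <- rep(paste0("b", 1:5), each = 2)
  ht <- twins_vs_siblings(d, tw, sb)
  expect_length(ht$twin_distances, 5)
  expect_length(ht$sibling_distances, 5)
  # exact enumeration oracle for the two-sided rank-sum p
  exact_p <- function(a, b) {
    obs <- sum(rank(c(a, b))[seq_along(a)])
    combos <- combn(length(a) + length(b), length(a))
    tots <- apply(combos, 2, function(idx) sum(rank(c(a, b))[idx]))
    mu <- mean(tots)
    min(1, 2 * min(mean(tots <= obs), mean(tots >= obs)))
  }
  expect_equal(ht$p.value, exact_p(ht$twin_distances, ht$sibling_distances),
               tolerance = 1e-10)
  # all twin distances below all sibling distances: smallest possible p
  d2 <- as.matrix(d)
  d2[1:10, 1:10] <- d2[1:10, 1:10] / 1000
  ht2 <- twins_vs_siblings(as.dist(d2), tw, sb)
  expect_equal(ht2$p.value, 2 / choose(10, 5), tolerance = 1e-10)
  # identical multisets -> p = 1
  ht3 <- suppressWarnings(twins_vs_siblings(d, tw, tw))  # ties: normal approx
  expect_equal(ht3$p.value, 1)
})

test_that("unit membership restricts to the requested relationship", {
  co <- quick_cohort(n = 300, p = 8, depth = 200, seed = 23)
  u_fam <- unit_membership(co$metadata, "family")
  u_sib <- unit_membership(co$metadata, "sibling")
  expect_true(all(names(u_sib[!is.na(u_sib)]) %in% names(u_fam[!is.na(u_fam)])))
  md <- co$metadata
  sib_ids <- md$sample_id[!is.na(md$relationship) & md$relationship == "sibling"]
  expect_setequal(names(u_sib)[!is.na(u_sib)], sib_ids)
  u_cls <- unit_membership(co$metadata, "classmates")
  expect_true(all(md$age[match(names(u_cls)[!is.na(u_cls)], md$sample_id)] < 20))
  tab <- table(u_cls)
  expect_true(all(tab >= 2))
})
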