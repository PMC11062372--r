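test_that("pcoa recovers planar configurations exactly", {
  pts <- matrix(c(0, 0, 4, 0, 4, 3, 1, 5, -2, 2), ncol = 2, byrow = TRUE,
                dimnames = list(paste0("S", 1:5), NULL))
  d <- dist(pts)
  ord <- pcoa(d, n_axes = 2)
  # exactly two positive eigenvalues, zero discarded negative mass
  tol <- max(abs(ord$eigenvalues)) * 1e-8
  expect_equal(sum(ord$eigenvalues > tol), 2)
  expect_equal(ord$negative_mass, 0)
  # inter-point distances reproduced to 1e-8
  expect_equal(as.matrix(dist(ord$scores)), as.matrix(d), tolerance = 1e-8)
  # scores are centred
  expect_equal(colMeans(ord$scores), c(PCo1 = 0, PCo2 = 0), tolerance = 1e-10)
})

test_that("pcoa degenerate geometries behave as the metric demands", {
  # equilateral: all off-diagonal distances equal -> two equal eigenvalues
  d3 <- matrix(1, 3, 3, dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  diag(d3) <- 0
  ord3 <- pcoa(d3, n_axes = 2)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-10]
  expect_equal(pos[1], pos[2])
  # duplicated sample -> coincident scores
  pts <- matrix(c(0, 0, 1, 0, 1, 0, 3, 2), ncol = 2, byrow = TRUE,
                dimnames = list(paste0("S", 1:4), NULL))
  ord4 <- pcoa(dist(pts), n_axes = 2)
  expect_equal(ord4$scores["S2", ], ord4$scores["S3", ], tolerance = 1e-10)
  # requesting more axes than positive eigenvalues truncates with a warning
  expect_warning(ord5 <- pcoa(dist(pts), n_axes = 4), "truncated")
  expect_lte(ncol(ord5$scores), 3)
})

test_that("pcoa agrees with vegan's metric MDS on Bray-Curtis data", {
  set.seed(41)
  m <- matrix(rpois(80, 6) + 1L, nrow = 10,
              dimnames = list(paste0("A", 1:10), paste0("S", 1:8)))
  d <- bray_curtis(feature_table(m))
  ord <- pcoa(d, n_axes = 3)
  ref <- vegan::wcmdscale(d, eig = TRUE)
  pos <- ref$eig[ref$eig > max(abs(ref$eig)) * 1e-8]
  expect_equal(sort(ord$eigenvalues, decreasing = TRUE)[seq_along(pos)],
               sort(pos, decreasing = TRUE), tolerance = 1e-10)
  expect_equal(abs(ord$scores), abs(ref$points[, 1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("envfit agrees with full permutation enumeration at n = 6", {
  set.seed(42)
  pts <- matrix(rnorm(12), ncol = 2, dimnames = list(paste0("S", 1:6), NULL))
  ord <- pcoa(dist(pts), n_axes = 2)
  v <- rnorm(6)
  perms <- all_permutations(6)  # 720 rows
  res <- fit_env_vectors(ord, tibble::tibble(sample_id = ord$sample_ids,
                                             var = v),
                         permutations = perms)
  # independent oracle: lm() r.squared and explicit enumeration
  s <- as.data.frame(ord$scores)
  r2_oracle <- summary(stats::lm(v ~ PCo1 + PCo2, data = s))$r.squared
  perm_r2 <- apply(perms, 1, function(p) {
    summary(stats::lm(v[p] ~ PCo1 + PCo2, data = s))$r.squared
  })
  p_oracle <- (1 + sum(perm_r2 >= r2_oracle)) / (1 + nrow(perms))
  expect_equal(res$r2, r2_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle)
})

test_that("a variable equal to axis-1 scores gives r2 = 1 and minimal p", {
  set.seed(43)
  pts <- matrix(rnorm(40), ncol = 2, dimnames = list(paste0("S", 1:20), NULL))
  ord <- pcoa(dist(pts), n_axes = 2)
  dat <- tibble::tibble(sample_id = ord$sample_ids,
                        ax1 = ord$scores[, 1],
                        orth = stats::residuals(stats::lm(
                          rnorm(20) ~ ord$scores[, 1] + ord$scores[, 2])))
  res <- fit_env_vectors(ord, dat, permutations = 999, seed = 7)
  expect_equal(res$r2[res$variable == "ax1"], 1, tolerance = 1e-10)
  expect_equal(res$p_value[res$variable == "ax1"], 1 / (999 + 1))
  expect_equal(res$axis_1[res$variable == "ax1"], 1, tolerance = 1e-8)
  expect_lt(res$r2[res$variable == "orth"], 1e-10)
})

test_that("envfit r2 is invariant to affine rescaling and axis rotation", {
  set.seed(44)
  pts <- matrix(rnorm(30), ncol = 2, dimnames = list(paste0("S", 1:15), NULL))
  ord <- pcoa(dist(pts), n_axes = 2)
  v <- rnorm(15)
  r_a <- fit_env_vectors(ord, tibble::tibble(sample_id = ord$sample_ids, v = v),
                         permutations = 99, seed = 1)
  r_b <- fit_env_vectors(ord, tibble::tibble(sample_id = ord$sample_ids,
                                             v = 3.7 * v - 11),
                         permutations = 99, seed = 1)
  expect_equal(r_a$r2, r_b$r2, tolerance = 1e-12)
  expect_equal(r_a$p_value, r_b$p_value)
  # rotate the ordination plane by 31 degrees
  th <- 31 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ord_rot <- ord
  ord_rot$scores <- ord$scores %*% rot
  colnames(ord_rot$scores) <- c("PCo1", "PCo2")
  r_c <- fit_env_vectors(ord_rot, tibble::tibble(sample_id = ord$sample_ids,
                                                 v = v),
                         permutations = 99, seed = 1)
  expect_equal(r_a$r2, r_c$r2, tolerance = 1e-10)
})

test_that("null permutation p-values are super-uniform and r2 follows the Beta null", {
  set.seed(45)
  pts <- matrix(rnorm(36), ncol = 2, dimnames = list(paste0("S", 1:18), NULL))
  ord <- pcoa(dist(pts), n_axes = 2)
  n <- 18
  r2s <- numeric(400); ps <- numeric(400)
  for (i in 1:400) {
    res <- fit_env_vectors(ord, tibble::tibble(sample_id = ord$sample_ids,
                                               v = rnorm(n)),
                           permutations = 49, seed = i)
    r2s[i] <- res$r2; ps[i] <- res$p_value
  }
  # super-uniform: P(p <= a) <= a (+ Monte-Carlo slack)
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 400))
  }
  # closed-form null of R^2 with k = 2 regressors: Beta(k/2, (n-k-1)/2)
  ks <- suppressWarnings(
    stats::ks.test(r2s, stats::pbeta, 1, (n - 3) / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("envfit flags constant variables and excludes missing values", {
  set.seed(46)
  pts <- matrix(rnorm(20), ncol = 2, dimnames = list(paste0("S", 1:10), NULL))
  ord <- pcoa(dist(pts), n_axes = 2)
  dat <- tibble::tibble(sample_id = ord$sample_ids,
                        const = rep(2, 10),
                        holey = c(rnorm(8), NA, NA))
  res <- fit_env_vectors(ord, dat, permutations = 49, seed = 2)
  cst <- res[res$variable == "const", ]
  expect_true(cst$flagged)
  expect_equal(cst$r2, 0)
  expect_equal(cst$p_value, 1)
  expect_equal(res$n_used[res$variable == "holey"], 8)
})
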