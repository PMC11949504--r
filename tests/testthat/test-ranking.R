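test_that("PCA recovers perfect collinearity on the diagonal", {
  set.seed(1)
  x <- rnorm(30)
  npx <- tibble::tibble(patient_id = sprintf("P%02d", 1:30), a = x, b = x)
  fit <- pca_loadings(npx)
  expect_equal(abs(unname(fit$loadings[, 1])), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(fit$explained_variance_ratio[1], 1, tolerance = 1e-10)
})

test_that("the PCA spectrum is invariant to orthogonal rotation of the data", {
  set.seed(2)
  m <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(sprintf("P%02d", 1:25), letters[1:4]))
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  f1 <- pca_loadings(m, scale = FALSE)
  f2 <- pca_loadings(m %*% q, scale = FALSE)
  expect_equal(f1$explained_variance, f2$explained_variance, tolerance = 1e-10)
})

test_that("loadings match a brute-force eigendecomposition of the covariance", {
  set.seed(3)
  m <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(sprintf("P%02d", 1:10), letters[1:6]))
  fit <- pca_loadings(m, scale = FALSE)
  eig <- eigen(cov(m))
  for (j in 1:5) {
    v <- eig$vectors[, j]
    w <- fit$loadings[, j]
    if (sum(v * w) < 0) v <- -v
    expect_equal(unname(w), unname(v), tolerance = 1e-8)
    expect_equal(fit$explained_variance[j], eig$values[j], tolerance = 1e-8)
  }
})

test_that("select_pc finds the component carrying the class separation", {
  set.seed(4)
  n <- 60
  g <- rep(c("a", "b"), each = n / 2)
  # class signal planted on a low-variance direction: PC1 is pure noise
  noise <- rnorm(n, sd = 5)
  signal <- ifelse(g == "a", -1, 1) + rnorm(n, sd = 0.3)
  npx <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                        big = noise, small = signal)
  fit <- pca_loadings(npx, scale = FALSE)
  expect_identical(select_pc(fit, g), 2L)
  expect_error(select_pc(fit, rep("a", n)), "two classes")
  expect_warning(pc <- select_pc(fit, NULL), "PC1")
  expect_identical(pc, 1L)
})

test_that("select_pc is deterministic under label shuffles (lowest-index argmax)", {
  set.seed(5)
  m <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(sprintf("P%02d", 1:40), letters[1:6]))
  fit <- pca_loadings(m)
  g <- sample(rep(c("x", "y"), 20))
  expect_identical(select_pc(fit, g), select_pc(fit, g))
  # a constant scores matrix makes every F equal: argmax must be PC1
  flat <- fit
  flat$scores <- matrix(rep(seq_len(40), 3), 40, 3)
  expect_identical(select_pc(flat, g), 1L)
})

test_that("a constant protein gets zero loading and lands at the bottom", {
  co <- fixture_strong()
  npx <- co$npx
  npx$FLATLINE <- 5
  sev <- co$clinical$severity[match(npx_patients(npx), co$clinical$patient_id)]
  rk <- bootstrap_rank(npx, sev, n_bootstraps = 20, seed = 1)
  flat_row <- rk[rk$protein_id == "FLATLINE", ]
  expect_equal(flat_row$median_abs_loading, 0)
  expect_equal(flat_row$rank, nrow(rk))
})

test_that("with resampling disabled the ranking equals plain PCA |loadings|", {
  co <- fixture_strong()
  sev <- co$clinical$severity[match(npx_patients(co$npx), co$clinical$patient_id)]
  rk <- bootstrap_rank(co$npx, sev, n_bootstraps = 1, resample = FALSE, seed = 1)
  fit <- pca_loadings(co$npx)
  pc <- select_pc(fit, sev)
  ref <- sort(abs(fit$loadings[, pc]), decreasing = TRUE)
  expect_equal(rk$median_abs_loading, unname(ref), tolerance = 1e-12)
  expect_equal(attr(rk, "selected_pc"), pc)
})

test_that("bootstrap ranking is deterministic given the seed and recovers planted proteins", {
  co <- fixture_strong()
  rk1 <- fixture_strong_ranked()
  sev <- co$clinical$severity[match(npx_patients(co$npx), co$clinical$patient_id)]
  rk2 <- bootstrap_rank(co$npx, sev, senescence = co$labels, n_bootstraps = 100, seed = 7)
  expect_identical(as.data.frame(rk1), as.data.frame(rk2))
  expect_gte(sum(head(rk1$protein_id, 15) %in% co$truth$informative), 9)
})

test_that("planted signal proteins rank above pure noise as bootstraps grow", {
  co <- fixture_strong()
  sev <- co$clinical$severity[match(npx_patients(co$npx), co$clinical$patient_id)]
  for (nb in c(100, 300)) {
    rk <- bootstrap_rank(co$npx, sev, n_bootstraps = nb, seed = 31)
    med_inf <- min(rk$median_abs_loading[rk$protein_id %in% co$truth$informative])
    med_noise <- median(rk$median_abs_loading[!rk$protein_id %in% co$truth$informative])
    expect_gt(med_inf, med_noise)
  }
})

test_that("top-k senescent fraction does set arithmetic and warns without labels", {
  rk <- fixture_strong_ranked()
  k <- 20
  expected <- mean(head(rk$protein_id, k) %in% fixture_strong()$labels)
  expect_equal(top_k_senescent_fraction(rk, k), expected)
  expect_equal(top_k_senescent_fraction(rk, nrow(rk)), mean(rk$senescent))
  expect_error(top_k_senescent_fraction(rk, nrow(rk) + 1), "exceeds")

  co <- fixture_strong()
  sev <- co$clinical$severity[match(npx_patients(co$npx), co$clinical$patient_id)]
  rk0 <- bootstrap_rank(co$npx, sev, senescence = NULL, n_bootstraps = 5, seed = 2)
  expect_warning(f <- top_k_senescent_fraction(rk0, 10), "No senescence labels")
  expect_equal(f, 0)
})
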