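# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default study-scale fixture: 79 patients x 535 proteins, 16 planted panel
# proteins.
fixture_cohort <- function() cached("cohort_default", generate_cohort(cohort_spec()))

fixture_imputed <- function() cached("imputed_default", {
  impute_missing(qc_filter_proteins(fixture_cohort()$npx))
})

fixture_severity <- function() {
  co <- fixture_cohort()
  co$clinical$severity[match(npx_patients(fixture_imputed()), co$clinical$patient_id)]
}

# Small strong-effect cohort for fast recovery checks.
fixture_strong <- function() cached("cohort_strong", {
  generate_cohort(cohort_spec(n_patients = 80, n_proteins = 60, n_informative = 10,
                              effect_size = 3, noise_sd = 1, missing_rate = 0,
                              seed = 424242))
})

fixture_strong_ranked <- function() cached("ranked_strong", {
  co <- fixture_strong()
  sev <- co$clinical$severity[match(npx_patients(co$npx), co$clinical$patient_id)]
  bootstrap_rank(co$npx, sev, senescence = co$labels, n_bootstraps = 100, seed = 7)
})

# Truth-label cohort assignment in de_table() form.
truth_assignment <- function(cohort) {
  tr <- cohort$truth$endotype
  tibble::tibble(patient_id = tr$patient_id,
                 cohort = ifelse(tr$endotype == "severe-like", "severe", "mild"))
}

# Adjusted Rand index between two labellings (independent of any clustering
# package): ARI = (sum_ij C(n_ij,2) - E) / (max - E).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(0)
  (sum_ij - expected) / (maximum - expected)
}

# Brute-force silhouette: straight from the definition, quadratic loops.
brute_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  euc <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(sapply(setdiff(own, i), euc, i = i))
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(sapply(which(labels == l), euc, i = i))
    }))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force Calinski-Harabasz via explicit group loops.
brute_ch <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(labels))
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (l in unique(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - gm)^2)
    for (r in seq_len(nrow(xi))) ssw <- ssw + sum((xi[r, ] - ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Exhaustive hypergeometric upper tail P[overlap >= k] by enumerating every
# n-subset of a size-N universe containing K successes (N <= 12).
brute_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # successes are items 1..K
  mean(hits >= k)
}

# Two-sided Welch p-value with the t CDF obtained by numerical integration,
# not pt().
quadrature_welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  upper <- stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
  2 * upper
}
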