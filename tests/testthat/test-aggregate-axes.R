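# The aggregate hydrophobicity axis (PCA) and property correlations.

fake_matrix <- function(values, scales) {
  # build a property_matrix directly from crafted columns
  prof <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("r%d", seq_len(nrow(values))), label = "unknown"),
    tibble::as_tibble(setNames(as.data.frame(values), scales))
  )
  build_property_matrix(prof, "zscored")
}

fake_registry <- function(scales) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vals <- as.data.frame(matrix(seq_len(20 * length(scales)), nrow = length(scales),
                               dimnames = list(NULL, aas)))
  tibble::as_tibble(cbind(
    data.frame(scale = scales, category = "hydrophobicity"), vals
  ))
}

test_that("perfectly correlated columns load entirely on PC1", {
  withr::with_seed(2, {
    x <- rnorm(12)
    m <- fake_matrix(cbind(x, x, x), c("s1", "s2", "s3"))
    pca <- hydrophobicity_pca(m, fake_registry(c("s1", "s2", "s3")),
                              reference = "s1")
    expect_equal(pca$variance_fraction[1], 1.0, tolerance = 1e-9)
    expect_equal(sum(pca$variance_fraction), 1.0, tolerance = 1e-9)
  })
})

test_that("two orthogonal equal-variance columns split the variance evenly", {
  m <- fake_matrix(cbind(c(1, -1, 1, -1), c(1, 1, -1, -1)), c("s1", "s2"))
  pca <- hydrophobicity_pca(m, fake_registry(c("s1", "s2")), reference = "s1")
  expect_equal(pca$variance_fraction[1], 0.5, tolerance = 1e-9)
})

test_that("loadings are orthonormal and reconstruction is exact", {
  cohort <- generate_cohort(c(background = 40), seed = 4)
  mat <- build_property_matrix(profile_proteins(cohort), "zscored")
  pca <- hydrophobicity_pca(mat)
  gram <- t(pca$loadings) %*% pca$loadings
  expect_equal(gram, diag(ncol(pca$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  # project on all components and back
  z <- as.matrix(mat[, pca$columns])
  scores <- z %*% pca$loadings
  expect_equal(scores %*% t(pca$loadings), z, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PC1 variance fraction is invariant under row and column permutation", {
  withr::with_seed(9, {
    cohort <- generate_cohort(c(background = 25), seed = 9)
    prof <- profile_proteins(cohort)
    pca <- hydrophobicity_pca(build_property_matrix(prof, "zscored"))
    perm_rows <- prof[sample(nrow(prof)), ]
    pca_r <- hydrophobicity_pca(build_property_matrix(perm_rows, "zscored"))
    expect_equal(pca_r$variance_fraction, pca$variance_fraction, tolerance = 1e-9)
    perm_cols <- prof[, c("id", "label", sample(setdiff(names(prof), c("id", "label"))))]
    pca_c <- hydrophobicity_pca(build_property_matrix(perm_cols, "zscored"))
    expect_equal(pca_c$variance_fraction[1], pca$variance_fraction[1],
                 tolerance = 1e-9)
  })
})

test_that("aggregate projection reproduces training scores with mean zero", {
  cohort <- generate_cohort(c(background = 30), seed = 6)
  prof <- profile_proteins(cohort)
  mat <- build_property_matrix(prof, "zscored")
  pca <- hydrophobicity_pca(mat)
  agg <- aggregate_hydrophobicity(prof, pca)
  expect_equal(agg$aggregate_hydrophobicity, pca$scores$aggregate_hydrophobicity,
               tolerance = 1e-9)
  expect_equal(mean(agg$aggregate_hydrophobicity), 0, tolerance = 1e-9)
})

test_that("sign convention puts hydrophobic homopolymers above acidic ones", {
  cohort <- generate_cohort(c(background = 30), seed = 6)
  prof <- profile_proteins(cohort)
  pca <- hydrophobicity_pca(build_property_matrix(prof, "zscored"))
  test <- profile_proteins(tibble::tibble(
    id = c("polyI", "polyD"),
    sequence = c(strrep("I", 50), strrep("D", 50))
  ))
  agg <- aggregate_hydrophobicity(test, pca)
  expect_gt(agg$aggregate_hydrophobicity[1], agg$aggregate_hydrophobicity[2])
})

test_that("PCA demands a z-scored matrix and all hydrophobicity columns", {
  cohort <- generate_cohort(c(background = 10), seed = 1)
  prof <- profile_proteins(cohort)
  raw <- build_property_matrix(prof, "raw")
  expect_error(hydrophobicity_pca(raw), "zscored")
  mat <- build_property_matrix(prof, "zscored")
  pca <- hydrophobicity_pca(mat)
  expect_error(aggregate_hydrophobicity(prof[, c("id", "net_charge")], pca),
               "lack")
})

test_that("signed squared correlation follows sign(r) * r^2", {
  x <- as.numeric(1:10)
  expect_equal(signed_squared_correlation(x, -x), -1.0)
  expect_equal(signed_squared_correlation(x, x), 1.0)
  withr::with_seed(123, {
    a <- rnorm(1000)
    b <- rnorm(1000)
    expect_lt(abs(signed_squared_correlation(a, b)), 0.05)
  })
  expect_error(signed_squared_correlation(x, rep(1, 10)), "variance")
  expect_error(signed_squared_correlation(1:2, 1:2), "at least 3")
})
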