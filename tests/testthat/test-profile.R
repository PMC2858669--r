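# Scale means, protein/complex property vectors and the property matrix.

test_that("scale_mean is the lookup-and-mean of per-residue values", {
  kd <- scale_values(default_scales(), "KYTJ820101")
  expect_equal(scale_mean("AAAA", kd), kd[["A"]])
  expect_equal(scale_mean("AIL", kd), (1.8 + 4.5 + 3.8) / 3, tolerance = 1e-9)
})

test_that("per-residue properties are invariant under sequence shuffling", {
  withr::with_seed(8, {
    reg <- default_scales()
    s <- random_sequence(120)
    shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    p1 <- profile_proteins(tibble::tibble(id = "x", sequence = s), reg)
    p2 <- profile_proteins(tibble::tibble(id = "x", sequence = shuffled), reg)
    expect_equal(p1, p2)
  })
})

test_that("protein profiles hold every scale plus net charge and pI", {
  reg <- default_scales()
  prof <- profile_proteins(tibble::tibble(id = "gg", sequence = "GG"), reg)
  expect_setequal(
    setdiff(names(prof), c("id", "label")),
    c(reg$scale, "net_charge", "pI")
  )
  expect_equal(ncol(prof) - 2, nrow(reg) + 2)
  expect_equal(prof$net_charge, -0.0380, tolerance = 1e-3)
  ext <- attr(prof, "extensive")
  expect_true(ext[["net_charge"]])
  expect_false(any(ext[setdiff(names(ext), "net_charge")]))
})

test_that("complex profiles are copy-weighted: charge sums, means concatenate", {
  withr::with_seed(13, {
    prots <- tibble::tibble(
      id = c("a", "b"),
      sequence = c(random_sequence(60), random_sequence(60))
    )
    reg <- default_scales()
    single <- profile_proteins(prots, reg)

    m_ab <- complex_manifest(c("c", "c"), c("a", "b"), proteins = prots)
    cplx <- profile_complexes(m_ab, prots, reg)
    expect_equal(cplx$net_charge, sum(single$net_charge), tolerance = 1e-12)
    # equal-length members: scale means are the simple average
    expect_equal(
      cplx$KYTJ820101,
      mean(single$KYTJ820101),
      tolerance = 1e-12
    )

    # copy count doubles the charge
    m_a2 <- complex_manifest("c2", "a", copies = 2L, proteins = prots)
    cplx2 <- profile_complexes(m_a2, prots, reg)
    expect_equal(cplx2$net_charge, 2 * single$net_charge[1], tolerance = 1e-12)

    # single-member complex reproduces the protein profile
    m_a1 <- complex_manifest("c1", "a", proteins = prots)
    cplx1 <- profile_complexes(m_a1, prots, reg)
    props <- setdiff(names(single), c("id", "label"))
    expect_equal(
      as.numeric(cplx1[1, props]),
      as.numeric(single[1, props]),
      tolerance = 1e-9
    )
  })
})

test_that("property matrix normalization states behave as defined", {
  withr::with_seed(21, {
    prots <- tibble::tibble(
      id = sprintf("p%d", 1:6),
      sequence = vapply(rep(80, 6), random_sequence, character(1))
    )
    prof <- profile_proteins(prots)

    raw <- build_property_matrix(prof, "raw")
    expect_equal(raw$net_charge, prof$net_charge)

    centered <- build_property_matrix(prof, "centered")
    vals <- as.matrix(centered[, setdiff(names(centered), c("id", "label"))])
    expect_true(all(abs(colMeans(vals)) < 1e-9))

    z <- build_property_matrix(prof, "zscored")
    zvals <- as.matrix(z[, setdiff(names(z), c("id", "label"))])
    expect_true(all(abs(colMeans(zvals)) < 1e-9))
    expect_true(all(abs(apply(zvals, 2, sd) - 1) < 1e-9))
  })
})

test_that("raw matrix of GG and poly-K carries their two net charges", {
  prof <- profile_proteins(tibble::tibble(
    id = c("gg", "k10"), sequence = c("GG", strrep("K", 10))
  ))
  raw <- build_property_matrix(prof, "raw")
  expect_equal(raw$net_charge, c(-0.0380, 9.959), tolerance = 1e-3)
})

test_that("degenerate normalization inputs are rejected by name", {
  prof <- profile_proteins(tibble::tibble(id = "only", sequence = "ACDK"))
  expect_error(build_property_matrix(prof, "zscored"), "at least 2")
  # identical rows make every column zero-variance
  prof2 <- profile_proteins(tibble::tibble(
    id = c("a", "b"), sequence = c("ACDK", "ACDK")
  ))
  expect_error(build_property_matrix(prof2, "zscored"), "zero-variance")
})
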