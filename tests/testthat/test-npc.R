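# Screened-Coulomb NPC electrostatics.

test_that("pore volume is the cylinder formula with the stated defaults", {
  expect_equal(pore_volume(npc_model()), pi * 19^2 * 37, tolerance = 1e-12)
  expect_equal(pore_volume(npc_model()), 41964, tolerance = 1e-4)
  expect_equal(pore_volume(npc_model(radius_nm = 1, height_nm = 1 / pi)), 1,
               tolerance = 1e-12)
  expect_equal(
    pore_volume(npc_model(radius_nm = 38)),
    4 * pore_volume(npc_model(radius_nm = 19)),
    tolerance = 1e-12
  )
})

test_that("local barrier charge follows the hemisphere expectation", {
  m <- npc_model(q_npc = NULL, median_charge = 10)
  expect_equal(
    local_npc_charge(m),
    104 * 10 * ((2 / 3) * pi * 1^3) / (pi * 19^2 * 37),
    tolerance = 1e-12
  )
  expect_equal(local_npc_charge(m), 0.0519, tolerance = 1e-3)
  expect_equal(local_npc_charge(npc_model(q_npc = NULL, median_charge = 0)), 0)
  expect_equal(
    local_npc_charge(npc_model(q_npc = NULL, median_charge = 10, copies = 16)),
    2 * local_npc_charge(m),
    tolerance = 1e-12
  )
  # full charge vector: the median is used
  expect_equal(
    local_npc_charge(npc_model(q_npc = NULL, nup_charges = c(-5, 10, 30))),
    local_npc_charge(m),
    tolerance = 1e-12
  )
  expect_error(local_npc_charge(npc_model(q_npc = NULL)), "neither")
})

test_that("pair energy matches longhand constant arithmetic to 1e-9", {
  # independent evaluation with the constants written out
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23
  longhand <- function(q1, q2, lam_nm, eps, temp) {
    q1 * q2 * e * e / (4 * pi * eps0 * eps * (lam_nm * 1e-9)) / (kb * temp)
  }
  expect_equal(pair_energy(1, 1), longhand(1, 1, 1, 80, 298.15),
               tolerance = 1e-9)
  expect_equal(pair_energy(1, 1), 0.700, tolerance = 0.005 / 0.7)
  withr::with_seed(19, {
    for (i in 1:20) {
      q1 <- runif(1, -60, 60); q2 <- runif(1, -1, 1)
      lam <- runif(1, 0.2, 3); eps <- runif(1, 2, 100); temp <- runif(1, 270, 370)
      expect_equal(pair_energy(q1, q2, lam, eps, temp),
                   longhand(q1, q2, lam, eps, temp), tolerance = 1e-9)
    }
  })
})

test_that("pair energy scales as 1/lambda and 1/epsilon and is symmetric", {
  expect_equal(pair_energy(0, 5), 0)
  expect_equal(pair_energy(2, 3), pair_energy(3, 2), tolerance = 1e-15)
  expect_equal(pair_energy(1, 1, lambda_nm = 0.5), 2 * pair_energy(1, 1),
               tolerance = 1e-12)
  expect_equal(pair_energy(1, 1, epsilon = 40), 2 * pair_energy(1, 1),
               tolerance = 1e-12)
  expect_error(pair_energy(1, 1, lambda_nm = 0), "> 0")
  expect_error(pair_energy(1, 1, temperature_k = -1), "> 0")
})

test_that("translocation enthalpy is linear with the expected sign", {
  model <- npc_model()
  expect_equal(translocation_enthalpy(0, model), 0)
  expect_equal(translocation_enthalpy(-50, model), -2.5, tolerance = 0.3 / 2.5)
  withr::with_seed(23, {
    for (i in 1:10) {
      q <- runif(1, -80, 80); a <- runif(1, -3, 3)
      expect_equal(translocation_enthalpy(a * q, model),
                   a * translocation_enthalpy(q, model), tolerance = 1e-12)
    }
  })
  # positive barrier charge: attraction iff the particle is negative
  expect_lt(translocation_enthalpy(-10, model), 0)
  expect_gt(translocation_enthalpy(10, model), 0)
})

test_that("census-derived coefficient agrees with the imposed one to 20%", {
  # a median FG-nucleoporin charge of ~+13 e (mid-teens, as for the yeast
  # census) reproduces the default per-unit-charge coefficient
  census <- npc_model(q_npc = NULL, median_charge = 13)
  imposed <- npc_model()
  expect_equal(
    translocation_enthalpy(1, census),
    translocation_enthalpy(1, imposed),
    tolerance = 0.2
  )
})

test_that("free-energy assembly and phosphorylation shifts are linear", {
  expect_equal(barrier(-2.5, -2.5), 0)
  expect_equal(barrier(0, -3), 3)
  a <- -1.2; b <- 0.7; cc <- 2.1
  expect_equal(barrier(a, b) + barrier(cc, 0), barrier(a + cc, b),
               tolerance = 1e-12)
  expect_error(barrier(Inf, 0), "finite")

  model <- npc_model()
  expect_equal(phosphorylation_shift(1, model), -0.05, tolerance = 0.01 / 0.05)
  expect_equal(phosphorylation_shift(0, model), 0)
  expect_equal(phosphorylation_shift(10, model),
               10 * phosphorylation_shift(1, model), tolerance = 1e-12)
  expect_error(phosphorylation_shift(-1, model), ">= 0")
})

test_that("particle predictions sum complex charges and can flip the sign", {
  model <- npc_model()
  # synthetic stand-ins: a lysine-excess cargo and two acidic receptors
  prots <- tibble::tibble(
    id = c("cargo_basic", "rec1", "rec2"),
    label = c("cargo", "importin", "importin"),
    sequence = c(
      paste0(strrep("K", 60), strrep("G", 120)),
      paste0(strrep("E", 50), strrep("L", 100)),
      paste0(strrep("D", 45), strrep("I", 90))
    )
  )
  manifest <- complex_manifest(rep("ternary", 3), prots$id, proteins = prots)
  pred <- predict_particles(prots, model, manifest = manifest)
  expect_equal(nrow(pred), 4)
  row <- function(id) pred[pred$id == id, ]
  expect_gt(row("cargo_basic")$delta_h, 0) # barrier for the basic protein alone
  expect_equal(
    row("ternary")$q_ntr,
    sum(pred$q_ntr[pred$id != "ternary"]),
    tolerance = 1e-12
  )
  expect_lt(row("ternary")$delta_h, 0) # receptors flip the sign
  expect_s3_class(autoplot(pred), "ggplot")
})

test_that("predictions carry the free-energy column when TdS is supplied", {
  prots <- tibble::tibble(id = "p", sequence = strrep("D", 30))
  pred <- predict_particles(prots, npc_model(), t_delta_s = -2)
  expect_equal(pred$delta_g, pred$delta_h + 2, tolerance = 1e-12)
})

test_that("tidy and glance summarize the model", {
  m <- npc_model()
  td <- tidy(m)
  expect_true(all(c("term", "value", "unit") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$pore_volume_nm3, pore_volume(m))
  expect_equal(gl$kbt_per_unit_charge, translocation_enthalpy(1, m))
})

test_that("NPC config files map onto model parameters", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("copies: 16", "q_npc: null", "median_charge: 10"), f)
  m <- read_npc_config(f)
  expect_equal(m$copies, 16L)
  expect_equal(local_npc_charge(m), 2 * 0.0519, tolerance = 1e-2)
  writeLines("bogus_key: 1", f)
  expect_error(read_npc_config(f), "bogus_key")
})
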