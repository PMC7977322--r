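test_that("random pedigree generation is valid, seeded and model-faithful", {
  one <- generate_random_pedigree(1, seed = 41)
  expect_identical(nrow(one), 1L)
  expect_true(is.na(one$sire) && is.na(one$dam))
  a <- generate_random_pedigree(200, n_paths = 3, n_traits = 2, seed = 42)
  b <- generate_random_pedigree(200, n_paths = 3, n_traits = 2, seed = 42)
  expect_identical(a, b)
  c <- generate_random_pedigree(200, n_paths = 3, n_traits = 2, seed = 43)
  expect_false(identical(a$bv1, c$bv1))
  expect_s3_class(validate_and_sort(a), "ped_table")
  # Mendelian sampling variance matches the infinitesimal model: for
  # offspring of non-inbred parents Var(w) = sigma2_a / 2
  ped <- generate_random_pedigree(500, n_paths = 2, seed = 44,
                                  missing_parent_prob = 0)
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  w <- ped$bv1[both] - 0.5 * ped$bv1[si[both]] - 0.5 * ped$bv1[di[both]]
  se <- 0.5 * sqrt(2 / (length(w) - 1))
  expect_lt(abs(stats::var(w) - 0.5), 3 * se)
})

test_that("the generator's RNG use does not disturb the caller's stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(generate_random_pedigree(20, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("import scenario: three populations, import starts on schedule", {
  imp <- simulate_import_example(import_config(seed = 51))
  expect_identical(sort(unique(imp$Population)), c("Pop1", "Pop2", "Pop3"))
  expect_identical(range(imp$time), c(1L, 20L))
  expect_s3_class(validate_and_sort(imp), "ped_table")
  pop <- imp$Population[match(imp$sire, imp$id)]
  cross <- imp$Population == "Pop1" & !is.na(pop) & pop != "Pop1"
  expect_true(all(imp$time[cross] >= 11))   # imports only after generation 10
  expect_gt(sum(cross), 0)
  # reproducibility
  imp2 <- simulate_import_example(import_config(seed = 51))
  expect_identical(imp$Bv, imp2$Bv)
})

test_that("a closed population's partitions stay entirely domestic", {
  cfg <- import_config(seed = 52, import_frac = c(Pop2 = 0, Pop3 = 0))
  imp <- simulate_import_example(cfg)
  reb <- set_base(imp, imp$time >= 11)
  p <- partition(reb)
  pop1 <- reb$Population == "Pop1"
  expect_equal(p$Bv$Bv_Pop1[pop1], reb$Bv[pop1])
  expect_equal(p$Bv$Bv_Pop2[pop1], rep(0, sum(pop1)))
  expect_equal(p$Bv$Bv_Pop3[pop1], rep(0, sum(pop1)))
})

test_that("multi-tier runs have the configured structure", {
  cfg <- multitier_config(seed = 53, scenario = "random",
                          n_burnin = 3, n_eval = 3,
                          nucleus_males = 5, nucleus_females = 30,
                          nucleus_progeny = 120, multiplier_females = 40,
                          multiplier_progeny = 160, multiplier_males = 10,
                          seed_females = 100)
  mt <- simulate_multitier(cfg)
  expect_identical(sort(unique(mt$Tier)), c("multiplier", "nucleus"))
  expect_identical(sort(unique(mt$TierGender)),
                   c("multiplier-female", "multiplier-male",
                     "nucleus-female", "nucleus-male"))
  expect_identical(range(mt$time), c(1L, 6L))
  # multiplier exists from the base generation on; seeded with females
  expect_identical(min(mt$time[mt$Tier == "multiplier"]), 3L)
  expect_true(all(mt$Sex[mt$Tier == "multiplier" & mt$time == 3] == "F"))
  # trait 2 is never measured in the multiplier
  expect_true(all(is.na(mt$Pheno2[mt$Tier == "multiplier"])))
  expect_true(all(!is.na(mt$Pheno2[mt$Tier == "nucleus"])))
  expect_s3_class(validate_and_sort(mt), "ped_table")
  expect_identical(mt$Tbv1,
                   simulate_multitier(cfg)$Tbv1)
})

test_that("infeasible selection counts are refused", {
  expect_error(multitier_config(nucleus_males = 500, nucleus_females = 200,
                                nucleus_progeny = 600),
               "nucleus_males")
  cfg <- multitier_config(seed = 54, scenario = "random", n_burnin = 2,
                          n_eval = 1, nucleus_males = 350,
                          nucleus_females = 100, nucleus_progeny = 600,
                          multiplier_females = 40, multiplier_progeny = 160,
                          seed_females = 100)
  expect_error(simulate_multitier(cfg), "exceed available nucleus")
})

test_that("evaluation-phase selection records estimated breeding values", {
  mt <- simulate_multitier(multitier_config(seed = 55, n_burnin = 3,
                                            n_eval = 3,
                                            scenario = "maleflow100",
                                            nucleus_males = 5,
                                            nucleus_females = 30,
                                            nucleus_progeny = 120,
                                            multiplier_females = 40,
                                            multiplier_progeny = 160,
                                            seed_females = 100))
  # every candidate generation that faced an EBV selection carries estimates
  expect_true(all(!is.na(mt$Ebv1[mt$time %in% 3:5])))
  # estimates predict true values far better than chance
  sel <- mt$time %in% 3:5
  expect_gt(stats::cor(mt$Ebv1[sel], mt$Tbv1[sel]), 0.3)
})

test_that("standardization centres and scales at the base generation", {
  mt <- simulate_multitier(multitier_config(seed = 56, scenario = "random",
                                            n_burnin = 3, n_eval = 2,
                                            nucleus_males = 5,
                                            nucleus_females = 30,
                                            nucleus_progeny = 120,
                                            multiplier_females = 40,
                                            multiplier_progeny = 160,
                                            seed_females = 100))
  st <- standardize_bv(mt, c("Tbv1", "Tbv2"), base_time = 3)
  base <- st$time == 3
  expect_equal(mean(st$Tbv1[base]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(st$Tbv2[base]), 1, tolerance = 1e-12)
  expect_error(standardize_bv(mt, "Tbv1", base_time = 99), "no records")
})

test_that("the animal-model solver matches a dense GLS oracle", {
  ped <- generate_random_pedigree(50, n_paths = 2, seed = 57)
  with_pheno <- as.data.frame(ped)
  set.seed(570)
  with_pheno$Pheno <- with_pheno$bv1 + rnorm(50, 0, sqrt(3))
  with_pheno$Pheno[sample(50, 12)] <- NA
  ped2 <- ped_table(with_pheno)
  est <- estimate_breeding_values(ped2, "Pheno", h2 = 0.25)
  expect_lt(max(abs(est - gls_oracle(ped2, "Pheno", 0.25))), 1e-6)
})

test_that("the solver obeys its analytic corollaries", {
  # near-unit heritability: the fit reproduces each phenotype's
  # deviation from the fitted mean
  ped <- generate_random_pedigree(40, n_paths = 2, seed = 58)
  df <- as.data.frame(ped)
  set.seed(580)
  df$Pheno <- df$bv1 + rnorm(40, 0, 0.05)
  est <- estimate_breeding_values(ped_table(df), "Pheno", h2 = 0.999)
  expect_lt(max(abs(est - (df$Pheno - attr(est, "mean")))), 0.01)
  # unphenotyped progeny of phenotyped parents sits at the parent average
  trio <- ped_table(data.frame(
    id = c("S", "D", "O"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
    time = c(0, 0, 1), Pheno = c(1.4, -0.6, NA)))
  est2 <- estimate_breeding_values(trio, "Pheno", h2 = 0.4)
  expect_equal(est2[3], 0.5 * (est2[1] + est2[2]), tolerance = 1e-10)
  nodata <- trio
  nodata$Pheno <- NA_real_
  expect_error(estimate_breeding_values(nodata, "Pheno", 0.4),
               "no phenotyped")
  expect_error(estimate_breeding_values(trio, "Pheno", 1.2), "h2")
})
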