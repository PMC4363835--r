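test_that("identical seeds produce byte-identical cohorts", {
  cfg <- sim_config(n_families = 10, seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$phenotypes, c2$phenotypes)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("pedigree.ped", "phenotypes.csv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  c3 <- simulate_cohort(sim_config(n_families = 10, seed = 43))
  expect_false(identical(c1$phenotypes$meq_total, c3$phenotypes$meq_total))
})

test_that("default family shape yields a cohort of about 825 over 112 families", {
  ped <- simulate_pedigree(sim_config(seed = 2))
  expect_identical(length(unique(ped$family)), 112L)
  expect_lt(abs(nrow(ped) - 825) / 825, 0.10)
})

test_that("cross-family relationships are zero by construction", {
  ped <- simulate_pedigree(sim_config(n_families = 6, seed = 5))
  K <- kinship(ped)
  fam <- ped$family
  off <- outer(fam, fam, "!=")
  expect_true(all(K[off] == 0))
})

test_that("degenerate generator configurations are refused", {
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(generations = 1), "generations")
  expect_error(sim_config(sigma2_a = -1), "variances")
  expect_error(sim_config(prop_female = 1.2), "prop_female")
  expect_error(sim_config(sigma2_a = 0, sigma2_e = 0), "total variance")
})

test_that("no genetic variance means no sib-pair phenotype correlation", {
  cfg <- sim_config(n_families = 700, generations = 2, mean_sibship = 1,
                    sigma2_a = 0, sigma2_e = 1,
                    beta_age = 0, beta_sex = 0, beta_residence = 0,
                    censor = FALSE, rescale = FALSE, seed = 8)
  coh <- simulate_cohort(cfg)
  ped <- coh$pedigree
  y <- coh$phenotypes$meq_total
  fidx <- attr(ped, "fidx")
  kids <- which(!is.na(fidx))
  sib_pairs <- do.call(rbind, lapply(split(kids, fidx[kids]), function(k)
    if (length(k) >= 2) t(utils::combn(k, 2)) else NULL))
  expect_gt(nrow(sib_pairs), 500)
  r <- stats::cor(y[sib_pairs[, 1]], y[sib_pairs[, 2]])
  expect_lt(abs(r), 0.05)
})

test_that("parent-offspring covariance of gene-dropped values is sigma2_a / 2", {
  cfg <- sim_config(n_families = 1000, generations = 2, mean_sibship = 0,
                    sigma2_a = 1, sigma2_e = 0,
                    beta_age = 0, beta_sex = 0, beta_residence = 0,
                    censor = FALSE, rescale = FALSE, seed = 13)
  coh <- simulate_cohort(cfg)
  ped <- coh$pedigree
  y <- coh$phenotypes$meq_total
  fidx <- attr(ped, "fidx")
  kids <- which(!is.na(fidx))
  x1 <- y[fidx[kids]]
  x2 <- y[kids]
  cv <- stats::cov(x1, x2)
  # MC standard error of a covariance of jointly normal pairs
  se <- sqrt((1 * 1 + 0.5^2) / length(kids))
  expect_lt(abs(cv - 0.5), 3 * se)
})

test_that("gene-dropped additive values reproduce 2*Phi*sigma2_a entrywise", {
  ped <- dfc_ped()
  K <- kinship(ped)
  cfg <- sim_config(n_families = 1, sigma2_a = 1, sigma2_e = 0,
                    beta_age = 0, beta_sex = 0, beta_residence = 0,
                    censor = FALSE, rescale = FALSE, seed = 1)
  set.seed(99)
  reps <- 4000
  vals <- replicate(reps, simulate_phenotypes(ped, cfg, seed = NULL)$phenotypes$meq_total)
  n <- nrow(ped)
  emp <- stats::cov(t(vals))
  # per-entry MC standard error for covariance of jointly normal values
  for (i in seq_len(n)) for (j in i:n) {
    se <- sqrt((K[i, i] * K[j, j] + K[i, j]^2) / reps)
    expect_lt(abs(emp[i, j] - K[i, j]), 4 * se)
  }
})

test_that("censoring to the questionnaire scale attenuates h2 only slightly", {
  fit_h2 <- function(censor, r) {
    cfg <- sim_config(n_families = 112, censor = censor, seed = 3000 + r)
    coh <- simulate_cohort(cfg)
    polygenic(meq_total ~ sex + age + residence, coh$phenotypes,
              coh$pedigree, se = FALSE)$h2
  }
  h2_cens <- vapply(1:30, function(r) fit_h2(TRUE, r), numeric(1))
  h2_raw <- vapply(1:30, function(r) fit_h2(FALSE, r), numeric(1))
  # same seeds with and without rounding/clipping: the only difference is
  # the scale ceiling/floor
  attenuation <- mean(h2_raw) - mean(h2_cens)
  expect_lt(abs(attenuation), 0.05)
  # and the uncensored fits are unbiased for the generating fraction
  expect_lt(abs(mean(h2_raw) - 26.3 / (26.3 + 28.5)), 0.04)
})

test_that("calibrated configuration encodes the variance-inflation identity", {
  expect_equal(covariate_variance(0.48, 0.21), 0.48 / 0.21 - 1)
  expect_error(covariate_variance(0.2, 0.4))
  cfg <- sim_config_calibrated(n_families = 50, seed = 1)
  tm <- chronoherit:::truncnorm_moments(cfg$age_mean, cfg$age_sd,
                                        cfg$age_min, cfg$age_max)
  p_male <- 1 - cfg$prop_female
  s2cov <- cfg$beta_age^2 * tm$var + cfg$beta_sex^2 * p_male * (1 - p_male)
  expect_equal(s2cov, 0.48 / 0.21 - 1, tolerance = 1e-10)
  expect_identical(cfg$censor, FALSE)
  expect_equal(cfg$sigma2_a + cfg$sigma2_e, 1)
})
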