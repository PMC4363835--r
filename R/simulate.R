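#' Configuration of the synthetic family-cohort generator
#'
#' Collects every generative parameter of the synthetic cohort: family count
#' and shape, true variance components, covariate effects, demographic
#' distributions, the affine mapping onto the 16-86 questionnaire scale, the
#' ceiling/floor censoring switch, and the seed (which fully determines the
#' output). The defaults emulate a cohort of ~112 extended families
#' (~800 adults) with mean age 46.4 (SD 16.3), 60.2% female and ~11.6%
#' rural residence, an additive fraction of 0.48 of the covariate-adjusted
#' phenotypic variance, and covariate effects on the questionnaire scale of
#' +0.263 points/year of age, +1.8 points for men and +7.6 points for rural
#' residence.
#'
#' @param n_families Number of independent families.
#' @param generations Pedigree depth (founder couple = generation 1).
#' @param mean_sibship Poisson mean; each couple has `Poisson(mean_sibship) + 1`
#'   offspring.
#' @param prop_mate Probability that an offspring founds a couple with a new
#'   unrelated spouse in the next generation.
#' @param sigma2_a,sigma2_e Additive genetic and residual environmental
#'   variances (score units squared before rescaling).
#' @param beta_age Age effect (score units per year, applied to age centred
#'   at `age_mean`).
#' @param beta_sex Male-female difference (score units).
#' @param beta_residence Rural-municipal difference (score units).
#' @param age_mean,age_sd,age_min,age_max Age distribution: normal truncated
#'   to `[age_min, age_max]`, drawn independently per individual.
#' @param prop_female,prop_rural Bernoulli fractions.
#' @param meq_mean,meq_sd Centre and SD of the affine mapping onto the
#'   questionnaire scale (applied when `rescale = TRUE`).
#' @param floor,ceiling Scale bounds used when censoring.
#' @param censor Round to integers and clip to `[floor, ceiling]`? Default
#'   `TRUE`.
#' @param rescale Affinely map the latent phenotype so its theoretical SD is
#'   `meq_sd` and mean `meq_mean`? Default `TRUE`. Heritability is invariant
#'   to this mapping.
#' @param seed Integer seed.
#' @return Object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_families = 112, generations = 3, mean_sibship = 2,
                       prop_mate = 0.2,
                       sigma2_a = 26.3, sigma2_e = 28.5,
                       beta_age = 0.263, beta_sex = 1.8, beta_residence = 7.6,
                       age_mean = 46.4, age_sd = 16.3,
                       age_min = 18, age_max = 89,
                       prop_female = 0.602, prop_rural = 96 / 825,
                       meq_mean = 63.5, meq_sd = 11.2,
                       floor = 16, ceiling = 86,
                       censor = TRUE, rescale = TRUE, seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              generations = as.integer(generations),
              mean_sibship = mean_sibship, prop_mate = prop_mate,
              sigma2_a = sigma2_a, sigma2_e = sigma2_e,
              beta_age = beta_age, beta_sex = beta_sex,
              beta_residence = beta_residence,
              age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max,
              prop_female = prop_female, prop_rural = prop_rural,
              meq_mean = meq_mean, meq_sd = meq_sd,
              floor = floor, ceiling = ceiling,
              censor = isTRUE(censor), rescale = isTRUE(rescale),
              seed = as.integer(seed))
  if (cfg$n_families < 1) stop("n_families must be >= 1")
  if (cfg$generations < 2) stop("generations must be >= 2")
  if (cfg$mean_sibship < 0) stop("mean_sibship must be >= 0")
  if (cfg$sigma2_a < 0 || cfg$sigma2_e < 0) stop("variances must be >= 0")
  if (cfg$sigma2_a + cfg$sigma2_e == 0) stop("total variance must be positive")
  for (f in c("prop_mate", "prop_female", "prop_rural"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$age_min >= cfg$age_max) stop("age_min must be below age_max")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d families x %d generations, ",
                     "sigma2_a = %.3g, sigma2_e = %.3g (h2 = %.2f adjusted), ",
                     "censor = %s, seed = %d\n"),
              x$n_families, x$generations, x$sigma2_a, x$sigma2_e,
              x$sigma2_a / (x$sigma2_a + x$sigma2_e), x$censor, x$seed))
  invisible(x)
}

#' Covariate variance implied by two heritability levels
#'
#' If the additive fraction of the covariate-adjusted variance is `h2_adj`
#' (with \eqn{\sigma^2_a + \sigma^2_e = 1}) and covariates independent of the
#' pedigree inflate the unadjusted phenotypic variance, the unadjusted
#' heritability is \eqn{h^2_{unadj} = \sigma^2_a / (1 + \sigma^2_{cov})}.
#' Inverting gives \eqn{\sigma^2_{cov} = h^2_{adj}/h^2_{unadj} - 1}.
#'
#' @param h2_adj Adjusted-model heritability.
#' @param h2_unadj Unadjusted-model heritability.
#' @return Covariate-explained variance on the \eqn{\sigma^2_a + \sigma^2_e = 1}
#'   scale.
#' @export
covariate_variance <- function(h2_adj, h2_unadj) {
  stopifnot(h2_adj > 0, h2_unadj > 0, h2_unadj <= h2_adj)
  h2_adj / h2_unadj - 1
}

#' Calibrated generator configuration for estimator validation
#'
#' Builds a [sim_config()] on the unit variance scale
#' (\eqn{\sigma^2_a + \sigma^2_e = 1}) whose sex and age effect sizes are set
#' by the variance-inflation identity of [covariate_variance()]: fitting the
#' sex+age-adjusted model on cohorts from this generator recovers `h2_adj`
#' in expectation, while the unadjusted fit recovers `h2_unadj`. The
#' covariate variance is split between age and sex in proportion
#' `share_age` : `1 - share_age` (default 0.96, the ratio of the
#' demographically motivated effect variances). Residence effects are zero
#' and phenotypes are left uncensored: this configuration validates the
#' estimator under the Gaussian polygenic model's own assumptions.
#'
#' @param h2_adj,h2_unadj The two target heritability levels (defaults 0.48
#'   and 0.21).
#' @param share_age Fraction of the covariate variance assigned to age.
#' @param ... Further arguments passed to [sim_config()] (e.g. `n_families`,
#'   `seed`).
#' @return A `sim_config`.
#' @export
sim_config_calibrated <- function(h2_adj = 0.48, h2_unadj = 0.21,
                                  share_age = 0.96, ...) {
  s2cov <- covariate_variance(h2_adj, h2_unadj)
  base <- sim_config(...)   # for the age/sex distribution parameters
  tm <- truncnorm_moments(base$age_mean, base$age_sd, base$age_min, base$age_max)
  p_male <- 1 - base$prop_female
  sim_config(
    sigma2_a = h2_adj, sigma2_e = 1 - h2_adj,
    beta_age = sqrt(share_age * s2cov / tm$var),
    beta_sex = sqrt((1 - share_age) * s2cov / (p_male * (1 - p_male))),
    beta_residence = 0, censor = FALSE, ...)
}

# mean and variance of N(mu, sd^2) truncated to [a, b]
truncnorm_moments <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}

rtruncnorm <- function(n, mu, sd, a, b) {
  lo <- stats::pnorm((a - mu) / sd)
  hi <- stats::pnorm((b - mu) / sd)
  mu + sd * stats::qnorm(lo + (hi - lo) * stats::runif(n))
}

#' Simulate a multi-family pedigree
#'
#' Each family starts from an unrelated founder couple; every couple has
#' `Poisson(mean_sibship) + 1` offspring; while generations remain, each
#' offspring founds a new couple with an unrelated incoming spouse with
#' probability `prop_mate`. Families are mutually unrelated, so cross-family
#' entries of the relationship matrix are zero by construction.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`. Pass `NULL` to use the
#'   current RNG state.
#' @return A [pedigree()].
#' @export
simulate_pedigree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%03d", f)
    nid <- 0L
    new_id <- function() {
      nid <<- nid + 1L
      sprintf("%s_I%03d", fam, nid)
    }
    id <- character(0); fa <- character(0); mo <- character(0); sx <- character(0)
    add <- function(father, mother, sex) {
      i <- new_id()
      id <<- c(id, i); fa <<- c(fa, father); mo <<- c(mo, mother)
      sx <<- c(sx, sex)
      i
    }
    p1 <- add(NA, NA, "male")
    p2 <- add(NA, NA, "female")
    couples <- list(c(p1, p2))
    for (g in seq_len(config$generations - 1L)) {
      nxt <- list()
      for (cp in couples) {
        nkids <- stats::rpois(1, config$mean_sibship) + 1L
        for (k in seq_len(nkids)) {
          sex <- if (stats::runif(1) < config$prop_female) "female" else "male"
          kid <- add(cp[1], cp[2], sex)
          if (g < config$generations - 1L &&
              stats::runif(1) < config$prop_mate) {
            spouse <- add(NA, NA, if (sex == "male") "female" else "male")
            nxt <- c(nxt, list(if (sex == "male") c(kid, spouse)
                               else c(spouse, kid)))
          }
        }
      }
      couples <- nxt
      if (!length(couples)) break
    }
    rows[[f]] <- data.frame(family = fam, id = id, father = fa, mother = mo,
                            sex = sx, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  pedigree(id = all$id, father = all$father, mother = all$mother,
           sex = all$sex, family = all$family)
}

#' Simulate phenotypes on a pedigree by gene dropping
#'
#' Additive genetic values are dropped down the pedigree: founders draw
#' \eqn{N(0, \sigma^2_a)}; each non-founder receives the parental midvalue
#' plus Mendelian segregation noise
#' \eqn{N(0, \tfrac{1}{2}\sigma^2_a (1 - (F_f + F_m)/2))}, where \eqn{F} is
#' the parental inbreeding coefficient. Independent environmental noise
#' \eqn{N(0, \sigma^2_e)} and fixed covariate effects (age, sex, residence,
#' drawn independently per individual) are added, and the latent value is
#' affinely mapped to the questionnaire scale and, if `censor`, rounded and
#' clipped to `[floor, ceiling]`.
#'
#' @param ped A [pedigree()].
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed + 1`. Pass `NULL` to use the
#'   current RNG state.
#' @return Object of class `synthetic_cohort`: list with `pedigree`,
#'   `phenotypes` (data frame: `individual_id`, `family_id`, `meq_total`,
#'   `latent_value`, `sex`, `age`, `residence`) and `truth` (the config plus
#'   realized variance fractions).
#' @export
simulate_phenotypes <- function(ped, config,
                                seed = if (is.null(config$seed)) NULL
                                       else config$seed + 1L) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  fidx <- attr(ped, "fidx")
  midx <- attr(ped, "midx")
  ord <- order(attr(ped, "depth"))
  Fcoef <- diag(kinship(ped)) - 1

  g <- numeric(n)
  s2a <- config$sigma2_a
  for (i in ord) {
    f <- fidx[i]; m <- midx[i]
    if (is.na(f) && is.na(m)) {
      g[i] <- stats::rnorm(1, 0, sqrt(s2a))
    } else {
      gf <- if (is.na(f)) stats::rnorm(1, 0, sqrt(s2a)) else g[f]
      gm <- if (is.na(m)) stats::rnorm(1, 0, sqrt(s2a)) else g[m]
      Ff <- if (is.na(f)) 0 else Fcoef[f]
      Fm <- if (is.na(m)) 0 else Fcoef[m]
      seg <- 0.5 * s2a * (1 - (Ff + Fm) / 2)
      g[i] <- 0.5 * (gf + gm) + stats::rnorm(1, 0, sqrt(seg))
    }
  }

  e <- stats::rnorm(n, 0, sqrt(config$sigma2_e))
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_min, config$age_max)
  sex <- ped$sex
  unk <- sex == "unknown"
  if (any(unk))
    sex[unk] <- ifelse(stats::runif(sum(unk)) < config$prop_female,
                       "female", "male")
  residence <- ifelse(stats::runif(n) < config$prop_rural, "rural", "municipal")

  covar <- config$beta_age * (age - config$age_mean) +
    config$beta_sex * (sex == "male") +
    config$beta_residence * (residence == "rural")
  latent <- g + e + covar

  tm <- truncnorm_moments(config$age_mean, config$age_sd,
                          config$age_min, config$age_max)
  p_male <- 1 - config$prop_female
  q <- config$prop_rural
  var_theory <- s2a + config$sigma2_e +
    config$beta_age^2 * tm$var +
    config$beta_sex^2 * p_male * (1 - p_male) +
    config$beta_residence^2 * q * (1 - q)
  mu_theory <- config$beta_age * (tm$mean - config$age_mean) +
    config$beta_sex * p_male + config$beta_residence * q

  if (config$rescale) {
    scl <- config$meq_sd / sqrt(var_theory)
    meq <- config$meq_mean + scl * (latent - mu_theory)
  } else {
    meq <- latent
  }
  if (config$censor)
    meq <- pmin(pmax(round(meq), config$floor), config$ceiling)

  phen <- data.frame(individual_id = ped$id, family_id = ped$family,
                     meq_total = meq, latent_value = latent,
                     sex = sex, age = age, residence = residence,
                     stringsAsFactors = FALSE)
  truth <- c(unclass(config), list(
    n = n,
    realized_var_genetic = stats::var(g),
    realized_var_environment = stats::var(e),
    realized_var_covariates = stats::var(covar),
    realized_h2_adjusted = stats::var(g) / (stats::var(g) + stats::var(e))
  ))
  structure(list(pedigree = ped, phenotypes = phen, truth = truth),
            class = "synthetic_cohort")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_pedigree()] then [simulate_phenotypes()],
#' both seeded from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` (see [simulate_phenotypes()]).
#' @export
simulate_cohort <- function(config) {
  ped <- simulate_pedigree(config)
  simulate_phenotypes(ped, config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d individuals, %d families, seed %d\n",
              nrow(x$phenotypes), length(unique(x$phenotypes$family_id)),
              x$truth$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `pedigree.ped` (PED-like), `phenotypes.csv`, and `truth.json`
#' (the generating parameters and realized variance fractions), the same
#' formats the analysis functions read.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(cohort$pedigree, file.path(dir, "pedigree.ped"))
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Allocate 19 item responses consistent with a target total
#'
#' Greedy allocator used to exercise the scoring path end-to-end: starts
#' from the all-minimum response vector and repeatedly advances items one
#' option at a time (largest feasible step first) until the selected option
#' scores sum to `total`. Any allocation summing to the target is valid;
#' this one is deterministic.
#'
#' @param total Target total score in 16..86.
#' @param instrument An [meq_instrument()].
#' @return Integer vector of 19 option indices with
#'   `score_meq(out, instrument)$total == total`.
#' @export
simulate_responses <- function(total, instrument = meq_instrument()) {
  total <- as.integer(total)
  if (total < 16 || total > 86) stop("target total must lie in 16..86")
  items <- instrument$items
  # options sorted ascending by score per item; response = position in
  # original option order
  ords <- lapply(items, function(it) order(it$scores))
  pos <- rep(1L, 19)   # position along the ascending-score ordering
  cur <- sum(vapply(items, function(it) min(it$scores), numeric(1)))
  repeat {
    deficit <- total - cur
    if (deficit == 0) break
    steps <- vapply(1:19, function(k) {
      sc <- items[[k]]$scores[ords[[k]]]
      if (pos[k] < length(sc)) sc[pos[k] + 1L] - sc[pos[k]] else NA_real_
    }, numeric(1))
    feasible <- which(!is.na(steps) & steps <= deficit)
    if (length(feasible)) {
      k <- feasible[which.max(steps[feasible])]
      pos[k] <- pos[k] + 1L
      cur <- cur + steps[k]
    } else {
      # deficit smaller than any available step: step one item up and
      # another down to close the gap (e.g. remaining 1 with only 2-steps)
      up <- which(!is.na(steps))
      done <- FALSE
      for (k in up) {
        back <- which(pos > 1L & seq_len(19) != k)
        for (j in back) {
          sc_j <- items[[j]]$scores[ords[[j]]]
          dn <- sc_j[pos[j]] - sc_j[pos[j] - 1L]
          if (steps[k] - dn == deficit) {
            pos[k] <- pos[k] + 1L
            pos[j] <- pos[j] - 1L
            cur <- cur + steps[k] - dn
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (!done) stop("cannot allocate responses for total ", total)
    }
  }
  vapply(1:19, function(k) ords[[k]][pos[k]], integer(1))
}
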