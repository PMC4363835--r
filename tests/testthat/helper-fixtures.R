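# Fixture pedigrees used across tests (all <= 12 members).

trio_ped <- function() {
  pedigree(id = c("dad", "mum", "kid"),
           father = c(NA, NA, "dad"),
           mother = c(NA, NA, "mum"),
           sex = c("male", "female", "female"))
}

sib_ped <- function() {
  pedigree(id = c("dad", "mum", "s1", "s2"),
           father = c(NA, NA, "dad", "dad"),
           mother = c(NA, NA, "mum", "mum"),
           sex = c("male", "female", "male", "female"))
}

half_sib_ped <- function() {
  pedigree(id = c("dad", "m1", "m2", "h1", "h2"),
           father = c(NA, NA, NA, "dad", "dad"),
           mother = c(NA, NA, NA, "m1", "m2"),
           sex = c("male", "female", "female", "male", "female"))
}

# ca and cb are first cousins
cousin_ped <- function() {
  pedigree(id = c("gp1", "gp2", "a", "b", "sa", "sb", "ca", "cb"),
           father = c(NA, NA, "gp1", "gp1", NA, NA, "a", "sb"),
           mother = c(NA, NA, "gp2", "gp2", NA, NA, "sa", "b"),
           sex = c("male", "female", "male", "female", "female", "male",
                   "male", "female"))
}

# c1 and c2 are double first cousins; z is their (inbred) offspring
dfc_ped <- function() {
  pedigree(id = c("fa", "ma", "fb", "mb", "a1", "a2", "b1", "b2",
                  "c1", "c2", "z"),
           father = c(NA, NA, NA, NA, "fa", "fa", "fb", "fb",
                      "a1", "a2", "c1"),
           mother = c(NA, NA, NA, NA, "ma", "ma", "mb", "mb",
                      "b1", "b2", "c2"),
           sex = c("male", "female", "male", "female", "male", "male",
                   "female", "female", "male", "female", "male"))
}

fixture_peds <- function() {
  list(trio = trio_ped(), sibs = sib_ped(), half_sibs = half_sib_ped(),
       cousins = cousin_ped(), double_cousins = dfc_ped())
}

# a small multi-family cohort (~30 individuals) for likelihood-oracle tests
fixture_cohort_30 <- function(seed = 421, h2 = 0.5) {
  cfg <- sim_config(n_families = 5, generations = 2, mean_sibship = 3,
                    sigma2_a = h2, sigma2_e = 1 - h2,
                    beta_age = 0, beta_sex = 0, beta_residence = 0,
                    censor = FALSE, rescale = FALSE, seed = seed)
  simulate_cohort(cfg)
}
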