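#' Classify residence zone from a free-text address
#'
#' A participant is classified as resident in the municipal zone if the
#' address contains a street token (rua, avenida/av., travessa, alameda,
#' praca, estrada, r.) followed by a house number; otherwise rural. An
#' explicit zone value always overrides the inference (pass it via `zone`).
#'
#' @param address Character vector of addresses.
#' @param zone Optional explicit zone vector (`"municipal"`/`"rural"`;
#'   `NA`/empty entries fall back to inference).
#' @param pattern Regular expression (case-insensitive) defining "street
#'   token followed by a number"; the default covers common Brazilian
#'   street designators.
#' @return Character vector of `"municipal"`/`"rural"`.
#' @export
classify_residence <- function(address, zone = NULL,
    pattern = "\\b(rua|av(enida)?\\.?|travessa|alameda|pra[cç]a|estrada|r\\.)\\b[^,;]*[,;]?\\s*(n[oº°]?\\.?\\s*)?[0-9]+") {
  address <- as.character(address)
  if (any(!is.na(address) & trimws(address) == ""))
    address[!is.na(address) & trimws(address) == ""] <- NA_character_
  inferred <- ifelse(!is.na(address) &
                       grepl(pattern, address, ignore.case = TRUE, perl = TRUE),
                     "municipal", "rural")
  if (is.null(zone)) return(inferred)
  zone <- as.character(zone)
  use_zone <- !is.na(zone) & zone %in% c("municipal", "rural")
  ifelse(use_zone, zone, inferred)
}

# FNV-1a 32-bit hash of a string, for config provenance stamps.
# The 32-bit state is kept as two 16-bit halves: R has no unsigned 32-bit
# integers and the naive product overflows double precision.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536))
    hi <- as.integer(h %/% 65536)
    if (b >= 65536) hi <- bitwXor(hi, as.integer(b %/% 65536))
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: load (or simulate) a pedigree and
#' phenotype table, apply the age >= 18 eligibility filter, derive residence
#' from addresses where no explicit zone is given, compute the descriptive
#' layer (zone-wise group summaries, t-test, Cohen's d, age trend), fit the
#' four-model heritability suite, and write the report bundle:
#' `table1.tsv` (group summaries), `table2.tsv` (heritability suite),
#' `fig1_hist.tsv` (score histogram by zone), `fig3_age.tsv` (age-score
#' pairs), `fig4_qq.tsv` (normality-plot coordinates), and `report.json`
#' (all statistics plus provenance: config hash, seed, package version).
#' Reruns with identical inputs and seed produce byte-identical outputs.
#'
#' @param config Named list: either `pedigree` and `phenotypes` file paths
#'   (or `responses`, an MEQ answer CSV to be scored, plus covariate columns
#'   in `phenotypes`), or `simulate = TRUE` with an optional `sim` sublist of
#'   [sim_config()] arguments; plus `out` (output directory), `seed`,
#'   `d_method` (`"unweighted_sd"`/`"pooled_sd"`), `ttest`
#'   (`"pooled"`/`"welch"`), `method` (`"ML"`/`"REML"`).
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (is.null(cfg$out)) stop("config$out (output directory) is required")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  d_method <- if (is.null(cfg$d_method)) "unweighted_sd" else cfg$d_method
  ttest_variant <- if (is.null(cfg$ttest)) "pooled" else cfg$ttest
  fit_method <- if (is.null(cfg$method)) "ML" else cfg$method
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  if (isTRUE(cfg$simulate)) {
    log_stage("simulate", "generating synthetic cohort (seed %d)", cfg$seed)
    sc_args <- if (is.null(cfg[["sim"]])) list() else cfg[["sim"]]
    sc_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sc_args)
    cohort <- simulate_cohort(scfg)
    ped <- cohort$pedigree
    phen <- cohort$phenotypes
  } else {
    if (is.null(cfg$pedigree)) stop("config$pedigree path is required")
    log_stage("load", "pedigree %s", cfg$pedigree)
    ped <- read_pedigree(cfg$pedigree)
    if (!is.null(cfg$responses)) {
      log_stage("score", "scoring responses %s", cfg$responses)
      scored <- score_meq_table(read_meq_responses(cfg$responses))
      covar <- utils::read.csv(cfg$phenotypes, stringsAsFactors = FALSE)
      phen <- merge(covar, scored, by = "individual_id")
    } else {
      if (is.null(cfg$phenotypes)) stop("config$phenotypes path is required")
      phen <- utils::read.csv(cfg$phenotypes, stringsAsFactors = FALSE)
    }
  }

  for (col in c("individual_id", "meq_total", "sex", "age"))
    if (!col %in% names(phen))
      stop("phenotype table lacks required column: ", col)
  if (!"residence" %in% names(phen)) {
    if (!"address" %in% names(phen))
      stop("phenotype table lacks required column: residence (or address)")
    log_stage("residence", "inferring zone from addresses")
    phen$residence <- classify_residence(phen$address)
  } else if ("address" %in% names(phen)) {
    phen$residence <- classify_residence(phen$address, zone = phen$residence)
  }

  n0 <- nrow(phen)
  phen <- phen[!is.na(phen$age) & phen$age >= 18, , drop = FALSE]
  log_stage("filter", "age >= 18 eligibility: excluded %d of %d", n0 - nrow(phen), n0)

  log_stage("describe", "descriptive layer (n = %d)", nrow(phen))
  by_zone <- split(phen, phen$residence)
  zone_sum <- lapply(names(by_zone), function(z)
    summarize_group(by_zone[[z]]$meq_total, z))
  names(zone_sum) <- names(by_zone)
  total_sum <- pool_groups(zone_sum)
  table1 <- do.call(rbind, lapply(c(zone_sum, list(total = total_sum)),
    function(g) data.frame(group = g$label, n = g$n, mean_meq = g$mean,
                           sd_meq = g$sd)))
  table1$mean_age <- c(vapply(names(by_zone), function(z)
    mean(by_zone[[z]]$age), numeric(1)), mean(phen$age))
  table1$sd_age <- c(vapply(names(by_zone), function(z)
    stats::sd(by_zone[[z]]$age), numeric(1)), stats::sd(phen$age))
  table1$prop_female <- c(vapply(names(by_zone), function(z)
    mean(by_zone[[z]]$sex == "female"), numeric(1)),
    mean(phen$sex == "female"))
  if ("preferred_wake" %in% names(phen)) {
    table1$mean_wake <- c(vapply(names(by_zone), function(z)
      mean(by_zone[[z]]$preferred_wake, na.rm = TRUE), numeric(1)),
      mean(phen$preferred_wake, na.rm = TRUE))
    table1$mean_bed <- c(vapply(names(by_zone), function(z)
      mean(by_zone[[z]]$preferred_bed, na.rm = TRUE), numeric(1)),
      mean(phen$preferred_bed, na.rm = TRUE))
  }

  desc <- list()
  if (all(c("rural", "municipal") %in% names(zone_sum))) {
    desc$zone_ttest <- ttest_from_summary(zone_sum$rural, zone_sum$municipal,
                                          variant = ttest_variant)
    dz <- cohens_d(zone_sum$rural, zone_sum$municipal, method = d_method)
    desc$zone_cohens_d <- dz[c("d", "ci_low", "ci_high", "method")]
  }
  sex_sum <- lapply(split(phen$meq_total, phen$sex), summarize_group)
  if (all(c("male", "female") %in% names(sex_sum))) {
    sex_sum$male$label <- "male"; sex_sum$female$label <- "female"
    desc$sex_ttest <- ttest_from_summary(sex_sum$male, sex_sum$female,
                                         variant = ttest_variant)
    ds <- cohens_d(sex_sum$male, sex_sum$female, method = d_method)
    desc$sex_cohens_d <- ds[c("d", "ci_low", "ci_high", "method")]
  }
  trend <- age_trend(phen)
  desc$age_trend <- trend[c("slope", "intercept", "p", "r_squared", "n")]

  log_stage("fit", "polygenic suite (%s)", fit_method)
  suite <- polygenic_suite(phen, ped, method = fit_method)

  log_stage("write", "report bundle -> %s", cfg$out)
  paths <- list(
    table1 = file.path(cfg$out, "table1.tsv"),
    table2 = file.path(cfg$out, "table2.tsv"),
    fig1 = file.path(cfg$out, "fig1_hist.tsv"),
    fig3 = file.path(cfg$out, "fig3_age.tsv"),
    fig4 = file.path(cfg$out, "fig4_qq.tsv"),
    report = file.path(cfg$out, "report.json")
  )
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  wt(table1, paths$table1)
  write_polygenic_suite(suite, paths$table2, format = "tsv")
  wt(histogram_counts(round(phen$meq_total), by = phen$residence),
     paths$fig1)
  wt(phen[order(phen$age), c("age", "meq_total")], paths$fig3)
  wt(qq_coordinates(phen$meq_total), paths$fig4)

  # hash the analysis-relevant configuration: where results go is not part
  # of what was computed
  cfg_canon <- cfg[setdiff(sort(names(cfg)), c("out", "print"))]
  report <- list(
    provenance = list(
      package = "chronoherit",
      version = as.character(utils::packageVersion("chronoherit")),
      seed = cfg$seed,
      config_hash = fnv1a(jsonlite::toJSON(cfg_canon, auto_unbox = TRUE))
    ),
    n = nrow(phen),
    table1 = table1,
    descriptives = desc,
    heritability = as.data.frame(suite)
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (isTRUE(cfg$print)) print(suite)

  invisible(list(table1 = table1, descriptives = desc, suite = suite,
                 phenotypes = phen, pedigree = ped, paths = paths))
}
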