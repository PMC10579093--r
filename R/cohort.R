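#' Configure a synthetic screening cohort
#'
#' Describes the three-group cohort (autistic / developmental-or-language
#' delay without autism / neurotypical) the generator emulates: group sizes,
#' standardized group shifts for each of the 23 app variables,
#' per-variable missingness rates, demographic strata and a master seed.
#'
#' @param n_autistic,n_ddld,n_neurotypical Group sizes. Defaults mirror the
#'   published study cohort (49 / 98 / 328).
#' @param effect_sizes Named numeric vector: latent-scale standardized mean
#'   shift of the autistic group relative to neurotypical, per variable.
#' @param ddld_attenuation Fraction in `[0, 1]` scaling the autistic shifts
#'   for the DD-LD group (default 0.5: intermediate presentation).
#' @param missingness_rates Named numeric vector of per-variable missing
#'   probabilities in `[0, 1]`.
#' @param missingness_dependence Non-negative scalar; 0 (default) gives
#'   missing-at-random, larger values multiply autistic children's missing
#'   rates by `1 + missingness_dependence` (informative missingness, used to
#'   exercise the missingness-attribution machinery).
#' @param demographics Named list of per-category proportion tables; each
#'   element is a list with one named numeric vector per diagnosis group
#'   (`NT`, `ASD`, `DDLD`) summing to 1.
#' @param mchat_positive_rate Named numeric vector: probability of a
#'   positive questionnaire screen (score > 2) per diagnosis group.
#' @param mchat_error Probability of flipping a child's questionnaire
#'   status, controlling how strongly the score tracks diagnosis.
#' @param seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_autistic = 49, n_ddld = 98, n_neurotypical = 328,
                          effect_sizes = default_effect_sizes(),
                          ddld_attenuation = 0.5,
                          missingness_rates = default_missingness_rates(),
                          missingness_dependence = 0,
                          demographics = default_demographics(),
                          mchat_positive_rate = c(NT = 0.006, ASD = 0.775,
                                                  DDLD = 0.184),
                          mchat_error = 0.0,
                          seed = 1L) {
  vars <- app_variable_names()
  stopifnot(length(n_autistic) == 1, length(n_ddld) == 1,
            length(n_neurotypical) == 1)
  counts <- c(n_autistic, n_ddld, n_neurotypical)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("group counts must be non-negative")
  if (sum(counts) == 0) stop("zero-size cohort")
  es <- setNames(rep(0, length(vars)), vars)
  es[names(effect_sizes)] <- effect_sizes
  if (any(!is.finite(es))) stop("effect sizes must be finite")
  mr <- setNames(rep(0, length(vars)), vars)
  mr[names(missingness_rates)] <- missingness_rates
  if (any(mr < 0 | mr > 1)) stop("missingness rates must be in [0, 1]")
  if (!is.finite(ddld_attenuation) || ddld_attenuation < 0 ||
      ddld_attenuation > 1)
    stop("ddld_attenuation must be in [0, 1]")
  for (cat in setdiff(names(demographics), "age")) {
    for (grp in names(demographics[[cat]])) {
      s <- sum(demographics[[cat]][[grp]])
      if (abs(s - 1) > 1e-9)
        stop("demographic proportions for ", cat, "/", grp,
             " sum to ", s, ", not 1")
    }
  }
  structure(list(n_autistic = as.integer(n_autistic),
                 n_ddld = as.integer(n_ddld),
                 n_neurotypical = as.integer(n_neurotypical),
                 effect_sizes = es, ddld_attenuation = ddld_attenuation,
                 missingness_rates = mr,
                 missingness_dependence = missingness_dependence,
                 demographics = demographics,
                 mchat_positive_rate = mchat_positive_rate,
                 mchat_error = mchat_error,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default demographic strata
#'
#' Group-conditional proportions for sex, ethnicity and race, and normal
#' age distributions (months), patterned on the published study sample.
#' Purely cosmetic for the classifier; used by stratified evaluation tests.
#'
#' @return Named list of per-category proportion tables.
#' @export
default_demographics <- function() {
  list(
    sex = list(NT = c(boy = 0.518, girl = 0.482),
               ASD = c(boy = 0.775, girl = 0.225),
               DDLD = c(boy = 0.620, girl = 0.380)),
    ethnicity = list(
      NT = c(not_hispanic = 0.933, hispanic = 0.067),
      ASD = c(not_hispanic = 0.734, hispanic = 0.266),
      DDLD = c(not_hispanic = 0.847, hispanic = 0.153)),
    race = list(
      NT = c(white = 0.777, black = 0.085, asian = 0.018,
             more_than_one = 0.099, other = 0.021),
      ASD = c(white = 0.469, black = 0.224, asian = 0.020,
              more_than_one = 0.143, other = 0.144),
      DDLD = c(white = 0.704, black = 0.153, asian = 0.000,
               more_than_one = 0.082, other = 0.061)),
    age = list(NT = c(mean = 20.4, sd = 3.0),
               ASD = c(mean = 24.2, sd = 4.6),
               DDLD = c(mean = 21.2, sd = 3.55)))
}

#' Generate a synthetic cohort feature table
#'
#' Draws one row per child: demographics, diagnosis, optional questionnaire
#' score and the 23 app variables with structured missingness. Group
#' differences are injected on a latent standard-normal scale (shift =
#' configured effect size) and mapped monotonically to each variable's
#' natural scale, so bounded variables stay in range while the configured
#' standardized separation (hence per-variable AUC) is preserved.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with columns `child_id`, `age_months`, `sex`,
#'   `race`, `ethnicity`, `diagnosis` (`ASD`/`DDLD`/`NT`), `mchat_score`
#'   (NA when not administered) and the 23 app variable columns (NA =
#'   missing). The latent Gaussian draws are attached as attribute
#'   `"latent"` and the missingness mask as attribute `"missing_mask"`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  vars <- app_variable_names()
  groups <- c(rep("ASD", config$n_autistic), rep("DDLD", config$n_ddld),
              rep("NT", config$n_neurotypical))
  n <- length(groups)
  with_seed(config$seed, {
    shift <- rbind(ASD = config$effect_sizes,
                   DDLD = config$effect_sizes * config$ddld_attenuation,
                   NT = setNames(rep(0, length(vars)), vars))
    latent <- matrix(rnorm(n * length(vars)), n, length(vars),
                     dimnames = list(NULL, vars))
    latent <- latent + shift[groups, , drop = FALSE]
    values <- latent
    for (v in vars) values[, v] <- latent_to_natural(latent[, v], v)
    # structured missingness
    rate <- matrix(config$missingness_rates, n, length(vars), byrow = TRUE,
                   dimnames = list(NULL, vars))
    if (config$missingness_dependence > 0)
      rate[groups == "ASD", ] <- pmin(
        1, rate[groups == "ASD", ] * (1 + config$missingness_dependence))
    mask <- matrix(runif(n * length(vars)) < rate, n, length(vars),
                   dimnames = list(NULL, vars))
    values[mask] <- NA_real_
    # demographics
    demo <- config$demographics
    pick <- function(cat) {
      vapply(groups, function(g) {
        p <- demo[[cat]][[g]]
        sample(names(p), 1, prob = p)
      }, character(1), USE.NAMES = FALSE)
    }
    sex <- pick("sex"); eth <- pick("ethnicity"); race <- pick("race")
    age <- vapply(groups, function(g) {
      a <- demo$age[[g]]
      min(36, max(17, rnorm(1, a["mean"], a["sd"])))
    }, numeric(1), USE.NAMES = FALSE)
    # questionnaire score: positive (> 2) with group-dependent probability,
    # flipped with probability mchat_error; ~1% not administered
    ppos <- config$mchat_positive_rate[groups]
    pos <- runif(n) < ppos
    flip <- runif(n) < config$mchat_error
    pos <- xor(pos, flip)
    mchat <- ifelse(pos, sample(3:12, n, replace = TRUE),
                    sample(0:2, n, replace = TRUE))
    mchat[runif(n) < 0.008] <- NA_integer_
    out <- data.frame(child_id = sprintf("child_%04d", seq_len(n)),
                      age_months = round(age, 1), sex = sex, race = race,
                      ethnicity = eth, diagnosis = groups,
                      mchat_score = mchat, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(values))
    attr(out, "latent") <- latent
    attr(out, "missing_mask") <- mask
    out
  })
}

#' Write / read a cohort table as CSV
#'
#' Missing cells are written as empty fields, one row per child.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("child_id", "diagnosis", app_variable_names())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
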