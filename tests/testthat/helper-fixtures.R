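# Shared fixtures, built once per test run and cached (training even a
# small ensemble is the expensive part of the suite).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

small_cohort <- function() {
  fixture("small_cohort", function()
    generate_cohort(cohort_config(n_autistic = 30, n_ddld = 20,
                                  n_neurotypical = 80, seed = 101L)))
}

small_ensemble <- function() {
  fixture("small_ensemble", function()
    train_ensemble(small_cohort(), "asd_vs_nt",
                   ensemble_config(K = 5, nrounds = 40, seed = 11L)))
}

small_attribution <- function() {
  fixture("small_attribution", function() attribute(small_ensemble()))
}

default_session <- function() {
  fixture("default_session", function()
    generate_session(session_script(), seed = 21L))
}

# internal C++ entry points (exercised directly by oracle-equivalence tests)
gbt_fit <- phenoscreen:::.gbt_fit_cpp
gbt_predict <- phenoscreen:::.gbt_predict_cpp
gbt_shap <- phenoscreen:::.gbt_shap_cpp
gbt_shap_inter <- phenoscreen:::.gbt_shap_inter_cpp
sampen <- phenoscreen:::.sampen_cpp
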