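# Shared fixtures for the test suite. Spectra are deterministic builtins;
# memoize them to avoid rebuilding per test.
.helper_env <- new.env()

kv_spectrum <- function() {
  if (is.null(.helper_env$kv)) .helper_env$kv <- load_spectrum("kv150")
  .helper_env$kv
}

mv_spectrum <- function() {
  if (is.null(.helper_env$mv)) .helper_env$mv <- load_spectrum("mv6")
  .helper_env$mv
}

# Enhancement ratio at the reference dose produced by dose-scaling k under
# the LQ truth -- the inverse of the generator's k solver, used to build
# configs with exact k targets.
ner_of_k <- function(k, alpha0, beta0, ref = 6) {
  exp(alpha0 * ref * (k - 1) + beta0 * ref^2 * (k^2 - 1))
}

one_material_cfg <- function(seed, k = NULL, ner = NULL, phi = 0,
                             alpha0 = 0.04, beta0 = 0.0013, cv = 0.05,
                             conc = 160, lc50 = 2000) {
  if (is.null(ner)) ner <- ner_of_k(k, alpha0, beta0)
  generator_config(
    seed = seed, alpha0 = alpha0, beta0 = beta0, cv = cv,
    materials = data.frame(material = "TiO2", conc_ug_mL = conc,
                           ner = ner, phi = phi, lc50 = lc50,
                           b_tox = 0.025))
}
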