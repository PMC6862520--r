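# cohort spec with every class count zeroed unless overridden — small
# fixtures for unit tests (the constructor defaults are the full study).
cohort_spec0 <- function(...) {
  base <- list(n_t21 = 0, n_t18 = 0, n_t13 = 0, n_monosomy_x = 0,
               n_xxxy = 0, n_euploid_male = 0, n_euploid_female = 0)
  do.call(cohort_spec, utils::modifyList(base, list(...)))
}
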