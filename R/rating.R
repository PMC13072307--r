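#' Specification for simulated rater tables
#'
#' Two-way random-effects model: `y_ij = grand_mean + subject_i + rater_j +
#' e_ij`, all components drawn from centred normals with the stated SDs.
#' The population single-measures absolute-agreement ICC of such a table is
#' `subject_sd^2 / (subject_sd^2 + rater_sd^2 + error_sd^2)` (see
#' [true_icc()]).
#'
#' @param n_subjects,n_raters Table dimensions (>= 2 each).
#' @param subject_sd,rater_sd,error_sd Component standard deviations (>= 0).
#' @param grand_mean Overall mean measurement.
#' @param seed RNG seed.
#' @return A `rating_spec`.
#' @export
rating_spec <- function(n_subjects = 12L, n_raters = 2L,
                        subject_sd = 3, rater_sd = 1, error_sd = 1,
                        grand_mean = 10, seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2) stop_ovm("n_subjects must be >= 2")
  if (!is_count(n_raters) || n_raters < 2) stop_ovm("n_raters must be >= 2")
  for (nm in c("subject_sd", "rater_sd", "error_sd"))
    if (!is_scalar_num(get(nm)) || get(nm) < 0) stop_ovm("%s must be >= 0", nm)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_raters = as.integer(n_raters),
                 subject_sd = subject_sd, rater_sd = rater_sd,
                 error_sd = error_sd, grand_mean = grand_mean,
                 seed = as.integer(seed)),
            class = "rating_spec")
}

#' Population ICC of a rating specification
#'
#' The variance-ratio truth against which the estimator is validated:
#' `sigma_subject^2 / (sigma_subject^2 + sigma_rater^2 + sigma_error^2)`.
#'
#' @param spec A [rating_spec()].
#' @return The true single-measures absolute-agreement ICC.
#' @export
true_icc <- function(spec) {
  stopifnot(inherits(spec, "rating_spec"))
  v <- c(spec$subject_sd, spec$rater_sd, spec$error_sd)^2
  if (sum(v) == 0) stop_ovm("all variance components are zero; ICC undefined")
  v[1] / sum(v)
}

#' Simulate a subjects x raters measurement table
#'
#' @param spec A [rating_spec()].
#' @return A [rating_table()]. Values are shifted, if necessary, to stay
#'   non-negative (a rigid shift leaves every ICC unchanged).
#' @export
generate_rating_table <- function(spec) {
  stopifnot(inherits(spec, "rating_spec"))
  values <- with_seed(spec$seed, {
    subj <- rnorm(spec$n_subjects, 0, spec$subject_sd)
    rater <- rnorm(spec$n_raters, 0, spec$rater_sd)
    err <- matrix(rnorm(spec$n_subjects * spec$n_raters, 0, spec$error_sd),
                  spec$n_subjects, spec$n_raters)
    spec$grand_mean + outer(subj, rater, "+") + err
  })
  if (min(values) < 0) values <- values - min(values)
  rating_table(values)
}
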