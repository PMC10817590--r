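#' Cohort configuration
#'
#' Parameters of a sex-balanced synthetic cohort. Each participant
#' contributes both eyes, so a group of `n_per_group` participants yields
#' `2 * n_per_group` acquisitions. Ages are drawn from a normal distribution
#' truncated to `[age_min, age_max]`.
#'
#' @param n_per_group Participants per sex group (>= 2).
#' @param age_mean,age_sd Age distribution in years before truncation.
#' @param age_min,age_max Truncation bounds in years.
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 49, age_mean = 42.5, age_sd = 16.3,
                          age_min = 19, age_max = 74, seed = 1L) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1 || n_per_group < 2) {
    stop("`n_per_group` must be a single number >= 2", call. = FALSE)
  }
  if (!(age_min <= age_mean && age_mean <= age_max)) {
    stop("age bounds must satisfy age_min <= age_mean <= age_max", call. = FALSE)
  }
  if (age_sd < 0) stop("`age_sd` must be non-negative", call. = FALSE)
  structure(
    list(n_per_group = as.integer(n_per_group), age_mean = age_mean,
         age_sd = age_sd, age_min = age_min, age_max = age_max,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_group` female and `n_per_group` male participants with ages
#' from a truncated normal distribution (inverse-CDF sampling, so truncation
#' is exact). Deterministic given `config$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `participant_id`, `sex`
#'   (`"female"`/`"male"`) and `age` (years).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  ages <- with_preserved_rng(config$seed, {
    rtruncnorm(2L * n, config$age_mean, config$age_sd,
               config$age_min, config$age_max)
  })
  data.frame(
    participant_id = c(sprintf("F%03d", seq_len(n)), sprintf("M%03d", seq_len(n))),
    sex = rep(c("female", "male"), each = n),
    age = ages,
    stringsAsFactors = FALSE
  )
}

# Truncated normal draws by inverse-CDF; degenerate sd collapses to the mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}
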