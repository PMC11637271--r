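# Shared fixtures.  base_params() caches the default parameter set;
# no_death_params() switches off all mortality so closed-form annuity
# oracles apply exactly.

.fixture_env <- new.env(parent = emptyenv())

base_params <- function() {
  if (is.null(.fixture_env$base))
    .fixture_env$base <- default_parameters()
  .fixture_env$base
}

# zero background mortality and zero premature death; ex kept strictly
# decreasing to satisfy the life-table invariant
no_death_params <- function(params = base_params()) {
  ages <- 18:100
  params$life_table <- data.frame(age = ages, q = 0, ex = 100 - 0.9 * ages)
  params$premature_death$p_complication <- 0
  validate_parameters(unclass(params))
}

# single-band pre-operative pain mix
pure_mix <- function(band) {
  px <- stats::setNames(rep(0, 4), c("none", "mild", "moderate", "severe"))
  px[band] <- 1
  px
}

# closed-form annuity oracles, frozen from (1 - 1.03^-10)/0.03 and the
# average of end- and start-of-cycle discount sums
ANNUITY_10Y_3PC <- 8.530202837
ANNUITY_10Y_3PC_HCC <- 8.658155922
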