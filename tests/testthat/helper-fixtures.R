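# fixtures built in code; all stochastic helpers take an explicit seed

decay_observations <- function(k = 0.12, volumes = c(0, 5, 10, 15, 20, 25),
                               cv = 0, n_rep = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- rep(volumes, each = n_rep)
  r <- exp(-k * v)
  if (cv > 0) {
    sdl <- sqrt(log1p(cv^2))
    r <- r * rlnorm(length(r), -sdl^2 / 2, sdl)
  }
  data.frame(exposure_volume_ul = v, residual_activity = r)
}

linear_trace <- function(slope_per_min = 0.05, a0 = 0.2,
                         times = seq(0, 120, 10), sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- a0 + slope_per_min * times / 60
  if (sigma > 0) a <- a + rnorm(length(times), 0, sigma)
  absorbance_trace("A1", times, a)
}

# a minimal scored-well table: one plate, n_wt wild-type controls with
# given activities/ratios, plus sample wells
well_table <- function(wt_pre, wt_post, sample_pre, sample_post,
                       plate = 1L) {
  n_wt <- length(wt_pre); n_s <- length(sample_pre)
  data.frame(
    plate = plate,
    well = sprintf("X%d", seq_len(n_wt + n_s)),
    role = c(rep("wildtype_control", n_wt), rep("sample", n_s)),
    pre_activity = c(wt_pre, sample_pre),
    post_activity = c(wt_post, sample_post),
    stringsAsFactors = FALSE
  )
}
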