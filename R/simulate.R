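#' Configuration of a simulated fermentation experiment
#'
#' Describes a batch/fed-batch-like cultivation from which calibration data
#' are generated: logistic OD600 growth, a ground-truth catalog structure
#' mapping OD to PHA concentration, replicate OD readings with
#' multiplicative noise, additive Gaussian noise on the PHA reference
#' measurement (truncated at zero, concentrations being physical), and an
#' optional post-shift multiplicative bias on PHA that emulates a
#' plant-model mismatch after a process-mode change (e.g. switching from
#' batch to continuous operation).
#'
#' Defaults emulate a PHB batch cultivation sampled every 1-3 h over two
#' days: inoculation at OD 0.4, plateau near OD 55, 24 sampling points,
#' triplicate OD readings with 2% relative noise, and 0.1 g/L noise on the
#' chromatographic PHA reference.
#'
#' @param od0 Initial OD600 (> 0; default 0.4, a typical inoculation
#'   target).
#' @param od_max Plateau OD600 (> `od0`; default 55).
#' @param growth_rate Logistic rate constant in 1/h (default 0.25, placing
#'   mid-growth near 20 h).
#' @param sampling_times Strictly increasing sampling times in hours
#'   (default 24 points over 0-45 h).
#' @param truth_structure Catalog id of the ground-truth OD-to-PHA curve
#'   (default 7).
#' @param truth_params Named parameters of the truth curve (default the
#'   PHB reference parameters, see [reference_model()]).
#' @param pha_noise_sd Additive SD of the PHA measurement in g/L
#'   (default 0.1).
#' @param od_rel_noise_sd Relative SD of a single OD replicate
#'   (default 0.02).
#' @param replicates OD replicates per sample (default 3).
#' @param shift_time Process-shift time in hours, or `NA` for none.
#' @param shift_bias Multiplicative factor applied to true PHA at
#'   `time >= shift_time` (default 1 = no mismatch).
#' @param seed Integer seed; simulation is deterministic per seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(od0 = 0.4, od_max = 55, growth_rate = 0.25,
                              sampling_times = default_sampling_times(),
                              truth_structure = 7L,
                              truth_params = reference_model("PHB")$params,
                              pha_noise_sd = 0.1, od_rel_noise_sd = 0.02,
                              replicates = 3L, shift_time = NA_real_,
                              shift_bias = 1, seed = 1L) {
  if (od0 <= 0 || od_max <= od0 || growth_rate <= 0) {
    stop(input_error("need od_max > od0 > 0 and growth_rate > 0"))
  }
  if (any(diff(sampling_times) <= 0)) {
    stop(input_error("sampling_times must be strictly increasing"))
  }
  if (pha_noise_sd < 0 || od_rel_noise_sd < 0 || replicates < 1) {
    stop(input_error("noise SDs must be >= 0 and replicates >= 1"))
  }
  structure(
    list(od0 = od0, od_max = od_max, growth_rate = growth_rate,
         sampling_times = sampling_times,
         truth_structure = as.integer(truth_structure),
         truth_params = truth_params, pha_noise_sd = pha_noise_sd,
         od_rel_noise_sd = od_rel_noise_sd, replicates = as.integer(replicates),
         shift_time = shift_time, shift_bias = shift_bias,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# 24 samples over 0-45 h at 1-3 h spacing (denser early, as in practice)
default_sampling_times <- function() {
  c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24,
    26, 28, 31, 34, 37, 40, 43, 45)
}

#' Noise-free logistic OD trajectory
#'
#' `od(t) = od_max / (1 + ((od_max - od0)/od0) * exp(-growth_rate * t))`:
#' the simplest monotone sigmoid consistent with typical batch growth
#' curves, with `od(0) = od0` exactly and plateau `od_max`.
#'
#' @param config A [simulation_config()].
#' @param times Numeric times in hours (default the config's sampling
#'   times).
#' @return Data frame with columns `time_h`, `od_true`.
#' @export
simulate_od <- function(config, times = config$sampling_times) {
  stopifnot(inherits(config, "simulation_config"))
  k <- (config$od_max - config$od0) / config$od0
  od <- config$od_max / (1 + k * exp(-config$growth_rate * times))
  data.frame(time_h = times, od_true = od)
}

#' Generate one simulated calibration experiment
#'
#' Draws a full labelled dataset from a [simulation_config()]: true OD from
#' the logistic trajectory, `replicates` noisy OD readings per sample
#' (multiplicative Gaussian noise) summarised by their mean and SD, and a
#' PHA measurement `truth(od_true) * bias + N(0, pha_noise_sd)` truncated at
#' zero, where the bias is `shift_bias` from `shift_time` onwards and 1
#' before. The result is deterministic per seed and independent of the
#' global RNG state.
#'
#' @inheritParams simulate_od
#' @return A [calibration_set()] with an attribute `od_replicates` (matrix
#'   of the individual OD readings, samples x replicates) and `od_true`
#'   column preserved in attribute `truth`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)

  traj <- simulate_od(config)
  n <- nrow(traj)
  reps <- matrix(
    traj$od_true * (1 + stats::rnorm(n * config$replicates,
                                     sd = config$od_rel_noise_sd)),
    nrow = n
  )
  od_mean <- rowMeans(reps)
  od_sd <- if (config$replicates > 1) apply(reps, 1, stats::sd) else rep(0, n)

  truth <- model_structure(config$truth_structure)
  pha_true <- evaluate_model(truth, config$truth_params, traj$od_true)
  bias <- ifelse(!is.na(config$shift_time) & traj$time_h >= config$shift_time,
                 config$shift_bias, 1)
  pha <- pmax(pha_true * bias + stats::rnorm(n, sd = config$pha_noise_sd), 0)

  out <- calibration_set(
    od = od_mean, pha = pha, time_h = traj$time_h, od_sd = od_sd,
    pha_sd = config$pha_noise_sd, weight = 1,
    label = sprintf("simulated (structure %d, seed %d)",
                    config$truth_structure, config$seed)
  )
  attr(out, "od_replicates") <- reps
  attr(out, "truth") <- data.frame(time_h = traj$time_h,
                                   od_true = traj$od_true,
                                   pha_true = pha_true * bias)
  out
}

#' Generate a matched training/test pair emulating the two study processes
#'
#' Builds the data layout on which the workflow is exercised end to end:
#'
#' * `process = "PHB"`: training is a batch-like run with the PHB reference
#'   curve (structure 7) as ground truth; the test run emulates a
#'   batch-then-continuous process whose PHA falls 15% below the batch
#'   calibration after the 12 h shift (`shift_bias = 0.85`) — the
#'   plant-model mismatch that motivates the online update. The test
#'   sampling grid is laid out so that updates triggered at the phase
#'   shifts (12 h and 40 h) with a 2 h measurement lag are applied at the
#'   14 h and 43 h samplings, using 9 and 20 new points.
#' * `process = "PHBV"`: training and test are fed-batch-like runs with the
#'   PHBV reference power law (structure 1) as ground truth and no shift;
#'   the test run differs only in its noise draw and a slightly higher
#'   plateau.
#'
#' @param process `"PHB"` or `"PHBV"`.
#' @param seed Integer seed; the training and test draws use distinct
#'   sub-streams derived from it.
#' @return List with elements `training` and `test`
#'   ([calibration_set()]s) and the two `simulation_config`s used.
#' @export
make_paperlike_pair <- function(process = c("PHB", "PHBV"), seed = 1L) {
  process <- match.arg(process)
  seed <- as.integer(seed)
  if (process == "PHB") {
    train_cfg <- simulation_config(seed = seed)
    test_cfg <- simulation_config(
      od_max = 60, growth_rate = 0.22,
      sampling_times = phb_test_sampling_times(),
      shift_time = 12, shift_bias = 0.85, seed = seed + 20000L
    )
  } else {
    ref <- reference_model("PHBV")
    train_cfg <- simulation_config(
      od_max = 35, growth_rate = 0.3,
      sampling_times = seq(0, 23, by = 1),
      truth_structure = 1L, truth_params = ref$params,
      seed = seed
    )
    test_cfg <- simulation_config(
      od_max = 40, growth_rate = 0.28,
      sampling_times = seq(0, 27, by = 1),
      truth_structure = 1L, truth_params = ref$params,
      seed = seed + 20000L
    )
  }
  list(training = simulate_experiment(train_cfg),
       test = simulate_experiment(test_cfg),
       training_config = train_cfg, test_config = test_cfg)
}

# 24 samplings for the continuous-mode test run: 9 points at or before the
# 12 h shift, a sampling at 14 h (first after 12 h + 2 h lag), 20 points at
# or before 41 h, and a sampling at 43 h (first after 40 h + 2 h lag).
phb_test_sampling_times <- function() {
  c(0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12,
    14, 16, 18.5, 21, 23.5, 26, 28.5, 31, 33.5, 36, 38.5,
    43, 45, 47, 48)
}
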