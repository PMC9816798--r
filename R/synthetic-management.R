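#' Default effect sizes for the management-factor generator
#'
#' Additive yield effects (t/ha) per factor level. Seeding rate follows an
#' inverted U peaking at 225 kg/ha (0.8 times the conventional rate; denser
#' sowing raises competition for water, nutrients and light and promotes
#' lodging). Irrigation increases yield monotonically up to 60 mm. Rotational
#' tillage and variable-rate fertilization carry the largest categorical
#' effects.
#'
#' @return Named list of effect specifications.
#' @export
default_management_effects <- function() {
  list(
    seeding_levels = c(150, 225, 300, 375),          # kg/ha
    seeding_peak = 225,
    seeding_curvature = 0.6,   # t/ha lost per unit of ((rate-peak)/150)^2
    tillage = c(Subsoiling = 0.00, Tillage = 0.10,
                Rotatillage = 0.35, Rototilling = 0.15),
    fertilizer = c(constant = 0.00, variable = 0.30),
    irrigation_levels = c(0, 20, 40, 60),            # mm
    irrigation_gain = 0.5,     # t/ha at full (60 mm) irrigation
    base_yield = 3.8,
    noise_sd = 0.25
  )
}

#' Generate a planting-management experiment table
#'
#' Samples random factor combinations (seeding rate, tillage method,
#' fertilization mode, irrigation amount) and draws yields from an additive
#' effects model plus Gaussian noise, clipped to the configured yield range.
#' Under the default effects, expected yield peaks at a 225 kg/ha seeding
#' rate, increases monotonically with irrigation up to 60 mm, and is highest
#' under rotational tillage and variable fertilization.
#'
#' @param config A [scene_config()] (supplies the yield range and seed).
#' @param n Number of samples (rows).
#' @param effects Effect specification, see [default_management_effects()].
#'   Set the numeric effect entries to zero for a null experiment.
#' @return A `data.frame` with columns `seeding_rate` (kg/ha), `tillage`,
#'   `fertilizer` (factors), `irrigation_mm`, and `yield` (t/ha).
#' @examples
#' tb <- generate_management_table(scene_config(seed = 4), n = 80)
#' aggregate(yield ~ seeding_rate, tb, mean)
#' @export
generate_management_table <- function(config, n = 160,
                                      effects = default_management_effects()) {
  config <- validate_scene_config(config)
  stopifnot(n >= 8)
  set.seed(config$seed + 3L)
  e <- effects

  seeding <- sample(e$seeding_levels, n, replace = TRUE)
  tillage <- sample(names(e$tillage), n, replace = TRUE)
  fertilizer <- sample(names(e$fertilizer), n, replace = TRUE)
  irrigation <- sample(e$irrigation_levels, n, replace = TRUE)

  mu <- e$base_yield -
    e$seeding_curvature * ((seeding - e$seeding_peak) / 150)^2 +
    unname(e$tillage[tillage]) +
    unname(e$fertilizer[fertilizer]) +
    e$irrigation_gain * irrigation / max(e$irrigation_levels, 1)

  y <- mu + stats::rnorm(n, sd = e$noise_sd)
  y <- pmin(pmax(y, config$yield_min), config$yield_max)

  data.frame(
    seeding_rate = seeding,
    tillage = factor(tillage, levels = names(e$tillage)),
    fertilizer = factor(fertilizer, levels = names(e$fertilizer)),
    irrigation_mm = irrigation,
    yield = y
  )
}
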