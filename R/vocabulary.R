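#' Controlled feature vocabulary
#'
#' The pipeline computes a fixed set of features: 10 summary gait features
#' available from any walking bout with at least two valid strides, 4 gated
#' gait features restricted to long bouts (sample-entropy ratio measures need
#' more than 30 s of walking, Lyapunov exponents more than 60 s), and 13
#' postural-sway features computed from standing bouts of 30 s or longer.
#' Feature tables are validated against this vocabulary on read and write.
#'
#' @return A tibble with columns `feature_name`, `domain` (one of `"gait"`,
#'   `"gait_gated"`, `"sway"`), `min_bout_s` (minimum bout duration in
#'   seconds) and `gate_strict` (`TRUE` when the bout must be strictly longer
#'   than `min_bout_s`).
#' @examples
#' feature_vocabulary()
#' @export
feature_vocabulary <- function() {
  gait <- c(
    "stride_duration", "stance_duration", "swing_duration", "duty_factor",
    "double_support_duration", "duty_factor_asymmetry",
    "correlation_asymmetry", "acceleration_asymmetry", "rms_ap",
    "frequency_dispersion_ml"
  )
  gated <- c("entropy_ratio", "entropy_ratio_asymmetry",
             "lyapunov_ap", "lyapunov_ml")
  sway <- c(
    "sway_area_per_s", "centroidal_frequency", "distance", "f50", "f95",
    "frequency_dispersion", "jerk", "mean_period", "mean_velocity",
    "path_per_s", "power", "range", "rms"
  )
  tibble::tibble(
    feature_name = c(gait, gated, sway),
    domain = c(rep("gait", length(gait)), rep("gait_gated", length(gated)),
               rep("sway", length(sway))),
    min_bout_s = c(rep(0, length(gait)),
                   30, 30, 60, 60,
                   rep(30, length(sway))),
    gate_strict = c(rep(FALSE, length(gait)),
                    TRUE, TRUE, TRUE, TRUE,
                    rep(FALSE, length(sway)))
  )
}

#' Names of features in one domain
#'
#' @param domain One of `"gait"`, `"gait_gated"`, `"sway"`, or `"all"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(domain = c("all", "gait", "gait_gated", "sway")) {
  domain <- match.arg(domain)
  vocab <- feature_vocabulary()
  if (domain == "all") vocab$feature_name
  else vocab$feature_name[vocab$domain == domain]
}

# Check feature names and bout-duration gates; stops on violation.
validate_feature_observations <- function(obs, call = rlang::caller_env()) {
  vocab <- feature_vocabulary()
  unknown <- setdiff(unique(obs$feature_name), vocab$feature_name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown feature name(s): ", paste(unknown, collapse = ", ")),
          class = "weartime_vocab_error", call = call)
  }
  gate <- vocab[match(obs$feature_name, vocab$feature_name), ]
  bad <- ifelse(gate$gate_strict,
                obs$bout_duration <= gate$min_bout_s,
                obs$bout_duration < gate$min_bout_s)
  if (any(bad, na.rm = TRUE)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Bout-duration gate violated for feature '%s': bout_duration %.3g s (row %d) %s %g s required",
      obs$feature_name[i], obs$bout_duration[i], i,
      if (gate$gate_strict[i]) "but more than" else "but at least",
      gate$min_bout_s[i]
    ), class = "weartime_gate_error", call = call)
  }
  invisible(obs)
}
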