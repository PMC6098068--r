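#' Movement-process parameters for the two-state switching random walk
#'
#' Bundles the state-specific movement parameters of the switching
#' first-difference correlated random walk: persistence `gamma` (autocorrelation
#' in speed and direction; state 1 = transit must exceed state 2 = search),
#' mean turn angles `theta` (radians; near 0 in transit, near pi in search),
#' Markov self-transition probabilities `stay_prob`, and the per-whale process
#' (step) standard deviation `process_sd` in km per 12 h.
#'
#' @param gamma length-2 numeric, `0 <= gamma[2] < gamma[1] <= 1`
#' @param theta length-2 numeric, wrapped to (-pi, pi] for state 1 and treated
#'   modulo 2*pi for state 2
#' @param stay_prob length-2 numeric in (0, 1): P(stay in transit), P(stay in
#'   search)
#' @param process_sd positive numeric, one value per whale (recycled). The
#'   default of 18 km per 12 h reproduces the observed scale of migratory
#'   travel (roughly 78 km per day in transit once the persistence of the
#'   transit state is accounted for).
#' @return an object of class `movement_params`
#' @examples
#' movement_params(gamma = c(0.82, 0.11), theta = c(0, pi),
#'                 stay_prob = c(0.9, 0.9), process_sd = 18)
#' @export
movement_params <- function(gamma = c(0.82, 0.11), theta = c(0, pi),
                            stay_prob = c(0.9, 0.9), process_sd = 18) {
  stopifnot(length(gamma) == 2, length(theta) == 2, length(stay_prob) == 2)
  if (!(gamma[1] <= 1 && gamma[2] >= 0 && gamma[2] < gamma[1]))
    stop("identifiability requires 0 <= gamma[2] < gamma[1] <= 1")
  if (any(stay_prob <= 0 | stay_prob >= 1))
    stop("stay_prob components must lie in (0, 1)")
  if (any(process_sd <= 0)) stop("process_sd must be positive for every whale")
  structure(list(gamma = as.numeric(gamma), theta = as.numeric(theta),
                 stay_prob = as.numeric(stay_prob),
                 process_sd = as.numeric(process_sd)),
            class = "movement_params")
}

#' Argos location-class error model
#'
#' Heavy-tailed (Student-t) location error scales per Argos location class.
#' Classes 3, 2, 1, 0, A, B carry usable positions with error scales that
#' increase from class 3 to class B; class Z is an invalid fix with no usable
#' location. The published literature gives a rough error ladder but no single
#' canonical table, so the scales are configurable; the default is a
#' 0.3 / 0.5 / 1 / 2 / 5 / 10 km ladder with 5 degrees of freedom, applied
#' independently to the east and north error components.
#'
#' @param scale_km named numeric: t-distribution scale (km) per class 3..B,
#'   strictly increasing from 3 to B
#' @param df degrees of freedom per class (recycled)
#' @param class_freq sampling frequencies per class (must sum to 1); the
#'   default is weighted towards the poor-quality A/B classes typical of
#'   whale-deployed tags
#' @return an object of class `argos_error_model`
#' @export
argos_error_model <- function(scale_km = c(`3` = 0.3, `2` = 0.5, `1` = 1,
                                           `0` = 2, A = 5, B = 10),
                              df = 5,
                              class_freq = c(`3` = 0.08, `2` = 0.10, `1` = 0.15,
                                             `0` = 0.17, A = 0.25, B = 0.25)) {
  cls <- c("3", "2", "1", "0", "A", "B")
  stopifnot(setequal(names(scale_km), cls), setequal(names(class_freq), cls))
  scale_km <- scale_km[cls]; class_freq <- class_freq[cls]
  if (any(diff(scale_km) <= 0))
    stop("error scales must strictly increase from class 3 to class B")
  if (abs(sum(class_freq) - 1) > 1e-8) stop("class frequencies must sum to 1")
  df <- rep_len(df, 6); names(df) <- cls
  structure(list(scale_km = scale_km, df = df, class_freq = class_freq),
            class = "argos_error_model")
}

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")
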