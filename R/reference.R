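# Published reference values from the field study this package's methods
# reproduce: per-species canopy temperature statistics along the diagonal
# cross-sections, and per-species classification scores of the evaluated
# CNN models. Used as simulator calibration, as inputs to the table
# arithmetic (contrasts, spans, average-per-class aggregation), and as
# fixtures in tests.

#' Reference canopy temperature statistics
#'
#' Cross-section temperature statistics (degC) of gas-stressed
#' (experimental) and control plots for the four vegetation types, as
#' measured in the field study the simulator is calibrated against.
#'
#' @return data frame with `species`, `condition`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
reference_canopy_stats <- function() {
  data.frame(
    species = rep(c("grass", "soybean", "corn", "wheat"), each = 2),
    condition = rep(c("experimental", "control"), 4),
    mean = c(31.07, 27.53, 35.36, 32.02, 30.56, 27.46, 30.98, 27.58),
    sd   = c(3.35, 0.67, 4.07, 0.96, 3.51, 0.52, 2.97, 1.48),
    min  = c(26.00, 26.06, 29.63, 30.06, 26.13, 25.44, 25.31, 25.31),
    max  = c(37.13, 29.44, 46.38, 34.88, 38.38, 29.00, 38.38, 34.81))
}

#' Reference classification scores
#'
#' Per-species accuracy, recall and specificity (percent) of the evaluated
#' models on the field test set. `model` selects among the five compared
#' architectures plus the transfer-learning variant (`"GLNB-TL"`).
#'
#' @param model model name.
#' @return data frame with `species`, `accuracy`, `recall`, `specificity`.
#' @export
reference_classification_scores <- function(model = c("GLNB-TL", "GLNB",
                                                      "AlexNet", "VGG16",
                                                      "GoogLeNet", "ResNet")) {
  model <- match.arg(model)
  species <- c("grass", "soybean", "corn", "wheat")
  tab <- switch(model,
    "AlexNet" = list(acc = c(94.39, 85.05, 85.98, 85.98),
                     rec = c(96.15, 85.71, 90.63, 88.14),
                     spe = c(92.73, 84.31, 84.00, 83.33)),
    "VGG16" = list(acc = c(90.65, 82.24, 86.92, 90.65),
                   rec = c(92.31, 76.79, 87.50, 91.53),
                   spe = c(89.09, 88.24, 86.67, 89.58)),
    "GoogLeNet" = list(acc = c(89.72, 86.92, 81.31, 87.85),
                       rec = c(88.46, 83.93, 81.25, 89.83),
                       spe = c(90.91, 90.20, 81.33, 85.42)),
    "ResNet" = list(acc = c(91.59, 79.44, 83.18, 84.11),
                    rec = c(90.38, 78.57, 90.63, 86.44),
                    spe = c(92.73, 80.39, 80.00, 81.25)),
    "GLNB" = list(acc = c(95.33, 90.65, 88.79, 91.59),
                  rec = c(96.15, 89.29, 90.63, 93.22),
                  spe = c(94.55, 92.16, 88.00, 89.58)),
    "GLNB-TL" = list(acc = c(98.13, 96.26, 91.59, 95.33),
                     rec = c(98.08, 96.43, 90.63, 94.92),
                     spe = c(98.18, 96.08, 92.00, 95.83)))
  data.frame(species = species, accuracy = tab$acc, recall = tab$rec,
             specificity = tab$spe)
}
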