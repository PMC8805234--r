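#' Forest plot of estimate records
#'
#' Draws point estimates with 95% confidence intervals for a tidy estimate
#' tibble (rows from [mv_regress()], [tsls()], [ratio_estimate()], ...),
#' grouped by outcome.
#'
#' @param records Estimate tibble with `method`, `outcome`, `beta`,
#'   `ci_low`, `ci_high`.
#' @return A ggplot object.
#' @export
plot_estimates <- function(records) {
  records$label <- paste(records$method,
                         ifelse(is.na(records$outcome), "", records$outcome))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "effect (SD outcome per SD exposure)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a meta-analysis
#'
#' Member estimates as points sized by pooling weight, with the pooled
#' estimate below.
#'
#' @param object An `ntmr_meta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ntmr_meta <- function(object, ...) {
  mem <- tidy(object)
  mem$label <- mem$stratum %||% paste("study", seq_len(nrow(mem)))
  if (all(is.na(mem$label))) mem$label <- paste("study", seq_len(nrow(mem)))
  pooled <- glance(object)
  pooled$label <- sprintf("pooled (%s)", object$method)
  pooled$weight <- NA_real_
  cols <- c("label", "beta", "se", "weight")
  mem$ci_low <- mem$beta - qnorm(0.975) * mem$se
  mem$ci_high <- mem$beta + qnorm(0.975) * mem$se
  dat <- dplyr::bind_rows(
    mem[, c(cols, "ci_low", "ci_high")],
    pooled[, c("label", "beta", "se", "weight", "ci_low", "ci_high")]
  )
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "pooled effect (SD per SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MR estimates across SNP effect-size bins
#'
#' Visualises the output of [effect_size_stratified_mr()]: per-bin MR
#' estimates with CIs against the bin median absolute SNP weight.
#'
#' @param strat Output of [effect_size_stratified_mr()].
#' @return A ggplot object.
#' @export
plot_effect_size_gradient <- function(strat) {
  ggplot2::ggplot(strat$per_bin,
                  ggplot2::aes(x = .data$median_abs_weight, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "bin median |SNP weight|",
                  y = "MR estimate (SD per SD)") +
    ggplot2::theme_minimal()
}
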