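#' @export
tidy.filter_report <- function(x, ...) {
  bind_rows(
    mutate(x$surviving, status = "surviving", reason = NA_character_),
    mutate(x$fail_reasons, status = "failed")
  ) |>
    arrange(.data$chrom, .data$pos, .data$alt)
}

#' @export
glance.filter_report <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' @export
tidy.deficiency_result <- function(x, ...) {
  tibble(observed = x$observed, expected = x$expected, deficit = x$deficit,
         deficit_percent = round_half_up(100 * x$deficit),
         p_value = x$p_value, model = x$model)
}

#' @export
glance.deficiency_result <- function(x, ...) tidy(x)

#' @export
tidy.hwe_result <- function(x, ...) {
  tibble(genotype = c("hom_ref", "het", "hom_alt"),
         observed = x$observed, expected = x$expected)
}

#' @export
glance.hwe_result <- function(x, ...) {
  tibble(n = x$n, q_hat = x$q_hat, chi2 = x$chi2, df = x$df,
         p_value = x$p_value)
}

#' @export
tidy.segregation_result <- function(x, ...) {
  tibble(genotype = names(x$observed), observed = unname(x$observed),
         expected = unname(x$expected))
}

#' @export
glance.segregation_result <- function(x, ...) {
  tibble(n_offspring = x$n_offspring, chi2 = x$chi2, df = x$df,
         p_value = x$p_value, n_mendelian_errors = nrow(x$mendelian_errors))
}

#' @export
tidy.concordance_audit <- function(x, ...) x$breakdown

#' @export
glance.concordance_audit <- function(x, ...) {
  tibble(n = x$n, n_discordant = x$n_discordant, n_missing = x$n_missing)
}

#' Plot the prioritization funnel
#'
#' Bar chart of variant counts surviving each filter stage.
#'
#' @param object A `filter_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_report <- function(object, ...) {
  cts <- object$counts[!is.na(object$counts)]
  stages <- factor(names(cts), levels = names(object$counts))
  ggplot2::ggplot(tibble(stage = stages, n = as.numeric(cts)),
                  ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Candidate-variant filter funnel") +
    ggplot2::theme_minimal()
}

obs_exp_plot <- function(tb, title) {
  long <- tidyr::pivot_longer(tb, c("observed", "expected"),
                              names_to = "type", values_to = "count")
  long$genotype <- factor(long$genotype,
                          levels = c("hom_ref", "het", "hom_alt"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genotype, y = .data$count,
                                     fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "lambs", fill = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.filter_report
#' @export
autoplot.hwe_result <- function(object, ...) {
  obs_exp_plot(tidy(object), "Observed vs Hardy-Weinberg expected counts")
}

#' @rdname autoplot.filter_report
#' @export
autoplot.segregation_result <- function(object, ...) {
  obs_exp_plot(tidy(object), "Observed vs Mendelian expected counts")
}

#' Plot average daily gain by genotype
#'
#' Boxplot of 0-15 day average daily gain for at-risk-mating lambs split
#' by genotype at the candidate variant, the comparison in which
#' homozygous carriers show their growth deficit.
#'
#' @param matings A mating tibble (see [read_matings()] /
#'   [simulate_matings()]).
#' @return A ggplot object.
#' @export
plot_adg <- function(matings) {
  x <- filter(as_tibble(matings), !is.na(.data$genotype))
  x$genotype <- factor(x$genotype, levels = c("hom_ref", "het", "hom_alt"))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$genotype, y = .data$adg_0_15)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6,
                         ggplot2::aes(colour = .data$sex)) +
    ggplot2::labs(x = NULL, y = "ADG days 0-15 (g/day)",
                  title = "Growth by candidate-variant genotype") +
    ggplot2::theme_minimal()
}
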