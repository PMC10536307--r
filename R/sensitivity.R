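# Contribution-to-variance sensitivity analysis of the simulated HQ.
#
# Spearman rank correlations of each model input with the HQ, squared and
# normalized to percentages — the convention of spreadsheet Monte Carlo
# tools' "contribution to variance" tornado charts. Signed correlations
# are retained so a divisor input (body weight) shows its negative
# direction while still contributing positively.

sensitivity_inputs <- c("concentration", "intake", "body_weight")

#' Contribution of each input to the variance of the hazard quotient
#'
#' @param draws Per-iteration draws tibble with columns `concentration`,
#'   `intake`, `body_weight` and `hq`, as stored by
#'   [simulate_hq()]`(keep_draws = TRUE)`. At least 1000 iterations are
#'   recommended for stable contributions.
#' @return A tibble with `input`, `rho` (signed Spearman correlation with
#'   the HQ) and `contribution_pct` (`100 * rho^2 / sum(rho^2)`, summing
#'   to 100).
#' @export
contribution_to_variance <- function(draws) {
  need <- c(sensitivity_inputs, "hq")
  missing <- setdiff(need, names(draws))
  if (length(missing)) {
    abort(paste0("draws lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(draws) < 2) abort("need at least 2 iterations")
  if (nrow(draws) < 1000) {
    warn("fewer than 1000 iterations; contributions will be noisy")
  }
  if (sd(draws$hq) == 0) {
    abort("degenerate simulation: hazard quotient has zero variance")
  }
  rho <- vapply(sensitivity_inputs, function(col) {
    x <- draws[[col]]
    if (sd(x) == 0) return(0)
    cor(x, draws$hq, method = "spearman")
  }, numeric(1))
  rho[is.na(rho)] <- 0
  tibble(input = sensitivity_inputs, rho = unname(rho),
         contribution_pct = 100 * unname(rho)^2 / sum(rho^2))
}

#' Sensitivity table over a probabilistic assessment grid
#'
#' Runs [contribution_to_variance()] on every row of an
#' [assess_probabilistic()] result that kept its draws.
#'
#' @param mc Result of `assess_probabilistic(..., keep_draws = TRUE)`.
#' @return A tibble with `analyte`, `age_group`, `input`, `rho`,
#'   `contribution_pct`.
#' @export
sensitivity_table <- function(mc) {
  if (!"draws" %in% names(mc)) {
    abort("run assess_probabilistic() with keep_draws = TRUE first")
  }
  out <- lapply(seq_len(nrow(mc)), function(i) {
    res <- contribution_to_variance(mc$draws[[i]])
    dplyr::bind_cols(tibble(analyte = mc$analyte[i],
                            age_group = mc$age_group[i]), res)
  })
  dplyr::bind_rows(out)
}

#' Tornado-style bar chart of input contributions
#'
#' @param contrib Output of [contribution_to_variance()] or
#'   [sensitivity_table()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(contrib) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  p <- ggplot2::ggplot(contrib, ggplot2::aes(
    x = .data$contribution_pct,
    y = stats::reorder(.data$input, .data$contribution_pct))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Contribution to HQ variance (%)", y = NULL)
  if ("analyte" %in% names(contrib)) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$analyte),
      cols = if ("age_group" %in% names(contrib))
        ggplot2::vars(.data$age_group) else NULL)
  }
  p
}
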