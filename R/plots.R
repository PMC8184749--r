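#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point labs
#'   scale_y_log10 theme_minimal geom_hline
#' @export
ggplot2::autoplot

#' Plot module sizes of a partition
#'
#' Bar chart of module sizes (unassigned genes shown as their own bar).
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.module_partition <- function(object, ...) {
  df <- tidy.module_partition(object) |>
    dplyr::count(.data$module, name = "size")
  df$module <- factor(df$module,
                      levels = c(names(object$module_sizes), "unassigned"))
  ggplot(df, aes(x = .data$module, y = .data$size)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "genes",
         title = paste0("Module sizes (", object$network_label, ")")) +
    theme_minimal()
}

#' Plot five-hypothesis colocalization posteriors
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coloc_result <- function(object, ...) {
  df <- tidy.coloc_result(object)
  ggplot(df, aes(x = .data$hypothesis, y = .data$posterior)) +
    geom_col(fill = "darkorange") +
    geom_hline(yintercept = 0.75, linetype = "dashed") +
    labs(x = NULL, y = "posterior probability",
         title = sprintf("Colocalization posteriors (%d SNPs)",
                         object$n_snps)) +
    theme_minimal()
}

#' Neighborhood size vs BAN p-value
#'
#' Scatter of each tested gene's 3-step neighborhood size against its
#' hypergeometric enrichment p-value, BAN calls highlighted.
#'
#' @param ban BAN tibble from [run_ban()].
#' @return A ggplot object.
#' @export
plot_ban_overview <- function(ban) {
  ggplot(ban, aes(x = .data$k, y = .data$p_value,
                  colour = .data$is_ban)) +
    geom_point(alpha = 0.7) +
    scale_y_log10() +
    geom_hline(yintercept = 0.05, linetype = "dashed") +
    labs(x = "3-step neighborhood size", y = "hypergeometric p",
         colour = "BAN") +
    theme_minimal()
}
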