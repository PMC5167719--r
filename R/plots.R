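# Quick-look figures: objective-space scatter of fronts and datasets, and
# trait trajectories. All return ggplot objects.

#' Plot an optimization result in objective space
#'
#' Archive (and optionally final population) projected on the three trait
#' pairs, on the trait scale (DM, SR, SU).
#'
#' @param object An `nsga_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nsga_result
#' @export
autoplot.nsga_result <- function(object, ...) {
  arch <- object$archive %>%
    mutate(DM = -.data$obj1, SR = .data$obj2, SU = -.data$obj3)
  long <- tidyr::pivot_longer(
    arch %>% select("DM", "SR", "SU") %>%
      mutate(DM2 = .data$DM, SR2 = .data$SR, SU2 = .data$SU),
    cols = c("DM", "SR", "SU"), names_to = "xtrait", values_to = "x"
  )
  pairs <- bind_rows(
    arch %>% mutate(x = .data$DM, y = .data$SR, panel = "SR vs DM"),
    arch %>% mutate(x = .data$DM, y = .data$SU, panel = "SU vs DM"),
    arch %>% mutate(x = .data$SU, y = .data$SR, panel = "SR vs SU")
  )
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#00589c") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Non-dominated archive in trait space") +
    ggplot2::theme_minimal()
}

#' Plot a fruit trajectory
#'
#' Dry masses, stone ratio and sugar concentration against days after
#' bloom.
#'
#' @param object A `fruit_trajectory` from [simulate_trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fruit_trajectory
#' @export
autoplot.fruit_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object) %>%
      select("day", "dm_fruit", "dm_stone", "dm_flesh", "sr", "su"),
    cols = -"day", names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(colour = "#b04a00") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "days after bloom", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare random and optimized datasets in trait space
#'
#' @param random_ds,optimized_ds Datasets with `DM`, `SR`, `SU` columns.
#' @return A ggplot with one panel per trait pair.
#' @export
plot_dataset_comparison <- function(random_ds, optimized_ds) {
  tag <- function(ds, which) {
    as_tibble(ds) %>% select("DM", "SR", "SU") %>% mutate(set = which)
  }
  both <- bind_rows(tag(random_ds, "random"), tag(optimized_ds, "optimized"))
  pairs <- bind_rows(
    both %>% mutate(x = .data$DM, y = .data$SR, panel = "SR vs DM"),
    both %>% mutate(x = .data$DM, y = .data$SU, panel = "SU vs DM"),
    both %>% mutate(x = .data$SU, y = .data$SR, panel = "SR vs SU")
  )
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_colour_manual(values = c(random = "grey55",
                                            optimized = "#c0154f")) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
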