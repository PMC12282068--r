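## Broom-style tidiers and ggplot2 figures for the result objects, so
## solutions, trajectories and samples drop straight into dplyr/ggplot
## pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble `reaction_id`, `flux`, `is_enzyme_usage`.
#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(reaction_id = names(x$fluxes),
                 flux = unname(x$fluxes),
                 is_enzyme_usage = names(x$fluxes) %in%
                   names(x$enzyme_usage))
}

#' Glance at a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return One-row tibble: `status`, `objective_kind`,
#'   `objective_value`, `n_reactions`, `total_enzyme_usage`.
#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective_kind = x$objective_kind,
                 objective_value = x$objective_value,
                 n_reactions = length(x$fluxes),
                 total_enzyme_usage = if (length(x$enzyme_usage)) {
                   sum(x$enzyme_usage)
                 } else NA_real_)
}

#' Tidy a simulated trajectory
#'
#' @param x A `dfba_trajectory`.
#' @param what `"states"` (default; long `time`, `variable`, `value`),
#'   `"fluxes"` or `"usage"` (long per-interval values with `phase`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dfba_trajectory
#' @export
tidy.dfba_trajectory <- function(x, what = c("states", "fluxes", "usage"),
                                 ...) {
  what <- match.arg(what)
  if (what == "states") {
    out <- tidyr::pivot_longer(x$states, -"t", names_to = "variable",
                               values_to = "value")
    return(dplyr::rename(out, time = "t"))
  }
  purrr::imap_dfr(x$solutions, function(s, k) {
    v <- if (what == "fluxes") s$fluxes else s$enzyme_usage
    tibble::tibble(interval = k, time = x$states$t[k],
                   phase = x$phase_labels[k],
                   id = names(v), value = unname(v))
  })
}

#' Glance at a simulated trajectory
#'
#' @param x A `dfba_trajectory`.
#' @param ... Unused.
#' @return One-row tibble: interval count, dt, time span, phase count,
#'   final biomass.
#' @method glance dfba_trajectory
#' @export
glance.dfba_trajectory <- function(x, ...) {
  tibble::tibble(n_intervals = length(x$solutions), dt = x$dt,
                 t_start = min(x$states$t), t_end = max(x$states$t),
                 n_phases = length(unique(x$phase_labels)),
                 final_biomass = x$states$biomass[nrow(x$states)])
}

#' Tidy a flux sample
#'
#' @param x A `flux_sample`.
#' @param reaction_ids Reactions to keep (default all).
#' @param ... Unused.
#' @return Tibble `sample`, `reaction_id`, `flux`.
#' @method tidy flux_sample
#' @export
tidy.flux_sample <- function(x, reaction_ids = NULL, ...) {
  if (is.null(reaction_ids)) reaction_ids <- x$reaction_ids
  mat <- x$matrix[, reaction_ids, drop = FALSE]
  tibble::tibble(
    sample = rep(seq_len(nrow(mat)), times = length(reaction_ids)),
    reaction_id = rep(reaction_ids, each = nrow(mat)),
    flux = as.vector(mat))
}

#' Plot a simulated trajectory
#'
#' Concentration and biomass curves over time (`type =
#' "concentrations"`), or enzyme-usage fluxes per interval (`type =
#' "usage"`), with phase switches marked.
#'
#' @param object A `dfba_trajectory`.
#' @param type What to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dfba_trajectory
#' @export
autoplot.dfba_trajectory <- function(object,
                                     type = c("concentrations", "usage"),
                                     ...) {
  type <- match.arg(type)
  switches <- object$states$t[which(diff(object$phase_labels) != 0) + 1]
  if (type == "concentrations") {
    df <- tidy(object)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                          colour = .data$variable)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "concentration (g/L), biomass (gDW/L)",
                    colour = NULL)
  } else {
    df <- tidy(object, what = "usage")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                          colour = .data$id)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "enzyme usage (mmol/gDW/h)",
                    colour = NULL)
  }
  if (length(switches)) {
    p <- p + ggplot2::geom_vline(xintercept = switches,
                                 linetype = "dashed", colour = "grey50")
  }
  p + ggplot2::theme_minimal()
}

#' Plot sampled flux distributions
#'
#' Histograms of the sampled fluxes for chosen reactions, optionally
#' overlaying a solution's predicted fluxes.
#'
#' @param object A `flux_sample`.
#' @param reaction_ids Reactions to show (default: the 6 widest).
#' @param solution Optional `flux_solution` drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flux_sample
#' @export
autoplot.flux_sample <- function(object, reaction_ids = NULL,
                                 solution = NULL, ...) {
  if (is.null(reaction_ids)) {
    spread <- apply(object$matrix, 2, function(v) diff(range(v)))
    reaction_ids <- names(sort(spread, decreasing = TRUE))[
      seq_len(min(6, length(spread)))]
  }
  df <- tidy(object, reaction_ids)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$flux)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~reaction_id, scales = "free") +
    ggplot2::labs(x = "flux (mmol/gDW/h)", y = "samples")
  if (!is.null(solution)) {
    vl <- tibble::tibble(reaction_id = reaction_ids,
                         flux = unname(solution$fluxes[reaction_ids]))
    p <- p + ggplot2::geom_vline(data = vl,
                                 ggplot2::aes(xintercept = .data$flux),
                                 colour = "red")
  }
  p + ggplot2::theme_minimal()
}
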