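# broom-style tidiers and ggplot2 methods for fitted models.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_abline
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted model
#'
#' One row per epoch with the training loss and the six validation
#' metrics.
#'
#' @param x An `event_gnn` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.event_gnn <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x An `event_gnn` object.
#' @param ... Unused.
#' @return Tibble with the graph size, best epoch and best validation
#'   AUC.
#' @export
glance.event_gnn <- function(x, ...) {
  tibble(
    n_events = x$graph$n_events,
    n_diseases = x$graph$n_diseases,
    n_train_pos = nrow(x$split$train_pos),
    epochs = x$config$epochs,
    best_epoch = x$best_epoch,
    best_val_auc = x$best_val_auc,
    final_loss = x$history$loss[nrow(x$history)]
  )
}

#' Plot training loss and validation AUC over epochs
#'
#' @param object An `event_gnn` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.event_gnn <- function(object, ...) {
  hist_long <- object$history |>
    select(epoch, loss, auc) |>
    tidyr::pivot_longer(c(loss, auc), names_to = "metric",
                        values_to = "value")
  ggplot(hist_long, aes(x = epoch, y = value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL,
         title = "Training loss and validation AUC") +
    theme_minimal()
}

#' Plot ROC and precision–recall curves for scored edges
#'
#' @param labels Binary 0/1 vector.
#' @param scores Predicted probabilities or scores.
#' @return A ggplot with the two curves side by side.
#' @export
plot_curves <- function(labels, scores) {
  roc <- roc_points(labels, scores) |>
    mutate(x = fpr, y = tpr, panel = sprintf("ROC (AUC %.3f)",
                                             roc_auc(labels, scores)))
  pr <- pr_points(labels, scores) |>
    mutate(x = recall, y = precision,
           panel = sprintf("PR (AUPR %.3f)", pr_auc(labels, scores)))
  dat <- bind_rows(roc[c("x", "y", "panel")], pr[c("x", "y", "panel")])
  ggplot(dat, aes(x = x, y = y)) +
    geom_step() +
    facet_wrap(~panel) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

utils::globalVariables(c("fpr", "tpr", "precision", "recall", "panel",
                         "x", "y"))
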