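## broom-style accessors --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained shock-advisory fit
#'
#' One row per training run with its seed, epochs actually run, best
#' validation loss and whether it was the selected (minimum-loss) run.
#'
#' @param x A `cnn_cpr_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cnn_cpr_fit <- function(x, ...) {
  x$runs
}

#' One-row summary of a trained shock-advisory fit
#'
#' @param x A `cnn_cpr_fit`.
#' @param ... Unused.
#' @return Tibble with the analysis duration, parameter count, best
#'   validation loss, validation ROC-AUC, and the operating point
#'   (threshold, Se, Sp).
#' @export
glance.cnn_cpr_fit <- function(x, ...) {
  auc <- roc_curve(x$validation$score, x$validation$category)$auc
  tibble::tibble(
    D = x$D,
    n_params = x$model$n_params,
    runs = nrow(x$runs),
    best_val_loss = min(x$runs$best_val_loss),
    val_auc = auc,
    threshold = x$operating_point$threshold,
    val_se = x$operating_point$se,
    val_sp = x$operating_point$sp
  )
}

#' Layer table of the network
#'
#' @param x A `cnn_cpr` model.
#' @param ... Unused.
#' @return Tibble with one row per weight tensor.
#' @export
tidy.cnn_cpr <- function(x, ...) {
  n_l <- length(x$kernels)
  chans <- c(1L, x$filters)
  tibble::tibble(
    layer = c(sprintf("conv%d", seq_len(n_l)), "dense"),
    kernel = c(x$kernels, NA),
    in_channels = c(chans[seq_len(n_l)], x$filters[n_l]),
    out_channels = c(x$filters, 1L),
    n_weights = c(x$kernels * chans[seq_len(n_l)] * x$filters,
                  x$filters[n_l]),
    n_biases = c(x$filters, 1L)
  )
}

#' @export
print.cnn_cpr_fit <- function(x, ...) {
  cat(sprintf("<cnn_cpr_fit> D = %g s, %d run(s), best val loss %.5f\n",
              x$D, nrow(x$runs), min(x$runs$best_val_loss)))
  print(x$operating_point)
  invisible(x)
}
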