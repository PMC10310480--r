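#' Shannon entropy of an intensity histogram
#'
#' \deqn{H = -\sum_b p_b \log_2 p_b} over the occupied equal-width bins of
#' the image histogram, in bits. Depends only on the histogram, so it is
#' invariant under pixel permutation; a constant image has zero entropy.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param n_bins Number of histogram bins.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(matrix(c(0, 0, 0.5, 1), 2, 2))   # 1.5 bits
#' @export
shannon_entropy <- function(image, n_bins = 256L) {
  check_image(image)
  if (n_bins < 2 || n_bins != round(n_bins)) {
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  }
  p <- tabulate(quantize_bins(image, as.integer(n_bins)),
                nbins = as.integer(n_bins)) / length(image)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Root-mean-square contrast
#'
#' Standard deviation of the pixel intensities (population form): the
#' plainest scalar measure of global contrast.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @return Non-negative double.
#' @export
rms_contrast <- function(image) {
  check_image(image)
  pixel_sd(image)
}

#' No-reference quality metric registry
#'
#' A registry mapping metric names to scoring callables plus a polarity
#' flag (`"lower_better"` or `"higher_better"`) used by [rho_sweep()] to
#' pick the best fractional order. The built-in entries are
#' histogram-based:
#'
#' * `"entropy"` — [shannon_entropy()], higher is better;
#' * `"neg_entropy"` — negated entropy, lower is better (a drop-in sweep
#'   objective with BRISQUE-style polarity);
#' * `"rms_contrast"` — [rms_contrast()], higher is better.
#'
#' Learned no-reference scores (BRISQUE, NIQE, PIQE — all lower-is-better)
#' depend on trained natural-scene-statistics models and are not
#' re-implemented here; an external implementation can be plugged in
#' through [register_metric()], and absolute scores differ between
#' implementations of those metrics.
#'
#' @return An environment of class `"metric_registry"`.
#' @export
metric_registry <- function() {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "metric_registry"
  register_metric(reg, "entropy",
                  function(img) shannon_entropy(img, 256L),
                  polarity = "higher_better")
  register_metric(reg, "neg_entropy",
                  function(img) -shannon_entropy(img, 256L),
                  polarity = "lower_better")
  register_metric(reg, "rms_contrast", rms_contrast,
                  polarity = "higher_better")
  reg
}

#' Register a quality metric
#'
#' @param registry A `"metric_registry"`.
#' @param name Unique metric name.
#' @param fn Callable mapping an image matrix to a single finite score.
#' @param polarity `"lower_better"` or `"higher_better"`.
#' @return The registry, invisibly.
#' @export
register_metric <- function(registry, name, fn,
                            polarity = c("lower_better", "higher_better")) {
  stopifnot(inherits(registry, "metric_registry"),
            is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  polarity <- match.arg(polarity)
  assign(name, list(fn = fn, polarity = polarity), envir = registry)
  invisible(registry)
}

#' Score an image with a registered metric
#'
#' Dispatches to the named metric; an unknown name is a configuration
#' error listing the registered metrics. A failure inside an externally
#' registered metric is wrapped with the metric name rather than
#' propagated bare, so a sweep can report which adapter broke.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param metric_name Name of a registered metric.
#' @param registry Registry to look the metric up in.
#' @return The score, with attribute `polarity`.
#' @export
score_image <- function(image, metric_name, registry = metric_registry()) {
  check_image(image)
  entry <- registry_lookup(registry, metric_name)
  value <- tryCatch(entry$fn(image), error = function(e) {
    stop(sprintf("metric '%s' failed: %s", metric_name,
                 conditionMessage(e)), call. = FALSE)
  })
  structure(value, polarity = entry$polarity)
}

#' @export
print.metric_registry <- function(x, ...) {
  nms <- sort(ls(x))
  pol <- vapply(nms, function(n) get(n, envir = x)$polarity, character(1))
  cat("registered metrics:\n")
  cat(sprintf("  %-14s %s\n", nms, pol), sep = "")
  invisible(x)
}

registry_lookup <- function(registry, name) {
  stopifnot(inherits(registry, "metric_registry"))
  if (!is.character(name) || length(name) != 1L ||
      !exists(name, envir = registry, inherits = FALSE)) {
    stop(sprintf("unknown metric '%s'; registered metrics: %s",
                 as.character(name)[1],
                 paste(sort(ls(registry)), collapse = ", ")),
         call. = FALSE)
  }
  get(name, envir = registry, inherits = FALSE)
}
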